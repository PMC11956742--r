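# naptp

Six-frame non-exon proteogenomic databases and verification of nascent
pioneer translation products (Na-PTPs).

## The problem

Ribosome profiling of polysome fractions combined with tandem mass
spectrometry can capture nascent peptides that do not come from any
annotated protein: products of translation of intronic sequence, in
alternative reading frames, on either the sense or the antisense strand
of a host gene.  Such nascent pioneer translation products (Na-PTPs)
are a source of MHC class I peptide substrates, so finding them — and
proving their genomic origin — matters for immunology and neoantigen
discovery.

An MS search engine can only match spectra against a database it is
given.  `naptp` builds that database and then adjudicates the matches:

1. **Sample-specific genome** — called variants (SNPs and indels,
   retained when the caller p-value is below 0.01) are incorporated
   into the reference, with a bidirectional coordinate liftover back to
   reference positions.
2. **Non-exon extraction** — for every gene, the gaps of the gene span
   left after removing the union of all exons of all its transcripts
   (intronic sequence; intergenic DNA is deliberately excluded).
3. **Six-frame translation** — every region is translated in frames
   `f0,f1,f2` (forward strand) and `r0,r1,r2` (reverse complement),
   split into stop-delimited segments, deduplicated, and written as a
   FASTA database (SFDB) with genomic provenance.
4. **Verification funnel** — each candidate peptide from the MS search
   is (a) excluded if it is a substring of the annotated proteome
   (I/L treated as equivalent, since their masses are identical),
   (b) located exhaustively in the six-frame space of the whole sample
   genome, and (c) classified: `known_protein`, `absent`,
   `multiple_occurrence`, `exonic`, or `unique_nonexon` — the Na-PTP
   verdict.  Unique hits are annotated with host gene, sense/antisense
   orientation, in-frame flanking residues (`X.PEPTIDE.Y`), tryptic
   termini, and the minimal product length: the peptide plus the
   residues to the first downstream in-frame stop codon.
5. **Epitope windows** — all 8–14-mer subsequences of each flanked
   Na-PTP are enumerated and exported as input for an external MHC-I
   binding predictor.

A deterministic fixture generator (`simulate_scenario()`) builds
synthetic genomes with planted peptide cassettes and a ground-truth
manifest, so the entire pipeline is testable offline.

## Worked example

```r
library(naptp)

dir <- tempfile()
sim <- simulate_scenario("funnel", seed = 7, out_dir = dir)

g     <- read_genome(sim$paths$genome)
v     <- read_variants(sim$paths$variants, p_threshold = 0.01)
s     <- apply_variants(g, v)
genes <- read_annotation(sim$paths$gtf)
ver   <- verify_candidates(read.delim(sim$paths$peptides)$sequence,
                           s, genes, proteome = sim$paths$proteome)
print(ver)
#> Na-PTP verification funnel:
#>   candidates           6
#>   ambiguous_aa         0
#>   known_protein        1
#>   absent               1
#>   multiple_occurrence  1
#>   exonic               1
#>   unique_nonexon       2
```

Six candidates went in; one was already in the proteome, one was
nowhere in the genome, one occurred twice, one overlapped an exon, and
two were verified as unique non-exonic Na-PTPs:

```r
ann <- ver$annotations
ann[ann$verdict == "unique_nonexon",
    c("peptide", "gene", "orientation", "frame", "ref_start", "ref_end",
      "flanked", "minimal_length")]
#>     peptide gene orientation frame ref_start ref_end        flanked minimal_length
#>  MVDPETRAYK   g1       sense    f1      6514    6543 R.MVDPETRAYK.A             22
#>  WHDYNQCTVF   g4   antisense    r2     16071   16100 F.WHDYNQCTVF.A             30
```

`MVDPETRAYK` reads in the sense direction of gene `g1`, is preceded by
an arginine (a tryptic N-terminus) and would run for 22 residues before
its first in-frame stop; `WHDYNQCTVF` comes from the strand opposite to
gene `g4`.  Both loci are reported in reference coordinates via the
liftover, even though indel variants shifted their positions in the
edited genome.  MHC-I candidate windows follow directly:

```r
w <- enumerate_windows(flank_and_measure("R.MVDPETRAYK.A"))
nrow(w)        # 15 windows of length 8..12 over the 12-residue flanked string
head(w, 3)
#>    window k offset
#>  RMVDPETR 8      0
#>  MVDPETRA 8      1
#>  VDPETRAY 8      2
export_predictor_input(w, "windows.peplist")
```

The same pipeline is available as a command-line tool after install
(`exec/naptp`): `naptp simulate`, `naptp build-genome`,
`naptp build-sfdb`, `naptp verify`, `naptp windows`, `naptp run-all`.

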