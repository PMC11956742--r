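---
title: "Finding intron-derived translation products: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding intron-derived translation products: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(naptp)
```

## The procedure

`naptp` implements a proteogenomic discovery-and-verification pipeline
for nascent peptides translated from non-exonic sequence.  The model of
the data is deliberately simple: a genome is a set of chromosomes over
`A,C,G,T,N`; a gene is a strand plus the union of the exons of all of
its transcripts; everything inside a gene span that is not exonic in
*any* isoform is "non-exon" (intronic); translation follows the
standard nuclear codon table in six reading frames, three per strand,
and a translation product is a maximal stop-delimited segment.  A
candidate peptide observed by mass spectrometry is *verified* as a
Na-PTP when, after excluding matches to the annotated proteome, it has
exactly one six-frame occurrence in the whole sample genome and that
occurrence overlaps no exon.

Key assumptions worth stating explicitly:

* **One edited haplotype.** Variants passing the significance filter
  (`p_value < 0.01` at read time) are applied as if homozygous.
  Overlapping calls are resolved in favour of the smallest p-value
  (ties: first in chromosome order); a call whose reference allele does
  not match the genome is skipped with a recorded reason rather than
  aborting the run, which tolerates annotation/genome version drift.
* **Exon union, not per-transcript introns.** A base is non-exonic
  only if no isoform exons it.  This is conservative: it can only
  shrink the database, never let an exonic sequence masquerade as
  intronic.
* **Intergenic sequence is out of scope.** The database covers only
  gene bodies; the verification scan, however, covers the entire
  genome, so a candidate that also matches outside a gene is still
  caught as a multiple occurrence.
* **Coordinates.** 1-based inclusive everywhere, matching GTF and
  genome browsers.  Occurrences are found on the sample (edited)
  genome but reported in reference coordinates through the liftover;
  hits inside inserted (sample-only) sequence get gap-flagged
  coordinates anchored at the nearest flanking reference position.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `p_threshold` | 0.01 | variant caller significance cutoff, applied when reading VCF/VarScan2 output |
| `min_len` | 7 aa | shortest segment kept in the SFDB; one below the shortest MS-identified core we expect (8 aa), leaving headroom for semi-tryptic matches |
| `kmin`, `kmax` | 8, 14 | MHC-I window lengths enumerated over flanked Na-PTPs |
| `il_proteome` | TRUE | I/L equivalence when excluding candidates against the proteome — isobaric residues are indistinguishable to MS |
| `il_genome` | FALSE | I/L equivalence in the genomic occurrence scan; off by default so "single unique occurrence" keeps its exact-match meaning |
| `no_cut_before_P` | FALSE | veto tryptic cleavage before proline; off to match a semi-tryptic search |
| `minlen_from_upstream_stop` | FALSE | alternative minimal-length convention (see below) |

## Numerical and convention choices

**Minimal product length.** Translation termination of pioneer
products uses canonical stop codons, but the initiation site cannot be
predicted.  The default definition is therefore the mathematically
minimal product containing the evidence: the detected peptide plus
every residue up to the first downstream in-frame stop.  When no stop
occurs before the sequence boundary the value is flagged as a lower
bound.  A second convention — measuring from the residue after the
first *upstream* stop, i.e. the whole open segment — is available via
`minlen_from_upstream_stop`; with in-paper loci unavailable, neither
convention can be singled out by the published range (20–245 aa), so
the minimal one is the default.

**Flanks.** The residues immediately up/downstream of a verified
peptide, in its frame, are reported in dot notation (`R.PEPTIDE.A`).
A sequence edge *or an adjacent stop codon* yields `-`: a stop is not a
residue, and reporting it as a flank would corrupt the reported-length
convention (core + number of real flanks) used for the published
tables.

**Ambiguity.** `N` bases are accepted; any codon containing `N`
translates to `X`, and `X` never matches a candidate (candidates are
restricted to the 20-letter alphabet).  Other IUPAC codes are rejected
unless `read_genome(lenient = TRUE)` collapses them to `N`.  This is
conservative for soft-masked or low-quality reference stretches.

**Deduplication.** SFDB records are keyed by exact peptide string;
I and L are *not* merged in the database so that provenance stays
unambiguous.  With `per_frame = TRUE` deduplication happens within each
frame label, mirroring a search in which each reading frame is queried
separately.

**Overlap ties, host genes.** Among overlapping variants the smallest
p-value wins deterministically.  When several genes' spans contain a
unique occurrence, the gene with the smallest span is reported as the
host (the most specific annotation); all hosts are listed.

## The synthetic scenes

`simulate_scenario()` generates the package's entire test world: two
100 kb chromosomes (GC 0.41, the human average), five genes with
realistic multi-exon layouts (one with two isoforms so the exon-union
rule is exercised), planted peptide cassettes, 26–40 variants, a decoy
proteome and a candidate list.  A cassette is
`stop | flank | peptide | pad | stop`, back-translated with a
deterministic lexicographic codon choice that re-rolls on accidental
extra occurrences, written sense or antisense at a position with a
prescribed reading-frame offset.  By construction the ground truth is
exact: the minimal length is `|peptide| + pad`, the flanks are the
written residues, and the verdict is fixed by where and how often the
cassette was planted (`unique_nonexon`, `multiple_occurrence`,
`exonic`, `known_protein` via the decoy proteome, or `absent`).

Variants are drawn *outside* gene spans (±100 bp).  This is the one
deliberate departure from realism: real intronic SNPs could touch a
real Na-PTP locus.  Keeping cassettes variant-free makes the manifest
exact while still exercising the coordinate machinery, because
intergenic indels shift every downstream gene in sample coordinates —
manifest frame labels are restated in sample coordinates and loci are
compared in reference coordinates through the liftover.  Consequently a
green end-to-end test establishes that the pipeline recovers planted
truth through variant editing, extraction, translation and
classification; it does not establish robustness to variants inside the
peptide codons themselves, nor anything about real MS noise, spectral
FDR, or alignment artefacts (all upstream of this toolkit's scope).

The independent checks are layered: a hand-written codon table and
per-codon translator validate `translate_six_frames`; a naive
genome-wide scanner validates `locate_occurrences`; a right-to-left
string splicer (`naive_apply_variants`) validates `apply_variants` and
its coordinate map; and the generator's manifest validates the funnel
end to end.

## Known limitations

* Single haplotype; no phasing, no structural variants.
* Non-exon means intronic only; intergenic translation is invisible to
  the database (though not to the verification scan).
* The proteome exclusion is exact-substring (with optional I/L
  folding), not a similarity search; one-mismatch homologs are not
  excluded.
* Binding prediction is out of scope: the package exports predictor
  input and can rank nothing by affinity.
* GTF errors are reported per exon feature index, not file line
  number.
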