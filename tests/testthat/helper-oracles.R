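# Independent brute-force oracles: a hand-written codon table and
# per-codon translators/scanners that share no code with the package's
# Biostrings-backed implementation.

ORACLE_CODONS <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# codon-by-codon translation of one frame; N-containing codons -> X
oracle_translate <- function(seq, offset = 0) {
  chars <- strsplit(seq, "")[[1]]
  out <- character(0)
  i <- offset + 1
  while (i + 2 <= length(chars)) {
    codon <- paste(chars[i:(i + 2)], collapse = "")
    out <- c(out, if (grepl("N", codon)) "X" else ORACLE_CODONS[[codon]])
    i <- i + 3
  }
  paste(out, collapse = "")
}

# frame label -> translation string for all six frames
oracle_frames <- function(seq) {
  rc <- oracle_revcomp(seq)
  list(f0 = oracle_translate(seq, 0), f1 = oracle_translate(seq, 1),
       f2 = oracle_translate(seq, 2), r0 = oracle_translate(rc, 0),
       r1 = oracle_translate(rc, 1), r2 = oracle_translate(rc, 2))
}

# maximal stop-delimited segments of one frame translation (peptides only)
oracle_segments <- function(aa) {
  segs <- strsplit(aa, "*", fixed = TRUE)[[1]]
  segs[nzchar(segs)]
}

# naive genome-wide scan: every chrom, every frame, every aa position
oracle_scan <- function(peptide, genome) {
  hits <- list()
  plen <- nchar(peptide)
  for (ch in names(genome)) {
    frames <- oracle_frames(genome[[ch]])
    for (lab in names(frames)) {
      aa <- frames[[lab]]
      n <- nchar(aa)
      if (n < plen) next
      for (i in seq_len(n - plen + 1)) {
        if (substr(aa, i, i + plen - 1) == peptide)
          hits[[length(hits) + 1]] <- data.frame(
            chrom = ch, frame = lab, aa_index = i,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(chrom = character(), frame = character(),
                      aa_index = integer(), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

random_dna <- function(n, with_n = FALSE) {
  alph <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(alph, n, replace = TRUE,
               prob = if (with_n) c(rep(0.24, 4), 0.04) else NULL),
        collapse = "")
}
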