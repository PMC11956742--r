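#' Frame labels
#'
#' The six reading frames: `f0,f1,f2` read the forward strand with
#' offsets 0/1/2 from the sequence start; `r0,r1,r2` read the reverse
#' complement with offsets 0/1/2 from *its* start.
#' @export
FRAME_LABELS <- c("f0", "f1", "f2", "r0", "r1", "r2")

# translate a nucleotide string (>= 3 nt, trimmed to codon multiple) into
# an amino-acid string; stops are '*', codons containing N become 'X'
.translate_nt <- function(seq) {
  L <- nchar(seq)
  ncod <- L %/% 3L
  if (ncod == 0L) return("")
  s <- Biostrings::DNAString(substr(seq, 1L, 3L * ncod))
  # no.init.codon: never promote an alternative initiator (TTG/CTG) to M
  as.character(Biostrings::translate(s, if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

# full-frame translation strings (stops kept) for one sequence;
# returns list(label -> list(aa, offset, strand))
.frame_translations <- function(seq) {
  L <- nchar(seq)
  rc <- if (L) reverse_complement(seq) else ""
  out <- vector("list", 6L)
  names(out) <- FRAME_LABELS
  for (o in 0:2) {
    out[[paste0("f", o)]] <- list(
      aa = if (L - o >= 3L) .translate_nt(substr(seq, o + 1L, L)) else "",
      offset = o, strand = "+")
    out[[paste0("r", o)]] <- list(
      aa = if (L - o >= 3L) .translate_nt(substr(rc, o + 1L, L)) else "",
      offset = o, strand = "-")
  }
  out
}

# genomic (sequence-local, 1-based) span of amino acids [i, i+len-1] of a
# frame translation; for reverse frames positions are on the forward axis
.aa_span <- function(L, offset, strand, i, len) {
  a <- offset + 3L * (i - 1L) + 1L       # frame-local nt start
  b <- a + 3L * len - 1L                 # frame-local nt end
  if (strand == "+") c(start = a, end = b)
  else c(start = L - b + 1L, end = L - a + 1L)
}

#' Translate a region in all six reading frames
#'
#' Translates `region_seq` with the standard nuclear codon table in the
#' three forward and three reverse-complement frames, splitting each
#' frame's translation into maximal stop-delimited peptide segments.
#' Stop codons (`TAA`, `TAG`, `TGA`) terminate a segment and are not
#' emitted; codons containing `N` translate to `X`; trailing bases
#' short of a full codon are dropped.
#'
#' @param region_seq nucleotide string over `A,C,G,T,N`.
#' @return a named list (one element per frame label) of data.frames
#'   with columns `peptide`, `aa_offset` (0-based offset of the segment
#'   within the frame's translation), `start`, `end` (1-based span of
#'   the segment's codons on the forward axis of `region_seq`) and
#'   `has_upstream_stop`/`has_downstream_stop` (whether the segment is
#'   delimited by a stop codon rather than the sequence boundary).
#' @export
translate_six_frames <- function(region_seq) {
  stopifnot(is.character(region_seq), length(region_seq) == 1L)
  if (grepl("[^ACGTN]", region_seq))
    stop("translate_six_frames: invalid character in sequence")
  L <- nchar(region_seq)
  tr <- .frame_translations(region_seq)
  lapply(tr, function(fr) .segment_frame(fr$aa, L, fr$offset, fr$strand))
}

.empty_segments <- function()
  data.frame(peptide = character(), aa_offset = integer(),
             start = integer(), end = integer(),
             has_upstream_stop = logical(), has_downstream_stop = logical(),
             stringsAsFactors = FALSE)

# split one frame translation (with '*') into maximal segments
.segment_frame <- function(aa, L, offset, strand) {
  n <- nchar(aa)
  if (n == 0L) return(.empty_segments())
  stops <- c(0L, which(strsplit(aa, "")[[1L]] == "*"), n + 1L)
  segs <- list()
  for (k in seq_len(length(stops) - 1L)) {
    from <- stops[k] + 1L
    to <- stops[k + 1L] - 1L
    if (to < from) next
    sp <- .aa_span(L, offset, strand, from, to - from + 1L)
    segs[[length(segs) + 1L]] <- data.frame(
      peptide = substr(aa, from, to), aa_offset = from - 1L,
      start = sp[["start"]], end = sp[["end"]],
      has_upstream_stop = stops[k] > 0L,
      has_downstream_stop = stops[k + 1L] <= n,
      stringsAsFactors = FALSE)
  }
  if (!length(segs)) return(.empty_segments())
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

# cached six-frame translations of every chromosome of a genome;
# reused by the occurrence scanner and the annotator
.six_frame_index <- function(genome) {
  lapply(unclass(genome), .frame_translations)
}

# all (possibly overlapping) 1-based match start positions of `sub` in `s`
.find_all <- function(sub, s) {
  out <- integer(0)
  from <- 1L
  repeat {
    i <- regexpr(sub, substr(s, from, nchar(s)), fixed = TRUE)
    if (i < 0L) break
    hit <- from + as.integer(i) - 1L
    out <- c(out, hit)
    from <- hit + 1L
  }
  out
}
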