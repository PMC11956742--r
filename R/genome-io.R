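#' @importFrom Biostrings readBStringSet writeXStringSet DNAString
#'   DNAStringSet AAStringSet reverseComplement translate subseq
#' @importFrom IRanges IRanges
NULL

# nucleotide alphabet accepted everywhere downstream; ambiguity codes other
# than N are rejected (strict) or collapsed to N (lenient)
.DNA_ALPHABET <- c("A", "C", "G", "T", "N")
.IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Read a genome FASTA into a named nucleotide vector
#'
#' Loads every record of a FASTA file, uppercases the sequence and
#' validates it against the strict alphabet `A,C,G,T,N`.  All
#' coordinates in this package are 1-based inclusive, matching GTF and
#' genome-browser conventions.
#'
#' @param path path to a FASTA file.
#' @param lenient if `TRUE`, IUPAC ambiguity codes other than `N` are
#'   replaced by `N` instead of raising an error.
#' @return a named character vector (one uppercase sequence per
#'   chromosome), of class `GenomeSequence`.
#' @export
read_genome <- function(path, lenient = FALSE) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate chromosome id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0L)) stop("empty sequence record in ", path)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    if (lenient)
      s <- chartr(paste(.IUPAC_AMBIG, collapse = ""),
                  strrep("N", length(.IUPAC_AMBIG)), s)
    bad <- regexpr("[^ACGTN]", s)
    if (bad > 0L)
      stop("invalid character '", substr(s, bad, bad), "' in sequence '",
           ids[i], "' at position ", bad)
    seqs[[i]] <- s
  }
  structure(seqs, class = "GenomeSequence")
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path; lines are wrapped at `width` columns.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 60L) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' Length preserving and an involution; `N` maps to `N`.  This is the
#' strand operation behind the three reverse reading frames
#' (`r0`,`r1`,`r2`).
#'
#' @param seq a single nucleotide string over `A,C,G,T,N`.
#' @return the reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return("")
  if (grepl("[^ACGTN]", seq))
    stop("reverse_complement: invalid character in sequence")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' @export
print.GenomeSequence <- function(x, ...) {
  cat("GenomeSequence with", length(x), "sequence(s)\n")
  for (nm in names(x))
    cat(sprintf("  %s: %s bp\n", nm, format(nchar(x[[nm]]), big.mark = ",")))
  invisible(x)
}

# internal: substring slice of one chromosome, 1-based inclusive
.genome_slice <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  substr(genome[[chrom]], start, end)
}
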