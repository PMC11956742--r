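#' Extract non-exon regions per gene
#'
#' For every gene, the non-exon regions are the gaps of the gene span
#' after removing the union of all exons of all its transcripts
#' (intronic gaps).  Intergenic sequence is never extracted: the
#' database deliberately covers only the gene-encoding fraction of the
#' genome.  When a coordinate `map` is supplied, the (reference
#' coordinate) gaps are lifted to sample-genome coordinates, clipping
#' edges that were deleted from the sample.
#'
#' @param genes a `GeneSet` from [read_annotation()].
#' @param map optional `CoordinateMap`; when given, output coordinates
#'   are sample-genome positions.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   and `region_index` (1-based index of the region within its gene).
#' @export
extract_nonexon_regions <- function(genes, map = NULL) {
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      region_index = integer(), stringsAsFactors = FALSE)
  rows <- lapply(genes, function(g) {
    span <- IRanges::IRanges(g$start, g$end)
    gaps <- IRanges::setdiff(span, .gene_exon_union(g))
    if (!length(gaps)) return(NULL)
    st <- BiocGenerics::start(gaps); en <- BiocGenerics::end(gaps)
    if (!is.null(map)) {
      lifted <- lapply(seq_along(st), function(i)
        .lift_interval_to_sample(map, g$chrom, st[i], en[i]))
      keep <- !vapply(lifted, is.null, TRUE)
      lifted <- lifted[keep]
      if (!length(lifted)) return(NULL)
      st <- vapply(lifted, `[[`, 0L, "start")
      en <- vapply(lifted, `[[`, 0L, "end")
    }
    data.frame(gene_id = g$gene_id, chrom = g$chrom, start = st, end = en,
               region_index = seq_along(st), stringsAsFactors = FALSE)
  })
  out <- .rbind_df(rows, empty)
  out
}

#' Build the six-frame non-exon database (SFDB)
#'
#' Translates every non-exon region in all six reading frames, keeps
#' stop-delimited segments of at least `min_len` residues, and
#' collapses exact-duplicate peptides into single records that
#' accumulate all genomic provenance.  Isoleucine and leucine are *not*
#' merged here: the database keys are exact strings so provenance stays
#' unambiguous (I/L-tolerant matching happens at verification time).
#'
#' @param regions data.frame from [extract_nonexon_regions()] in
#'   sample-genome coordinates.
#' @param sample a `SampleGenome` (or a bare `GenomeSequence`).
#' @param min_len minimal segment length in amino acids (default 7,
#'   one below the shortest reported MS-identified core of 8).
#' @param per_frame deduplicate and key records per frame label
#'   (mirrors searching each reading frame separately) instead of
#'   globally.
#' @return an object of class `Sfdb`: list with `records` (one row per
#'   unique peptide: `peptide`, first-locus `gene_id`, `chrom`,
#'   `start`, `end`, `frame`, and `n_extra` additional loci),
#'   `provenance` (all loci incl. `boundary_truncated`) and the
#'   `per_frame` flag.
#' @export
build_sfdb <- function(regions, sample, min_len = 7L, per_frame = FALSE) {
  genome <- if (inherits(sample, "SampleGenome")) sample$genome else sample
  prov <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    seqs <- .genome_slice(genome, r$chrom, r$start, r$end)
    frames <- translate_six_frames(seqs)
    for (lab in FRAME_LABELS) {
      seg <- frames[[lab]]
      seg <- seg[nchar(seg$peptide) >= min_len, , drop = FALSE]
      if (!nrow(seg)) next
      prov[[length(prov) + 1L]] <- data.frame(
        peptide = seg$peptide, gene_id = r$gene_id, chrom = r$chrom,
        start = r$start + seg$start - 1L, end = r$start + seg$end - 1L,
        frame = lab,
        boundary_truncated = !(seg$has_upstream_stop &
                                 seg$has_downstream_stop),
        stringsAsFactors = FALSE)
    }
  }
  prov <- .rbind_df(prov, data.frame(
    peptide = character(), gene_id = character(), chrom = character(),
    start = integer(), end = integer(), frame = character(),
    boundary_truncated = logical(), stringsAsFactors = FALSE))
  key <- if (per_frame) paste(prov$frame, prov$peptide) else prov$peptide
  first <- !duplicated(key)
  records <- prov[first, c("peptide", "gene_id", "chrom", "start", "end",
                           "frame"), drop = FALSE]
  records$n_extra <- as.integer(table(key)[key[first]]) - 1L
  rownames(records) <- NULL
  structure(list(records = records, provenance = prov,
                 per_frame = per_frame), class = "Sfdb")
}

#' Write an SFDB to FASTA (+ provenance sidecar)
#'
#' One record per unique peptide with header grammar
#' `>NAPTP|<gene>|<chrom>:<start>-<end>|<frame>|<n_extra_loci>`
#' (first locus in the header; the full provenance goes to a sidecar
#' TSV).
#'
#' @param sfdb an `Sfdb`.
#' @param path output FASTA path.
#' @param sidecar provenance TSV path (default `<path>.provenance.tsv`).
#' @return `path`, invisibly.
#' @export
write_sfdb_fasta <- function(sfdb, path,
                             sidecar = paste0(path, ".provenance.tsv")) {
  r <- sfdb$records
  headers <- sprintf("NAPTP|%s|%s:%d-%d|%s|%d", r$gene_id, r$chrom,
                     r$start, r$end, r$frame, r$n_extra)
  set <- Biostrings::AAStringSet(r$peptide)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 60L)
  utils::write.table(sfdb$provenance, sidecar, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back an SFDB FASTA written by [write_sfdb_fasta()]
#'
#' @param path FASTA path.
#' @return data.frame with the peptides and their first-locus
#'   provenance parsed from the headers.
#' @export
read_sfdb_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (!length(set))
    return(data.frame(peptide = character(), gene_id = character(),
                      chrom = character(), start = integer(),
                      end = integer(), frame = character(),
                      n_extra = integer(), stringsAsFactors = FALSE))
  parts <- strsplit(names(set), "|", fixed = TRUE)
  if (any(vapply(parts, length, 0L) != 5L) ||
      any(vapply(parts, `[[`, "", 1L) != "NAPTP"))
    stop("not an SFDB FASTA: malformed header in ", path)
  locus <- vapply(parts, `[[`, "", 3L)
  m <- regmatches(locus, regexec("^(.+):([0-9]+)-([0-9]+)$", locus))
  data.frame(
    peptide = as.character(set),
    gene_id = vapply(parts, `[[`, "", 2L),
    chrom = vapply(m, `[[`, "", 2L),
    start = as.integer(vapply(m, `[[`, "", 3L)),
    end = as.integer(vapply(m, `[[`, "", 4L)),
    frame = vapply(parts, `[[`, "", 4L),
    n_extra = as.integer(vapply(parts, `[[`, "", 5L)),
    stringsAsFactors = FALSE)
}

#' @export
print.Sfdb <- function(x, ...) {
  cat("Sfdb:", nrow(x$records), "unique peptide(s),",
      nrow(x$provenance), "loci",
      if (x$per_frame) "(per-frame keys)" else "", "\n")
  invisible(x)
}
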