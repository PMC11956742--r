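#' Read gene models from a GTF annotation
#'
#' Imports exon features from an ENSEMBL-style GTF and groups them into
#' transcript and gene models.  Native GTF coordinates (1-based
#' inclusive) are kept unchanged; all feature types other than `exon`
#' are ignored.
#'
#' @param path path to a GTF file whose exon features carry `gene_id`
#'   and `transcript_id` attributes.
#' @return an object of class `GeneSet`: a named list of `GeneModel`
#'   objects.  Each `GeneModel` is a list with fields `gene_id`,
#'   `chrom`, `strand`, `start`, `end` (the gene span over all
#'   transcripts) and `transcripts`, itself a named list of
#'   `transcript_id` -> two-column `exons` matrix (start, end; sorted,
#'   non-overlapping).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- !is.na(md$type) & md$type == "exon"
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) return(structure(list(), class = "GeneSet"))
  gid <- as.character(md$gene_id)
  tid <- if ("transcript_id" %in% colnames(md))
    as.character(md$transcript_id) else rep(NA_character_, length(gr))
  bad <- which(is.na(gid) | gid == "" | is.na(tid) | tid == "")
  if (length(bad))
    stop("exon feature #", bad[1L],
         " lacks a gene_id/transcript_id attribute")
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*"))
    stop("exon feature #", which(strand == "*")[1L],
         " has no strand ('.'); stranded exons are required")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
    strand = strand, gene_id = gid, transcript_id = tid,
    stringsAsFactors = FALSE)
  genes <- lapply(split(df, df$gene_id), function(g) {
    if (length(unique(g$strand)) != 1L)
      stop("strand conflict within gene ", g$gene_id[1L])
    if (length(unique(g$chrom)) != 1L)
      stop("chromosome conflict within gene ", g$gene_id[1L])
    txs <- lapply(split(g, g$transcript_id), function(t) {
      o <- order(t$start)
      ex <- cbind(start = t$start[o], end = t$end[o])
      if (any(ex[, "start"] > ex[, "end"]))
        stop("exon with start > end in transcript ", t$transcript_id[1L])
      if (nrow(ex) > 1L && any(ex[-1L, "start"] <= ex[-nrow(ex), "end"]))
        stop("overlapping exons in transcript ", t$transcript_id[1L])
      list(transcript_id = t$transcript_id[1L], exons = ex)
    })
    structure(list(
      gene_id = g$gene_id[1L], chrom = g$chrom[1L], strand = g$strand[1L],
      start = min(g$start), end = max(g$end), transcripts = txs),
      class = "GeneModel")
  })
  structure(genes[order(names(genes))], class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat("GeneSet with", length(x), "gene(s)\n")
  for (g in x)
    cat(sprintf("  %s %s:%d-%d (%s), %d transcript(s)\n", g$gene_id,
                g$chrom, g$start, g$end, g$strand, length(g$transcripts)))
  invisible(x)
}

# union of all exons of all transcripts of one gene, as an IRanges
.gene_exon_union <- function(gene) {
  ex <- do.call(rbind, lapply(gene$transcripts, `[[`, "exons"))
  IRanges::reduce(IRanges::IRanges(ex[, "start"], ex[, "end"]))
}

# per-chromosome union of all exons of all genes (reference coordinates)
.exon_union_by_chrom <- function(genes) {
  chroms <- unique(vapply(genes, `[[`, "", "chrom"))
  out <- lapply(chroms, function(ch) {
    rs <- lapply(genes[vapply(genes, `[[`, "", "chrom") == ch],
                 .gene_exon_union)
    IRanges::reduce(do.call(c, unname(rs)))
  })
  names(out) <- chroms
  out
}

# gene spans as a data.frame (reference coordinates)
.gene_spans <- function(genes) {
  data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    chrom = vapply(genes, `[[`, "", "chrom"),
    strand = vapply(genes, `[[`, "", "strand"),
    start = vapply(genes, function(g) as.integer(g$start), 0L),
    end = vapply(genes, function(g) as.integer(g$end), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
}
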