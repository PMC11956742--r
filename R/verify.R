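.AA20 <- "ACDEFGHIKLMNPQRSTVWY"

# I/L-tolerant canonical form: both residues map to 'J'
.il_fold <- function(x) chartr("IL", "JJ", x)

#' Exclude candidates already present in an annotated proteome
#'
#' A candidate is excluded iff it occurs as a contiguous substring of
#' any proteome sequence.  By default isoleucine and leucine are
#' treated as equivalent during this match (their residue masses are
#' identical, so an MS search cannot distinguish them).
#'
#' @param candidates character vector of candidate peptides (uppercase).
#' @param proteome a named character vector of protein sequences, or a
#'   path to a proteome FASTA.
#' @param il_equivalent treat I and L as the same residue.
#' @return list with `retained` (character vector) and `excluded`
#'   (data.frame `peptide`, `reason`, `hit` = id of the first matching
#'   protein).
#' @export
exclude_known <- function(candidates, proteome, il_equivalent = TRUE) {
  if (is.character(proteome) && length(proteome) == 1L &&
      file.exists(proteome))
    proteome <- .read_proteome(proteome)
  if (!length(proteome)) {
    warning("empty proteome: all candidates retained")
    return(list(retained = candidates,
                excluded = data.frame(peptide = character(),
                                      reason = character(),
                                      hit = character(),
                                      stringsAsFactors = FALSE)))
  }
  prot <- toupper(proteome)
  if (il_equivalent) prot <- .il_fold(prot)
  hits <- vapply(candidates, function(p) {
    q <- if (il_equivalent) .il_fold(p) else p
    i <- which(vapply(prot, function(s) grepl(q, s, fixed = TRUE), TRUE))[1L]
    if (is.na(i)) NA_character_ else names(prot)[i]
  }, "")
  excl <- !is.na(hits)
  list(retained = candidates[!excl],
       excluded = data.frame(peptide = candidates[excl],
                             reason = rep("known_protein", sum(excl)),
                             hit = unname(hits[excl]),
                             stringsAsFactors = FALSE))
}

.read_proteome <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Locate all six-frame genomic occurrences of a peptide
#'
#' Exhaustively scans all six reading frames of every chromosome of the
#' sample genome.  A hit is reported with its frame label, strand,
#' codon span in sample coordinates, the reference span obtained
#' through the coordinate liftover, whether any of its codons overlap
#' an annotated exon (`in_exon`), and the genes whose span contains it.
#' Matches never span a stop codon, and `X` residues (from `N`-masked
#' codons) never match.
#'
#' @param peptide candidate peptide (uppercase amino-acid string).
#' @param sample a `SampleGenome` (or bare `GenomeSequence`, in which
#'   case reference and sample coordinates coincide).
#' @param genes a `GeneSet`; exon overlap and host genes are evaluated
#'   in reference coordinates.
#' @param il_equivalent treat I and L as equivalent during the genomic
#'   match (default off: genomic verification is exact so the
#'   "single unique occurrence" semantics stay strict).
#' @param index optional precomputed internal six-frame index (reused
#'   across many peptides by [verify_candidates()]).
#' @return data.frame with one row per occurrence: `chrom`, `strand`,
#'   `frame`, `start`, `end` (sample coords), `ref_start`, `ref_end`,
#'   `ref_gap`, `in_exon`, `host_genes` (comma-separated ids).
#' @export
locate_occurrences <- function(peptide, sample, genes,
                               il_equivalent = FALSE, index = NULL) {
  stopifnot(is.character(peptide), length(peptide) == 1L,
            nchar(peptide) >= 1L)
  genome <- if (inherits(sample, "SampleGenome")) sample$genome else sample
  map <- if (inherits(sample, "SampleGenome")) sample$map else
    .identity_map(genome)
  if (is.null(index)) index <- .six_frame_index(genome)
  exons <- .exon_union_by_chrom(genes)
  spans <- .gene_spans(genes)
  len <- nchar(peptide)
  q <- if (il_equivalent) .il_fold(peptide) else peptide
  rows <- list()
  for (ch in names(index)) {
    L <- nchar(genome[[ch]])
    for (lab in FRAME_LABELS) {
      fr <- index[[ch]][[lab]]
      aa <- if (il_equivalent) .il_fold(fr$aa) else fr$aa
      for (i in .find_all(q, aa)) {
        sp <- .aa_span(L, fr$offset, fr$strand, i, len)
        lifted <- .lift_interval_to_reference(map, ch, sp[["start"]],
                                              sp[["end"]])
        ex <- exons[[ch]]
        in_exon <- !is.null(ex) && length(ex) > 0L &&
          any(BiocGenerics::start(ex) <= lifted$end &
                BiocGenerics::end(ex) >= lifted$start)
        host <- spans$gene_id[spans$chrom == ch &
                                spans$start <= lifted$start &
                                spans$end >= lifted$end]
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, strand = fr$strand, frame = lab,
          start = sp[["start"]], end = sp[["end"]],
          ref_start = lifted$start, ref_end = lifted$end,
          ref_gap = lifted$gap, in_exon = in_exon,
          host_genes = paste(host, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- .rbind_df(rows, data.frame(
    chrom = character(), strand = character(), frame = character(),
    start = integer(), end = integer(), ref_start = integer(),
    ref_end = integer(), ref_gap = logical(), in_exon = logical(),
    host_genes = character(), stringsAsFactors = FALSE))
  # consistency: re-translating every reported span must reproduce the
  # peptide under the active match policy
  for (i in seq_len(nrow(out))) {
    nt <- .genome_slice(genome, out$chrom[i], out$start[i], out$end[i])
    if (out$strand[i] == "-") nt <- reverse_complement(nt)
    tr <- .translate_nt(nt)
    ok <- if (il_equivalent) .il_fold(tr) == q else tr == peptide
    if (!ok) stop("internal error: occurrence span does not re-translate ",
                  "to the peptide")
  }
  out
}

#' Classify a candidate from its genomic occurrences
#'
#' Zero hits give `absent`; two or more give `multiple_occurrence`; a
#' single hit is `exonic` when any codon overlaps an exon, otherwise
#' `unique_nonexon`.
#'
#' @param occurrences data.frame from [locate_occurrences()].
#' @return one of `"absent"`, `"multiple_occurrence"`, `"exonic"`,
#'   `"unique_nonexon"`.
#' @export
classify_occurrences <- function(occurrences) {
  n <- nrow(occurrences)
  if (n == 0L) return("absent")
  if (n >= 2L) return("multiple_occurrence")
  if (occurrences$in_exon[1L]) "exonic" else "unique_nonexon"
}

#' Annotate a unique non-exon occurrence
#'
#' Determines the host gene (smallest span when several contain the
#' hit), the orientation of translation relative to the host gene's
#' strand (`antisense` iff they differ), the in-frame flanking residues
#' immediately up/downstream of the peptide at the locus (sequence edge
#' or adjacent stop codon gives `"-"`), the tryptic status of both
#' termini (N-terminus tryptic iff preceded by K/R; C-terminus tryptic
#' iff the peptide ends in K/R; `no_cut_before_P` vetoes a cleavage
#' followed by proline), and the minimal product length.
#'
#' @param peptide the candidate peptide.
#' @param occurrence single-row data.frame from [locate_occurrences()].
#' @param genes a `GeneSet`.
#' @param sample a `SampleGenome` or `GenomeSequence`.
#' @param index optional precomputed six-frame index.
#' @param no_cut_before_P veto tryptic cleavage before proline (default
#'   off, matching a semi-tryptic search).
#' @param minlen_from_upstream_stop measure the minimal length from the
#'   residue after the first upstream in-frame stop instead of from the
#'   peptide start.
#' @return a list of class `NaPtpAnnotation` with fields `peptide`,
#'   `verdict`, `chrom`, `strand`, `frame`, `start`, `end`,
#'   `ref_start`, `ref_end`, `gene`, `host_genes`, `orientation`,
#'   `flank_up`, `flank_down`, `flanked` (dot notation),
#'   `nterm_tryptic`, `cterm_tryptic`, `minimal_length` and
#'   `minlen_lower_bound` (TRUE when no downstream stop was found
#'   before the sequence boundary).
#' @export
annotate_occurrence <- function(peptide, occurrence, genes, sample,
                                index = NULL, no_cut_before_P = FALSE,
                                minlen_from_upstream_stop = FALSE) {
  stopifnot(nrow(occurrence) == 1L)
  genome <- if (inherits(sample, "SampleGenome")) sample$genome else sample
  if (is.null(index)) index <- .six_frame_index(genome)
  ctx <- .frame_context(peptide, occurrence, index, genome)
  host <- strsplit(occurrence$host_genes, ",", fixed = TRUE)[[1L]]
  host <- host[nzchar(host)]
  gene <- NA_character_
  orientation <- "intergenic"
  if (length(host)) {
    sp <- .gene_spans(genes)
    sp <- sp[sp$gene_id %in% host, , drop = FALSE]
    sp <- sp[order(sp$end - sp$start), , drop = FALSE]  # smallest span wins
    gene <- sp$gene_id[1L]
    orientation <- if (sp$strand[1L] == occurrence$strand) "sense"
      else "antisense"
  }
  up <- ctx$flank_up; down <- ctx$flank_down
  nterm <- up %in% c("K", "R")
  if (no_cut_before_P && substr(peptide, 1L, 1L) == "P") nterm <- FALSE
  cterm <- substr(peptide, nchar(peptide), nchar(peptide)) %in% c("K", "R")
  if (no_cut_before_P && down == "P") cterm <- FALSE
  ml <- .minimal_length(peptide, ctx, minlen_from_upstream_stop)
  structure(list(
    peptide = peptide, verdict = "unique_nonexon",
    chrom = occurrence$chrom, strand = occurrence$strand,
    frame = occurrence$frame, start = occurrence$start,
    end = occurrence$end, ref_start = occurrence$ref_start,
    ref_end = occurrence$ref_end, gene = gene,
    host_genes = occurrence$host_genes, orientation = orientation,
    flank_up = up, flank_down = down,
    flanked = paste0(up, ".", peptide, ".", down),
    nterm_tryptic = nterm, cterm_tryptic = cterm,
    minimal_length = ml$len, minlen_lower_bound = ml$lower_bound),
    class = "NaPtpAnnotation")
}

# frame-local context of an occurrence: aa index, flanks, downstream tail
.frame_context <- function(peptide, occurrence, index, genome) {
  fr <- index[[occurrence$chrom]][[occurrence$frame]]
  L <- nchar(genome[[occurrence$chrom]])
  len <- nchar(peptide)
  # recover the aa index from the genomic span
  a <- if (fr$strand == "+") occurrence$start else L - occurrence$end + 1L
  i <- (a - fr$offset - 1L) %/% 3L + 1L
  n <- nchar(fr$aa)
  ch_up <- if (i > 1L) substr(fr$aa, i - 1L, i - 1L) else "-"
  ch_dn <- if (i + len <= n) substr(fr$aa, i + len, i + len) else "-"
  list(aa = fr$aa, i = i, len = len, n = n,
       flank_up = if (ch_up == "*") "-" else ch_up,
       flank_down = if (ch_dn == "*") "-" else ch_dn)
}

#' Estimate the minimal Na-PTP length
#'
#' Walks the occurrence's reading frame downstream (in translation
#' direction) to the first in-frame stop codon; the minimal length is
#' the peptide length plus the number of residues between the peptide
#' end and that stop — the shortest product containing the detected
#' peptide and terminating at the canonical stop.  When the sequence
#' boundary is reached before a stop the value is a flagged lower
#' bound.
#'
#' @inheritParams annotate_occurrence
#' @return integer minimal length with attribute `lower_bound`.
#' @export
estimate_minimal_length <- function(peptide, occurrence, sample,
                                    index = NULL,
                                    minlen_from_upstream_stop = FALSE) {
  genome <- if (inherits(sample, "SampleGenome")) sample$genome else sample
  if (is.null(index)) index <- .six_frame_index(genome)
  ctx <- .frame_context(peptide, occurrence, index, genome)
  ml <- .minimal_length(peptide, ctx, minlen_from_upstream_stop)
  structure(ml$len, lower_bound = ml$lower_bound)
}

.minimal_length <- function(peptide, ctx, from_upstream_stop) {
  aa_vec <- strsplit(ctx$aa, "")[[1L]]
  after <- ctx$i + ctx$len  # first residue index after the peptide
  down_stops <- which(aa_vec == "*" & seq_along(aa_vec) >= after)
  lower_bound <- !length(down_stops)
  stop_at <- if (lower_bound) ctx$n + 1L else down_stops[1L]
  start_at <- ctx$i
  if (from_upstream_stop) {
    up_stops <- which(aa_vec == "*" & seq_along(aa_vec) < ctx$i)
    start_at <- if (length(up_stops)) max(up_stops) + 1L else 1L
  }
  list(len = stop_at - start_at, lower_bound = lower_bound)
}

#' Run the full verification funnel over a candidate list
#'
#' Validates the candidates, excludes those present in the annotated
#' proteome, locates every survivor in the six-frame space of the
#' sample genome, classifies it, and annotates unique non-exon hits.
#'
#' @param candidates character vector of candidate peptides.
#' @param sample a `SampleGenome` or `GenomeSequence`.
#' @param genes a `GeneSet`.
#' @param proteome optional proteome (named character vector or FASTA
#'   path) for the known-protein exclusion.
#' @param il_proteome I/L equivalence for the proteome exclusion
#'   (default on).
#' @param il_genome I/L equivalence for the genomic scan (default off).
#' @param lenient_aa auto-reject candidates containing B/Z/X/U/O with
#'   reason `ambiguous_aa` instead of raising an error.
#' @param no_cut_before_P,minlen_from_upstream_stop see
#'   [annotate_occurrence()].
#' @return list of class `NaPtpVerification` with `annotations` (a
#'   data.frame, one row per candidate) and `funnel` (named counts:
#'   `candidates`, `ambiguous_aa`, `known_protein`, `absent`,
#'   `multiple_occurrence`, `exonic`, `unique_nonexon`).
#' @export
verify_candidates <- function(candidates, sample, genes, proteome = NULL,
                              il_proteome = TRUE, il_genome = FALSE,
                              lenient_aa = FALSE, no_cut_before_P = FALSE,
                              minlen_from_upstream_stop = FALSE) {
  stopifnot(is.character(candidates))
  candidates <- toupper(candidates)
  bad <- grepl(paste0("[^", .AA20, "]"), candidates)
  if (any(bad) && !lenient_aa)
    stop("candidate with non-standard residue: ",
         paste(candidates[bad], collapse = ", "),
         " (set lenient_aa = TRUE to auto-reject)")
  genome <- if (inherits(sample, "SampleGenome")) sample$genome else sample
  index <- .six_frame_index(genome)
  rows <- list()
  blank <- list(chrom = NA_character_, strand = NA_character_,
                frame = NA_character_, start = NA_integer_,
                end = NA_integer_, ref_start = NA_integer_,
                ref_end = NA_integer_, gene = NA_character_,
                host_genes = NA_character_, orientation = NA_character_,
                flank_up = NA_character_, flank_down = NA_character_,
                flanked = NA_character_, nterm_tryptic = NA,
                cterm_tryptic = NA, minimal_length = NA_integer_,
                minlen_lower_bound = NA, n_occurrences = NA_integer_)
  known <- character(0)
  pool <- candidates[!bad]
  if (!is.null(proteome) && length(pool)) {
    ex <- exclude_known(pool, proteome, il_equivalent = il_proteome)
    known <- ex$excluded$peptide
  }
  for (p in candidates) {
    row <- c(list(peptide = p), blank)
    if (grepl(paste0("[^", .AA20, "]"), p)) {
      row$verdict <- "ambiguous_aa"
    } else if (p %in% known) {
      row$verdict <- "known_protein"
    } else {
      occ <- locate_occurrences(p, sample, genes,
                                il_equivalent = il_genome, index = index)
      row$n_occurrences <- nrow(occ)
      row$verdict <- classify_occurrences(occ)
      if (row$verdict == "unique_nonexon") {
        ann <- annotate_occurrence(
          p, occ, genes, sample, index = index,
          no_cut_before_P = no_cut_before_P,
          minlen_from_upstream_stop = minlen_from_upstream_stop)
        for (f in setdiff(names(ann), c("peptide", "verdict")))
          row[[f]] <- ann[[f]]
      }
    }
    rows[[length(rows) + 1L]] <-
      as.data.frame(row[c("peptide", "verdict", names(blank))],
                    stringsAsFactors = FALSE)
  }
  ann <- .rbind_df(rows, as.data.frame(
    c(list(peptide = character(), verdict = character()),
      lapply(blank, `[`, 0L)), stringsAsFactors = FALSE))
  funnel <- c(candidates = length(candidates),
              ambiguous_aa = sum(ann$verdict == "ambiguous_aa"),
              known_protein = sum(ann$verdict == "known_protein"),
              absent = sum(ann$verdict == "absent"),
              multiple_occurrence = sum(ann$verdict ==
                                          "multiple_occurrence"),
              exonic = sum(ann$verdict == "exonic"),
              unique_nonexon = sum(ann$verdict == "unique_nonexon"))
  structure(list(annotations = ann, funnel = funnel),
            class = "NaPtpVerification")
}

#' Write the verification report
#'
#' One TSV row per candidate: verdict, reference-coordinate locus,
#' orientation, flanked dot notation, minimal length and tryptic
#' status.
#'
#' @param verification a `NaPtpVerification` (or its `annotations`
#'   data.frame).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(verification, path) {
  ann <- if (inherits(verification, "NaPtpVerification"))
    verification$annotations else verification
  utils::write.table(ann, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a verification report
#' @param path TSV written by [write_report()].
#' @return the annotations data.frame.
#' @export
read_report <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE)

#' @export
print.NaPtpVerification <- function(x, ...) {
  cat("Na-PTP verification funnel:\n")
  for (nm in names(x$funnel))
    cat(sprintf("  %-20s %d\n", nm, x$funnel[[nm]]))
  invisible(x)
}
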