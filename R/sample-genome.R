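#' Incorporate variants into the reference genome
#'
#' Edits the reference with the supplied (sorted) variants to produce
#' the sample-specific genome together with a bidirectional coordinate
#' map.  Individual variants never abort the edit: a record whose ref
#' allele does not match the genome is skipped with reason
#' `ref_mismatch`, and among overlapping records only the one with the
#' smallest p-value is applied (ties resolved by sort order), the rest
#' skipped with reason `overlap`.  Heterozygous calls are applied as if
#' homozygous; the result is a single edited haplotype.
#'
#' @param genome a `GenomeSequence` (named character vector).
#' @param variants data.frame as returned by [read_variants()], sorted
#'   by `(chrom, pos)`.
#' @return an object of class `SampleGenome`: a list with fields
#'   `genome` (edited `GenomeSequence`), `map` (a `CoordinateMap`),
#'   `applied` (data.frame of applied variants) and `skipped`
#'   (data.frame of skipped variants with a `reason` column).
#' @export
apply_variants <- function(genome, variants) {
  if (is.null(variants) || nrow(variants) == 0L) {
    map <- .identity_map(genome)
    return(structure(list(genome = genome, map = map,
                          applied = .empty_variants(),
                          skipped = .empty_skipped()),
                     class = "SampleGenome"))
  }
  o <- order(variants$chrom, variants$pos)
  if (!identical(o, seq_len(nrow(variants))))
    stop("variants must be sorted by (chrom, pos)")
  edited <- unclass(genome)
  blocks <- list()
  applied_all <- list()
  skipped_all <- list()
  for (chrom in names(genome)) {
    v <- variants[variants$chrom == chrom, , drop = FALSE]
    res <- .apply_chrom(genome[[chrom]], v)
    edited[[chrom]] <- res$seq
    blocks[[chrom]] <- res$blocks
    applied_all[[chrom]] <- res$applied
    skipped_all[[chrom]] <- res$skipped
  }
  unknown <- !(variants$chrom %in% names(genome))
  if (any(unknown)) {
    u <- variants[unknown, , drop = FALSE]
    u$reason <- "unknown_chrom"
    skipped_all[["..unknown"]] <- u
  }
  map <- structure(list(blocks = blocks,
                        ref_len = vapply(unclass(genome), nchar, 0L),
                        sample_len = vapply(edited, nchar, 0L)),
                   class = "CoordinateMap")
  structure(list(genome = structure(edited, class = "GenomeSequence"),
                 map = map,
                 applied = .rbind_df(applied_all, .empty_variants()),
                 skipped = .rbind_df(skipped_all, .empty_skipped())),
            class = "SampleGenome")
}

.empty_variants <- function()
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), kind = character(), p_value = numeric(),
             stringsAsFactors = FALSE)

.empty_skipped <- function() {
  d <- .empty_variants()
  d$reason <- character()
  d
}

.rbind_df <- function(lst, empty) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0L, lst)
  if (!length(lst)) return(empty)
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

# longest common prefix length of two allele strings
.lcp <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(a, "")[[1L]][seq_len(n)]
  bv <- strsplit(b, "")[[1L]][seq_len(n)]
  d <- which(av != bv)
  if (!length(d)) n else d[1L] - 1L
}

# edit one chromosome; returns edited sequence, alignment blocks and the
# applied/skipped bookkeeping
.apply_chrom <- function(refseq, v) {
  cols <- c("chrom", "pos", "ref", "alt", "kind", "p_value")
  skipped <- list()
  if (nrow(v)) {
    # ref-allele check first: mismatching records never compete for overlap
    ok <- logical(nrow(v))
    for (i in seq_len(nrow(v)))
      ok[i] <- substr(refseq, v$pos[i], v$pos[i] + nchar(v$ref[i]) - 1L) ==
        v$ref[i]
    if (any(!ok)) {
      s <- v[!ok, cols, drop = FALSE]
      s$reason <- "ref_mismatch"
      skipped$mismatch <- s
    }
    v <- v[ok, , drop = FALSE]
  }
  if (nrow(v)) {
    # overlap resolution: smallest p-value wins, ties by sort order
    ends <- v$pos + nchar(v$ref) - 1L
    pr <- order(ifelse(is.na(v$p_value), Inf, v$p_value), seq_len(nrow(v)))
    keep <- logical(nrow(v))
    acc_start <- integer(0); acc_end <- integer(0)
    for (i in pr) {
      if (!any(v$pos[i] <= acc_end & ends[i] >= acc_start)) {
        keep[i] <- TRUE
        acc_start <- c(acc_start, v$pos[i]); acc_end <- c(acc_end, ends[i])
      }
    }
    if (any(!keep)) {
      s <- v[!keep, cols, drop = FALSE]
      s$reason <- "overlap"
      skipped$overlap <- s
    }
    v <- v[keep, , drop = FALSE]
    v <- v[order(v$pos), , drop = FALSE]
  }
  # left-to-right block construction (equivalent to right-to-left editing:
  # every edit is expressed in original reference coordinates)
  L <- nchar(refseq)
  pieces <- character(0)
  blocks <- list()
  cr <- 1L; cs <- 1L  # reference / sample cursors
  add <- function(kind, rs, rl, ss, sl)
    blocks[[length(blocks) + 1L]] <<- c(kind = kind, ref_start = rs,
                                        ref_len = rl, sample_start = ss,
                                        sample_len = sl)
  for (i in seq_len(nrow(v))) {
    pos <- v$pos[i]; ref <- v$ref[i]; alt <- v$alt[i]
    pre <- pos - cr
    if (pre > 0L) {
      pieces <- c(pieces, substr(refseq, cr, pos - 1L))
      add("M", cr, pre, cs, pre)
      cr <- cr + pre; cs <- cs + pre
    }
    pieces <- c(pieces, alt)
    k <- .lcp(ref, alt)
    rm_ <- nchar(ref) - k; rn <- nchar(alt) - k
    sub <- min(rm_, rn)
    m_len <- k + sub  # shared prefix + substituted stretch map 1:1
    if (m_len > 0L) {
      add("M", cr, m_len, cs, m_len)
      cr <- cr + m_len; cs <- cs + m_len
    }
    if (rm_ > sub) {               # net deletion
      add("D", cr, rm_ - sub, cs, 0L)
      cr <- cr + (rm_ - sub)
    } else if (rn > sub) {         # net insertion
      add("I", cr, 0L, cs, rn - sub)
      cs <- cs + (rn - sub)
    }
  }
  if (cr <= L) {
    pieces <- c(pieces, substr(refseq, cr, L))
    add("M", cr, L - cr + 1L, cs, L - cr + 1L)
  }
  bl <- if (length(blocks)) {
    b <- as.data.frame(do.call(rbind, blocks), stringsAsFactors = FALSE)
    for (cc in c("ref_start", "ref_len", "sample_start", "sample_len"))
      b[[cc]] <- as.integer(b[[cc]])
    .merge_match_blocks(b)
  } else data.frame(kind = "M", ref_start = 1L, ref_len = L,
                    sample_start = 1L, sample_len = L,
                    stringsAsFactors = FALSE)
  app <- v[, cols, drop = FALSE]
  rownames(app) <- NULL
  list(seq = paste(pieces, collapse = ""), blocks = bl, applied = app,
       skipped = .rbind_df(skipped, .empty_skipped()))
}

.merge_match_blocks <- function(b) {
  keep <- logical(nrow(b))
  out <- b[0, , drop = FALSE]
  for (i in seq_len(nrow(b))) {
    n <- nrow(out)
    if (n > 0L && out$kind[n] == "M" && b$kind[i] == "M" &&
        out$ref_start[n] + out$ref_len[n] == b$ref_start[i]) {
      out$ref_len[n] <- out$ref_len[n] + b$ref_len[i]
      out$sample_len[n] <- out$sample_len[n] + b$sample_len[i]
    } else out <- rbind(out, b[i, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

.identity_map <- function(genome) {
  lens <- vapply(unclass(genome), nchar, 0L)
  blocks <- lapply(lens, function(L)
    data.frame(kind = "M", ref_start = 1L, ref_len = L, sample_start = 1L,
               sample_len = L, stringsAsFactors = FALSE))
  structure(list(blocks = blocks, ref_len = lens, sample_len = lens),
            class = "CoordinateMap")
}

#' Lift sample-genome positions to reference coordinates
#'
#' Positions that fall inside inserted (sample-only) sequence are
#' gap-flagged and reported with the nearest flanking reference
#' position.
#'
#' @param map a `CoordinateMap` from [apply_variants()].
#' @param chrom chromosome id.
#' @param pos vector of 1-based sample positions.
#' @return data.frame with columns `sample_pos`, `ref_pos` (`NA` inside
#'   insertions), `gap` (logical) and `flank` (nearest reference
#'   position left of a gap, `NA` otherwise).
#' @export
lift_to_reference <- function(map, chrom, pos) {
  b <- .map_blocks(map, chrom)
  pos <- as.integer(pos)
  if (any(pos < 1L | pos > map$sample_len[[chrom]]))
    stop("sample position out of range for ", chrom)
  .lift(b, pos, from = "sample")
}

#' Lift reference positions to sample-genome coordinates
#'
#' The inverse of [lift_to_reference()]; positions deleted from the
#' sample are gap-flagged with the nearest flanking sample position.
#'
#' @inheritParams lift_to_reference
#' @param pos vector of 1-based reference positions.
#' @return data.frame with columns `ref_pos`, `sample_pos` (`NA` inside
#'   deletions), `gap` and `flank`.
#' @export
lift_to_sample <- function(map, chrom, pos) {
  b <- .map_blocks(map, chrom)
  pos <- as.integer(pos)
  if (any(pos < 1L | pos > map$ref_len[[chrom]]))
    stop("reference position out of range for ", chrom)
  out <- .lift(b, pos, from = "reference")
  names(out) <- c("ref_pos", "sample_pos", "gap", "flank")
  out
}

.map_blocks <- function(map, chrom) {
  stopifnot(inherits(map, "CoordinateMap"))
  if (!chrom %in% names(map$blocks)) stop("unknown chromosome: ", chrom)
  map$blocks[[chrom]]
}

.lift <- function(b, pos, from) {
  if (from == "sample") {
    src_start <- b$sample_start; src_len <- b$sample_len
    dst_start <- b$ref_start; gap_kind <- "I"
  } else {
    src_start <- b$ref_start; src_len <- b$ref_len
    dst_start <- b$sample_start; gap_kind <- "D"
  }
  n <- length(pos)
  res_pos <- rep(NA_integer_, n); gap <- logical(n)
  flank <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    p <- pos[j]
    i <- which(src_len > 0L & src_start <= p & p < src_start + src_len)[1L]
    if (is.na(i)) stop("position ", p, " not covered by the coordinate map")
    if (b$kind[i] == "M") {
      res_pos[j] <- dst_start[i] + (p - src_start[i])
    } else {
      gap[j] <- TRUE
      flank[j] <- dst_start[i] - 1L
    }
  }
  data.frame(sample_pos = if (from == "sample") pos else res_pos,
             ref_pos = if (from == "sample") res_pos else pos,
             gap = gap, flank = flank)[,
    if (from == "sample") c("sample_pos", "ref_pos", "gap", "flank")
    else c("ref_pos", "sample_pos", "gap", "flank")]
}

# lift a sample-coordinate interval to reference coordinates; gaps at the
# ends fall back to their flanking reference positions
.lift_interval_to_reference <- function(map, chrom, start, end) {
  l <- lift_to_reference(map, chrom, c(start, end))
  rs <- if (l$gap[1L]) l$flank[1L] else l$ref_pos[1L]
  re <- if (l$gap[2L]) l$flank[2L] else l$ref_pos[2L]
  if (rs < 1L) rs <- 1L
  list(start = rs, end = max(rs, re), gap = any(l$gap))
}

# lift a reference interval to sample coordinates (clipping deleted ends
# inward); NULL when the whole interval was deleted
.lift_interval_to_sample <- function(map, chrom, start, end) {
  l <- lift_to_sample(map, chrom, c(start, end))
  ss <- if (l$gap[1L]) l$flank[1L] + 1L else l$sample_pos[1L]
  se <- if (l$gap[2L]) l$flank[2L] else l$sample_pos[2L]
  if (is.na(ss) || is.na(se) || ss > se) return(NULL)
  list(start = ss, end = se)
}

#' Write a liftover sidecar table
#'
#' One row per alignment block: `chrom`, `sample_start`, `ref_start`,
#' `length` (block length on its non-empty side) and `kind`
#' (`M`atch/`I`nsertion/`D`eletion).
#'
#' @param map a `CoordinateMap`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_liftover <- function(map, path) {
  rows <- lapply(names(map$blocks), function(ch) {
    b <- map$blocks[[ch]]
    data.frame(chrom = ch, sample_start = b$sample_start,
               ref_start = b$ref_start,
               length = pmax(b$ref_len, b$sample_len), kind = b$kind,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.SampleGenome <- function(x, ...) {
  cat("SampleGenome:", length(x$genome), "chromosome(s);",
      nrow(x$applied), "variant(s) applied,",
      nrow(x$skipped), "skipped\n")
  invisible(x)
}
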