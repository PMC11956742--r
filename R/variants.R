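#' Read called variants (VCF or VarScan2 tabular)
#'
#' Auto-detects the dialect from the header: files starting with
#' `##fileformat=VCF` are parsed as VCF 4.x sites, anything else with a
#' tab-separated header line is treated as VarScan2 native output.
#' Only records whose caller significance passes `p_value <
#' p_threshold` are retained (the read-time significance filter);
#' multi-allelic VCF records are split into one record per alternate
#' allele and the output is sorted by `(chrom, pos)`.
#'
#' The variant p-value is taken from the VCF INFO key `pval_info_key`
#' (default `PVAL`).  When absent, `qual_as_pvalue = TRUE` converts the
#' QUAL column as `10^(-QUAL/10)`; otherwise a missing p-value is an
#' error unless `permissive = TRUE` (then the record passes the
#' filter).  VarScan2 tables are recognised by a header containing a
#' column whose name contains `p_value`/`Pvalue`/`PValue`.
#'
#' @param path variant file.
#' @param p_threshold retain records with `p_value < p_threshold`.
#' @param permissive treat a missing p-value as passing.
#' @param pval_info_key INFO key holding the p-value in VCF input.
#' @param qual_as_pvalue derive the p-value from QUAL when the INFO key
#'   is absent.
#' @return a data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `kind` (`SNP`/`INS`/`DEL`) and `p_value`, sorted by
#'   `(chrom, pos)`.
#' @export
read_variants <- function(path, p_threshold = 0.01, permissive = FALSE,
                          pval_info_key = "PVAL", qual_as_pvalue = FALSE) {
  if (!file.exists(path)) stop("variant file not found: ", path)
  stopifnot(p_threshold > 0, p_threshold <= 1)
  lines <- readLines(path)
  is_vcf <- length(lines) > 0L && grepl("^##fileformat=VCF", lines[1L])
  v <- if (is_vcf)
    .parse_vcf(lines, permissive, pval_info_key, qual_as_pvalue)
  else
    .parse_varscan(lines, permissive)
  v <- v[is.na(v$p_value) | v$p_value < p_threshold, , drop = FALSE]
  if (!permissive && anyNA(v$p_value))
    stop("variant record without a p-value (use permissive = TRUE to keep)")
  v <- v[order(v$chrom, v$pos), , drop = FALSE]
  rownames(v) <- NULL
  v
}

.variant_kind <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP",
         ifelse(nchar(alt) > nchar(ref), "INS",
                ifelse(nchar(ref) > nchar(alt), "DEL", "MNP")))
}

.parse_vcf <- function(lines, permissive, pval_info_key, qual_as_pvalue) {
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  empty <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      kind = character(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(body)) return(empty)
  lineno <- which(!startsWith(lines, "#") & nzchar(lines))
  fields <- strsplit(body, "\t", fixed = TRUE)
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 8L)
      stop("unparsable VCF record at line ", lineno[i],
           " (fewer than 8 columns)")
    pos <- suppressWarnings(as.integer(f[2L]))
    if (is.na(pos))
      stop("unparsable VCF POS at line ", lineno[i])
    ref <- toupper(f[4L])
    alts <- toupper(strsplit(f[5L], ",", fixed = TRUE)[[1L]])
    if (grepl("[^ACGTN]", ref) || any(grepl("[^ACGTN]", alts)))
      stop("non-ACGTN allele in VCF record at line ", lineno[i])
    pv <- NA_real_
    m <- regmatches(f[8L], regexec(
      paste0("(?:^|;)", pval_info_key, "=([^;]+)"), f[8L]))[[1L]]
    if (length(m) == 2L) pv <- suppressWarnings(as.numeric(m[2L]))
    if (is.na(pv) && qual_as_pvalue) {
      q <- suppressWarnings(as.numeric(f[6L]))
      if (!is.na(q)) pv <- 10^(-q / 10)
    }
    out[[i]] <- data.frame(chrom = f[1L], pos = pos, ref = ref, alt = alts,
                           kind = .variant_kind(ref, alts), p_value = pv,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.parse_varscan <- function(lines, permissive) {
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    stop("empty variant file without a recognisable header")
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  pcol <- grep("p._?value|Pvalue", hdr, ignore.case = TRUE)[1L]
  ccol <- grep("^(Chrom|chrom|CHROM)$", hdr)[1L]
  pos_col <- grep("^(Position|position|POS|Pos)$", hdr)[1L]
  ref_col <- grep("^(Ref|ref|REF)$", hdr)[1L]
  # VarScan calls the observed allele "Cons"/"VarAllele"/"Var" by mode
  alt_col <- grep("^(Var|VarAllele|var|Alt|alt|ALT|Cons)$", hdr)[1L]
  if (anyNA(c(ccol, pos_col, ref_col, alt_col)))
    stop("unrecognised VarScan2 header: need Chrom/Position/Ref/Var columns")
  if (length(lines) == 1L)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      kind = character(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < length(hdr))
      stop("unparsable VarScan2 record at line ", i + 1L)
    pos <- suppressWarnings(as.integer(f[pos_col]))
    if (is.na(pos)) stop("unparsable position at line ", i + 1L)
    ref <- toupper(f[ref_col])
    alt <- toupper(f[alt_col])
    # VarScan indel notation: "+AC" insertion, "-AC" deletion, anchored on ref
    if (startsWith(alt, "+")) alt <- paste0(ref, substring(alt, 2L))
    else if (startsWith(alt, "-")) {
      ref <- paste0(ref, substring(alt, 2L))
      alt <- substr(ref, 1L, 1L)
    }
    if (grepl("[^ACGTN]", ref) || grepl("[^ACGTN]", alt))
      stop("non-ACGTN allele in VarScan2 record at line ", i + 1L)
    pv <- if (is.na(pcol)) NA_real_ else
      suppressWarnings(as.numeric(f[pcol]))
    out[[i]] <- data.frame(chrom = f[ccol], pos = pos, ref = ref, alt = alt,
                           kind = .variant_kind(ref, alt), p_value = pv,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
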