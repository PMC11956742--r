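#' Parse flanked dot notation and measure the reported length
#'
#' Flanked dot notation `X.PEPTIDE.Y` carries the MS-identified core
#' together with the in-frame residues immediately up- and downstream
#' at the genomic locus; a `-` flank marks a sequence/region edge (or
#' an adjacent stop codon).  The reported length counts the core plus
#' every real flanking residue, the convention used when quoting
#' Na-PTP lengths.
#'
#' @param x either a dot-notation string (`"F.AFLTTAILVGMK.W"`) or an
#'   `NaPtpAnnotation`.
#' @return an object of class `FlankedNaPtp`: list with `core`,
#'   `flank_up`, `flank_down`, `flanked` (concatenation skipping `-`
#'   flanks) and `reported_length`.
#' @export
flank_and_measure <- function(x) {
  if (inherits(x, "NaPtpAnnotation")) x <- x$flanked
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec("^([A-Z-])\\.([A-Z]+)\\.([A-Z-])$", x))[[1L]]
  if (length(m) != 4L)
    stop("not a flanked dot-notation string: ", x)
  up <- m[2L]; core <- m[3L]; down <- m[4L]
  flanked <- paste0(if (up != "-") up else "", core,
                    if (down != "-") down else "")
  structure(list(core = core, flank_up = up, flank_down = down,
                 flanked = flanked, reported_length = nchar(flanked)),
            class = "FlankedNaPtp")
}

#' Enumerate MHC-I candidate windows over a flanked Na-PTP
#'
#' All contiguous `k`-mers, `kmin <= k <= kmax`, of the flanked string
#' (flanking residues included: predicted ligands routinely span them),
#' ordered by `(k, offset)`.  The count follows the closed form
#' `sum over k of (L - k + 1)` for `k` up to `min(kmax, L)`.
#'
#' @param flanked a `FlankedNaPtp` (or a plain peptide string).
#' @param kmin,kmax window length bounds (defaults 8 and 14, the
#'   class-I ligand range scanned for binding predictions).
#' @return data.frame with columns `window`, `k`, `offset` (0-based).
#' @export
enumerate_windows <- function(flanked, kmin = 8L, kmax = 14L) {
  stopifnot(kmin >= 1L, kmin <= kmax)
  s <- if (inherits(flanked, "FlankedNaPtp")) flanked$flanked else flanked
  L <- nchar(s)
  rows <- list()
  for (k in seq(kmin, kmax)) {
    if (k > L) break
    off <- 0:(L - k)
    rows[[length(rows) + 1L]] <- data.frame(
      window = substring(s, off + 1L, off + k), k = k, offset = off,
      stringsAsFactors = FALSE)
  }
  .rbind_df(rows, data.frame(window = character(), k = integer(),
                             offset = integer(), stringsAsFactors = FALSE))
}

#' Export epitope windows for an external binding predictor
#'
#' `peplist` writes one peptide per line (the peptide-mode input of
#' class-I predictors such as NetMHCpan); `fasta` writes records whose
#' headers carry `gene|offset|k`.
#'
#' @param windows data.frame from [enumerate_windows()]; an optional
#'   `gene` column is used in FASTA headers.
#' @param path output path.
#' @param format `"peplist"` or `"fasta"`.
#' @param unique deduplicate identical window sequences across entries.
#' @return `path`, invisibly.
#' @export
export_predictor_input <- function(windows, path,
                                   format = c("peplist", "fasta"),
                                   unique = FALSE) {
  format <- match.arg(format)
  w <- windows
  if (unique) w <- w[!duplicated(w$window), , drop = FALSE]
  if (format == "peplist") {
    writeLines(w$window, path)
  } else {
    gene <- if ("gene" %in% names(w)) w$gene else rep("NA", nrow(w))
    lines <- character(0)
    for (i in seq_len(nrow(w)))
      lines <- c(lines, sprintf(">%s|%d|%d", gene[i], w$offset[i], w$k[i]),
                 w$window[i])
    writeLines(lines, path)
  }
  invisible(path)
}

#' Count sense vs antisense entries
#'
#' @param x a character vector of orientations, a data.frame with an
#'   `orientation` column, or a list of `NaPtpAnnotation`s.
#' @return named integer vector `c(sense = , antisense = )`.
#' @export
summarize_orientation <- function(x) {
  ori <- if (is.character(x)) x
  else if (is.data.frame(x)) x$orientation
  else vapply(x, `[[`, "", "orientation")
  c(sense = sum(ori == "sense", na.rm = TRUE),
    antisense = sum(ori == "antisense", na.rm = TRUE))
}

#' @export
print.FlankedNaPtp <- function(x, ...) {
  cat(sprintf("FlankedNaPtp %s.%s.%s  (reported length %d aa)\n",
              x$flank_up, x$core, x$flank_down, x$reported_length))
  invisible(x)
}
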