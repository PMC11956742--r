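#' Generate a random genome
#'
#' Bit-reproducible for a fixed seed; base composition matches
#' `gc_fraction` in expectation (within ~3 percentage points for
#' chromosomes of 10 kb and more).
#'
#' @param n_chrom number of chromosomes (`c1`, `c2`, ...).
#' @param chrom_length length of each chromosome in bp.
#' @param gc_fraction target GC content (default 0.41, the
#'   human-genome average).
#' @param seed RNG seed.
#' @return a `GenomeSequence`.
#' @export
make_genome <- function(n_chrom = 2L, chrom_length = 100000L,
                        gc_fraction = 0.41, seed = 1L) {
  set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seqs <- character(n_chrom)
  for (i in seq_len(n_chrom))
    seqs[i] <- paste(sample(names(p), chrom_length, replace = TRUE,
                            prob = p), collapse = "")
  names(seqs) <- if (n_chrom) paste0("c", seq_len(n_chrom)) else character()
  structure(seqs, class = "GenomeSequence")
}

#' Define a gene model and its GTF lines
#'
#' Builds a `GeneModel` from an explicit exon layout (one element per
#' transcript; each a two-column start/end matrix in genome
#' coordinates) together with GTF text lines that parse back into an
#' equal model via [read_annotation()].
#'
#' @param chrom chromosome id.
#' @param exon_layout list of two-column matrices (one per transcript),
#'   or a single matrix for a single-transcript gene.
#' @param strand `"+"` or `"-"`.
#' @param gene_id gene identifier.
#' @return list with `gene` (a `GeneModel`) and `gtf` (character
#'   lines).
#' @export
plant_gene <- function(chrom, exon_layout, strand, gene_id) {
  if (is.matrix(exon_layout)) exon_layout <- list(exon_layout)
  if (is.null(names(exon_layout)))
    names(exon_layout) <- paste0(gene_id, ".t", seq_along(exon_layout))
  txs <- lapply(names(exon_layout), function(tid) {
    ex <- exon_layout[[tid]]
    storage.mode(ex) <- "integer"
    colnames(ex) <- c("start", "end")
    ex <- ex[order(ex[, "start"]), , drop = FALSE]
    list(transcript_id = tid, exons = ex)
  })
  names(txs) <- names(exon_layout)
  allex <- do.call(rbind, lapply(txs, `[[`, "exons"))
  gene <- structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                         start = as.integer(min(allex[, "start"])),
                         end = as.integer(max(allex[, "end"])),
                         transcripts = txs),
                    class = "GeneModel")
  gtf <- character(0)
  for (tid in names(txs)) {
    ex <- txs[[tid]]$exons
    for (i in seq_len(nrow(ex)))
      gtf <- c(gtf, sprintf(
        "%s\tsynthfix\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
        chrom, ex[i, "start"], ex[i, "end"], strand, gene_id, tid))
  }
  list(gene = gene, gtf = gtf)
}

# inverse codon table: amino acid -> lexicographically sorted codons
.codon_choices <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(sort(names(gc)), gc[sort(names(gc))])
    }
    tab
  }
})

# deterministic back-translation; `attempt` selects codon combinations in
# mixed-radix order (attempt 0 = all-lexicographic-first)
.backtranslate <- function(aa, attempt = 0L) {
  tab <- .codon_choices()
  res <- strsplit(aa, "")[[1L]]
  codons <- character(length(res))
  t <- attempt
  for (i in seq_along(res)) {
    ch <- tab[[res[i]]]
    if (is.null(ch)) stop("cannot back-translate residue: ", res[i])
    d <- t %% length(ch)
    t <- t %/% length(ch)
    codons[i] <- ch[d + 1L]
  }
  paste(codons, collapse = "")
}

.PAD_RESIDUES <- c("A", "D", "E", "G", "S", "T", "V", "N", "Q", "H")

# six-frame occurrence count of a peptide in a genome (exact match)
.count_occurrences <- function(peptide, genome, index = NULL) {
  if (is.null(index)) index <- .six_frame_index(genome)
  n <- 0L
  for (ch in names(index))
    for (lab in FRAME_LABELS)
      n <- n + length(.find_all(peptide, index[[ch]][[lab]]$aa))
  n
}

# frame label of a codon span in a genome of length L
.frame_label_for <- function(start, end, strand, L) {
  if (strand == "+") paste0("f", (start - 1L) %% 3L)
  else paste0("r", (L - end) %% 3L)
}

#' Plant a peptide-encoding cassette into a gene region
#'
#' Writes `stop | flank | peptide | pad | stop` (back-translated with a
#' deterministic lexicographic codon choice) into an intron (or exon)
#' of `gene`, on the requested strand orientation relative to the gene,
#' at a position whose reading-frame offset matches `frame_offset`.
#' A stop codon sits `pad_to_stop` residues downstream of the peptide,
#' so the ground-truth minimal product length is
#' `nchar(peptide) + pad_to_stop`.  After writing, a six-frame scan
#' confirms the peptide occurs exactly `expected_occurrences` times
#' genome-wide; on collision the codon choice is re-rolled (up to
#' `max_attempts` mixed-radix combinations) before giving up.
#'
#' @param genome a `GenomeSequence` (modified copy is returned).
#' @param gene a `GeneModel`.
#' @param region_index which intron (or exon, see `where`) of the gene
#'   to use, 1-based in genomic order.
#' @param orientation `"sense"` or `"antisense"` relative to the gene
#'   strand.
#' @param frame_offset requested frame offset 0/1/2 (chromosome frame
#'   convention, evaluated on the strand carrying the peptide).
#' @param peptide amino-acid string to plant.
#' @param pad_to_stop residues between the peptide end and the
#'   downstream stop codon.
#' @param flank_up residue written immediately upstream of the peptide
#'   (`"-"` for none, leaving the upstream stop adjacent).
#' @param where `"intron"` (default) or `"exon"`.
#' @param at optional offset (bp) of the cassette inside the region.
#' @param expected_occurrences genome-wide occurrence count to verify
#'   after planting (2 when deliberately planting a duplicate).
#' @param max_attempts codon re-roll budget.
#' @return list with `genome` (updated), `entry` (the ground-truth
#'   manifest entry: sequence, gene, orientation, strand, frame, span,
#'   flanks, minimal_length).
#' @export
plant_peptide <- function(genome, gene, region_index, orientation,
                          frame_offset, peptide, pad_to_stop,
                          flank_up = "R", where = c("intron", "exon"),
                          at = 6L, expected_occurrences = 1L,
                          max_attempts = 100L) {
  where <- match.arg(where)
  stopifnot(orientation %in% c("sense", "antisense"),
            frame_offset %in% 0:2, nchar(peptide) >= 1L, pad_to_stop >= 0L)
  chrom <- gene$chrom
  L <- nchar(genome[[chrom]])
  region <- .plant_region(gene, region_index, where)
  strand <- if (orientation == "sense") gene$strand
    else setdiff(c("+", "-"), gene$strand)
  has_flank <- flank_up != "-"
  pads <- if (pad_to_stop > 0L)
    .PAD_RESIDUES[(seq_len(pad_to_stop) - 1L) %% length(.PAD_RESIDUES) + 1L]
  else character(0)
  aa_insert <- paste0(if (has_flank) flank_up else "", peptide,
                      paste(pads, collapse = ""))
  ni <- 3L * (nchar(aa_insert) + 2L)  # two stop codons bracket the cassette
  if (region$end - region$start + 1L < ni + at + 6L)
    stop("cassette (", ni, " nt) does not fit in ", where, " ",
         region_index, " of ", gene$gene_id)
  # position so that the peptide's first codon hits the requested frame
  lo <- region$start + at
  s <- if (strand == "+") {
    lo + (frame_offset + 1L - lo) %% 3L
  } else {
    want <- (L - frame_offset - ni + 1L) %% 3L
    lo + (want - lo) %% 3L
  }
  e <- s + ni - 1L
  if (e > region$end) stop("cassette does not fit after frame adjustment")
  q <- 3L * (1L + has_flank) + 1L  # insert-local nt start of the peptide
  if (strand == "+") {
    p_start <- s + q - 1L
    p_end <- p_start + 3L * nchar(peptide) - 1L
  } else {
    p_end <- e - q + 1L
    p_start <- p_end - 3L * nchar(peptide) + 1L
  }
  for (attempt in 0:(max_attempts - 1L)) {
    nt <- paste0("TAA", .backtranslate(aa_insert, attempt), "TAA")
    if (strand == "-") nt <- reverse_complement(nt)
    g2 <- unclass(genome)
    substr(g2[[chrom]], s, e) <- nt
    g2 <- structure(g2, class = "GenomeSequence")
    if (.count_occurrences(peptide, g2) == expected_occurrences) {
      entry <- list(
        sequence = peptide, gene = gene$gene_id, chrom = chrom,
        orientation = orientation, strand = strand,
        frame = .frame_label_for(p_start, p_end, strand, L),
        start = p_start, end = p_end,
        flank_up = flank_up,
        flank_down = if (pad_to_stop > 0L) pads[1L] else "-",
        minimal_length = nchar(peptide) + pad_to_stop,
        where = where)
      return(list(genome = g2, entry = entry))
    }
  }
  stop("plant_peptide: no collision-free codon choice for ", peptide,
       " after ", max_attempts, " attempts")
}

.plant_region <- function(gene, region_index, where) {
  if (where == "intron") {
    gaps <- IRanges::setdiff(IRanges::IRanges(gene$start, gene$end),
                             .gene_exon_union(gene))
    if (region_index > length(gaps))
      stop("gene ", gene$gene_id, " has no intron ", region_index)
    list(start = BiocGenerics::start(gaps)[region_index],
         end = BiocGenerics::end(gaps)[region_index])
  } else {
    ex <- .gene_exon_union(gene)
    if (region_index > length(ex))
      stop("gene ", gene$gene_id, " has no exon ", region_index)
    list(start = BiocGenerics::start(ex)[region_index],
         end = BiocGenerics::end(ex)[region_index])
  }
}

#' Generate a decoy proteome
#'
#' Random protein sequences with the requested planted peptides
#' embedded as substrings (their ground-truth verdict becomes
#' `known_protein`).
#'
#' @param n number of decoy proteins.
#' @param len length of each decoy protein (aa).
#' @param include peptides to embed (one per protein, reused in order).
#' @param seed RNG seed.
#' @return named character vector of protein sequences.
#' @export
make_decoys <- function(n = 20L, len = 150L, include = character(),
                        seed = 1L) {
  set.seed(seed)
  aa <- strsplit(.AA20, "")[[1L]]
  prot <- vapply(seq_len(n), function(i)
    paste(sample(aa, len, replace = TRUE), collapse = ""), "")
  for (i in seq_along(include)) {
    j <- (i - 1L) %% n + 1L
    at <- 40L + 5L * i
    substr(prot[j], at, at + nchar(include[i]) - 1L) <- include[i]
  }
  names(prot) <- sprintf("decoy%03d", seq_len(n))
  prot
}

#' Generate non-overlapping variants with a known expected outcome
#'
#' Draws SNPs and short indels at positions at least 10 bp apart,
#' avoiding the supplied intervals, with caller p-values below 0.01;
#' `n_filtered` additional records are emitted with p-values above the
#' threshold so the read-time significance filter is exercised.  The
#' expected edited genome is computed by [naive_apply_variants()], an
#' independent right-to-left string splicer that serves as the oracle
#' for [apply_variants()].
#'
#' @param genome a `GenomeSequence`.
#' @param n_snp,n_indel counts of significant SNPs / indels.
#' @param seed RNG seed.
#' @param avoid optional data.frame (`chrom`, `start`, `end`) of
#'   intervals variants must stay clear of (a 100 bp margin is added).
#' @param n_filtered count of extra above-threshold records.
#' @return list with `variants` (data.frame incl. the filtered-out
#'   records, sorted by chrom/pos), `expected` (naive-edited
#'   `GenomeSequence` using only the significant records).
#' @export
make_variants <- function(genome, n_snp = 30L, n_indel = 10L, seed = 1L,
                          avoid = NULL, n_filtered = 8L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  total <- n_snp + n_indel + n_filtered
  per_chrom <- table(sample(names(genome), total, replace = TRUE))
  rows <- list()
  for (ch in names(per_chrom)) {
    L <- nchar(genome[[ch]])
    allowed <- IRanges::IRanges(11L, L - 11L)
    if (!is.null(avoid)) {
      a <- avoid[avoid$chrom == ch, , drop = FALSE]
      if (nrow(a))
        allowed <- IRanges::setdiff(allowed, IRanges::IRanges(
          pmax(1L, a$start - 100L), pmin(L, a$end + 100L)))
    }
    pool <- unlist(lapply(seq_along(allowed), function(i)
      seq(BiocGenerics::start(allowed)[i], BiocGenerics::end(allowed)[i])))
    pos <- sort(sample(pool, min(per_chrom[[ch]] * 3L, length(pool))))
    pos <- pos[c(TRUE, diff(pos) >= 10L)]
    pos <- pos[seq_len(min(per_chrom[[ch]], length(pos)))]
    for (p in pos)
      rows[[length(rows) + 1L]] <- list(chrom = ch, pos = p)
  }
  n_avail <- length(rows)
  if (n_avail < total)
    stop("make_variants: not enough room for ", total, " variants")
  type <- sample(rep(c("SNP", "INDEL", "FILTERED"),
                     c(n_snp, n_indel, n_filtered)))
  out <- vector("list", n_avail)
  for (i in seq_len(n_avail)) {
    ch <- rows[[i]]$chrom; p <- rows[[i]]$pos
    refbase <- substr(genome[[ch]], p, p)
    kind <- type[i]
    if (kind == "FILTERED") {
      alt <- sample(setdiff(bases, refbase), 1L)
      ref <- refbase
      pv <- stats::runif(1, 0.02, 0.5)
    } else if (kind == "SNP") {
      alt <- sample(setdiff(bases, refbase), 1L)
      ref <- refbase
      pv <- stats::runif(1, 1e-5, 0.009)
    } else {
      d <- sample(1:3, 1L)
      if (stats::runif(1) < 0.5) {          # insertion, anchored
        ref <- refbase
        alt <- paste0(refbase,
                      paste(sample(bases, d, replace = TRUE),
                            collapse = ""))
      } else {                               # deletion, anchored
        ref <- substr(genome[[ch]], p, p + d)
        alt <- refbase
      }
      pv <- stats::runif(1, 1e-5, 0.009)
    }
    out[[i]] <- data.frame(chrom = ch, pos = p, ref = ref, alt = alt,
                           kind = .variant_kind(ref, alt), p_value = pv,
                           stringsAsFactors = FALSE)
  }
  v <- do.call(rbind, out)
  v <- v[order(v$chrom, v$pos), , drop = FALSE]
  rownames(v) <- NULL
  sig <- v[v$p_value < 0.01, , drop = FALSE]
  list(variants = v, expected = naive_apply_variants(genome, sig))
}

#' Naive right-to-left variant application (oracle)
#'
#' An independent reference implementation of genome editing used as
#' the oracle for [apply_variants()]: variants (assumed non-overlapping
#' and ref-matching) are spliced into the sequence from the rightmost
#' position leftwards with plain string surgery.  No coordinate map is
#' produced.
#'
#' @param genome a `GenomeSequence`.
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @return the edited `GenomeSequence`.
#' @export
naive_apply_variants <- function(genome, variants) {
  out <- unclass(genome)
  for (ch in unique(variants$chrom)) {
    v <- variants[variants$chrom == ch, , drop = FALSE]
    v <- v[order(-v$pos), , drop = FALSE]
    s <- out[[ch]]
    for (i in seq_len(nrow(v))) {
      p <- v$pos[i]
      stopifnot(substr(s, p, p + nchar(v$ref[i]) - 1L) == v$ref[i])
      s <- paste0(substr(s, 1L, p - 1L), v$alt[i],
                  substr(s, p + nchar(v$ref[i]), nchar(s)))
    }
    out[[ch]] <- s
  }
  structure(out, class = "GenomeSequence")
}

#' Write variants as a minimal VCF 4.2 file
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `p_value`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=PVAL,Number=1,Type=Float,Description=\"Variant p-value\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tPVAL=%.6g",
                  variants$chrom, variants$pos, variants$ref, variants$alt,
                  variants$p_value)
  writeLines(c(hdr, body), path)
  invisible(path)
}
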