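no_genes <- gene_set()

test_that("exclude_known applies substring matching with I/L folding", {
  prot <- c(sp1 = "GGGAMKWVTFIGGG")
  ex <- exclude_known("MKWVTF", prot)
  expect_equal(nrow(ex$excluded), 1L)
  expect_identical(ex$excluded$hit, "sp1")

  ex2 <- exclude_known("MKWVTF", c(sp1 = "GGGAMKWVTLIGGG"))
  expect_identical(ex2$retained, "MKWVTF")  # F != L even under folding

  ex3 <- exclude_known("PEPTIDE", c(sp1 = "AAPEPTLDEAA"))
  expect_equal(nrow(ex3$excluded), 1L)
  ex4 <- exclude_known("PEPTIDE", c(sp1 = "AAPEPTLDEAA"),
                       il_equivalent = FALSE)
  expect_identical(ex4$retained, "PEPTIDE")

  expect_warning(r <- exclude_known("MK", character(0)), "empty proteome")
  expect_identical(r$retained, "MK")
})

test_that("classify_occurrences implements the verdict rule table", {
  occ <- function(n, in_exon = FALSE)
    data.frame(in_exon = rep(in_exon, n))
  expect_identical(classify_occurrences(occ(0)), "absent")
  expect_identical(classify_occurrences(occ(1)), "unique_nonexon")
  expect_identical(classify_occurrences(occ(1, TRUE)), "exonic")
  expect_identical(classify_occurrences(occ(2)), "multiple_occurrence")
  expect_identical(classify_occurrences(occ(2, TRUE)),
                   "multiple_occurrence")
})

test_that("locate_occurrences agrees with the naive six-frame oracle", {
  set.seed(21)
  for (rep in 1:4) {
    g <- as_genome(c(c1 = random_dna(400), c2 = random_dna(250)))
    # draw query peptides from the oracle translations themselves
    fr <- oracle_frames(g[["c1"]])
    segs <- unlist(lapply(fr, oracle_segments))
    segs <- segs[nchar(segs) >= 2 & !grepl("X", segs)]
    peps <- c(utils::head(segs, 3), "MK", "WWWWW")
    for (p in peps) {
      got <- locate_occurrences(p, g, no_genes)
      want <- oracle_scan(p, g)
      expect_equal(nrow(got), nrow(want))
      if (nrow(got)) {
        off <- as.integer(substr(got$frame, 2, 2))
        L <- nchar(g[[1]])
        i <- ifelse(got$strand == "+",
                    (got$start - off - 1) %/% 3 + 1,
                    (nchar(unclass(g)[got$chrom]) - got$end - off) %/% 3 + 1)
        expect_identical(
          sort(paste(got$chrom, got$frame, i)),
          sort(paste(want$chrom, want$frame, want$aa_index)))
      }
    }
  }
})

test_that("exon overlap and host genes drive the verdict", {
  # gene with exons (1,30) and (200,230); intron in between
  g <- as_genome(c(c1 = paste0(strrep("T", 50), "TAAATGAAAGGGTAA",
                               strrep("T", 170))))
  gene <- simple_gene("g1", "c1", "+", rbind(c(1, 30), c(200, 230)))
  gs <- gene_set(gene)
  occ <- locate_occurrences("MKG", g, gs)
  expect_equal(nrow(occ), 1L)
  expect_false(occ$in_exon)
  expect_identical(occ$host_genes, "g1")
  expect_identical(classify_occurrences(occ), "unique_nonexon")

  # same hit, but an exon now overlaps its first codon -> exonic
  gene2 <- simple_gene("g1", "c1", "+", rbind(c(1, 56), c(200, 230)))
  occ2 <- locate_occurrences("MKG", g, gene_set(gene2))
  expect_true(occ2$in_exon)
  expect_identical(classify_occurrences(occ2), "exonic")
})

test_that("annotation recovers flanks, tryptic status and orientation", {
  # cassette: stop | R | M K G | W | stop, in f0
  g <- as_genome(c(c1 = paste0(strrep("T", 51), "TAA", "CGT",
                               "ATGAAAGGG", "TGG", "TAA",
                               strrep("T", 150))))
  gene <- simple_gene("g1", "c1", "+", rbind(c(1, 30), c(200, 230)))
  gs <- gene_set(gene)
  occ <- locate_occurrences("MKG", g, gs)
  ann <- annotate_occurrence("MKG", occ, gs, g)
  expect_identical(ann$flank_up, "R")
  expect_identical(ann$flank_down, "W")
  expect_identical(ann$flanked, "R.MKG.W")
  expect_true(ann$nterm_tryptic)    # preceded by R
  expect_false(ann$cterm_tryptic)   # ends in G
  expect_identical(ann$orientation, "sense")
  expect_identical(ann$gene, "g1")
  expect_identical(ann$minimal_length, 4L)  # MKG + W, then stop

  # antisense: the reverse-complemented cassette on a + gene
  cass <- paste0("TAA", "CGT", "ATGAAAGGG", "TGG", "TAA")
  g2 <- as_genome(c(c1 = paste0(strrep("T", 51),
                                reverse_complement(cass),
                                strrep("T", 150))))
  occ2 <- locate_occurrences("MKG", g2, gs)
  expect_identical(occ2$strand, "-")
  ann2 <- annotate_occurrence("MKG", occ2, gs, g2)
  expect_identical(ann2$orientation, "antisense")
  expect_identical(ann2$flank_up, "R")
  expect_identical(ann2$minimal_length, 4L)
})

test_that("minimal length walks to the first downstream in-frame stop", {
  # MK at the start of segment MKAAAA followed by a stop -> 6
  g <- as_genome(c(c1 = paste0("TTTTTT", "TAA", "ATGAAAGCTGCTGCTGCT",
                               "TAA", "TTTTTT")))
  occ <- locate_occurrences("MK", g, no_genes)
  occ <- occ[occ$frame == "f0", ]
  expect_equal(as.integer(estimate_minimal_length("MK", occ, g)), 6L)
  # peptide ending immediately before the stop -> its own length
  occ6 <- locate_occurrences("MKAAAA", g, no_genes)
  expect_equal(as.integer(estimate_minimal_length("MKAAAA", occ6, g)), 6L)
  # upstream-stop convention measures the whole segment
  occK <- locate_occurrences("KAAAA", g, no_genes)
  expect_equal(as.integer(estimate_minimal_length(
    "KAAAA", occK, g, minlen_from_upstream_stop = TRUE)), 6L)

  # no downstream stop before the boundary -> flagged lower bound
  g2 <- as_genome(c(c1 = "ATGAAAGCTGCTGCTGCT"))
  occ2 <- locate_occurrences("MK", g2, no_genes)
  occ2 <- occ2[occ2$frame == "f0", ]
  ml <- estimate_minimal_length("MK", occ2, g2)
  expect_equal(as.integer(ml), 6L)
  expect_true(attr(ml, "lower_bound"))
})

test_that("verify_candidates partitions the funnel exhaustively", {
  g <- as_genome(c(c1 = paste0(strrep("T", 51), "TAA", "CGT",
                               "ATGAAAGGGCATTGGCCA", "TAA",
                               strrep("T", 150))))
  gene <- simple_gene("g1", "c1", "+", rbind(c(1, 30), c(200, 230)))
  gs <- gene_set(gene)
  prot <- c(sp = "AAAWQPHRDEAAA")
  ver <- verify_candidates(c("MKGHWP", "WQPHRDE", "EEEEEE", "BZX"),
                           g, gs, proteome = prot, lenient_aa = TRUE)
  ann <- ver$annotations
  expect_identical(ann$verdict[ann$peptide == "MKGHWP"], "unique_nonexon")
  expect_identical(ann$verdict[ann$peptide == "WQPHRDE"], "known_protein")
  expect_identical(ann$verdict[ann$peptide == "EEEEEE"], "absent")
  expect_identical(ann$verdict[ann$peptide == "BZX"], "ambiguous_aa")
  expect_equal(sum(ver$funnel[-1]), ver$funnel[["candidates"]])
  expect_error(verify_candidates("BZX", g, gs), "non-standard")

  # report round-trip
  out <- withr::local_tempfile(fileext = ".tsv")
  write_report(ver, out)
  back <- read_report(out)
  expect_equal(nrow(back), 4L)
  expect_identical(back$verdict, ann$verdict)
})
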