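test_that("non-exon regions are the per-gene gaps of the exon union", {
  g1 <- simple_gene("g1", "c1", "+", rbind(c(1, 20), c(51, 100)))
  r <- extract_nonexon_regions(gene_set(g1))
  expect_identical(r$start, 21L)
  expect_identical(r$end, 50L)

  # union across transcripts, checked against per-base membership
  g2 <- naptp::plant_gene("c1", list(
    t1 = rbind(c(1, 30), c(61, 100)),
    t2 = rbind(c(1, 40), c(81, 100))), "+", "g2")$gene
  r2 <- extract_nonexon_regions(gene_set(g2))
  covered <- rep(FALSE, 100)
  for (tx in g2$transcripts)
    for (i in seq_len(nrow(tx$exons)))
      covered[tx$exons[i, "start"]:tx$exons[i, "end"]] <- TRUE
  gaps <- which(!covered)
  expect_identical(r2$start, min(gaps))
  expect_identical(r2$end, max(gaps))
  expect_true(all(diff(gaps) == 1))  # a single contiguous gap here
  expect_identical(c(r2$start, r2$end), c(41L, 60L))

  # single-exon gene has no non-exon region
  g3 <- simple_gene("g3", "c1", "+", rbind(c(5, 50)))
  expect_equal(nrow(extract_nonexon_regions(gene_set(g3))), 0L)
})

test_that("six-frame translation matches the worked examples", {
  fr <- translate_six_frames("ATGAAATAGGCC")
  expect_identical(fr$f0$peptide, c("MK", "A"))
  expect_identical(fr$r0$peptide, "GLFH")
  # below codon length: empty everywhere
  fr2 <- translate_six_frames("AT")
  expect_true(all(vapply(fr2, nrow, 0L) == 0L))
  # N-containing codons become X, and stops split segments
  fr3 <- translate_six_frames("ATGNNNTAGAAA")
  expect_identical(fr3$f0$peptide, c("MX", "K"))
})

test_that("segment genomic spans re-translate to their peptides", {
  set.seed(11)
  for (i in 1:10) {
    s <- random_dna(sample(30:120, 1))
    fr <- translate_six_frames(s)
    for (lab in names(fr)) {
      seg <- fr[[lab]]
      for (j in seq_len(nrow(seg))) {
        nt <- substr(s, seg$start[j], seg$end[j])
        if (startsWith(lab, "r")) nt <- oracle_revcomp(nt)
        expect_identical(oracle_translate(nt), seg$peptide[j])
      }
    }
  }
})

test_that("six-frame segments match the brute-force oracle", {
  set.seed(12)
  for (i in 1:30) {
    s <- random_dna(sample(3:300, 1), with_n = i %% 3 == 0)
    fr <- translate_six_frames(s)
    or <- oracle_frames(s)
    expect_identical(names(fr), c("f0", "f1", "f2", "r0", "r1", "r2"))
    for (lab in names(fr))
      expect_identical(fr[[lab]]$peptide, oracle_segments(or[[lab]]))
  }
})

test_that("strand symmetry: reverse frames mirror the reverse complement", {
  set.seed(13)
  for (i in 1:10) {
    s <- random_dna(sample(20:90, 1))
    a <- translate_six_frames(s)
    b <- translate_six_frames(reverse_complement(s))
    for (o in 0:2)
      expect_identical(a[[paste0("r", o)]]$peptide,
                       b[[paste0("f", o)]]$peptide)
  }
})

test_that("stop-free regions give the closed-form f0 segment length", {
  # poly-(GCT) has no stop in any f frame; f0 yields floor(len/3) residues
  for (k in c(4, 10, 33)) {
    s <- strrep("GCT", k)
    fr <- translate_six_frames(s)
    expect_identical(nchar(paste(fr$f0$peptide, collapse = "")),
                     nchar(s) %/% 3L)
  }
})

test_that("build_sfdb deduplicates and filters by min_len", {
  g <- as_genome(c(c1 = paste0(strrep("T", 12),
                               "ATGAAATAG",   # MK in f0 at 13
                               strrep("T", 9),
                               "ATGAAATAG",   # MK again at 31
                               strrep("T", 12))))
  regions <- data.frame(gene_id = c("gA", "gB"), chrom = "c1",
                        start = c(13L, 31L), end = c(24L, 42L),
                        region_index = 1L, stringsAsFactors = FALSE)
  sfdb <- build_sfdb(regions, g, min_len = 2L)
  rec <- sfdb$records[sfdb$records$peptide == "MK", ]
  expect_equal(nrow(rec), 1L)
  expect_identical(rec$n_extra, 1L)
  prov <- sfdb$provenance[sfdb$provenance$peptide == "MK", ]
  expect_identical(sort(prov$gene_id), c("gA", "gB"))

  # a high threshold drops everything
  empty <- build_sfdb(regions, g, min_len = 7L)
  expect_equal(nrow(empty$records), 0L)

  # per-frame keys deduplicate within each frame only
  pf <- build_sfdb(regions, g, min_len = 2L, per_frame = TRUE)
  expect_true(all(!duplicated(paste(pf$records$frame, pf$records$peptide))))
})

test_that("SFDB FASTA round-trips with the header grammar", {
  g <- as_genome(c(c1 = "TTTTTTATGAAATAGTTTTTT"))
  regions <- data.frame(gene_id = "g1", chrom = "c1", start = 4L,
                        end = 18L, region_index = 1L,
                        stringsAsFactors = FALSE)
  sfdb <- build_sfdb(regions, g, min_len = 1L)
  out <- withr::local_tempfile(fileext = ".fa")
  write_sfdb_fasta(sfdb, out)
  lines <- readLines(out)
  expect_true(all(grepl("^>NAPTP\\|g1\\|c1:[0-9]+-[0-9]+\\|[fr][012]\\|\\d+$",
                        lines[startsWith(lines, ">")])))
  back <- read_sfdb_fasta(out)
  expect_identical(back$peptide, sfdb$records$peptide)
  expect_identical(back$start, sfdb$records$start)
  expect_identical(back$frame, sfdb$records$frame)
  expect_true(file.exists(paste0(out, ".provenance.tsv")))

  # empty SFDB -> empty file round-trips too
  e <- build_sfdb(regions[0, ], g)
  out2 <- withr::local_tempfile(fileext = ".fa")
  write_sfdb_fasta(e, out2)
  expect_equal(nrow(read_sfdb_fasta(out2)), 0L)
})

test_that("boundary-truncated segments are flagged in provenance", {
  # region with no stops at all: every segment lacks flanking stops
  g <- as_genome(c(c1 = strrep("GCT", 20)))
  regions <- data.frame(gene_id = "g1", chrom = "c1", start = 1L,
                        end = 60L, region_index = 1L,
                        stringsAsFactors = FALSE)
  sfdb <- build_sfdb(regions, g, min_len = 1L)
  expect_true(all(sfdb$provenance$boundary_truncated))
})
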