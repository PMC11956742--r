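test_that("make_genome is seed-deterministic with calibrated GC", {
  g1 <- make_genome(2L, 50000L, gc_fraction = 0.5, seed = 5L)
  g2 <- make_genome(2L, 50000L, gc_fraction = 0.5, seed = 5L)
  expect_identical(unclass(g1), unclass(g2))
  gc <- sum(strsplit(g1[["c1"]], "")[[1]] %in% c("G", "C")) /
    nchar(g1[["c1"]])
  expect_gt(gc, 0.47)
  expect_lt(gc, 0.53)
  expect_length(make_genome(0L, 100L, seed = 1L), 0L)
})

test_that("planted genes round-trip through their GTF lines", {
  pg <- plant_gene("c1", list(tA = rbind(c(100, 200), c(400, 500)),
                              tB = rbind(c(100, 250), c(450, 500))),
                   "-", "gX")
  path <- tmp_gtf(pg$gtf)
  back <- read_annotation(path)$gX
  expect_identical(back$gene_id, pg$gene$gene_id)
  expect_identical(back$strand, "-")
  expect_identical(c(back$start, back$end), c(pg$gene$start, pg$gene$end))
  expect_identical(
    lapply(back$transcripts, `[[`, "exons")[order(names(back$transcripts))],
    lapply(pg$gene$transcripts, `[[`, "exons"))
})

test_that("plant_peptide writes a recoverable cassette", {
  g <- make_genome(1L, 8000L, seed = 8L)
  gene <- simple_gene("gY", "c1", "+", rbind(c(500, 900), c(4000, 4400)))
  res <- plant_peptide(g, gene, 1L, "antisense", 1L, "FAFLTTAIL", 11L,
                       flank_up = "K")
  e <- res$entry
  expect_identical(e$minimal_length, 20L)  # 9 + 11, by construction
  expect_identical(e$strand, "-")
  expect_identical(e$frame, "r1")
  # the cassette sits inside the intron
  expect_gt(e$start, 900)
  expect_lt(e$end, 4000)
  # re-translating the span reproduces the peptide
  nt <- reverse_complement(substr(res$genome[["c1"]], e$start, e$end))
  expect_identical(oracle_translate(nt), "FAFLTTAIL")
  # and the pipeline recovers verdict/flanks/minimal length
  occ <- locate_occurrences("FAFLTTAIL", res$genome, gene_set(gene))
  expect_identical(classify_occurrences(occ), "unique_nonexon")
  ann <- annotate_occurrence("FAFLTTAIL", occ, gene_set(gene), res$genome)
  expect_identical(ann$orientation, "antisense")
  expect_identical(ann$flank_up, "K")
  expect_identical(ann$flank_down, e$flank_down)
  expect_identical(ann$minimal_length, 20L)

  # planting the same peptide twice yields a duplicate by construction
  gene2 <- simple_gene("gZ", "c1", "+", rbind(c(5000, 5200), c(7500, 7700)))
  res2 <- plant_peptide(res$genome, gene2, 1L, "sense", 0L, "FAFLTTAIL",
                        11L, expected_occurrences = 2L)
  occ2 <- locate_occurrences("FAFLTTAIL", res2$genome, gene_set(gene))
  expect_identical(classify_occurrences(occ2), "multiple_occurrence")

  # impossible placement errors out
  tiny <- simple_gene("gT", "c1", "+", rbind(c(100, 110), c(120, 130)))
  expect_error(plant_peptide(g, tiny, 1L, "sense", 0L, "FAFLTTAIL", 11L),
               "does not fit")
})

test_that("make_decoys embeds the requested peptides", {
  prot <- make_decoys(5L, 80L, include = c("WQPHRDE"), seed = 3L)
  expect_length(prot, 5L)
  expect_true(any(grepl("WQPHRDE", prot, fixed = TRUE)))
  expect_identical(prot, make_decoys(5L, 80L, include = c("WQPHRDE"),
                                     seed = 3L))
})

test_that("make_variants stays clear of avoided intervals", {
  g <- make_genome(1L, 5000L, seed = 4L)
  avoid <- data.frame(chrom = "c1", start = 2000L, end = 3000L)
  mv <- make_variants(g, n_snp = 20L, n_indel = 5L, seed = 6L,
                      avoid = avoid, n_filtered = 4L)
  v <- mv$variants
  expect_true(all(v$pos + nchar(v$ref) - 1L < 1900 | v$pos > 3100))
  expect_equal(sum(v$p_value >= 0.01), 4L)
  # significant records alone produce the expected genome
  sig <- v[v$p_value < 0.01, ]
  expect_identical(unclass(naive_apply_variants(g, sig)),
                   unclass(mv$expected))
})

test_that("scenario generation is bit-reproducible and self-consistent", {
  a <- simulate_scenario("basic", seed = 17L, chrom_length = 30000L)
  b <- simulate_scenario("basic", seed = 17L, chrom_length = 30000L)
  expect_identical(unclass(a$genome), unclass(b$genome))
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$variants, b$variants)
  # manifest verdicts cover the plants plus one absent candidate
  verdicts <- vapply(a$manifest$peptides, `[[`, "", "verdict")
  expect_identical(sort(unique(verdicts)),
                   c("absent", "unique_nonexon"))
  # emitted files parse back into the in-memory objects
  dir <- withr::local_tempdir()
  c_ <- simulate_scenario("basic", seed = 17L, out_dir = dir,
                          chrom_length = 30000L)
  expect_identical(unclass(read_genome(c_$paths$genome)),
                   unclass(a$genome))
  expect_identical(names(read_annotation(c_$paths$gtf)), names(a$genes))
  m <- jsonlite::read_json(c_$paths$manifest)
  expect_identical(m$scenario, "basic")
  expect_length(m$peptides, length(a$manifest$peptides))
})
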