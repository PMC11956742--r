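#' Generate a complete synthetic test scene
#'
#' Builds a deterministic toy world — genome, gene annotation, planted
#' peptide cassettes, variants, decoy proteome and a candidate peptide
#' list — together with a ground-truth manifest, so the whole pipeline
#' (genome editing, intron extraction, six-frame database, candidate
#' verification) can be exercised without any external data.
#'
#' Scenarios: `basic` plants two unique intronic peptides (one sense,
#' one antisense); `funnel` covers every verdict of the verification
#' funnel (unique sense/antisense, a duplicated plant, an exonic plant,
#' a proteome-known plant and an absent candidate); `antisense` plants
#' peptides on the opposite strand of four genes across frames, plus a
#' sense control.  Variants (SNPs and indels) are drawn outside gene
#' spans so planted cassettes survive editing verbatim; manifest frame
#' labels and spans are stated in sample coordinates/reference
#' coordinates respectively, accounting for upstream indel shifts.
#'
#' @param scenario `"basic"`, `"funnel"` or `"antisense"`.
#' @param seed RNG seed (all randomness derives from it).
#' @param out_dir optional directory: when given, `genome.fa`,
#'   `genes.gtf`, `variants.vcf`, `proteome.fa`, `peptides.tsv` and
#'   `manifest.json` are written there.
#' @param chrom_length chromosome length (default 100 kb, two
#'   chromosomes).
#' @return list with `genome` (reference incl. plants), `genes`
#'   (`GeneSet`), `gtf` (lines), `variants` (data.frame incl.
#'   above-threshold records), `expected_sample` (naive-edited
#'   `GenomeSequence`), `proteome`, `candidates` (character vector) and
#'   `manifest` (list; one `peptides` entry per candidate with the
#'   intended verdict and, for plants, orientation/frame/span/flanks/
#'   minimal length), plus `paths` when `out_dir` was given.
#' @export
simulate_scenario <- function(scenario = c("basic", "funnel", "antisense"),
                              seed = 1L, out_dir = NULL,
                              chrom_length = 100000L) {
  scenario <- match.arg(scenario)
  genome <- make_genome(2L, chrom_length, gc_fraction = 0.41, seed = seed)
  sc <- function(x) round(x / 100000 * chrom_length)
  gdefs <- list(
    plant_gene("c1", rbind(c(sc(5000), sc(6500)), c(sc(9000), sc(10500)),
                           c(sc(14000), sc(15500)), c(sc(18500), sc(20000))),
               "+", "g1"),
    plant_gene("c1", rbind(c(sc(30000), sc(31000)), c(sc(35000), sc(36000)),
                           c(sc(40000), sc(41000)), c(sc(44000), sc(45000))),
               "-", "g2"),
    plant_gene("c1", list(g3.t1 = rbind(c(sc(60000), sc(61000)),
                                        c(sc(65000), sc(66000)),
                                        c(sc(70000), sc(75000))),
                          g3.t2 = rbind(c(sc(60000), sc(62000)),
                                        c(sc(68000), sc(69000)),
                                        c(sc(70000), sc(75000)))),
               "+", "g3"),
    plant_gene("c2", rbind(c(sc(10000), sc(11000)), c(sc(15000), sc(16000)),
                           c(sc(20000), sc(25000))), "+", "g4"),
    plant_gene("c2", rbind(c(sc(40000), sc(42000)), c(sc(46000), sc(48000)),
                           c(sc(52000), sc(55000))), "-", "g5"))
  genes <- lapply(gdefs, `[[`, "gene")
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  genes <- structure(genes, class = "GeneSet")
  gtf <- unlist(lapply(gdefs, `[[`, "gtf"))

  plants <- switch(scenario,
    basic = list(
      list(pep = "MVDPETRAYK", gene = "g1", region = 1L, ori = "sense",
           fo = 0L, pad = 15L, flank = "R", verdict = "unique_nonexon"),
      list(pep = "FAWNTESQGY", gene = "g2", region = 2L, ori = "antisense",
           fo = 1L, pad = 30L, flank = "K", verdict = "unique_nonexon")),
    funnel = list(
      list(pep = "MVDPETRAYK", gene = "g1", region = 1L, ori = "sense",
           fo = 0L, pad = 12L, flank = "R", verdict = "unique_nonexon"),
      list(pep = "WHDYNQCTVF", gene = "g4", region = 2L, ori = "antisense",
           fo = 2L, pad = 20L, flank = "F", verdict = "unique_nonexon"),
      list(pep = "GQSTHNWEVD", gene = "g1", region = 2L, ori = "sense",
           fo = 1L, pad = 10L, verdict = "multiple_occurrence",
           flank = "R", dup = list(gene = "g5", region = 1L,
                                   ori = "antisense", fo = 0L)),
      list(pep = "YTDHSNQAGW", gene = "g3", region = 0L, ori = "sense",
           fo = 0L, pad = 10L, flank = "K", verdict = "exonic",
           where = "exon", exon = 4L),
      list(pep = "CEDQWHNTYV", gene = "g2", region = 1L, ori = "sense",
           fo = 0L, pad = 10L, flank = "R", verdict = "known_protein")),
    antisense = list(
      list(pep = "MVDPETRAYK", gene = "g1", region = 3L, ori = "antisense",
           fo = 0L, pad = 11L, flank = "R", verdict = "unique_nonexon"),
      list(pep = "FAWNTESQGY", gene = "g3", region = 1L, ori = "antisense",
           fo = 1L, pad = 25L, flank = "K", verdict = "unique_nonexon"),
      list(pep = "WHDYNQCTVF", gene = "g4", region = 1L, ori = "antisense",
           fo = 2L, pad = 40L, flank = "F", verdict = "unique_nonexon"),
      list(pep = "GQSTHNWEVD", gene = "g5", region = 2L, ori = "antisense",
           fo = 0L, pad = 60L, flank = "R", verdict = "unique_nonexon"),
      list(pep = "CEDQWHNTYV", gene = "g2", region = 3L, ori = "sense",
           fo = 1L, pad = 18L, flank = "K", verdict = "unique_nonexon")))

  entries <- list()
  for (pl in plants) {
    where <- if (!is.null(pl$where)) pl$where else "intron"
    ridx <- if (where == "exon") pl$exon else pl$region
    res <- plant_peptide(genome, genes[[pl$gene]], ridx, pl$ori, pl$fo,
                         pl$pep, pl$pad, flank_up = pl$flank, where = where)
    genome <- res$genome
    entry <- res$entry
    entry$verdict <- pl$verdict
    if (!is.null(pl$dup)) {
      res2 <- plant_peptide(genome, genes[[pl$dup$gene]], pl$dup$region,
                            pl$dup$ori, pl$dup$fo, pl$pep, pl$pad,
                            flank_up = pl$flank,
                            expected_occurrences = 2L)
      genome <- res2$genome
    }
    entries[[length(entries) + 1L]] <- entry
  }

  # an absent candidate: on the list, never planted anywhere
  absent <- "WYHDNPQTVK"
  stopifnot(.count_occurrences(absent, genome) == 0L)
  entries[[length(entries) + 1L]] <- list(
    sequence = absent, gene = NA, chrom = NA, orientation = NA,
    strand = NA, frame = NA, start = NA, end = NA, flank_up = NA,
    flank_down = NA, minimal_length = NA, where = NA, verdict = "absent")

  known <- vapply(Filter(function(e) e$verdict == "known_protein", entries),
                  `[[`, "", "sequence")
  proteome <- make_decoys(20L, 150L, include = known, seed = seed + 1L)

  spans <- .gene_spans(genes)
  mv <- make_variants(genome,
                      n_snp = if (scenario == "basic") 30L else 20L,
                      n_indel = if (scenario == "basic") 10L else 6L,
                      seed = seed + 2L, avoid = spans, n_filtered = 6L)

  # restate frames in sample coordinates: indels upstream of a cassette
  # shift its position (and the chromosome length) in the edited genome
  sig <- mv$variants[mv$variants$p_value < 0.01, , drop = FALSE]
  delta <- nchar(sig$alt) - nchar(sig$ref)
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    if (is.na(e$gene) || e$verdict == "known_protein") next
    before <- sig$chrom == e$chrom &
      (sig$pos + nchar(sig$ref) - 1L) < e$start
    shift <- sum(delta[before])
    Ls <- nchar(mv$expected[[e$chrom]])
    entries[[i]]$frame <- .frame_label_for(e$start + shift, e$end + shift,
                                           e$strand, Ls)
  }

  # generator self-check: occurrence counts on the expected (naive-edited)
  # sample genome must agree with every intended verdict
  idx <- .six_frame_index(mv$expected)
  for (e in entries) {
    n <- .count_occurrences(e$sequence, mv$expected, index = idx)
    want <- switch(e$verdict, absent = 0L, multiple_occurrence = 2L, 1L)
    if (n != want)
      stop("synthfix self-check failed for ", e$sequence, ": ", n,
           " occurrence(s), expected ", want)
  }

  candidates <- vapply(entries, `[[`, "", "sequence")
  manifest <- list(scenario = scenario, seed = seed,
                   chrom_length = chrom_length,
                   n_chrom = 2L, peptides = entries)
  out <- list(genome = genome, genes = genes, gtf = gtf,
              variants = mv$variants, expected_sample = mv$expected,
              proteome = proteome, candidates = candidates,
              manifest = manifest)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- list(
      genome = file.path(out_dir, "genome.fa"),
      gtf = file.path(out_dir, "genes.gtf"),
      variants = file.path(out_dir, "variants.vcf"),
      proteome = file.path(out_dir, "proteome.fa"),
      peptides = file.path(out_dir, "peptides.tsv"),
      manifest = file.path(out_dir, "manifest.json"))
    write_genome(genome, paths$genome)
    writeLines(gtf, paths$gtf)
    write_variants_vcf(mv$variants, paths$variants)
    pset <- Biostrings::AAStringSet(proteome)
    Biostrings::writeXStringSet(pset, paths$proteome, width = 60L)
    utils::write.table(
      data.frame(sequence = candidates, sample = "synthetic",
                 stringsAsFactors = FALSE),
      paths$peptides, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE, na = "null")
    out$paths <- paths
  }
  out
}
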