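# small in-code fixture builders shared across test files

tmp_fasta <- function(records, width = 60L) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  lines <- character(0)
  for (nm in names(records)) {
    s <- records[[nm]]
    starts <- seq(1, nchar(s), by = width)
    lines <- c(lines, paste0(">", nm),
               substring(s, starts, pmin(starts + width - 1, nchar(s))))
  }
  writeLines(lines, path)
  path
}

tmp_gtf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gtf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

gtf_exon <- function(chrom, start, end, strand, gene, tx)
  sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
          chrom, start, end, strand, gene, tx)

tmp_vcf <- function(df) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  naptp::write_variants_vcf(df, path)
  path
}

# one-gene GeneSet built directly (bypassing GTF) for unit tests
gene_set <- function(...) {
  genes <- list(...)
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  structure(genes, class = "GeneSet")
}

simple_gene <- function(gene_id, chrom, strand, exons)
  naptp::plant_gene(chrom, exons, strand, gene_id)$gene

# bare genome from named character vector
as_genome <- function(x) structure(x, class = "GenomeSequence")
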