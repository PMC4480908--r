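# Small in-code fixtures shared across test files.

write_tmp_gtf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gtf", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

gtf_gene_line <- function(gene_id, chrom, start1, end1, strand) {
  sprintf('%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s";',
          chrom, start1, end1, strand, gene_id, gene_id)
}

write_tmp_bed <- function(df) {
  path <- withr::local_tempfile(fileext = ".bed", .local_envir = parent.frame())
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  path
}

toy_gene_models <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tss = c(10000, 60000, 500),
    cds_end = c(15000, 52000, 3000),
    stringsAsFactors = FALSE
  )
}

# A table of random 2x2 contingency tables with all expected cells >= 5,
# generated under independence with random margins.
random_tables <- function(n, seed) {
  set.seed(seed)
  out <- vector("list", n)
  i <- 0L
  while (i < n) {
    N <- sample(200:2000, 1)
    pa <- runif(1, 0.1, 0.5)
    pb <- runif(1, 0.1, 0.5)
    a <- rbinom(1, N, pa * pb)
    b <- rbinom(1, N, pa * (1 - pb))
    cc <- rbinom(1, N, (1 - pa) * pb)
    d <- N - a - b - cc
    if (d < 0 || a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) next
    expected <- outer(c(a + b, cc + d), c(a + cc, b + d)) / N
    if (any(expected < 5)) next
    i <- i + 1L
    out[[i]] <- contingency_table(a, b, cc, d)
  }
  out
}
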