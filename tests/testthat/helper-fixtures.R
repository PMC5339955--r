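# Shared fixtures and independent oracles for the test suite.

monarda_records <- function() {
  read_isolate_table(endodiv_example("monarda_isolates.tsv"))
}

monarda_matrix <- function(mode = "label") {
  build_abundance_matrix(monarda_records(), mode = mode)
}

# The three tissue count vectors of the bundled survey.
leaf_counts <- rep(1L, 18)
root_counts <- c(1L, 1L)
flower_counts <- c(3L, 1L, 1L, 1L, 1L, 1L)

# Independent bisection oracle for Fisher's log-series alpha (kept free of
# the package's uniroot/Newton path).
fisher_alpha_bisect <- function(S, N, lo = 1e-6, hi = 1e6) {
  f <- function(a) a * log(1 + N / a) - S
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Random abundance vector with at least 2 positive taxa.
random_counts <- function(max_s = 12, max_n = 30) {
  s <- sample(2:max_s, 1)
  as.integer(sample(1:max_n, s, replace = TRUE))
}

# Write a small table to a temp TSV and return the path.
write_tsv_fixture <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  path
}
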