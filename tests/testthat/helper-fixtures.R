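# fixtures are built in code at test time; nothing binary ships with the tests

write_sumstats_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# deterministic three-SNP panel: SNP2 is strongly correlated with SNP1,
# SNP3 nearly uncorrelated with both; all within one clumping window
three_snp_panel <- function(n = 400, seed = 42) {
  set.seed(seed)
  g1 <- rbinom(n, 2, 0.4)
  flip <- runif(n) < 0.15
  g2 <- ifelse(flip, rbinom(n, 2, 0.4), g1)      # r2(1,2) well above 0.25
  g3 <- rbinom(n, 2, 0.3)                        # r2(.,3) near zero
  genotype_panel(cbind(g1, g2, g3),
                 variant_id = c("s1", "s2", "s3"),
                 chrom = c("1", "1", "1"), pos = c(1e5, 1.5e5, 2e5))
}

pairwise_r2 <- function(panel) {
  p <- standardize(panel)
  (crossprod(p$dosage) / nrow(p$dosage))^2
}

# small quantitative study reused by several test files
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- architecture_spec(n_snps = 1000, fraction_causal = 0.05,
                                h2 = 0.5)
      cache <<- simulate_independent_study(spec, n_train = 500,
                                           n_test = 500, seed = 99)
    }
    cache
  }
})
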