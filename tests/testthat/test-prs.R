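test_that("standardization uses the population-sd convention", {
  p <- genotype_panel(matrix(c(0, 1, 2), ncol = 1), "s1")
  s <- standardize(p)
  expect_equal(s$dosage[, 1], c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(s$dosage[, 1], 4), c(-1.2247, 0, 1.2247))
})

test_that("zero-variance columns become zero and are flagged", {
  p <- genotype_panel(cbind(a = c(1, 1, 1), b = c(0, 1, 2)), c("a", "b"))
  s <- standardize(p)
  expect_true(s$zero_variance[1])
  expect_false(s$zero_variance[2])
  expect_equal(s$dosage[, 1], c(0, 0, 0))
})

test_that("standardization mean-imputes missing dosages first", {
  p <- genotype_panel(matrix(c(0, NA, 2, 2), ncol = 1), "s1")
  s <- standardize(p)
  # NA -> mean(0,2,2) = 4/3; the imputed entry sits at the column mean
  expect_equal(s$dosage[2, 1], 0)
  expect_equal(mean(s$dosage[, 1]), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(s$dosage[, 1]^2)), 1, tolerance = 1e-12)
})

test_that("standardize is idempotent", {
  p <- standardize(three_snp_panel())
  q <- standardize(p)
  expect_identical(p$dosage, q$dosage)
})

test_that("the threshold grid is the fixed 18-value ascending sequence", {
  g <- threshold_grid()
  expect_length(g, 18L)
  expect_identical(g[18], 1)
  expect_true(all(diff(g) > 0))
  expect_true(all(c(1e-5, 5e-3, 0.05, 0.5) %in% g))
})

test_that("greedy clumping keeps the most significant of a correlated pair", {
  panel <- three_snp_panel()
  r2 <- pairwise_r2(panel)
  expect_gt(r2[1, 2], 0.25)   # fixture built to prune s2 against s1
  expect_lt(r2[1, 3], 0.25)
  expect_lt(r2[2, 3], 0.25)
  ss <- sumstats(c("s1", "s2", "s3"), chrom = "1",
                 pos = c(1e5, 1.5e5, 2e5),
                 beta = c(0.5, 0.4, 0.3), se = 0.08,
                 p = c(1e-8, 1e-4, 1e-3), n = 400)
  ck <- clump(ss, panel)
  expect_setequal(ck$kept_ids, c("s1", "s3"))
  expect_identical(ck$removed, c(s2 = "s1"))
})

test_that("uncorrelated or distant variants are never pruned", {
  set.seed(31)
  X <- matrix(rbinom(200 * 6, 2, 0.3), 200)
  near <- genotype_panel(X, paste0("v", 1:6), chrom = "1",
                         pos = seq(1e5, by = 2e4, length.out = 6))
  ss <- sumstats(paste0("v", 1:6), chrom = "1", pos = near$pos,
                 beta = rnorm(6), se = 1, p = runif(6), n = 200)
  ck <- clump(ss, near)
  expect_setequal(ck$kept_ids, paste0("v", 1:6))

  # a strongly correlated pair outside the window is kept too
  far <- genotype_panel(cbind(X[, 1], X[, 1]), c("w1", "w2"), chrom = "1",
                        pos = c(1e5, 5e5))
  ss2 <- sumstats(c("w1", "w2"), chrom = "1", pos = far$pos,
                  beta = c(1, 1), se = 0.1, p = c(1e-4, 1e-3), n = 200)
  ck2 <- clump(ss2, far, window_kb = 250)
  expect_setequal(ck2$kept_ids, c("w1", "w2"))
})

test_that("clumping is invariant to input row order", {
  panel <- three_snp_panel()
  ss <- sumstats(c("s1", "s2", "s3"), chrom = "1",
                 pos = c(1e5, 1.5e5, 2e5),
                 beta = c(0.5, 0.4, 0.3), se = 0.08,
                 p = c(1e-8, 1e-4, 1e-3), n = 400)
  shuffled <- ss[c(3, 1, 2), ]
  class(shuffled) <- class(ss)
  expect_identical(clump(shuffled, panel)$kept_ids,
                   clump(ss, panel)$kept_ids)
})

test_that("no kept pair within a window exceeds the r2 threshold (brute force)", {
  spec <- architecture_spec(n_snps = 120, fraction_causal = 0.1, h2 = 0.4)
  st <- simulate_independent_study(spec, n_train = 300, seed = 55,
                                   ld = list(rho = 0.9, block_size = 6))
  ck <- clump(st$sumstats, st$train_panel)
  expect_lt(length(ck$kept_ids), 120L)  # LD blocks force real pruning
  expect_setequal(c(ck$kept_ids, names(ck$removed)), st$sumstats$variant_id)
  kept <- match(ck$kept_ids, st$train_panel$variant_id)
  X <- st$train_panel$dosage
  pos <- st$train_panel$pos[kept]
  chrom <- st$train_panel$chrom[kept]
  for (i in seq_along(kept)) {
    for (j in seq_len(i - 1L)) {
      if (chrom[i] == chrom[j] && abs(pos[i] - pos[j]) <= 250e3) {
        r2 <- (mean(X[, kept[i]] * X[, kept[j]]))^2
        expect_lte(r2, 0.25)
      }
    }
  }
})

test_that("with r2 = 1 nothing can be pruned", {
  panel <- three_snp_panel()
  ss <- sumstats(c("s1", "s2", "s3"), chrom = "1",
                 pos = c(1e5, 1.5e5, 2e5), beta = 1, se = 1,
                 p = c(0.1, 0.2, 0.3), n = 400)
  ck <- clump(ss, panel, r2 = 1)
  expect_setequal(ck$kept_ids, c("s1", "s2", "s3"))
})

test_that("scores are the weighted sum of standardized dosages", {
  X <- matrix(c(2, 1, 0,
                2, 2, 0), ncol = 2)  # two variants, three individuals
  panel <- genotype_panel(X, c("v1", "v2"))
  panel <- standardize(panel)
  eff <- structure(data.frame(variant_id = c("v1", "v2"),
                              allele_effect = NA, method = "standard",
                              weight = c(0.5, -0.2)),
                   class = c("effect_estimates", "data.frame"))
  prof <- prs_score(panel, eff)
  expect_equal(prof$score, as.numeric(panel$dosage %*% c(0.5, -0.2)))
  expect_equal(attr(prof, "n_variants_used"), 2L)

  # hand example on already-standardized values
  direct <- 0.5 * 1 + (-0.2) * 2
  p2 <- genotype_panel(matrix(0, 1, 2), c("a", "b"))
  p2 <- standardize(p2)
  p2$dosage <- matrix(c(1, 2), 1)  # inject standardized genotype directly
  eff2 <- structure(data.frame(variant_id = c("a", "b"), allele_effect = NA,
                               method = "standard", weight = c(0.5, -0.2)),
                    class = c("effect_estimates", "data.frame"))
  expect_equal(prs_score(p2, eff2)$score, direct)
  expect_equal(direct, 0.1)
})

test_that("thresholded variant sets are nested and scores respect them", {
  st <- small_study()
  eff <- corrected_effects(st$sumstats, "standard")
  used <- vapply(c(1e-3, 0.05, 0.5, 1), function(t) {
    attr(prs_score(st$test_panel, eff, stats = st$sumstats,
                   p_threshold = t), "n_variants_used")
  }, integer(1))
  expect_true(all(diff(used) >= 0))
  expect_equal(used[4], nrow(st$sumstats))
})

test_that("an empty threshold set yields zero scores and a warning", {
  st <- small_study()
  eff <- corrected_effects(st$sumstats, "standard")
  ss <- st$sumstats
  ss$p <- pmax(ss$p, 0.5)
  expect_warning(
    prof <- prs_score(st$test_panel, eff, stats = ss, p_threshold = 1e-9),
    "no variants")
  expect_true(all(prof$score == 0))
  expect_equal(attr(prof, "n_variants_used"), 0L)
})

test_that("all-zero weights give all-zero scores", {
  st <- small_study()
  eff <- corrected_effects(st$sumstats, "standard")
  eff$weight[] <- 0
  prof <- prs_score(st$test_panel, eff)
  expect_true(all(prof$score == 0))
})

test_that("panel TSV round trip preserves dosages and metadata", {
  p <- three_snp_panel(n = 25)
  prefix <- tempfile("panel")
  write_panel(p, prefix)
  q <- read_panel(prefix)
  expect_equal(q$dosage, p$dosage, ignore_attr = TRUE)
  expect_identical(q$variant_id, p$variant_id)
  expect_identical(q$pos, p$pos)
})

test_that("the PLINK .bed reader decodes the two-bit codes", {
  prefix <- tempfile("plink")
  # 4 individuals, 2 variants; codes packed LSB-first per byte:
  # variant 1: hom-A1, het, hom-A2, missing -> dosages 2, 1, 0, NA
  # variant 2: het, het, hom-A1, hom-A2    -> dosages 1, 1, 2, 0
  v1 <- as.raw(0x00 + 0x02 * 4 + 0x03 * 16 + 0x01 * 64)
  v2 <- as.raw(0x02 + 0x02 * 4 + 0x00 * 16 + 0x03 * 64)
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), v1, v2),
           paste0(prefix, ".bed"))
  writeLines(c("1\trs1\t0\t1000\tA\tG", "1\trs2\t0\t2000\tC\tT"),
             paste0(prefix, ".bim"))
  writeLines(sprintf("F%d I%d 0 0 0 -9", 1:4, 1:4), paste0(prefix, ".fam"))
  panel <- read_plink(prefix)
  expect_equal(panel$dosage[, 1], c(2, 1, 0, NA))
  expect_equal(panel$dosage[, 2], c(1, 1, 2, 0))
  expect_identical(panel$variant_id, c("rs1", "rs2"))
  expect_identical(attr(panel, "allele_effect"), c("A", "C"))
  expect_error(read_plink(tempfile()), "not found")
})
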