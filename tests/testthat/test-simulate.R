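test_that("sparse architecture puts exactly the stated variance on each hit", {
  spec <- architecture_spec(n_snps = 5000, model = "sparse_large_effect",
                            n_large = 10, vg_per_large = 0.006)
  beta <- simulate_effects(spec, seed = 1)
  nz <- which(beta != 0)
  expect_length(nz, 10L)
  expect_equal(unname(beta[nz]^2), rep(0.006, 10))
  expect_identical(sort(nz), as.integer(attr(beta, "causal")))
})

test_that("laplace mixture rescales per-variant variances to h2 exactly", {
  spec <- architecture_spec(n_snps = 8000, fraction_causal = 0.01,
                            h2 = 0.3, model = "laplace_mixture",
                            h2_large_fraction = 0.25)
  beta <- simulate_effects(spec, seed = 2)
  expect_equal(sum(beta^2), 0.3, tolerance = 1e-10)
  # pure-Laplace limit: all of h2 carried by the small-effect set
  spec0 <- architecture_spec(n_snps = 8000, fraction_causal = 0.01,
                             h2 = 0.3, model = "laplace_mixture",
                             h2_large_fraction = 0)
  beta0 <- simulate_effects(spec0, seed = 3)
  expect_equal(sum(beta0^2), 0.3, tolerance = 1e-10)
  expect_length(attr(beta0, "causal"), 80L)
})

test_that("infinitesimal effects have variance h2/M and sum to h2", {
  spec <- architecture_spec(n_snps = 50000, fraction_causal = 1, h2 = 0.2)
  beta <- simulate_effects(spec, seed = 4)
  expect_equal(sum(beta^2), 0.2, tolerance = 1e-12)
  expect_equal(var(beta), 0.2 / 50000, tolerance = 0.1)  # 10% relative
})

test_that("phenotype noise follows the stated variance decomposition", {
  set.seed(5)
  panel <- standardize(genotype_panel(
    matrix(rbinom(20000 * 50, 2, 0.3), 20000), paste0("v", 1:50)))
  # null architecture: the phenotype is pure unit-variance noise
  y0 <- phenotype_from_genotypes(panel, rep(0, 50), h2 = 0, seed = 6)
  expect_equal(var(y0), 1, tolerance = 0.05)
  # with signal, squared correlation with the genetic value recovers h2
  beta <- rnorm(50); beta <- beta * sqrt(0.5 / sum(beta^2))
  y <- phenotype_from_genotypes(panel, beta, h2 = 0.5, seed = 7)
  expect_equal(cor(y, attr(y, "genetic"))^2, 0.5, tolerance = 0.03)
  expect_error(phenotype_from_genotypes(panel, beta, h2 = 1), "h2")
})

test_that("studies are bit-identical under a fixed master seed", {
  spec <- architecture_spec(n_snps = 300, fraction_causal = 0.1, h2 = 0.4)
  s1 <- simulate_independent_study(spec, 150, 80, seed = 12)
  s2 <- simulate_independent_study(spec, 150, 80, seed = 12)
  expect_identical(s1$train_panel$dosage, s2$train_panel$dosage)
  expect_identical(s1$y_test, s2$y_test)
  expect_identical(s1$sumstats$z, s2$sumstats$z)
  s3 <- simulate_independent_study(spec, 150, 80, seed = 13)
  expect_false(identical(s1$sumstats$z, s3$sumstats$z))
})

test_that("the realized genetic variance matches the target heritability", {
  spec <- architecture_spec(n_snps = 20000, fraction_causal = 0.025,
                            h2 = 0.55)
  st <- simulate_independent_study(spec, n_train = 5000, n_test = 50,
                                   seed = 14)
  g <- attr(st$y_train, "genetic")
  expect_gt(var(g), 0.50)
  expect_lt(var(g), 0.60)
})

test_that("the association scan flags perfect and null associations", {
  spec <- architecture_spec(n_snps = 400, fraction_causal = 0.05, h2 = 0.5)
  st <- simulate_independent_study(spec, 300, 50, seed = 15)
  panel <- st$train_panel
  y <- panel$dosage[, 7]  # phenotype IS one standardized SNP
  ss <- gwas_scan(panel, y)
  expect_equal(which.max(abs(ss$z)), 7L)
  expect_lt(ss$p[7], 1e-100)
  expect_equal(unique(ss$n), 300L)

  set.seed(16)
  ssp <- gwas_scan(panel, sample(st$y_train))  # permuted: null calibration
  expect_lt(abs(mean(ssp$p < 0.05) - 0.05), 0.03)
})

test_that("zero-variance variants yield z = 0, p = 1 and a flag", {
  X <- cbind(rep(1, 40), rbinom(40, 2, 0.4))
  panel <- standardize(genotype_panel(X, c("mono", "poly")))
  ss <- gwas_scan(panel, rnorm(40))
  expect_equal(ss$z[1], 0)
  expect_equal(ss$p[1], 1)
  expect_true(attr(ss, "zero_variance")[1])
})

test_that("liability thresholding realises the stated prevalence", {
  spec <- architecture_spec(n_snps = 200, fraction_causal = 0.25, h2 = 0.4,
                            prevalence = 0.45)
  beta <- simulate_effects(spec, seed = 17)
  set.seed(18)
  panel <- standardize(genotype_panel(
    tweedieprs:::sim_dosages_cpp(50000, runif(200, 0.05, 0.5)),
    paste0("v", 1:200), validate = FALSE), in_place = TRUE)
  y <- phenotype_from_genotypes(panel, beta, h2 = 0.4, seed = 19)
  expect_equal(mean(y > qnorm(1 - 0.45)), 0.45, tolerance = 0.01)
})

test_that("case-control sampling balances both splits exactly", {
  spec <- architecture_spec(n_snps = 250, fraction_causal = 0.1, h2 = 0.5,
                            prevalence = 0.45)
  st <- simulate_independent_study(spec, n_train = 200, n_test = 100,
                                   binary = TRUE, seed = 20)
  expect_equal(sum(st$status_train == 1), 100L)
  expect_equal(sum(st$status_train == 0), 100L)
  expect_equal(sum(st$status_test == 1), 50L)
  expect_equal(sum(st$status_test == 0), 50L)
  # cases sit above controls on the liability scale
  expect_gt(mean(st$y_train[st$status_train == 1]),
            mean(st$y_train[st$status_train == 0]))
})

test_that("a pure-noise architecture carries no predictive signal", {
  spec <- architecture_spec(n_snps = 300, fraction_causal = 0.1, h2 = 0)
  st <- simulate_independent_study(spec, 400, 400, seed = 21)
  s <- as.numeric(st$test_panel$dosage %*% st$true_beta)
  expect_true(all(st$true_beta == 0))
  expect_true(all(s == 0))
  lf <- fit_locfdr(st$sumstats$z)  # only 300 markers: pi0 is noisy here
  expect_gte(lf$pi0, 0.8)
})

test_that("logistic and linear scans agree on strong associations", {
  spec <- architecture_spec(n_snps = 40, fraction_causal = 0.5, h2 = 0.5,
                            prevalence = 0.45)
  st <- simulate_independent_study(spec, 300, 60, binary = TRUE, seed = 22)
  lin <- st$sumstats
  logi <- gwas_scan(st$train_panel, st$status_train, family = "logistic")
  strong <- abs(lin$z) > 3
  expect_gt(sum(strong), 0)
  expect_equal(sign(logi$z[strong]), sign(lin$z[strong]))
  expect_gt(cor(logi$z, lin$z), 0.98)
})

test_that("block-LD panels show decaying within-block correlation", {
  spec <- architecture_spec(n_snps = 60, fraction_causal = 0.2, h2 = 0.4)
  st <- simulate_independent_study(spec, 600, 60, seed = 23,
                                   ld = list(rho = 0.9, block_size = 6))
  X <- st$train_panel$dosage
  r_adj <- mean(sapply(seq(1, 49, by = 6), function(j)
    cor(X[, j], X[, j + 1])))
  r_far <- mean(sapply(seq(1, 49, by = 6), function(j)
    cor(X[, j], X[, j + 5])))
  expect_gt(r_adj, 0.5)
  expect_lt(abs(r_far), r_adj)
})
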