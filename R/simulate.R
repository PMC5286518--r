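#' Specify a genetic architecture for simulation
#'
#' Bundles the parameters of the three architecture families used by the
#' simulator:
#' \describe{
#'   \item{`gaussian_infinitesimal`}{a fraction `fraction_causal` of the
#'     `n_snps` markers is causal with effects `N(0, h2/M_causal)`,
#'     rescaled so the per-variant variances sum exactly to `h2`.}
#'   \item{`sparse_large_effect`}{`n_large` markers each explain exactly
#'     `vg_per_large` of the variance (realized heritability is
#'     `n_large * vg_per_large`); all other markers are null.}
#'   \item{`laplace_mixture`}{small effects `Laplace(laplace_mu, laplace_b)`
#'     on the causal fraction, rescaled to carry
#'     `(1 - h2_large_fraction) * h2`; plus large-effect markers whose
#'     per-variant variance is drawn `U(vg_large_low, vg_large_high)` until
#'     their total reaches `h2_large_fraction * h2` (then rescaled to hit
#'     it exactly).}
#' }
#'
#' @param n_snps number of markers `M`.
#' @param fraction_causal fraction of causal markers in (0, 1].
#' @param h2 total heritability in `[0, 1)`.
#' @param model architecture family (see Details).
#' @param n_large,vg_per_large sparse model: count of large-effect markers
#'   and variance explained by each.
#' @param laplace_mu,laplace_b location and scale of the Laplace small
#'   effects.
#' @param vg_large_low,vg_large_high uniform interval for the large-effect
#'   per-variant variance in the mixture model (defaults 0.4%-0.8%).
#' @param h2_large_fraction share of `h2` carried by the large-effect set
#'   in the mixture model.
#' @param maf_low lower bound of the uniform minor-allele-frequency
#'   distribution (MAF ~ U(maf_low, 0.5)).
#' @param prevalence disease prevalence for the liability-threshold binary
#'   design.
#' @return A validated list of class `"architecture_spec"`.
#' @export
architecture_spec <- function(n_snps = 20000L, fraction_causal = 0.025,
                              h2 = 0.55,
                              model = c("gaussian_infinitesimal",
                                        "sparse_large_effect",
                                        "laplace_mixture"),
                              n_large = 10L, vg_per_large = 0.006,
                              laplace_mu = 0, laplace_b = 1,
                              vg_large_low = 0.004, vg_large_high = 0.008,
                              h2_large_fraction = 0.25,
                              maf_low = 0.05, prevalence = 0.45) {
  model <- match.arg(model)
  if (!(fraction_causal > 0 && fraction_causal <= 1))
    stop("fraction_causal must lie in (0, 1]")
  if (!(h2 >= 0 && h2 < 1)) stop("h2 must lie in [0, 1)")
  if (!(maf_low >= 0 && maf_low < 0.5)) stop("maf_low must lie in [0, 0.5)")
  if (!(prevalence > 0 && prevalence < 1)) stop("prevalence must lie in (0, 1)")
  if (model == "sparse_large_effect" && n_large * vg_per_large >= 1)
    stop("sparse model explains >= 100% variance (n_large * vg_per_large)")
  if (!(h2_large_fraction >= 0 && h2_large_fraction <= 1))
    stop("h2_large_fraction must lie in [0, 1]")
  structure(list(n_snps = as.integer(n_snps),
                 fraction_causal = fraction_causal, h2 = h2, model = model,
                 n_large = as.integer(n_large), vg_per_large = vg_per_large,
                 laplace_mu = laplace_mu, laplace_b = laplace_b,
                 vg_large_low = vg_large_low, vg_large_high = vg_large_high,
                 h2_large_fraction = h2_large_fraction,
                 maf_low = maf_low, prevalence = prevalence),
            class = "architecture_spec")
}

# difference of two exponentials is Laplace(0, b)
rlaplace <- function(n, mu, b) {
  mu + rexp(n, rate = 1 / b) - rexp(n, rate = 1 / b)
}

#' Draw true per-variant effects under an architecture
#'
#' Effects are on the standardized-genotype scale, so with independent
#' markers the per-variant variance explained is `beta^2` and the realized
#' heritability is `sum(beta^2)`.
#'
#' @param spec an [architecture_spec].
#' @param seed optional integer seed (set before drawing).
#' @return Numeric vector of length `n_snps`; attribute `"causal"` holds
#'   the causal indices.
#' @export
simulate_effects <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "architecture_spec"))
  if (!is.null(seed)) set.seed(seed)
  M <- spec$n_snps
  beta <- numeric(M)
  causal <- integer(0)
  if (spec$model == "gaussian_infinitesimal") {
    mc <- max(1L, round(spec$fraction_causal * M))
    causal <- sort(sample.int(M, mc))
    b <- rnorm(mc, 0, sqrt(spec$h2 / mc))
    if (spec$h2 > 0) b <- b * sqrt(spec$h2 / sum(b^2))  # realized h2 == h2
    beta[causal] <- b
  } else if (spec$model == "sparse_large_effect") {
    causal <- sort(sample.int(M, spec$n_large))
    beta[causal] <- sample(c(-1, 1), spec$n_large, replace = TRUE) *
      sqrt(spec$vg_per_large)
  } else { # laplace_mixture
    mc <- max(1L, round(spec$fraction_causal * M))
    small <- sort(sample.int(M, mc))
    theta <- rlaplace(mc, spec$laplace_mu, spec$laplace_b)
    h2_small <- (1 - spec$h2_large_fraction) * spec$h2
    if (sum(theta^2) > 0)
      theta <- theta * sqrt(h2_small / sum(theta^2))
    beta[small] <- theta
    h2_large <- spec$h2_large_fraction * spec$h2
    if (h2_large > 0) {
      # draw large-effect variances until the target is reached, then
      # rescale so the total matches exactly
      vg <- numeric(0)
      while (sum(vg) < h2_large)
        vg <- c(vg, runif(1L, spec$vg_large_low, spec$vg_large_high))
      vg <- vg * (h2_large / sum(vg))
      free <- setdiff(seq_len(M), small)
      if (length(free) < length(vg))
        stop("not enough non-causal markers for the large-effect set")
      large <- sort(sample(free, length(vg)))
      beta[large] <- sample(c(-1, 1), length(vg), replace = TRUE) * sqrt(vg)
      causal <- sort(c(small, large))
    } else causal <- small
  }
  attr(beta, "causal") <- if (length(causal)) causal else
    sort(which(beta != 0))
  beta
}

#' Simulate a phenotype from a standardized genotype panel
#'
#' Liability (equivalently, the quantitative phenotype) is
#' `y = X beta + e`, `e ~ N(0, 1 - h2)`, so that the phenotype has unit
#' variance when the effects carry `h2` of it.
#'
#' @param panel a standardized [genotype_panel].
#' @param beta true effects on the standardized scale.
#' @param h2 heritability in `[0, 1)` (only sets the noise variance; the
#'   genetic variance is fixed by `beta`).
#' @param seed optional integer seed.
#' @return Numeric phenotype vector with the genetic component in
#'   attribute `"genetic"`.
#' @export
phenotype_from_genotypes <- function(panel, beta, h2, seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!panel$standardized) stop("panel must be standardized first")
  if (h2 >= 1) stop("h2 must be < 1")
  if (!is.null(seed)) set.seed(seed)
  g <- as.numeric(panel$dosage %*% beta)
  y <- g + rnorm(length(g), 0, sqrt(1 - h2))
  attr(y, "genetic") <- g
  y
}

#' Per-variant association scan
#'
#' Univariate linear regression of the phenotype on each standardized
#' genotype column (optionally after residualizing phenotype and genotypes
#' on covariates), returning signed test statistics, two-sided p-values
#' and effect estimates as a [sumstats] table.  Binary phenotypes coded
#' 0/1 can either be analysed by the same linear model (fast, and
#' monotone-equivalent to logistic at GWAS-scale effects) or by per-variant
#' logistic regression.
#'
#' @param panel a standardized [genotype_panel].
#' @param y phenotype vector (quantitative, or 0/1 status).
#' @param covariates optional numeric matrix of covariates.
#' @param family `"linear"` (default) or `"logistic"`.
#' @return A [sumstats] object; zero-variance variants get `z = 0`,
#'   `p = 1` and are flagged in attribute `"zero_variance"`.
#' @export
gwas_scan <- function(panel, y, covariates = NULL,
                      family = c("linear", "logistic")) {
  family <- match.arg(family)
  stopifnot(inherits(panel, "genotype_panel"))
  if (!panel$standardized) stop("panel must be standardized first")
  X <- panel$dosage
  n <- nrow(X)
  y <- as.numeric(y)
  if (length(y) != n) stop("phenotype length must match panel samples")

  if (family == "logistic") {
    if (!all(y %in% c(0, 1))) stop("logistic scan needs 0/1 status")
    m <- ncol(X)
    beta <- se <- zst <- rep(NA_real_, m)
    for (j in seq_len(m)) {
      if (panel$zero_variance[j]) { beta[j] <- 0; zst[j] <- 0; next }
      dat <- if (is.null(covariates)) data.frame(y = y, x = X[, j])
             else data.frame(y = y, x = X[, j], covariates)
      fit <- suppressWarnings(glm(y ~ ., family = binomial(), data = dat))
      cf <- summary(fit)$coefficients
      beta[j] <- cf["x", 1L]; se[j] <- cf["x", 2L]; zst[j] <- cf["x", 3L]
    }
    p <- 2 * pnorm(-abs(zst))
    p[panel$zero_variance] <- 1
  } else {
    ncov <- 0L
    if (!is.null(covariates)) {
      covariates <- as.matrix(covariates)
      Q <- qr.Q(qr(cbind(1, covariates)))
      y <- y - as.numeric(Q %*% crossprod(Q, y))
      X <- X - Q %*% crossprod(Q, X)
      ncov <- ncol(covariates)
      yc <- y
    } else {
      yc <- y - mean(y)
    }
    sdy <- sqrt(mean(yc^2))
    if (sdy == 0) stop("phenotype is constant")
    if (is.null(covariates)) {
      # standardized columns have sum of squares exactly n (0 if degenerate)
      xss <- rep(n, ncol(X)); xss[panel$zero_variance] <- 0
    } else {
      xss <- .colSums(X * X, n, ncol(X))
    }
    xy <- as.numeric(crossprod(X, yc))
    r <- xy / sqrt(xss * sum(yc^2))
    r[panel$zero_variance] <- 0
    r <- pmax(pmin(r, 1 - 1e-12), -1 + 1e-12)
    df <- n - 2L - ncov
    zst <- r * sqrt(df) / sqrt(1 - r^2)
    beta <- ifelse(xss > 0, xy / pmax(xss, 1e-300), 0)
    se <- ifelse(zst != 0, beta / zst, NA_real_)
    p <- 2 * pt(-abs(zst), df)
    p[panel$zero_variance] <- 1
  }

  out <- sumstats(variant_id = panel$variant_id, chrom = panel$chrom,
                  pos = panel$pos, beta = beta, se = se, p = p,
                  n = n, z = zst)
  attr(out, "zero_variance") <- panel$zero_variance
  out
}

# dosages with within-block AR(1) latent correlation, for exercising
# LD-clumping on synthetic data (haplotype = thresholded latent Gaussian)
sim_ld_dosages <- function(n, maf, rho, block_size) {
  m <- length(maf)
  X <- matrix(0, n, m)
  thr <- qnorm(maf)
  for (start in seq(1L, m, by = block_size)) {
    cols <- start:min(start + block_size - 1L, m)
    for (hap in 1:2) {
      Z <- matrix(rnorm(n * length(cols)), n)
      if (length(cols) > 1L)
        for (j in 2:length(cols))
          Z[, j] <- rho * Z[, j - 1L] + sqrt(1 - rho^2) * Z[, j]
      X[, cols] <- X[, cols] + (Z < rep(thr[cols], each = n))
    }
  }
  X
}

#' Simulate a complete two-sample PRS study
#'
#' Generates a training and a testing panel of biallelic markers with
#' MAF ~ U(maf_low, 0.5) and independent `Binomial(2, MAF)` dosages (or
#' block-correlated dosages when `ld` is given), draws true effects from
#' the architecture, simulates liabilities `y = X beta + e`, and runs the
#' per-variant association scan on the training split.
#'
#' For a binary trait, disease status is liability exceeding the
#' `1 - prevalence` normal quantile; individuals are simulated in batches
#' until `n/2` cases and `n/2` controls are collected for each split
#' (batch liabilities use the theoretical dosage standardization, since
#' empirical standardization is only defined once the sample is fixed).
#'
#' @param spec an [architecture_spec].
#' @param n_train,n_test individuals per split (for a binary trait, half
#'   cases and half controls each).
#' @param binary simulate a liability-threshold case-control study?
#' @param seed master seed; stage seeds are derived deterministically.
#' @param ld optional `list(rho =, block_size =)` for block-AR(1) LD.
#' @param max_oversample abort if case-control sampling needs more than
#'   `max_oversample * n` simulated individuals.
#' @return Object of class `"simulated_study"`: `train_panel`,
#'   `test_panel` (standardized), `true_beta`, `y_train`, `y_test`,
#'   `status_train`, `status_test` (binary only), `sumstats` (from the
#'   training split), `maf`, `spec`, `seed`.
#' @export
simulate_independent_study <- function(spec, n_train, n_test = n_train,
                                       binary = FALSE, seed = 1,
                                       ld = NULL, max_oversample = 50) {
  stopifnot(inherits(spec, "architecture_spec"))
  M <- spec$n_snps
  set.seed(child_seed(seed, 1L))
  maf <- runif(M, spec$maf_low, 0.5)
  beta <- simulate_effects(spec, seed = child_seed(seed, 2L))

  # synthetic map: independent loci are spaced 500 kb apart (outside any
  # clumping window); LD blocks sit at 10 kb spacing within a block
  if (is.null(ld)) {
    chrom <- rep(as.character(1:22), length.out = M)
    pos <- stats::ave(seq_len(M), chrom, FUN = seq_along) * 5e5
  } else {
    chrom <- rep("1", M)
    block <- (seq_len(M) - 1L) %/% ld$block_size
    within <- (seq_len(M) - 1L) %% ld$block_size
    pos <- block * 1e6 + within * 1e4 + 1
  }
  ids <- paste0("snp", seq_len(M))

  gen <- function(n) {
    if (is.null(ld)) sim_dosages_cpp(n, maf)
    else sim_ld_dosages(n, maf, ld$rho, ld$block_size)
  }
  make_panel <- function(X, prefix)
    standardize(genotype_panel(X, variant_id = ids, chrom = chrom, pos = pos,
                               sample_id = paste0(prefix, seq_len(nrow(X))),
                               validate = FALSE),
                in_place = TRUE)

  if (!binary) {
    set.seed(child_seed(seed, 3L))
    train <- make_panel(gen(n_train), "train")
    y_train <- phenotype_from_genotypes(train, beta, spec$h2)
    set.seed(child_seed(seed, 4L))
    test <- make_panel(gen(n_test), "test")
    y_test <- phenotype_from_genotypes(test, beta, spec$h2)
    status_train <- status_test <- NULL
  } else {
    thr <- qnorm(1 - spec$prevalence)
    causal <- attr(beta, "causal")
    sd_theo <- sqrt(2 * maf * (1 - maf))
    draw_split <- function(n, stage) {
      set.seed(child_seed(seed, stage))
      need <- c(case = ceiling(n / 2), control = floor(n / 2))
      got_X <- vector("list", 0L); got_y <- numeric(0); got_s <- integer(0)
      simulated <- 0L
      while (any(need > 0)) {
        nb <- max(n, 1000L)
        simulated <- simulated + nb
        if (simulated > max_oversample * n)
          stop("case-control oversampling budget exceeded")
        D <- sim_dosages_cpp(nb, maf[causal])
        Xs <- sweep(D, 2L, 2 * maf[causal]) /
          rep(sd_theo[causal], each = nb)
        g <- as.numeric(Xs %*% beta[causal])
        yb <- g + rnorm(nb, 0, sqrt(1 - spec$h2))
        case <- yb > thr
        for (grp in c(TRUE, FALSE)) {
          key <- if (grp) "case" else "control"
          take <- which(case == grp)[seq_len(min(need[[key]], sum(case == grp)))]
          if (length(take)) {
            got_X[[length(got_X) + 1L]] <- D[take, , drop = FALSE]
            got_y <- c(got_y, yb[take])
            got_s <- c(got_s, rep(as.integer(grp), length(take)))
            need[[key]] <- need[[key]] - length(take)
          }
        }
      }
      Dc <- do.call(rbind, got_X)
      # non-causal genotypes are independent of the liability, hence of the
      # case-control selection: generate them only for the kept individuals
      X <- matrix(0, n, M)
      X[, causal] <- Dc
      X[, -causal] <- sim_dosages_cpp(n, maf[-causal])
      list(X = X, y = got_y, status = got_s)
    }
    tr <- draw_split(n_train, 3L)
    train <- make_panel(tr$X, "train")
    y_train <- tr$y; status_train <- tr$status
    te <- draw_split(n_test, 4L)
    test <- make_panel(te$X, "test")
    y_test <- te$y; status_test <- te$status
  }

  ss <- gwas_scan(train, if (binary) status_train else y_train)
  structure(list(train_panel = train, test_panel = test, true_beta = beta,
                 y_train = y_train, y_test = y_test,
                 status_train = status_train, status_test = status_test,
                 sumstats = ss, maf = maf, spec = spec, seed = seed),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "Simulated %s study: %d + %d individuals, %d SNPs (%s, h2 = %g)\n",
    if (is.null(x$status_train)) "quantitative" else "case-control",
    length(x$y_train), length(x$y_test), x$spec$n_snps, x$spec$model,
    x$spec$h2))
  invisible(x)
}
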