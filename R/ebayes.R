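#' Rule-of-thumb bandwidth for the Gaussian kernel density estimate
#'
#' Silverman's rule of thumb as used by R's default density estimate:
#' `h = 0.9 * min(sd, IQR/1.34) * n^(-1/5)`.  When both spread measures are
#' zero (constant input) the fallback `0.9 * max(|z1|, 1) * n^(-1/5)` keeps
#' the bandwidth positive.
#'
#' @param z numeric vector of observed z-statistics (length >= 2).
#' @return Positive bandwidth.
#' @export
nrd0_bandwidth <- function(z) {
  if (length(z) < 2L) stop("need at least 2 points to choose a bandwidth")
  if (any(!is.finite(z))) stop("z must be finite")
  lo <- min(sd(z), IQR(z) / 1.34)
  if (lo == 0) lo <- max(abs(z[1L]), 1)
  0.9 * lo * length(z)^(-0.2)
}

#' Fit a Gaussian kernel density estimate to observed z-statistics
#'
#' The fitted object evaluates the exact mixture density
#' `f(x) = (1/(n h)) sum_i phi((x - z_i)/h)` and its analytic first
#' derivative at arbitrary points; no grid interpolation is involved, so the
#' log-density gradient used by Tweedie's formula is exact for the fitted
#' density.
#'
#' @param z numeric vector of training z-statistics (finite).
#' @param h bandwidth; defaults to [nrd0_bandwidth()].
#' @return An object of class `"kde_fit"` with elements `train_z`, `h`.
#' @export
fit_kde <- function(z, h = nrd0_bandwidth(z)) {
  if (any(!is.finite(z))) stop("z must be finite")
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("bandwidth h must be a positive number")
  structure(list(train_z = as.numeric(z), h = h, n = length(z)),
            class = "kde_fit")
}

#' @export
print.kde_fit <- function(x, ...) {
  cat(sprintf("Gaussian KDE: %d points, bandwidth h = %.4g\n", x$n, x$h))
  invisible(x)
}

#' Evaluate a fitted KDE (and its derivative)
#'
#' @param object a `"kde_fit"` from [fit_kde()].
#' @param x points at which to evaluate.
#' @param ... unused.
#' @return data.frame with columns `x`, `f` (density) and `fprime` (exact
#'   first derivative).
#' @export
predict.kde_fit <- function(object, x, ...) {
  ev <- kde_eval_cpp(as.numeric(x), object$train_z, object$h)
  data.frame(x = as.numeric(x), f = ev$f, fprime = ev$fprime)
}

#' Tweedie's formula: posterior mean of the true effect given observed z
#'
#' Empirical Bayes correction for selection bias (winner's curse) in GWAS
#' z-statistics: `E(delta | z) = z + d/dz log f(z)`, where `f` is the
#' marginal density of the observed statistics.  Only the marginal density
#' is needed, so no prior on the effect sizes has to be specified.
#'
#' @param z numeric vector of observed z-statistics.
#' @param fit a `"kde_fit"` trained on the z population (defaults to a fit
#'   on `z` itself).
#' @return Numeric vector of corrected z-statistics, aligned with `z`.
#' @export
tweedie_correct <- function(z, fit = fit_kde(z)) {
  stopifnot(inherits(fit, "kde_fit"))
  ev <- kde_eval_cpp(as.numeric(z), fit$train_z, fit$h)
  grad <- ifelse(ev$f > 0, ev$fprime / ev$f, 0)
  z + grad
}

#' Convert a z-statistic to the variance in liability explained
#'
#' For a univariate regression on a standardized genotype, the squared
#' t-statistic maps to the coefficient of determination via
#' `Vg = z^2 / (z^2 + n - 2)`: monotone increasing in `|z|`, decreasing in
#' `n`.
#'
#' @param z numeric vector of (possibly corrected) z-statistics.
#' @param n per-variant sample size(s), each > 2; recycled.
#' @return Variance explained per variant, in `[0, 1)`.
#' @export
z_to_vg <- function(z, n) {
  n <- rep_len(as.numeric(n), length(z))
  if (any(!is.finite(n)) || any(n <= 2)) stop("sample size n must exceed 2")
  z^2 / (z^2 + n - 2)
}

#' Corrected per-variant PRS weights
#'
#' Computes signed per-standardized-allele weights for one of four
#' estimators:
#' \describe{
#'   \item{`standard`}{`sign(z) * sqrt(Vg(z, n))` — the raw association
#'     estimate on the variance-explained scale.}
#'   \item{`tweedie`}{`sign(z) * sqrt(Vg(E(delta|z), n))` — effect size from
#'     the Tweedie-corrected statistic.}
#'   \item{`tdr`}{standard weight times the local true discovery rate
#'     `(1 - fdr)`.}
#'   \item{`tweedie_tdr`}{Tweedie weight times `(1 - fdr)` — shrinkage and
#'     null down-weighting combined.}
#' }
#'
#' @param stats a [sumstats] object.
#' @param method one of `"standard"`, `"tweedie"`, `"tdr"`, `"tweedie_tdr"`.
#' @param fdr_fit a `"locfdr_fit"` from [fit_locfdr()], aligned to
#'   `stats$z`; required by the tdr-weighted methods.
#' @param kde_fit optional `"kde_fit"`; defaults to a fit on `stats$z` for
#'   the Tweedie-based methods (pass one to reuse across methods).
#' @param corrected_z optional precomputed [tweedie_correct()] output
#'   aligned to `stats$z`, so pipelines evaluating several Tweedie-based
#'   methods run the correction once.
#' @return A `data.frame` of class `"effect_estimates"` with columns
#'   `variant_id`, `allele_effect`, `method`, `weight`, `corrected_z`, `vg`.
#' @export
corrected_effects <- function(stats,
                              method = c("standard", "tweedie", "tdr",
                                         "tweedie_tdr"),
                              fdr_fit = NULL, kde_fit = NULL,
                              corrected_z = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(stats, "sumstats"))
  z <- stats$z
  n <- stats$n
  needs_fdr <- method %in% c("tdr", "tweedie_tdr")
  if (needs_fdr) {
    if (is.null(fdr_fit))
      stop("method '", method, "' requires a local-fdr fit (fdr_fit)")
    stopifnot(inherits(fdr_fit, "locfdr_fit"))
    if (length(fdr_fit$fdr) != length(z))
      stop("fdr_fit is not aligned to stats (length mismatch)")
  }
  cz <- if (method %in% c("tweedie", "tweedie_tdr")) {
    if (!is.null(corrected_z)) {
      if (length(corrected_z) != length(z))
        stop("corrected_z is not aligned to stats (length mismatch)")
      corrected_z
    } else {
      tweedie_correct(z, kde_fit %||% fit_kde(z))
    }
  } else z
  vg <- z_to_vg(cz, n)
  w <- sign(z) * sqrt(vg)
  if (needs_fdr) w <- w * (1 - fdr_fit$fdr)
  structure(
    data.frame(variant_id = stats$variant_id,
               allele_effect = stats$allele_effect,
               method = method, weight = w, corrected_z = cz, vg = vg,
               stringsAsFactors = FALSE),
    class = c("effect_estimates", "data.frame")
  )
}
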