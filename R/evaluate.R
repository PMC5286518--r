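#' Prediction R-squared
#'
#' Squared Pearson correlation between observed outcome and polygenic
#' score — the standard PRS evaluation metric (affine-invariant in the
#' score).
#'
#' @param y observed outcome vector.
#' @param s predicted score vector of the same length (>= 3).
#' @return R-squared in `[0, 1]`; a constant score yields 0 with a warning.
#' @export
prediction_r2 <- function(y, s) {
  if (length(y) != length(s)) stop("y and s must have equal length")
  if (length(y) < 3L) stop("need at least 3 observations")
  if (sd(s) == 0) {
    warning("score is constant; R2 set to 0")
    return(0)
  }
  cor(y, s)^2
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a randomly chosen case outscores
#' a randomly chosen control, with ties counted as 1/2.
#'
#' @param status binary vector (0 = control, 1 = case; both present).
#' @param s score vector of the same length.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(status, s) {
  if (length(status) != length(s)) stop("status and s must have equal length")
  status <- as.integer(status)
  if (!all(status %in% c(0L, 1L))) stop("status must be 0/1")
  n1 <- sum(status == 1L); n0 <- sum(status == 0L)
  if (n1 == 0L || n0 == 0L) stop("both cases and controls are required")
  r <- rank(s)  # midranks give ties a half credit
  (sum(r[status == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated k-fold cross-validation splits
#'
#' Per repeat, a random partition of `1:n` into `k` folds; each fold in
#' turn is the test set with the remainder as training set, giving
#' `k * repeats` train/test pairs in total (the default 5 x 4 yields 20).
#'
#' @param n number of observations.
#' @param k number of folds (default 5).
#' @param repeats number of independent repetitions (default 4).
#' @param seed integer seed fixing the partitions.
#' @return List of `k * repeats` elements, each
#'   `list(train_idx =, test_idx =)`.
#' @export
repeated_kfold <- function(n, k = 5L, repeats = 4L, seed = 1L) {
  if (k > n) stop("k must not exceed n")
  if (k < 2L) stop("k must be at least 2")
  set.seed(seed)
  out <- vector("list", k * repeats)
  i <- 0L
  for (r in seq_len(repeats)) {
    fold <- sample(rep_len(seq_len(k), n))
    for (f in seq_len(k)) {
      i <- i + 1L
      out[[i]] <- list(train_idx = which(fold != f),
                       test_idx = which(fold == f))
    }
  }
  out
}

#' Benchmark PRS weighting methods on simulated studies
#'
#' For each replicate: simulate a study ([simulate_independent_study()]),
#' run the association scan on the training split, fit the KDE and
#' local-fdr models once, compute the per-variant weights for every
#' requested method, LD-clump, and score the test split across the
#' p-value threshold grid.  Quantitative studies are evaluated by
#' prediction R-squared, case-control studies by AUC on the balanced test
#' sample.
#'
#' @param spec an [architecture_spec].
#' @param n_train,n_test individuals per split.
#' @param binary liability-threshold case-control design?
#' @param methods subset of
#'   `c("standard", "tdr", "tweedie", "tweedie_tdr")`; an empty vector
#'   returns an empty result without simulating.
#' @param replicates number of independent simulated studies.
#' @param thresholds p-value threshold grid (default [threshold_grid()]).
#' @param clump_r2,clump_window_kb LD-clumping parameters.
#' @param null_type null model for [fit_locfdr()].
#' @param seed master seed; replicate seeds are derived deterministically.
#' @param ld optional LD block structure, passed to the simulator.
#' @param verbose print per-replicate progress to stderr?
#' @return Object of class `"prs_benchmark"`: `results` (long data.frame:
#'   `replicate`, `method`, `p_threshold`, `metric`, `value`),
#'   `by_threshold` (mean over replicates per method and threshold) and
#'   `summary` (per method: `best` = max over thresholds of the mean,
#'   `best_threshold`, and `all_snps` = mean at threshold 1).
#' @export
run_benchmark <- function(spec, n_train = 5000L, n_test = n_train,
                          binary = FALSE,
                          methods = c("standard", "tdr", "tweedie",
                                      "tweedie_tdr"),
                          replicates = 20L,
                          thresholds = threshold_grid(),
                          clump_r2 = 0.25, clump_window_kb = 250,
                          null_type = "empirical_mle", seed = 1L,
                          ld = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "architecture_spec"))
  metric_name <- if (binary) "auc" else "r2"
  empty <- data.frame(replicate = integer(0), method = character(0),
                      p_threshold = numeric(0), metric = character(0),
                      value = numeric(0), stringsAsFactors = FALSE)
  if (length(methods) == 0L || replicates == 0L)
    return(structure(list(results = empty, by_threshold = empty[0, ],
                          summary = empty[0, ], metric = metric_name),
                     class = "prs_benchmark"))
  methods <- match.arg(methods, c("standard", "tdr", "tweedie",
                                  "tweedie_tdr"), several.ok = TRUE)

  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    if (verbose) message(sprintf("replicate %d/%d", r, replicates))
    study <- simulate_independent_study(spec, n_train, n_test,
                                        binary = binary,
                                        seed = child_seed(seed, 100L + r),
                                        ld = ld)
    ss <- study$sumstats
    needs_kde <- any(methods %in% c("tweedie", "tweedie_tdr"))
    kfit <- if (needs_kde) fit_kde(ss$z) else NULL
    cz <- if (needs_kde) tweedie_correct(ss$z, kfit) else NULL
    lfit <- if (any(methods %in% c("tdr", "tweedie_tdr")))
      fit_locfdr(ss$z, null_type = null_type) else NULL

    ck <- clump(ss, study$train_panel, r2 = clump_r2,
                window_kb = clump_window_kb)
    in_clump <- ss$variant_id %in% ck$kept_ids

    # one weight column per (method, threshold); a single GEMM scores all
    nm <- length(methods); nt <- length(thresholds)
    W <- matrix(0, nrow(ss), nm * nt)
    for (j in seq_len(nm)) {
      eff <- corrected_effects(ss, methods[j], fdr_fit = lfit,
                               kde_fit = kfit, corrected_z = cz)
      w <- eff$weight * in_clump
      for (t in seq_len(nt))
        W[, (j - 1L) * nt + t] <- w * (ss$p <= thresholds[t])
    }
    S <- study$test_panel$dosage %*% W
    outcome <- if (binary) study$status_test else study$y_test
    vals <- apply(S, 2L, function(sc) {
      if (sd(sc) == 0) return(if (binary) 0.5 else 0)
      if (binary) auc(outcome, sc) else cor(outcome, sc)^2
    })
    rows[[r]] <- data.frame(
      replicate = r,
      method = rep(methods, each = nt),
      p_threshold = rep(thresholds, nm),
      metric = metric_name, value = vals,
      stringsAsFactors = FALSE)
    rm(study, S, W); gc(FALSE)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL

  by_thr <- aggregate(value ~ method + p_threshold, data = results,
                      FUN = mean)
  names(by_thr)[names(by_thr) == "value"] <- "mean_value"
  summ <- do.call(rbind, lapply(split(by_thr, by_thr$method), function(d) {
    b <- which.max(d$mean_value)
    data.frame(method = d$method[1L], metric = metric_name,
               best = d$mean_value[b], best_threshold = d$p_threshold[b],
               all_snps = d$mean_value[d$p_threshold == 1],
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(results = results, by_threshold = by_thr, summary = summ,
                 metric = metric_name, replicates = replicates,
                 seed = seed),
            class = "prs_benchmark")
}

#' @export
print.prs_benchmark <- function(x, ...) {
  cat(sprintf("PRS benchmark (%s, %d replicates)\n", x$metric,
              x$replicates %||% 0L))
  if (nrow(x$summary %||% data.frame()) > 0) print(x$summary, digits = 3)
  invisible(x)
}
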