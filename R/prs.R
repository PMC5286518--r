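#' Construct a genotype panel
#'
#' Wraps an individuals-by-variants dosage matrix (values in `[0, 2]`,
#' `NA` allowed) together with variant and sample metadata.
#'
#' @param dosage numeric matrix, `n` samples by `m` variants.
#' @param variant_id character vector of length `m` (unique).
#' @param chrom,pos per-variant chromosome and base-pair position.
#' @param sample_id character vector of length `n`.
#' @param validate check the dosage range; internal callers that just
#'   generated the matrix may skip the scan.
#' @return Object of class `"genotype_panel"` with elements `dosage`,
#'   `variant_id`, `chrom`, `pos`, `sample_id`, `standardized` and
#'   `zero_variance` (filled by [standardize()]).
#' @export
genotype_panel <- function(dosage, variant_id,
                           chrom = rep("1", ncol(dosage)),
                           pos = seq_len(ncol(dosage)),
                           sample_id = paste0("S", seq_len(nrow(dosage))),
                           validate = TRUE) {
  m <- ncol(dosage); n <- nrow(dosage)
  variant_id <- as.character(variant_id)
  if (length(variant_id) != m) stop("variant_id length must match ncol(dosage)")
  if (anyDuplicated(variant_id)) stop("variant_id must be unique")
  if (validate) {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "double"
    rng <- range(dosage, na.rm = TRUE)
    if (rng[1L] < 0 || rng[2L] > 2)
      stop("dosages must lie in [0, 2] (or be missing)")
  }
  structure(list(dosage = dosage, variant_id = variant_id,
                 chrom = rep_len(as.character(chrom), m),
                 pos = rep_len(as.numeric(pos), m),
                 sample_id = rep_len(as.character(sample_id), n),
                 standardized = FALSE, zero_variance = logical(m)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("Genotype panel: %d samples x %d variants (%s)\n",
              length(x$sample_id), length(x$variant_id),
              if (x$standardized) "standardized" else "raw dosages"))
  invisible(x)
}

#' Standardize a genotype panel
#'
#' Mean-imputes missing dosages, then centres each variant column and
#' scales it to unit variance using the population (divide-by-n) standard
#' deviation.  Zero-variance columns are set to all zeros and flagged in
#' `$zero_variance`.  Idempotent: standardizing an already standardized
#' panel is a no-op.
#'
#' @param panel a [genotype_panel].
#' @param in_place if `TRUE` the dosage matrix is overwritten without a
#'   copy; only safe when no other reference to the matrix exists (the
#'   simulator uses this on matrices it owns).
#' @return The standardized panel.
#' @export
standardize <- function(panel, in_place = FALSE) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (panel$standardized) return(panel)
  X <- panel$dosage
  if (!in_place) X <- X + 0  # force a copy before in-place C++ mutation
  panel$zero_variance <- as.logical(standardize_inplace_cpp(X))
  panel$dosage <- X
  panel$standardized <- TRUE
  panel
}

#' The p-value threshold grid used for PRS threshold sweeps
#'
#' @return The 18-value ascending grid
#'   `1e-5, 1e-4, 5e-4, 1e-3, 5e-3, 1e-2, 0.03, 0.05, 0.1, 0.2, ..., 0.9, 1`;
#'   the final threshold of 1 is the "all markers" score.
#' @export
threshold_grid <- function() {
  c(1e-5, 1e-4, 5e-4, 1e-3, 5e-3, 1e-2, 0.03, 0.05,
    0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1)
}

#' Greedy LD-clumping
#'
#' PLINK-style clumping: variants are visited in order of ascending
#' p-value (ties broken by chromosome, then position); each unclaimed
#' variant with `p <= p1` becomes an index variant and claims every
#' unclaimed variant with `p <= p2` on the same chromosome within
#' `window_kb` kb whose squared Pearson correlation with it exceeds `r2`.
#' Index variants are kept; claimed variants are removed.
#'
#' @param stats a [sumstats] object with p-values.
#' @param panel a [genotype_panel] covering (at least) the shared variants;
#'   correlations are computed on mean-imputed standardized dosages.
#' @param r2 squared-correlation threshold (default 0.25).
#' @param window_kb half-window in kb around the index variant,
#'   inclusive (default 250).
#' @param p1,p2 index / clumped significance thresholds (default 1: all).
#' @return Object of class `"clump_result"`: `kept_ids` (in visit order),
#'   `removed` (named character vector mapping removed variant -> its index
#'   variant), and the parameters used.
#' @export
clump <- function(stats, panel, r2 = 0.25, window_kb = 250, p1 = 1, p2 = 1) {
  stopifnot(inherits(stats, "sumstats"), inherits(panel, "genotype_panel"))
  shared <- intersect(stats$variant_id, panel$variant_id)
  if (length(shared) == 0L)
    stop("no shared variants between summary statistics and panel")
  panel <- standardize(panel)
  s <- stats[match(shared, stats$variant_id), , drop = FALSE]
  col <- match(shared, panel$variant_id)
  p <- s$p
  if (all(is.na(p))) stop("clumping needs p-values in the summary statistics")
  ord <- order(p, s$chrom, s$pos)
  window_bp <- window_kb * 1000

  nvar <- length(shared)
  # precompute physical neighbours per variant; variants with none (e.g.
  # widely spaced independent loci) never need a correlation lookup
  nb <- vector("list", nvar)
  for (idx in split(seq_len(nvar), s$chrom)) {
    o <- idx[order(s$pos[idx])]
    po <- s$pos[o]
    # positions are integral bp; +/-0.5 makes the window ends inclusive
    lo <- findInterval(po - window_bp - 0.5, po) + 1L
    hi <- findInterval(po + window_bp + 0.5, po)
    for (k in seq_along(o)) {
      if (hi[k] > lo[k])
        nb[[o[k]]] <- setdiff(o[lo[k]:hi[k]], o[k])
    }
  }

  claimed <- logical(nvar)
  kept <- integer(nvar); n_kept <- 0L
  removed_from <- character(0); removed_to <- character(0)
  X <- panel$dosage
  nind <- nrow(X)
  for (i in ord) {
    if (claimed[i] || is.na(p[i]) || p[i] > p1) next
    claimed[i] <- TRUE
    n_kept <- n_kept + 1L
    kept[n_kept] <- i
    cand <- nb[[i]]
    cand <- cand[!claimed[cand] & !is.na(p[cand]) & p[cand] <= p2]
    if (length(cand) == 0L) next
    # columns are standardized (mean 0, population sd 1): r = x'y / n
    rr <- as.numeric(crossprod(X[, col[cand], drop = FALSE], X[, col[i]])) / nind
    hit <- cand[rr^2 > r2]
    if (length(hit) > 0L) {
      claimed[hit] <- TRUE
      removed_from <- c(removed_from, shared[hit])
      removed_to <- c(removed_to, rep(shared[i], length(hit)))
    }
  }
  kept <- kept[seq_len(n_kept)]
  removed <- removed_to
  names(removed) <- removed_from
  structure(list(kept_ids = shared[kept], removed = removed,
                 r2_threshold = r2, window_kb = window_kb,
                 p1 = p1, p2 = p2, n_input = nvar),
            class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat(sprintf("LD clumping (r2 > %g within +/-%g kb): kept %d of %d variants\n",
              x$r2_threshold, x$window_kb, length(x$kept_ids), x$n_input))
  invisible(x)
}

#' Score individuals with a polygenic risk score
#'
#' Computes `score_j = sum_i w_i x_ji` over the variants whose training
#' p-value passes `p_threshold`, where `x` is the standardized genotype and
#' `w` the chosen per-variant weight.  Restrict to an LD-clumped set by
#' passing the [clump()] result as `keep`.
#'
#' @param panel a [genotype_panel] of the target individuals.
#' @param effects an `effect_estimates` table from [corrected_effects()].
#' @param stats the [sumstats] used to fit the weights (provides the
#'   p-values for thresholding); may be `NULL` when `p_threshold = 1`.
#' @param p_threshold p-value threshold in (0, 1]; 1 keeps every variant.
#' @param keep optional `"clump_result"` (or character vector of variant
#'   ids) restricting the candidate set.
#' @return data.frame of class `"prs_profile"` with columns `sample_id`,
#'   `method`, `p_threshold`, `score`, and attribute `n_variants_used`.
#' @export
prs_score <- function(panel, effects, stats = NULL, p_threshold = 1,
                      keep = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!(p_threshold > 0 && p_threshold <= 1))
    stop("p_threshold must lie in (0, 1]")
  panel <- standardize(panel)
  ids <- effects$variant_id
  use <- ids %in% panel$variant_id
  if (!is.null(keep)) {
    keep_ids <- if (inherits(keep, "clump_result")) keep$kept_ids else keep
    use <- use & ids %in% keep_ids
  }
  if (p_threshold < 1) {
    if (is.null(stats)) stop("p-value thresholding needs the sumstats table")
    pv <- stats$p[match(ids, stats$variant_id)]
    use <- use & !is.na(pv) & pv <= p_threshold
  }
  n_used <- sum(use)
  if (n_used == 0L) {
    warning("no variants pass the threshold; scores are all zero")
    score <- rep(0, length(panel$sample_id))
  } else {
    cols <- match(ids[use], panel$variant_id)
    score <- as.numeric(panel$dosage[, cols, drop = FALSE] %*%
                          effects$weight[use])
  }
  structure(
    data.frame(sample_id = panel$sample_id,
               method = if (nrow(effects)) effects$method[1L] else NA_character_,
               p_threshold = p_threshold, score = score,
               stringsAsFactors = FALSE),
    class = c("prs_profile", "data.frame"), n_variants_used = n_used)
}
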