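#' Default column mapping for summary-statistics files
#'
#' Maps the fields of a [sumstats] object onto header names of a
#' tab/whitespace-delimited GWAS summary-statistics file.  Override any
#' entry to match non-standard headers, e.g.
#' `sumstats_columns(snp = "rsid", p = "pval")`.
#'
#' @param snp,chr,bp,a1,a2,beta,or_,se,p,n header names for, respectively,
#'   variant id, chromosome, base-pair position, effect allele, other
#'   allele, linear effect, odds ratio, standard error, p-value and
#'   per-variant sample size.
#' @return Named list of header names.
#' @export
sumstats_columns <- function(snp = "SNP", chr = "CHR", bp = "BP",
                             a1 = "A1", a2 = "A2", beta = "BETA",
                             or_ = "OR", se = "SE", p = "P", n = "N") {
  list(snp = snp, chr = chr, bp = bp, a1 = a1, a2 = a2,
       beta = beta, or_ = or_, se = se, p = p, n = n)
}

#' Construct a summary-statistics table
#'
#' Builds the per-variant GWAS summary-statistics container used throughout
#' the package.  The signed test statistic `z` is derived with [derive_z()]
#' unless supplied directly; records whose `z` cannot be derived (or is not
#' finite) are dropped and counted in the `n_rejected` attribute.
#'
#' @param variant_id character vector of unique variant identifiers.
#' @param chrom,pos chromosome label and 1-based base-pair position.
#' @param allele_effect,allele_other effect and other allele (taken at face
#'   value; no harmonisation against a reference is attempted).
#' @param beta per-standardized-genotype effect estimate (optional).
#' @param se standard error of `beta`, strictly positive (optional).
#' @param p two-sided p-value in (0, 1] (optional).
#' @param n per-variant sample size; a scalar is recycled.
#' @param z signed test statistic; derived from the other columns when `NULL`.
#' @param z_max optional cap applied when `z` must be derived from an
#'   underflowed `p = 0` (see [derive_z()]); `NULL` rejects such records.
#' @return A `data.frame` of class `"sumstats"` with columns `variant_id`,
#'   `chrom`, `pos`, `allele_effect`, `allele_other`, `beta`, `se`, `p`,
#'   `n`, `z`, and attributes `n_accepted` / `n_rejected`.
#' @export
sumstats <- function(variant_id, chrom = NA, pos = NA_integer_,
                     allele_effect = NA_character_, allele_other = NA_character_,
                     beta = NA_real_, se = NA_real_, p = NA_real_,
                     n, z = NULL, z_max = NULL) {
  variant_id <- as.character(variant_id)
  m <- length(variant_id)
  if (m == 0L) stop("empty summary statistics: no variants")
  if (anyDuplicated(variant_id))
    stop("variant_id must be unique within a summary-statistics set")
  rec <- function(x, mode = as.numeric) rep_len(mode(x), m)
  df <- data.frame(
    variant_id = variant_id,
    chrom = rec(chrom, as.character),
    pos = rec(pos, as.integer),
    allele_effect = rec(allele_effect, as.character),
    allele_other = rec(allele_other, as.character),
    beta = rec(beta), se = rec(se), p = rec(p),
    n = rec(n, as.integer),
    stringsAsFactors = FALSE
  )
  if (any(!is.na(df$n) & df$n <= 0L)) stop("sample size n must be positive")
  if (is.null(z)) {
    z <- derive_z_quiet(df$beta, df$se, df$p, z_max = z_max)$z
  } else {
    z <- rep_len(as.numeric(z), m)
  }
  df$z <- z
  keep <- is.finite(df$z)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) stop("no record has a derivable finite z-statistic")
  structure(out, class = c("sumstats", "data.frame"),
            n_accepted = nrow(out), n_rejected = sum(!keep))
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %d variants (%d rejected on read)\n",
              nrow(x), attr(x, "n_rejected") %||% 0L))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

# vectorized z derivation that flags failures instead of stopping; the
# exported derive_z() and read_sumstats() wrap this with their own policies
derive_z_quiet <- function(beta = NA_real_, se = NA_real_, p = NA_real_,
                           odds_ratio = NA_real_, z_max = NULL) {
  m <- max(length(beta), length(se), length(p), length(odds_ratio))
  beta <- rep_len(as.numeric(beta), m)
  se <- rep_len(as.numeric(se), m)
  p <- rep_len(as.numeric(p), m)
  odds_ratio <- rep_len(as.numeric(odds_ratio), m)
  beta <- ifelse(is.na(beta) & !is.na(odds_ratio), log(odds_ratio), beta)

  z <- rep(NA_real_, m)
  bad <- rep("", m)
  bad[!is.na(se) & se <= 0] <- "se <= 0"
  bad[!is.na(p) & (p > 1 | p < 0)] <- "p outside (0,1]"

  use_ratio <- bad == "" & !is.na(beta) & !is.na(se)
  z[use_ratio] <- beta[use_ratio] / se[use_ratio]

  use_p <- bad == "" & !use_ratio & !is.na(p) & !is.na(beta)
  pz <- ifelse(p[use_p] > 0, qnorm(1 - p[use_p] / 2), Inf)
  if (!is.null(z_max)) pz <- pmin(pz, z_max)
  z[use_p] <- sign(beta[use_p]) * pz
  # beta = 0 with only a p-value carries no sign but is unambiguously z = 0
  z[use_p][beta[use_p] == 0] <- 0

  bad[bad == "" & !use_ratio & !use_p] <- "no beta+se, nor p with sign carrier"
  bad[bad == "" & !is.finite(z)] <- "p = 0 underflow (set z_max to cap)"
  list(z = z, reason = bad)
}

#' Derive a signed z-statistic from summary-level fields
#'
#' Uses `z = beta/se` when both are present; otherwise the two-sided normal
#' quantile `z = sign * qnorm(1 - p/2)` with the sign taken from `beta` (or
#' from `log(odds_ratio)` when only an odds ratio is available).
#'
#' @inheritParams sumstats
#' @param odds_ratio odds ratio; used as `beta = log(odds_ratio)`.
#' @return Numeric vector of signed z-statistics.
#' @details `p = 0` (underflow in the source file) is rejected unless
#'   `z_max` is set, in which case `|z|` is capped at `z_max`.  `se <= 0`
#'   or `p > 1` raise a validation error.
#' @examples
#' derive_z(beta = 0.1, se = 0.05)          # 2
#' derive_z(beta = 1, p = 0.05)             # 1.959964
#' @export
derive_z <- function(beta = NA_real_, se = NA_real_, p = NA_real_,
                     odds_ratio = NA_real_, z_max = NULL) {
  res <- derive_z_quiet(beta, se, p, odds_ratio, z_max)
  if (any(res$reason != "")) {
    i <- which(res$reason != "")[1L]
    stop(sprintf("cannot derive z for element %d: %s", i, res$reason[i]))
  }
  res$z
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or whitespace-delimited file with a header line, applies a
#' configurable column mapping, derives signed z-statistics, and drops
#' malformed rows with a message reporting the accepted/rejected counts.
#'
#' @param path path to the summary-statistics file.
#' @param column_map mapping from field names to file headers, as produced
#'   by [sumstats_columns()].
#' @param study_n study-level sample size used for rows without a mapped
#'   `N` column (required by the variance-explained conversion).
#' @param z_max optional cap for `p = 0` rows; see [derive_z()].
#' @return A [sumstats] object; attributes `n_accepted` and `n_rejected`
#'   give the row accounting.
#' @export
read_sumstats <- function(path, column_map = sumstats_columns(),
                          study_n = NULL, z_max = NULL) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  raw <- read.table(path, header = TRUE, sep = "", stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
  if (nrow(raw) == 0L) stop("summary-statistics file is empty: ", path)
  hdr <- names(raw)
  pick <- function(key) if (column_map[[key]] %in% hdr) raw[[column_map[[key]]]] else NULL

  id <- pick("snp")
  if (is.null(id)) stop("mapped variant-id column '", column_map$snp,
                        "' not present in header")
  beta <- pick("beta"); or_ <- pick("or_"); se <- pick("se"); p <- pick("p")
  if (is.null(beta) && is.null(or_))
    stop("neither effect column '", column_map$beta, "' nor odds-ratio column '",
         column_map$or_, "' present in header")
  if (is.null(se) && is.null(p))
    stop("neither standard-error column '", column_map$se,
         "' nor p-value column '", column_map$p, "' present in header")
  n <- pick("n")
  if (is.null(n)) {
    if (is.null(study_n)) stop("file has no sample-size column '", column_map$n,
                               "'; supply study_n")
    n <- rep_len(as.integer(study_n), nrow(raw))
  }

  dz <- derive_z_quiet(beta = beta %||% NA_real_, se = se %||% NA_real_,
                       p = p %||% NA_real_, odds_ratio = or_ %||% NA_real_,
                       z_max = z_max)
  keep <- is.finite(dz$z) & !is.na(id) & !is.na(n) & n > 0
  n_rej <- sum(!keep)
  if (n_rej > 0L)
    message(sprintf("read_sumstats: rejected %d of %d rows (e.g. %s)",
                    n_rej, nrow(raw), dz$reason[!keep][1L]))
  if (!any(keep)) stop("no usable rows in ", path)

  full <- function(x, default) rep_len(x %||% default, nrow(raw))
  out <- sumstats(
    variant_id = id[keep],
    chrom = full(pick("chr"), NA_character_)[keep],
    pos = full(pick("bp"), NA_integer_)[keep],
    allele_effect = full(pick("a1"), NA_character_)[keep],
    allele_other = full(pick("a2"), NA_character_)[keep],
    beta = full(beta %||% (if (is.null(or_)) NULL else log(or_)), NA_real_)[keep],
    se = full(se, NA_real_)[keep],
    p = full(p, NA_real_)[keep],
    n = n[keep],
    z = dz$z[keep]
  )
  attr(out, "n_rejected") <- n_rej
  attr(out, "n_accepted") <- nrow(out)
  out
}

#' Write summary statistics with conventional GWAS headers
#'
#' Writes a tab-delimited file with the default headers understood by
#' [read_sumstats()] (`SNP CHR BP A1 A2 BETA SE P N`), so a written table
#' can be re-read without a custom column map.
#'
#' @param stats a [sumstats] object.
#' @param path output path; written atomically (temp file + rename).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  stopifnot(inherits(stats, "sumstats"))
  df <- data.frame(SNP = stats$variant_id, CHR = stats$chrom,
                   BP = stats$pos, A1 = stats$allele_effect,
                   A2 = stats$allele_other,
                   BETA = sprintf("%.17g", stats$beta),
                   SE = sprintf("%.17g", stats$se),
                   P = sprintf("%.17g", stats$p), N = stats$n,
                   stringsAsFactors = FALSE)
  tmp <- tempfile("sumstats", tmpdir = dirname(path))
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write PRS weights to a TSV file
#'
#' Writes the long-format weights table (`variant_id`, `allele_effect`,
#' `method`, `weight`) with full double precision so that a write/read
#' round-trip preserves finite weights bit-identically.
#'
#' @param effects an `effect_estimates` table from [corrected_effects()].
#' @param path output path; written atomically (temp file + rename).
#' @return `path`, invisibly.
#' @export
write_weights <- function(effects, path) {
  stopifnot(all(c("variant_id", "method", "weight") %in% names(effects)))
  df <- data.frame(
    variant_id = effects$variant_id,
    allele_effect = effects$allele_effect %||% NA_character_,
    method = effects$method,
    weight = sprintf("%.17g", effects$weight),
    stringsAsFactors = FALSE
  )
  tmp <- tempfile("weights", tmpdir = dirname(path))
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a PRS weights TSV written by [write_weights()]
#' @param path path to the weights file.
#' @return data.frame with columns `variant_id`, `allele_effect`, `method`,
#'   `weight`.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop("weights file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  df$weight <- as.numeric(df$weight)
  df
}
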