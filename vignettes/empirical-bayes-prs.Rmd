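---
title: "Empirical Bayes weighting of polygenic risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical Bayes weighting of polygenic risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tweedieprs)
```

## The problem

A polygenic risk score (PRS) predicts a trait or disease liability for one
individual as a weighted sum of allele counts,
$s_j = \sum_i \hat\beta_i x_{ji}$, with weights taken from univariate GWAS
regression coefficients.  Two things degrade the naive score.  First, the
raw $\hat\beta_i$ of the most significant variants are inflated by selection
(the winner's curse): conditional on being large, an observed effect
overstates the true one.  Second, the usual remedy — keeping only variants
below some p-value threshold — forces an arbitrary tuning choice, and the
performance reported at the best threshold is optimistically biased.

`tweedieprs` implements an empirical-Bayes weighting scheme that addresses
both: shrink each variant's statistic toward its posterior mean given the
whole distribution of observed statistics, down-weight likely-null variants
by their local false discovery rate, and score with *all* markers so that no
threshold has to be chosen.

## Model

Let $z_i$ be the signed statistic of variant $i$ from a univariate
regression on a standardized genotype, modelled as $z_i \sim N(\delta_i, 1)$
where $\delta_i$ is the noise-free statistic ($\delta_i = 0$ for null
variants).  Tweedie's formula gives the posterior mean of $\delta$ without
any prior on the effect sizes:

$$E(\delta \mid z) = z + \frac{d}{dz}\log f(z),$$

where $f$ is the *marginal* density of the observed statistics.  The package
estimates $f$ by a Gaussian kernel density estimate over all observed $z$,
with the standard rule-of-thumb bandwidth
$h = 0.9\,\min(\mathrm{sd}, \mathrm{IQR}/1.34)\,n^{-1/5}$, and evaluates the
mixture density and its derivative analytically at each observed point
(`fit_kde()`, `tweedie_correct()`).  Because the derivative is exact for the
fitted density, the log-gradient carries no discretisation error; kernels
beyond ten bandwidths are truncated (relative error $<2\times10^{-22}$).

The local false discovery rate is the posterior null probability
$\mathrm{fdr}(z) = \pi_0 f_0(z)/f(z)$ under the two-group model.
`fit_locfdr()` estimates it in the binned style of large-scale empirical
null inference: histogram the $z$ into `bins` equal-width bins (default
120), fit expected counts by Poisson regression on a natural-spline basis
(default 7 df) to obtain a smooth $f$, and estimate the null component
either as a theoretical $N(0,1)$, by a truncated-normal maximum-likelihood
fit to the central 80% of the data (the default; the 10–90% window is wide
enough that the truncated likelihood identifies the null sd, yet central
enough to stay null-dominated), or by central matching (a quadratic fit to
the central log-counts, also the automatic fallback if the Poisson fit does
not converge).  Statistics with $|z| \ge 6$ (two-sided $p \approx
1.97\times10^{-9}$) are treated as unambiguously non-null and clamped to
$\mathrm{fdr}=0$; the threshold is a parameter (`z_clamp`).

A corrected statistic is converted to the variance in liability explained
through the squared-t identity for a univariate standardized regression,
$V_g = z^2/(z^2 + n - 2)$, and to a signed weight
$w = \mathrm{sign}(z)\sqrt{V_g}$.  Four weighting schemes are available
(`corrected_effects()`):

| method        | weight                                              |
|---------------|-----------------------------------------------------|
| `standard`    | $\mathrm{sign}(z)\sqrt{V_g(z)}$                     |
| `tweedie`     | $\mathrm{sign}(z)\sqrt{V_g(E(\delta\mid z))}$       |
| `tdr`         | standard weight $\times\ (1-\mathrm{fdr})$          |
| `tweedie_tdr` | Tweedie weight $\times\ (1-\mathrm{fdr})$           |

The same $V_g$ form is used for quantitative and case-control inputs (with
total $n$); a liability-scale conversion for odds-ratio inputs is an
extension hook, not a default, because its exact form depends on external
conventions.

## Scoring and clumping

`clump()` implements greedy PLINK-style LD-clumping on a genotype panel:
variants are visited by ascending p-value (ties broken by chromosome and
position, so results are reproducible), each unclaimed variant with
$p \le p_1$ becomes an index, and unclaimed variants within `window_kb`
(inclusive, default ±250 kb) on the same chromosome with squared Pearson
correlation above `r2` (default 0.25) and $p \le p_2$ are removed into its
clump.  Correlations are computed on mean-imputed, population-sd
standardized dosages.  `prs_score()` then sums weights over the kept
variants passing a p-value threshold; `threshold_grid()` supplies the fixed
18-value sweep ($10^{-5}$ … 1), whose final entry (threshold 1) is the
"all markers" score that needs no tuning.

## What the simulator emulates

`simulate_independent_study()` generates the benchmark design used
throughout the tests: $M$ = 20,000 biallelic markers with MAF drawn
uniformly on $[0.05, 0.5]$ and independent $\mathrm{Binomial}(2,
\mathrm{MAF})$ dosages; a fraction (default 2.5%) of markers causal with
Gaussian effects of variance $h^2/M_{\text{causal}}$ on the standardized
scale, rescaled so the per-variant variances sum to $h^2$ exactly; and
liability $y = \sum_i \beta_i x_i + \varepsilon$ with $\varepsilon \sim
N(0, 1-h^2)$, so the phenotype has unit variance.  For case-control
studies, disease status is liability above the $(1-K)$ normal quantile
(default prevalence $K = 0.45$), and individuals are simulated in batches
until each split holds exactly $n/2$ cases and $n/2$ controls.  Batch
liabilities use the theoretical dosage standardization
($(d - 2p)/\sqrt{2p(1-p)}$), since empirical standardization is undefined
before the sample is fixed; panels are re-standardized empirically once
sampled, as a real analysis would.  Summary statistics come from per-variant
linear regression (`gwas_scan()`); for binary traits the default is linear
regression on 0/1 status, which is monotone-equivalent to logistic at
GWAS-scale effects (a logistic option exists and agrees closely in tests).

Two further architectures support sensitivity analyses
(`simulate_effects()`): a sparse model with `n_large` markers each
explaining exactly `vg_per_large` of variance, and a Laplace mixture in
which a causal fraction carries $(1-\lambda) h^2$ via double-exponential
small effects and a second set of large effects with per-variant variance
$\sim U(0.4\%, 0.8\%)$ carries $\lambda h^2$ (default
`h2_large_fraction` $\lambda = 0.25$ — a configuration parameter, since no
canonical split exists).  Optional block-AR(1) LD (`ld = list(rho =,
block_size =)`) generates correlated dosages by thresholding
autocorrelated latent Gaussians per haplotype, so that clumping is
exercised with known ground truth.

The simulator deliberately does **not** emulate realistic LD beyond those
blocks, allele-frequency/effect-size coupling, population stratification,
genotyping error, or imputation uncertainty.  Passing benchmarks on these
synthetic panels therefore demonstrates correctness of the estimators under
the stated model, not performance on real cohort data.

## Numerical choices and edge cases

* Standardization divides by the population (divide-by-$n$) standard
  deviation; zero-variance markers become all-zero columns, are flagged,
  and report $z = 0$, $p = 1$ in scans.
* Records whose $z$ cannot be derived are rejected with a count;
  $p = 0$ rows (underflow in source files) are rejected unless a cap
  `z_max` (suggested 40) is configured.
* The locfdr Poisson fit falls back to a KDE density with central-matching
  null if it fails to converge, and flags the fit; an all-identical $z$
  vector is an error.
* Seeds: every stochastic entry point takes one master seed; stage seeds
  are derived deterministically (`child_seed()`), so studies and benchmark
  tables are bit-reproducible.
* `run_benchmark()` assembles one weight column per (method, threshold)
  and scores the test panel with a single matrix product; results are kept
  per replicate so summaries can be recomputed without reruns.

## Problem sizes used by the test-suite benchmarks

The packaged benchmark reproduction runs the quantitative scenario
($n_{\text{train}} = n_{\text{test}} = 5000$, $h^2 = 0.55$) at 10
replicates, the case-control scenario (2500+2500 per split) at 10
replicates, and the larger case-control scenario (5000+5000) at 5
replicates.  These replicate counts are the package's chosen benchmark
configuration; per-cell Monte-Carlo standard errors at these sizes are
about 0.005–0.01 on $R^2$/AUC.  Property checks (shrinkage slope,
closed-form two-group fdr, clump invariants) run at $n = 50{,}000$ draws
or 500-marker panels, where their oracles are tight.

## Known limitations

* LD is not modelled in the posterior: weights are corrected marker by
  marker, and residual correlation is handled only by pre-clumping.  Under
  dense LD with multiple causal variants per block, methods that model the
  full LD matrix can outperform these weights.
* The local fdr estimator is a binned approximation; with fewer than a few
  hundred markers its $\pi_0$ and null-sd estimates are noisy (a warning is
  issued below 200).
* The empirical-null MLE can absorb genuine weak signal into a slightly
  inflated null sd when the alternative density overlaps the centre; the
  theoretical-null option is preferable when the null is known to be
  exactly $N(0,1)$.
* Best-threshold performance reported by `run_benchmark()` selects the
  threshold on the test split itself.  This mirrors the standard PRS
  evaluation practice it benchmarks against and is optimistically biased;
  the all-marker columns are the unbiased-by-construction alternative.
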