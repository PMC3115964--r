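---
title: "Quantifying methylation levels from restriction-enzyme and bisulfite sequencing counts"
author: "methylquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying methylation levels from restriction-enzyme and bisulfite sequencing counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylquant)
```

## The measurement problem

Methyl-Seq interrogates DNA methylation at 5'-CCGG-3' sites by digesting
the same sample twice: once with MspI, which cuts every CCGG, and once
with HpaII, which cuts only unmethylated CCGG. After size selection and
sequencing, the tag count $x_i$ at site $i$ in the MspI library measures
how sequenceable the site is, while the HpaII count $y_i$ measures how
often it was *unmethylated* in the sampled molecules. Because samples are
heterogeneous cell mixtures, the estimand is not a binary state but the
methylation level $\mu \in [0,1]$ — the fraction of molecules methylated —
assumed constant across the handful of neighboring sites that form a
region. Genome-wide, regions are small: 77% contain exactly two cleavage
sites and 95% at most five, so per-region information is limited and the
random sampling noise of sequencing matters.

Before estimation, strand-level tag counts are collapsed by taking the
larger of the forward and reverse counts (summing would double-count
sites flanked by two nearby cleaved sites), and only sites with at least
4 MspI reads on one strand are considered assayable.

## The three Methyl-Seq estimators

**Binary call.** The historical approach: a region whose mean collapsed
HpaII count exceeds 1 is called unmethylated ($\mu = 0$), else methylated
($\mu = 1$). MspI counts are used only for assayability.

**Truncated Proportional Estimate (TPE).** Model the counts as a Poisson
thinning process: $x_i \sim \mathrm{Poisson}(\lambda_i)$ and
$y_i \sim \mathrm{Poisson}(c\,(1-\mu)\lambda_i)$, where $\lambda_i$ is the
site's local sequencing depth and $c$ the library-wide HpaII/MspI
depth-bias ratio. Maximizing the likelihood in $\mu$ gives
$$\hat\mu = \max\!\left(0,\; 1 - \frac{\sum_i y_i / \sum_i x_i}{c}\right),$$
the intuitive count ratio, truncated at 0 because sampling noise can push
the ratio above 1. The truncation makes the estimator biased downward at
low methylation and it piles estimates onto the exact values 0 and 1; with
regions this small, an observed-information variance would not be
trustworthy, so TPE is reported without a variance.

**Bayesian hierarchical model.** The same thinning likelihood with priors
$\mu \sim \mathrm{U}(0,1)$ and, in the default *negbin* mode, a
Gamma-Poisson mixture on the depths:
$\lambda_i \sim \mathrm{Gamma}(r_i, \text{rate}\ (1-p_i)/p_i)$ with
$p_i \sim \mathrm{U}(0,1)$ and $r_i \sim \mathrm{Gamma}(0.01, 0.01)$, so
the MspI count is marginally negative binomial ($3K+1$ parameters for a
$K$-site region). As the over-dispersion $r_i \to \infty$ this collapses
to the *poisson* mode, where $\lambda_i \sim \mathrm{Gamma}(0.001, 0.001)$
vague ($K+1$ parameters). The posterior mean is the estimate and the
posterior variance comes free — the practical advantage over TPE for
downstream association testing — and posterior mass never concentrates on
the boundary values 0 and 1.

The depth-bias ratio $c$ (per HpaII library) is estimated from the
genome-wide totals of CGG-aligned tags as HpaII-total / MspI-total
(`compute_depth_bias()`). The orientation matters and is easy to invert
silently: in this package `c < 1` always means "HpaII sequenced
shallower", the adjusted TPE divides the count ratio by `c`, and the
thinning rate is `c (1 - mu) lambda`. Because HpaII yield also depends on
methylation itself, the ratio conflates the two effects and the
correction is approximate; `c` is therefore exposed as data, not policy.

## The sampler

The paper-scale benchmarks need tens of thousands of independent region
fits, so the MCMC kernel is compiled (Rcpp) with all randomness drawn
from R's RNG — a fixed seed reproduces every fit bit-exactly.

Within a region, conjugacy does most of the work:

* $\lambda_i \mid \cdot \sim \mathrm{Gamma}(x_i + y_i + a_i,\;
  1 + c(1-\mu) + b_i)$, where $(a_i, b_i)$ is the prior (poisson mode) or
  $(r_i, (1-p_i)/p_i)$ (negbin mode);
* $\phi = 1-\mu \mid \cdot \sim \mathrm{Gamma}(\textstyle\sum y_i + 1,\;
  c \sum \lambda_i)$ truncated to $(0,1)$, drawn by inverse CDF evaluated
  in log space so the draw stays accurate whether the truncation keeps
  almost none or almost all of the Gamma mass.

The negbin-mode nuisance parameters need Metropolis steps. The mixture
rate $\eta_i = (1-p_i)/p_i$ uses an *independence* proposal
$\eta^\star \sim \mathrm{Gamma}(r_i + 1, \lambda_i)$, whose acceptance
ratio is just $((1+\eta)/(1+\eta^\star))^2$; a random walk on
$\mathrm{logit}\,p_i$ was rejected because the conditional's width shrinks
like $r^{-1/2}$, which would stall mixing exactly in the large-$r$ regime
used to validate the Poisson limit. $r_i$ gets a random walk on
$\log r_i$ (sd 0.8, configurable).

Defaults follow the published protocol: 3 chains from deterministically
staggered starting values $\mu_0 = k/4$, 500 burn-in and 500 retained
iterations per chain. Convergence is *reported* (Gelman-Rubin $\hat R$
over the pooled chains, flagged above 1.1) but not enforced; with $3K+1$
parameters and $K$ mostly 2, the conjugate chains converge in a handful
of iterations. Degenerate input (all counts zero) is an error; a region
with $\sum x = 0$ but HpaII signal still fits, since the likelihood
remains informative.

The test suite pins the sampler to deterministic quadrature oracles: in
poisson mode the $\lambda$-marginalized posterior of $\mu$ is
one-dimensional and grid-integrable, and posterior means must agree
within three Monte-Carlo standard errors (estimated from the spread of
many independent chain means, which honestly reflects autocorrelation).
The Poisson-limit check runs negbin mode with $r$ fixed at 2000 against a
poisson-mode run with a matched effectively-flat depth prior
($\mathrm{Gamma}(1, 10^{-9})$), because with $p \sim \mathrm{U}(0,1)$ and
large fixed $r$ the induced prior on $\lambda = r p/(1-p)$ is locally
flat — matching priors makes the limit a statement about the likelihood,
not about prior mismatch. Chains are lengthened there since the
$(\lambda_i, p_i)$ pair mixes at a rate of roughly $(x_i+y_i)/r$ per
sweep.

## RRBS

Reduced-representation bisulfite sequencing reads methylation directly:
methylated cytosines stay 'C', unmethylated convert to 'T'. With
$x \sim \mathrm{Poisson}(\mu\lambda)$ C-tags and
$y \sim \mathrm{Poisson}((1-\mu)\lambda)$ T-tags, the estimator is the
pooled proportion $\sum x_i / \sum (x_i + y_i)$. The C/T symmetry makes
its sampling variance symmetric in $\mu \leftrightarrow 1-\mu$ — in sharp
contrast to Methyl-Seq, where the MspI count acts as a noisy denominator
and the TPE variance inflates as $\mu \to 0$. The simulation benchmarks
verify this contrast empirically (the analytic argument is not
reproduced here).

## What the generators emulate — and what they do not

The synthetic-data module reproduces the benchmark designs the
estimators were validated on; its defaults are the study conditions and
are not tuned per run.

* **Truth distribution.** True levels are drawn from a U-shaped
  $\mathrm{Beta}(0.4, 0.4)$, a bimodal stand-in for the empirical
  microarray beta-value density, which is not published. This is the one
  place where the emulation is known to be coarse: the real density has
  sharper spikes near 0 and 1 than any smooth Beta. Quantities that
  depend on the exact shape of the truth density (correlations under
  noise, the Bayes-TPE gap) inherit some offset from this choice; the
  suite's depth-50 correlations land within a point of the published
  ones, while noisier designs sit a few points lower (see limitations).
* **Counts.** $x_i \sim \mathrm{Poisson}(\lambda)$ at a constant design
  depth, $y_{ij} \sim \mathrm{Poisson}(c_j(1-\mu_{gj})\lambda)$ drawn
  from the Poisson marginal (a tag-level binomial thinning variant with
  the identical marginal law sits behind a flag for thinning-property
  tests). Region sizes follow the published genome-wide quantiles
  (77% $K{=}2$, 95% $K \le 5$).
* **Benchmark scale.** 6 libraries × 155 regions = 930 levels per
  dataset, at depth 50 for the accuracy benchmark and depths 40–350 for
  the consistency sweeps.
* **Depth discordance.** Per region, the HpaII depth is drawn
  log-normally around the MspI depth,
  $\log \lambda_H \sim N(\log \lambda_M, \sigma^2)$, shared by the
  region's libraries; $\sigma = 0$ reduces bit-exactly to the basic
  generator under the same seed. The sweep uses
  $\lambda_M \in \{5, 30, 300\}$ and $\sigma \in \{0, 0.5, 1\}$.
* **Correlated neighboring sites.** Pairs $(\mu_1, \mu_2)$ share a Beta
  marginal and hit a target Pearson correlation through a Gaussian
  copula whose latent correlation is calibrated by Gauss-Hermite
  quadrature (80 nodes, Golub-Welsch), so the calibration is
  deterministic and exact to quadrature accuracy rather than fitted by
  simulation. MspI counts are held fixed at the design depth in this
  design, isolating the site- vs region-level question.
* **Technical replicates.** One truth table, two independent count
  draws.

Not emulated, deliberately: fragment-length selection bias, GC-driven
depth variation, dependence of a site's read yield on its neighbors'
methylation, inter-site autocorrelation priors, and read-level
artifacts (alignment, bisulfite conversion failure). Passing benchmarks
therefore demonstrate correctness of the estimators *under the count
model*, not robustness to every artifact of real libraries — the
depth-discordance design exists precisely to probe the first-order
violation of the equal-depth assumption.

## Numerical and design choices

* Coordinates are 1-based fully closed in the tag-count dialect; BED
  export converts to 0-based half-open explicitly.
* The tag-count reader drops non-assayable sites; the estimators still
  tolerate $x_i = 0$ sites supplied by callers (the formulas pool
  counts), and `sum(x) = 0` is an error rather than a silent default.
* Estimation is per (region, library); no pooling across libraries.
* `binary_call` uses the strict inequality (mean HpaII $> 1$), so a
  region at exactly 1 is called methylated.
* The Williams/Steiger $t$ (on $n-3$ df) is used for comparing two
  estimators' correlations with a shared truth; the choice is guarded by
  a simulation calibration test (type-I error $0.05 \pm 0.02$ on a
  simulated null) since the source literature names only "a t-test".
* AUC is the normalized Mann-Whitney statistic with midrank ties; the
  predictor orientation is an explicit flag because the historical
  HpaII-count predictor ranks *unmethylated* regions highest.
* Infinium renormalization floors background-subtracted intensities at
  zero and returns `NA` (not an error) when both channels are floored.
* Per-task seeds are derived from one global seed by a fixed integer
  recurrence kept inside 32-bit range, so dataset-level runs are
  reproducible end to end.

## Problem sizes used by the shipped benchmarks

The packaged acceptance runs use the published design sizes where they
are feasible at a desk: the depth-50 benchmark at full size (930 region
fits), and the discordance sweep at $\lambda_M = 30$ with 10 datasets
per $\sigma$ (the published design used 100); the replicate-consistency
and site-vs-region suites run at 100 regions × 2 libraries and 1000
sites respectively. These sizes are the package's own benchmarking
choices; every one of them is a function argument.

## Known limitations

* The Beta(0.4, 0.4) truth stand-in (above) shifts noise-sensitive
  summary statistics slightly relative to the unavailable empirical
  density; in the shipped discordance benchmark the $\sigma = 0.5$ cell
  averages ~0.86–0.87 where the published figure reads about 0.90.
* The depth-bias adjustment inherits the approximation of the published
  procedure: the CGG-tag ratio conflates methylation with depth, and no
  iterative re-adjustment is attempted.
* Region definitions are taken as given (`region_id`); the gap-based
  grouper is a stand-in for published region construction.
* No spatial autocorrelation across neighboring sites and no joint
  modeling across libraries.
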