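---
title: "Modeling cell-to-cell DNA methylation heterogeneity with methvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cell-to-cell DNA methylation heterogeneity with methvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methvar)
```

## The problem

Single-cell bisulphite sequencing measures DNA methylation at cellular
resolution, but each cell observes only a small, essentially random subset
of CpG sites. Binary calls at individual CpGs are therefore aggregated over
genomic features — promoters, enhancer peaks, or tiling windows — giving,
for cell $i$ and feature $j$, the number of covered CpGs $n_{ij}$ and the
number of those called methylated $Y_{ij}$. Even after aggregation the data
remain sparse (most feature-cell pairs are unobserved) and shallow
($n_{ij}$ is often below ten), so naive per-feature variance estimates are
dominated by binomial sampling noise and confounded by mean methylation.
`methvar` addresses this with a hierarchical beta-binomial model that
shares information across features and cells, and bases all downstream
decisions on posterior tail probabilities.

## The model

Counts follow a beta-binomial parameterized by mean and overdispersion:

$$Y_{ij} \mid \theta_{ij} \sim \text{Binomial}(n_{ij}, \theta_{ij}), \qquad
\theta_{ij} \sim \text{Beta}(\alpha_j, \beta_j),$$

with $\alpha_j = \mu_j(1-\gamma_j)/\gamma_j$ and
$\beta_j = (1-\mu_j)(1-\gamma_j)/\gamma_j$, so that
$E[\theta_{ij}] = \mu_j$ and $\gamma_j \in (0,1)$ is the intraclass
correlation of the CpG calls. The count variance then decomposes as

$$\text{Var}[Y_{ij}] =
\underbrace{n_{ij}\mu_j(1-\mu_j)}_{\text{binomial (technical)}} +
\underbrace{n_{ij}\mu_j(1-\mu_j)(n_{ij}-1)\gamma_j}_{\text{extra-binomial
(biological)}},$$

so $\gamma_j = 0$ recovers the binomial model and $\gamma_j$ measures
genuine cell-to-cell heterogeneity ([`bb_variance()`] exposes both terms;
both identities are verified against exact enumeration in the test suite).

Two regressions tie the features together:

* **Mean model.** $\text{logit}(\mu_j) \sim N(w_\mu^\top x_j, s_\mu^2)$
  where $x_j = (1, C_j)$ and $C_j$ is the standardized CpG density of the
  feature. Densely CpG-covered features (CpG islands) tend to be
  unmethylated, so the density coefficient is typically negative.
* **Mean-overdispersion trend.**
  $\text{logit}(\gamma_j) = f_\gamma(\mu_j; w_\gamma) + \epsilon_j$, with
  $\epsilon_j \sim N(0, s_\gamma^2)$ and
  $f_\gamma(\mu) = w_{\gamma 1} + \sum_{l=2}^{L} w_{\gamma l}\, g_l(\mu)$
  a radial-basis regression. The **residual overdispersion** $\epsilon_j$
  is the package's measure of variability: it quantifies how much more (or
  less) variable a feature is than features with the same mean, and is
  therefore unconfounded by the strong mean-variance relationship of
  methylation data.

The basis uses $L = 4$ coefficients by default: an intercept plus three
Gaussian kernels with centers at $0.25, 0.5, 0.75$ and bandwidth equal to
the center spacing. The exact kernel shape only relabels $w_\gamma$;
$\epsilon_j$ is defined relative to whatever trend is fitted, which is why
the default basis is shared between the simulator and the fitting code.

Priors on the global parameters are weakly informative on the logit scale:
$N(0, 2)$ on every regression coefficient and half-normal(1) on $s_\mu$
and $s_\gamma$, all adjustable through `prior_config()`.

## Inference

The posterior is not tractable analytically, and joint posterior modes are
unusable for the hierarchical scales: optimizing features and scales
together collapses $s_\gamma \to 0$ in the centered parameterization and
inflates it in the non-centered one (both are manifestations of the
well-known funnel geometry). `fit_model()` therefore estimates the eight
global parameters $(w_\mu, w_\gamma, \log s_\mu, \log s_\gamma)$ by
maximizing a **Laplace-approximated marginal posterior**: given the
globals, features are conditionally independent, and each feature's pair
$(\text{logit}\,\mu_j, \text{logit}\,\gamma_j)$ is integrated out by an
exact 2-D Laplace block. The marginal optimum is located by an EM-style
loop — per-feature Newton modes as the E-step, closed-form ridge and
variance updates as the M-step — monitored on the exact marginal objective
and finished with a short simplex polish. Posterior draws (default 4,000)
are then taken from the Gaussian curvature of the globals and from each
feature's conditional 2-D Laplace block; `gamma` draws are reconstructed
through the trend, so the identity
$\text{logit}(\gamma) = f_\gamma(\mu; w_\gamma) + \epsilon$ holds exactly
in every draw.

Because counts are small integers, every digamma/trigamma/log-gamma
difference in the likelihood reduces, via the recurrence
$\psi(x+k) - \psi(x) = \sum_{m=0}^{k-1} (x+m)^{-1}$, to a short
reciprocal sum over pooled tail counts. A full likelihood/gradient/Hessian
sweep is $O(\max n)$ per feature rather than $O(\text{cells})$
special-function calls, which is what makes whole-dataset fits take
seconds.

An independent `method = "mcmc"` path runs Metropolis-within-Gibbs in the
non-centered space (per-feature 2-D blocks plus a joint global block, with
proposals shaped by the joint curvature). It exists as a cross-check: on
simulated data the two methods' posterior-median overdispersion estimates
correlate above 0.9 (asserted in the test suite), and the sampler is free
of the mode biases discussed above because warmup moves it off the
initialization. Missing entries contribute nothing to the likelihood under
either method; no imputation is performed.

Numerical choices: $\mu$ and $\gamma$ are clamped to
$[10^{-6}, 1-10^{-6}]$ inside the inference likelihood (the exported
`bb_loglik()` clamps $\gamma$ only below $10^{-10}$ so the binomial limit
is numerically faithful); inner Newton steps are damped, capped at 4 logit
units, and fall back to a ridge when curvature is indefinite; the
convergence tolerance `elbo_tol` (default $10^{-4}$) applies to the
objective improvement between iterations, with `max_iter` (default
50,000) as a cap; identical seeds give bitwise-identical draws.

## Decision rules

All tests are posterior tail probabilities calibrated to control the
expected false discovery rate

$$\text{EFDR}(\alpha) = \frac{\sum_j (1-\pi_j)\,\mathbb{1}[\pi_j > \alpha]}
{\sum_j \mathbb{1}[\pi_j > \alpha]},$$

searched over a grid $\alpha \in \{0.600, 0.605, \dots, 0.995\}$,
preferring values whose EFDR is at or below the target and breaking ties
toward the larger (more conservative) threshold; when no feature clears
any grid point the fallback $\alpha = 0.9$ is used with a warning.

* **Highly variable features** (`detect_hvf()`): $\epsilon_0$ is the
  `delta_e` (default 0.9) quantile of the per-feature posterior medians of
  $\epsilon$ (a pooled-draw variant is available via `use_pooled`);
  $\pi_j = P(\epsilon_j > \epsilon_0 \mid \text{data})$ is estimated as
  the fraction of draws exceeding $\epsilon_0$; the default EFDR target is
  10%.
* **Differential mean** (`dm_test()`): groups are fitted independently and
  draws paired by index; the statistic is the log-odds ratio
  $\text{logit}(\mu^A_j) - \text{logit}(\mu^B_j)$ with minimum effect
  `psi_m` (default $\log 2$, a two-fold odds change) and EFDR target 5%.
* **Differential variability** (`dv_test()`): the statistic is
  $\epsilon^A_j - \epsilon^B_j$ with minimum effect `psi_e` (default
  $\log 1.5$). The overdispersion log-odds ratio decomposes exactly, per
  draw, into a trend part (the change in $f_\gamma$ explained by mean
  methylation, computed per group as
  $\text{logit}(\gamma) - \epsilon$) plus this residual change; testing
  the residual is what keeps variability calls decoupled from mean shifts.
  Both tables report the decomposition medians.

A Fisher's-exact baseline (`fisher_dm()`) pools counts within groups and
calls features with pooled $|\text{LOR}| > \log 1.5$ and BH-adjusted
$p < 0.1$; its p-values are checked against direct hypergeometric
enumeration in the tests. Four baseline HVF rankings
(`rank_hvf_baseline()`) — binomial variance, Gaussian standard deviation,
bin-normalized dispersion, and random — are included for comparison
studies.

## The synthetic-data generator

`simulate_dataset()` draws, per feature, a cell-coverage probability
$p_j \sim U(0.4, 0.8)$ and CpG-coverage probability
$q_j \sim U(0.4, 0.8)$; $I_j \sim \text{Binomial}(I, p_j)$ cells observe
the feature, each with $n_{ij} \sim \text{Binomial}(N, q_j)$ covered CpGs
(zeros redrawn, since a covered cell must observe at least one CpG), under
three density regimes: rich ($N = 50$), moderate ($N = 15$, the default),
poor ($N = 8$). Mean methylation is logit-normal around the covariate
regression with $w_\mu = (-0.5, -1.5)$ and $s_\mu = 1$; overdispersion is
logit-normal around the radial-basis trend with
$w_\gamma = (-1.2, -0.3, 1.1, -0.9)$ and $s_\gamma = 0.25$. The CpG
density covariate is the standardized $q_j$ — the only density-like
per-feature quantity in the recipe — so the negative weight reproduces the
expected negative association between density and mean methylation.
`simulate_two_groups()` perturbs a 15% subset of features by a fixed
logit-scale offset (sign by fair coin) on either $\mu$ or $\gamma$;
shifting $\text{logit}(\gamma)$ with $\mu$ untouched shifts the true
$\epsilon$ by exactly the same amount.

The generator emulates partial cell and CpG coverage, the mean-density
association, the mean-overdispersion trend, and beta-binomial counts. It
does **not** emulate genomic coordinates or spatial correlation along the
genome, batch or library-size effects, non-CpG methylation, doublets, or
mapping artifacts — so green tests certify the statistical machinery under
the model's own assumptions, not robustness to every failure mode of real
libraries.

## Quality control

`apply_qc()` applies, in order: censoring of entries with fewer than 3
covered CpGs; removal of features covered in fewer than 15 cells (5 is
recommended for small datasets, as in the down-sampling experiment);
removal of features with across-cell mean methylation outside
$[0.1, 0.9]$ (fully (un)methylated features carry no heterogeneity
signal, and their overdispersion estimates are dominated by single
outlier cells); and removal of features whose mean coverage falls below a
threshold that adapts to the number of cells (3 above 100 cells, 5 below
50, midpoint 4 in the gap, where estimation uncertainty justifies the
stricter floor). The mean-methylation bound uses the unweighted mean of
per-cell rates. The order censor-first means every later statistic is
computed on the censored data. Features whose posterior sd of $\epsilon$
exceeds 0.5 are flagged `uncertain_epsilon` in `posterior_summary()`.

## Design decisions

* **Coordinates.** Annotations are 0-based half-open (BED); CpG call
  positions are 1-based (bisulphite coverage files); conversion happens
  only inside `aggregate_to_features()`. Promoters are centered windows
  $[t - \text{flank}, t + \text{flank})$ around the TSS, identical for
  both strands.
* **Binarization.** A site is methylated iff methylated reads outnumber
  unmethylated reads; ties are dropped from both counts. Majority vote is
  the least surprising rule and ties are rare at single-cell depth.
* **Terminal windows.** Clipped tiling windows are kept iff at least half
  the nominal width remains, preventing tiny-coverage artifacts.
* **Duplicate rows** in count tables are an error, not summed — silent
  summation hides upstream bugs.
* **$\epsilon$ at per-draw $\mu$.** The trend is evaluated at each draw's
  own $\mu$ and coefficients (full uncertainty propagation), not at a
  point estimate.
* **Trend term of the DV decomposition.** The decomposition of the
  overdispersion LOR uses the $\gamma$-trend evaluated per group; this is
  the only choice under which the per-draw identity holds, and it is
  asserted to $10^{-10}$ in the tests.
* **Per-chromosome fits.** `combine_fits()` concatenates independent fits
  over disjoint feature partitions; global parameters stay
  partition-specific, and HVF/differential calls run on the concatenated
  per-feature draws (`--by-chrom` in the CLI).
* **Draw pairing.** Groups are fitted independently, so any pairing of
  their draws is valid; index pairing (after seeded subsampling of the
  larger fit) is used for reproducibility.

## Problem sizes and what the checks show

The test suite exercises the full pipeline at the simulation design's
standard scale — 300 features with 20 to 300 cells, moderate CpG density —
chosen so each fit completes in seconds while leaving enough signal for
the power and calibration properties to be sharp. The acceptance script
(`scripts/acceptance.R`) recomputes the two headline quantities from
scratch: differential-variability power at effect size 5 with 50 cells per
group and at effect size 2 with 300 cells per group, each averaged over
five seeds. Calibration checks (null call rates, decoupling of DV calls
from mean-only perturbations, HVF false discovery proportion under QC) are
asserted at twice the nominal EFDR target to leave room for Monte Carlo
noise at these problem sizes.

## Known limitations

* The default fit is a Gaussian approximation: skewed feature posteriors
  (very shallow coverage, boundary-adjacent $\mu$) are summarized by a
  symmetric approximation, and global-parameter uncertainty is propagated
  through a quadratic expansion. The MCMC path exists precisely to audit
  this; on the simulated designs the two agree closely.
* Under strong group-specific perturbations the perturbed group's
  $s_\gamma$ estimate inflates, which loosens shrinkage for its null
  features and can raise the realized false discovery proportion of the
  DV test above its nominal EFDR even though power targets are met; the
  null-data calibration is unaffected.
* Feature-level aggregation discards within-feature spatial structure;
  the model assumes exchangeable CpG calls within a feature.
* Overdispersion is weakly identified for features observed in few cells
  or at extreme mean methylation — hence the QC defaults and the
  `uncertain_epsilon` flag.
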