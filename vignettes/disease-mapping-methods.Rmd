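---
title: "Methods: hierarchical disease mapping and Bernoulli scan statistics for survey data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical disease mapping and Bernoulli scan statistics for survey data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models implemented in `bymscan`,
the assumptions and numerical choices behind them, and what the synthetic
data generator does and does not emulate. It is written in the spirit of a
model-documentation vignette: every empirical claim here is one the test
suite or `scripts/acceptance.R` actually computes.

## 1. The setting

The package targets binary outcomes measured in two-stage stratified
cluster surveys (the DHS design family): households are sampled within
enumeration areas (the primary sampling units, PSUs), PSUs within strata
defined by region crossed with urban/rural, and each respondent carries a
design weight proportional to her inverse inclusion probability. Analyses
have three layers:

1. *Design-weighted description* — national and subgroup prevalences that
   respect weights, strata and clustering.
2. *Model-based smoothing* — a hierarchical spatial logistic regression
   that borrows strength across neighbouring areas to stabilise small-area
   prevalence estimates and to estimate covariate effects.
3. *Cluster detection* — a spatial scan statistic that tests where rates
   are significantly elevated (or depressed) relative to the rest of the
   map.

## 2. Hierarchical spatial logistic regression

For respondent $i$ living in area $s_i$, $Y_i \sim \text{Bern}(p_i)$ with

$$\operatorname{logit} p_i = \beta_0 + x_i'\beta + f_s(s_i) + f_u(s_i).$$

The covariates are categorical with treatment (dummy) coding; the lowest
declared level of each factor is the default reference and references are
user-configurable (`reference_levels`), since published tables sometimes
disagree with their own text about which level was used as reference.

* $f_u$ is an exchangeable area effect, $f_u(a) \mid \tau_u \sim
  N(0, \tau_u^{-1})$ iid — "excess heterogeneity".
* $f_s$ is an intrinsic CAR (intrinsic Gaussian Markov random field)
  effect: its improper prior kernel is
  $\tau_s^{(n-k)/2}\exp\{-\tfrac{\tau_s}{2}\sum_{i\sim j}(f_{s i}-f_{s j})^2\}$,
  where $n$ is the number of areas and $k$ the number of connected
  components of the adjacency graph. The quadratic form equals $f_s' Q
  f_s$ for the graph Laplacian $Q$ (`structure_matrix()`), which has rank
  $n-k$.
* Fixed effects have independent $N(0, \tau_\beta^{-1})$ priors with
  $\tau_\beta = 10^{-4}$ by default (near-flat).
* Precisions carry vague Gamma(shape $a$, rate $b$) priors with default
  $a = 0.5$, $b = 0.0005$ — a standard weakly-informative disease-mapping
  choice. The source analyses this package generalises state only that
  "vague" gamma priors were used, so the exact hyperparameters are an
  explicit, configurable assumption here.

The model ladder Model 1 (neither effect), Model 2 ($f_u$), Model 3
($f_s$), Model 4 (both, the Besag–York–Mollié convolution) is compared by
DIC.

### 2.1 Inference: MCMC rather than nested Laplace approximation

Analyses of this type are often fitted with integrated nested Laplace
approximations. This package instead samples the identical posterior by
Markov chain Monte Carlo. That is a deliberate methodological choice: an
MCMC sampler can be verified piecewise (conjugate conditionals against
their analytic gamma densities, fixed-effect posteriors against maximum
likelihood at large $n$, parameter recovery on simulated data), which
suits a package whose purpose includes being testable without restricted
microdata.

The sampler (C++ core) is Metropolis-within-Gibbs:

* Random-walk proposals for $\beta_0$ and each $\beta_j$, with proposal
  scales adapted every 50 iterations during burn-in toward a 35%
  acceptance rate (the standard scalar random-walk target range of
  20–50%), then frozen so the post-burn-in chain satisfies detailed
  balance.
* Single-site random-walk updates for each $f_s(a)$ and $f_u(a)$. The
  ICAR prior contribution uses the local pairwise-difference form, so each
  site update costs only its neighbourhood.
* Conjugate draws $\tau_u \sim \Gamma(a + n/2,\; b + \tfrac12\sum_a
  f_u(a)^2)$ and $\tau_s \sim \Gamma(a + (n-k)/2,\; b + \tfrac12
  \sum_{i\sim j}(f_{si}-f_{sj})^2)$.
* Likelihood evaluations use binomial cells aggregated by (area ×
  covariate pattern), which is exact for categorical covariates and makes
  the per-iteration cost depend on the number of distinct cells rather
  than the number of respondents.

**Identifiability.** The ICAR prior is invariant to adding a constant per
connected component, so after each sweep $f_s$ is re-centred to sum to
zero within each component. On a connected map the subtracted mean is
added to $\beta_0$, leaving the linear predictor — and hence the posterior
— exactly invariant. On disconnected maps a single intercept cannot absorb
per-component shifts, so the sampler uses the classical
centering-on-the-fly convention instead; isolated areas have their $f_s$
pinned at zero. Stored draws satisfy the constraint to machine precision.

**Defaults.** 20 000 iterations, 5 000 burn-in, thinning 5; a seed is
mandatory (`mcmc$seed`), and identical seeds reproduce draws exactly. The
test suite and acceptance script use 8 000 iterations (1 200 stored
draws), a length at which fixed-effect posterior means sit within Monte
Carlo error of maximum-likelihood fits at $n = 3000$ and effective sample
sizes for $\beta_0$ are several hundred.

### 2.2 DIC

$\mathrm{DIC} = \bar D + p_D$ with $\bar D$ the posterior mean of the
Bernoulli deviance $-2\log L$ over stored draws, and $p_D = \bar D -
D(\hat\theta)$ evaluated at the posterior means of the linear-predictor
parameters ($\beta_0$, $\beta$, $f_s$, $f_u$). `select_best_model()`
takes the DIC argmin; exact ties go to the smaller model number, i.e. the
earlier, simpler entry in the ladder. On data simulated with a strong
structured field, Model 3 beats Model 1 by large margins (the acceptance
suite measures the win rate and the mean DIC gap); on data without
spatial structure Model 1 stays within a few DIC units of the spatial
model, reflecting the small effective parameter count a shrunk-away
random effect contributes.

### 2.3 Posterior prevalence maps

For each stored draw and each area, prevalence is the average of
$\operatorname{logit}^{-1}$(linear predictor) over that area's observed
covariate cells (weighted by cell size); summarising over draws gives the
posterior mean, median and 2.5%/97.5% maps. Areas with no respondents are
evaluated at reference covariate values and flagged `extrapolated`. Both a
covariate-adjusted map (from the full model) and an intercept-plus-spatial
map (fit the model with no factors) are possible, since published maps of
this kind rarely state which was used.

## 3. Design-weighted survey estimation

* **Prevalence** uses the ratio estimator $\hat p = \sum w_i y_i / \sum
  w_i$ with the stratified between-PSU Taylor-linearisation variance and
  $t$ intervals on design degrees of freedom (#PSUs − #strata), computed
  on the logit scale and back-transformed — the convention of the major
  survey packages, which keeps intervals inside $[0,1]$. Wald intervals
  are available behind a flag. A stratum with a single PSU is an error
  instructing collapse rather than a silent variance understatement.
* **Tests of association** use the Pearson chi-square on weighted cell
  proportions with the second-order (Satterthwaite) Rao–Scott correction,
  referred to an $F$ distribution — the default of the survey software
  whose output layout the descriptive table mirrors. Under iid sampling
  the corrected statistic tracks the ordinary Pearson chi-square (the
  suite checks agreement within 2% at $n = 5000$) and its p-values are
  near-uniform under independence. For degenerate tables whose
  design-effect matrix is singular (e.g. structural-zero cells), the
  correction falls back to unit design effects.
* **Media exposure index**: items are standardised, the first principal
  component of their correlation matrix is extracted, the sign is fixed by
  requiring a nonnegative loading sum (higher score = more exposure), and
  respondents are cut at *weighted* tertiles into low/mid/high. Ties at a
  boundary go to the lower category, deterministically. Tertiles are an
  assumption: source analyses of this kind state only that respondents
  were "classified as low, medium or high".

## 4. Bernoulli spatial scan statistic

Aggregated per-area cases $c_i$ and totals $n_i$ are scanned with
circular windows: for each centroid, areas are sorted by great-circle
distance (haversine, Earth radius 6371 km; ties broken by map order) and
the nested prefixes form candidate windows, capped at 50% of the at-risk
population — the conventional maximum, configurable, and echoed into
output headers because published scans often omit it. The one-sided
Bernoulli log-likelihood ratio is evaluated for every window; high- and
low-rate scans are run separately.

Inference conditions on the totals and the overall case count: each Monte
Carlo replicate redistributes the $C$ cases among the $N$ individuals
without replacement (a multivariate hypergeometric draw per area),
rescans, and records the maximum LLR. P-values use $(R+1)/(S+1)$ so they
can never be zero, and secondary clusters are selected greedily in LLR
order under a strict no-geographical-overlap rule, stopping at the chosen
significance level (default α = 0.05), matching reports that list
disjoint "most likely / secondary / third" clusters.

The implementation is validated two ways: exact agreement (LLR to
$10^{-9}$, identical windows, identical relative risks) with an
independent exhaustive enumeration on hundreds of random small maps, and
calibration of the Monte Carlo test's type-I error at α = 0.05 within
Monte Carlo error on null data.

**Weighted counts.** When aggregating weighted records for the scan, real
analyses rarely say whether counts were weighted. Both modes are
supported; the weighted mode scales weighted sums to preserve the overall
unweighted case and respondent totals and rounds by largest remainder so
the scan receives integers whose grand totals match the sample
(unweighted is the default).

## 5. The synthetic survey generator

`make_lattice_map()` + `simulate_icar_field()` + `simulate_survey()`
produce ground-truth data: a rook-adjacency lattice standing in for a
county system, an ICAR field drawn through the spectral pseudo-inverse of
$Q$ (centred per component; isolated areas zero), and respondents sampled
under the declared design with outcomes from the exact logistic model.
Default design: 4 regions, 2 PSUs per area alternately labelled
urban/rural, 25 respondents per PSU, covariate levels uniform and
independent of area (an `area_confounded` mode exists for robustness
experiments). Weights are inverse inclusion probabilities — constant under
this equal-allocation design — jittered lognormally with log-sd
`weight_dispersion` and normalised to mean 1, so `weight_dispersion = 0`
yields weights exactly 1.

What this emulates: the nesting, stratification, weighting and
spatial-confounding structure that the estimators must respect. What it
does not: questionnaire content, household rosters, nonresponse,
informative weighting, or real administrative geography. Passing tests
therefore demonstrate the estimators' correctness under a faithful design
model, not robustness to every pathology of real survey data.

## 6. Numerical and design choices

* $0\log 0 = 0$ throughout the scan likelihood; windows equal to the whole
  region score 0; a window with rate exactly at the overall rate scores 0
  in both directions.
* Relative risk $(c/E)/((C-c)/(C-E))$ reports `Inf` when all cases fall
  inside the window.
* Distance ties and equidistant windows resolve by map (file) order, so
  runs are reproducible across platforms.
* Adjacency input is explicit (GAL dialect) rather than derived from
  polygons: which contiguity rule generated a published county graph is
  usually unstated, so the graph is taken as data. One-directional
  adjacency entries are symmetrised with a warning; unknown or duplicate
  ids are errors naming the offender.
* The ICAR draw uses the spectral pseudo-inverse rather than conditional
  simulation: exact, and cheap at the map sizes involved.
* Problem sizes in the test and acceptance runs — 30-area lattices,
  $n = 3000$ respondents, 8 000 MCMC iterations, 500 null scans of 999
  replicates — were chosen as the smallest sizes at which the measured
  properties (ML agreement, coverage, type-I error) are stable; the
  package itself has no such limits.

## 7. Known limitations

* Single-chain sampling; no cross-chain convergence diagnostic is built
  in (inspect `samples` with your favourite diagnostics).
* Single-site updates mix slowly on very strong spatial fields with tiny
  areas; the intercept/field trade-off is the slowest direction.
* The scan supports circular windows and the Bernoulli model only — no
  elliptic windows, space-time scans, or covariate adjustment.
* Survey estimation covers single-response categorical tables; no
  replicate-weight (jackknife/BRR) variances, no imputation.
* DIC is reported as the deviance-based criterion defined above;
  alternatives (WAIC, cross-validation) are out of scope.
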