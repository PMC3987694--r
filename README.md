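# bymscan

Spatial analysis of binary outcomes measured in complex household surveys:
disease mapping with Besag–York–Mollié-type hierarchical logistic models,
and local cluster detection with a Bernoulli spatial scan statistic.

The package is aimed at epidemiologists and biostatisticians who have
individual-level survey records (a binary outcome, categorical covariates,
design weights, strata and primary sampling units, and an area identifier)
plus an area geography (centroids and an adjacency list), and who want the
standard small-area analysis of prevalence: design-correct descriptive
estimates, smoothed posterior risk maps, and significance-tested spatial
clusters. Because the survey microdata such analyses are usually run on are
access-restricted, the package ships a synthetic generator for DHS-like
two-stage stratified cluster samples with known ground truth, so the whole
pipeline is testable end to end.

## The models

**Hierarchical spatial logistic regression.** For respondent *i* in area
*s*ᵢ with outcome *Y*ᵢ ~ Bernoulli(*p*ᵢ),

```
logit p_i = β0 + x_i'β + f_s(s_i) + f_u(s_i)
```

where *f*ᵤ is an unstructured iid area effect, *f*ₛ a spatially structured
effect with an intrinsic CAR (Gaussian Markov random field) prior whose
kernel penalises squared differences between neighbouring areas, and the
precisions τₛ, τᵤ carry vague Gamma priors. Four nested models are
compared by DIC: Model 1 (no area effects), Model 2 (*f*ᵤ only), Model 3
(*f*ₛ only), Model 4 (both). Posteriors are sampled by an adaptive
Metropolis-within-Gibbs sampler (Rcpp core) with conjugate gamma updates
for the precisions and a hard sum-to-zero constraint on *f*ₛ.

**Bernoulli spatial scan.** Cases and totals aggregated to areas are
scanned with circular windows (distance-ordered prefixes from every
centroid, capped at half the at-risk population). Each window's Bernoulli
log-likelihood ratio

```
LLR = c ln(c/n) + (n−c) ln((n−c)/n) + (C−c) ln((C−c)/(N−n))
    + (N−n−C+c) ln(1−(C−c)/(N−n)) − C ln(C/N) − (N−C) ln((N−C)/N)
```

is maximised over windows; significance comes from Monte Carlo
randomisation of the cases conditional on totals, and non-overlapping
secondary clusters are reported in LLR order with relative risks.

**Survey estimation.** Design-weighted prevalence with stratified
between-PSU Taylor-linearised variances and logit-scale confidence
intervals; weighted cross-tabulations tested with the second-order
(Satterthwaite) Rao–Scott F correction; and a principal-components media
exposure index cut at weighted tertiles.

## Worked example: cluster detection

Eight synthetic areas with a deliberate high-rate cluster in the north
(data shipped in `inst/extdata`):

```r
library(bymscan)
ext <- system.file("extdata", package = "bymscan")
map   <- read_area_map(file.path(ext, "demo_centroids.csv"),
                       file.path(ext, "demo_adjacency.gal"))
cases <- read_case_data(file.path(ext, "demo_cases.csv"))
res <- monte_carlo_pvalues(cases, map, "high", replications = 999, seed = 42)
secondary_clusters(res, 0.05)
#>   rank center_area observed expected relative_risk p_value
#> 1    1      north1      120 55.25463      3.438535   0.001
```

The most likely cluster is `north1, north2`: 120 observed cases against
55.25 expected under the overall rate, relative risk 3.44 inside versus
outside, and none of the 999 case-randomised replicates reached the
observed LLR (p = 0.001).

## Worked example: model fitting and mapping

```r
map <- make_lattice_map(5, 6)                      # 30 areas
f_s <- simulate_icar_field(map, tau_s = 2, seed = 1)
truth <- truth_set(beta0 = -1,
                   beta = c("edu=primary" = 0.5, "edu=secondary" = 1.0),
                   f_s = f_s, tau_s = 2)
records <- simulate_survey(map, truth,
                           design = list(respondents_per_psu = 50),
                           factor_spec = list(edu = c("none", "primary", "secondary")),
                           seed = 2)
weighted_prevalence(records)
#> 39.2% (95% CI: 36.5-41.9%), se = 0.0134, design df = 52

mc <- list(iterations = 8000, burn_in = 2000, thin = 5)
fit1 <- fit_model(records, map, model_spec(),
                  mcmc = c(mc, seed = 11))
fit3 <- fit_model(records, map, model_spec(include_structured = TRUE),
                  mcmc = c(mc, seed = 13))
fit3
#> Model 3 fit: 1200 stored samples, DIC = 3820.65, pD = 23.80
select_best_model(list(`1` = fit1, `3` = fit3))
#> [1] 3
odds_ratio_table(fit3)
#>            term   or ci_low ci_high reference
#> 1      edu=none 1.00   1.00     1.0      TRUE
#> 2   edu=primary 1.89   1.60     2.3     FALSE
#> 3 edu=secondary 2.62   2.17     3.1     FALSE
head(posterior_prevalence_map(fit3)[, 1:5], 2)
#>   area_id mean median q025 q975
#> 1     A01 0.33   0.33 0.25 0.41
#> 2     A02 0.24   0.24 0.17 0.31
```

The spatial model (Model 3) beats the ordinary logistic model by over 100
DIC units on data with a genuine structured field, the odds ratios bracket
the simulated effects (1.65 and 2.72 on the OR scale), and the posterior
map columns are the mean/median/2.5%/97.5% per-area prevalences used for
choropleth output (`write_choropleth`, `posterior_prevalence.geojson`).

A full configuration-driven run (simulate → describe → fit 4 models →
map → scan → report with a reproducibility manifest) is available through
`run_pipeline()`; see `inst/scripts/run_pipeline.R` for a shell wrapper.

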