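# Independent reference implementations used as test oracles. These are
# deliberately written from the defining formulas, on different code paths
# than the package internals they check.

# Bernoulli scan LLR from the rate parameterization (0 log 0 = 0 handled via
# explicit guards); one-sided.
oracle_llr <- function(c, n, C, N, direction) {
  if (n == 0 || n == N) return(0)
  p1 <- c / n
  p2 <- (C - c) / (N - n)
  p0 <- C / N
  if (direction == "high" && !(p1 > p0)) return(0)
  if (direction == "low" && !(p1 < p0)) return(0)
  term <- function(k, size, p) {
    if (size == 0) return(0)
    v <- 0
    if (k > 0) v <- v + k * log(p)
    if (size - k > 0) v <- v + (size - k) * log(1 - p)
    v
  }
  term(c, n, p1) + term(C - c, N - n, p2) - term(C, N, p0)
}

# Exhaustive scan: every center, every distance-ordered prefix window under
# the population cap; returns the global max LLR and its window.
oracle_scan <- function(cases, totals, map, direction, max_fraction = 0.5) {
  D <- distance_matrix(map)
  C <- sum(cases)
  N <- sum(totals)
  n_areas <- length(cases)
  best <- list(llr = 0, members = integer(0))
  for (ctr in seq_len(n_areas)) {
    ord <- order(D[ctr, ], seq_len(n_areas))
    for (k in seq_len(n_areas)) {
      w <- ord[seq_len(k)]
      n_in <- sum(totals[w])
      if (k > 1 && n_in > max_fraction * N) break
      llr <- oracle_llr(sum(cases[w]), n_in, C, N, direction)
      if (llr > best$llr + 1e-12) {
        best <- list(llr = llr, members = sort(w),
                     c = sum(cases[w]), n = n_in)
      }
    }
  }
  best
}

# Term-by-term log-posterior from normalized densities (matches the package
# value up to an additive constant, so compare differences between samples).
oracle_log_posterior <- function(sample, data, spec, map) {
  eta <- rep(sample$beta0, length(data$y))
  if (ncol(data$X) > 0) eta <- eta + as.vector(data$X %*% sample$beta)
  if (spec$include_structured) eta <- eta + sample$f_s[data$area_idx]
  if (spec$include_unstructured) eta <- eta + sample$f_u[data$area_idx]
  lp <- sum(stats::dbinom(data$y, 1, stats::plogis(eta), log = TRUE))
  sdb <- 1 / sqrt(spec$beta_prior_precision)
  lp <- lp + stats::dnorm(sample$beta0, 0, sdb, log = TRUE) +
    sum(stats::dnorm(sample$beta, 0, sdb, log = TRUE))
  if (spec$include_unstructured) {
    lp <- lp + sum(stats::dnorm(sample$f_u, 0, 1 / sqrt(sample$tau_u),
                                log = TRUE)) +
      stats::dgamma(sample$tau_u, spec$prior_a, rate = spec$prior_b, log = TRUE)
  }
  if (spec$include_structured) {
    quad <- 0
    ids <- map$area_ids
    for (i in seq_along(ids)) {
      for (nb in map$neighbors[[i]]) {
        j <- match(nb, ids)
        if (j > i) quad <- quad + (sample$f_s[i] - sample$f_s[j])^2
      }
    }
    k <- map$n_components
    lp <- lp + 0.5 * (length(ids) - k) * log(sample$tau_s) -
      0.5 * sample$tau_s * quad +
      stats::dgamma(sample$tau_s, spec$prior_a, rate = spec$prior_b, log = TRUE)
  }
  lp
}

# random small case/control instance for oracle-equivalence sweeps
random_instance <- function(n_areas, seed) {
  set.seed(seed)
  map <- area_map(
    paste0("z", seq_len(n_areas)),
    cbind(runif(n_areas, -2, 2), runif(n_areas, -2, 2)),
    replicate(n_areas, character(0), simplify = FALSE))
  totals <- sample(5:30, n_areas, replace = TRUE)
  rate <- runif(1, 0.05, 0.4) + sample(c(0, 0.4), n_areas, replace = TRUE,
                                       prob = c(0.7, 0.3))
  cases <- rbinom(n_areas, totals, pmin(rate, 0.9))
  if (sum(cases) == 0) cases[1] <- 1L
  list(map = map,
       data = data.frame(area_id = map$area_ids, cases = cases,
                         total = totals, stringsAsFactors = FALSE))
}

# small survey with known spatial signal for model tests
demo_survey <- function(seed, rows = 5, cols = 6, per_psu = 50,
                        fs_scale = 1.5, tau_s = 2) {
  map <- make_lattice_map(rows, cols)
  f <- simulate_icar_field(map, tau_s, seed = seed) * fs_scale
  fspec <- list(edu = c("none", "primary", "secondary"))
  tr <- truth_set(beta0 = -1,
                  beta = c("edu=primary" = 0.5, "edu=secondary" = 1.0),
                  f_s = f, tau_s = tau_s)
  rec <- simulate_survey(map, tr, design = list(respondents_per_psu = per_psu),
                         factor_spec = fspec, seed = seed + 1000)
  list(map = map, records = rec, truth = tr)
}
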