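#' Specify one of the four hierarchical logistic models
#'
#' The model ladder compared by DIC: Model 1 is ordinary Bayesian logistic
#' regression (no area effects), Model 2 adds an iid unstructured area effect
#' `f_u`, Model 3 a spatially structured intrinsic-CAR effect `f_s`, and
#' Model 4 both (the Besag-York-Mollie convolution). Precisions carry vague
#' Gamma(shape `prior_a`, rate `prior_b`) priors; fixed effects have
#' independent N(0, 1/`beta_prior_precision`) priors.
#'
#' @param include_structured include the ICAR effect `f_s`?
#' @param include_unstructured include the iid effect `f_u`?
#' @param prior_a,prior_b gamma shape/rate for the precisions (defaults
#'   0.5 / 0.0005, a standard vague disease-mapping choice).
#' @param beta_prior_precision prior precision of (beta0, beta); default 1e-4
#'   (near-flat).
#' @param reference_levels named list factor -> reference level (default:
#'   first level of each factor).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(include_structured = FALSE, include_unstructured = FALSE,
                       prior_a = 0.5, prior_b = 0.0005,
                       beta_prior_precision = 1e-4, reference_levels = list()) {
  stopifnot(prior_a > 0, prior_b > 0, beta_prior_precision > 0)
  structure(list(include_structured = include_structured,
                 include_unstructured = include_unstructured,
                 prior_a = prior_a, prior_b = prior_b,
                 beta_prior_precision = beta_prior_precision,
                 reference_levels = reference_levels),
            class = "model_spec")
}

#' @rdname model_spec
#' @param spec a `model_spec`.
#' @return `model_number()`: the model index 1-4.
#' @export
model_number <- function(spec) {
  1L + 1L * spec$include_unstructured + 2L * spec$include_structured
}

#' Dummy-coded design matrix for categorical covariates
#'
#' Treatment coding with the reference column dropped and no intercept
#' column (the intercept is a separate parameter). Column names are
#' `"factor=level"`.
#'
#' @param records survey record data frame.
#' @param factor_spec named list factor -> character vector of levels
#'   (defaults to the `factor_spec` attribute of `records`, else the factor
#'   levels found in the data).
#' @param reference_levels named list factor -> reference level; default is
#'   each factor's first declared level.
#' @return list with `X` (n x p numeric matrix), `columns` (colnames),
#'   `factor_spec`, `reference_levels`.
#' @export
build_design_matrix <- function(records, factor_spec = NULL,
                                reference_levels = list()) {
  if (is.null(factor_spec)) {
    factor_spec <- attr(records, "factor_spec")
    if (is.null(factor_spec)) {
      fac <- attr(records, "factors")
      factor_spec <- if (is.null(fac)) list() else
        lapply(records[fac], function(x) levels(factor(x)))
    }
  }
  cols <- character(0)
  Xs <- list()
  refs <- list()
  for (f in names(factor_spec)) {
    lv <- factor_spec[[f]]
    obs <- as.character(records[[f]])
    unseen <- setdiff(unique(obs), lv)
    if (length(unseen) > 0) {
      stop("level(s) ", paste(unseen, collapse = ", "),
           " of factor ", f, " not declared in factor_spec")
    }
    ref <- reference_levels[[f]] %||% lv[1]
    if (!(ref %in% lv)) stop("reference level ", ref, " unknown for factor ", f)
    refs[[f]] <- ref
    for (l in setdiff(lv, ref)) {
      cols <- c(cols, paste0(f, "=", l))
      Xs[[length(Xs) + 1]] <- as.numeric(obs == l)
    }
  }
  X <- if (length(Xs) > 0) do.call(cbind, Xs) else
    matrix(0, nrow(records), 0)
  colnames(X) <- cols
  list(X = X, columns = cols, factor_spec = factor_spec,
       reference_levels = refs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Unnormalized log-posterior of the hierarchical spatial logistic model
#'
#' Direct (R-level) evaluation of the joint log-density, up to an additive
#' constant: Bernoulli log-likelihood + N(0, 1/tau_beta) prior on (beta0,
#' beta) + iid normal log-density of `f_u` + intrinsic CAR log-kernel of
#' `f_s` (exponent `(n-k)/2` on `tau_s`, quadratic form
#' `tau_s/2 * sum_{i~j} (f_si - f_sj)^2`) + Gamma log-densities of the
#' precisions. Serves as the reference the sampler is validated against.
#'
#' @param sample list with `beta0`, `beta`, and (as included by `spec`)
#'   `f_s`, `f_u`, `tau_s`, `tau_u`.
#' @param data list with `y` (0/1), `X` (matrix), `area_idx` (1-based).
#' @param spec a [model_spec].
#' @param structure a [structure_matrix] result for the map.
#' @return scalar log-posterior (up to a constant).
#' @export
log_posterior <- function(sample, data, spec, structure) {
  eta <- sample$beta0 +
    (if (ncol(data$X) > 0) as.vector(data$X %*% sample$beta) else 0)
  n_areas <- nrow(structure$Q)
  if (spec$include_structured) eta <- eta + sample$f_s[data$area_idx]
  if (spec$include_unstructured) eta <- eta + sample$f_u[data$area_idx]
  ll <- sum(data$y * eta - log1p(exp(eta)))
  lp <- ll - 0.5 * spec$beta_prior_precision *
    (sample$beta0^2 + sum(sample$beta^2))
  if (spec$include_unstructured) {
    lp <- lp + 0.5 * n_areas * log(sample$tau_u) -
      0.5 * sample$tau_u * sum(sample$f_u^2) +
      stats::dgamma(sample$tau_u, spec$prior_a, rate = spec$prior_b, log = TRUE)
  }
  if (spec$include_structured) {
    Q <- structure$Q
    k <- structure$n_components
    quad <- as.numeric(t(sample$f_s) %*% Q %*% sample$f_s)  # sum_{i~j}(fi-fj)^2
    lp <- lp + 0.5 * (n_areas - k) * log(sample$tau_s) -
      0.5 * sample$tau_s * quad +
      stats::dgamma(sample$tau_s, spec$prior_a, rate = spec$prior_b, log = TRUE)
  }
  if (!is.finite(lp)) {
    parts <- c(loglik = ll)
    stop("non-finite log-posterior; components: ",
         paste(names(parts), round(parts, 3), collapse = ", "))
  }
  lp
}

#' Conditional precision draw
#'
#' Samples from the full conditional `Gamma(a + m_eff/2, b + ss/2)` of a
#' random-effect precision given its effect vector, the same conjugate update
#' the MCMC sampler uses: `ss` is the sum of squares (iid effect) or the
#' pairwise-difference quadratic form (ICAR effect, with
#' `m_eff = n_areas - k`).
#'
#' @param ss sum of squares of the conditioning effect.
#' @param m_eff effective dimension of the effect.
#' @param a,b gamma prior shape and rate.
#' @param n number of draws.
#' @return numeric vector of draws.
#' @export
draw_precision_conditional <- function(ss, m_eff, a, b, n = 1) {
  stats::rgamma(n, shape = a + m_eff / 2, rate = b + ss / 2)
}

# aggregate individual records into binomial cells (area x covariate pattern)
.aggregate_cells <- function(y, X, area_idx) {
  key <- if (ncol(X) > 0) {
    do.call(paste, c(list(area_idx), as.data.frame(X), list(sep = "\r")))
  } else as.character(area_idx)
  first <- !duplicated(key)
  kf <- factor(key, levels = key[first])
  list(y = as.integer(tapply(y, kf, sum)),
       m = as.integer(table(kf)),
       X = X[first, , drop = FALSE],
       area_idx = area_idx[first])
}

#' Fit a hierarchical spatial logistic model by MCMC
#'
#' Metropolis-within-Gibbs: adaptive random-walk proposals for `beta0` and
#' each fixed effect, single-site random-walk updates for `f_s` and `f_u`
#' (with per-component re-centering of `f_s`, the deficit absorbed into
#' `beta0` on connected maps), and conjugate gamma draws for the precisions.
#' The likelihood is evaluated on aggregated binomial cells (exact for
#' categorical covariates). Proposal adaptation stops at the end of burn-in.
#'
#' @param records survey record data frame referencing `map` areas.
#' @param map an [area_map].
#' @param spec a [model_spec].
#' @param mcmc list: `iterations` (default 20000), `burn_in` (5000),
#'   `thin` (5), `seed` (required).
#' @param factor_spec optional named list factor -> levels (see
#'   [build_design_matrix]); default taken from `records`.
#' @return object of class `bym_fit`: `samples` (matrices of stored draws),
#'   `summaries` (mean, sd, 2.5/50/97.5 percentiles per parameter), `dic`,
#'   `pd`, `acceptance_rates`, `seed`, plus the design/data used.
#' @export
fit_model <- function(records, map, spec, mcmc = list(), factor_spec = NULL) {
  stopifnot(inherits(map, "area_map"), inherits(spec, "model_spec"))
  mc <- utils::modifyList(list(iterations = 20000, burn_in = 5000, thin = 5,
                               seed = NULL), mcmc)
  if (is.null(mc$seed)) stop("mcmc$seed must be supplied for reproducibility")
  if (mc$iterations <= mc$burn_in) stop("iterations must exceed burn_in")
  bad <- setdiff(unique(records$area_id), map$area_ids)
  if (length(bad) > 0) stop("records reference unknown area(s): ",
                            paste(bad, collapse = ", "))
  if (spec$include_structured && sum(lengths(map$neighbors)) == 0) {
    stop("structured effect requested on a graph with no edges")
  }

  des <- build_design_matrix(records, factor_spec, spec$reference_levels)
  y <- records$outcome
  if (is.factor(y)) y <- as.integer(y) - 1L
  area_idx <- match(records$area_id, map$area_ids)
  cells <- .aggregate_cells(y, des$X, area_idx)
  n_areas <- length(map$area_ids)
  nb_idx <- lapply(map$neighbors, function(nb) match(nb, map$area_ids) - 1L)
  p <- ncol(des$X)

  set.seed(mc$seed)
  raw <- bym_mcmc_cpp(
    y = cells$y, m = cells$m, X = cells$X, area = cells$area_idx - 1L,
    n_areas = n_areas, nb_list = unname(nb_idx),
    comp = map$component - 1L, n_comp = map$n_components,
    include_s = spec$include_structured,
    include_u = spec$include_unstructured,
    prior_a = spec$prior_a, prior_b = spec$prior_b,
    tau_beta = spec$beta_prior_precision,
    n_iter = mc$iterations, burn_in = mc$burn_in, thin = mc$thin,
    init = list(beta0 = 0, beta = rep(0, p), fs = rep(0, n_areas),
                fu = rep(0, n_areas), tau_s = 1, tau_u = 1),
    updates = list(beta = TRUE, fs = TRUE, fu = TRUE,
                   tau_s = TRUE, tau_u = TRUE))

  colnames(raw$beta) <- des$columns
  colnames(raw$f_s) <- colnames(raw$f_u) <- map$area_ids
  samples <- list(beta0 = raw$beta0, beta = raw$beta, deviance = raw$deviance)
  if (spec$include_structured) {
    samples$f_s <- raw$f_s
    samples$tau_s <- raw$tau_s
  }
  if (spec$include_unstructured) {
    samples$f_u <- raw$f_u
    samples$tau_u <- raw$tau_u
  }

  fit <- structure(
    list(samples = samples, spec = spec, design = des, map = map,
         cells = cells, acceptance_rates = raw$acceptance_rates,
         scales = raw$scales, seed = mc$seed, mcmc = mc,
         model = model_number(spec)),
    class = "bym_fit")
  dic <- compute_dic(fit)
  fit$dic <- dic$dic
  fit$pd <- dic$pd
  fit$summaries <- .summarize_fit(fit)
  fit
}

.param_matrix <- function(fit) {
  s <- fit$samples
  out <- cbind(beta0 = s$beta0, s$beta)
  if (!is.null(s$f_s)) out <- cbind(out, s$f_s, tau_s = s$tau_s)
  if (!is.null(s$f_u)) {
    fu <- s$f_u
    colnames(fu) <- paste0("f_u:", colnames(fu))
    out <- cbind(out, fu, tau_u = s$tau_u)
  }
  out
}

.summarize_fit <- function(fit) {
  M <- .param_matrix(fit)
  data.frame(
    parameter = colnames(M),
    mean = colMeans(M),
    sd = apply(M, 2, stats::sd),
    q025 = apply(M, 2, stats::quantile, 0.025),
    q50 = apply(M, 2, stats::quantile, 0.5),
    q975 = apply(M, 2, stats::quantile, 0.975),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.bym_fit <- function(x, ...) {
  cat(sprintf("Model %d fit: %d stored samples, DIC = %.2f, pD = %.2f\n",
              x$model, length(x$samples$beta0), x$dic, x$pd))
  invisible(x)
}

# linear predictor per cell for one stored sample (or posterior means)
.cell_eta <- function(fit, beta0, beta, f_s, f_u) {
  cells <- fit$cells
  eta <- rep(beta0, length(cells$y))
  if (ncol(cells$X) > 0) eta <- eta + as.vector(cells$X %*% beta)
  if (!is.null(f_s)) eta <- eta + f_s[cells$area_idx]
  if (!is.null(f_u)) eta <- eta + f_u[cells$area_idx]
  eta
}

#' Deviance information criterion of a fitted model
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean of the Bernoulli deviance
#' `D = -2 log L` over stored samples and `pD = Dbar - D(thetahat)`, the
#' deviance evaluated at the posterior means of the linear-predictor
#' parameters.
#'
#' @param fit a `bym_fit` (needs >= 50 stored samples).
#' @return list `dic`, `pd`, `dbar`, `dhat`.
#' @export
compute_dic <- function(fit) {
  s <- fit$samples
  if (length(s$beta0) < 50) stop("need >= 50 stored samples for DIC")
  dbar <- mean(s$deviance)
  eta_hat <- .cell_eta(
    fit,
    beta0 = mean(s$beta0),
    beta = if (ncol(s$beta) > 0) colMeans(s$beta) else numeric(0),
    f_s = if (!is.null(s$f_s)) colMeans(s$f_s) else NULL,
    f_u = if (!is.null(s$f_u)) colMeans(s$f_u) else NULL)
  ll_hat <- sum(fit$cells$y * eta_hat -
                  fit$cells$m * .log1pexp(eta_hat))
  dhat <- -2 * ll_hat
  pd <- dbar - dhat
  list(dic = dbar + pd, pd = pd, dbar = dbar, dhat = dhat)
}

.log1pexp <- function(x) ifelse(x > 35, x, log1p(exp(pmin(x, 35))))

#' Select the best model by DIC
#'
#' Returns the model with the smallest DIC; exact ties go to the
#' smaller model number (fewer random-effect components / earlier in the
#' ladder).
#'
#' @param fits a named list of `bym_fit` objects, or a named numeric vector
#'   of DIC values; names identify the models (e.g. `"1"`, `"M3"`,
#'   `"Model 2"` all parse to their integer id; unnamed input uses position).
#' @return integer model id of the best-fitting model.
#' @export
select_best_model <- function(fits) {
  if (is.list(fits)) {
    dic <- vapply(fits, function(f) f$dic, numeric(1))
  } else {
    dic <- as.numeric(fits)
    names(dic) <- names(fits)
  }
  if (length(dic) < 2) stop("need >= 2 fitted models to compare")
  ids <- if (is.null(names(dic)) || any(names(dic) == "")) {
    seq_along(dic)
  } else {
    as.integer(gsub("[^0-9]", "", names(dic)))
  }
  o <- order(ids)
  dic <- dic[o]
  ids <- ids[o]
  ids[which.min(dic)]
}

#' Odds-ratio table from a fitted model
#'
#' Posterior percentiles of each fixed-effect coefficient, exponentiated:
#' point estimate = exp(posterior median), interval = exp of the 2.5% and
#' 97.5% percentiles. Reference levels are reported as OR 1.00.
#'
#' @param fit a `bym_fit`.
#' @return data.frame `term`, `or`, `ci_low`, `ci_high`, `reference`.
#' @export
odds_ratio_table <- function(fit) {
  B <- fit$samples$beta
  rows <- list()
  for (f in names(fit$design$factor_spec)) {
    ref <- fit$design$reference_levels[[f]]
    for (l in fit$design$factor_spec[[f]]) {
      nm <- paste0(f, "=", l)
      if (l == ref) {
        rows[[nm]] <- data.frame(term = nm, or = 1, ci_low = 1, ci_high = 1,
                                 reference = TRUE)
      } else {
        q <- stats::quantile(B[, nm], c(0.025, 0.5, 0.975))
        rows[[nm]] <- data.frame(term = nm, or = exp(q[2]),
                                 ci_low = exp(q[1]), ci_high = exp(q[3]),
                                 reference = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior prevalence map summaries
#'
#' For each stored posterior sample and area, the area prevalence is the
#' average of `plogis(linear predictor)` over that area's records; the
#' function returns the posterior mean, median and 2.5/97.5 percentiles of
#' these per-area prevalences. Areas with no records are evaluated at
#' reference covariate values (all dummies zero) and flagged.
#'
#' @param fit a `bym_fit`.
#' @return data.frame `area_id`, `mean`, `median`, `q025`, `q975`,
#'   `n_records`, `extrapolated`.
#' @export
posterior_prevalence_map <- function(fit) {
  s <- fit$samples
  cells <- fit$cells
  map <- fit$map
  n_areas <- length(map$area_ids)
  n_keep <- length(s$beta0)

  # cells x samples matrix of linear predictors
  eta <- matrix(s$beta0, nrow = length(cells$y), ncol = n_keep, byrow = TRUE)
  if (ncol(cells$X) > 0) eta <- eta + cells$X %*% t(s$beta)
  if (!is.null(s$f_s)) eta <- eta + t(s$f_s)[cells$area_idx, , drop = FALSE]
  if (!is.null(s$f_u)) eta <- eta + t(s$f_u)[cells$area_idx, , drop = FALSE]
  pmat <- stats::plogis(eta) * cells$m
  num <- rowsum(pmat, cells$area_idx)
  den <- as.numeric(rowsum(cells$m, cells$area_idx))
  prev <- num / den                      # observed-area x samples
  obs_areas <- sort(unique(cells$area_idx))

  out <- matrix(NA_real_, n_areas, n_keep)
  out[obs_areas, ] <- prev
  empty <- setdiff(seq_len(n_areas), obs_areas)
  for (a in empty) {
    eta_a <- s$beta0
    if (!is.null(s$f_s)) eta_a <- eta_a + s$f_s[, a]
    if (!is.null(s$f_u)) eta_a <- eta_a + s$f_u[, a]
    out[a, ] <- stats::plogis(eta_a)
  }
  n_rec <- integer(n_areas)
  n_rec[obs_areas] <- den
  data.frame(
    area_id = map$area_ids,
    mean = rowMeans(out),
    median = apply(out, 1, stats::median),
    q025 = apply(out, 1, stats::quantile, 0.025),
    q975 = apply(out, 1, stats::quantile, 0.975),
    n_records = n_rec,
    extrapolated = seq_len(n_areas) %in% empty,
    stringsAsFactors = FALSE)
}

#' Serialize a fitted model to a directory
#'
#' Writes `samples.csv` (stored draws of all parameters), `summary.csv`
#' (posterior summaries with the DIC/pD footer columns), and `config.json`
#' (model spec, MCMC settings, seed, acceptance rates).
#'
#' @param fit a `bym_fit`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(.param_matrix(fit)),
                   file.path(dir, "samples.csv"), row.names = FALSE)
  sm <- fit$summaries
  sm$dic <- fit$dic
  sm$pd <- fit$pd
  utils::write.csv(sm, file.path(dir, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(model = fit$model,
         spec = fit$spec[c("include_structured", "include_unstructured",
                           "prior_a", "prior_b", "beta_prior_precision")],
         mcmc = fit$mcmc, seed = fit$seed,
         acceptance_rates = fit$acceptance_rates,
         dic = fit$dic, pd = fit$pd),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
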