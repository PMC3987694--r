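#' Rectangular lattice area map
#'
#' A rook-adjacency `rows x cols` lattice with pseudo-centroids laid out as
#' small longitude/latitude offsets (0.1 degree spacing) around the origin.
#' Serves as a stand-in spatial support for a county system when real
#' geography is not needed.
#'
#' @param rows,cols lattice dimensions (>= 1).
#' @return An [area_map] with `rows * cols` areas named `A01`, `A02`, ...
#'   in row-major order and `rows*(cols-1) + cols*(rows-1)` edges.
#' @export
make_lattice_map <- function(rows, cols) {
  stopifnot(rows >= 1, cols >= 1)
  n <- rows * cols
  ids <- sprintf("A%0*d", max(2, nchar(n)), seq_len(n))
  idx <- function(r, c) (r - 1) * cols + c
  cen <- matrix(0, n, 2)
  nbs <- vector("list", n)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      i <- idx(r, c)
      cen[i, ] <- c((c - 1) * 0.1, (r - 1) * 0.1)
      nb <- integer(0)
      if (r > 1) nb <- c(nb, idx(r - 1, c))
      if (r < rows) nb <- c(nb, idx(r + 1, c))
      if (c > 1) nb <- c(nb, idx(r, c - 1))
      if (c < cols) nb <- c(nb, idx(r, c + 1))
      nbs[[i]] <- ids[nb]
    }
  }
  area_map(ids, cen, nbs)
}

#' Simulate an intrinsic CAR (ICAR) spatial field
#'
#' Draws one realization of the intrinsic Gaussian Markov random field with
#' precision structure `tau_s * Q` (Q the graph Laplacian of the map), via the
#' spectral pseudo-inverse of Q, then centres the field to sum to zero within
#' each connected component. Isolated areas receive value 0.
#'
#' @param map an [area_map].
#' @param tau_s positive precision of the field.
#' @param seed optional integer seed (draw is deterministic given the seed).
#' @return numeric vector, one value per area, per-component sum zero.
#' @export
simulate_icar_field <- function(map, tau_s, seed = NULL) {
  stopifnot(inherits(map, "area_map"), tau_s > 0)
  if (!is.null(seed)) set.seed(seed)
  Q <- structure_matrix(map)$Q
  n <- nrow(Q)
  eg <- eigen(Q, symmetric = TRUE)
  pos <- eg$values > max(eg$values, 1) * 1e-10
  f <- numeric(n)
  if (any(pos)) {
    z <- stats::rnorm(sum(pos), sd = sqrt(1 / (tau_s * eg$values[pos])))
    f <- as.vector(eg$vectors[, pos, drop = FALSE] %*% z)
  }
  # exact sum-to-zero per component (null space of Q is component indicators)
  for (k in seq_len(map$n_components)) {
    in_k <- map$component == k
    f[in_k] <- f[in_k] - mean(f[in_k])
  }
  names(f) <- map$area_ids
  f
}

#' Bundle ground-truth parameters for the synthetic survey
#'
#' @param beta0 intercept on the logit scale.
#' @param beta named numeric vector of fixed effects on dummy-coded levels;
#'   names `"factor=level"` (reference levels omitted). May be empty.
#' @param f_s,f_u per-area structured / unstructured effects (or NULL for
#'   none); named by area id or in map order.
#' @param tau_s,tau_u precisions that generated `f_s` / `f_u` (bookkeeping
#'   only; recorded so recovery checks know the truth).
#' @return list of class `truth_set`.
#' @export
truth_set <- function(beta0 = 0, beta = numeric(0), f_s = NULL, f_u = NULL,
                      tau_s = NA_real_, tau_u = NA_real_) {
  structure(list(beta0 = beta0, beta = beta, f_s = f_s, f_u = f_u,
                 tau_s = tau_s, tau_u = tau_u),
            class = "truth_set")
}

#' Simulate a DHS-like two-stage stratified cluster survey
#'
#' Areas are partitioned into `n_regions` contiguous regions (by map order);
#' strata are region x urban/rural, with PSUs (synthetic enumeration areas)
#' nested in areas and alternately labelled urban/rural. Each respondent
#' draws categorical covariate levels, a Bernoulli outcome with
#' `logit p = beta0 + x'beta + f_s(area) + f_u(area)`, and a design weight:
#' inverse inclusion probabilities (constant under the equal-allocation
#' design) jittered by a lognormal factor with log-sd `weight_dispersion`,
#' then normalized to mean 1 (the DHS convention). With
#' `weight_dispersion = 0` all weights are exactly 1.
#'
#' @param map an [area_map].
#' @param truth a [truth_set]; every name in `truth$beta` must be
#'   `"factor=level"` with the factor and level declared in `factor_spec`.
#' @param design list with `n_regions` (default 4), `psus_per_area`
#'   (default 2), `respondents_per_psu` (default 25), `weight_dispersion`
#'   (default 0).
#' @param factor_spec named list: factor name -> character vector of levels
#'   (first level is the reference). Levels are sampled uniformly and
#'   independently of area unless `area_confounded = TRUE`, which tilts level
#'   probabilities along the map order (for robustness experiments).
#' @param seed integer seed; the draw is reproducible given the seed.
#' @param area_confounded logical, see `factor_spec`.
#' @return data.frame with columns `outcome`, `weight`, `stratum_id`,
#'   `psu_id`, `area_id`, plus one column per declared factor; attributes
#'   `factors` (factor names) and `factor_spec`.
#' @export
simulate_survey <- function(map, truth, design = list(), factor_spec = list(),
                            seed = NULL, area_confounded = FALSE) {
  stopifnot(inherits(map, "area_map"), inherits(truth, "truth_set"))
  des <- utils::modifyList(
    list(n_regions = 4, psus_per_area = 2, respondents_per_psu = 25,
         weight_dispersion = 0), design)
  if (!is.null(seed)) set.seed(seed)

  n_areas <- length(map$area_ids)
  # validate truth$beta against factor_spec
  if (length(truth$beta) > 0) {
    parts <- strsplit(names(truth$beta), "=", fixed = TRUE)
    for (p in parts) {
      if (length(p) != 2 || is.null(factor_spec[[p[1]]]) ||
          !(p[2] %in% factor_spec[[p[1]]])) {
        stop("truth$beta entry '", paste(p, collapse = "="),
             "' not declared in factor_spec")
      }
    }
  }
  f_s <- .align_field(truth$f_s, map)
  f_u <- .align_field(truth$f_u, map)

  region <- ceiling(seq_len(n_areas) / (n_areas / des$n_regions))
  n_psu_tot <- n_areas * des$psus_per_area
  n <- n_psu_tot * des$respondents_per_psu

  area_idx <- rep(seq_len(n_areas), each = des$psus_per_area * des$respondents_per_psu)
  psu_in_area <- rep(rep(seq_len(des$psus_per_area), each = des$respondents_per_psu),
                     times = n_areas)
  urban <- psu_in_area %% 2 == 1
  psu_id <- sprintf("%s_psu%d", map$area_ids[area_idx], psu_in_area)
  stratum_id <- sprintf("R%d_%s", region[area_idx],
                        ifelse(urban, "urban", "rural"))

  covs <- list()
  eta <- rep(truth$beta0, n)
  for (f in names(factor_spec)) {
    lv <- factor_spec[[f]]
    if (area_confounded) {
      # tilt level probabilities linearly along the map order
      tilt <- (area_idx - 1) / max(1, n_areas - 1)
      pmat <- t(vapply(tilt, function(t) {
        w <- (1 - t) * rev(seq_along(lv)) + t * seq_along(lv)
        w / sum(w)
      }, numeric(length(lv))))
      draw <- vapply(seq_len(n), function(i)
        sample.int(length(lv), 1, prob = pmat[i, ]), integer(1))
    } else {
      draw <- sample.int(length(lv), n, replace = TRUE)
    }
    x <- factor(lv[draw], levels = lv)
    covs[[f]] <- x
    for (l in lv[-1]) {
      nm <- paste0(f, "=", l)
      if (nm %in% names(truth$beta)) {
        eta <- eta + truth$beta[[nm]] * (x == l)
      }
    }
  }
  eta <- eta + f_s[area_idx] + f_u[area_idx]
  y <- stats::rbinom(n, 1, stats::plogis(eta))

  w <- exp(stats::rnorm(n, 0, des$weight_dispersion))
  w <- w / mean(w)

  out <- data.frame(outcome = y, weight = w, stratum_id = stratum_id,
                    psu_id = psu_id, area_id = map$area_ids[area_idx],
                    stringsAsFactors = FALSE)
  for (f in names(covs)) out[[f]] <- covs[[f]]
  attr(out, "factors") <- names(factor_spec)
  attr(out, "factor_spec") <- factor_spec
  out
}

.align_field <- function(f, map) {
  n <- length(map$area_ids)
  if (is.null(f)) return(numeric(n))
  if (!is.null(names(f))) {
    miss <- setdiff(map$area_ids, names(f))
    if (length(miss) > 0) stop("field missing areas: ", paste(miss, collapse = ", "))
    return(as.numeric(f[map$area_ids]))
  }
  if (length(f) != n) stop("field length != number of areas")
  as.numeric(f)
}

#' Aggregate survey records to per-area case/control counts
#'
#' Unweighted aggregation counts outcome = 1 records as cases and all records
#' as totals. Weighted aggregation sums design weights, rescales so the
#' overall case and total counts equal their unweighted values, and rounds to
#' integers by largest-remainder rounding (so the Bernoulli scan receives
#' integer counts whose grand totals are preserved). Rounded cases are capped
#' at the rounded area total. Areas with no records are retained with zero
#' counts.
#'
#' @param records a survey record data frame (see [simulate_survey]).
#' @param map an [area_map]; its areas define the output rows.
#' @param use_weights logical, default FALSE.
#' @return data.frame `area_id`, `cases`, `total` in map order.
#' @export
aggregate_to_areas <- function(records, map, use_weights = FALSE) {
  stopifnot(inherits(map, "area_map"))
  bad <- setdiff(unique(records$area_id), map$area_ids)
  if (length(bad) > 0) stop("records reference unknown area(s): ",
                            paste(bad, collapse = ", "))
  a <- factor(records$area_id, levels = map$area_ids)
  if (!use_weights) {
    cases <- as.integer(tapply(records$outcome, a, sum, default = 0))
    total <- as.integer(table(a))
  } else {
    C <- sum(records$outcome)
    N <- nrow(records)
    wc <- as.numeric(tapply(records$weight * records$outcome, a, sum, default = 0))
    wt <- as.numeric(tapply(records$weight, a, sum, default = 0))
    total <- .largest_remainder(wt, N)
    cases <- .largest_remainder(wc, C)
    cases <- pmin(cases, total)
  }
  data.frame(area_id = map$area_ids, cases = cases, total = total,
             stringsAsFactors = FALSE)
}

# scale x to sum to target and round to integers preserving the total
.largest_remainder <- function(x, target) {
  if (sum(x) == 0) return(integer(length(x)))
  x <- x * target / sum(x)
  fl <- floor(x)
  rem <- as.integer(round(target - sum(fl)))
  out <- as.integer(fl)
  if (rem > 0) {
    give <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    out[give] <- out[give] + 1L
  }
  out
}

#' Write / read survey records as CSV
#'
#' The CSV round-trips through [read_survey_records]: columns `outcome`,
#' `weight`, `stratum_id`, `psu_id`, `area_id` plus factor columns.
#'
#' @param records survey record data frame.
#' @param path output path.
#' @export
write_survey_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survey_records
#' @param factors character vector naming the covariate columns (defaults to
#'   every column that is not a design column).
#' @export
read_survey_records <- function(path, factors = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  design_cols <- c("outcome", "weight", "stratum_id", "psu_id", "area_id")
  if (!all(design_cols %in% names(df))) {
    stop("survey CSV must contain columns: ", paste(design_cols, collapse = ", "))
  }
  if (is.null(factors)) factors <- setdiff(names(df), design_cols)
  for (f in factors) df[[f]] <- factor(df[[f]])
  df$area_id <- as.character(df$area_id)
  attr(df, "factors") <- factors
  attr(df, "factor_spec") <- lapply(df[factors], levels)
  df
}

#' Write / read per-area case data as CSV (`id,cases,total`)
#'
#' @param case_data data.frame `area_id`, `cases`, `total`.
#' @param path file path.
#' @export
write_case_data <- function(case_data, path) {
  utils::write.csv(
    data.frame(id = case_data$area_id, cases = case_data$cases,
               total = case_data$total), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_case_data
#' @export
read_case_data <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "cases", "total") %in% names(df))) {
    stop("case data CSV must have header id,cases,total")
  }
  if (any(df$cases < 0 | df$cases > df$total)) {
    stop("case counts must satisfy 0 <= cases <= total")
  }
  data.frame(area_id = as.character(df$id), cases = as.integer(df$cases),
             total = as.integer(df$total), stringsAsFactors = FALSE)
}
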