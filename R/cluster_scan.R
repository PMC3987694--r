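#' Bernoulli scan log-likelihood ratio
#'
#' The Kulldorff Bernoulli-model log-likelihood ratio of a window holding
#' `c` cases among `n` at-risk, against totals `C` cases of `N`:
#' `c log(c/n) + (n-c) log((n-c)/n) + (C-c) log((C-c)/(N-n)) +
#' ((N-n)-(C-c)) log(1 - (C-c)/(N-n)) - C log(C/N) - (N-C) log((N-C)/N)`,
#' with `0 log 0 = 0`. The statistic is one-sided: it is reported only when
#' the window rate lies strictly on the requested side of the overall rate
#' `C/N`, and is 0 otherwise (also 0 when the window is the whole region).
#' All arguments are vectorized over `c` and `n`.
#'
#' @param c cases inside the window.
#' @param n at-risk total inside the window.
#' @param C,N overall cases and at-risk total.
#' @param direction `"high"` or `"low"`.
#' @return numeric vector of nonnegative log-likelihood ratios.
#' @export
bernoulli_llr <- function(c, n, C, N, direction = c("high", "low")) {
  direction <- match.arg(direction)
  stopifnot(all(c >= 0), all(c <= n), all(n <= N), C >= 0, C <= N)
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  # c log(c/n) + (n-c) log((n-c)/n) etc., written via x log x terms
  inside <- xlx(c) + xlx(n - c) - xlx(n)
  out_c <- C - c
  out_n <- N - n
  outside <- xlx(out_c) + xlx(out_n - out_c) - xlx(out_n)
  null <- xlx(C) + xlx(N - C) - xlx(N)
  llr <- inside + outside - null
  rate_in <- ifelse(n > 0, c / n, NA_real_)
  side <- if (direction == "high") rate_in > C / N else rate_in < C / N
  side[is.na(side)] <- FALSE
  llr <- ifelse(side & n < N, llr, 0)
  pmax(llr, 0)
}

#' Relative risk of a scan window
#'
#' `RR = (c/E) / ((C-c)/(C-E))` with expected cases `E = n C / N`: the ratio
#' of observed-to-expected inside the window to observed-to-expected
#' outside. `Inf` when all cases fall inside (`c = C`).
#'
#' @inheritParams bernoulli_llr
#' @return numeric vector of relative risks.
#' @export
relative_risk <- function(c, n, C, N) {
  E <- n * C / N
  if (any(E == 0)) stop("expected count is zero (empty window or no cases)")
  ifelse(c == C, Inf, (c / E) / ((C - c) / (C - E)))
}

#' Nested circular windows around a center area
#'
#' Areas sorted by distance from the center (ties broken by map order);
#' windows are the nested prefixes whose cumulative at-risk total stays
#' within `max_fraction` of the overall total. The center-only window is
#' always included.
#'
#' @param center area index (1-based) of the window center.
#' @param D distance matrix from [distance_matrix].
#' @param totals per-area at-risk totals.
#' @param max_fraction maximum window share of the total population,
#'   in (0, 0.5].
#' @return list with `order` (area indices by distance) and `n_windows`
#'   (number of admissible prefixes).
#' @export
window_sequence <- function(center, D, totals, max_fraction = 0.5) {
  stopifnot(max_fraction > 0, max_fraction <= 0.5)
  n <- length(totals)
  ord <- order(D[center, ], seq_len(n))
  cum <- cumsum(totals[ord])
  nw <- max(1L, sum(cum <= max_fraction * sum(totals)))
  list(order = ord, n_windows = nw)
}

# window membership for all centers: sparse indicator (windows x areas) plus
# bookkeeping of center and prefix length per window row
.build_windows <- function(map, totals, max_fraction) {
  D <- distance_matrix(map)
  n <- length(totals)
  ii <- jj <- vector("list", 0)
  center <- size <- integer(0)
  orders <- vector("list", n)
  for (ctr in seq_len(n)) {
    ws <- window_sequence(ctr, D, totals, max_fraction)
    orders[[ctr]] <- ws$order
    for (k in seq_len(ws$n_windows)) {
      ii[[length(ii) + 1]] <- rep.int(length(center) + 1L, k)
      jj[[length(jj) + 1]] <- ws$order[seq_len(k)]
      center <- c(center, ctr)
      size <- c(size, k)
    }
  }
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1,
                            dims = c(length(center), n))
  list(M = M, center = center, size = size,
       n_in = as.numeric(M %*% totals), order = orders)
}

#' Bernoulli spatial scan over all circular windows
#'
#' Evaluates the one-sided Bernoulli log-likelihood ratio over every nested
#' circular window from every center and returns one candidate cluster per
#' center (its best window), ranked by LLR. The top-ranked candidate is the
#' most likely cluster.
#'
#' @param case_data data.frame `area_id`, `cases`, `total` (map order;
#'   see [aggregate_to_areas] / [read_case_data]).
#' @param map an [area_map].
#' @param direction `"high"` or `"low"` rate clusters.
#' @param max_fraction maximum window population share, default 0.5.
#' @return data.frame of candidate clusters (one per center with positive
#'   LLR): `center_area`, `members` (list column, ordered by distance),
#'   `observed`, `expected`, `total_in`, `llr`, `relative_risk`, ranked by
#'   decreasing LLR. Empty when no window lies on the requested side.
#' @export
scan <- function(case_data, map, direction = c("high", "low"),
                 max_fraction = 0.5) {
  direction <- match.arg(direction)
  stopifnot(inherits(map, "area_map"),
            identical(case_data$area_id, map$area_ids))
  cases <- case_data$cases
  totals <- case_data$total
  C <- sum(cases)
  N <- sum(totals)
  if (C < 1) {
    if (direction == "high") {
      return(.empty_cluster_df())
    }
  }
  win <- .build_windows(map, totals, max_fraction)
  c_in <- as.numeric(win$M %*% cases)
  llr <- bernoulli_llr(c_in, win$n_in, C, N, direction)

  # best window per center
  best <- tapply(seq_along(llr), win$center, function(ix) ix[which.max(llr[ix])])
  best <- unlist(best)
  keep <- best[llr[best] > 0]
  if (length(keep) == 0) return(.empty_cluster_df())
  o <- keep[order(llr[keep], decreasing = TRUE)]
  data.frame(
    center_area = map$area_ids[win$center[o]],
    members = I(lapply(o, function(i)
      map$area_ids[win$order[[win$center[i]]][seq_len(win$size[i])]])),
    observed = c_in[o],
    expected = win$n_in[o] * C / N,
    total_in = win$n_in[o],
    llr = llr[o],
    relative_risk = relative_risk(c_in[o], win$n_in[o], C, N),
    stringsAsFactors = FALSE)
}

.empty_cluster_df <- function() {
  data.frame(center_area = character(0), members = I(list()),
             observed = numeric(0), expected = numeric(0),
             total_in = numeric(0), llr = numeric(0),
             relative_risk = numeric(0), p_value = numeric(0))
}

# distribute C cases over areas with fixed totals (multivariate
# hypergeometric), vectorized over replicates: columns are replicates
.null_case_matrix <- function(totals, C, reps) {
  n_areas <- length(totals)
  out <- matrix(0L, n_areas, reps)
  remC <- rep.int(C, reps)
  remN <- sum(totals)
  for (i in seq_len(n_areas - 1)) {
    ci <- stats::rhyper(reps, totals[i], remN - totals[i], remC)
    out[i, ] <- ci
    remC <- remC - ci
    remN <- remN - totals[i]
  }
  out[n_areas, ] <- remC
  out
}

#' Monte Carlo p-values for scan clusters
#'
#' Conditional on the observed totals `n_i` and case total `C`, each
#' replicate redistributes the `C` cases among the `N` individuals without
#' replacement, rescans, and records the maximum LLR. Every candidate
#' cluster is referred to this null distribution of the maximum:
#' `p = (1 + #{replicate max >= candidate llr}) / (1 + replications)`.
#'
#' @inheritParams scan
#' @param replications number of Monte Carlo replicates (e.g. 999 or 9999).
#' @param seed integer seed (results deterministic given the seed).
#' @return the [scan] candidate data.frame with a `p_value` column, plus
#'   attribute `null_max` (the replicate maxima).
#' @export
monte_carlo_pvalues <- function(case_data, map, direction = c("high", "low"),
                                max_fraction = 0.5, replications = 999,
                                seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(replications >= 1)
  if (!is.null(seed)) set.seed(seed)
  cand <- scan(case_data, map, direction, max_fraction)
  totals <- case_data$total
  C <- sum(case_data$cases)
  N <- sum(totals)
  win <- .build_windows(map, totals, max_fraction)
  null_cases <- .null_case_matrix(totals, C, replications)
  c_in <- as.matrix(win$M %*% null_cases)           # windows x reps
  llr <- bernoulli_llr(c_in, matrix(win$n_in, nrow(c_in), ncol(c_in)),
                       C, N, direction)
  null_max <- apply(matrix(llr, nrow(c_in)), 2, max)
  if (nrow(cand) > 0) {
    cand$p_value <- vapply(cand$llr, function(l)
      (1 + sum(null_max >= l)) / (1 + replications), numeric(1))
  } else {
    cand$p_value <- numeric(0)
  }
  attr(cand, "null_max") <- null_max
  cand
}

#' Report non-overlapping significant clusters
#'
#' Greedy selection in LLR order: a candidate sharing any area with an
#' already-reported cluster is suppressed; selection stops when the next
#' non-overlapping candidate has `p > significance_level`. This is the
#' "no geographical overlap" secondary-cluster rule.
#'
#' @param ranked candidate data.frame from [monte_carlo_pvalues].
#' @param significance_level alpha, default 0.05.
#' @return the reported subset with a `rank` column (1 = most likely
#'   cluster).
#' @export
secondary_clusters <- function(ranked, significance_level = 0.05) {
  if (nrow(ranked) == 0 || !"p_value" %in% names(ranked)) {
    out <- ranked
    out$rank <- integer(0)
    return(out)
  }
  used <- character(0)
  take <- integer(0)
  for (i in seq_len(nrow(ranked))) {
    mem <- ranked$members[[i]]
    if (length(intersect(mem, used)) > 0) next
    if (ranked$p_value[i] > significance_level) next
    take <- c(take, i)
    used <- c(used, mem)
  }
  out <- ranked[take, , drop = FALSE]
  out$rank <- seq_along(take)
  rownames(out) <- NULL
  out
}

#' Write a cluster report CSV
#'
#' One row per reported cluster: rank, direction, observed and expected
#' cases, relative risk, p-value and the member areas (semicolon-joined) —
#' the conventional scan-output table layout.
#'
#' @param clusters output of [secondary_clusters].
#' @param direction scan direction the clusters came from.
#' @param path output CSV path.
#' @param assumptions named list of settings echoed as comment header lines
#'   (e.g. max window fraction), since they are analysis assumptions.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(clusters, direction, path,
                                 assumptions = list()) {
  df <- data.frame(
    rank = clusters$rank,
    direction = rep(direction, nrow(clusters)),
    observed = clusters$observed,
    expected = round(clusters$expected, 2),
    relative_risk = round(clusters$relative_risk, 3),
    p_value = clusters$p_value,
    center_area = clusters$center_area,
    members = vapply(clusters$members, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(assumptions)) {
    writeLines(sprintf("# %s: %s", nm, assumptions[[nm]]), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
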