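#' Design-weighted prevalence with linearized variance
#'
#' Ratio estimator `p = sum(w*y)/sum(w)` with the stratified between-PSU
#' Taylor-linearization variance and a 95% confidence interval computed on
#' the logit scale and back-transformed (the complex-survey software
#' convention); a symmetric Wald interval is available via `ci_method`.
#' Design degrees of freedom are `n_PSU - n_strata`.
#'
#' @param records survey record data frame with `weight`, `stratum_id`,
#'   `psu_id` columns.
#' @param outcome_name name of the binary (0/1) outcome column.
#' @param ci_method `"logit"` (default) or `"wald"`.
#' @param level confidence level, default 0.95.
#' @return list of class `survey_estimate`: `point`, `se`, `ci_low`,
#'   `ci_high`, `design_df`, `n`.
#' @export
weighted_prevalence <- function(records, outcome_name = "outcome",
                                ci_method = c("logit", "wald"), level = 0.95) {
  ci_method <- match.arg(ci_method)
  y <- records[[outcome_name]]
  if (is.factor(y)) y <- as.integer(y) - 1L
  stopifnot(all(y %in% c(0, 1)))
  w <- records$weight
  stopifnot(all(w > 0))

  strat <- as.character(records$stratum_id)
  psu <- paste(strat, records$psu_id, sep = "\r")
  n_h <- tapply(psu, strat, function(p) length(unique(p)))
  if (any(n_h < 2) && length(unique(psu)) > 1) {
    stop("stratum ", paste(names(n_h)[n_h < 2], collapse = ", "),
         " has a single PSU; collapse strata before variance estimation")
  }
  W <- sum(w)
  p <- sum(w * y) / W

  # linearized scores, aggregated to PSU totals within strata
  z <- w * (y - p) / W
  v <- 0
  for (h in unique(strat)) {
    in_h <- strat == h
    zt <- tapply(z[in_h], psu[in_h], sum)
    nh <- length(zt)
    if (nh >= 2) v <- v + nh / (nh - 1) * sum((zt - mean(zt))^2)
  }
  se <- sqrt(v)
  df <- length(unique(psu)) - length(unique(strat))
  tq <- stats::qt(1 - (1 - level) / 2, df = max(df, 1))

  if (se == 0 || p == 0 || p == 1) {
    ci <- c(p, p)
    if (se > 0) {  # p at boundary but nonzero variance cannot occur for 0/1 y
      ci <- pmin(pmax(c(p - tq * se, p + tq * se), 0), 1)
    }
  } else if (ci_method == "logit") {
    lg <- stats::qlogis(p)
    se_lg <- se / (p * (1 - p))
    ci <- stats::plogis(c(lg - tq * se_lg, lg + tq * se_lg))
  } else {
    ci <- pmin(pmax(c(p - tq * se, p + tq * se), 0), 1)
  }
  structure(list(point = p, se = se, ci_low = ci[1], ci_high = ci[2],
                 design_df = df, n = length(y)),
            class = "survey_estimate")
}

#' @export
print.survey_estimate <- function(x, ...) {
  cat(sprintf("%.1f%% (95%% CI: %.1f-%.1f%%), se = %.4f, design df = %d\n",
              100 * x$point, 100 * x$ci_low, 100 * x$ci_high, x$se, x$design_df))
  invisible(x)
}

#' Design-weighted cross-tabulation with Rao-Scott corrected test
#'
#' Weighted outcome percentage and unweighted n per factor level, with the
#' second-order (Satterthwaite) Rao-Scott correction of the Pearson
#' chi-square statistic referred to an F distribution — the default test of
#' association in complex-survey software. Empty levels are dropped with a
#' warning.
#'
#' @param records survey record data frame.
#' @param outcome_name binary outcome column name.
#' @param factor_name factor column name (>= 2 observed levels).
#' @return list of class `crosstab_result`: `table` (data.frame level,
#'   weighted_percent, unweighted_n), `F_stat`, `df1`, `df2`, `p_value`,
#'   `pearson_chisq`, `design_df`.
#' @export
weighted_crosstab <- function(records, outcome_name = "outcome", factor_name) {
  y <- records[[outcome_name]]
  if (is.factor(y)) y <- as.integer(y) - 1L
  x <- records[[factor_name]]
  if (!is.factor(x)) x <- factor(x)
  if (any(table(x) == 0)) {
    warning("dropping empty level(s) of ", factor_name, ": ",
            paste(levels(x)[table(x) == 0], collapse = ", "))
    x <- droplevels(x)
  }
  L <- nlevels(x)
  if (L < 2) stop("factor must have >= 2 observed levels")
  w <- records$weight
  n <- length(y)

  # per-level weighted outcome % and unweighted n
  tab <- data.frame(
    level = levels(x),
    weighted_percent = 100 * as.numeric(
      tapply(w * y, x, sum) / tapply(w, x, sum)),
    unweighted_n = as.integer(table(x)),
    stringsAsFactors = FALSE)

  # cell proportions, cells = (outcome r in {0,1}) x (level c)
  cell <- interaction(factor(y, levels = c(0, 1)), x, drop = FALSE)
  RC <- 2L * L
  W <- sum(w)
  phat <- as.numeric(tapply(w, cell, sum, default = 0)) / W
  pr <- c(sum(phat[seq(1, RC, by = 2)]), sum(phat[seq(2, RC, by = 2)]))
  pc <- as.numeric(tapply(w, x, sum)) / W
  p0 <- as.numeric(sapply(seq_len(L), function(c) pr * pc[c]))
  X2 <- n * sum((phat - p0)^2 / p0)

  # design-based covariance of phat via stratified between-PSU linearization
  strat <- as.character(records$stratum_id)
  psu <- paste(strat, records$psu_id, sep = "\r")
  ind <- matrix(0, n, RC)
  ind[cbind(seq_len(n), as.integer(cell))] <- 1
  Z <- (w / W) * (ind - matrix(phat, n, RC, byrow = TRUE))
  V <- matrix(0, RC, RC)
  for (h in unique(strat)) {
    in_h <- strat == h
    Zt <- rowsum(Z[in_h, , drop = FALSE], psu[in_h])
    nh <- nrow(Zt)
    if (nh >= 2) {
      Zc <- sweep(Zt, 2, colMeans(Zt))
      V <- V + nh / (nh - 1) * crossprod(Zc)
    }
  }

  # contrast basis for the interaction space (dimension (2-1)(L-1))
  lev_ind <- matrix(0, RC, L)
  lev_ind[cbind(seq_len(RC), rep(seq_len(L), each = 2))] <- 1
  main <- cbind(1, rep(c(1, 0), L), lev_ind)
  Cmat <- qr.Q(qr(main), complete = TRUE)[, (qr(main)$rank + 1):RC, drop = FALSE]

  V0n <- diag(phat) - tcrossprod(phat)       # multinomial covariance * n
  A <- crossprod(Cmat, V0n %*% Cmat)
  B <- crossprod(Cmat, V %*% Cmat)
  # degenerate tables (structural-zero cells) make A singular; the
  # uncorrected statistic (unit design effects) is the conservative fallback
  lam <- tryCatch(
    Re(eigen(solve(A, B * n), only.values = TRUE)$values),
    error = function(e) numeric(0))
  lam <- lam[is.finite(lam) & lam > 1e-12]
  if (length(lam) == 0) lam <- 1
  d0 <- L - 1                                 # (R-1)(C-1) with R = 2
  lbar <- mean(lam)
  a2 <- if (length(lam) > 1) sum((lam - lbar)^2) / (length(lam) * lbar^2) else 0

  nu <- d0 / (1 + a2)
  Fstat <- X2 / (lbar * (1 + a2) * nu)
  ddf <- length(unique(psu)) - length(unique(strat))
  df2 <- nu * max(ddf, 1)
  p_value <- stats::pf(Fstat, nu, df2, lower.tail = FALSE)

  structure(list(table = tab, F_stat = Fstat, df1 = nu, df2 = df2,
                 p_value = p_value, pearson_chisq = X2, design_df = ddf),
            class = "crosstab_result")
}

#' @export
print.crosstab_result <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("Design-based F(%.2f, %.2f) = %.3f, p = %.4g\n",
              x$df1, x$df2, x$F_stat, x$p_value))
  invisible(x)
}

#' Principal-components media exposure index
#'
#' Standardizes the ordinal exposure items, extracts the first principal
#' component of their correlation matrix, orients it so that higher exposure
#' maps to a higher score (loading sum made nonnegative), and cuts the score
#' at weighted tertiles into `low`/`mid`/`high`. Ties at a boundary go to the
#' lower category. Zero-variance items are excluded with a warning.
#'
#' @param records data frame holding the items (and `weight`, used for the
#'   tertile cuts; equal weights assumed if absent).
#' @param item_names character vector (>= 3) of ordinal item columns.
#' @return list of class `media_index`: `category` (factor low/mid/high per
#'   record), `score`, `loadings`, `explained` (share of variance of the
#'   first component), `cuts`.
#' @export
media_exposure_index <- function(records, item_names) {
  stopifnot(length(item_names) >= 3)
  X <- as.matrix(records[, item_names, drop = FALSE])
  storage.mode(X) <- "double"
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("excluding zero-variance item(s): ",
            paste(item_names[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) < 2) stop("need >= 2 items with variance")
  Z <- scale(X)
  eg <- eigen(stats::cor(X), symmetric = TRUE)
  v <- eg$vectors[, 1]
  if (sum(v) < 0) v <- -v
  score <- as.numeric(Z %*% v)
  w <- if ("weight" %in% names(records)) records$weight else rep(1, nrow(X))
  cuts <- c(.weighted_quantile(score, w, 1 / 3),
            .weighted_quantile(score, w, 2 / 3))
  category <- cut(score, breaks = c(-Inf, cuts[1], cuts[2], Inf),
                  labels = c("low", "mid", "high"), right = TRUE)
  structure(list(category = category, score = score,
                 loadings = stats::setNames(v, colnames(X)),
                 explained = eg$values[1] / sum(eg$values), cuts = cuts),
            class = "media_index")
}

# smallest x with cumulative weight share >= q
.weighted_quantile <- function(x, w, q) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= q)[1]]
}

#' Write a Table-1-style descriptive CSV
#'
#' One row per (factor, level) with the weighted outcome percentage,
#' unweighted n, and the factor's Rao-Scott F and p-value.
#'
#' @param records survey record data frame.
#' @param outcome_name binary outcome column.
#' @param factor_names covariate columns to tabulate.
#' @param path output CSV path.
#' @return the table, invisibly.
#' @export
write_descriptive_table <- function(records, outcome_name = "outcome",
                                    factor_names, path) {
  rows <- lapply(factor_names, function(f) {
    ct <- weighted_crosstab(records, outcome_name, f)
    data.frame(factor = f, ct$table, F_stat = ct$F_stat,
               p_value = ct$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
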