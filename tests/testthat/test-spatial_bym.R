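test_that("model ladder numbering follows the random-effect structure", {
  expect_equal(model_number(model_spec(FALSE, FALSE)), 1)
  expect_equal(model_number(model_spec(FALSE, TRUE)), 2)
  expect_equal(model_number(model_spec(TRUE, FALSE)), 3)
  expect_equal(model_number(model_spec(TRUE, TRUE)), 4)
})

test_that("design matrix uses treatment coding with dropped reference", {
  rec <- data.frame(f1 = c("a", "b", "c", "a"),
                    f2 = c("x", "x", "y", "x"))
  d <- build_design_matrix(rec, factor_spec = list(f1 = c("a", "b", "c"),
                                                   f2 = c("x", "y")))
  expect_equal(ncol(d$X), 3)
  expect_equal(d$columns, c("f1=b", "f1=c", "f2=y"))
  expect_equal(unname(d$X[1, ]), c(0, 0, 0))   # all-reference row
  expect_equal(unname(d$X[3, ]), c(0, 1, 1))

  # column count is sum(levels - 1)
  spec3 <- list(a = paste0("a", 1:7), b = paste0("b", 1:8), c = c("c1", "c2"))
  rec3 <- data.frame(a = "a1", b = "b1", c = "c1")
  expect_equal(ncol(build_design_matrix(rec3, spec3)$X), 14)

  expect_error(build_design_matrix(data.frame(f1 = "zz"),
                                   factor_spec = list(f1 = c("a", "b"))),
               "zz")
  # configurable reference level
  d2 <- build_design_matrix(rec, factor_spec = list(f1 = c("a", "b", "c")),
                            reference_levels = list(f1 = "c"))
  expect_equal(d2$columns, c("f1=a", "f1=b"))
})

test_that("log-posterior matches balanced-data closed form and the
           term-by-term oracle", {
  # balanced outcomes, all effects zero: likelihood term is n log(1/2) and
  # the zero-valued priors contribute nothing
  data0 <- list(y = c(0, 1, 0, 1), X = matrix(0, 4, 0), area_idx = c(1, 1, 2, 2))
  map0 <- area_map(c("a", "b"), cbind(0:1, c(0, 0)), list("b", "a"))
  st0 <- structure_matrix(map0)
  s0 <- list(beta0 = 0, beta = numeric(0))
  expect_equal(log_posterior(s0, data0, model_spec(), st0), 4 * log(0.5))

  # ICAR kernel is invariant to adding a constant to f_s
  Q <- st0$Q
  f <- c(0.7, -0.7)
  expect_equal(as.numeric(t(f + 3) %*% Q %*% (f + 3)),
               as.numeric(t(f) %*% Q %*% f))

  # n = 6 dataset: differences between samples match the independent
  # normalized-density re-derivation
  map <- area_map(c("1", "2", "3"), cbind(0:2, c(0, 0, 0)),
                  list("2", c("1", "3"), "2"))
  st <- structure_matrix(map)
  data <- list(y = c(1, 0, 1, 1, 0, 0),
               X = matrix(c(1, 0, 1, 0, 0, 1), 6, 1,
                          dimnames = list(NULL, "g=b")),
               area_idx = c(1, 1, 2, 2, 3, 3))
  spec <- model_spec(TRUE, TRUE)
  set.seed(12)
  for (i in 1:5) {
    s1 <- list(beta0 = rnorm(1), beta = rnorm(1),
               f_s = c(rnorm(2), 0), f_u = rnorm(3),
               tau_s = rexp(1) + 0.1, tau_u = rexp(1) + 0.1)
    s1$f_s[3] <- -sum(s1$f_s)
    s2 <- list(beta0 = rnorm(1), beta = rnorm(1),
               f_s = c(rnorm(2), 0), f_u = rnorm(3),
               tau_s = rexp(1) + 0.1, tau_u = rexp(1) + 0.1)
    s2$f_s[3] <- -sum(s2$f_s)
    expect_equal(
      log_posterior(s1, data, spec, st) - log_posterior(s2, data, spec, st),
      oracle_log_posterior(s1, data, spec, map) -
        oracle_log_posterior(s2, data, spec, map),
      tolerance = 1e-8)
  }
})

test_that("tau_s conditional has the plug-in gamma parameters on a path graph", {
  # f_s = (-1, 0, 1), edges (1,2), (2,3): ss = 2, shape = a + (n-k)/2 = 2,
  # rate = b + ss/2 = 2 for a = b = 1
  f <- c(-1, 0, 1)
  ss <- (f[1] - f[2])^2 + (f[2] - f[3])^2
  set.seed(31)
  draws <- draw_precision_conditional(ss, m_eff = 2, a = 1, b = 1, n = 200000)
  expect_equal(mean(draws), 2 / 2, tolerance = 0.01)
  expect_equal(var(draws), 2 / 4, tolerance = 0.02)
})

test_that("Model 1 posterior agrees with maximum likelihood on big data", {
  d <- demo_survey(seed = 300, fs_scale = 0)
  fit <- fit_model(d$records, d$map, model_spec(),
                   mcmc = list(iterations = 6000, burn_in = 2000, thin = 4,
                               seed = 301))
  ml <- glm(outcome ~ edu, binomial, data = d$records)
  post <- fit$summaries$mean[match(c("beta0", "edu=primary", "edu=secondary"),
                                   fit$summaries$parameter)]
  se <- sqrt(diag(vcov(ml)))
  expect_true(all(abs(post - coef(ml)) < 2.5 * se + 0.02))
  # pD for a GLM is about the number of parameters
  expect_equal(fit$pd, 3, tolerance = 0.3 * 3 + 1)
})

test_that("MCMC draws are deterministic given the seed and keep the
           sum-to-zero constraint", {
  d <- demo_survey(seed = 310)
  mc <- list(iterations = 1500, burn_in = 500, thin = 2, seed = 311)
  f1 <- fit_model(d$records, d$map, model_spec(TRUE, TRUE), mcmc = mc)
  f2 <- fit_model(d$records, d$map, model_spec(TRUE, TRUE), mcmc = mc)
  expect_identical(f1$samples, f2$samples)
  expect_lt(max(abs(rowSums(f1$samples$f_s))), 1e-8)
  expect_true(all(f1$samples$tau_s > 0) && all(f1$samples$tau_u > 0))
  expect_true(fit_model(d$records, d$map, model_spec(TRUE, TRUE),
                        mcmc = utils::modifyList(mc, list(seed = 312))
  )$samples$beta0[1] != f1$samples$beta0[1])
})

test_that("structured effects are refused on an edgeless graph", {
  m <- area_map(c("a", "b"), cbind(0:1, c(0, 0)),
                list(character(0), character(0)))
  rec <- data.frame(outcome = rbinom(20, 1, 0.5), weight = 1,
                    stratum_id = "s", psu_id = rep(c("p", "q"), 10),
                    area_id = rep(c("a", "b"), each = 10))
  expect_error(fit_model(rec, m, model_spec(TRUE, FALSE),
                         mcmc = list(seed = 1)), "no edges")
})

test_that("DIC decomposition is internally consistent", {
  d <- demo_survey(seed = 320)
  fit <- fit_model(d$records, d$map, model_spec(TRUE, FALSE),
                   mcmc = list(iterations = 3000, burn_in = 1000, thin = 4,
                               seed = 321))
  dic <- compute_dic(fit)
  expect_equal(dic$dic, dic$dbar + dic$pd, tolerance = 1e-10)
  expect_equal(dic$pd, dic$dbar - dic$dhat, tolerance = 1e-10)
  expect_equal(fit$dic, dic$dic)
  expect_gt(dic$pd, 0)
})

test_that("model selection minimizes DIC with ties to the earlier model", {
  expect_equal(select_best_model(c(`1` = 100, `2` = 90, `3` = 95)), 2)
  expect_equal(select_best_model(c(`1` = 100, `2` = 90, `3` = 90)), 2)
  expect_equal(select_best_model(c(M4 = 50, M1 = 50)), 1)
  expect_error(select_best_model(c(`1` = 10)), ">= 2")
})

test_that("odds ratios are monotone transforms of coefficient percentiles", {
  d <- demo_survey(seed = 330)
  fit <- fit_model(d$records, d$map, model_spec(TRUE, FALSE),
                   mcmc = list(iterations = 2000, burn_in = 500, thin = 3,
                               seed = 331))
  or <- odds_ratio_table(fit)
  expect_equal(or$or[or$reference], 1)
  b <- fit$samples$beta[, "edu=primary"]
  row <- or[or$term == "edu=primary", ]
  expect_equal(row$or, exp(unname(quantile(b, 0.5))))
  expect_equal(row$ci_low, exp(unname(quantile(b, 0.025))))
  expect_equal(row$ci_high, exp(unname(quantile(b, 0.975))))
  expect_true(row$ci_low <= row$or && row$or <= row$ci_high)
})

test_that("posterior prevalence maps are ordered, bounded and flag empty
           areas", {
  d <- demo_survey(seed = 340, rows = 3, cols = 3, per_psu = 30)
  rec <- d$records[d$records$area_id != d$map$area_ids[5], ]
  attr(rec, "factor_spec") <- attr(d$records, "factor_spec")
  attr(rec, "factors") <- attr(d$records, "factors")
  fit <- fit_model(rec, d$map, model_spec(TRUE, FALSE),
                   mcmc = list(iterations = 2000, burn_in = 500, thin = 3,
                               seed = 341))
  pm <- posterior_prevalence_map(fit)
  expect_true(all(pm$q025 <= pm$median & pm$median <= pm$q975))
  expect_true(all(pm$mean >= 0 & pm$mean <= 1))
  expect_true(pm$extrapolated[5])
  expect_equal(sum(pm$extrapolated), 1)
  expect_equal(pm$n_records[1], sum(rec$area_id == d$map$area_ids[1]))
})

test_that("fit serialization writes samples, summaries and config", {
  d <- demo_survey(seed = 350, rows = 2, cols = 3, per_psu = 20)
  fit <- fit_model(d$records, d$map, model_spec(FALSE, TRUE),
                   mcmc = list(iterations = 1200, burn_in = 400, thin = 2,
                               seed = 351))
  dir <- tempfile()
  write_fit(fit, dir)
  expect_true(all(file.exists(file.path(dir,
    c("samples.csv", "summary.csv", "config.json")))))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(cfg$model, 2)
  expect_equal(cfg$seed, 351)
  sm <- utils::read.csv(file.path(dir, "summary.csv"))
  expect_equal(sm$dic[1], fit$dic)
})
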