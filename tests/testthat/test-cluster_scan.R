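line_map <- function(n) {
  area_map(paste0("L", seq_len(n)), cbind((seq_len(n) - 1) * 0.5, 0),
           replicate(n, character(0), simplify = FALSE))
}

test_that("Bernoulli LLR matches the worked value and its boundary rules", {
  expect_equal(bernoulli_llr(5, 10, 10, 100, "high"), 6.2665,
               tolerance = 1e-3 / 6.2665)
  # independent oracle to full precision
  expect_equal(bernoulli_llr(5, 10, 10, 100, "high"),
               oracle_llr(5, 10, 10, 100, "high"), tolerance = 1e-12)

  expect_equal(bernoulli_llr(1, 10, 10, 100, "high"), 0)  # rate equals null
  expect_equal(bernoulli_llr(1, 10, 10, 100, "low"), 0)
  expect_gt(bernoulli_llr(0, 10, 10, 100, "low"), 0)      # one-sidedness
  expect_equal(bernoulli_llr(0, 10, 10, 100, "high"), 0)
  expect_equal(bernoulli_llr(10, 100, 10, 100, "high"), 0) # window = region
})

test_that("high and low LLR are never both positive", {
  set.seed(50)
  for (i in 1:200) {
    N <- sample(20:200, 1)
    n <- sample(1:(N - 1), 1)
    C <- sample(0:N, 1)
    c <- sample(max(0, C - (N - n)):min(c(n, C)), 1)
    hi <- bernoulli_llr(c, n, C, N, "high")
    lo <- bernoulli_llr(c, n, C, N, "low")
    expect_false(hi > 0 && lo > 0)
    expect_gte(hi, 0)
    expect_gte(lo, 0)
  }
})

test_that("relative risk: worked value, null case and boundaries", {
  expect_equal(relative_risk(5, 10, 10, 100), 9)
  expect_equal(relative_risk(1, 10, 10, 100), 1)
  expect_equal(relative_risk(10, 10, 10, 100), Inf)
  expect_error(relative_risk(0, 0, 10, 100), "zero")
})

test_that("window sequences are distance-ordered capped prefixes", {
  m <- line_map(3)
  D <- distance_matrix(m)
  totals <- c(10, 10, 10)
  ws <- window_sequence(1, D, totals, 0.5)
  expect_equal(ws$order, 1:3)
  expect_equal(ws$n_windows, 1)           # 20/30 > 0.5 already at 2 areas

  ws2 <- window_sequence(1, D, totals, 1 / 3)
  expect_equal(ws2$n_windows, 1)
  ws3 <- window_sequence(2, D, c(1, 1, 28), 0.5)
  expect_equal(ws3$order[1], 2)
  expect_equal(ws3$n_windows, 2)          # center, center+tied-neighbour

  # equidistant tie resolved in map order
  sq <- area_map(c("c", "e", "w"), rbind(c(0, 0), c(1, 0), c(-1, 0)),
                 replicate(3, character(0), simplify = FALSE))
  wt <- window_sequence(1, distance_matrix(sq), c(5, 5, 5), 0.5)
  expect_equal(wt$order, c(1, 2, 3))
})

test_that("scan finds the obvious cluster and is silent under uniformity", {
  m <- line_map(5)
  d <- data.frame(area_id = m$area_ids, cases = c(0, 0, 20, 0, 0),
                  total = rep(20, 5))
  res <- scan(d, m, "high")
  expect_equal(res$members[[1]], "L3")
  expect_equal(res$observed[1], 20)

  d0 <- data.frame(area_id = m$area_ids, cases = rep(4, 5), total = rep(20, 5))
  expect_equal(nrow(scan(d0, m, "high")), 0)
  expect_equal(nrow(scan(
    data.frame(area_id = m$area_ids, cases = rep(0, 5), total = rep(20, 5)),
    m, "high")), 0)
})

test_that("scan agrees exactly with exhaustive enumeration on small maps", {
  for (i in 1:30) {
    inst <- random_instance(sample(3:8, 1), seed = 500 + i)
    for (dir in c("high", "low")) {
      o <- oracle_scan(inst$data$cases, inst$data$total, inst$map, dir)
      res <- scan(inst$data, inst$map, dir)
      if (o$llr == 0) {
        expect_equal(nrow(res), 0)
      } else {
        expect_equal(res$llr[1], o$llr, tolerance = 1e-9)
        expect_equal(sort(match(res$members[[1]], inst$map$area_ids)),
                     o$members)
        expect_equal(res$relative_risk[1],
                     relative_risk(o$c, o$n, sum(inst$data$cases),
                                   sum(inst$data$total)))
      }
    }
  }
})

test_that("max LLR is invariant to relabelling areas", {
  inst <- random_instance(7, seed = 77)
  set.seed(78)
  perm <- sample(7)
  m2 <- area_map(inst$map$area_ids, inst$map$centroids[perm, ],
                 replicate(7, character(0), simplify = FALSE))
  d2 <- inst$data
  d2$cases <- inst$data$cases[perm]
  d2$total <- inst$data$total[perm]
  r1 <- scan(inst$data, inst$map, "high")
  r2 <- scan(d2, m2, "high")
  expect_equal(r1$llr[1], r2$llr[1], tolerance = 1e-12)
})

test_that("Monte Carlo p-values follow the (R+1)/(S+1) rule and reproduce
           under a seed", {
  m <- line_map(6)
  d <- data.frame(area_id = m$area_ids, cases = c(30, 0, 0, 0, 0, 0),
                  total = rep(30, 6))
  r <- monte_carlo_pvalues(d, m, "high", replications = 999, seed = 60)
  expect_equal(r$p_value[1], 1 / 1000)   # observed beats every replicate

  r2 <- monte_carlo_pvalues(d, m, "high", replications = 999, seed = 60)
  expect_identical(r$p_value, r2$p_value)
  expect_identical(attr(r, "null_max"), attr(r2, "null_max"))

  # weak signal: p cannot drop below the formula floor, stays in (0, 1]
  d3 <- data.frame(area_id = m$area_ids, cases = c(6, 5, 4, 5, 5, 5),
                   total = rep(30, 6))
  r3 <- monte_carlo_pvalues(d3, m, "high", replications = 99, seed = 61)
  if (nrow(r3) > 0) {
    expect_true(all(r3$p_value >= 1 / 100 & r3$p_value <= 1))
  }
})

test_that("secondary clusters are disjoint, ranked and alpha-gated", {
  m <- line_map(8)
  d <- data.frame(area_id = m$area_ids,
                  cases = c(25, 25, 2, 2, 2, 2, 24, 24),
                  total = rep(30, 8))
  r <- monte_carlo_pvalues(d, m, "high", replications = 999, seed = 62)
  rep <- secondary_clusters(r, 0.05)
  expect_gte(nrow(rep), 2)
  expect_equal(rep$rank, seq_len(nrow(rep)))
  all_members <- unlist(rep$members)
  expect_equal(anyDuplicated(all_members), 0)
  expect_true(all(diff(rep$llr) <= 0))

  none <- secondary_clusters(r, significance_level = 1e-6)
  expect_equal(nrow(none), 0)
})

test_that("cluster report CSV carries assumptions header and member lists", {
  m <- line_map(5)
  d <- data.frame(area_id = m$area_ids, cases = c(20, 18, 0, 0, 0),
                  total = rep(20, 5))
  r <- secondary_clusters(
    monte_carlo_pvalues(d, m, "high", replications = 99, seed = 63))
  p <- tempfile(fileext = ".csv")
  write_cluster_report(r, "high", p,
                       assumptions = list(max_fraction = 0.5))
  lines <- readLines(p)
  expect_true(grepl("^# max_fraction", lines[1]))
  tab <- utils::read.csv(p, comment.char = "#")
  expect_equal(nrow(tab), nrow(r))
  expect_true(all(grepl(";|^L", tab$members)))
})
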