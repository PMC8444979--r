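clin <- function(time, event, ids = NULL) {
  data.frame(sample_id = if (is.null(ids)) sprintf("p%02d", seq_along(time))
             else ids, time = time, event = event, stringsAsFactors = FALSE)
}

test_that("median split labels H strictly above the median, ties to L", {
  expect_equal(unname(median_split(c(a = 1, b = 2, c = 3, d = 4))$labels),
               c("L", "L", "H", "H"))
  expect_equal(unname(median_split(c(a = 1, b = 2, c = 2, d = 3))$labels),
               c("L", "L", "L", "H"))
  expect_equal(unname(median_split(c(a = 1, b = 2, c = 3))$labels),
               c("L", "L", "H"))
  expect_error(median_split(c(a = 2, b = 2, c = 2)), "degenerate")
  expect_error(median_split(c(a = 1)), "2 samples")
})

test_that("KM estimator matches hand and brute-force product-limit results", {
  # all censored: survival stays at 1
  d <- clin(c(5, 7, 9), c(0, 0, 0))
  km <- km_estimate(d, setNames(rep("all", 3), d$sample_id))
  expect_true(all(km$curves$surv == 1))

  # three events: 2/3, 1/3, 0
  d2 <- clin(c(1, 2, 3), c(1, 1, 1))
  km2 <- km_estimate(d2, setNames(rep("all", 3), d2$sample_id))
  expect_equal(km2$curves$surv, c(2 / 3, 1 / 3, 0))

  # 20-record mixed fixture vs oracle
  set.seed(12)
  t20 <- round(rexp(20, 1 / 10), 2)
  e20 <- rbinom(20, 1, 0.7)
  d3 <- clin(t20, e20)
  km3 <- km_estimate(d3, setNames(rep("all", 20), d3$sample_id))
  orc <- km_oracle(t20, e20)
  got <- km3$curves[km3$curves$n_event > 0, ]
  expect_equal(got$surv, orc$surv[match(got$time, orc$time)],
               tolerance = 1e-12)
})

test_that("log-rank matches the O/E table and is order-invariant", {
  # identical groups: no signal
  d <- clin(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 1, 1, 1))
  strat <- setNames(rep(c("g1", "g2"), each = 3), d$sample_id)
  lr <- logrank_test(d, strat)
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)

  # hand-computable 6-patient example
  d2 <- clin(c(1, 3, 5, 2, 4, 6), c(1, 1, 1, 1, 1, 0))
  strat2 <- setNames(rep(c("g1", "g2"), each = 3), d2$sample_id)
  lr2 <- logrank_test(d2, strat2)
  orc <- logrank_oracle(d2$time, d2$event, unname(strat2))
  expect_equal(lr2$chi2, orc$chi2, tolerance = 1e-6)
  expect_equal(lr2$p_value, orc$p, tolerance = 1e-6)

  # permuting the records changes nothing
  set.seed(5)
  perm <- sample(6)
  lr3 <- logrank_test(d2[perm, ], strat2)
  expect_equal(lr3$chi2, lr2$chi2, tolerance = 1e-12)

  expect_error(logrank_test(d2, setNames(rep("g1", 6), d2$sample_id)),
               "2 non-empty groups")
})

test_that("BH adjustment matches the step-up definition and its edge cases", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(2)
  p <- runif(37)
  q <- bh_adjust(p)
  expect_equal(q, bh_oracle(p), tolerance = 1e-12)
  expect_true(all(q >= p))
  # re-adjustment never decreases a q-value; flat families are fixed points
  expect_true(all(bh_adjust(q) >= q - 1e-12))
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("two-factor strata cross the medians into four balanced groups", {
  x <- setNames(1:8, paste0("s", 1:8))
  same <- two_factor_strata(x, x)
  expect_setequal(unique(same$labels), c("L/L", "H/H"))

  set.seed(33)
  n <- 1000
  u <- setNames(runif(n), paste0("s", 1:n))
  v <- setNames(runif(n), paste0("s", 1:n))
  st <- two_factor_strata(u, v)
  tab <- table(st$labels)
  expect_setequal(names(tab), c("L/L", "L/H", "H/L", "H/H"))
  expect_equal(sum(tab), n)
  # independent uniforms: each cell within 3 binomial SDs of n/4
  expect_true(all(abs(tab - n / 4) < 3 * sqrt(n * 0.25 * 0.75)))

  expect_error(two_factor_strata(setNames(rep(1, 4), paste0("s", 1:4)), u[1:4]),
               "factor x")
})

test_that("KM + log-rank separate survival-coupled strata end to end", {
  set.seed(9)
  n <- 120
  frac <- setNames(runif(n), sprintf("p%03d", seq_len(n)))
  time <- rexp(n, rate = 1 / (200 + 1500 * frac))  # high fraction lives longer
  d <- clin(time, rbinom(n, 1, 0.8), ids = names(frac))
  strat <- median_split(frac)
  lr <- logrank_test(d, strat)
  expect_lt(lr$p_value, 0.01)
  km <- km_estimate(d, strat)
  expect_setequal(km$groups, c("L", "H"))
  # survival starts at 1 and is non-increasing within each group
  for (g in km$groups) {
    s <- km$curves$surv[km$curves$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_lte(s[1], 1)
  }
})

test_that("survival screen BH-adjusts the whole feature family", {
  set.seed(14)
  n <- 80
  f <- matrix(runif(n * 4), n, dimnames = list(sprintf("p%03d", 1:n),
                                               paste0("f", 1:4)))
  f <- cbind(f, flat = rep(1, n))    # degenerate feature is skipped
  d <- clin(rexp(n, 1 / 500), rbinom(n, 1, 0.7), ids = rownames(f))
  scr <- survival_screen(f, d)
  expect_true(is.na(scr$p_value[scr$feature == "flat"]))
  ok <- !is.na(scr$p_value)
  expect_equal(scr$q_value[ok], bh_oracle(scr$p_value[ok]), tolerance = 1e-12)
})

test_that("gene-fraction correlations match the direct formula", {
  set.seed(6)
  fr <- matrix(runif(5 * 2), 5, dimnames = list(paste0("s", 1:5),
                                                c("tA", "tB")))
  expr <- matrix(rexp(5 * 5, 1 / 100), 5,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:5)))
  cc <- correlate_features(expr, fr)
  for (g in rownames(expr)) for (ty in colnames(fr))
    expect_equal(cc[g, ty], pearson_oracle(log1p(expr[g, ]), fr[, ty]),
                 tolerance = 1e-12)

  # a gene equal to a fraction column correlates perfectly (and its
  # negation perfectly negatively) without transformation
  expr2 <- rbind(pos = fr[, "tA"], neg = max(fr[, "tA"]) - fr[, "tA"])
  cc2 <- correlate_features(expr2, fr, transform = "none")
  expect_equal(unname(cc2["pos", "tA"]), 1, tolerance = 1e-12)
  expect_equal(unname(cc2["neg", "tA"]), -1, tolerance = 1e-12)

  # zero-variance rows are flagged, not fatal
  expr3 <- rbind(expr, flat = rep(3, 5))
  cc3 <- correlate_features(expr3, fr)
  expect_true(all(is.na(cc3["flat", ])))
  expect_true("flat" %in% attr(cc3, "undefined")$feature)
  expect_error(correlate_features(expr[, 1:2], fr[1:2, ]), "3 shared")
})
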