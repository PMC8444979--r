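test_that("survival sampling draws from the pool deterministically", {
  pool <- generate_clinical(30, seed = 1)
  expect_error(sample_survival(pool[0, ], 5), "empty")
  s1 <- sample_survival(pool, 100, seed = 3)
  expect_true(all(s1 %in% pool$time))
  expect_identical(s1, sample_survival(pool, 100, seed = 3))
  # without replacement at pool size: a permutation of the pool
  perm <- sample_survival(pool, 30, replace = FALSE, seed = 4)
  expect_setequal(perm, pool$time)
})

test_that("simulated proportions follow the logit-linear Dirichlet model", {
  types <- paste0("t", 1:5)
  times <- rexp(5000, 1 / 800)
  p0 <- simulate_proportions(times, "t3", types, slope = 0, seed = 7)
  expect_equal(unname(rowSums(p0)), rep(1, 5000), tolerance = 1e-12)
  expect_true(all(p0 >= 0))
  # S = 0: every type's mean proportion sits at the common baseline 1/K
  expect_equal(unname(colMeans(p0)), rep(0.2, 5), tolerance = 0.01)

  p1 <- simulate_proportions(times[1:1000], "t3", types, slope = 0.7,
                             seed = 8)
  z <- scale(times[1:1000])[, 1]
  expect_gt(cor(z, p1[, "t3"]), 0.3)

  expect_error(simulate_proportions(times[1:10], "t1", types, slope = 1,
                                    intercept = 0.3), "infeasible")
  expect_error(simulate_proportions(times[1:10], "zz", types, slope = 1),
               "variable_type")
})

test_that("mixture composition is convex in CPM space and linear in P", {
  ref <- small_ref(seed = 3, replicates_per_type = 1L)
  types <- hierarchy_leaves(ref$hierarchy)
  pure <- matrix(0, 1, length(types), dimnames = list("m1", types))
  pure[1, "beta"] <- 1
  mix <- compose_mixtures(pure, ref)
  cpm <- cpm_normalize(ref$counts)
  expect_equal(unname(mix[, 1]), unname(cpm[, ref$labels == "beta"]))

  set.seed(10)
  props <- matrix(rgamma(4 * length(types), 1), 4)
  props <- props / rowSums(props)
  dimnames(props) <- list(paste0("m", 1:4), types)
  fp <- generate_foreign_profile(ref$spec, ref$hierarchy)
  m0 <- compose_mixtures(props, ref, fp, P = 0, seed = 5)
  m5 <- compose_mixtures(props, ref, fp, P = 0.5, seed = 5)
  expect_equal(unname(colSums(m0)), rep(1e6, 4), tolerance = 1e-6)
  expect_equal(m5, 0.5 * m0 + 0.5 * fp$profile[rownames(m0)],
               tolerance = 1e-9)

  bad <- props; colnames(bad)[1] <- "unknown"
  expect_error(compose_mixtures(bad, ref), "without reference")
})

test_that("half-sample censoring halves a random half and keeps event times", {
  expect_error(censor_half(8), ">= 2")
  cl <- censor_half(rep(8, 4), seed = 2)
  expect_equal(sum(cl$event == 0), 2L)
  expect_equal(sort(cl$time), c(4, 4, 8, 8))
  cl2 <- censor_half(c(10, 20, 30, 40, 50), seed = 3)
  expect_equal(sum(cl2$event == 0), 2L)
  expect_equal(cl2$time[cl2$event == 1], c(10, 20, 30, 40, 50)[cl2$event == 1])
})

test_that("Cox fit matches an independent Newton-Raphson partial likelihood", {
  set.seed(20)
  n <- 10
  f <- matrix(rgamma(n * 2, 2), n)
  f <- cbind(f, 3) ; f <- f / rowSums(f)
  colnames(f) <- c("tA", "tB", "tC")
  rownames(f) <- sprintf("p%02d", 1:n)
  time <- sort(rexp(n, 1 / 100)) + seq_len(n) * 1e-3  # distinct times
  event <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1)
  d <- data.frame(sample_id = rownames(f), time = time, event = event)
  got <- cox_regression(f, d)
  eps <- max(1e-6, min(f[f > 0]) / 2)
  X <- qlogis(f + eps)
  expect_equal(got$coef, unname(cox_oracle(time, event, X)), tolerance = 1e-6)
  expect_true(all(got$flag == "ok"))
  expect_error(cox_regression(f, transform(d, event = 0)), "events")
})

test_that("a strong planted effect yields the simulated coefficient sign", {
  types <- paste0("t", 1:6)
  hits <- 0
  for (r in 1:20) {
    set.seed(100 + r)
    times <- rexp(200, 1 / 800)
    props <- simulate_proportions(times, "t2", types, slope = 1)
    clinical <- censor_half(times)
    rownames(props) <- clinical$sample_id
    cox <- cox_regression(props, clinical)
    # higher fraction tracks longer survival, i.e. lower hazard
    hits <- hits + (cox$coef[cox$cell_type == "t2"] < 0)
  }
  expect_gte(hits, 19)
})

test_that("ROC/AUC equals the Mann-Whitney statistic and handles edge cases", {
  p <- matrix(c(0.001, 0.8, 0.9, 0.002, 0.7, 0.6), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, c("tA", "tB", "tC")))
  perfect <- roc_auc(p, c("tA", "tA"))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$points$fpr[1], 0)
  expect_equal(utils::tail(perfect$points$tpr, 1), 1)
  expect_true(all(diff(perfect$points$tpr) >= 0))

  set.seed(31)
  pr <- matrix(runif(500 * 2), 500, dimnames = list(NULL, c("tA", "tB")))
  null_roc <- roc_auc(pr, sample(c("tA", "tB"), 500, replace = TRUE))
  expect_equal(null_roc$auc, 0.5, tolerance = 0.05)

  # U-statistic identity on a small fixture with ties
  set.seed(32)
  pm <- matrix(round(runif(10 * 2), 1), 10,
               dimnames = list(NULL, c("tA", "tB")))
  truth <- rep(c("tA", "tB"), 5)
  r <- roc_auc(pm, truth)
  lab <- as.vector(col(pm) == match(truth, colnames(pm)))
  expect_equal(r$auc, auc_u_oracle(1 - as.vector(pm), lab), tolerance = 1e-12)

  expect_error(roc_auc(pm[, 1, drop = FALSE], rep("tA", 10)), "undefined")
})

test_that("the full benchmark is deterministic and supports oracle mode", {
  ref <- small_ref(seed = 3)
  post <- memo("unit_post", fit_abundance_model(ref))
  ml <- select_markers(post, ref$hierarchy, marker_config(c("1" = 5L)))
  sig <- build_signature_matrix(post, ml)
  pool <- generate_clinical(100, seed = 6)
  cond <- data.frame(N = 40, S = 1, P = 0)
  b1 <- run_benchmark(ref, sig, pool, cond, runs_per_condition = 4L,
                      seed = 17L)
  b2 <- run_benchmark(ref, sig, pool, cond, runs_per_condition = 4L,
                      seed = 17L)
  expect_identical(b1$summary, b2$summary)
  expect_identical(b1$runs[[1]]$p_values, b2$runs[[1]]$p_values)
  expect_equal(b1$runs[[1]]$truth,
               rep(hierarchy_leaves(ref$hierarchy), 1)[1:4])
  expect_true(b1$summary$auc >= 0 && b1$summary$auc <= 1)

  b3 <- run_benchmark(ref, sig, pool, cond, runs_per_condition = 4L,
                      proportions = "oracle", seed = 17L)
  expect_true(is.finite(b3$summary$auc))
})
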