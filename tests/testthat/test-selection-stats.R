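test_that("z-scoring follows the sample-sd convention and flags zero variance", {
  m <- cbind(muCT_t = c(1, 3), muFT_t = c(5, 5))
  z <- zscore(m)
  expect_equal(z[, "muCT_t"], c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(z[, "muFT_t"], c(0, 0))
  expect_identical(attr(z, "zero_variance"), "muFT_t")
  # already-normalized column unchanged
  set.seed(1)
  x <- rnorm(50); x <- (x - mean(x)) / sd(x)
  z2 <- zscore(cbind(muVS_t = x))
  expect_equal(z2[, "muVS_t"], x, tolerance = 1e-12)
  # columns have mean 0 and sd 1
  set.seed(2)
  z3 <- zscore(matrix(rnorm(200), 20, dimnames = list(NULL, all_metric_names()[1:10])))
  expect_true(all(abs(colMeans(z3)) < 1e-9))
  expect_true(all(abs(apply(z3, 2, sd) - 1) < 1e-9))
})

test_that("multicollinearity pruning keeps the longer time segment", {
  set.seed(3)
  x <- rnorm(30)
  m <- cbind(muVS_t = x, muVS_s = x, muFT_sy = rnorm(30))
  expect_setequal(prune_multicollinear(m), c("muVS_t", "muFT_sy"))
  # three mutual duplicates across t/sy/s: only t survives
  m2 <- cbind(muVS_sy = x, muVS_s = x, muVS_t = x)
  expect_identical(prune_multicollinear(m2), "muVS_t")
  # equal-duration tie (s vs e): the earlier segment wins
  m3 <- cbind(muVS_e = x, muVS_s = x, muFT_t = rnorm(30))
  expect_setequal(prune_multicollinear(m3), c("muVS_s", "muFT_t"))
  # independent Gaussian columns all survive
  set.seed(4)
  m4 <- matrix(rnorm(200 * 12), 200,
               dimnames = list(NULL, all_metric_names()[1:12]))
  expect_length(prune_multicollinear(m4), 12)
  # anti-correlated duplicates are pruned too (|r| used)
  m5 <- cbind(muVS_t = x, muVS_s = -x)
  expect_identical(prune_multicollinear(m5), "muVS_t")
})

test_that("target-correlation filter retains |r| >= threshold", {
  set.seed(5)
  y <- rnorm(1000)
  m <- cbind(muVS_t = y, muCT_t = -0.9 * y + rnorm(1000, 0, sqrt(1 - 0.81)),
             muFT_t = rnorm(1000))
  kept <- filter_by_target(m, y)
  expect_true("muVS_t" %in% kept)       # r = 1
  expect_true("muCT_t" %in% kept)       # r ~ -0.9, |r| retained
  expect_false("muFT_t" %in% kept)      # pure noise
})

test_that("LOOCV-LASSO selects a noiseless planted metric with near-perfect fit", {
  set.seed(6)
  X <- matrix(rnorm(40 * 10), 40,
              dimnames = list(NULL, all_metric_names()[1:10]))
  z <- zscore(X)
  y <- 2 * z[, 3]
  fit <- lasso_select(z, y)
  expect_identical(fit$selected, colnames(z)[3])
  expect_gte(fit$r2, 0.99)
  expect_lt(fit$rmse, 0.2)
  expect_error(lasso_select(z, rep(1, 40)), "zero variance")
  expect_error(lasso_select(z[1:3, ], y[1:3]), "at least 5")
})

test_that("LOOCV-LASSO returns near-zero fit on pure-noise targets", {
  r2 <- vapply(1:9, function(s) {
    set.seed(s)
    X <- matrix(rnorm(40 * 20), 40,
                dimnames = list(NULL, all_metric_names()[1:20]))
    lasso_select(zscore(X), rnorm(40))$r2
  }, numeric(1))
  expect_lte(median(r2), 0.1)
})

test_that("the full selection chain recovers planted support in >= 90% of seeds", {
  hits <- 0L
  n_rep <- 50L
  for (s in seq_len(n_rep)) {
    sim <- planted_matrix(seed = s)
    z <- zscore(sim$X)
    keep <- prune_multicollinear(z)
    keep <- filter_by_target(z[, keep, drop = FALSE], sim$y)
    fit <- lasso_select(z[, keep, drop = FALSE], sim$y)
    ok <- all(names(sim$planted) %in% fit$selected) &&
      all(sign(fit$coefficients[names(sim$planted)]) == sign(sim$planted))
    hits <- hits + ok
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("category contributions are shares of absolute weights", {
  fit <- structure(list(coefficients = c(muVS_t = 2, muGT_t = -1, muCT_d = 1),
                        selected = c("muVS_t", "muGT_t", "muCT_d")),
                   class = "lasso_fit")
  shares <- category_contributions(fit)
  expect_equal(sum(shares), 100, tolerance = 1e-9)
  expect_equal(unname(shares["technique"]), 50)
  expect_equal(unname(shares["pace"]), 25)
  expect_equal(unname(shares["fatigue"]), 25)
  one <- structure(list(coefficients = c(muVS_t = 0.4),
                        selected = "muVS_t"), class = "lasso_fit")
  expect_equal(unname(category_contributions(one)), 100)
})

test_that("Welch comparison handles constants, planted shifts and grouping", {
  set.seed(7)
  y <- rnorm(33)
  m <- cbind(muVS_t = rep(1, 33), muCT_t = rnorm(33))
  w <- welch_compare(m, y, k = 10)
  row <- w[w$metric == "muVS_t", ]
  expect_equal(row$t, 0)
  expect_equal(row$cohens_d, 0)
  expect_false(row$significant)
  expect_length(intersect(attr(w, "top"), attr(w, "bottom")), 0)
  expect_error(welch_compare(m, y, k = 20), "disjoint")

  # planted 1.5-pooled-sd shift between groups detected in >= 80% of seeds
  hits <- vapply(1:25, function(s) {
    set.seed(s)
    y <- rnorm(33)
    x <- rnorm(33)
    ord <- order(y, decreasing = TRUE)
    x[ord[1:10]] <- x[ord[1:10]] + 1.5
    w <- welch_compare(cbind(muVS_t = x), y, k = 10)
    w$significant[1]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("Welch test is calibrated under the global null", {
  fp <- 0L; tot <- 0L
  for (r in 1:20) {
    set.seed(100 + r)
    X <- matrix(rnorm(33 * 110), 33,
                dimnames = list(NULL, sprintf("m%03d", 1:110)))
    w <- welch_compare(X, rnorm(33), k = 10)
    fp <- fp + sum(w$significant); tot <- tot + nrow(w)
  }
  rate <- fp / tot
  expect_gte(tot, 2000)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("profile construction is union-then-intersection set arithmetic", {
  mk <- function(lasso_sel, welch_sig, welch_all = c("A", "B", "C", "D")) {
    list(lasso = structure(list(selected = lasso_sel,
                                coefficients = numeric(0)),
                           class = "lasso_fit"),
         welch = structure(data.frame(metric = welch_all,
                                      significant = welch_all %in% welch_sig,
                                      stringsAsFactors = FALSE),
                           class = c("group_comparison", "data.frame")))
  }
  sel <- list(mas = mk("muVS_t", "sdCT_t", c("muVS_t", "sdCT_t", "muCT_d")),
              svt2 = mk(c("sdCT_t", "muCT_d"), character(0),
                        c("muVS_t", "sdCT_t", "muCT_d")),
              cas = mk("sdCT_t", "muCT_d", c("muVS_t", "sdCT_t", "muCT_d")))
  prof <- build_profile(sel)
  expect_identical(prof$metrics$name, "sdCT_t")
  expect_identical(prof$metrics$category, "regularity")
  # identical sets: profile equals the common set
  sel2 <- list(a = mk("muVS_t", "sdCT_t", c("muVS_t", "sdCT_t")),
               b = mk("muVS_t", "sdCT_t", c("muVS_t", "sdCT_t")))
  expect_setequal(build_profile(sel2)$metrics$name, c("muVS_t", "sdCT_t"))
  # disjoint sets: empty profile with a warning
  sel3 <- list(a = mk("muVS_t", character(0)), b = mk("muCT_d", character(0)))
  expect_warning(p3 <- build_profile(sel3), "empty")
  expect_equal(nrow(p3$metrics), 0)
})

test_that("select_metrics chains the funnel and reports counts", {
  sim <- planted_matrix(seed = 11)
  res <- select_metrics(sim$X, sim$y, k = 10)
  expect_true(all(names(sim$planted) %in% res$lasso$selected))
  expect_equal(unname(res$counts["total"]), ncol(sim$X))
  expect_lte(res$counts["correlation"], res$counts["collinearity"])
  expect_equal(sum(res$contributions), 100, tolerance = 1e-9)
})
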