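# Prediction aggregation, error features, cross-validation drivers, metrics.

test_that("numeric aggregation gives mean prediction and per-compound RMSE", {
  tab <- validation_table(compound_index = c(1, 1, 2), run_id = c(1, 2, 1),
                          predicted = c(1.0, 3.0, 5.0))
  agg <- aggregate_numeric(tab, actual = c(2.0, 5.0))
  expect_equal(agg$prediction, c(2.0, 5.0))
  expect_equal(agg$error, c(1.0, 0))          # sqrt((1 + 1)/2); exact run
  expect_equal(agg$n_runs, c(2L, 1L))
  nominal <- validation_table(1:2, 1, c("a", "b"))
  expect_error(aggregate_numeric(nominal, c(1, 2)), "numeric")
})

test_that("binary aggregation produces active ratios, error ratios and the always-wrong flag", {
  tab <- validation_table(rep(1:2, each = 10), rep(1:10, 2),
                          c(rep("active", 7), rep("inactive", 3),
                            rep("inactive", 10)))
  agg <- aggregate_binary(tab, actual = c("active", "active"), positive = "active")
  expect_equal(agg$prediction, c(0.7, 0))
  expect_equal(agg$error, c(0.3, 1))
  expect_equal(agg$always_wrong, c(FALSE, TRUE))
  # prediction ratio + opposite-class ratio = 1 and error bounded (property)
  set.seed(51)
  for (i in 1:20) {
    n_runs <- sample(2:8, 1)
    preds <- sample(c("active", "inactive"), n_runs, replace = TRUE)
    t2 <- validation_table(rep(1, n_runs), seq_len(n_runs), preds)
    a2 <- aggregate_binary(t2, "inactive", positive = "active")
    expect_equal(a2$prediction + mean(preds == "inactive"), 1)
    expect_true(a2$error >= 0 && a2$error <= 1)
  }
  # actual active, runs {active, inactive, inactive} => error 2/3
  t3 <- validation_table(rep(1, 3), 1:3, c("active", "inactive", "inactive"))
  expect_equal(aggregate_binary(t3, "active", "active")$error, 2 / 3)
  expect_error(aggregate_binary(t3, "active", positive = "bogus"), "bogus")
})

test_that("multi-class aggregation requires a strict majority", {
  expect_equal(aggregate_multiclass(validation_table(c(1, 1, 1), 1:3, c("A", "A", "B")),
                                    "A")$prediction, "A")
  expect_equal(aggregate_multiclass(validation_table(c(1, 1), 1:2, c("A", "B")),
                                    "A")$prediction, "inconclusive")
  expect_equal(aggregate_multiclass(validation_table(c(1, 1, 1), 1:3, c("A", "B", "C")),
                                    "A")$prediction, "inconclusive")
})

test_that("AD ratios and probability means aggregate per compound", {
  tab <- validation_table(rep(1, 4), 1:4, rnorm(4),
                          probability = c(0.9, 0.8, 0.7, 0.6),
                          ad_inside = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(aggregate_ad(tab)$ad_ratio, 0.75)
  agg <- aggregate_numeric(tab, actual = 0)
  expect_equal(agg$ad_ratio, 0.75)
  expect_equal(agg$probability, 0.75)
  expect_error(aggregate_ad(validation_table(1, 1, 0.5)), "AD flags")
})

test_that("aggregation is invariant to run order", {
  set.seed(52)
  preds <- rnorm(6)
  t1 <- validation_table(rep(1:2, 3), rep(1:3, each = 2), preds)
  perm <- sample(6)
  t2 <- validation_table(t1$compound_index[perm], t1$run_id[perm], t1$predicted[perm])
  expect_equal(aggregate_numeric(t2, c(0, 0)), aggregate_numeric(t1, c(0, 0)))
})

test_that("error difference is a signed per-compound comparison", {
  expect_equal(error_difference(c(2, 0), c(0, 1)), c(2, -1))
  expect_equal(error_difference(c(1, 1), c(1, 1)), c(0, 0))
  # model A worse on a compound => positive entry
  expect_gt(error_difference(5, 1)[1], 0)
  expect_error(error_difference(1:3, 1:2), "length")
})

test_that("LOO with OLS is exact on noise-free linear data and honest on the mean predictor", {
  set.seed(53)
  x <- matrix(runif(40), 20, 2)
  y <- 2 + 3 * x[, 1] - 5 * x[, 2]
  ds <- cs_dataset(features = data.frame(f1 = x[, 1], f2 = x[, 2], y = y),
                   endpoints = "y")
  tab <- loo_cross_validate(ds, "y")
  expect_equal(tab$predicted, y, tolerance = 1e-9)     # perfect model, zero residuals
  expect_equal(nrow(tab), 20)

  # mean predictor on {0, 10}: LOO predicts the *other* value; R^2 < 0
  mean_learner <- list(name = "mean",
                       fit = function(x, y) mean(y),
                       predict = function(model, x) rep(model, nrow(x)))
  ds2 <- cs_dataset(features = data.frame(f = c(0, 1), y = c(0, 10)), endpoints = "y")
  tab2 <- loo_cross_validate(ds2, "y", learner = mean_learner)
  expect_equal(tab2$predicted, c(10, 0))
  expect_lt(metrics(c(0, 10), tab2$predicted)$r2, 0)
})

test_that("repeated k-fold records one run per repetition per compound", {
  ds <- generate_caco2_like(n = 30, noise_sd = 0.2, seed = 54)
  tab <- kfold_cross_validate(ds, "logPeff", k = 10, repeats = 10, seed = 7)
  expect_equal(nrow(tab), 300)                              # 100 runs of 30 predictions... 10x30
  expect_equal(as.integer(table(tab$compound_index)), rep(10L, 30))
  expect_equal(as.integer(table(tab$run_id)), rep(30L, 10))
  # deterministic given the seed
  tab2 <- kfold_cross_validate(ds, "logPeff", k = 10, repeats = 10, seed = 7)
  expect_identical(tab, tab2)
})

test_that("metrics follow the scorer convention for R^2", {
  expect_equal(metrics(c(1, 2, 3), c(1, 2, 3))$r2, 1)
  expect_equal(metrics(c(1, 2, 3), rep(2, 3))$r2, 0)        # mean predictor
  expect_equal(metrics(c(0, 2), c(1, 1))$r2, 0)             # SSE = SST = 2
  expect_equal(metrics(c("a", "b", "a"), c("a", "b", "b"))$accuracy, 2 / 3)
  expect_error(metrics(c(1, 1), c(0, 2)), "zero variance")
})

test_that("OLS recovers generator coefficients and noise degrades R^2 monotonically", {
  # clamp-inactive, noise-free: the model is exactly linear
  ds <- generate_caco2_like(n = 60, noise_sd = 0, seed = 55, logD_range = c(-1.8, 2))
  fit <- lm(logPeff ~ logD + HCPSA + rgyr + frotb, data = ds$features)
  expect_equal(unname(coef(fit)),
               c(-4.358, 0.317, -0.00558, -0.179, 1.074), tolerance = 1e-8)
  r2 <- sapply(c(0, 0.3, 1, 3), function(s) {
    d <- generate_caco2_like(n = 80, noise_sd = s, seed = 56)
    tab <- loo_cross_validate(d, "logPeff")
    metrics(d$features$logPeff, tab$predicted)$r2
  })
  expect_true(all(diff(r2) < 0))
})
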