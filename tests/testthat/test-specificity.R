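# Subset-vs-dataset feature specificity: chi-squared, ANOVA, adaptive binning.

test_that("nominal chi-squared matches the hand-computed enrichment case", {
  # 10-compound subset all 'match' in a 20/80 dataset: chi2 = 32 + 8 = 40
  values <- rep(c("match", "no"), c(20, 80))
  p <- nominal_specificity(values, subset = 1:10)
  expect_equal(attr(p, "statistic"), 40)
  expect_equal(as.numeric(p), pchisq(40, 1, lower.tail = FALSE))
  expect_lt(p, 1e-9)   # ~2.5e-10

  # proportions equal to the dataset's => chi2 = 0, p = 1
  values2 <- rep(c("a", "b"), 50)
  p2 <- nominal_specificity(values2, subset = 1:10)  # 5 a's, 5 b's
  expect_equal(attr(p2, "statistic"), 0)
  expect_equal(as.numeric(p2), 1)

  # single-category feature is degenerate
  p3 <- nominal_specificity(rep("x", 20), 1:5)
  expect_equal(as.numeric(p3), 1)
  expect_equal(attr(p3, "flag"), "degenerate")
})

test_that("chi-squared agrees with a brute-force oracle on random subsets", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(30:80, 1)
    vals <- sample(letters[1:sample(2:4, 1)], n, replace = TRUE)
    if (length(unique(vals)) < 2) next
    subset <- sample(n, sample(2:(n - 1), 1))
    p <- nominal_specificity(vals, subset)
    # brute force: explicit sum over categories + survival function
    cats <- unique(vals)
    obs <- sapply(cats, function(cl) sum(vals[subset] == cl))
    expd <- sapply(cats, function(cl) mean(vals == cl) * length(subset))
    stat <- sum((obs - expd)^2 / expd)
    expect_equal(attr(p, "statistic"), stat, tolerance = 1e-10)
    expect_equal(as.numeric(p),
                 max(pchisq(stat, length(cats) - 1, lower.tail = FALSE),
                     .Machine$double.xmin),
                 tolerance = 1e-10)
  }
})

test_that("ANOVA specificity agrees with R's reference ANOVA", {
  vals <- c(10, 11, 12, 0, 1, 2)
  p <- numeric_specificity(vals, subset = 1:3)
  expect_lt(p, 0.01)
  # oracle: anova on the two-group factor
  grp <- factor(c(1, 1, 1, 2, 2, 2))
  ref <- anova(lm(vals ~ grp))
  expect_equal(attr(p, "statistic"), ref$`F value`[1], tolerance = 1e-10)
  expect_equal(as.numeric(p), ref$`Pr(>F)`[1], tolerance = 1e-10)

  # identical distributions in subset and complement => p = 1
  same <- rep(c(5, 7, 9), 2)
  p2 <- numeric_specificity(same, subset = 1:3)
  expect_equal(as.numeric(p2), 1, tolerance = 1e-12)
})

test_that("ANOVA agrees with brute force on random splits (property)", {
  set.seed(22)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    vals <- rnorm(n)
    subset <- sample(n, sample(2:(n - 2), 1))
    p <- numeric_specificity(vals, subset)
    grp <- factor(seq_len(n) %in% subset)
    ref <- anova(lm(vals ~ grp))
    expect_equal(as.numeric(p), ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("adaptive equal-width binning descends to the largest empty-free k", {
  e <- adaptive_equal_width_bins(c(0, 1, 2))
  expect_equal(attr(e, "k"), 3)       # k = 20..4 all leave empty bins
  expect_equal(as.numeric(e), c(0, 2 / 3, 4 / 3, 2), tolerance = 1e-12)

  grid <- seq(0, 1, length.out = 20)
  expect_equal(attr(adaptive_equal_width_bins(grid), "k"), 20)

  expect_equal(attr(adaptive_equal_width_bins(c(0, 100)), "k"), 2)
  expect_error(adaptive_equal_width_bins(rep(1, 5)), "identical")
})

test_that("adaptive binning never returns an empty bin (property, 1000 vectors)", {
  set.seed(23)
  for (i in 1:1000) {
    v <- switch(sample(3, 1),
                rnorm(sample(2:40, 1)),
                rexp(sample(2:40, 1)),
                sample(0:5, sample(2:40, 1), replace = TRUE))
    if (length(unique(v)) < 2) next
    edges <- adaptive_equal_width_bins(v)
    k <- attr(edges, "k")
    counts <- tabulate(findInterval(v, edges, rightmost.closed = TRUE), nbins = k)
    expect_true(all(counts > 0))
    expect_equal(range(edges), range(v))
  }
})

test_that("single-compound specificity orders typical vs extreme compounds", {
  # skewed sample: one compound far out in its own bin
  vals <- c(rep(1, 20) + seq(0, 0.5, length.out = 20), 30)
  p_extreme <- single_compound_specificity(vals, length(vals))
  p_typical <- single_compound_specificity(vals, 1)
  expect_lt(p_extreme, p_typical)
  # compound whose bin contains the entire dataset: impossible once binned,
  # but a 2-value dataset in one bin each gives p < 1; degenerate constant => 1
  p_deg <- single_compound_specificity(rep(4, 10), 1)
  expect_equal(as.numeric(p_deg), 1)
})

test_that("feature ranking routes tests correctly and ranks planted signal first", {
  set.seed(24)
  n <- 60
  subset <- 1:15
  sep <- rep("out", n); sep[subset] <- "in"      # perfectly separating nominal
  noise <- runif(n)
  num <- rnorm(n); num[subset] <- num[subset] + 4  # separating numeric
  ds <- cs_dataset(features = data.frame(separator = sep, noise = noise, shifted = num))
  rk <- rank_features(ds, subset)
  expect_s3_class(rk, "specificity_ranking")
  expect_equal(nrow(rk), 3)
  expect_true(all(rk$p > 0 & rk$p <= 1))
  expect_equal(sort(rk$feature), sort(names(ds$features)))  # a permutation
  expect_equal(rk$feature[3], "noise")                      # signal outranks noise
  expect_equal(rk$test[rk$feature == "separator"], "chi2")
  expect_equal(rk$test[rk$feature == "shifted"], "anova")
  # single-compound subsets route numerics to the binned test
  rk1 <- rank_features(ds, 42)
  expect_equal(rk1$test[rk1$feature == "shifted"], "binned-chi2")
  # whole-dataset subset distinguishes nothing
  rk_all <- rank_features(ds, 1:n)
  expect_true(all(rk_all$p == 1))
})

test_that("p-values converge to 1 as subset proportions approach dataset proportions", {
  vals <- rep(c("a", "b"), c(40, 60))
  # subsets with a-proportion marching toward the dataset's 0.4
  subsets <- list(c(1:10),                 # all 'a'
                  c(1:8, 41:42),           # 80% 'a'
                  c(1:6, 41:44),           # 60% 'a'
                  c(1:4, 41:46))           # 40% 'a' == dataset proportion
  ps <- vapply(subsets, function(s) as.numeric(nominal_specificity(vals, s)), numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_equal(ps[4], 1)
})
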