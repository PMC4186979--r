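# Fragment matching, frequency filtering, discretization, standardization.

test_that("SMARTS matching agrees with hand-enumerated substructure hits", {
  ds <- cs_dataset(smiles = c("CCO", "CCC", "OCO"), features = data.frame(i = 1:3))
  fm <- match_fragments(ds, c("[#8]", "CC"))
  # oxygen in CCO and OCO; C-C bond in CCO and CCC
  expect_equal(unname(fm$counts), c(2, 2))
  expect_equal(fm$matrix[, "[#8]"], c(1L, 0L, 1L))
  expect_equal(fm$matrix[, "CC"], c(1L, 1L, 0L))
  # self-match and absent-atom cases
  ds2 <- cs_dataset(smiles = c("c1ccccc1", "CC"), features = data.frame(i = 1:2))
  fm2 <- match_fragments(ds2, c("c1ccccc1", "[#8]"))
  expect_equal(unname(fm2$matrix[1, "c1ccccc1"]), 1L)
  expect_equal(unname(fm2$matrix[2, ]), c(0L, 0L))
})

test_that("matching errors name the offending pattern or compound", {
  ds <- cs_dataset(smiles = "CCO", features = data.frame(i = 1))
  expect_error(match_fragments(ds, "C1CC"), "C1CC")
  ds_na <- cs_dataset(smiles = NA_character_, features = data.frame(i = 1))
  expect_error(match_fragments(ds_na, "[#8]"), "without structure")
})

test_that("permuting compounds permutes fragment-matrix rows identically", {
  smiles <- c("CCO", "CCC", "OCO", "c1ccccc1", "CCN")
  perm <- c(3, 1, 5, 2, 4)
  pats <- c("[#8]", "CC", "[#7]")
  f1 <- match_fragments(cs_dataset(smiles = smiles, features = data.frame(i = 1:5)), pats)
  f2 <- match_fragments(cs_dataset(smiles = smiles[perm], features = data.frame(i = 1:5)), pats)
  expect_equal(f2$matrix, f1$matrix[perm, ])
})

test_that("frequency filter is two-sided, boundary-exact, and idempotent", {
  n <- 100
  m <- matrix(0L, n, 4)
  m[1:9, 1] <- 1L     # below min_count: dropped
  m[1:10, 2] <- 1L    # exactly min_count: kept
  m[, 3] <- 1L        # constant: dropped (two-sided)
  m[1:90, 4] <- 1L    # n - min_count: kept
  fm <- fragment_matrix(m, c("s1", "s2", "s3", "s4"))
  filt <- filter_min_frequency(fm, min_count = 10)
  expect_equal(filt$smarts, c("s2", "s4"))
  expect_equal(filter_min_frequency(filt, 10)$matrix, filt$matrix)  # idempotent
  # one-sided mode keeps the constant column
  expect_equal(filter_min_frequency(fm, 10, two_sided = FALSE)$smarts,
               c("s2", "s3", "s4"))
  expect_error(filter_min_frequency(fm, min_count = 95), "no informative")
})

test_that("equal-frequency discretization honours the tie rule", {
  r <- discretize_equal_frequency(1:10)
  expect_equal(r$thresholds, 5)
  expect_equal(sum(r$classes == "active"), 5)
  # ties at the threshold go with the lower class
  r2 <- discretize_equal_frequency(c(1, 1, 1, 1, 2))
  expect_equal(as.integer(table(r2$classes)[c("active", "inactive")]), c(4L, 1L))
  expect_error(discretize_equal_frequency(rep(3, 5)), "distinct")
  # class sizes always sum to n; thresholds monotone (property)
  set.seed(11)
  for (i in 1:20) {
    v <- sample(1:8, 40, replace = TRUE)
    k <- sample(2:4, 1)
    rr <- discretize_equal_frequency(v, n_classes = k)
    expect_equal(length(rr$classes), 40)
    expect_true(all(diff(rr$thresholds) >= 0))
  }
})

test_that("equal-frequency split of 467 potency values marks 234 active", {
  # mirrors a median split with distinct values: ceiling(467/2) actives
  set.seed(5)
  ic50 <- exp(rnorm(467))
  r <- discretize_equal_frequency(ic50, low_is_active = TRUE)
  expect_equal(sum(r$classes == "active"), 234)
  expect_true(all(ic50[r$classes == "active"] <= r$thresholds))
})

test_that("standardization hits mean 0 / unit population variance and is idempotent", {
  ds <- cs_dataset(features = data.frame(a = c(0, 10), b = c(3, 4)))
  std <- standardize_numeric(ds, c("a", "b"))
  expect_equal(std$features$a, c(-1, 1))                 # mean 5, pop SD 5
  expect_equal(std$standardization$a$mean, 5)
  expect_equal(std$standardization$a$sd, 5)
  again <- standardize_numeric(std, c("a", "b"))
  expect_equal(again$features$a, std$features$a, tolerance = 1e-12)
  expect_error(standardize_numeric(cs_dataset(features = data.frame(c = rep(2, 4)))),
               "constant")
})

test_that("descriptor computation delegates to the toolkit", {
  ds <- cs_dataset(smiles = c("O", "C"), features = data.frame(i = 1:2))
  out <- compute_descriptors(ds, c("mw", "nbonds"))
  expect_equal(out$features$mw[1], 18.02, tolerance = 1e-3)  # water
  expect_equal(out$features$nbonds[2], 0)                    # methane: no heavy bonds
  expect_error(compute_descriptors(ds, "foo"), "mw")         # lists available names
})

test_that("MACCS list retrieval and SMARTS files work", {
  pats <- maccs_smarts()
  expect_gte(length(pats), 160)
  expect_true(all(nzchar(pats)))
  expect_equal(length(maccs_smarts(keep_placeholders = TRUE)), 166)
  f <- system.file("extdata", "example_fragments.smarts", package = "chemspacemap")
  lst <- read_smarts_list(f)
  expect_gte(length(lst), 10)
  expect_false(any(grepl("#", lst)))
})
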