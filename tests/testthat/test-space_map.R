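# Distances, PCA and Sammon embeddings, clustering, duplicate positions.

test_that("euclidean distances match hand geometry", {
  m <- rbind(c(0, 0), c(3, 4), c(0, 0))
  d <- euclidean_distances(m)
  expect_equal(d$matrix[1, 2], 5)       # 3-4-5 triangle
  expect_equal(d$matrix[1, 3], 0)       # identical rows
  one <- euclidean_distances(matrix(1, 1, 2))$matrix
  expect_equal(dim(one), c(1L, 1L))
  expect_equal(one[1, 1], 0)
  expect_error(euclidean_distances(matrix(c(1, NA), 1, 2)), "missing")
})

test_that("tanimoto distances follow the set formula", {
  m <- rbind(c(1, 1, 0), c(1, 0, 1), c(1, 1, 0), c(0, 0, 0), c(0, 0, 0))
  d <- tanimoto_distances(m)
  expect_equal(d$matrix[1, 2], 2 / 3)   # intersection 1, union 3
  expect_equal(d$matrix[1, 3], 0)       # identical fingerprints
  expect_equal(d$matrix[4, 5], 0)       # two all-zero fingerprints
  disj <- tanimoto_distances(rbind(c(1, 0), c(0, 1)))
  expect_equal(disj$matrix[1, 2], 1)    # disjoint nonempty
  expect_error(tanimoto_distances(rbind(c(2, 0), c(0, 1))), "binary")
})

test_that("tanimoto distance satisfies the triangle inequality (property)", {
  for (seed in 1:5) {
    m <- random_binary_matrix(30, 12, seed)
    d <- tanimoto_distances(m)$matrix
    n <- nrow(d)
    for (i in 1:n) for (k in 1:n)
      expect_true(all(d[i, ] <= d[i, k] + d[k, ] + 1e-12))
  }
})

test_that("PCA embedding is lossless up to intrinsic dimension 3", {
  set.seed(2)
  base <- matrix(rnorm(30 * 3), 30, 3)
  # rank-3 data in 5 feature dimensions
  x <- base %*% matrix(rnorm(15), 3, 5)
  emb <- embed_pca(x)
  d_feat <- lower_tri(as.matrix(dist(x)))
  d_emb <- lower_tri(as.matrix(dist(emb$coords)))
  expect_equal(d_feat, d_emb, tolerance = 1e-9)
  expect_equal(cor(d_feat, d_emb), 1, tolerance = 1e-9)
  # rank-1 data lands on a line: y and z coordinates all zero
  x1 <- cbind(1:10) %*% t(c(1, 2, 0.5))
  emb1 <- embed_pca(x1)
  expect_equal(max(abs(emb1$coords[, 2:3])), 0, tolerance = 1e-9)
  expect_error(embed_pca(matrix(1:4, 2, 2)), "at least 3")
})

test_that("PCA sign convention makes the embedding reproducible", {
  set.seed(3)
  x <- matrix(rnorm(60), 20, 3)
  expect_identical(embed_pca(x)$coords, embed_pca(x)$coords)
  # the largest-magnitude loading of each used component is positive
  centered <- sweep(x, 2, colMeans(x))
  sv <- svd(centered)
  coords <- embed_pca(x)$coords
  recovered <- qr.solve(centered, coords)  # loadings actually applied
  for (j in 1:3) expect_gt(recovered[which.max(abs(recovered[, j])), j], 0)
})

test_that("Sammon mapping recovers exactly embeddable configurations", {
  emb <- embed_sammon(tetrahedron_distances())
  expect_lt(emb$stress, 1e-6)
  d <- as.matrix(dist(emb$coords))
  expect_equal(lower_tri(d), rep(1, 6), tolerance = 1e-3)
})

test_that("Sammon stress is monotone nonincreasing and matches MASS on a clean case", {
  delta <- matrix(1, 4, 4); diag(delta) <- 0
  delta[1, 2] <- delta[2, 1] <- 10       # unembeddable pair
  emb <- embed_sammon(cs_distances(delta, "euclidean"))
  trace <- emb$parameters$stress_trace
  expect_gt(emb$stress, 0)
  expect_true(all(diff(trace) <= 0))
  expect_lte(emb$stress, trace[1])

  # independent oracle: MASS::sammon on a distinct random configuration
  set.seed(9)
  x <- matrix(rnorm(8 * 5), 8, 5)
  dd <- euclidean_distances(x)
  ours <- embed_sammon(dd)
  ref <- MASS::sammon(stats::as.dist(dd$matrix), y = stats::cmdscale(dd$matrix, k = 3),
                      k = 3, trace = FALSE)
  # MASS reports stress with the same normalisation; allow optimizer slack
  expect_equal(ours$stress, ref$stress, tolerance = 0.05)
  expect_error(embed_sammon(cs_distances(matrix(0, 2, 2), "euclidean")), "at least 4")
})

test_that("Sammon pins identical compounds to identical coordinates", {
  x <- rbind(c(0, 0), c(0, 0), c(3, 0), c(0, 4), c(5, 5))
  emb <- embed_sammon(euclidean_distances(x))
  expect_equal(emb$coords[1, ], emb$coords[2, ])
  expect_equal(emb$parameters$n_distinct, 4)
})

test_that("clustering recovers planted blobs and is reproducible", {
  set.seed(4)
  blobs <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
                 matrix(rnorm(40, 8, 0.3), 20, 2))
  truth <- rep(1:2, each = 20)
  cl <- cluster_compounds(blobs, "kmeans", k = "auto", seed = 7)
  expect_equal(cl$k, 2)
  expect_true(all(table(cl$labels, truth) %in% c(0, 20)))  # exact recovery
  cl2 <- cluster_compounds(blobs, "kmeans", k = "auto", seed = 7)
  expect_identical(cl$labels, cl2$labels)
  # hierarchical route on distances
  ch <- cluster_compounds(euclidean_distances(blobs), "hierarchical-average", k = 2)
  expect_true(all(table(ch$labels, truth) %in% c(0, 20)))
  # duplicated compounds land in the same cluster
  dup <- rbind(blobs, blobs[1, ])
  cd <- cluster_compounds(dup, "kmeans", k = 2, seed = 1)
  expect_equal(cd$labels[41], cd$labels[1])
})

test_that("clustering rejects invalid requests", {
  m <- matrix(rnorm(20), 10, 2)
  expect_error(cluster_compounds(m, "kmeans", k = 1), ">= 2")
  expect_error(cluster_compounds(m, "kmeans", k = 10), "smaller")
  expect_error(cluster_compounds(euclidean_distances(m), "kmeans", k = 2),
               "coordinate")
})

test_that("duplicate-position detection partitions identical feature vectors", {
  m <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expect_warning(res <- detect_duplicate_positions(m), "2 distinct")
  expect_equal(res$n_distinct, 2)
  expect_equal(res$groups[[1]], c(1L, 2L))
  expect_equal(res$duplicated, c(TRUE, TRUE, FALSE))
  all_distinct <- detect_duplicate_positions(diag(3), warn = FALSE)
  expect_equal(all_distinct$n_distinct, 3)
})
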