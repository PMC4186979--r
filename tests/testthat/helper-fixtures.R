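# Shared fixtures, all built in code.

lower_tri <- function(m) m[lower.tri(m)]

# Tiny numeric dataset: 4 compounds, 2 standardizable features + endpoint.
tiny_numeric_dataset <- function() {
  cs_dataset(
    features = data.frame(a = c(0, 10, 5, 2.5), b = c(1, 2, 3, 4),
                          y = c(0.1, 0.9, 0.4, 0.3)),
    endpoints = "y",
    names = paste0("c", 1:4)
  )
}

# 3 collinear points in feature space (distances 1, 2, 1) and a 3D embedding
# on a line with distances 1, 3, 2 -- the hand-Pearson case r = sqrt(3)/2.
hand_pearson_case <- function() {
  fd <- cs_distances(as.matrix(dist(c(0, 1, 2))), "euclidean")
  coords <- cbind(c(0, 1, 3), 0, 0)
  list(fd = fd, coords = coords)
}

# Random binary fragment matrix.
random_binary_matrix <- function(n, f, seed) {
  with_seed <- function(s, expr) { set.seed(s); expr }
  with_seed(seed, matrix(rbinom(n * f, 1, 0.4), n, f))
}

# Distance matrix of a unit tetrahedron (exactly embeddable in 3D).
tetrahedron_distances <- function() {
  m <- matrix(1, 4, 4); diag(m) <- 0
  cs_distances(m, "euclidean")
}

expect_symmetric <- function(m, tol = 1e-12) {
  expect_lt(max(abs(m - t(m))), tol)
}

# Adjusted Rand index, hand-rolled from the contingency table (test oracle).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(length(a))
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
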