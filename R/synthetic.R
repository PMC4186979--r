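#' Caco-2-like endpoint formula
#'
#' Deterministic part of the synthetic permeability endpoint:
#' \deqn{logP_{eff} = -4.358 + 0.317 \min(\max(-1.8, logD), 2.0)
#'       - 0.00558\, HCPSA - 0.179\, rgyr + 1.074\, f_{rotb}}
#' The logD term is clamped to `[-1.8, 2.0]`, so the relationship is linear
#' only inside that window -- the feature a plain linear model cannot capture.
#'
#' @param logD Octanol/water distribution coefficient.
#' @param HCPSA High-charged polar surface area (A^2).
#' @param rgyr Radius of gyration (A).
#' @param frotb Fraction of rotatable bonds.
#' @return Numeric endpoint (log effective permeability).
#' @export
caco2_endpoint <- function(logD, HCPSA, rgyr, frotb) {
  -4.358 + 0.317 * pmin(pmax(-1.8, logD), 2.0) -
    0.00558 * HCPSA - 0.179 * rgyr + 1.074 * frotb
}

#' Generate a Caco-2-like permeability dataset
#'
#' Emulates a small, structurally diverse permeability dataset: four numeric
#' molecular properties drawn uniformly from plausible ranges (logD in
#' `[-4, 6]`, HCPSA in `[0, 150]`, rgyr in `[2, 8]`, frotb in `[0, 0.6]`) and
#' a numeric endpoint following [caco2_endpoint()] plus Gaussian noise.
#' Mirroring the real data, logD and HCPSA are anticorrelated (compounds with
#' a lot of charged polar surface are hydrophilic): the pair is drawn from a
#' Gaussian copula with correlation `rho`, which keeps the marginals exactly
#' uniform on the stated ranges. With the default logD range the clamp is
#' active on a known minority of rows (logD outside `[-1.8, 2.0]`, expected
#' fraction 62%), which is what makes simple linear regression measurably
#' worse than a non-linear learner on this data. Regeneration with the same
#' seed is bit-identical.
#'
#' @param n Number of compounds (default 100, the size of the real dataset
#'   this emulates; n >= 10).
#' @param noise_sd Gaussian noise SD on the endpoint in log units (default
#'   0.3; >= 0).
#' @param seed Integer seed.
#' @param logD_range Sampling range for logD; restrict to `[-1.8, 2]` to
#'   deactivate the clamp and make the generator exactly linear.
#' @param rho Copula correlation between logD and HCPSA (default -0.8).
#' @return A [cs_dataset] with numeric features `logD`, `HCPSA`, `rgyr`,
#'   `frotb` and endpoint column `logPeff`.
#' @export
generate_caco2_like <- function(n = 100, noise_sd = 0.3, seed = 1L,
                                logD_range = c(-4, 6), rho = -0.8) {
  if (n < 10) stop("n must be >= 10", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)", call. = FALSE)
  feats <- with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    f <- data.frame(
      logD = logD_range[1] + diff(logD_range) * stats::pnorm(z1),
      HCPSA = 150 * stats::pnorm(z2),
      rgyr = stats::runif(n, 2, 8),
      frotb = stats::runif(n, 0, 0.6)
    )
    f$logPeff <- caco2_endpoint(f$logD, f$HCPSA, f$rgyr, f$frotb) +
      stats::rnorm(n, 0, noise_sd)
    f
  })
  cs_dataset(features = feats, endpoints = "logPeff",
             names = sprintf("cmpd_%03d", seq_len(n)))
}

#' Generate a binary-fragment dataset with planted structure
#'
#' Emulates a congeneric inhibitor dataset described by binary structural
#' fragments: compounds fall into `n_clusters` planted clusters, each with its
#' own Bernoulli fragment profile (cluster-characteristic fragments present
#' with probability 0.85, background fragments with probability 0.08); the
#' binary class is a threshold on a linear score of the fragments (median
#' split, emulating equal-frequency discretization of a potency value); and
#' `n_conflict_pairs` activity cliffs are planted by copying one compound's
#' fragment vector onto another and flipping its class -- pairs with identical
#' features and opposite activity that no model on these features can
#' separate.
#'
#' @param n Number of compounds (default 467).
#' @param n_fragments Number of fragment features (default 97).
#' @param n_clusters Planted clusters (default 7; <= n_fragments).
#' @param n_conflict_pairs Planted identical-vector/opposite-class pairs
#'   (default 10; `2 * n_conflict_pairs <= n`).
#' @param seed Integer seed.
#' @return List with `dataset` (a [cs_dataset] of nominal 0/1 fragment columns
#'   `frag_*` and nominal endpoint `activity`), `fragments` (the
#'   [fragment_matrix]), and ground truth `clusters` (integer labels) and
#'   `conflict_pairs` (two-column matrix).
#' @export
generate_fragment_dataset <- function(n = 467, n_fragments = 97, n_clusters = 7,
                                      n_conflict_pairs = 10, seed = 1L) {
  if (n_fragments < n_clusters)
    stop("need n_fragments >= n_clusters", call. = FALSE)
  if (2 * n_conflict_pairs > n)
    stop("2 * n_conflict_pairs must be <= n", call. = FALSE)
  if (n_clusters < 1 || n < 4) stop("infeasible parameters", call. = FALSE)

  gen <- with_seed(seed, {
    cluster_of <- sort(rep_len(seq_len(n_clusters), n))
    # disjoint blocks of characteristic fragments per cluster
    block <- split(seq_len(n_fragments),
                   sort(rep_len(seq_len(n_clusters), n_fragments)))
    m <- matrix(0L, n, n_fragments)
    for (i in seq_len(n)) {
      p <- rep(0.08, n_fragments)
      p[block[[cluster_of[i]]]] <- 0.85
      m[i, ] <- as.integer(stats::runif(n_fragments) < p)
    }
    w <- stats::rnorm(n_fragments)
    score <- as.numeric(m %*% w)
    cls <- ifelse(score <= stats::median(score), "active", "inactive")
    # plant identical-feature conflicts: copy vector, force opposite classes
    pairs <- matrix(integer(0), ncol = 2)
    if (n_conflict_pairs > 0) {
      picked <- sample(n, 2 * n_conflict_pairs)
      pairs <- cbind(picked[seq_len(n_conflict_pairs)],
                     picked[n_conflict_pairs + seq_len(n_conflict_pairs)])
      for (r in seq_len(n_conflict_pairs)) {
        a <- pairs[r, 1]; b <- pairs[r, 2]
        m[b, ] <- m[a, ]
        cluster_of[b] <- cluster_of[a]
        cls[b] <- if (cls[a] == "active") "inactive" else "active"
      }
    }
    list(m = m, cls = cls, cluster_of = cluster_of, pairs = pairs)
  })

  colnames(gen$m) <- sprintf("frag_%03d", seq_len(n_fragments))
  feats <- as.data.frame(gen$m)
  feats[] <- lapply(feats, as.character)  # 0/1 fragments are nominal features
  feats$activity <- gen$cls
  types <- stats::setNames(rep("nominal", ncol(feats)), names(feats))
  dataset <- cs_dataset(features = feats, feature_types = types,
                        endpoints = "activity",
                        names = sprintf("cmpd_%03d", seq_len(n)))
  pairs <- t(apply(gen$pairs, 1, sort))
  if (length(pairs) == 0) pairs <- matrix(integer(0), ncol = 2)
  colnames(pairs) <- c("i", "j")
  list(dataset = dataset,
       fragments = fragment_matrix(gen$m, colnames(gen$m)),
       clusters = gen$cluster_of,
       conflict_pairs = pairs)
}
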