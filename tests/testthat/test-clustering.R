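planted_block_distance <- function(n_blocks = 3, per_block = 6, seed = 3,
                                   noise = 0.02) {
  set.seed(seed)
  dirs <- diag(n_blocks) + 0.05
  L <- do.call(rbind, lapply(seq_len(n_blocks), function(b)
    matrix(rep(dirs[b, ], each = per_block), per_block) +
      matrix(rnorm(per_block * n_blocks, 0, noise), per_block)))
  rownames(L) <- sprintf("b%d_dv%d", rep(seq_len(n_blocks), each = per_block),
                         seq_len(n_blocks * per_block))
  list(L = L, labels = rep(seq_len(n_blocks), each = per_block))
}

test_that("loading distance is the sign-invariant correlation dissimilarity", {
  L <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(-1, -2, -3),
             d = c(1, 0, 0), e = c(0, 1, 0))
  d <- loading_distance(L)
  expect_equal(d$d["a", "b"], 0)
  expect_equal(d$d["a", "c"], 0)           # sign invariance
  expect_equal(d$d["d", "e"], 0.5)         # cor((1,0,0),(0,1,0)) = -1/2
  expect_equal(d$d, t(d$d))
  expect_equal(diag(d$d), rep(0, 5), ignore_attr = TRUE)
  # invariant to row scaling and sign flips
  L2 <- diag(c(2, -1, 0.5, 3, -4)) %*% L
  rownames(L2) <- rownames(L)
  expect_equal(loading_distance(L2)$d, d$d, tolerance = 1e-12)
  expect_error(loading_distance(rbind(L, f = c(2, 2, 2))), "constant.*f")
})

test_that("tree building follows the distances and reproduces ultrametrics", {
  d3 <- dv_distance(matrix(c(0, .1, .9, .1, 0, .9, .9, .9, 0), 3,
                           dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  tr <- build_tree(d3)
  expect_equal(sort(tr$tree$merge[1, ]), c(-2, -1))  # first merge (A, B)
  # ultrametric input: cophenetic distances reproduce the input exactly
  expect_equal(as.matrix(stats::cophenetic(tr$tree))[c("A", "B", "C"),
                                                     c("A", "B", "C")],
               d3$d, tolerance = 1e-12)
  # permutation invariance up to relabeling
  pb <- planted_block_distance(seed = 5)
  d <- loading_distance(pb$L)
  perm <- sample(seq_len(nrow(pb$L)))
  dp <- dv_distance(d$d[perm, perm])
  coph1 <- as.matrix(stats::cophenetic(build_tree(d)$tree))
  coph2 <- as.matrix(stats::cophenetic(build_tree(dp)$tree))
  nm <- rownames(coph1)
  expect_equal(coph2[nm, nm], coph1[nm, nm], tolerance = 1e-12)
})

test_that("dynamic hybrid cut recovers planted blocks and respects guards", {
  pb <- planted_block_distance(3, 6, seed = 7)
  tr <- build_tree(loading_distance(pb$L))
  dyn <- dynamic_tree_cut(tr)
  expect_equal(length(setdiff(unique(dyn$labels), 0L)), 3)
  expect_equal(adjusted_mutual_information(dyn$labels, pb$labels), 1)
  # a single tight block stays one cluster
  set.seed(8)
  L1 <- matrix(rep(c(.8, .3, .1), each = 10), 10) + matrix(rnorm(30, 0, .01), 10)
  rownames(L1) <- paste0("x", 1:10)
  dyn1 <- dynamic_tree_cut(build_tree(loading_distance(L1)))
  expect_equal(unname(dyn1$labels), rep(1L, 10))
  expect_error(dynamic_tree_cut(tr, min_cluster_size = 100), "exceeds")
  expect_error(dynamic_tree_cut(tr, deep_split = 7), "deep_split")
})

test_that("fixed-height cut: root, leaves, and silhouette-maximizing sweep", {
  pb <- planted_block_distance(3, 6, seed = 9)
  d <- loading_distance(pb$L)
  tr <- build_tree(d)
  expect_equal(length(unique(fixed_height_cut(tr,
                                              height = max(tr$tree$height))$labels)),
               1)
  below <- fixed_height_cut(tr, height = min(tr$tree$height) / 2)
  expect_equal(length(unique(below$labels)), nrow(pb$L))
  sw <- fixed_height_cut(tr)
  expect_equal(length(unique(sw$labels)), 3)
  expect_equal(adjusted_mutual_information(sw$labels, pb$labels), 1)
  expect_true(is.data.frame(sw$params$sweep))
  expect_error(fixed_height_cut(tr, height = 2), "outside")
  # dynamic and fixed cut agree at matched cluster count on clean data
  dyn <- dynamic_tree_cut(tr)
  fh <- fixed_height_cut(tr, n_clusters = length(unique(dyn$labels)))
  expect_gte(adjusted_mutual_information(dyn$labels, fh$labels), 0.95)
})

test_that("silhouette matches hand-worked values and conventions", {
  # two far tight pairs
  D <- matrix(0.99, 4, 4); D[1, 2] <- D[2, 1] <- 0.01; D[3, 4] <- D[4, 3] <- 0.01
  diag(D) <- 0
  dimnames(D) <- list(paste0("v", 1:4), paste0("v", 1:4))
  s <- silhouette_scores(dv_distance(D), c(1, 1, 2, 2))
  expect_equal(unname(s$scores), rep((0.99 - 0.01) / 0.99, 4))
  expect_gt(s$mean, 0.97)
  # hand-worked asymmetric 4-point case: labels (1,1,2,2)
  D2 <- matrix(c(0, .2, .8, .7,
                 .2, 0, .6, .9,
                 .8, .6, 0, .3,
                 .7, .9, .3, 0), 4, 4,
               dimnames = list(paste0("u", 1:4), paste0("u", 1:4)))
  s2 <- silhouette_scores(dv_distance(D2), c(1, 1, 2, 2))
  a <- c(.2, .2, .3, .3)
  b <- c(mean(c(.8, .7)), mean(c(.6, .9)), mean(c(.8, .6)), mean(c(.7, .9)))
  expect_equal(unname(s2$scores), (b - a) / pmax(a, b), tolerance = 1e-12)
  # random labels on uniform distances hover near zero
  set.seed(10)
  Du <- matrix(0.5, 20, 20); diag(Du) <- 0
  dimnames(Du) <- list(paste0("w", 1:20), paste0("w", 1:20))
  s3 <- silhouette_scores(dv_distance(Du), sample(1:3, 20, replace = TRUE))
  expect_lt(abs(s3$mean), 1e-10)
  expect_error(silhouette_scores(dv_distance(Du), rep(1, 20)), "single cluster")
  expect_warning(silhouette_scores(dv_distance(Du),
                                   c(rep(0, 2), sample(1:2, 18, TRUE))),
                 "unassigned")
})

test_that("AMI matches a brute-force permutation-null oracle", {
  cases <- list(list(a = c(1, 1, 2, 2, 2, 3), b = c(1, 2, 2, 3, 3, 3)),
                list(a = c(1, 1, 1, 2, 2), b = c(1, 2, 1, 2, 2)),
                list(a = rep(1:2, 4), b = c(1, 1, 2, 2, 3, 3, 4, 4)))
  for (cs in cases) {
    N <- length(cs$a)
    mi <- function(a, b) {
      t <- table(a, b); s <- 0
      for (i in seq_len(nrow(t))) for (j in seq_len(ncol(t))) {
        n <- t[i, j]
        if (n > 0) s <- s + n / N * log(N * n / (sum(t[i, ]) * sum(t[, j])))
      }
      s
    }
    emi_bf <- mean(vapply(all_permutations(seq_len(N)),
                          function(p) mi(cs$a, cs$b[p]), 0))
    H <- function(l) { p <- table(l) / N; -sum(p * log(p)) }
    ami_bf <- (mi(cs$a, cs$b) - emi_bf) /
      (mean(c(H(cs$a), H(cs$b))) - emi_bf)
    expect_equal(adjusted_mutual_information(cs$a, cs$b), ami_bf,
                 tolerance = 1e-10)
  }
})

test_that("AMI conventions: identity, triviality, symmetry, relabeling", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_mutual_information(a, a), 1)
  expect_equal(adjusted_mutual_information(a, c(7, 7, 9, 9, 4, 4)), 1)
  expect_equal(adjusted_mutual_information(rep(1, 6), 1:6), 0)
  b <- c(1, 2, 2, 3, 3, 3)
  expect_equal(adjusted_mutual_information(a, b),
               adjusted_mutual_information(b, a))
  expect_error(adjusted_mutual_information(a, b[-1]), "length")
})

test_that("consensus clustering: degenerate limit and planted separation", {
  pb <- planted_block_distance(3, 6, seed = 11)
  base <- dynamic_tree_cut(build_tree(loading_distance(pb$L)))$labels
  # sd = 0, no dropout: every simulation reproduces the original clustering
  cons0 <- consensus_cluster(pb$L, matrix(0, nrow(pb$L), ncol(pb$L)),
                             n_sim = 120, drop_frac = 0, seed = 2)
  expect_equal(cons0$ami_vs_original, 1)
  expect_true(all(cons0$cooccurrence %in% c(0, 1)))
  expect_equal(cons0$within_mean, 1)
  # noisy loadings with dropout: within-block co-occurrence far above between
  cons <- consensus_cluster(pb$L, matrix(0.05, nrow(pb$L), ncol(pb$L)),
                            n_sim = 300, drop_frac = 0.2, seed = 3)
  expect_true(all(cons$cooccurrence >= 0 & cons$cooccurrence <= 1))
  expect_gt(cons$within_mean - cons$between_mean, 0.5)
  expect_warning(consensus_cluster(pb$L, matrix(0, nrow(pb$L), ncol(pb$L)),
                                   n_sim = 50, drop_frac = 0, seed = 1),
                 "n_sim")
})

test_that("consensus co-occurrence stabilizes with simulation count", {
  pb <- planted_block_distance(3, 5, seed = 13)
  sdm <- matrix(0.08, nrow(pb$L), ncol(pb$L))
  c_small <- consensus_cluster(pb$L, sdm, n_sim = 500, seed = 5)
  c_big <- consensus_cluster(pb$L, sdm, n_sim = 5000, seed = 6)
  expect_lt(max(abs(c_small$cooccurrence - c_big$cooccurrence)), 0.05)
})

test_that("2-D embeddings: MDS geometry and PCA variance", {
  D <- matrix(0.6, 3, 3); diag(D) <- 0
  dimnames(D) <- list(c("a", "b", "c"), c("a", "b", "c"))
  mds <- embed_2d(dv_distance(D), "mds", seed = 1)
  dd <- as.matrix(dist(mds$coords))
  ratios <- dd[upper.tri(dd)] / mean(dd[upper.tri(dd)])
  expect_equal(ratios, rep(1, 3), tolerance = 1e-3)   # equilateral triangle
  expect_true(all(diff(mds$stress_trace) <= 1e-12))   # stress non-increasing
  set.seed(14)
  Y <- matrix(rnorm(40), 20, 2) %*% matrix(rnorm(8), 2, 4)  # rank 2
  pca <- embed_2d(Y, "pca")
  expect_equal(pca$var_explained, 1, tolerance = 1e-10)
})
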