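# effect table with k planted Gaussian clusters in effect space
planted_effect_table <- function(n, centroids, scatter = 0.05, seed = 1) {
  set.seed(seed)
  k <- nrow(centroids)
  assign_k <- rep_len(seq_len(k), n)
  vals <- centroids[assign_k, , drop = FALSE] +
    matrix(stats::rnorm(n * ncol(centroids), 0, scatter), n)
  rownames(vals) <- paste0("cell_", seq_len(n))
  list(effects = effect_table(vals), truth = assign_k)
}

test_that("the elbow finds three well-separated planted clusters with
           perfect assignments", {
  cents <- matrix(c(0, 0, 0, 0,
                    1, 1, 0, 0,
                    0, 1, 1, 1), 3, 4, byrow = TRUE,
                  dimnames = list(NULL, paste0("cond", 1:4)))
  pe <- planted_effect_table(300, cents, scatter = 0.05, seed = 61)
  cp <- kmeans_profile(pe$effects, k_range = 1:8, seed = 62)
  expect_equal(cp$k, 3L)
  # perfect recovery up to label permutation
  tab <- table(cp$assignment, pe$truth)
  expect_equal(sum(apply(tab, 1, max)), 300)
})

test_that("within-SS at k = 1 is the total SS and the curve is monotone
           non-increasing", {
  set.seed(63)
  vals <- matrix(stats::rnorm(200 * 5), 200, 5,
                 dimnames = list(paste0("cell_", 1:200), paste0("c", 1:5)))
  e <- effect_table(vals)
  cp <- kmeans_profile(e, k_range = 1:8, seed = 64)
  z <- scale(vals)
  total_ss <- sum(sweep(z, 2, colMeans(z))^2)
  expect_equal(cp$wss$within_ss[1], total_ss, tolerance = 1e-10)
  expect_true(all(diff(cp$wss$within_ss) <= 1e-8))
})

test_that("duplicating every cell changes neither the elbow nor the
           assignments", {
  cents <- matrix(c(0, 0, 1, 1, 0, 1), 3, 2, byrow = TRUE,
                  dimnames = list(NULL, c("a", "b")))
  pe <- planted_effect_table(150, cents, scatter = 0.04, seed = 65)
  dup_vals <- rbind(unclass(pe$effects), unclass(pe$effects))
  rownames(dup_vals) <- paste0("cell_", seq_len(300))
  dup <- effect_table(dup_vals)
  cp1 <- kmeans_profile(pe$effects, k_range = 1:6, seed = 66)
  cp2 <- kmeans_profile(dup, k_range = 1:6, seed = 66)
  expect_equal(cp2$k, cp1$k)
  tab <- table(cp2$assignment[1:150], cp1$assignment)
  expect_equal(sum(apply(tab, 1, max)), 150)
})

test_that("assignments are invariant to column order and per-condition
           affine rescaling", {
  cents <- matrix(c(0, 0, 0, 1, 1, 0), 3, 2, byrow = TRUE,
                  dimnames = list(NULL, c("a", "b")))
  pe <- planted_effect_table(120, cents, scatter = 0.04, seed = 67)
  v <- unclass(pe$effects)
  perm <- effect_table(v[, c(2, 1)])
  affine <- effect_table(sweep(sweep(v, 2, c(10, 0.2), "*"), 2, c(3, -7),
                               "+"))
  cp0 <- kmeans_profile(pe$effects, k_range = 1:5, seed = 68)
  cpp <- kmeans_profile(perm, k_range = 1:5, seed = 68)
  cpa <- kmeans_profile(affine, k_range = 1:5, seed = 68)
  for (cp in list(cpp, cpa)) {
    expect_equal(cp$k, cp0$k)
    tab <- table(cp$assignment, cp0$assignment)
    expect_equal(sum(apply(tab, 1, max)), 120)
  }
})

test_that("identical cells collapse to one forced cluster", {
  vals <- matrix(0.5, 20, 3,
                 dimnames = list(paste0("cell_", 1:20), c("a", "b", "c")))
  expect_warning(cp <- kmeans_profile(effect_table(vals), k_range = 1:4),
                 "identical")
  expect_equal(cp$k, 1L)
  expect_true(all(cp$assignment == 1L))
})

test_that("Ward dendrograms merge identical items at height zero with
           n - 1 non-decreasing merges", {
  vals <- matrix(c(0, 0, 1, 1, 0, 0, 2, 2), 4, 2, byrow = TRUE,
                 dimnames = list(paste0("cell_", 1:4), c("a", "b")))
  h <- hierarchical_profile(effect_table(vals), "cells")
  expect_equal(nrow(h$merge), 3L)
  expect_true(all(diff(h$height) >= -1e-12))
  expect_equal(h$height[1], 0, tolerance = 1e-12)  # cells 1 and 3 identical
})

test_that("conditions sharing a latent factor form a clade before joining
           unrelated conditions", {
  set.seed(69)
  n <- 250
  f <- stats::rnorm(n)
  vals <- cbind(A1 = 0.3 * f + stats::rnorm(n, 0, 0.05),
                A2 = 0.3 * f + stats::rnorm(n, 0, 0.05),
                A3 = 0.3 * f + stats::rnorm(n, 0, 0.05),
                B1 = stats::rnorm(n, 0, 0.15),
                B2 = stats::rnorm(n, 0, 0.15))
  rownames(vals) <- paste0("cell_", seq_len(n))
  h <- hierarchical_profile(effect_table(vals), "conditions")
  # at some cut the three A conditions are alone in one cluster
  clade <- any(vapply(2:4, function(k) {
    ct <- stats::cutree(h, k)
    g <- ct[c("A1", "A2", "A3")]
    length(unique(g)) == 1 && sum(ct == g[1]) == 3
  }, logical(1)))
  expect_true(clade)
})

test_that("PCA contributions are normalized percentages that reflect
           correlated structure", {
  set.seed(70)
  n <- 400
  f <- stats::rnorm(n)
  vals <- cbind(A1 = f + stats::rnorm(n, 0, 0.1),
                A2 = f + stats::rnorm(n, 0, 0.1),
                A3 = f + stats::rnorm(n, 0, 0.1),
                B1 = stats::rnorm(n),
                B2 = stats::rnorm(n))
  rownames(vals) <- paste0("cell_", seq_len(n))
  pc <- pca_contributions(effect_table(vals))
  expect_equal(sum(pc$pc1_contrib_pct), 100, tolerance = 1e-9)
  expect_equal(sum(pc$pc2_contrib_pct), 100, tolerance = 1e-9)
  # the correlated trio dominates PC1 at roughly a third each
  trio <- pc$pc1_contrib_pct[pc$condition %in% c("A1", "A2", "A3")]
  expect_gt(sum(trio), 90)
  expect_true(all(abs(trio - 100 / 3) < 5))

  # isotropic noise spreads contributions roughly evenly
  iso <- matrix(stats::rnorm(4000), 1000, 4,
                dimnames = list(paste0("cell_", 1:1000), paste0("c", 1:4)))
  pci <- pca_contributions(effect_table(iso))
  expect_true(all(pci$pc1_contrib_pct < 60))

  # zero-variance condition excluded with a warning
  zv <- cbind(vals, Z = rep(1, n))
  expect_warning(pcz <- pca_contributions(effect_table(zv)), "Z")
  expect_false("Z" %in% pcz$condition)
})
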