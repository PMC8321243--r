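test_that("the sorting statistic is signed window variability", {
  s <- tiny_schedule()
  t <- 0:119

  # flat trace at 1: sgn(0) * 0 = 0
  flat <- trace_matrix(matrix(1, 120, 1))
  expect_equal(unclass(sorting_statistic(flat, s, "A"))[[1]], 0)

  # step 1 -> 1.5 at the window midpoint: S = +SD of a two-level sequence
  v_up <- matrix(1 + 0.5 * (t >= 20), 120, 1)
  s_up <- unclass(sorting_statistic(trace_matrix(v_up), s, "A"))[[1]]
  two_level_sd <- sqrt(20 * 0.25^2 / 19)
  expect_equal(s_up, two_level_sd, tolerance = 1e-12)

  # symmetric negative step: opposite sign, same magnitude
  v_dn2 <- matrix(ifelse(t >= 20, 0.6, 1), 120, 1)
  s_dn <- unclass(sorting_statistic(trace_matrix(v_dn2), s, "A"))[[1]]
  v_up2 <- matrix(ifelse(t >= 20, 1.4, 1), 120, 1)
  s_up2 <- unclass(sorting_statistic(trace_matrix(v_up2), s, "A"))[[1]]
  expect_lt(s_dn, 0)
  expect_equal(abs(s_dn), s_up2, tolerance = 1e-12)

  expect_error(sorting_statistic(flat, s, "A", n_before = 30), "out of bounds")
})

test_that("the statistic is invariant under permuting frames inside the
           window", {
  s <- tiny_schedule()
  set.seed(51)
  v <- matrix(1 + stats::rnorm(120 * 4, 0, 0.1), 120, 4)
  x1 <- trace_matrix(v)
  w <- 11:30  # rows of the 10+10 window around frame 20
  v2 <- v
  v2[w, ] <- v2[sample(w), ]
  x2 <- trace_matrix(v2)
  expect_equal(unclass(sorting_statistic(x1, s, "A")),
               unclass(sorting_statistic(x2, s, "A")), tolerance = 1e-12)
})

test_that("ranking is a stable bijection matching an independent sort", {
  s <- tiny_schedule()
  set.seed(52)
  v <- matrix(1 + stats::rnorm(120 * 10, 0, 0.05), 120, 10)
  x <- trace_matrix(v)
  st <- sorting_statistic(x, s, "A")
  perm <- rank_cells(x, st)
  expect_setequal(perm, 1:10)
  expect_equal(unclass(st)[perm], sort(unclass(st), decreasing = TRUE),
               ignore_attr = TRUE)

  # already sorted -> identity; reversed -> reversing permutation
  xs <- x[, perm]
  expect_equal(rank_cells(xs, sorting_statistic(xs, s, "A")), 1:10)
  xr <- x[, rev(perm)]
  expect_equal(rank_cells(xr, sorting_statistic(xr, s, "A")), 10:1)

  # applying the ranking twice is idempotent
  expect_equal(rank_cells(xs, sorting_statistic(xs, s, "A")), 1:10)
})

test_that("the marker split classifies by amplitude sign and recovers a
           planted mixture fraction", {
  e <- effect_table(matrix(c(0.3, -0.3), 2, 1,
                           dimnames = list(c("a", "b"), "adrenaline")))
  sp <- split_population(e, "adrenaline")
  expect_equal(as.character(sp), c("alpha_like", "beta_like"))
  expect_error(split_population(e, "nope"), "not in the effect table")

  s <- study_schedule()
  cells <- random_cells(400, study_labels,
                        marker_label = "adrenaline @ 10 uM",
                        marker_positive_frac = 0.3, seed = 53)
  sim <- simulate_traces(cells, s, study_drift(), seed = 54)
  x <- correct_traces(sim, s)
  eff <- quantify_effects(x, s, "linear")
  sp2 <- split_population(eff, "adrenaline @ 10 uM")
  frac <- mean(sp2 == "alpha_like")
  # binomial sampling error around the planted 30 %
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 400) + 0.02)
})

test_that("per-class Pearson correlations behave like cor.test", {
  set.seed(55)
  n <- 1000
  x1 <- stats::rnorm(n)
  vals <- cbind(a = x1, b = 2 * x1, c = stats::rnorm(n))
  rownames(vals) <- paste0("cell_", seq_len(n))
  e <- effect_table(vals)
  sp <- factor(rep("alpha_like", n), levels = c("alpha_like"))
  names(sp) <- rownames(vals)

  out <- effect_correlations(e, sp, list(c("a", "b"), c("a", "c")))
  expect_equal(out$r[1], 1, tolerance = 1e-12)
  expect_lt(abs(out$r[2]), 0.1)
  ct <- stats::cor.test(vals[, "a"], vals[, "c"])
  expect_equal(out$p[2], ct$p.value, tolerance = 1e-12)
  expect_equal(out$slope[1], 2, tolerance = 1e-12)

  # zero-variance column reported as NA
  zv <- cbind(a = x1, b = rep(1, n))
  rownames(zv) <- rownames(vals)
  e2 <- effect_table(zv)
  out2 <- effect_correlations(e2, sp, list(c("a", "b")))
  expect_true(is.na(out2$r))
})

test_that("a latent factor planted in one class only shows up in that
           class's correlation", {
  set.seed(56)
  n <- 300
  f <- stats::rnorm(n)
  beta_rows <- cbind(a = 0.3 * f + stats::rnorm(n, 0, 0.05),
                     b = 0.3 * f + stats::rnorm(n, 0, 0.05))
  alpha_rows <- cbind(a = stats::rnorm(n, 0, 0.15),
                      b = stats::rnorm(n, 0, 0.15))
  vals <- rbind(beta_rows, alpha_rows)
  rownames(vals) <- paste0("cell_", seq_len(2 * n))
  e <- effect_table(vals)
  sp <- factor(rep(c("beta_like", "alpha_like"), each = n),
               levels = c("alpha_like", "beta_like"))
  names(sp) <- rownames(vals)
  out <- effect_correlations(e, sp, list(c("a", "b")))
  r_beta <- out$r[out$class == "beta_like"]
  r_alpha <- out$r[out$class == "alpha_like"]
  expect_gt(r_beta, r_alpha)
  expect_gt(r_beta, 0.9)
})
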