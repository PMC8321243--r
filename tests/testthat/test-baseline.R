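baseline_methods <- c("linear", "exponential", "spline", "polynomial",
                      "piecewise_linear", "piecewise_square")

test_that("a drift-free constant matrix gives a unit baseline for every
           method", {
  s <- tiny_schedule()
  x <- trace_matrix(matrix(1, 120, 3))
  for (m in baseline_methods) {
    b <- fit_baseline(x, s, m)
    expect_equal(unname(b$baseline), matrix(1, 120, 3), tolerance = 1e-7)
    corrected <- subtract_baseline(x, b)
    expect_equal(unclass(corrected), matrix(1, 120, 3),
                 ignore_attr = TRUE, tolerance = 1e-7)
    expect_equal(unname(b$diagnostics$basal_rss), rep(0, 3),
                 tolerance = 1e-12)
  }
})

test_that("piecewise-linear correction recovers a planted linear drift
           slope within 1%", {
  s <- study_schedule()
  t <- 0:(total_frames(s) - 1)
  slope <- -0.001
  v <- sapply(1:5, function(j) 1 + slope * t)
  x <- trace_matrix(v)
  b <- fit_baseline(x, s, "piecewise_linear")
  for (j in 1:5) {
    est <- stats::coef(stats::lm(b$baseline[, j] ~ t))[2]
    expect_lt(abs(est - slope) / abs(slope), 0.01)
  }
  # exact removal: drift linear between basal anchors
  expect_equal(unname(b$baseline), unname(v), tolerance = 1e-9)
})

test_that("polynomial degree equals the number of basal regions minus one", {
  # 4 basal regions -> cubic: a cubic drift is reproduced exactly
  s <- timestamp_schedule(c("a", "b", "c"), c(10, 30, 50), c(20, 40, 60),
                         80)
  expect_length(basal_regions(s), 4L)
  t <- 0:79
  cubic <- 1 + 1e-3 * t - 3e-5 * t^2 + 2e-7 * t^3
  x <- trace_matrix(matrix(cubic, 80, 1))
  b <- fit_baseline(x, s, "polynomial")
  expect_equal(b$baseline[, 1], cubic, tolerance = 1e-8,
               ignore_attr = TRUE)

  # 3 basal regions -> quadratic: the same cubic cannot be reproduced
  s2 <- timestamp_schedule(c("a", "b"), c(10, 30), c(20, 40), 80)
  b2 <- fit_baseline(trace_matrix(matrix(cubic, 80, 1)), s2, "polynomial")
  expect_gt(max(abs(b2$baseline[, 1] - cubic)), 1e-5)
})

test_that("methods reject schedules with too few basal regions", {
  s <- timestamp_schedule(character(0), integer(0), integer(0), 50)
  x <- trace_matrix(matrix(1, 50, 2))
  expect_error(fit_baseline(x, s, "linear"), "at least 2 basal regions")
})

test_that("subtraction re-anchors at 1 and preserves planted steps", {
  s <- tiny_schedule()
  t <- 0:119
  drift <- 1 - 4e-4 * t
  step <- 0.4 * (t >= 20 & t < 40)
  x <- trace_matrix(matrix(drift + step, 120, 1))
  b <- fit_baseline(x, s, "piecewise_linear")
  corrected <- unclass(subtract_baseline(x, b))[, 1]
  expect_equal(corrected[t < 20 | (t >= 40 & t < 60) | t >= 80],
               rep(1, sum(t < 20 | (t >= 40 & t < 60) | t >= 80)),
               tolerance = 1e-9)
  expect_equal(corrected[t >= 21 & t < 39], rep(1.4, 18), tolerance = 1e-9)
})

test_that("baseline fits use only basal-frame data", {
  s <- tiny_schedule()
  set.seed(31)
  v <- matrix(1 + stats::rnorm(120 * 2, 0, 0.02), 120, 2)
  x1 <- trace_matrix(v)
  v2 <- v
  for (r in list(21:40, 61:80)) {  # permute values inside the conditions
    v2[r, ] <- v2[sample(r), ]
  }
  x2 <- trace_matrix(v2)
  for (m in baseline_methods) {
    b1 <- fit_baseline(x1, s, m)
    b2 <- fit_baseline(x2, s, m)
    expect_equal(b1$baseline, b2$baseline, tolerance = 1e-12)
  }
})

test_that("every method beats the best constant fit on basal residual SS", {
  s <- study_schedule()
  cells <- random_cells(6, study_labels, seed = 32)
  sim <- simulate_traces(cells, s, study_drift(), seed = 33)
  nrm <- normalize_to_initial(compute_ratio(sim$acceptor, sim$donor))
  regions <- basal_regions(s)
  bas <- unlist(lapply(regions, function(r) seq.int(r[1], r[2] - 1)))
  v <- unclass(nrm)[bas + 1, , drop = FALSE]
  const_rss <- colSums(sweep(v, 2, colMeans(v))^2)
  # methods anchored on all basal regions beat the best constant everywhere
  for (m in c("spline", "polynomial", "piecewise_linear",
              "piecewise_square")) {
    b <- fit_baseline(nrm, s, m)
    expect_true(all(b$diagnostics$basal_rss <= const_rss + 1e-10),
                label = m)
  }
  # endpoint-anchored methods beat the constant on the regions they use
  ends <- regions[c(1, length(regions))]
  fr_end <- unlist(lapply(ends, function(r) seq.int(r[1], r[2] - 1)))
  v_end <- unclass(nrm)[fr_end + 1, , drop = FALSE]
  const_end <- colSums(sweep(v_end, 2, colMeans(v_end))^2)
  for (m in c("linear", "exponential")) {
    b <- fit_baseline(nrm, s, m)
    rss_end <- colSums((v_end - b$baseline[fr_end + 1, , drop = FALSE])^2)
    expect_true(all(rss_end <= const_end + 1e-10), label = m)
  }
})

test_that("correction shrinks basal deviations and preserves effect
           amplitudes", {
  s <- study_schedule()
  cells <- random_cells(10, study_labels, seed = 34)
  sim <- simulate_traces(cells, s, study_drift(), seed = 35)
  nrm <- normalize_to_initial(compute_ratio(sim$acceptor, sim$donor))
  corrected <- subtract_baseline(nrm, fit_baseline(nrm, s,
                                                   "piecewise_linear"))
  bas <- unlist(lapply(basal_regions(s), function(r) seq.int(r[1], r[2] - 1)))
  dev_before <- mean(abs(unclass(nrm)[bas + 1, ] - 1))
  dev_after <- mean(abs(unclass(corrected)[bas + 1, ] - 1))
  expect_lt(dev_after, dev_before)

  # planted steps survive within fit error
  eff <- quantify_effects(corrected, s, "two_region")
  truth <- sim$truth[colnames(corrected), ]
  expect_lt(max(abs(unclass(eff) - truth)), 0.2)
})

test_that("SNR matches its construction and handles degenerate noise", {
  s <- tiny_schedule()
  set.seed(36)
  n_cells <- 40
  t <- 0:119
  v <- matrix(1 + stats::rnorm(120 * n_cells, 0, 0.05), 120, n_cells)
  v[t >= 20 & t < 40, ] <- v[t >= 20 & t < 40, ] + 0.5
  x <- trace_matrix(v)
  r <- compute_snr(x, s, "A")
  expect_equal(r$n, n_cells)
  expect_lt(abs(r$mean - 10), 1)

  # noiseless step: zero basal variance, cells excluded with a warning
  v0 <- matrix(1, 120, 3)
  v0[t >= 20 & t < 40, ] <- 1.5
  expect_warning(r0 <- compute_snr(trace_matrix(v0), s, "A"),
                 "zero basal variance")
  expect_equal(r0$n, 0L)
  expect_equal(r0$n_excluded, 3L)

  expect_error(compute_snr(x, s, "missing"), "not in schedule")
})

test_that("SNR improves from raw to normalized to corrected", {
  s <- study_schedule()
  cells <- random_cells(40, study_labels, seed = 37)
  sim <- simulate_traces(cells, s, study_drift(), seed = 38)
  r <- compute_ratio(sim$acceptor, sim$donor)
  nrm <- normalize_to_initial(r)
  corrected <- subtract_baseline(nrm, fit_baseline(nrm, s,
                                                   "piecewise_linear"))
  tab <- snr_table(list(raw = r, normalized = nrm, corrected = corrected),
                   s, "forskolin+IBMX")
  expect_equal(tab$procedure, c("raw", "normalized", "corrected"))
  expect_true(all(diff(tab$snr_mean) > 0))
})
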