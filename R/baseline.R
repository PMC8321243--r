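#' Fit per-cell baseline drift models
#'
#' Estimates one slow-drift baseline trace per cell from the basal
#' (agent-free) frames of a normalized trace matrix.  Every return to basal
#' conditions is assumed to restore the initial analyte level, so only
#' basal-region data enter the fits.
#'
#' Methods:
#' \describe{
#'   \item{`linear`}{least-squares line through the data of the first and
#'     last basal regions.}
#'   \item{`exponential`}{`a * exp(b * t) + c` (Levenberg-Marquardt) through
#'     the same data; cells whose fit fails fall back to `linear` and are
#'     flagged.}
#'   \item{`spline`}{natural cubic spline interpolating the per-region means
#'     of all basal regions (option `spline_all_points = TRUE` uses a
#'     smoothing spline through every basal point instead).}
#'   \item{`polynomial`}{least-squares polynomial over all basal data with
#'     degree equal to the number of basal regions minus one.}
#'   \item{`piecewise_linear`, `piecewise_square`}{each basal region gets
#'     its own local line; each condition region gets a line / quadratic
#'     fitted to the two nearest (preceding and succeeding) basal regions;
#'     boundary frames are blended between the adjoining fits to keep the
#'     baseline continuous.}
#' }
#'
#' @param x a [normalize_to_initial()] result (frames x cells).
#' @param schedule a [timestamp_schedule()].
#' @param method baseline model; see Details.
#' @param spline_all_points for `method = "spline"`: smooth through all
#'   basal points rather than interpolating region means.
#' @return object of class `baseline_model`: list with `method`, `baseline`
#'   (frames x cells matrix) and `diagnostics` (per-cell residual SS on
#'   basal frames, convergence/fallback flags).
#' @export
fit_baseline <- function(x, schedule,
                         method = c("piecewise_linear", "linear",
                                    "exponential", "spline", "polynomial",
                                    "piecewise_square"),
                         spline_all_points = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(x, "trace_matrix"),
            inherits(schedule, "timestamp_schedule"))
  n <- nrow(x); m <- ncol(x)
  if (n != total_frames(schedule)) {
    stop(sprintf("matrix has %d frames but schedule covers %d", n,
                 total_frames(schedule)))
  }
  bas <- basal_regions(schedule)
  nb <- length(bas)
  need <- switch(method, linear = 2L, exponential = 2L, spline = 2L,
                 polynomial = 2L, piecewise_linear = 2L,
                 piecewise_square = 2L)
  if (nb < need) {
    stop(sprintf("method '%s' requires at least %d basal regions, found %d",
                 method, need, nb))
  }
  t_all <- seq_len(n) - 1
  basal_frames <- unlist(lapply(bas, function(r) seq.int(r[1], r[2] - 1)))
  v <- unclass(x)

  baseline <- matrix(NA_real_, n, m, dimnames = list(NULL, colnames(v)))
  converged <- rep(TRUE, m)
  fallback <- rep(FALSE, m)

  fit_one <- switch(
    method,
    linear = function(y) baseline_endpoints_linear(y, bas, t_all),
    exponential = function(y) baseline_endpoints_exponential(y, bas, t_all),
    spline = function(y) baseline_spline(y, bas, t_all, spline_all_points),
    polynomial = function(y) baseline_polynomial(y, bas, t_all, nb - 1L),
    piecewise_linear = function(y) baseline_piecewise(y, schedule, bas, t_all,
                                                      quadratic = FALSE),
    piecewise_square = function(y) baseline_piecewise(y, schedule, bas, t_all,
                                                      quadratic = TRUE)
  )
  for (j in seq_len(m)) {
    res <- fit_one(v[, j])
    baseline[, j] <- res$baseline
    converged[j] <- res$converged
    fallback[j] <- res$fallback
  }
  rss <- colSums((v[basal_frames + 1, , drop = FALSE] -
                    baseline[basal_frames + 1, , drop = FALSE])^2)
  structure(list(
    method = method,
    baseline = baseline,
    diagnostics = data.frame(cell_id = colnames(v), basal_rss = rss,
                             converged = converged, fallback = fallback,
                             row.names = NULL)
  ), class = "baseline_model")
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("Baseline model '%s': %d cells, %d frames\n", x$method,
              ncol(x$baseline), nrow(x$baseline)))
  cat(sprintf("  median basal RSS %.4g; %d fallback cell(s)\n",
              stats::median(x$diagnostics$basal_rss),
              sum(x$diagnostics$fallback)))
  invisible(x)
}

# --- per-cell fitters ------------------------------------------------------

endpoint_data <- function(y, bas, t_all) {
  regions <- bas[c(1L, length(bas))]
  fr <- unlist(lapply(regions, function(r) seq.int(r[1], r[2] - 1)))
  list(t = t_all[fr + 1], y = y[fr + 1])
}

baseline_endpoints_linear <- function(y, bas, t_all) {
  d <- endpoint_data(y, bas, t_all)
  fit <- stats::lm.fit(cbind(1, d$t), d$y)
  b <- fit$coefficients
  list(baseline = b[1] + b[2] * t_all, converged = TRUE, fallback = FALSE)
}

baseline_endpoints_exponential <- function(y, bas, t_all) {
  d <- endpoint_data(y, bas, t_all)
  m1 <- mean(y[seq.int(bas[[1]][1], bas[[1]][2] - 1) + 1])
  last <- bas[[length(bas)]]
  m2 <- mean(y[seq.int(last[1], last[2] - 1) + 1])
  t1 <- mean(seq.int(bas[[1]][1], bas[[1]][2] - 1))
  t2 <- mean(seq.int(last[1], last[2] - 1))
  b0 <- if (m1 > 0 && m2 > 0 && m1 != m2) log(m2 / m1) / (t2 - t1) else -1e-3
  a0 <- if (abs(b0) > 0) (m1 - 0) / exp(b0 * t1) else m1
  fit <- suppressWarnings(tryCatch(
    minpack.lm::nlsLM(yy ~ a * exp(b * tt) + c0,
                      data = list(yy = d$y, tt = d$t),
                      start = list(a = a0, b = b0, c0 = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200,
                                                           ftol = 1e-8)),
    error = function(e) NULL))
  if (is.null(fit) || !isTRUE(fit$convInfo$isConv)) {
    out <- baseline_endpoints_linear(y, bas, t_all)
    out$converged <- FALSE
    out$fallback <- TRUE
    return(out)
  }
  cf <- stats::coef(fit)
  list(baseline = cf[["a"]] * exp(cf[["b"]] * t_all) + cf[["c0"]],
       converged = TRUE, fallback = FALSE)
}

baseline_spline <- function(y, bas, t_all, all_points) {
  if (all_points) {
    fr <- unlist(lapply(bas, function(r) seq.int(r[1], r[2] - 1)))
    sp <- stats::smooth.spline(t_all[fr + 1], y[fr + 1])
    bl <- stats::predict(sp, t_all)$y
  } else {
    tc <- vapply(bas, function(r) mean(seq.int(r[1], r[2] - 1)), 1)
    yc <- vapply(bas, function(r) mean(y[seq.int(r[1], r[2] - 1) + 1]), 1)
    bl <- stats::spline(tc, yc, xout = t_all, method = "natural")$y
  }
  list(baseline = bl, converged = TRUE, fallback = FALSE)
}

baseline_polynomial <- function(y, bas, t_all, degree) {
  fr <- unlist(lapply(bas, function(r) seq.int(r[1], r[2] - 1)))
  tt <- t_all[fr + 1]; yy <- y[fr + 1]
  degree <- min(degree, length(unique(tt)) - 1L)
  pb <- stats::poly(tt, degree)
  fit <- stats::lm.fit(cbind(1, pb), yy)
  bl <- cbind(1, stats::predict(pb, t_all)) %*% fit$coefficients
  list(baseline = as.vector(bl), converged = TRUE, fallback = FALSE)
}

lin_eval <- function(tt, yy, at) {
  if (length(unique(tt)) < 2) return(rep(mean(yy), length(at)))
  cf <- stats::lm.fit(cbind(1, tt), yy)$coefficients
  cf[1] + cf[2] * at
}

quad_eval <- function(tt, yy, at) {
  if (length(unique(tt)) < 3) return(lin_eval(tt, yy, at))
  cf <- stats::lm.fit(cbind(1, tt, tt^2), yy)$coefficients
  cf[1] + cf[2] * at + cf[3] * at^2
}

baseline_piecewise <- function(y, schedule, bas, t_all, quadratic) {
  n <- length(y)
  bl <- rep(NA_real_, n)
  # local fit over each basal region
  for (r in bas) {
    fr <- seq.int(r[1], r[2] - 1)
    bl[fr + 1] <- lin_eval(fr, y[fr + 1], fr)
  }
  starts <- vapply(bas, `[`, 1L, 1)
  ends <- vapply(bas, `[`, 1L, 2)
  for (i in seq_len(nrow(schedule))) {
    cs <- schedule$start_frame[i]; ce <- schedule$end_frame[i]
    prev <- which(ends <= cs)
    nxt <- which(starts >= ce)
    if (length(prev) == 0 || length(nxt) == 0) {
      stop(sprintf("condition '%s' lacks a basal region on one side",
                   schedule$label[i]))
    }
    p <- bas[[max(prev)]]; s <- bas[[min(nxt)]]
    fr_anchor <- c(seq.int(p[1], p[2] - 1), seq.int(s[1], s[2] - 1))
    fr_cond <- seq.int(cs, ce - 1)
    fit_fun <- if (quadratic) quad_eval else lin_eval
    vals <- fit_fun(fr_anchor, y[fr_anchor + 1], fr_cond)
    # blend the first/last condition frame with the neighboring basal fits
    # to keep the assembled baseline continuous at region boundaries
    pb <- lin_eval(seq.int(p[1], p[2] - 1),
                   y[seq.int(p[1], p[2] - 1) + 1], fr_cond[1])
    sb <- lin_eval(seq.int(s[1], s[2] - 1),
                   y[seq.int(s[1], s[2] - 1) + 1], fr_cond[length(fr_cond)])
    vals[1] <- (vals[1] + pb) / 2
    vals[length(vals)] <- (vals[length(vals)] + sb) / 2
    bl[fr_cond + 1] <- vals
  }
  # frames that are neither basal nor condition cannot occur (partition)
  list(baseline = bl, converged = TRUE, fallback = FALSE)
}

#' Subtract a fitted baseline
#'
#' Removes the per-cell drift and re-anchors the basal level at 1, so that
#' downstream effect amplitudes read as deviations from 1.
#'
#' @param x the [normalize_to_initial()] matrix the baseline was fitted to.
#' @param b a [fit_baseline()] model.
#' @return corrected [trace_matrix()] (class `normalized_traces`).
#' @export
subtract_baseline <- function(x, b) {
  stopifnot(inherits(x, "trace_matrix"), inherits(b, "baseline_model"),
            all(dim(x) == dim(b$baseline)))
  out <- trace_matrix(unclass(x) - b$baseline + 1,
                      cell_ids = colnames(x),
                      frame_interval_s = attr(x, "frame_interval_s"),
                      channel_name = paste0(attr(x, "channel_name"),
                                            " [", b$method, "]"))
  class(out) <- c("normalized_traces", class(out))
  out
}

#' Signal-to-noise ratio of a trace matrix
#'
#' Per-cell SNR of the response to a reference condition: the absolute
#' difference between the mean over the condition's plateau frames (its last
#' half by default) and the mean over the immediately preceding basal
#' region, divided by the population noise floor — the SD of all basal-frame
#' values around their grand mean, pooled over cells.  The pooled
#' denominator makes the statistic sensitive to cell-to-cell scatter and
#' residual drift, so it rewards normalization and baseline correction.
#'
#' @param x a [trace_matrix()] (raw ratio, normalized, or corrected).
#' @param schedule a [timestamp_schedule()].
#' @param reference_condition label of the reference condition (typically
#'   the strongest positive control).
#' @param plateau_frac fraction of the condition interval, counted from its
#'   end, treated as plateau.
#' @return object of class `snr_report`: list with `per_cell`, `mean`,
#'   `sem`, `n`, `n_excluded`, `noise_sd`, `reference`.
#' @export
compute_snr <- function(x, schedule, reference_condition,
                        plateau_frac = 0.5) {
  stopifnot(inherits(x, "trace_matrix"),
            inherits(schedule, "timestamp_schedule"))
  i <- match(reference_condition, schedule$label)
  if (is.na(i)) {
    stop(sprintf("reference condition '%s' not in schedule",
                 reference_condition))
  }
  cs <- schedule$start_frame[i]; ce <- schedule$end_frame[i]
  len <- ce - cs
  plateau <- seq.int(ce - max(1L, ceiling(len * plateau_frac)), ce - 1L)
  bas <- basal_regions(schedule)
  ends <- vapply(bas, `[`, 1L, 2)
  prev <- which(ends <= cs)
  if (length(prev) == 0) stop("reference condition has no preceding basal region")
  pr <- bas[[max(prev)]]
  basal_adj <- seq.int(pr[1], pr[2] - 1L)
  basal_all <- unlist(lapply(bas, function(r) seq.int(r[1], r[2] - 1)))

  v <- unclass(x)
  pooled <- v[basal_all + 1, , drop = FALSE]
  noise_sd <- stats::sd(as.vector(pooled))
  num <- abs(colMeans(v[plateau + 1, , drop = FALSE]) -
               colMeans(v[basal_adj + 1, , drop = FALSE]))
  if (!is.finite(noise_sd) || noise_sd == 0) {
    warning("zero basal variance: SNR undefined, all cells excluded")
    per_cell <- rep(NA_real_, ncol(v))
    names(per_cell) <- colnames(v)
    return(structure(list(per_cell = per_cell, mean = NA_real_,
                          sem = NA_real_, n = 0L, n_excluded = ncol(v),
                          noise_sd = noise_sd,
                          reference = reference_condition),
                     class = "snr_report"))
  }
  per_cell <- num / noise_sd
  names(per_cell) <- colnames(v)
  structure(list(per_cell = per_cell, mean = mean(per_cell),
                 sem = stats::sd(per_cell) / sqrt(length(per_cell)),
                 n = length(per_cell), n_excluded = 0L,
                 noise_sd = noise_sd, reference = reference_condition),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("SNR vs '%s': %.3g +/- %.2g (n = %d, %d excluded)\n",
              x$reference, x$mean, x$sem, x$n, x$n_excluded))
  invisible(x)
}

#' SNR benchmark across correction procedures
#'
#' Applies [compute_snr()] to each named matrix (e.g. raw ratio, normalized,
#' and corrected variants) and tabulates mean, SEM and cell counts.
#'
#' @param matrices named list of [trace_matrix()]s.
#' @param schedule a [timestamp_schedule()].
#' @param reference_condition reference condition label.
#' @param ... passed to [compute_snr()].
#' @return data.frame with columns `procedure`, `snr_mean`, `snr_sem`, `n`.
#' @export
snr_table <- function(matrices, schedule, reference_condition, ...) {
  stopifnot(is.list(matrices), !is.null(names(matrices)))
  rows <- lapply(names(matrices), function(nm) {
    r <- compute_snr(matrices[[nm]], schedule, reference_condition, ...)
    data.frame(procedure = nm, snr_mean = r$mean, snr_sem = r$sem, n = r$n)
  })
  do.call(rbind, rows)
}
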