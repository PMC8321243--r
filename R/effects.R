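#' Build expanded quantification regions
#'
#' For each condition, the immediately preceding basal region is expanded to
#' include the first `n_post` timepoints after agent addition (20 by
#' default), so every region holds both basal and experimental data.  A
#' region is clipped at the start of the next condition.
#'
#' @param schedule a [timestamp_schedule()].
#' @param n_post number of post-addition timepoints (at least 1).
#' @return named list of `expanded_region` objects: lists with `label`,
#'   `region_start`, `region_end`, `addition_frame`, `condition_end`
#'   (half-open 0-based frame bounds).
#' @export
build_expanded_regions <- function(schedule, n_post = 20) {
  stopifnot(inherits(schedule, "timestamp_schedule"))
  if (n_post < 1) stop("n_post must be at least 1 (region needs a condition frame)")
  bas <- basal_regions(schedule)
  starts <- vapply(bas, `[`, 1L, 1)
  ends <- vapply(bas, `[`, 1L, 2)
  nfr <- total_frames(schedule)
  out <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    cs <- schedule$start_frame[i]; ce <- schedule$end_frame[i]
    ib <- which(ends == cs)
    if (length(ib) == 0) {
      stop(sprintf("condition '%s' has no immediately preceding basal region",
                   schedule$label[i]))
    }
    next_start <- if (i < nrow(schedule)) schedule$start_frame[i + 1] else nfr
    region_end <- min(cs + n_post, next_start, nfr)
    out[[i]] <- structure(list(label = schedule$label[i],
                               region_start = starts[ib],
                               region_end = region_end,
                               addition_frame = cs,
                               condition_end = min(ce, region_end)),
                          class = "expanded_region")
  }
  names(out) <- schedule$label
  out
}

#' Quantify a per-cell agent effect within an expanded region
#'
#' Amplitude definitions (sign convention: positive = increase upon agent
#' addition):
#' \describe{
#'   \item{`two_region`}{mean over condition frames minus mean over basal
#'     frames — the bona fide but slow reference.}
#'   \item{`linear`}{slope of a least-squares line over the region times the
#'     region span.}
#'   \item{`square`}{one-sided quadratic onset ramp `base + c * u^2` with
#'     `u = max(t - t0, 0)`; amplitude is the realized change
#'     `c * u_end^2`.  (A full-region quadratic evaluated end-minus-start
#'     is degenerate: the quadratic component is even about the region
#'     center and cancels, collapsing to the linear estimate.)}
#'   \item{`end_start`}{last minus first value after moving-average
#'     smoothing (`smooth_window` frames).}
#'   \item{`sigmoid`}{amplitude `A` of `base + A / (1 + exp(-(t - t_half) /
#'     tau))` (Levenberg-Marquardt).}
#'   \item{`hill`}{fit of `base + A * u^h / (k^h + u^h)` with
#'     `u = max(t - t0, 0)`, `t0` fixed at the addition frame.  The
#'     reported amplitude is the fitted curve's realized change at the
#'     region end, `A * u_end^h / (k^h + u_end^h)`: the asymptote `A`
#'     itself is weakly identified whenever the half-saturation `k`
#'     approaches the window end.}
#' }
#' Cells whose transcendental fit fails fall back to the linear estimate
#' and are flagged as non-converged.
#'
#' @param x corrected [trace_matrix()].
#' @param region one element of [build_expanded_regions()].
#' @param method amplitude estimator; see Details.
#' @param smooth_window moving-average window of the `end_start` method.
#' @return data.frame with columns `cell_id`, `amplitude`, `converged`,
#'   `method_used`.
#' @export
quantify_effect <- function(x, region,
                            method = c("two_region", "linear", "square",
                                       "end_start", "sigmoid", "hill"),
                            smooth_window = 3) {
  method <- match.arg(method)
  stopifnot(inherits(x, "trace_matrix"), inherits(region, "expanded_region"))
  n <- nrow(x)
  if (region$region_end > n) stop("region exceeds the trace matrix")
  fr <- seq.int(region$region_start, region$region_end - 1L)
  if (method %in% c("sigmoid", "hill") && length(fr) < 4) {
    stop("transcendental fits need at least 4 points in the region")
  }
  basal_fr <- fr[fr < region$addition_frame]
  cond_fr <- fr[fr >= region$addition_frame & fr < region$condition_end]
  if (length(basal_fr) == 0 || length(cond_fr) == 0) {
    stop("expanded region must contain basal and condition frames")
  }
  v <- unclass(x)[fr + 1, , drop = FALSE]
  tt <- as.numeric(fr)
  m <- ncol(v)
  amp <- numeric(m); conv <- rep(TRUE, m); used <- rep(method, m)

  two_region_est <- colMeans(v[match(cond_fr, fr), , drop = FALSE]) -
    colMeans(v[match(basal_fr, fr), , drop = FALSE])
  span <- tt[length(tt)] - tt[1]

  linear_est <- function(y) {
    cf <- stats::lm.fit(cbind(1, tt), y)$coefficients
    cf[2] * span
  }

  for (j in seq_len(m)) {
    y <- v[, j]
    amp[j] <- switch(
      method,
      two_region = two_region_est[j],
      linear = linear_est(y),
      square = {
        u <- pmax(tt - (region$addition_frame - 1), 0)
        cf <- stats::lm.fit(cbind(1, u^2), y)$coefficients
        cf[2] * u[length(u)]^2
      },
      end_start = {
        w <- min(smooth_window, length(y))
        mean(y[(length(y) - w + 1):length(y)]) - mean(y[1:w])
      },
      sigmoid = {
        a0 <- unname(two_region_est[j])
        if (a0 == 0) a0 <- 1e-3
        base0 <- mean(y[seq_along(basal_fr)])
        fit <- suppressWarnings(tryCatch(
          minpack.lm::nlsLM(
            yy ~ base + A / (1 + exp(-(ti - th) / tau)),
            data = list(yy = y, ti = tt),
            start = list(base = base0, A = max(min(a0, 5), -5),
                         th = region$addition_frame + 5, tau = 3),
            lower = c(base = -Inf, A = -5, th = tt[1], tau = 0.3),
            upper = c(base = Inf, A = 5, th = tt[length(tt)],
                      tau = length(tt)),
            control = minpack.lm::nls.lm.control(maxiter = 500)),
          error = function(e) NULL))
        if (is.null(fit) || !isTRUE(fit$convInfo$isConv)) {
          conv[j] <- FALSE; used[j] <- "linear"
          linear_est(y)
        } else stats::coef(fit)[["A"]]
      },
      hill = {
        a0 <- unname(two_region_est[j])
        if (a0 == 0) a0 <- 1e-3
        base0 <- mean(y[seq_along(basal_fr)])
        u <- pmax(tt - (region$addition_frame - 0.5), 0)
        fit <- suppressWarnings(tryCatch(
          minpack.lm::nlsLM(
            yy ~ base + A * uu^h / (k^h + uu^h),
            data = list(yy = y, uu = u),
            start = list(base = base0, A = max(min(a0, 5), -5), k = 5,
                         h = 2),
            lower = c(base = -Inf, A = -5, k = 0.5, h = 0.5),
            upper = c(base = Inf, A = 5, k = 2 * max(u), h = 10),
            control = minpack.lm::nls.lm.control(maxiter = 500)),
          error = function(e) NULL))
        if (is.null(fit) || !isTRUE(fit$convInfo$isConv)) {
          conv[j] <- FALSE; used[j] <- "linear"
          linear_est(y)
        } else {
          cf <- stats::coef(fit)
          ue <- max(u)
          cf[["A"]] * ue^cf[["h"]] / (cf[["k"]]^cf[["h"]] + ue^cf[["h"]])
        }
      }
    )
  }
  data.frame(cell_id = colnames(v), amplitude = unname(amp),
             converged = conv, method_used = used, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-cell effect table over all conditions
#'
#' Applies [quantify_effect()] to every condition's expanded region and
#' assembles a cells x conditions amplitude matrix.
#'
#' @param x corrected [trace_matrix()].
#' @param schedule a [timestamp_schedule()].
#' @param method amplitude estimator (the stable `linear` fit is the
#'   routine default; transcendental fits are more precise but can fail to
#'   converge on a few percent of cells).
#' @param n_post post-addition timepoints per region.
#' @param smooth_window see [quantify_effect()].
#' @return matrix of class `effect_table` (cells x conditions) with
#'   attributes `converged` (logical matrix), `method_used` (character
#'   matrix) and `method`.
#' @export
quantify_effects <- function(x, schedule, method = "linear", n_post = 20,
                             smooth_window = 3) {
  regions <- build_expanded_regions(schedule, n_post)
  cells <- colnames(x)
  eff <- matrix(NA_real_, length(cells), length(regions),
                dimnames = list(cells, names(regions)))
  conv <- matrix(TRUE, length(cells), length(regions),
                 dimnames = dimnames(eff))
  used <- matrix(method, length(cells), length(regions),
                 dimnames = dimnames(eff))
  for (k in seq_along(regions)) {
    q <- quantify_effect(x, regions[[k]], method, smooth_window)
    eff[, k] <- q$amplitude
    conv[, k] <- q$converged
    used[, k] <- q$method_used
  }
  effect_table(eff, converged = conv, method_used = used, method = method)
}

#' Construct an effect table
#'
#' @param values cells x conditions numeric matrix (row names = cell ids,
#'   column names = condition labels).
#' @param converged logical matrix of the same shape (default all TRUE).
#' @param method_used character matrix of per-entry estimators.
#' @param method the nominal estimator.
#' @return matrix of class `effect_table`.
#' @export
effect_table <- function(values, converged = NULL, method_used = NULL,
                         method = "unknown") {
  values <- as.matrix(values)
  if (is.null(converged)) {
    converged <- matrix(TRUE, nrow(values), ncol(values),
                        dimnames = dimnames(values))
  }
  if (is.null(method_used)) {
    method_used <- matrix(method, nrow(values), ncol(values),
                          dimnames = dimnames(values))
  }
  if (any(!is.finite(values) & converged)) {
    stop("non-finite amplitudes must be flagged as non-converged")
  }
  structure(values, converged = converged, method_used = method_used,
            method = method, class = c("effect_table", "matrix", "array"))
}

#' @export
print.effect_table <- function(x, ...) {
  cat(sprintf("Effect table [%s]: %d cells x %d conditions, %d flagged\n",
              attr(x, "method"), nrow(x), ncol(x),
              sum(!attr(x, "converged"))))
  inner <- x
  attributes(inner) <- list(dim = dim(x), dimnames = dimnames(x))
  print(utils::head(inner, 5L))
  if (nrow(x) > 5L) cat(sprintf("... %d more cells\n", nrow(x) - 5L))
  invisible(x)
}

#' Write an effect table (and diagnostics) as CSV
#' @param effects an [effect_table()].
#' @param path amplitudes CSV path.
#' @param diagnostics_path optional CSV of per-entry convergence flags.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(effects, path, diagnostics_path = NULL) {
  df <- data.frame(cell_id = rownames(effects),
                   as.data.frame(unclass(effects)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(diagnostics_path)) {
    conv <- attr(effects, "converged")
    used <- attr(effects, "method_used")
    rows <- expand.grid(cell_id = rownames(effects),
                        condition = colnames(effects),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows$converged <- as.vector(conv)
    rows$method_used <- as.vector(used)
    utils::write.csv(rows, diagnostics_path, row.names = FALSE)
  }
  invisible(path)
}

#' RMS deviation of amplitude estimators from the two-region reference
#'
#' Benchmarks single-region estimators against the two-region reference:
#' for every method, the root-mean-square difference of amplitudes over all
#' (cell, condition) pairs where both the method and the reference
#' converged; flagged pairs are excluded pairwise and counted.
#'
#' @param x corrected [trace_matrix()].
#' @param schedule a [timestamp_schedule()].
#' @param methods estimators to benchmark.
#' @param reference reference estimator (two-region by default).
#' @param n_post,smooth_window see [quantify_effects()].
#' @return data.frame with columns `method`, `rms`, `n_pairs`,
#'   `n_excluded`.
#' @export
compare_methods_rms <- function(x, schedule,
                                methods = c("linear", "square", "end_start",
                                            "sigmoid", "hill"),
                                reference = "two_region", n_post = 20,
                                smooth_window = 3) {
  ref <- quantify_effects(x, schedule, reference, n_post, smooth_window)
  ref_ok <- attr(ref, "converged")
  rows <- lapply(methods, function(mth) {
    est <- quantify_effects(x, schedule, mth, n_post, smooth_window)
    ok <- ref_ok & attr(est, "converged")
    if (!any(ok)) stop(sprintf("no converged pairs for method '%s'", mth))
    d <- (unclass(est) - unclass(ref))[ok]
    data.frame(method = mth, rms = sqrt(mean(d^2)), n_pairs = sum(ok),
               n_excluded = sum(!ok))
  })
  do.call(rbind, rows)
}
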