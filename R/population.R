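#' Variance-based sorting statistic
#'
#' For each cell, a window of `n_before + n_after` timepoints around the
#' agent-addition frame is selected and the statistic
#' `S = sign(mean - 1) * SD` computed over it: an agent that moves the
#' signal away from the basal level 1 both shifts the window mean and
#' inflates its SD, so ranking by `S` sorts responders by signed response
#' strength.
#'
#' @param x corrected [trace_matrix()] (basal level 1).
#' @param schedule a [timestamp_schedule()].
#' @param condition label of the condition to sort by.
#' @param n_before,n_after window frames before/after the addition.
#' @return named numeric vector of class `sorting_statistic` with
#'   attributes `condition` and `window` (`c(start, end)`).
#' @export
sorting_statistic <- function(x, schedule, condition, n_before = 10,
                              n_after = 10) {
  stopifnot(inherits(x, "trace_matrix"),
            inherits(schedule, "timestamp_schedule"))
  i <- match(condition, schedule$label)
  if (is.na(i)) stop(sprintf("condition '%s' not in schedule", condition))
  s <- schedule$start_frame[i]
  w0 <- s - n_before; w1 <- s + n_after
  if (w0 < 0 || w1 > nrow(x)) {
    stop(sprintf("window [%d, %d) out of bounds for %d frames", w0, w1,
                 nrow(x)))
  }
  v <- unclass(x)[(w0 + 1):w1, , drop = FALSE]
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  out <- sign(mu - 1) * sdv
  names(out) <- colnames(x)
  attr(out, "condition") <- condition
  attr(out, "window") <- c(w0, w1)
  class(out) <- "sorting_statistic"
  out
}

#' Rank cells by a sorting statistic
#'
#' @param x a [trace_matrix()] or [effect_table()] whose cells are to be
#'   permuted.
#' @param stat a [sorting_statistic()] covering the same cells.
#' @return integer permutation placing cells in descending `S` order
#'   (stable for ties); apply it to trace-matrix columns or effect-table
#'   rows.
#' @export
rank_cells <- function(x, stat) {
  ids <- if (inherits(x, "effect_table")) rownames(x) else colnames(x)
  if (!all(ids %in% names(stat))) {
    stop("sorting statistic does not cover all cells")
  }
  s <- unclass(stat)[ids]
  order(-s)  # radix order: stable for ties
}

#' Split the population by a marker-compound response
#'
#' Classifies cells by the sign of their response to a marker compound
#' (e.g. adrenaline, which raises cAMP in alpha-cells and lowers it in
#' beta-cells): marker amplitude above `threshold` is `alpha_like`,
#' otherwise `beta_like`.
#'
#' @param effects an [effect_table()].
#' @param marker marker condition label.
#' @param threshold classification threshold on the amplitude.
#' @return factor of class `population_split` (levels `alpha_like`,
#'   `beta_like`) named by cell, with attributes `marker` and `threshold`.
#' @export
split_population <- function(effects, marker, threshold = 0) {
  stopifnot(inherits(effects, "effect_table"))
  if (!marker %in% colnames(effects)) {
    stop(sprintf("marker condition '%s' not in the effect table", marker))
  }
  cls <- ifelse(unclass(effects)[, marker] > threshold, "alpha_like",
                "beta_like")
  out <- factor(cls, levels = c("alpha_like", "beta_like"))
  names(out) <- rownames(effects)
  attr(out, "marker") <- marker
  attr(out, "threshold") <- threshold
  class(out) <- c("population_split", "factor")
  out
}

#' Per-class correlations between condition effects
#'
#' Pearson correlation (with two-sided p-value and least-squares line) of
#' per-cell amplitudes between pairs of conditions, computed separately in
#' each population class.
#'
#' @param effects an [effect_table()].
#' @param split a [split_population()] factor (or any factor over the
#'   cells).
#' @param pairs list of length-2 character vectors of condition labels.
#' @param adjust apply Benjamini-Hochberg correction across all rows.
#' @return data.frame with columns `class`, `condition_x`, `condition_y`,
#'   `n`, `r`, `p`, `slope`, `intercept`.  Zero-variance pairs report `NA`
#'   correlations.
#' @export
effect_correlations <- function(effects, split, pairs, adjust = FALSE) {
  stopifnot(inherits(effects, "effect_table"), is.factor(split))
  if (is.character(pairs[[1]]) && !is.list(pairs)) pairs <- list(pairs)
  rows <- list()
  for (cl in levels(split)) {
    cells <- names(split)[split == cl & !is.na(split)]
    cells <- intersect(cells, rownames(effects))
    for (pr in pairs) {
      stopifnot(length(pr) == 2)
      if (!all(pr %in% colnames(effects))) {
        stop(sprintf("pair (%s, %s) not in the effect table", pr[1], pr[2]))
      }
      xv <- unclass(effects)[cells, pr[1]]
      yv <- unclass(effects)[cells, pr[2]]
      n <- length(cells)
      if (n < 3) {
        stop(sprintf("class '%s' has fewer than 3 cells", cl))
      }
      if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          class = cl, condition_x = pr[1], condition_y = pr[2], n = n,
          r = NA_real_, p = NA_real_, slope = NA_real_,
          intercept = NA_real_)
        next
      }
      ct <- stats::cor.test(xv, yv, method = "pearson")
      cf <- stats::lm.fit(cbind(1, xv), yv)$coefficients
      rows[[length(rows) + 1]] <- data.frame(
        class = cl, condition_x = pr[1], condition_y = pr[2], n = n,
        r = unname(ct$estimate), p = ct$p.value, slope = unname(cf[2]),
        intercept = unname(cf[1]))
    }
  }
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
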