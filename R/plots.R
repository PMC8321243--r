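#' Heat map of a trace matrix
#'
#' Cells-by-time color map of a (corrected) trace matrix, optionally sorted
#' by a sorting statistic, with condition intervals marked along the time
#' axis.
#'
#' @param x a [trace_matrix()].
#' @param schedule optional [timestamp_schedule()] to annotate conditions.
#' @param order optional cell permutation (e.g. from [rank_cells()]).
#' @param zlim color range; defaults to symmetric around 1 at the 99th
#'   percentile of |x - 1|.
#' @param main plot title.
#' @return invisibly, the plotted matrix.
#' @export
plot_trace_heatmap <- function(x, schedule = NULL, order = NULL,
                               zlim = NULL, main = "") {
  stopifnot(inherits(x, "trace_matrix"))
  v <- unclass(x)
  if (!is.null(order)) v <- v[, order, drop = FALSE]
  if (is.null(zlim)) {
    r <- stats::quantile(abs(v - 1), 0.99)
    zlim <- c(1 - r, 1 + r)
  }
  vc <- pmin(pmax(v, zlim[1]), zlim[2])
  pal <- grDevices::hcl.colors(64, "RdYlBu", rev = TRUE)
  graphics::image(x = seq_len(nrow(v)), y = seq_len(ncol(v)), z = vc,
                  zlim = zlim, col = pal, xlab = "frame", ylab = "cell",
                  main = main, useRaster = TRUE)
  if (!is.null(schedule)) {
    graphics::abline(v = schedule$start_frame + 1, col = "grey30",
                     lty = 3)
    graphics::mtext(schedule$label, side = 3, cex = 0.5, las = 2,
                    at = (schedule$start_frame + schedule$end_frame) / 2)
  }
  invisible(vc)
}

#' Scatter plot of effects for a condition pair
#'
#' Per-cell amplitudes of one condition against another, colored by
#' population class, with per-class least-squares lines and Pearson r in
#' the legend.
#'
#' @param effects an [effect_table()].
#' @param pair length-2 character vector of condition labels.
#' @param split optional [split_population()] factor.
#' @return invisibly, the correlation table used for the annotation.
#' @export
plot_effect_scatter <- function(effects, pair, split = NULL) {
  stopifnot(inherits(effects, "effect_table"), length(pair) == 2)
  xv <- unclass(effects)[, pair[1]]
  yv <- unclass(effects)[, pair[2]]
  if (is.null(split)) {
    split <- factor(rep("all", nrow(effects)))
    names(split) <- rownames(effects)
  }
  cols <- c("#4477AA", "#CC6677", "#228833", "#AA3377")
  cls <- levels(split)
  graphics::plot(xv, yv, pch = 16, cex = 0.5,
                 col = cols[as.integer(split)],
                 xlab = pair[1], ylab = pair[2])
  leg <- character(0)
  stats_rows <- list()
  for (i in seq_along(cls)) {
    cells <- names(split)[split == cls[i]]
    xs <- xv[cells]; ys <- yv[cells]
    if (length(cells) >= 3 && stats::sd(xs) > 0 && stats::sd(ys) > 0) {
      cf <- stats::lm.fit(cbind(1, xs), ys)$coefficients
      graphics::abline(cf[1], cf[2], col = cols[i])
      r <- stats::cor(xs, ys)
      leg <- c(leg, sprintf("%s: r = %.2f (n = %d)", cls[i], r,
                            length(cells)))
      stats_rows[[i]] <- data.frame(class = cls[i], r = r,
                                    n = length(cells))
    }
  }
  if (length(leg)) {
    graphics::legend("topleft", legend = leg, text.col = cols, bty = "n",
                     cex = 0.8)
  }
  invisible(do.call(rbind, stats_rows))
}

#' @export
plot.cluster_profile <- function(x, ...) {
  graphics::plot(x$wss$k, x$wss$within_ss, type = "b", pch = 16,
                 xlab = "number of clusters k",
                 ylab = "total within-cluster SS", ...)
  graphics::abline(v = x$k, col = "red3", lty = 2)
  invisible(x)
}

#' @export
plot.profile_dendrogram <- function(x, ...) {
  axis_lab <- attr(x, "axis")
  y <- x
  class(y) <- "hclust"
  graphics::plot(y, xlab = axis_lab, sub = "", ...)
  invisible(x)
}
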