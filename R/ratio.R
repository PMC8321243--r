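#' Acceptor/donor ratio matrix
#'
#' Element-wise ratio of the acceptor (YFP) to the donor (CFP) trace
#' matrices.  Computing the ratio per ROI rather than per pixel suppresses
#' noise from small channel misalignments.
#'
#' @param acceptor,donor [trace_matrix()]s of identical shape and cell ids.
#' @return a [trace_matrix()] with channel `"ratio"`.
#' @export
compute_ratio <- function(acceptor, donor) {
  stopifnot(inherits(acceptor, "trace_matrix"), inherits(donor, "trace_matrix"))
  if (!all(dim(acceptor) == dim(donor))) {
    stop("acceptor and donor matrices have different shapes")
  }
  if (!identical(colnames(acceptor), colnames(donor))) {
    stop("acceptor and donor matrices have different cell ids")
  }
  bad <- which(unclass(donor) <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-positive donor intensity at frame %d, cell '%s'",
                 bad[1, 1], colnames(donor)[bad[1, 2]]))
  }
  trace_matrix(unclass(acceptor) / unclass(donor),
               cell_ids = colnames(acceptor),
               frame_interval_s = attr(acceptor, "frame_interval_s"),
               channel_name = "ratio")
}

#' Normalize each cell's ratio to its initial value
#'
#' Divides every column by R0, the mean of its first `n_initial` timepoints
#' (five by default), removing the per-cell variation caused by differing
#' sensor expression.  Cells whose initial mean is not positive cannot be
#' normalized; they are dropped with a warning.
#'
#' @param r a ratio [trace_matrix()].
#' @param n_initial number of initial timepoints averaged into R0.
#' @return a [trace_matrix()] of class `normalized_traces` with attribute
#'   `r0` (named per-cell initial ratios) and `dropped_cells`.
#' @export
normalize_to_initial <- function(r, n_initial = 5) {
  stopifnot(inherits(r, "trace_matrix"), n_initial >= 1,
            nrow(r) >= n_initial)
  v <- unclass(r)
  r0 <- colMeans(v[seq_len(n_initial), , drop = FALSE])
  bad <- !is.finite(r0) | r0 <= 0
  if (any(bad)) {
    warning(sprintf("dropping %d cell(s) with non-positive initial ratio: %s",
                    sum(bad), paste(colnames(v)[bad], collapse = ", ")))
  }
  keep <- which(!bad)
  out <- sweep(v[, keep, drop = FALSE], 2, r0[keep], "/")
  out <- trace_matrix(out, cell_ids = colnames(v)[keep],
                      frame_interval_s = attr(r, "frame_interval_s"),
                      channel_name = "R/R0")
  attr(out, "r0") <- r0[keep]
  attr(out, "dropped_cells") <- colnames(v)[bad]
  class(out) <- c("normalized_traces", class(out))
  out
}
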