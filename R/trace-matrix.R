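#' Intensity-versus-time trace matrix
#'
#' The central container of the pipeline: an `n` timepoints by `m` cells
#' matrix of per-ROI mean intensities (or derived ratios).  Rows are frames,
#' columns are cells.
#'
#' @param values numeric matrix, frames in rows, cells in columns.
#' @param cell_ids identifiers aligned to columns; defaults to existing
#'   column names or `cell_1 ... cell_m`.
#' @param frame_interval_s frame interval in seconds (metadata).
#' @param channel_name channel label, e.g. `"YFP"`, `"CFP"`, `"ratio"`.
#' @return a numeric matrix of class `trace_matrix` with `cell_ids` as
#'   column names and metadata attributes.
#' @export
trace_matrix <- function(values, cell_ids = NULL, frame_interval_s = NA_real_,
                         channel_name = "unknown") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("trace matrix entries must be finite")
  if (is.null(cell_ids)) {
    cell_ids <- colnames(values)
    if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(ncol(values)))
  }
  stopifnot(length(cell_ids) == ncol(values))
  colnames(values) <- as.character(cell_ids)
  rownames(values) <- NULL
  attr(values, "frame_interval_s") <- frame_interval_s
  attr(values, "channel_name") <- channel_name
  class(values) <- c("trace_matrix", "matrix", "array")
  values
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("Trace matrix [%s]: %d frames x %d cells\n",
              attr(x, "channel_name"), nrow(x), ncol(x)))
  inner <- x
  attributes(inner) <- list(dim = dim(x), dimnames = dimnames(x))
  print(utils::head(inner, 4L))
  if (nrow(x) > 4L) cat(sprintf("... %d more frames\n", nrow(x) - 4L))
  invisible(x)
}

#' @export
`[.trace_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "frame_interval_s") <- attr(x, "frame_interval_s")
    attr(out, "channel_name") <- attr(x, "channel_name")
    class(out) <- class(x)
  }
  out
}

#' Write a trace matrix as CSV
#'
#' Writes a one-row header of cell ids and a first column `time_s` of frame
#' timestamps in seconds (frame index when the interval is unknown).
#'
#' @param x a [trace_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(x, path) {
  stopifnot(inherits(x, "trace_matrix"))
  fi <- attr(x, "frame_interval_s")
  if (is.na(fi)) fi <- 1
  df <- data.frame(time_s = (seq_len(nrow(x)) - 1) * fi, unclass(x)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trace matrix from CSV
#'
#' Expects the format written by [write_traces()]: a `time_s` first column
#' and one column per cell.
#'
#' @param path CSV path.
#' @param channel_name channel label to attach.
#' @return a [trace_matrix()].
#' @export
read_traces <- function(path, channel_name = "unknown") {
  if (!file.exists(path)) stop(sprintf("trace file not found: '%s'", path))
  df <- utils::read.csv(path, check.names = FALSE)
  tcol <- which(names(df) == "time_s")
  fi <- NA_real_
  if (length(tcol) == 1L) {
    tv <- df[[tcol]]
    if (nrow(df) > 1L) fi <- tv[2L] - tv[1L]
    df <- df[, -tcol, drop = FALSE]
  }
  trace_matrix(as.matrix(df), cell_ids = names(df),
               frame_interval_s = fi, channel_name = channel_name)
}
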