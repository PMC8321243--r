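#' Time-lapse image stack
#'
#' A 3D array of nonnegative intensities indexed `(x, y, t)` with physical
#' calibration metadata.
#'
#' @param voxels 3D numeric array `(x, y, t)`.
#' @param pixel_size_um physical pixel size in micrometers.
#' @param frame_interval_s frame interval in seconds.
#' @param channel_name channel label.
#' @return list of class `time_lapse_stack`.
#' @export
time_lapse_stack <- function(voxels, pixel_size_um, frame_interval_s = NA_real_,
                             channel_name = "unknown") {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3,
            dim(voxels)[3] >= 1, pixel_size_um > 0)
  if (!all(is.finite(voxels))) stop("stack intensities must be finite")
  structure(list(voxels = voxels, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 channel_name = channel_name),
            class = "time_lapse_stack")
}

#' @export
print.time_lapse_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Time-lapse stack [%s]: %d x %d px, %d frames, %.3g um/px\n",
              x$channel_name, d[1], d[2], d[3], x$pixel_size_um))
  invisible(x)
}

#' Read a multi-frame TIFF as a time-lapse stack
#'
#' @param path TIFF file path (one channel per file; frames along the page
#'   axis).
#' @param pixel_size_um physical pixel size (not all TIFFs carry it).
#' @param frame_interval_s frame interval in seconds.
#' @param channel_name channel label.
#' @param full_scale intensity corresponding to the TIFF's full scale;
#'   stored values in `[0, 1]` are multiplied by it (use the `full_scale`
#'   given to [write_stack()] to recover the original intensities).
#' @return a [time_lapse_stack()].
#' @export
read_stack <- function(path, pixel_size_um, frame_interval_s = NA_real_,
                       channel_name = "unknown", full_scale = 1) {
  if (!file.exists(path)) stop(sprintf("TIFF file not found: '%s'", path))
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(frames)) frames <- list(frames)
  d <- dim(frames[[1]])
  voxels <- array(0, c(d[1], d[2], length(frames)))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (length(dim(f)) == 3) f <- f[, , 1]  # collapse any sample axis
    voxels[, , i] <- f * full_scale
  }
  time_lapse_stack(voxels, pixel_size_um, frame_interval_s, channel_name)
}

#' Write a time-lapse stack as a multi-frame 16-bit TIFF
#'
#' Intensities are stored camera-style as 16-bit fractions of `full_scale`;
#' negative values (noise excursions) are clipped at zero.
#'
#' @param stack a [time_lapse_stack()].
#' @param path output path.
#' @param full_scale intensity mapped to the TIFF's full scale (defaults to
#'   the stack maximum).
#' @return `full_scale`, invisibly (pass it to [read_stack()]).
#' @export
write_stack <- function(stack, path, full_scale = max(stack$voxels)) {
  stopifnot(inherits(stack, "time_lapse_stack"), full_scale > 0)
  n <- dim(stack$voxels)[3]
  frames <- lapply(seq_len(n), function(i) {
    pmin(pmax(stack$voxels[, , i] / full_scale, 0), 1)
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(full_scale)
}
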