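#' Average intensity projection
#'
#' Collapses a time-lapse stack to a single pattern image by averaging each
#' pixel over all frames; the projection of the brighter acceptor channel is
#' the standard input for ROI detection.
#'
#' @param stack a [time_lapse_stack()].
#' @return numeric matrix of class `projection_image` with attribute
#'   `pixel_size_um`.
#' @export
average_projection <- function(stack) {
  stopifnot(inherits(stack, "time_lapse_stack"))
  d <- dim(stack$voxels)
  if (d[3] < 1) stop("empty stack")
  p <- rowMeans(stack$voxels, dims = 2)
  attr(p, "pixel_size_um") <- stack$pixel_size_um
  class(p) <- c("projection_image", "matrix", "array")
  p
}

# offsets of the 8-neighborhood in (dx, dy)
.neigh8 <- cbind(dx = c(-1, -1, -1, 0, 0, 1, 1, 1),
                 dy = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Detect ROIs by local maxima and flood fill
#'
#' Cells are detected on a projection image by (i) finding local intensity
#' maxima standing at least `prominence` above the image floor, and (ii)
#' flood-filling 8-connected pixels around each maximum down to
#' `seed value - tolerance`.  Maxima falling inside an already-claimed
#' region are merged into it (claims are resolved to the higher maximum,
#' which is processed first).  Filled regions whose equivalent circular
#' diameter exceeds `max_linear_size_um` are excluded as artefacts
#' (default 30 um).
#'
#' @param projection a [average_projection()] output (or plain matrix).
#' @param prominence minimum intensity elevation of a maximum above the
#'   image minimum.
#' @param tolerance flood-fill threshold: a pixel joins an ROI if its value
#'   is at least `seed - tolerance` and it is 8-connected to the seed.
#' @param max_linear_size_um size-exclusion threshold in micrometers.
#' @param pixel_size_um pixel size; taken from the projection attribute when
#'   absent.
#' @return data.frame of class `roi_set` with columns `id`, `centroid_x`,
#'   `centroid_y`, `area_px`, `size_um`, `peak`; attribute `pixels` holds
#'   the per-ROI linear pixel indices.
#' @export
detect_rois <- function(projection, prominence, tolerance,
                        max_linear_size_um = 30, pixel_size_um = NULL) {
  stopifnot(prominence > 0, tolerance > 0)
  if (is.null(pixel_size_um)) pixel_size_um <- attr(projection, "pixel_size_um")
  if (is.null(pixel_size_um)) stop("pixel_size_um is required")
  p <- unclass(projection)
  attr(p, "pixel_size_um") <- NULL
  if (!all(is.finite(p))) stop("projection must be finite")
  nx <- nrow(p); ny <- ncol(p)

  # strict 8-neighborhood local maxima (interior pixels only)
  if (nx < 3 || ny < 3) {
    maxima <- integer(0)
  } else {
    core <- p[2:(nx - 1), 2:(ny - 1)]
    is_max <- matrix(TRUE, nx - 2, ny - 2)
    is_strict <- matrix(FALSE, nx - 2, ny - 2)
    for (k in seq_len(nrow(.neigh8))) {
      dx <- .neigh8[k, 1]; dy <- .neigh8[k, 2]
      nbr <- p[(2 + dx):(nx - 1 + dx), (2 + dy):(ny - 1 + dy)]
      is_max <- is_max & (core >= nbr)
      is_strict <- is_strict | (core > nbr)
    }
    # plateau maxima (ties) are kept and merged during flood fill;
    # fully flat pixels are not maxima
    is_max <- is_max & is_strict
    floor_val <- min(p)
    is_max <- is_max & (core >= floor_val + prominence)
    idx <- which(is_max)
    ix <- ((idx - 1) %% (nx - 2)) + 2
    iy <- ((idx - 1) %/% (nx - 2)) + 2
    maxima <- (iy - 1) * nx + ix  # linear indices into p
  }

  claimed <- matrix(0L, nx, ny)
  rois <- list()
  if (length(maxima) > 0) {
    ord <- order(p[maxima], decreasing = TRUE)
    maxima <- maxima[ord]
    next_id <- 0L
    for (seed in maxima) {
      if (claimed[seed] != 0L) next  # merged into a higher maximum's region
      next_id <- next_id + 1L
      thr <- p[seed] - tolerance
      region <- flood_fill(p, claimed, seed, thr, next_id)
      claimed <- region$claimed
      rois[[next_id]] <- region$pixels
    }
  }

  keep <- logical(length(rois))
  rows <- vector("list", length(rois))
  pix_keep <- list()
  id <- 0L
  for (i in seq_along(rois)) {
    px <- rois[[i]]
    area <- length(px)
    size_um <- 2 * sqrt(area / pi) * pixel_size_um
    if (size_um > max_linear_size_um) next  # size-exclusion post-filter
    id <- id + 1L
    xs <- ((px - 1) %% nx) + 1
    ys <- ((px - 1) %/% nx) + 1
    rows[[id]] <- data.frame(id = id, centroid_x = mean(xs),
                             centroid_y = mean(ys), area_px = area,
                             size_um = size_um, peak = max(p[px]))
    pix_keep[[id]] <- px
  }
  out <- if (id > 0) do.call(rbind, rows[seq_len(id)]) else
    data.frame(id = integer(0), centroid_x = numeric(0),
               centroid_y = numeric(0), area_px = integer(0),
               size_um = numeric(0), peak = numeric(0))
  attr(out, "pixels") <- pix_keep
  attr(out, "pixel_size_um") <- pixel_size_um
  class(out) <- c("roi_set", "data.frame")
  out
}

# Breadth-first 8-connected flood fill over unclaimed pixels >= thr.
# Returns the filled pixel indices and the updated claim matrix.
flood_fill <- function(p, claimed, seed, thr, id) {
  nx <- nrow(p); ny <- ncol(p)
  frontier <- seed
  claimed[seed] <- id
  pixels <- seed
  while (length(frontier) > 0) {
    fx <- ((frontier - 1) %% nx) + 1
    fy <- ((frontier - 1) %/% nx) + 1
    cand <- integer(0)
    for (k in seq_len(nrow(.neigh8))) {
      qx <- fx + .neigh8[k, 1]
      qy <- fy + .neigh8[k, 2]
      ok <- qx >= 1 & qx <= nx & qy >= 1 & qy <= ny
      if (any(ok)) cand <- c(cand, (qy[ok] - 1) * nx + qx[ok])
    }
    cand <- unique(cand)
    cand <- cand[claimed[cand] == 0L & p[cand] >= thr]
    if (length(cand) == 0) break
    claimed[cand] <- id
    pixels <- c(pixels, cand)
    frontier <- cand
  }
  list(pixels = pixels, claimed = claimed)
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("ROI set: %d region(s)\n", nrow(x)))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10),
                                    row.names = FALSE)
  invisible(x)
}

#' Extract per-ROI mean-intensity traces
#'
#' Computes the mean grayscale intensity over each ROI's pixels for every
#' frame, yielding the intensity-versus-time matrix.  The same ROI set
#' (detected once on the brighter acceptor channel) is reused for both
#' channels.
#'
#' @param stack a [time_lapse_stack()].
#' @param rois a [detect_rois()] result.
#' @return a [trace_matrix()], frames x ROIs.
#' @export
extract_traces <- function(stack, rois) {
  stopifnot(inherits(stack, "time_lapse_stack"), inherits(rois, "roi_set"))
  d <- dim(stack$voxels)
  npx <- d[1] * d[2]
  pixels <- attr(rois, "pixels")
  if (length(pixels) == 0) stop("ROI set is empty")
  if (any(vapply(pixels, length, 1L) == 0)) stop("ROI with zero pixels")
  if (any(unlist(pixels) > npx)) stop("ROI pixels outside stack bounds")
  flat <- matrix(stack$voxels, npx, d[3])
  vals <- vapply(pixels, function(px) {
    if (length(px) == 1) flat[px, ] else colMeans(flat[px, , drop = FALSE])
  }, numeric(d[3]))
  trace_matrix(vals, cell_ids = paste0("cell_", rois$id),
               frame_interval_s = stack$frame_interval_s,
               channel_name = stack$channel_name)
}

#' Integer-pixel channel alignment
#'
#' Finds the integer `(dx, dy)` translation of channel `b` that maximizes
#' the Pearson correlation between the two channels' average projections,
#' searching `[-max_shift_px, max_shift_px]` in each axis.  Ties are broken
#' towards the smaller shift; the zero shift is always a candidate.
#'
#' @param a,b two [time_lapse_stack()]s of identical dimensions.
#' @param max_shift_px search radius in pixels.
#' @return integer vector `c(dx, dy)`: `b`'s content is displaced by
#'   `(dx, dy)` relative to `a` (i.e. shifting `b` back by `(dx, dy)`
#'   aligns it).
#' @export
align_channels <- function(a, b, max_shift_px = 5) {
  stopifnot(inherits(a, "time_lapse_stack"), inherits(b, "time_lapse_stack"),
            all(dim(a$voxels)[1:2] == dim(b$voxels)[1:2]))
  pa <- unclass(average_projection(a))
  pb <- unclass(average_projection(b))
  nx <- nrow(pa); ny <- ncol(pa)
  m <- as.integer(max_shift_px)
  grid <- expand.grid(dx = -m:m, dy = -m:m)
  grid <- grid[order(grid$dx^2 + grid$dy^2, abs(grid$dx), abs(grid$dy)), ]
  best <- c(0L, 0L); best_cor <- -Inf
  for (i in seq_len(nrow(grid))) {
    dx <- grid$dx[i]; dy <- grid$dy[i]
    ax <- max(1, 1 + dx):min(nx, nx + dx)
    ay <- max(1, 1 + dy):min(ny, ny + dy)
    sa <- pa[ax - dx, ay - dy]
    sb <- pb[ax, ay]
    if (stats::sd(sa) == 0 || stats::sd(sb) == 0) next
    r <- stats::cor(as.vector(sa), as.vector(sb))
    if (r > best_cor + 1e-12) {  # strict improvement keeps the smaller shift
      best_cor <- r
      best <- c(dx, dy)
    }
  }
  as.integer(best)
}

#' Apply an integer shift to a stack
#'
#' Translates every frame by `-shift` (undoing the displacement reported by
#' [align_channels()]); uncovered borders are filled with the frame median.
#'
#' @param stack a [time_lapse_stack()].
#' @param shift integer `c(dx, dy)` from [align_channels()].
#' @return shifted [time_lapse_stack()].
#' @export
shift_stack <- function(stack, shift) {
  dx <- as.integer(shift[1]); dy <- as.integer(shift[2])
  if (dx == 0 && dy == 0) return(stack)
  v <- stack$voxels
  d <- dim(v)
  out <- array(0, d)
  for (f in seq_len(d[3])) {
    fr <- v[, , f]
    new <- matrix(stats::median(fr), d[1], d[2])
    xs <- max(1, 1 - dx):min(d[1], d[1] - dx)
    ys <- max(1, 1 - dy):min(d[2], d[2] - dy)
    new[xs, ys] <- fr[xs + dx, ys + dy]
    out[, , f] <- new
  }
  time_lapse_stack(out, stack$pixel_size_um, stack$frame_interval_s,
                   stack$channel_name)
}

#' Write an ROI set as CSV
#' @param rois a [detect_rois()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  utils::write.csv(as.data.frame(rois), path, row.names = FALSE)
  invisible(path)
}
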