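#' Specification of one simulated cell
#'
#' Describes a single cell of the synthetic population: its sensor
#' expression level, its baseline acceptor/donor ratio, and its reversible
#' response amplitudes to the scheduled agents.
#'
#' @param cell_id integer or string identifier.
#' @param expression_scale positive multiplier applied to both raw channels
#'   (sensor expression level; a pure nuisance that ratioing removes).
#' @param response_amplitudes named numeric vector: condition label ->
#'   fractional change of the normalized ratio at plateau (signed;
#'   negative for inhibitory responses).
#' @param onset_tau onset time constant in frames; the response rises as
#'   `1 - exp(-t/onset_tau)` towards its plateau.
#' @param relax_tau relaxation time constant in frames; after washout the
#'   response decays as `exp(-t/relax_tau)`.
#' @param baseline_ratio resting acceptor/donor ratio of the cell (per-cell
#'   FRET baseline; removed by the initial-value normalization).
#' @param subpopulation free-text class label carried into the ground truth
#'   (e.g. `"alpha-like"`, `"beta-like"`).
#' @return list of class `cell_spec`.
#' @export
cell_spec <- function(cell_id, expression_scale = 1,
                      response_amplitudes = numeric(0),
                      onset_tau = 1, relax_tau = 3,
                      baseline_ratio = 1, subpopulation = NA_character_) {
  stopifnot(expression_scale > 0, onset_tau > 0, relax_tau > 0,
            baseline_ratio > 0)
  if (length(response_amplitudes) > 0 && is.null(names(response_amplitudes))) {
    stop("response_amplitudes must be a named vector (condition labels)")
  }
  structure(list(cell_id = as.character(cell_id),
                 expression_scale = expression_scale,
                 response_amplitudes = response_amplitudes,
                 onset_tau = onset_tau, relax_tau = relax_tau,
                 baseline_ratio = baseline_ratio,
                 subpopulation = subpopulation),
            class = "cell_spec")
}

#' Specification of slow drift and measurement noise
#'
#' Photobleaching is modeled as a multiplicative, monotone decay applied to
#' each raw channel, with different rates for donor and acceptor (their
#' bleaching rates differ, which is why ratioing alone does not cancel the
#' drift).  Measurement noise is additive Gaussian on the raw intensity
#' scale.
#'
#' @param model `"none"`, `"linear"` (`1 + rate * t`) or `"exponential"`
#'   (`exp(rate * t)`); `t` is the 0-based frame index.
#' @param per_channel_rate length-2 numeric `c(donor, acceptor)` decay rates
#'   per frame (typically small and negative).
#' @param noise_sd nonnegative additive noise SD on the raw intensity scale.
#' @return list of class `drift_spec`.
#' @export
drift_spec <- function(model = c("none", "linear", "exponential"),
                       per_channel_rate = c(0, 0), noise_sd = 0) {
  model <- match.arg(model)
  stopifnot(length(per_channel_rate) == 2, noise_sd >= 0)
  structure(list(model = model,
                 per_channel_rate = as.numeric(per_channel_rate),
                 noise_sd = noise_sd),
            class = "drift_spec")
}

drift_curve <- function(model, rate, n_frames) {
  t <- seq_len(n_frames) - 1
  d <- switch(model,
              none = rep(1, n_frames),
              linear = 1 + rate * t,
              exponential = exp(rate * t))
  if (any(d <= 0)) {
    stop(sprintf("drift model '%s' with rate %g reaches non-positive intensity within %d frames",
                 model, rate, n_frames))
  }
  d
}

#' Planted response curve of one cell (noise- and drift-free)
#'
#' During each scheduled interval the response rises towards its plateau as
#' `amplitude * (1 - exp(-k/onset_tau))` (k frames since addition); after
#' removal it relaxes exponentially with `relax_tau`.  Contributions of
#' successive agents add.
#'
#' @param cell a [cell_spec()].
#' @param schedule a [timestamp_schedule()].
#' @param n_frames number of frames.
#' @return numeric vector: the planted normalized ratio `1 + response(t)`.
#' @export
response_curve <- function(cell, schedule, n_frames) {
  r <- rep(0, n_frames)
  t <- seq_len(n_frames) - 1
  for (i in seq_len(nrow(schedule))) {
    lab <- schedule$label[i]
    a <- cell$response_amplitudes[[lab]]
    if (is.null(a) || is.na(a) || a == 0) next
    s <- schedule$start_frame[i]; e <- schedule$end_frame[i]
    on <- t >= s & t < e
    r[on] <- r[on] + a * (1 - exp(-(t[on] - s + 1) / cell$onset_tau))
    plateau <- a * (1 - exp(-(e - s) / cell$onset_tau))
    off <- t >= e
    r[off] <- r[off] + plateau * exp(-(t[off] - e + 1) / cell$relax_tau)
  }
  1 + r
}

#' Simulate two-channel trace matrices for a cell population
#'
#' Generates donor and acceptor intensity-versus-time matrices whose
#' acceptor/donor ratio, after removal of the planted drift and
#' normalization, equals each cell's planted response curve.  The response
#' is split symmetrically between the channels (acceptor rises, donor falls
#' by the square-root factor), mimicking opposite-going FRET channels.
#'
#' @param cells list of [cell_spec()] objects.
#' @param schedule a [timestamp_schedule()].
#' @param drift a [drift_spec()].
#' @param n_frames number of frames; defaults to the schedule's
#'   `total_frames`.  Must be at least 10 and cover the schedule.
#' @param seed integer seed fixing all randomness.
#' @return list of class `simulated_traces`: `acceptor`, `donor`
#'   ([trace_matrix()]), `truth` (cells x conditions matrix of planted
#'   plateau amplitudes), `cells` (data.frame of per-cell nuisance
#'   parameters and subpopulation labels), and `schedule`.
#' @export
simulate_traces <- function(cells, schedule, drift = drift_spec(),
                            n_frames = total_frames(schedule), seed = 1) {
  stopifnot(inherits(schedule, "timestamp_schedule"),
            inherits(drift, "drift_spec"))
  if (n_frames < 10) stop("n_frames must be at least 10")
  over <- which(schedule$end_frame > n_frames)
  if (length(over) > 0) {
    stop(sprintf("schedule interval '%s' [%d, %d) exceeds n_frames = %d",
                 schedule$label[over[1]], schedule$start_frame[over[1]],
                 schedule$end_frame[over[1]], n_frames))
  }
  if (inherits(cells, "cell_spec")) cells <- list(cells)
  m <- length(cells)
  dd <- drift_curve(drift$model, drift$per_channel_rate[1], n_frames)
  da <- drift_curve(drift$model, drift$per_channel_rate[2], n_frames)

  acceptor <- matrix(0, n_frames, m)
  donor <- matrix(0, n_frames, m)
  labs <- schedule$label
  truth <- matrix(0, m, length(labs), dimnames = list(NULL, labs))
  ids <- vapply(cells, function(cl) cl$cell_id, character(1))
  meta <- data.frame(
    cell_id = ids,
    expression_scale = vapply(cells, function(cl) cl$expression_scale, 1),
    baseline_ratio = vapply(cells, function(cl) cl$baseline_ratio, 1),
    onset_tau = vapply(cells, function(cl) cl$onset_tau, 1),
    relax_tau = vapply(cells, function(cl) cl$relax_tau, 1),
    subpopulation = vapply(cells, function(cl) as.character(cl$subpopulation),
                           character(1)),
    stringsAsFactors = FALSE
  )

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  for (j in seq_len(m)) {
    cl <- cells[[j]]
    r <- response_curve(cl, schedule, n_frames)
    if (any(r <= 0)) {
      stop(sprintf(
        "cell '%s': planted responses drive the ratio non-positive (min %.3g)",
        cl$cell_id, min(r)))
    }
    sq <- sqrt(r)
    acceptor[, j] <- cl$expression_scale * cl$baseline_ratio * sq * da
    donor[, j] <- cl$expression_scale * (1 / sq) * dd
    for (lab in labs) {
      a <- cl$response_amplitudes[[lab]]
      if (!is.null(a) && !is.na(a)) truth[j, lab] <- a
    }
  }
  if (drift$noise_sd > 0) {
    acceptor <- acceptor + matrix(stats::rnorm(n_frames * m, 0, drift$noise_sd),
                                  n_frames, m)
    donor <- donor + matrix(stats::rnorm(n_frames * m, 0, drift$noise_sd),
                            n_frames, m)
  }
  rownames(truth) <- ids
  fi <- attr(schedule, "frame_interval_s")
  structure(list(
    acceptor = trace_matrix(acceptor, ids, fi, "YFP"),
    donor = trace_matrix(donor, ids, fi, "CFP"),
    truth = truth,
    cells = meta,
    schedule = schedule
  ), class = "simulated_traces")
}

#' @export
print.simulated_traces <- function(x, ...) {
  cat(sprintf("Simulated traces: %d cells x %d frames, %d conditions\n",
              ncol(x$acceptor), nrow(x$acceptor), ncol(x$truth)))
  invisible(x)
}

#' Random heterogeneous cell population
#'
#' Draws a population of [cell_spec()]s with log-normal expression scales
#' and baseline ratios, uniformly distributed response amplitudes, and an
#' optional marker condition with sign-opposed subpopulations (e.g.
#' adrenaline-positive "alpha-like" versus adrenaline-negative "beta-like"
#' cells).  Optionally, groups of conditions can share a per-cell latent
#' factor so their amplitudes correlate across the population.
#'
#' @param n_cells number of cells.
#' @param labels condition labels the cells respond to.
#' @param amplitude_range range of the uniform draw for non-marker
#'   amplitudes.
#' @param marker_label optional label of the marker condition.
#' @param marker_positive_frac fraction of cells with a positive marker
#'   response (`alpha-like`); the rest respond negatively (`beta-like`).
#' @param marker_amplitude_range range of |marker amplitude|.
#' @param expression_sdlog,ratio_sdlog log-normal spread of the expression
#'   scale and the baseline ratio.
#' @param onset_tau,relax_tau kinetic time constants (frames), common to all
#'   cells.
#' @param latent_groups optional named list: group name -> character vector
#'   of labels sharing one per-cell latent factor.
#' @param latent_scale,latent_resid loading of the latent factor and SD of
#'   the label-specific residual for latent-group amplitudes.
#' @param seed integer seed.
#' @return list of [cell_spec()]s.
#' @export
random_cells <- function(n_cells, labels,
                         amplitude_range = c(-0.5, 0.8),
                         marker_label = NULL, marker_positive_frac = 0.25,
                         marker_amplitude_range = c(0.2, 0.6),
                         expression_sdlog = 0.25, ratio_sdlog = 0.2,
                         onset_tau = 1, relax_tau = 3,
                         latent_groups = NULL, latent_scale = 0.25,
                         latent_resid = 0.05, seed = 1) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  scales <- stats::rlnorm(n_cells, 0, expression_sdlog)
  ratios <- stats::rlnorm(n_cells, 0, ratio_sdlog)
  amp <- matrix(stats::runif(n_cells * length(labels),
                             amplitude_range[1], amplitude_range[2]),
                n_cells, length(labels), dimnames = list(NULL, labels))
  subpop <- rep(NA_character_, n_cells)
  if (!is.null(marker_label)) {
    stopifnot(marker_label %in% labels)
    pos <- stats::runif(n_cells) < marker_positive_frac
    mag <- stats::runif(n_cells, marker_amplitude_range[1],
                        marker_amplitude_range[2])
    amp[, marker_label] <- ifelse(pos, mag, -mag)
    subpop <- ifelse(pos, "alpha-like", "beta-like")
  }
  if (!is.null(latent_groups)) {
    for (g in latent_groups) {
      stopifnot(all(g %in% labels))
      f <- stats::rnorm(n_cells)
      for (lab in g) {
        # truncated at -0.9: a response cannot drive the sensor ratio to 0
        amp[, lab] <- pmax(latent_scale * f +
                             stats::rnorm(n_cells, 0, latent_resid), -0.9)
      }
    }
  }
  lapply(seq_len(n_cells), function(i) {
    cell_spec(sprintf("cell_%04d", i), expression_scale = scales[i],
              response_amplitudes = amp[i, ], onset_tau = onset_tau,
              relax_tau = relax_tau, baseline_ratio = ratios[i],
              subpopulation = subpop[i])
  })
}

#' Cell population with planted effect-space clusters
#'
#' Each cell's amplitude vector is a cluster centroid plus isotropic
#' Gaussian scatter; used to validate cluster recovery.
#'
#' @param n_cells number of cells (distributed evenly across clusters).
#' @param centroids numeric matrix, clusters in rows, one column per
#'   condition label (column names are the labels).
#' @param scatter_sd SD of the within-cluster scatter per condition.
#' @param onset_tau,relax_tau kinetic time constants (frames).
#' @param seed integer seed.
#' @return list of [cell_spec()]s with `subpopulation` set to
#'   `"cluster_<i>"`.
#' @export
clustered_cells <- function(n_cells, centroids, scatter_sd = 0.05,
                            onset_tau = 1, relax_tau = 3, seed = 1) {
  stopifnot(is.matrix(centroids), !is.null(colnames(centroids)))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  k <- nrow(centroids)
  assign_k <- rep_len(seq_len(k), n_cells)
  labels <- colnames(centroids)
  lapply(seq_len(n_cells), function(i) {
    a <- centroids[assign_k[i], ] + stats::rnorm(length(labels), 0, scatter_sd)
    names(a) <- labels
    cell_spec(sprintf("cell_%04d", i), response_amplitudes = a,
              onset_tau = onset_tau, relax_tau = relax_tau,
              subpopulation = sprintf("cluster_%d", assign_k[i]))
  })
}

#' Simulate a blob-image time-lapse stack
#'
#' Renders each cell as an isotropic 2D Gaussian whose intensity falls to
#' half its peak at the stated radius, so a detection tolerance of half the
#' peak recovers an ROI of equivalent linear size `2 * radius_um`.
#' Background noise is zero-mean Gaussian, independent per pixel and frame.
#'
#' @param cells_xy data.frame with columns `x`, `y` (pixel coordinates of
#'   blob centers, 1-based), `radius_um`, `peak` (peak intensity).
#' @param n_frames number of frames.
#' @param dim image dimensions `c(nx, ny)` in pixels.
#' @param pixel_size_um physical pixel size.
#' @param noise_sd additive noise SD.
#' @param frame_scale optional `n_frames x n_blobs` matrix of per-frame
#'   multiplicative factors for each blob's peak (defaults to constant 1,
#'   i.e. frames identical up to noise).
#' @param seed integer seed.
#' @param frame_interval_s frame interval metadata.
#' @param channel_name channel metadata.
#' @return a [time_lapse_stack()].
#' @export
simulate_image_stack <- function(cells_xy, n_frames, dim = c(256, 256),
                                 pixel_size_um = 1, noise_sd = 0,
                                 frame_scale = NULL, seed = 1,
                                 frame_interval_s = 60,
                                 channel_name = "YFP") {
  stopifnot(all(c("x", "y", "radius_um", "peak") %in% names(cells_xy)))
  nx <- dim[1]; ny <- dim[2]
  nb <- nrow(cells_xy)
  if (any(cells_xy$x < 1 | cells_xy$x > nx | cells_xy$y < 1 |
          cells_xy$y > ny)) {
    stop("blob center outside the frame")
  }
  if (any(cells_xy$radius_um <= 0)) stop("blob radius must be positive")
  if (is.null(frame_scale)) {
    frame_scale <- matrix(1, n_frames, nb)
  }
  stopifnot(nrow(frame_scale) == n_frames, ncol(frame_scale) == nb)

  # one clean template per blob, added frame-wise with its scale factor
  base <- matrix(0, nx, ny)
  templates <- vector("list", nb)
  for (b in seq_len(nb)) {
    sigma_px <- (cells_xy$radius_um[b] / pixel_size_um) / sqrt(2 * log(2))
    w <- ceiling(4 * sigma_px)
    xs <- max(1, round(cells_xy$x[b]) - w):min(nx, round(cells_xy$x[b]) + w)
    ys <- max(1, round(cells_xy$y[b]) - w):min(ny, round(cells_xy$y[b]) + w)
    g <- outer(xs, ys, function(i, j) {
      cells_xy$peak[b] *
        exp(-((i - cells_xy$x[b])^2 + (j - cells_xy$y[b])^2) /
              (2 * sigma_px^2))
    })
    templates[[b]] <- list(xs = xs, ys = ys, g = g)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  voxels <- array(0, c(nx, ny, n_frames))
  constant <- all(frame_scale == frame_scale[1, ][col(frame_scale)])
  frame0 <- base
  for (b in seq_len(nb)) {
    tp <- templates[[b]]
    frame0[tp$xs, tp$ys] <- frame0[tp$xs, tp$ys] + tp$g
  }
  for (f in seq_len(n_frames)) {
    if (constant && all(frame_scale[f, ] == 1)) {
      fr <- frame0
    } else {
      fr <- base
      for (b in seq_len(nb)) {
        tp <- templates[[b]]
        fr[tp$xs, tp$ys] <- fr[tp$xs, tp$ys] + frame_scale[f, b] * tp$g
      }
    }
    if (noise_sd > 0) {
      fr <- fr + matrix(stats::rnorm(nx * ny, 0, noise_sd), nx, ny)
    }
    voxels[, , f] <- fr
  }
  time_lapse_stack(voxels, pixel_size_um = pixel_size_um,
                   frame_interval_s = frame_interval_s,
                   channel_name = channel_name)
}
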