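#' Run the full functional-cytometry pipeline
#'
#' Orchestrates all stages from input (a TIFF channel pair or pre-extracted
#' CSV trace matrices) to the corrected traces, effect table, population
#' split, correlations and clusters, writing every intermediate artifact
#' plus a machine-readable manifest into an output directory.  The run is
#' deterministic given `seed`.
#'
#' @param config named list (or path to a YAML file) with fields:
#'   \describe{
#'     \item{`schedule`}{path to the schedule YAML (required).}
#'     \item{`acceptor_tiff`, `donor_tiff`}{TIFF stack paths, or}
#'     \item{`acceptor_csv`, `donor_csv`}{trace CSV paths, or}
#'     \item{`traces_csv`}{single-channel CSV treated directly as the ratio
#'       (single-fluorophore sensors).}
#'     \item{`pixel_size_um`, `frame_interval_s`}{calibration for TIFF
#'       input.}
#'     \item{`detection`}{list `prominence`, `tolerance`,
#'       `max_linear_size_um` for TIFF input.}
#'     \item{`align_channels`}{logical; estimate and undo an integer
#'       channel shift (default FALSE).}
#'     \item{`baseline_method`}{one of the [fit_baseline()] methods
#'       (default `piecewise_linear`).}
#'     \item{`effect_method`}{one of the [quantify_effect()] methods
#'       (default `linear`).}
#'     \item{`marker`}{marker condition label for the population split
#'       (optional).}
#'     \item{`cluster`}{logical; run k-means/PCA profiling (default TRUE
#'       when >= 10 cells).}
#'     \item{`figures`}{logical; write PNG figures (default FALSE).}
#'     \item{`out_dir`}{output directory (required).}
#'     \item{`seed`}{integer seed (default 1).}
#'   }
#' @return invisibly, a list with the main stage outputs and the manifest.
#' @export
run_pipeline <- function(config) {
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    if (!file.exists(config)) {
      stop(sprintf("config file not found: '%s'", config))
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) stop("config lacks 'out_dir'")
  if (is.null(config$schedule)) stop("config lacks 'schedule'")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  baseline_method <- config$baseline_method %||% "piecewise_linear"
  effect_method <- config$effect_method %||% "linear"
  manifest <- list(
    package_version = as.character(utils::packageVersion("funcyto")),
    r_version = R.version.string,
    seed = seed,
    baseline_method = baseline_method,
    effect_method = effect_method,
    stages = list()
  )
  if (!is.null(config_path)) {
    manifest$config_md5 <- unname(tools::md5sum(config_path))
  }

  schedule <- read_schedule(config$schedule)
  manifest$stages$schedule <- list(n_conditions = nrow(schedule),
                                   total_frames = total_frames(schedule))

  # --- stage 1: traces -----------------------------------------------------
  if (!is.null(config$acceptor_tiff)) {
    if (is.null(config$pixel_size_um)) {
      stop("TIFF input requires 'pixel_size_um'")
    }
    det <- config$detection
    if (is.null(det)) stop("TIFF input requires 'detection' parameters")
    acc_stack <- read_stack(config$acceptor_tiff, config$pixel_size_um,
                            config$frame_interval_s %||% NA_real_, "YFP")
    don_stack <- read_stack(config$donor_tiff, config$pixel_size_um,
                            config$frame_interval_s %||% NA_real_, "CFP")
    if (isTRUE(config$align_channels)) {
      shift <- align_channels(acc_stack, don_stack,
                              det$max_shift_px %||% 5)
      don_stack <- shift_stack(don_stack, shift)
      manifest$stages$alignment <- list(shift = shift)
    }
    proj <- average_projection(acc_stack)  # ROIs mapped on the brighter channel
    rois <- detect_rois(proj, det$prominence, det$tolerance,
                        det$max_linear_size_um %||% 30)
    if (nrow(rois) == 0) stop("stage roi_extraction: no ROIs detected")
    write_rois(rois, file.path(out, "rois.csv"))
    acceptor <- extract_traces(acc_stack, rois)
    donor <- extract_traces(don_stack, rois)
    manifest$stages$roi_extraction <- list(n_rois = nrow(rois))
  } else if (!is.null(config$acceptor_csv)) {
    acceptor <- read_traces(config$acceptor_csv, "YFP")
    donor <- read_traces(config$donor_csv, "CFP")
  } else if (!is.null(config$traces_csv)) {
    acceptor <- NULL
    donor <- NULL
    ratio <- read_traces(config$traces_csv, "ratio")
  } else {
    stop("config must provide acceptor_tiff, acceptor_csv or traces_csv")
  }

  # --- stage 2: ratio + normalization -------------------------------------
  if (!is.null(config$traces_csv)) {
    # single-fluorophore input enters directly as R
  } else {
    write_traces(acceptor, file.path(out, "traces_acceptor.csv"))
    write_traces(donor, file.path(out, "traces_donor.csv"))
    ratio <- compute_ratio(acceptor, donor)
  }
  normalized <- normalize_to_initial(ratio)
  manifest$stages$normalization <- list(
    n_cells = ncol(normalized),
    dropped_cells = as.list(attr(normalized, "dropped_cells")))

  # --- stage 3: baseline correction ---------------------------------------
  bl <- fit_baseline(normalized, schedule, baseline_method)
  corrected <- subtract_baseline(normalized, bl)
  write_traces(corrected, file.path(out, "traces_corrected.csv"))
  jsonlite::write_json(
    list(baseline_method = baseline_method,
         n_fallback = sum(bl$diagnostics$fallback)),
    file.path(out, "traces_corrected.json"), auto_unbox = TRUE)
  manifest$stages$baseline <- list(method = baseline_method,
                                   n_fallback = sum(bl$diagnostics$fallback))

  # --- stage 4: effect quantification -------------------------------------
  effects <- quantify_effects(corrected, schedule, effect_method)
  write_effect_table(effects, file.path(out, "effects.csv"),
                     file.path(out, "effects_diagnostics.csv"))
  manifest$stages$effects <- list(
    method = effect_method,
    n_flagged = sum(!attr(effects, "converged")))

  # --- stage 5: population profiling --------------------------------------
  split <- NULL
  if (!is.null(config$marker)) {
    stat <- sorting_statistic(corrected, schedule, config$marker)
    split <- split_population(effects, config$marker)
    utils::write.csv(
      data.frame(cell_id = names(split), class = as.character(split),
                 sorting_statistic = unclass(stat)[names(split)]),
      file.path(out, "population_split.csv"), row.names = FALSE)
    manifest$stages$population <- as.list(table(split))
  }

  # --- stage 6: cluster analysis ------------------------------------------
  clusters <- NULL
  do_cluster <- config$cluster %||% (nrow(effects) >= 10)
  if (isTRUE(do_cluster)) {
    clusters <- kmeans_profile(effects, seed = seed)
    utils::write.csv(
      data.frame(cell_id = names(clusters$assignment),
                 cluster = clusters$assignment),
      file.path(out, "cluster_assignment.csv"), row.names = FALSE)
    utils::write.csv(clusters$wss, file.path(out, "cluster_wss.csv"),
                     row.names = FALSE)
    pca <- pca_contributions(effects)
    utils::write.csv(pca, file.path(out, "pca_contributions.csv"),
                     row.names = FALSE)
    dend <- hierarchical_profile(effects, "conditions")
    if (requireNamespace("ape", quietly = TRUE)) {
      write_dendrogram_newick(dend, file.path(out,
                                              "condition_dendrogram.nwk"))
    }
    manifest$stages$clusters <- list(elbow_k = clusters$k)
  }

  if (isTRUE(config$figures)) {
    grDevices::png(file.path(out, "heatmap_corrected.png"), 900, 600)
    ord <- if (!is.null(config$marker)) {
      rank_cells(corrected, sorting_statistic(corrected, schedule,
                                              config$marker))
    } else NULL
    plot_trace_heatmap(corrected, schedule, order = ord,
                       main = "corrected R/R0")
    grDevices::dev.off()
    if (!is.null(clusters)) {
      grDevices::png(file.path(out, "cluster_wss.png"), 600, 450)
      plot(clusters)
      grDevices::dev.off()
    }
  }

  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(schedule = schedule, corrected = corrected,
                 baseline = bl, effects = effects, split = split,
                 clusters = clusters, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
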