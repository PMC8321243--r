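#' Timestamp schedule of agent applications
#'
#' An ordered set of half-open frame intervals `[start_frame, end_frame)`
#' during which a pharmacological agent was present in the bath.  The
#' complement of the intervals defines the basal (agent-free) regions that
#' anchor baseline correction and effect quantification.  Frames are 0-based,
#' matching the convention used throughout the package.
#'
#' @param label character vector of condition labels (e.g.
#'   `"GLP-1 7-36 @ 1 pM"`). Must be unique.
#' @param start_frame,end_frame integer vectors of interval bounds, half-open
#'   `[start, end)`, 0-based.
#' @param total_frames total number of frames in the recording.
#' @param frame_interval_s optional frame interval in seconds (metadata only).
#'
#' @return An object of class `timestamp_schedule`: a data.frame with columns
#'   `label`, `start_frame`, `end_frame`, plus attributes `total_frames` and
#'   `frame_interval_s`.
#'
#' @details Intervals must be sorted, non-overlapping, and lie strictly inside
#'   `[0, total_frames)` such that at least one basal frame precedes the first
#'   interval and follows the last one (the piecewise baseline methods need a
#'   basal anchor on both sides of every condition).
#'
#' @seealso [basal_regions()], [read_schedule()], [write_schedule()]
#' @export
timestamp_schedule <- function(label, start_frame, end_frame, total_frames,
                               frame_interval_s = NA_real_) {
  stopifnot(length(label) == length(start_frame),
            length(label) == length(end_frame))
  label <- as.character(label)
  start_frame <- as.integer(start_frame)
  end_frame <- as.integer(end_frame)
  total_frames <- as.integer(total_frames)
  if (anyDuplicated(label)) {
    stop("condition labels must be unique")
  }
  if (length(label) > 0L) {
    if (any(end_frame <= start_frame)) {
      bad <- which(end_frame <= start_frame)[1L]
      stop(sprintf("empty or inverted interval '%s' [%d, %d)",
                   label[bad], start_frame[bad], end_frame[bad]))
    }
    if (any(start_frame < 1L) || any(end_frame > total_frames - 1L)) {
      bad <- which(start_frame < 1L | end_frame > total_frames - 1L)[1L]
      stop(sprintf(
        paste0("interval '%s' [%d, %d) leaves no basal frame before the ",
               "first or after the last condition (total_frames = %d)"),
        label[bad], start_frame[bad], end_frame[bad], total_frames))
    }
    o <- order(start_frame)
    label <- label[o]; start_frame <- start_frame[o]; end_frame <- end_frame[o]
    if (length(label) > 1L &&
        any(start_frame[-1L] < end_frame[-length(end_frame)])) {
      stop("condition intervals overlap")
    }
  }
  out <- data.frame(label = label, start_frame = start_frame,
                    end_frame = end_frame, stringsAsFactors = FALSE)
  attr(out, "total_frames") <- total_frames
  attr(out, "frame_interval_s") <- frame_interval_s
  class(out) <- c("timestamp_schedule", "data.frame")
  out
}

#' @export
print.timestamp_schedule <- function(x, ...) {
  cat(sprintf("Timestamp schedule: %d condition(s), %d frames\n",
              nrow(x), attr(x, "total_frames")))
  if (nrow(x) > 0L) {
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

#' Total number of frames covered by a schedule
#' @param schedule a [timestamp_schedule()].
#' @return integer frame count.
#' @export
total_frames <- function(schedule) {
  stopifnot(inherits(schedule, "timestamp_schedule"))
  attr(schedule, "total_frames")
}

#' Basal (agent-free) regions of a schedule
#'
#' Returns the maximal runs of frames not covered by any condition interval,
#' in temporal order.  Every return to basal conditions is assumed to restore
#' the initial analyte level; these regions drive baseline correction.
#'
#' @param schedule a [timestamp_schedule()].
#' @return list of integer vectors `c(start, end)`, half-open 0-based
#'   intervals.
#' @export
basal_regions <- function(schedule) {
  stopifnot(inherits(schedule, "timestamp_schedule"))
  n <- total_frames(schedule)
  covered <- rep(FALSE, n)
  for (i in seq_len(nrow(schedule))) {
    covered[(schedule$start_frame[i] + 1L):schedule$end_frame[i]] <- TRUE
  }
  basal <- !covered
  # run-length decomposition of the complement
  r <- rle(basal)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  keep <- r$values
  mapply(function(s, e) c(s, e), starts[keep], ends[keep], SIMPLIFY = FALSE)
}

#' Frames belonging to each condition
#' @param schedule a [timestamp_schedule()].
#' @return named list of 0-based frame index vectors, one per condition.
#' @export
condition_frames <- function(schedule) {
  out <- lapply(seq_len(nrow(schedule)), function(i) {
    seq.int(schedule$start_frame[i], schedule$end_frame[i] - 1L)
  })
  names(out) <- schedule$label
  out
}

#' Read a timestamp schedule from YAML
#'
#' The file holds `total_frames`, optionally `frame_interval_s`, and a list
#' `conditions` of entries with `label` (or `agent` + `concentration`) and
#' either `start_frame`/`end_frame` or `start_s`/`end_s`.  Second-based
#' bounds are converted with round-to-nearest using `frame_interval_s`.
#'
#' @param path path to a YAML file.
#' @return a [timestamp_schedule()].
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("schedule file not found: '%s'", path))
  }
  y <- yaml::read_yaml(path)
  if (is.null(y$total_frames)) stop("schedule YAML lacks 'total_frames'")
  fi <- if (is.null(y$frame_interval_s)) NA_real_ else as.numeric(y$frame_interval_s)
  entries <- y$conditions
  if (is.null(entries)) entries <- list()
  lab <- character(0); s <- integer(0); e <- integer(0)
  for (en in entries) {
    l <- en$label
    if (is.null(l)) {
      if (is.null(en$agent)) stop("schedule entry lacks 'label' or 'agent'")
      l <- if (is.null(en$concentration)) en$agent else
        paste(en$agent, "@", en$concentration)
    }
    if (!is.null(en$start_frame)) {
      sf <- as.integer(en$start_frame); ef <- as.integer(en$end_frame)
    } else if (!is.null(en$start_s)) {
      if (is.na(fi)) stop("second-based schedule entries need 'frame_interval_s'")
      sf <- as.integer(round(as.numeric(en$start_s) / fi))
      ef <- as.integer(round(as.numeric(en$end_s) / fi))
    } else {
      stop(sprintf("schedule entry '%s' lacks start_frame/start_s", l))
    }
    lab <- c(lab, l); s <- c(s, sf); e <- c(e, ef)
  }
  timestamp_schedule(lab, s, e, y$total_frames, fi)
}

#' Write a timestamp schedule to YAML
#' @param schedule a [timestamp_schedule()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "timestamp_schedule"))
  y <- list(
    total_frames = total_frames(schedule),
    frame_interval_s = attr(schedule, "frame_interval_s"),
    conditions = lapply(seq_len(nrow(schedule)), function(i) {
      list(label = schedule$label[i],
           start_frame = schedule$start_frame[i],
           end_frame = schedule$end_frame[i])
    })
  )
  if (is.na(y$frame_interval_s)) y$frame_interval_s <- NULL
  yaml::write_yaml(y, path)
  invisible(path)
}
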