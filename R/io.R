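trajectory_cols <- c("participant", "trial", "compatibility", "correct_side",
                     "response_error", "t_ms", "x_px", "y_px")

#' Read and write long-format trajectory logs
#'
#' A trajectory log is a CSV with one row per cursor sample and the
#' columns `participant`, `trial`, `compatibility`
#' (`compatible`/`incompatible`), `correct_side` (`left`/`right`),
#' `response_error` (logical), `t_ms` (time since imperative-stimulus
#' onset), `x_px`, `y_px`. Any additional columns are carried along as
#' extra condition labels. One trial is the contiguous set of rows
#' sharing (`participant`, `trial`).
#'
#' Trials violating the sampling invariants — fewer than 3 samples,
#' non-strictly-increasing `t_ms`, or (when `geometry` is supplied) a
#' first sample outside the start area — are dropped with a warning; the
#' dropped trials are recorded in the `"rejections"` attribute of the
#' returned tibble (columns `participant`, `trial`, `reason`).
#'
#' @param path CSV file path.
#' @param geometry Optional [display_geometry()] in the same frame as the
#'   file coordinates; if supplied, the first-sample-inside-start check is
#'   performed at load time.
#' @return A tibble of samples ordered by `t_ms` within trial, coordinates
#'   untouched (file frame), with attribute `"rejections"`.
#' @export
read_trajectories <- function(path, geometry = NULL) {
  if (!file.exists(path)) stop("trajectory file not found: ", path, call. = FALSE)
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_samples(dat, geometry = geometry)
}

#' @param samples A samples tibble as returned by [read_trajectories()] or
#'   [simulate_rec_experiment()].
#' @rdname read_trajectories
#' @export
write_trajectories <- function(samples, path) {
  missing_cols <- setdiff(trajectory_cols, names(samples))
  if (length(missing_cols) > 0) {
    stop("samples are missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(samples, path, progress = FALSE)
  invisible(path)
}

#' Validate a samples table against the trajectory-log contract
#'
#' Applied automatically by [read_trajectories()]; call directly on tables
#' assembled in memory.
#'
#' @inheritParams read_trajectories
#' @param samples A data frame of cursor samples.
#' @return The validated tibble (invalid trials dropped), with attribute
#'   `"rejections"`.
#' @export
validate_samples <- function(samples, geometry = NULL) {
  missing_cols <- setdiff(trajectory_cols, names(samples))
  if (length(missing_cols) > 0) {
    stop("trajectory data are missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dat <- tibble::as_tibble(samples)
  dat$response_error <- as.logical(dat$response_error)
  bad_side <- !dat$correct_side %in% c("left", "right")
  if (any(bad_side)) {
    stop("correct_side must be 'left' or 'right'", call. = FALSE)
  }

  dat <- dplyr::arrange(dat, .data$participant, .data$trial, .data$t_ms)
  key <- paste(dat$participant, dat$trial, sep = "\r")
  grp <- split(seq_len(nrow(dat)), factor(key, levels = unique(key)))

  reasons <- character(0)
  rej_part <- character(0)
  rej_trial <- character(0)
  keep <- rep(TRUE, nrow(dat))
  for (idx in grp) {
    t <- dat$t_ms[idx]
    reason <- NULL
    if (length(idx) < 3) {
      reason <- "fewer_than_3_samples"
    } else if (any(diff(t) <= 0)) {
      reason <- "non_monotone_time"
    } else if (!is.null(geometry) &&
               !in_region(dat$x_px[idx[1]], dat$y_px[idx[1]], geometry$start)) {
      reason <- "first_sample_outside_start"
    }
    if (!is.null(reason)) {
      keep[idx] <- FALSE
      reasons <- c(reasons, reason)
      rej_part <- c(rej_part, as.character(dat$participant[idx[1]]))
      rej_trial <- c(rej_trial, as.character(dat$trial[idx[1]]))
    }
  }
  rejections <- tibble::tibble(
    participant = rej_part, trial = rej_trial, reason = reasons
  )
  if (nrow(rejections) > 0) {
    warning(nrow(rejections), " trial(s) rejected at load: ",
            paste(unique(rejections$reason), collapse = ", "), call. = FALSE)
  }
  out <- dat[keep, , drop = FALSE]
  attr(out, "rejections") <- rejections
  out
}

# design-factor columns: everything that is not a sample coordinate,
# per-trial measure, or pipeline flag. correct_side is counterbalancing,
# not a condition factor.
condition_columns <- function(samples) {
  reserved <- c(
    "participant", "trial", "correct_side", "response_error",
    "t_ms", "x_px", "y_px", "x", "y", "flipped", "step", "time_frac",
    "it_ms", "mt_ms", "auc_px2", "mad_px", "mad_index", "min_x",
    "multistep", "error", "downward", "unusable", "unusable_reason",
    "outlier", "outlier_reasons", "retained", "speed", "segment",
    "percent", "it_nominal_ms", "mt_nominal_ms"
  )
  setdiff(names(samples), reserved)
}
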