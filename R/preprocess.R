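# Per-trial grouping helper: row indices per (participant, trial), in the
# order trials first appear. Assumes samples already sorted by t within trial.
split_trials <- function(df) {
  key <- paste(df$participant, df$trial, sep = "\r")
  split(seq_len(nrow(df)), factor(key, levels = unique(key)))
}

trial_meta <- function(df, groups) {
  first <- vapply(groups, `[`, integer(1), 1L)
  cols <- intersect(
    c("participant", "trial", condition_columns(df), "correct_side",
      "response_error", "flipped"),
    names(df)
  )
  df[first, cols, drop = FALSE]
}

#' Map trajectories into the canonical analysis frame
#'
#' Translates coordinates so the start-area centre is the origin, makes y
#' increase upward (negating screen-frame y), and mirrors every trial whose
#' correct target is on the left about the vertical axis, so that after
#' canonicalization the correct target always lies at positive x and the
#' wrong target at negative x. Mirroring about the line through the
#' start-area centre is an isometry, so all distance-based measures are
#' unaffected.
#'
#' @param samples A samples tibble (see [read_trajectories()]), coordinates
#'   in the same frame as `geometry`.
#' @param geometry A [display_geometry()].
#' @param on_violation What to do with trials whose first sample lies
#'   outside the start area: `"error"` (default) or `"drop"` with a
#'   warning (dropped trials recorded in the `"rejections"` attribute).
#' @return A tibble with canonical coordinates in columns `x`, `y`, a
#'   logical `flipped` column, and the original metadata columns
#'   (`x_px`/`y_px` are dropped).
#' @export
canonicalize <- function(samples, geometry, on_violation = c("error", "drop")) {
  on_violation <- match.arg(on_violation)
  stopifnot(inherits(geometry, "display_geometry"))
  g <- as_canonical(geometry)
  s <- if (geometry$frame == "screen") -1 else 1

  dat <- tibble::as_tibble(samples)
  x <- dat$x_px - geometry$start$x_center
  y <- s * (dat$y_px - geometry$start$y_center)
  flipped <- dat$correct_side == "left"
  x <- ifelse(flipped, -x, x)

  dat$x <- x
  dat$y <- y
  dat$flipped <- flipped
  dat$x_px <- NULL
  dat$y_px <- NULL

  groups <- split_trials(dat)
  first <- vapply(groups, `[`, integer(1), 1L)
  # mirroring maps the start area onto itself, so membership is frame-safe
  ok <- in_region(dat$x[first], dat$y[first], g$start)
  if (!all(ok)) {
    offenders <- trial_meta(dat, groups)[!ok, c("participant", "trial")]
    msg <- paste0(
      sum(!ok), " trial(s) start outside the start area (e.g. participant ",
      offenders$participant[1], ", trial ", offenders$trial[1], ")"
    )
    if (on_violation == "error") stop(msg, call. = FALSE)
    warning(msg, "; dropped", call. = FALSE)
    drop_rows <- unlist(groups[!ok], use.names = FALSE)
    rejections <- tibble::tibble(
      participant = as.character(offenders$participant),
      trial = as.character(offenders$trial),
      reason = "first_sample_outside_start"
    )
    dat <- dat[-drop_rows, , drop = FALSE]
    attr(dat, "rejections") <- rejections
  }
  dat
}

find_exit_entry <- function(x, y, start_region, target_region) {
  inside_start <- in_region(x, y, start_region)
  exit <- which(!inside_start)[1]
  if (is.na(exit)) return(c(NA_integer_, NA_integer_))
  in_target <- in_region(x, y, target_region)
  entry <- which(in_target & seq_along(x) >= exit)[1]
  c(exit, if (is.na(entry)) NA_integer_ else entry)
}

#' Truncate trajectories to the movement proper
#'
#' Cuts each canonical trajectory down to the samples between leaving the
#' start area and reaching the correct target area, anchored at whole
#' samples: the movement runs from the first sample outside the start area
#' through the first sample inside the correct target area. Initiation
#' time (IT) is the timestamp of the first sample outside the start area;
#' movement time (MT) is the time from that sample to target entry. A
#' trajectory that re-enters the start area after exiting is still
#' anchored at its first exit.
#'
#' Trials that never leave the start area or never reach the correct
#' target are unusable for movement analysis (distinct from response
#' errors); they are dropped and recorded in the `"unusable"` attribute.
#'
#' @param canon A canonicalized samples tibble (see [canonicalize()]).
#' @param geometry A [display_geometry()].
#' @return A tibble of movement samples with per-trial `it_ms` and `mt_ms`
#'   columns, plus attribute `"unusable"` (participant, trial, reason).
#' @export
truncate_movements <- function(canon, geometry) {
  g <- as_canonical(geometry)
  groups <- split_trials(canon)
  x <- canon$x; y <- canon$y; t <- canon$t_ms

  keep_rows <- vector("list", length(groups))
  it <- mt <- numeric(length(groups))
  reason <- character(length(groups))
  for (i in seq_along(groups)) {
    idx <- groups[[i]]
    ee <- find_exit_entry(x[idx], y[idx], g$start, g$target_right)
    if (is.na(ee[1])) {
      reason[i] <- "never_left_start"
    } else if (is.na(ee[2])) {
      reason[i] <- "never_reached_target"
    } else {
      keep_rows[[i]] <- idx[ee[1]:ee[2]]
      it[i] <- t[idx[ee[1]]]
      mt[i] <- t[idx[ee[2]]] - t[idx[ee[1]]]
    }
  }
  usable <- reason == ""
  meta <- trial_meta(canon, groups)
  unusable <- tibble::tibble(
    participant = as.character(meta$participant[!usable]),
    trial = as.character(meta$trial[!usable]),
    reason = reason[!usable]
  )
  if (nrow(unusable) > 0) {
    warning(nrow(unusable), " trial(s) unusable: ",
            paste(unique(unusable$reason), collapse = ", "), call. = FALSE)
  }
  lens <- lengths(keep_rows[usable])
  out <- canon[unlist(keep_rows[usable], use.names = FALSE), , drop = FALSE]
  out$it_ms <- rep(it[usable], lens)
  out$mt_ms <- rep(mt[usable], lens)
  attr(out, "unusable") <- unusable
  out
}

#' Flag trials containing downward movement
#'
#' A trial counts as a downward movement if, at any point after the cursor
#' first leaves the start area, its y coordinate falls strictly below the
#' bottom edge of the start area (canonical frame). Samples exactly on the
#' edge do not count.
#'
#' @inheritParams truncate_movements
#' @return A tibble with one row per trial: `participant`, `trial`,
#'   `downward`.
#' @export
flag_downward <- function(canon, geometry) {
  g <- as_canonical(geometry)
  bottom <- g$start$y_center - g$start$height / 2
  groups <- split_trials(canon)
  x <- canon$x; y <- canon$y
  down <- vapply(groups, function(idx) {
    inside <- in_region(x[idx], y[idx], g$start)
    exit <- which(!inside)[1]
    if (is.na(exit)) return(FALSE)
    any(y[idx[exit:length(idx)]] < bottom)
  }, logical(1))
  meta <- trial_meta(canon, groups)
  tibble::tibble(
    participant = meta$participant, trial = meta$trial,
    downward = unname(down)
  )
}

#' Time-normalize movements to a fixed number of steps
#'
#' Resamples each truncated movement to `n_steps` points at equally spaced
#' times between start-area exit and target entry, linearly interpolating
#' x and y between the bracketing raw samples. Endpoints are reproduced
#' exactly, and resampling a trajectory already sampled at the same
#' equally spaced times returns it unchanged (to machine precision), so
#' the operation is idempotent.
#'
#' @param movement Movement samples from [truncate_movements()] (or any
#'   canonical samples tibble with strictly increasing `t_ms` per trial).
#' @param n_steps Number of time steps (default 101, i.e. 1% increments).
#' @return A tibble with one row per trial and step: trial metadata,
#'   `step` (0 to `n_steps - 1`), `time_frac`, `t_ms`, `x`, `y`, `it_ms`,
#'   `mt_ms`.
#' @export
normalize_time <- function(movement, n_steps = 101) {
  if (n_steps < 2) stop("n_steps must be at least 2", call. = FALSE)
  groups <- split_trials(movement)
  short <- lengths(groups) < 2
  if (any(short)) {
    stop("time normalization needs at least 2 samples per trial", call. = FALSE)
  }
  x <- movement$x; y <- movement$y; t <- movement$t_ms
  nt <- length(groups)
  xs <- ys <- ts <- vector("list", nt)
  for (i in seq_len(nt)) {
    idx <- groups[[i]]
    grid <- seq(t[idx[1]], t[idx[length(idx)]], length.out = n_steps)
    xs[[i]] <- stats::approx(t[idx], x[idx], xout = grid)$y
    ys[[i]] <- stats::approx(t[idx], y[idx], xout = grid)$y
    ts[[i]] <- grid
  }
  meta <- trial_meta(movement, groups)
  first <- vapply(groups, `[`, integer(1), 1L)
  out <- meta[rep(seq_len(nt), each = n_steps), , drop = FALSE]
  out$step <- rep.int(0:(n_steps - 1), nt)
  out$time_frac <- out$step / (n_steps - 1)
  out$t_ms <- unlist(ts, use.names = FALSE)
  out$x <- unlist(xs, use.names = FALSE)
  out$y <- unlist(ys, use.names = FALSE)
  out$it_ms <- rep(movement$it_ms[first], each = n_steps)
  out$mt_ms <- rep(movement$mt_ms[first], each = n_steps)
  tibble::as_tibble(out)
}

#' Flag per-trial outliers within participant-by-condition cells
#'
#' Within each cell — one participant crossed with the full combination of
#' condition factors — each of the four measures (IT, MT, AUC, MAD) gets a
#' mean and sample SD (n - 1 denominator), computed once in a single pass.
#' A trial is an outlier if any measure deviates from its cell mean by
#' more than `k` SDs. Cells with fewer than `min_cell` trials are left
#' unflagged with a warning. Error, downward and unusable trials should be
#' removed before calling.
#'
#' @param measures A per-trial measures tibble (see [trial_measures()])
#'   with columns `participant`, the condition columns, `it_ms`, `mt_ms`,
#'   `auc_px2`, `mad_px`.
#' @param k SD multiplier (default 2.5).
#' @param min_cell Minimum trials per cell for flagging (default 3).
#' @return `measures` with logical `outlier` and character
#'   `outlier_reasons` (semicolon-separated measure labels) added.
#' @export
flag_outliers <- function(measures, k = 2.5, min_cell = 3) {
  vars <- c(IT = "it_ms", MT = "mt_ms", AUC = "auc_px2", MAD = "mad_px")
  stopifnot(all(vars %in% names(measures)))
  cell_vars <- c("participant", condition_columns(measures))
  key <- do.call(paste, c(measures[cell_vars], sep = "\r"))
  groups <- split(seq_len(nrow(measures)), factor(key, levels = unique(key)))

  n <- nrow(measures)
  flagged <- rep(FALSE, n)
  reasons <- rep("", n)
  small_cells <- 0L
  for (idx in groups) {
    if (length(idx) < min_cell) {
      small_cells <- small_cells + 1L
      next
    }
    for (lab in names(vars)) {
      v <- measures[[vars[[lab]]]][idx]
      dev <- abs(v - mean(v))
      hit <- dev > k * stats::sd(v)
      hit[is.na(hit)] <- FALSE
      flagged[idx][hit] <- TRUE
      reasons[idx][hit] <- ifelse(
        reasons[idx][hit] == "", lab, paste(reasons[idx][hit], lab, sep = ";")
      )
    }
  }
  if (small_cells > 0) {
    warning(small_cells, " cell(s) with fewer than ", min_cell,
            " trials: no outlier flagging there", call. = FALSE)
  }
  measures$outlier <- flagged
  measures$outlier_reasons <- reasons
  measures
}
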