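#' Vertical cutoff specification
#'
#' The classifier for multi-step movements draws a vertical line at
#' `x_cut = -f * |x_wrong|`, where `x_wrong` is the x coordinate of the
#' wrong-target centre in the canonical flipped frame (correct target on
#' the right) and the fraction `f` in `[0, 1]` is the allowed horizontal
#' travel from the start-area centre toward the wrong target: `f = 0`
#' puts the line at the start centre, `f = 1` at the wrong-target centre.
#'
#' [default_cutoff()] is the criterion used throughout the reporting
#' functions: the line touching the start area on its left edge, i.e.
#' `f = (start width / 2) / |x_wrong|`.
#'
#' @param geometry A [display_geometry()].
#' @param fraction Cutoff fraction `f` in `[0, 1]`.
#' @return A `cutoff_spec` object: list with `fraction` and `x_cut` (px).
#' @examples
#' geom <- display_geometry(
#'   start        = c(x_center = 0, y_center = 0, width = 100, height = 100),
#'   target_left  = c(x_center = -600, y_center = 500, width = 140, height = 140),
#'   target_right = c(x_center = 600, y_center = 500, width = 140, height = 140)
#' )
#' default_cutoff(geom) # f = 50/600, x_cut = -50
#' @export
cutoff_spec <- function(geometry, fraction) {
  stopifnot(inherits(geometry, "display_geometry"))
  if (fraction < 0 || fraction > 1) {
    stop("cutoff fraction must lie in [0, 1]", call. = FALSE)
  }
  g <- as_canonical(geometry)
  # in the flipped frame the wrong target is the left one
  x_wrong <- g$target_left$x_center
  structure(
    list(fraction = fraction, x_cut = -fraction * abs(x_wrong)),
    class = "cutoff_spec"
  )
}

#' @rdname cutoff_spec
#' @export
default_cutoff <- function(geometry) {
  g <- as_canonical(geometry)
  x_wrong <- abs(g$target_left$x_center)
  f <- if (x_wrong == 0) 0 else (g$start$width / 2) / x_wrong
  cutoff_spec(geometry, f)
}

#' @export
print.cutoff_spec <- function(x, ...) {
  cat(sprintf("<cutoff_spec> fraction %.4f (x_cut = %g px)\n",
              x$fraction, x$x_cut))
  invisible(x)
}

#' Classify movements as multi-step by the vertical cutoff
#'
#' A movement is multi-step if any of its truncated raw samples lies
#' strictly beyond the cutoff line, i.e. has x < `x_cut` in the canonical
#' flipped frame (a sample exactly on the line does not count).
#' Classification is evaluated on the truncated raw samples rather than
#' the resampled path, so brief excursions between resampling knots are
#' not missed.
#'
#' @param movement Truncated movement samples from [truncate_movements()].
#' @param cutoff A [cutoff_spec()].
#' @return A tibble with one row per trial: `participant`, `trial`,
#'   `min_x` (px) and logical `multistep`.
#' @export
is_multistep <- function(movement, cutoff) {
  stopifnot(inherits(cutoff, "cutoff_spec"))
  mx <- movement_min_x(movement)
  mx$multistep <- mx$min_x < cutoff$x_cut
  mx
}

movement_min_x <- function(movement) {
  groups <- split_trials(movement)
  x <- movement$x
  meta <- trial_meta(movement, groups)
  tibble::tibble(
    participant = meta$participant, trial = meta$trial,
    min_x = unname(vapply(groups, function(idx) min(x[idx]), numeric(1)))
  )
}

#' Per-participant percentage of cutoff-classified trials (%CC)
#'
#' For each participant and compatibility condition, the percentage of
#' analysed trials classified as multi-step movements by the cutoff
#' criterion.
#'
#' @param trials A per-trial tibble with columns `participant`,
#'   `compatibility` and logical `multistep` (e.g. the analysis set of a
#'   classified [rec_data] object).
#' @return A tibble `participant` x `compatibility` with `n_trials`,
#'   `n_multistep`, `pct_cc`.
#' @export
percent_cc <- function(trials) {
  stopifnot(all(c("participant", "compatibility", "multistep") %in%
                  names(trials)))
  out <- trials |>
    dplyr::group_by(.data$participant, .data$compatibility) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_multistep = sum(.data$multistep),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct_cc = 100 * .data$n_multistep / .data$n_trials)
  # participants missing a condition cannot enter the paired comparison
  counts <- table(out$participant)
  incomplete <- names(counts)[counts < 2]
  if (length(incomplete) > 0) {
    warning("participant(s) without trials in one condition: ",
            paste(incomplete, collapse = ", "), call. = FALSE)
  }
  out
}

#' Sweep the cutoff fraction and trace the compatibility effect size
#'
#' Relaxes the cutoff from its default location (the left edge of the
#' start area) toward the wrong-target centre. At each fraction `f` of
#' the grid, trials classified multi-step at that cutoff are excluded,
#' per-participant condition means of the chosen measure are recomputed,
#' and the paired compatibility test (t, p, Cohen's dz) is run.
#' Participants lacking trials in either condition cell at some `f` are
#' dropped at that `f` (their number is recorded).
#'
#' @param data A classified [rec_data] object (see [classify_multistep()]),
#'   or a per-trial tibble with `participant`, `compatibility`, `min_x`
#'   and the measure column.
#' @param geometry A [display_geometry()] (taken from `data` when it is a
#'   `rec_data` object).
#' @param fractions Increasing grid of cutoff fractions in
#'   `[default_f, 1]`. Default: `default_f` to 1 in steps of 0.025.
#' @param measure Measure column to analyse (default `"auc_px2"`).
#' @return A tibble of class `rec_sweep`: one row per fraction with
#'   `fraction`, `x_cut`, `n_excluded`, `n_participants`, `t`, `df`, `p`,
#'   `dz`, and per-condition %CC columns. The default fraction is stored
#'   in attribute `"default_f"`.
#' @export
cutoff_sweep <- function(data, geometry = NULL, fractions = NULL,
                         measure = "auc_px2") {
  if (inherits(data, "rec_data")) {
    geometry <- data$geometry
    trials <- analysis_set(data)
  } else {
    trials <- data
  }
  if (is.null(geometry)) stop("geometry required", call. = FALSE)
  stopifnot(all(c("participant", "compatibility", "min_x", measure) %in%
                  names(trials)))
  f0 <- default_cutoff(geometry)$fraction
  if (is.null(fractions)) {
    fractions <- seq(f0, 1, by = 0.025)
    if (max(fractions) < 1) fractions <- c(fractions, 1)
  }
  if (any(diff(fractions) <= 0)) {
    stop("fractions must be strictly increasing", call. = FALSE)
  }
  if (min(fractions) < f0 - 1e-12 || max(fractions) > 1 + 1e-12) {
    stop("fractions must lie in [default_f, 1]", call. = FALSE)
  }
  g <- as_canonical(geometry)
  x_wrong <- abs(g$target_left$x_center)

  rows <- lapply(fractions, function(f) {
    x_cut <- -f * x_wrong
    keep <- trials$min_x >= x_cut
    kept <- trials[keep, , drop = FALSE]
    means <- kept |>
      dplyr::group_by(.data$participant, .data$compatibility) |>
      dplyr::summarise(m = mean(.data[[measure]]), .groups = "drop")
    res <- paired_t(means, value = "m")
    pcc <- trials |>
      dplyr::group_by(.data$compatibility) |>
      dplyr::summarise(pct = 100 * mean(.data$min_x < x_cut), .groups = "drop")
    tibble::tibble(
      fraction = f, x_cut = x_cut, n_excluded = sum(!keep),
      n_participants = res$n_participants,
      t = res$t, df = res$df, p = res$p, dz = res$dz,
      pct_cc_compatible = pcc$pct[pcc$compatibility == "compatible"],
      pct_cc_incompatible = pcc$pct[pcc$compatibility == "incompatible"]
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "default_f") <- f0
  attr(out, "measure") <- measure
  class(out) <- c("rec_sweep", class(out))
  out
}
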