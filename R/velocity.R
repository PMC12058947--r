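#' Instantaneous speed along a time-normalized movement
#'
#' Speed between consecutive points of the time-normalized path, with
#' physical time restored from the movement time: with N points over
#' `mt_ms` milliseconds, each step spans `mt_ms / (N - 1)` ms, so
#' `v_i = ||p[i+1] - p[i]|| / (mt_ms / (N - 1))` in px/ms, for
#' i = 0..N-2. Using the same time-normalized grid that the measures use
#' keeps the MAD step index consistent between the two.
#'
#' @param normalized A normalized-trajectory tibble from
#'   [normalize_time()].
#' @return A tibble with one row per trial and inter-sample step:
#'   metadata, `step` (0-based index of the step's left point), `speed`
#'   (px/ms).
#' @export
trial_speeds <- function(normalized) {
  groups <- split_trials(normalized)
  x <- normalized$x; y <- normalized$y
  nt <- length(groups)
  first <- vapply(groups, `[`, integer(1), 1L)
  mt <- normalized$mt_ms[first]
  vs <- vector("list", nt)
  for (i in seq_len(nt)) {
    idx <- groups[[i]]
    n <- length(idx)
    dt <- mt[i] / (n - 1)
    vs[[i]] <- sqrt(diff(x[idx])^2 + diff(y[idx])^2) / dt
  }
  lens <- lengths(vs)
  meta <- trial_meta(normalized, groups)
  out <- meta[rep(seq_len(nt), lens), , drop = FALSE]
  out$step <- unlist(lapply(lens, function(l) 0:(l - 1)), use.names = FALSE)
  out$speed <- unlist(vs, use.names = FALSE)
  tibble::as_tibble(out)
}

resample_curve <- function(v, m) {
  if (length(v) == 1) return(rep(v, m))
  stats::approx(seq(0, 1, length.out = length(v)), v,
                xout = seq(0, 1, length.out = m))$y
}

#' Pre/post-MAD velocity profiles
#'
#' For each trial the instantaneous speed curve is split at the time step
#' of the maximum absolute deviation (MAD) and each part is
#' time-normalized again to `m` points over its own 0-100% time axis.
#' This per-movement temporal alignment is what makes averaging
#' meaningful: two movements may reach their MAD at the same point in
#' space but at very different times, and aligning at the MAD step keeps
#' the deceleration/re-acceleration signature of multi-step movements
#' from being smeared out.
#'
#' Trials whose MAD step lies at either end of the path (e.g. perfectly
#' straight movements) have an empty segment and are excluded from the
#' profiles only; their number is recorded in the `"n_skipped"`
#' attribute.
#'
#' @param normalized A normalized-trajectory tibble from
#'   [normalize_time()].
#' @param trials A per-trial tibble with `participant`, `trial`,
#'   `mad_index` (see [trial_measures()]) and any grouping columns to
#'   carry (e.g. `multistep`).
#' @param m Resolution of each renormalized segment (default 101).
#' @return A tibble with one row per trial, segment and percent step:
#'   trial identifiers, carried columns, `segment` (`"pre"`/`"post"`),
#'   `percent` (0-100), `speed` (px/ms). Attribute `"n_skipped"` counts
#'   endpoint-MAD trials.
#' @export
speed_profiles <- function(normalized, trials, m = 101) {
  stopifnot(all(c("participant", "trial", "mad_index") %in% names(trials)))
  groups <- split_trials(normalized)
  x <- normalized$x; y <- normalized$y
  nt <- length(groups)
  first <- vapply(groups, `[`, integer(1), 1L)
  mt <- normalized$mt_ms[first]
  meta <- trial_meta(normalized, groups)
  key <- paste(meta$participant, meta$trial, sep = "\r")
  tkey <- paste(trials$participant, trials$trial, sep = "\r")
  mad_index <- trials$mad_index[match(key, tkey)]

  pre <- post <- vector("list", nt)
  keep <- logical(nt)
  for (i in seq_len(nt)) {
    idx <- groups[[i]]
    n <- length(idx)
    k <- mad_index[i]
    if (is.na(k) || k < 1 || k > n - 2) next
    dt <- mt[i] / (n - 1)
    v <- sqrt(diff(x[idx])^2 + diff(y[idx])^2) / dt
    # v has n-1 entries indexed 0..n-2; pre-MAD steps 0..k-1, post k..n-2
    pre[[i]] <- resample_curve(v[seq_len(k)], m)
    post[[i]] <- resample_curve(v[(k + 1):(n - 1)], m)
    keep[i] <- TRUE
  }
  n_skipped <- sum(!keep & !is.na(mad_index))
  if (n_skipped > 0) {
    warning(n_skipped, " trial(s) with MAD at a path endpoint excluded ",
            "from velocity profiles", call. = FALSE)
  }
  kept <- which(keep)
  carry <- setdiff(names(trials), c("mad_index", names(meta)))
  meta_k <- meta[kept, , drop = FALSE]
  if (length(carry) > 0) {
    meta_k <- cbind(meta_k,
                    trials[match(key[kept], tkey), carry, drop = FALSE])
  }
  percent <- seq(0, 100, length.out = m)
  out <- meta_k[rep(seq_along(kept), each = 2 * m), , drop = FALSE]
  out$segment <- rep(rep(c("pre", "post"), each = m), length(kept))
  out$percent <- rep(percent, 2 * length(kept))
  out$speed <- unlist(
    lapply(kept, function(i) c(pre[[i]], post[[i]])),
    use.names = FALSE
  )
  out <- tibble::as_tibble(out)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Average velocity profiles by group
#'
#' Pointwise arithmetic mean of the pre- and post-MAD speed curves within
#' each group. Averaging is linear: pooling two sets of profiles gives
#' the count-weighted mean of their group averages.
#'
#' @param profiles Per-trial profiles from [speed_profiles()].
#' @param by Character vector of grouping columns (e.g. `"multistep"` or
#'   `"compatibility"`). Empty for a single overall group.
#' @return A tibble of class `velocity_profiles`: grouping columns,
#'   `segment`, `percent`, `speed` (mean, px/ms), `n` (trials).
#' @export
average_profiles <- function(profiles, by = character(0)) {
  stopifnot(all(by %in% names(profiles)))
  out <- profiles |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(by, "segment", "percent")
    ))) |>
    dplyr::summarise(
      speed = mean(.data$speed), n = dplyr::n(), .groups = "drop"
    )
  class(out) <- c("velocity_profiles", class(out))
  out
}
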