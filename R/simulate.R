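#' Minimum-jerk time course
#'
#' Position fraction and speed of the minimum-jerk profile, the standard
#' smooth point-to-point movement model: a movement of extent L and
#' duration T has path position `L * (10 tau^3 - 15 tau^4 + 6 tau^5)` and
#' speed `L/T * (30 tau^2 - 60 tau^3 + 30 tau^4)` at normalized time
#' `tau` in [0, 1] — a bell-shaped speed curve starting and ending at
#' rest.
#'
#' @param tau Normalized time in [0, 1].
#' @return Position fraction (dimensionless) or speed fraction (units of
#'   L/T).
#' @export
min_jerk_position <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' @rdname min_jerk_position
#' @export
min_jerk_speed <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  30 * tau^2 - 60 * tau^3 + 30 * tau^4
}

#' Default simulated display geometry
#'
#' A 1920x1080 screen-frame (y-down) layout: 100x100 px start area at the
#' bottom centre and 140x140 px targets 600 px to each side and 600 px
#' above the start centre.
#'
#' @return A [display_geometry()] with `frame = "screen"`.
#' @export
rec_sim_geometry <- function() {
  display_geometry(
    start        = c(x_center = 960, y_center = 940, width = 100, height = 100),
    target_left  = c(x_center = 360, y_center = 340, width = 140, height = 140),
    target_right = c(x_center = 1560, y_center = 340, width = 140, height = 140),
    frame = "screen"
  )
}

#' Parameters of the synthetic-experiment generator
#'
#' Defaults encode the study conditions the package is designed around: a
#' two-level compatibility factor varied trial-wise, multi-step
#' (initially wrong-direction) movements more frequent under incompatible
#' mappings (9.8% vs 17.5%), and initiation times slower for incompatible
#' trials (639 vs 693 ms). Single-step movement paths are identically
#' distributed across conditions, so by construction any compatibility
#' effect in the spatial measures enters only through the multi-step
#' trials; `execution_bias_px` can inject a genuine execution-level
#' curvature effect (px of extra control-point offset toward the wrong
#' target in incompatible trials) for power studies.
#'
#' @param n_participants Number of participants.
#' @param n_trials Trials per condition per participant.
#' @param p_multistep Named probabilities of a multi-step trial per
#'   condition.
#' @param it_mean_ms,it_sd_ms Lognormal initiation-time mean (named per
#'   condition) and SD, ms.
#' @param it_participant_sd_ms SD of the per-participant initiation-time
#'   intercept (between-participant speed differences), ms.
#' @param it_effect_sd_ms SD of the per-participant compatibility effect
#'   on initiation time (zero-mean, so condition means are preserved),
#'   ms. Sized so the simulated within-subject effect size for IT is
#'   near the values reported for real response-effect compatibility
#'   data (dz around 1.3) rather than implausibly large.
#' @param p_multistep_concentration Concentration of the Beta
#'   distribution from which each participant-by-condition multi-step
#'   probability is drawn (mean fixed at `p_multistep`); `Inf` disables
#'   the heterogeneity. The default gives between-participant %CC spread
#'   comparable to published data (dz near 0.9).
#' @param mt_mean_ms,mt_sd_ms Lognormal submovement-duration mean and SD,
#'   ms.
#' @param sample_interval_ms Cursor sampling interval (default 10 ms, i.e.
#'   100 Hz logging).
#' @param path_noise_sd Gaussian positional noise per movement sample, px.
#' @param curvature_sd_px SD of the lateral (perpendicular) offset of the
#'   single-step path's control point, px.
#' @param wrong_excursion_range Range (fractions of the start-to-wrong-
#'   target distance) of the multi-step first submovement's extent.
#' @param turn_dwell_ms Range of the pause at the turn point, ms.
#' @param execution_bias_px Extra incompatible-condition control-point
#'   offset, px (default 0: no execution-level effect).
#' @param p_error Probability of a response error (movement to the wrong
#'   target).
#' @param geometry A [display_geometry()] (default [rec_sim_geometry()]).
#' @param seed Default seed used by [simulate_rec_experiment()].
#' @return A list of class `rec_sim_params`.
#' @export
rec_sim_params <- function(n_participants = 40,
                           n_trials = 200,
                           p_multistep = c(compatible = 0.098,
                                           incompatible = 0.175),
                           it_mean_ms = c(compatible = 639,
                                          incompatible = 693),
                           it_sd_ms = 120,
                           it_participant_sd_ms = 80,
                           it_effect_sd_ms = 40,
                           p_multistep_concentration = 40,
                           mt_mean_ms = 650,
                           mt_sd_ms = 200,
                           sample_interval_ms = 10,
                           path_noise_sd = 1.5,
                           curvature_sd_px = 450,
                           wrong_excursion_range = c(0.15, 0.60),
                           turn_dwell_ms = c(40, 160),
                           execution_bias_px = 0,
                           p_error = 0.02,
                           geometry = rec_sim_geometry(),
                           seed = 1) {
  p <- as.list(environment())
  stopifnot(
    all(p$p_multistep >= 0 & p$p_multistep <= 1),
    p$p_error >= 0 && p$p_error <= 1,
    p$it_sd_ms >= 0, p$mt_sd_ms >= 0, p$path_noise_sd >= 0,
    p$it_participant_sd_ms >= 0, p$it_effect_sd_ms >= 0,
    p$p_multistep_concentration > 0,
    p$sample_interval_ms > 0,
    length(p$wrong_excursion_range) == 2,
    diff(p$wrong_excursion_range) >= 0,
    all(p$wrong_excursion_range >= 0 & p$wrong_excursion_range <= 1)
  )
  f0 <- default_cutoff(p$geometry)$fraction
  if (p$wrong_excursion_range[1] <= f0) {
    stop("wrong_excursion_range must start above the default cutoff ",
         "fraction (", signif(f0, 3), ") so multi-step trials are ",
         "classifiable", call. = FALSE)
  }
  structure(p, class = "rec_sim_params")
}

# lognormal draws parameterized by mean and sd on the natural (ms) scale
rlnorm_ms <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

clamp <- function(v, lim) pmin(pmax(v, -lim), lim)

# one simulated trial in canonical coordinates relative to the start-area
# centre (y up); returns t/x/y vectors plus nominal timing
sim_trial <- function(kind, cond, correct_dir, p, geom_rel,
                      it_mean = p$it_mean_ms[[cond]]) {
  dt <- p$sample_interval_ms
  it <- rlnorm_ms(1, it_mean, p$it_sd_ms)
  s <- clamp(stats::rnorm(2, 0, 4), geom_rel$start_half - 10)
  tx <- geom_rel$dx * correct_dir
  ty <- geom_rel$dy
  wrong <- c(-tx, ty)
  goal <- if (kind == "error") wrong else c(tx, ty)
  e <- goal + clamp(stats::rnorm(2, 0, 18), geom_rel$target_half - 15)

  # perpendicular unit vector pointing toward the wrong-target side
  d <- e - s
  perp <- correct_dir * c(-d[2], d[1]) / sqrt(sum(d^2))
  bias <- if (cond == "incompatible") p$execution_bias_px else 0

  if (kind == "multistep") {
    u <- stats::runif(1, p$wrong_excursion_range[1], p$wrong_excursion_range[2])
    # turn point: fraction u of the horizontal wrong-target distance,
    # along the line from the movement start toward the wrong target
    m <- s + u * (wrong - s)
    d1 <- 0.3 * rlnorm_ms(1, p$mt_mean_ms, p$mt_sd_ms)
    dwell <- stats::runif(1, p$turn_dwell_ms[1], p$turn_dwell_ms[2])
    d2 <- 0.55 * rlnorm_ms(1, p$mt_mean_ms, p$mt_sd_ms)
    o2 <- stats::rnorm(1, 0, 15)
    dur <- d1 + dwell + d2
    pos <- function(tm) {
      if (tm < d1) {
        tau <- min_jerk_position(tm / d1)
        s + tau * (m - s)
      } else if (tm < d1 + dwell) {
        m
      } else {
        tau <- min_jerk_position((tm - d1 - dwell) / d2)
        dd <- e - m
        pp <- correct_dir * c(-dd[2], dd[1]) / sqrt(sum(dd^2))
        c2 <- (m + e) / 2 + o2 * pp
        (1 - tau)^2 * m + 2 * tau * (1 - tau) * c2 + tau^2 * e
      }
    }
  } else {
    o <- stats::rnorm(1, bias, p$curvature_sd_px)
    ctrl <- (s + e) / 2 + o * perp
    # single-step movements keep net drive toward the correct side: the
    # control point never crosses into the start column, so by
    # construction they stay on the correct side of any cutoff at or
    # beyond the start area's far edge (large lateral offsets bend the
    # path upward, not backward)
    ctrl[1] <- correct_dir * max(correct_dir * ctrl[1], geom_rel$start_half)
    dur <- max(150, rlnorm_ms(1, p$mt_mean_ms, p$mt_sd_ms))
    pos <- function(tm) {
      tau <- min_jerk_position(tm / dur)
      (1 - tau)^2 * s + 2 * tau * (1 - tau) * ctrl + tau^2 * e
    }
  }

  # noise-free movement samples on the logging grid
  mov_t <- seq(0, dur + 3 * dt, by = dt)
  mov <- t(vapply(pmin(mov_t, dur), pos, numeric(2)))

  # anchor movement onset so that the first sample outside the start area
  # falls on the drawn initiation time (the analysis measures IT at
  # start-area exit, not at kinematic onset)
  outside <- abs(mov[, 1]) > geom_rel$start_half |
    abs(mov[, 2]) > geom_rel$start_half
  k_exit <- which(outside)[1] - 1L
  if (is.na(k_exit)) k_exit <- 0L
  onset_k <- max(1L, round(it / dt) - k_exit)

  dwell_t <- seq(0, by = dt, length.out = onset_k)
  times <- c(dwell_t, onset_k * dt + mov_t)
  xy <- rbind(
    matrix(s, nrow = onset_k, ncol = 2, byrow = TRUE),
    mov
  )
  n <- length(times)
  jitter_sd <- c(rep(0.3, onset_k), rep(p$path_noise_sd, length(mov_t)))
  xy <- xy + cbind(stats::rnorm(n, 0, 1), stats::rnorm(n, 0, 1)) * jitter_sd

  list(t = times, x = xy[, 1], y = xy[, 2], it_nominal = it, mt_nominal = dur)
}

#' Simulate a two-choice mouse-tracking experiment
#'
#' Generates a full synthetic dataset with known ground truth: per
#' participant and condition, a Bernoulli draw selects single-step or
#' multi-step trials; single-step trials follow a gently curved
#' minimum-jerk path from the start area to the correct target,
#' multi-step trials first launch a minimum-jerk submovement toward the
#' wrong target (reaching a uniform fraction of the wrong-target
#' distance), decelerate to a stop, dwell, and then move to the correct
#' target. Initiation times are lognormal with condition-specific means.
#' Coordinates are written in the screen frame of the accompanying
#' geometry; all randomness flows through one seeded generator, so equal
#' seeds give identical output.
#'
#' @param params A [rec_sim_params()] list.
#' @param seed Integer seed (default `params$seed`).
#' @return A list of class `rec_sim`: `samples` (trajectory-log tibble,
#'   see [read_trajectories()]), `geometry`, `truth` (one row per trial:
#'   `participant`, `trial`, `compatibility`, `correct_side`,
#'   `multistep`, `response_error`, `it_nominal_ms`, `mt_nominal_ms`),
#'   `params`, `seed`.
#' @examples
#' sim <- simulate_rec_experiment(rec_sim_params(n_participants = 2,
#'                                               n_trials = 10))
#' dplyr::count(sim$truth, compatibility, multistep)
#' @export
simulate_rec_experiment <- function(params = rec_sim_params(),
                                    seed = params$seed) {
  stopifnot(inherits(params, "rec_sim_params"))
  set.seed(seed)
  geom <- params$geometry
  gc_ <- as_canonical(geom)
  geom_rel <- list(
    dx = gc_$target_right$x_center,
    dy = gc_$target_right$y_center,
    start_half = gc_$start$width / 2,
    target_half = gc_$target_right$width / 2
  )
  sgn <- if (geom$frame == "screen") -1 else 1
  ox <- geom$start$x_center
  oy <- geom$start$y_center

  n_per <- 2 * params$n_trials
  conds <- c("compatible", "incompatible")

  res_t <- res_x <- res_y <- vector("list", params$n_participants * n_per)
  meta <- vector("list", params$n_participants * n_per)
  k <- 0
  conc <- params$p_multistep_concentration
  for (pid in seq_len(params$n_participants)) {
    cond_seq <- sample(rep(conds, params$n_trials))
    # participant-level heterogeneity: IT intercept, zero-mean IT
    # compatibility effect, and Beta-distributed multi-step probabilities
    # whose means equal the nominal condition probabilities
    it_int <- stats::rnorm(1, 0, params$it_participant_sd_ms)
    it_eff <- stats::rnorm(1, 0, params$it_effect_sd_ms)
    it_mean_p <- c(
      compatible = params$it_mean_ms[["compatible"]] + it_int - it_eff / 2,
      incompatible = params$it_mean_ms[["incompatible"]] + it_int + it_eff / 2
    )
    it_mean_p <- pmax(it_mean_p, 200)
    p_ms_p <- vapply(conds, function(cn) {
      p0 <- params$p_multistep[[cn]]
      if (!is.finite(conc) || p0 %in% c(0, 1)) return(p0)
      stats::rbeta(1, p0 * conc, (1 - p0) * conc)
    }, numeric(1))
    for (tr in seq_len(n_per)) {
      cond <- cond_seq[tr]
      correct_side <- if (stats::runif(1) < 0.5) "left" else "right"
      is_err <- stats::runif(1) < params$p_error
      is_ms <- !is_err && stats::runif(1) < p_ms_p[[cond]]
      kind <- if (is_err) "error" else if (is_ms) "multistep" else "single"
      trial <- sim_trial(kind, cond,
                         if (correct_side == "right") 1 else -1,
                         params, geom_rel, it_mean = it_mean_p[[cond]])
      k <- k + 1
      res_t[[k]] <- trial$t
      res_x[[k]] <- trial$x
      res_y[[k]] <- trial$y
      meta[[k]] <- list(
        participant = pid, trial = tr, compatibility = cond,
        correct_side = correct_side, response_error = is_err,
        multistep = is_ms, it_nominal = trial$it_nominal,
        mt_nominal = trial$mt_nominal, n = length(trial$t)
      )
    }
  }
  lens <- vapply(meta, function(m) as.numeric(m$n), numeric(1))
  meta_df <- tibble::tibble(
    participant = vapply(meta, `[[`, numeric(1), "participant"),
    trial = vapply(meta, `[[`, numeric(1), "trial"),
    compatibility = vapply(meta, `[[`, character(1), "compatibility"),
    correct_side = vapply(meta, `[[`, character(1), "correct_side"),
    response_error = vapply(meta, `[[`, logical(1), "response_error"),
    multistep = vapply(meta, `[[`, logical(1), "multistep"),
    it_nominal_ms = vapply(meta, `[[`, numeric(1), "it_nominal"),
    mt_nominal_ms = vapply(meta, `[[`, numeric(1), "mt_nominal")
  )
  rep_idx <- rep(seq_along(lens), lens)
  x_rel <- unlist(res_x, use.names = FALSE)
  y_rel <- unlist(res_y, use.names = FALSE)
  samples <- tibble::tibble(
    participant = meta_df$participant[rep_idx],
    trial = meta_df$trial[rep_idx],
    compatibility = meta_df$compatibility[rep_idx],
    correct_side = meta_df$correct_side[rep_idx],
    response_error = meta_df$response_error[rep_idx],
    t_ms = unlist(res_t, use.names = FALSE),
    x_px = x_rel + ox,
    y_px = sgn * y_rel + oy
  )
  truth <- meta_df[, c("participant", "trial", "compatibility",
                       "correct_side", "multistep", "response_error",
                       "it_nominal_ms", "mt_nominal_ms")]
  structure(
    list(samples = samples, geometry = geom, truth = truth,
         params = params, seed = seed),
    class = "rec_sim"
  )
}

#' @export
print.rec_sim <- function(x, ...) {
  cat("<rec_sim>", nrow(x$truth), "trials,",
      x$params$n_participants, "participants, seed", x$seed, "\n")
  tab <- x$truth |>
    dplyr::group_by(.data$compatibility) |>
    dplyr::summarise(pct_multistep = 100 * mean(.data$multistep),
                     .groups = "drop")
  print(tab)
  invisible(x)
}
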