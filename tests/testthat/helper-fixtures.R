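# Shared fixtures, all built in code.

# canonical-frame geometry matching the documented example layout
test_geometry <- function() {
  display_geometry(
    start        = c(x_center = 0, y_center = 0, width = 100, height = 100),
    target_left  = c(x_center = -600, y_center = 500, width = 140, height = 140),
    target_right = c(x_center = 600, y_center = 500, width = 140, height = 140)
  )
}

# a single-trial samples tibble from coordinate vectors
make_trial <- function(x, y, t = seq(0, by = 10, length.out = length(x)),
                       participant = "p1", trial = 1,
                       compatibility = "compatible",
                       correct_side = "right", response_error = FALSE) {
  tibble::tibble(
    participant = participant, trial = trial,
    compatibility = compatibility, correct_side = correct_side,
    response_error = response_error, t_ms = t, x_px = x, y_px = y
  )
}

# straight constant-velocity trial from inside the start area into the
# right target of test_geometry(): dwell at the origin, first sample
# outside the start area at exactly t = it, first sample inside the
# target area at exactly t = it + mt (the movement runs linearly from
# (60, 48), outside the 50 px start square, to (530, 430), the target's
# lower-left corner, so no earlier sample is inside the target)
straight_trial <- function(it = 500, mt = 400, ...) {
  t_dwell <- seq(0, it - 10, by = 10)
  t_move <- seq(it, it + mt, by = 10)
  f <- (t_move - it) / mt
  make_trial(
    x = c(rep(0, length(t_dwell)), 60 + f * (530 - 60)),
    y = c(rep(0, length(t_dwell)), 48 + f * (430 - 48)),
    t = c(t_dwell, t_move), ...
  )
}

# small default-parameter simulation for unit tests
small_sim <- function(n_participants = 4, n_trials = 30, seed = 42, ...) {
  simulate_rec_experiment(
    rec_sim_params(n_participants = n_participants, n_trials = n_trials, ...),
    seed = seed
  )
}

# the full default-conditions experiment, generated once and cached for
# the acceptance checks (40 participants x 200 trials/condition, seed 1)
.accept_cache <- new.env(parent = emptyenv())
default_experiment <- function() {
  if (is.null(.accept_cache$sim)) {
    .accept_cache$sim <- simulate_rec_experiment(rec_sim_params())
    dat <- suppressWarnings(
      preprocess_trials(.accept_cache$sim$samples, .accept_cache$sim$geometry)
    )
    .accept_cache$data <- classify_multistep(dat)
  }
  list(sim = .accept_cache$sim, data = .accept_cache$data)
}

# independent shoelace oracle: signed area of the closed polygon formed
# by the path and the reversed ideal line; orientation chosen so that
# deviation toward the left of the travel direction counts positive
shoelace_auc <- function(x, y) {
  n <- length(x)
  xs <- c(x, x[1])
  ys <- c(y, y[1])
  -sum(xs[-(n + 1)] * ys[-1] - xs[-1] * ys[-(n + 1)]) / 2
}

# independent projection oracle for point-to-line signed distance
projection_deviations <- function(x, y) {
  p0 <- c(x[1], y[1])
  p1 <- c(x[length(x)], y[length(y)])
  v <- p1 - p0
  nrm <- c(-v[2], v[1]) / sqrt(sum(v^2)) # left normal
  vapply(seq_along(x), function(i) {
    sum((c(x[i], y[i]) - p0) * nrm)
  }, numeric(1))
}
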