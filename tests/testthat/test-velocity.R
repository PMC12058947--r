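norm_path <- function(x, y, mt, trial = 1, ...) {
  n <- length(x)
  tibble::tibble(
    participant = "p1", trial = trial, compatibility = "compatible",
    correct_side = "right", response_error = FALSE,
    step = 0:(n - 1), time_frac = (0:(n - 1)) / (n - 1),
    t_ms = 500 + mt * (0:(n - 1)) / (n - 1),
    x = x, y = y, it_ms = 500, mt_ms = mt, ...
  )
}

test_that("instantaneous speed recovers constant and zero velocity", {
  # 400 px in 400 ms at constant velocity: 1 px/ms everywhere
  norm <- norm_path(x = seq(0, 400, length.out = 101), y = rep(0, 101),
                    mt = 400)
  v <- trial_speeds(norm)
  expect_equal(nrow(v), 100)
  expect_equal(v$speed, rep(1, 100))

  # stationary segment: zero speed there
  x <- c(seq(0, 200, length.out = 51), rep(200, 20),
         seq(200, 400, length.out = 30))
  norm2 <- norm_path(x = x, y = rep(0, 101), mt = 400)
  v2 <- trial_speeds(norm2)
  expect_true(all(v2$speed[51:70] == 0))
})

test_that("speed along a minimum-jerk movement matches the closed form", {
  n <- 101
  mt <- 500
  L <- 800
  tau <- (0:(n - 1)) / (n - 1)
  norm <- norm_path(x = L * min_jerk_position(tau), y = rep(0, n), mt = mt)
  v <- trial_speeds(norm)$speed
  # the discrete speed over step i approximates the closed-form bell
  # profile at the interval midpoint
  v_true <- (L / mt) * min_jerk_speed((0:(n - 2) + 0.5) / (n - 1))
  expect_equal(v, v_true, tolerance = 5e-4)
  # bell shape: zero at the ends, peak 1.875 L/T in the middle
  expect_equal(max(v_true), 1.875 * L / mt, tolerance = 1e-3)
})

test_that("pre/post-MAD splitting renormalizes each segment to 0-100%", {
  # constant speed with any interior MAD index: both segments all ones
  norm <- norm_path(x = seq(0, 400, length.out = 101), y = rep(0, 101),
                    mt = 400)
  trials <- tibble::tibble(participant = "p1", trial = 1, mad_index = 30L)
  prof <- speed_profiles(norm, trials, m = 101)
  expect_equal(nrow(prof), 202)
  expect_equal(prof$speed, rep(1, 202))
  expect_setequal(unique(prof$segment), c("pre", "post"))
  expect_equal(range(prof$percent), c(0, 100))

  # two trials with MADs at steps 20 and 80 both contribute aligned
  # 0-100% curves of the same length
  norm2 <- dplyr::bind_rows(
    norm_path(x = seq(0, 400, length.out = 101), y = rep(0, 101),
              mt = 400, trial = 1),
    norm_path(x = 400 * ((0:100) / 100)^2, y = rep(0, 101),
              mt = 400, trial = 2)
  )
  trials2 <- tibble::tibble(participant = "p1", trial = c(1, 2),
                            mad_index = c(20L, 80L))
  prof2 <- speed_profiles(norm2, trials2, m = 101)
  lens <- dplyr::count(prof2, trial, segment)
  expect_true(all(lens$n == 101))

  # a linear speed ramp resamples to a linear ramp (interpolation
  # exactness on the quadratic path: v is linear in step)
  ramp <- prof2[prof2$trial == 2 & prof2$segment == "pre", ]
  expect_equal(diff(ramp$speed), rep(diff(ramp$speed)[1], 100),
               tolerance = 1e-9)
})

test_that("endpoint-MAD trials are excluded from profiles only, with a count", {
  norm <- norm_path(x = seq(0, 400, length.out = 101), y = rep(0, 101),
                    mt = 400)
  trials <- tibble::tibble(participant = "p1", trial = 1, mad_index = 0L)
  expect_warning(prof <- speed_profiles(norm, trials), "endpoint")
  expect_equal(nrow(prof), 0)
  expect_equal(attr(prof, "n_skipped"), 1)
})

test_that("profile averaging is linear in the contributing trials", {
  set.seed(12)
  n_tr <- 6
  norm <- dplyr::bind_rows(lapply(seq_len(n_tr), function(i) {
    norm_path(x = cumsum(runif(101, 0, 8)), y = cumsum(runif(101, 0, 4)),
              mt = 400, trial = i)
  }))
  trials <- tibble::tibble(
    participant = "p1", trial = seq_len(n_tr),
    mad_index = sample(20:80, n_tr), grp = rep(c("a", "b"), each = 3)
  )
  prof <- speed_profiles(norm, trials)
  overall <- average_profiles(prof)
  by_grp <- average_profiles(prof, by = "grp")
  pooled <- by_grp |>
    dplyr::group_by(segment, percent) |>
    dplyr::summarise(speed = weighted.mean(speed, n), .groups = "drop") |>
    dplyr::arrange(segment, percent)
  overall <- dplyr::arrange(tibble::as_tibble(overall), segment, percent)
  expect_equal(pooled$speed, overall$speed, tolerance = 1e-12)

  # single trial: group mean equals that trial's profile
  one <- average_profiles(prof[prof$trial == 1, ])
  one_raw <- prof[prof$trial == 1, ]
  expect_equal(
    dplyr::arrange(tibble::as_tibble(one), segment, percent)$speed,
    dplyr::arrange(one_raw, segment, percent)$speed
  )
})

test_that("generated movement classes carry their kinematic signatures", {
  sim <- small_sim(n_participants = 5, n_trials = 50, seed = 17)
  dat <- suppressWarnings(
    classify_multistep(preprocess_trials(sim$samples, sim$geometry))
  )
  tr <- trajsplit:::analysis_set(dat)
  key <- paste(dat$paths$participant, dat$paths$trial)
  paths <- dat$paths[key %in% paste(tr$participant, tr$trial), ]
  prof <- suppressWarnings(speed_profiles(
    paths, tr[, c("participant", "trial", "mad_index", "multistep")]
  ))
  avg <- average_profiles(prof, by = "multistep")
  for (cls in c(TRUE, FALSE)) {
    a <- avg[avg$multistep == cls, ]
    pre <- a$speed[a$segment == "pre"][order(a$percent[a$segment == "pre"])]
    post <- a$speed[a$segment == "post"][order(a$percent[a$segment == "post"])]
    peak <- max(c(pre, post))
    tail_min <- min(pre[81:101]) # last 20% of the pre-MAD segment
    if (cls) {
      # multi-step: deceleration into the turn, then re-acceleration
      expect_lt(tail_min, 0.5 * peak)
      expect_gt(max(post[1:21]), 3 * tail_min)
    } else {
      # single-step: smooth speed around the MAD timepoint
      expect_gt(pre[101], 0.5 * peak)
    }
  }
})
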