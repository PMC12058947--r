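geom <- test_geometry()

test_that("truncation reads IT and MT off the region crossings", {
  canon <- canonicalize(straight_trial(it = 500, mt = 400), geom)
  mov <- truncate_movements(canon, geom)
  expect_equal(unique(mov$it_ms), 500)
  expect_equal(unique(mov$mt_ms), 400)
  # movement runs from first sample outside start to first inside target
  expect_equal(mov$t_ms[1], 500)
  expect_equal(mov$t_ms[nrow(mov)], 900)
})

test_that("truncation anchors at the first start-area exit on re-entry", {
  # exits at t = 200, dips back into the start area, then exits again
  tr <- make_trial(
    x = c(0, 0, 60, 0, 0, 100, 300, 530),
    y = c(0, 0, 48, 0, 0, 80, 250, 430),
    t = c(0, 100, 200, 300, 400, 500, 600, 700)
  )
  mov <- truncate_movements(canonicalize(tr, geom), geom)
  expect_equal(unique(mov$it_ms), 200)
  expect_equal(unique(mov$mt_ms), 500)
})

test_that("truncation agrees with a brute-force membership scan", {
  sim <- small_sim(n_participants = 3, n_trials = 20)
  canon <- canonicalize(
    sim$samples[!sim$samples$response_error, , drop = FALSE],
    sim$geometry
  )
  mov <- truncate_movements(canon, sim$geometry)
  got <- dplyr::distinct(mov[, c("participant", "trial", "it_ms", "mt_ms")])

  # independent oracle: explicit per-sample scan using raw interval
  # arithmetic rather than in_region()
  oracle <- canon |>
    dplyr::group_by(participant, trial) |>
    dplyr::group_modify(function(df, key) {
      inside_start <- abs(df$x) <= 50 & abs(df$y) <= 50
      inside_target <- df$x >= 530 & df$x <= 670 & df$y >= 530 & df$y <= 670
      ex <- Position(isFALSE, inside_start)
      en <- Position(isTRUE, inside_target & seq_along(df$x) >= ex)
      if (is.null(ex) || is.null(en)) return(tibble::tibble())
      tibble::tibble(it_ms = df$t_ms[ex], mt_ms = df$t_ms[en] - df$t_ms[ex])
    }) |>
    dplyr::ungroup()
  joined <- dplyr::inner_join(got, oracle, by = c("participant", "trial"),
                              suffix = c("", ".oracle"))
  expect_equal(nrow(joined), nrow(got))
  expect_equal(joined$it_ms, joined$it_ms.oracle)
  expect_equal(joined$mt_ms, joined$mt_ms.oracle)
})

test_that("trials that never exit or never arrive are unusable, not errors", {
  never_leaves <- make_trial(x = c(0, 5, -5, 0), y = c(0, 5, 0, -5),
                             trial = 1)
  never_arrives <- make_trial(x = c(0, 100, 200, 300), y = c(0, 50, 60, 70),
                              trial = 2)
  canon <- canonicalize(dplyr::bind_rows(never_leaves, never_arrives), geom)
  expect_warning(mov <- truncate_movements(canon, geom), "unusable")
  expect_equal(nrow(mov), 0)
  un <- attr(mov, "unusable")
  expect_setequal(un$reason, c("never_left_start", "never_reached_target"))
})

test_that("time normalization reproduces endpoints and equal spacing", {
  canon <- canonicalize(straight_trial(), geom)
  mov <- truncate_movements(canon, geom)

  # N = 2 gives exactly the endpoints
  two <- normalize_time(mov, n_steps = 2)
  expect_equal(two$x, c(mov$x[1], mov$x[nrow(mov)]))
  expect_equal(two$y, c(mov$y[1], mov$y[nrow(mov)]))

  # constant-velocity movement: normalized points equally spaced in space
  norm <- normalize_time(mov, n_steps = 101)
  expect_equal(diff(norm$x), rep(diff(norm$x)[1], 100), tolerance = 1e-9)

  # input already sampled at N equally spaced times is reproduced exactly
  n_raw <- nrow(mov)
  same <- normalize_time(mov, n_steps = n_raw)
  expect_equal(same$x, mov$x, tolerance = 1e-12)
  expect_equal(same$t_ms, mov$t_ms, tolerance = 1e-12)

  # idempotence: renormalizing with the same N is the identity
  renorm <- normalize_time(norm, n_steps = 101)
  expect_equal(renorm$x, norm$x, tolerance = 1e-12)
  expect_equal(renorm$y, norm$y, tolerance = 1e-12)

  expect_error(normalize_time(mov[1, ], n_steps = 101), "at least 2")
})

test_that("IT + MT equals the target-entry timestamp for every trial", {
  sim <- small_sim(n_participants = 3, n_trials = 15)
  canon <- canonicalize(
    sim$samples[!sim$samples$response_error, , drop = FALSE], sim$geometry
  )
  mov <- truncate_movements(canon, sim$geometry)
  per_trial <- mov |>
    dplyr::group_by(participant, trial) |>
    dplyr::summarise(
      entry_t = dplyr::last(t_ms),
      it = it_ms[1], mt = mt_ms[1], .groups = "drop"
    )
  expect_equal(per_trial$it + per_trial$mt, per_trial$entry_t)
})

test_that("downward flagging uses a strict post-exit bottom-edge rule", {
  up <- straight_trial(trial = 1)
  # dips 10 px below the start area's bottom edge after exiting
  dip <- make_trial(
    x = c(0, 60, 80, 100, 300, 530),
    y = c(0, 48, -60, 80, 250, 430),
    t = seq(0, 500, by = 100), trial = 2
  )
  # touches the bottom edge exactly: not downward (strict inequality)
  edge <- make_trial(
    x = c(0, 60, 80, 100, 300, 530),
    y = c(0, 48, -50, 80, 250, 430),
    t = seq(0, 500, by = 100), trial = 3
  )
  canon <- canonicalize(dplyr::bind_rows(up, dip, edge), geom)
  flags <- flag_downward(canon, geom)
  expect_equal(flags$downward, c(FALSE, TRUE, FALSE))
})

test_that("outlier flagging matches the hand-computed cell oracle", {
  base <- tibble::tibble(
    participant = "p1", trial = 1:5, compatibility = "compatible",
    it_ms = c(10, 10, 10, 10, 100), mt_ms = 500, auc_px2 = 0, mad_px = 0
  )
  # hand oracle: mean 28, sample SD sqrt(6480/4) = 40.249; the deviation
  # |100 - 28| = 72 stays below 2.5 * 40.249 = 100.62, so nothing is
  # flagged (and constant measures have SD 0, which never flags)
  out <- flag_outliers(base)
  expect_false(any(out$outlier))

  # a genuinely extreme trial in a larger cell is flagged on that
  # measure only
  big <- tibble::tibble(
    participant = "p1", trial = 1:21, compatibility = "compatible",
    it_ms = 500, mt_ms = c(rep(10, 20), 100), auc_px2 = 0, mad_px = 0
  )
  v <- big$mt_ms
  expect_true(abs(100 - mean(v)) > 2.5 * sd(v)) # oracle arithmetic
  out2 <- flag_outliers(big)
  expect_equal(which(out2$outlier), 21L)
  expect_equal(out2$outlier_reasons[21], "MT")

  # cells below the minimum size are skipped with a warning
  expect_warning(out3 <- flag_outliers(base[1:2, ]), "fewer than 3")
  expect_false(any(out3$outlier))
})

test_that("outlier flags are invariant to trial order within a cell", {
  set.seed(77)
  cell <- tibble::tibble(
    participant = rep(c("a", "b"), each = 30),
    trial = rep(1:30, 2),
    compatibility = rep(c("compatible", "incompatible"), 30),
    it_ms = rnorm(60, 600, 100), mt_ms = rnorm(60, 400, 80),
    auc_px2 = rnorm(60, 0, 5000), mad_px = rnorm(60, 0, 40)
  )
  perm <- sample(nrow(cell))
  a <- flag_outliers(cell)
  b <- flag_outliers(cell[perm, ])[order(perm), ]
  expect_equal(a$outlier, b$outlier)
  expect_equal(a$outlier_reasons, b$outlier_reasons)
})
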