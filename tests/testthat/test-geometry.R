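test_that("a symmetric layout constructs and degenerate layouts are rejected", {
  geom <- test_geometry()
  expect_s3_class(geom, "display_geometry")
  expect_identical(geom$frame, "canonical")

  # both targets on the same side of the start area
  expect_error(
    display_geometry(
      start = c(x_center = 0, y_center = 0, width = 100, height = 100),
      target_left = c(x_center = 300, y_center = 500, width = 140, height = 140),
      target_right = c(x_center = 600, y_center = 500, width = 140, height = 140)
    ),
    "opposite sides"
  )
  # targets not above the start area
  expect_error(
    display_geometry(
      start = c(x_center = 0, y_center = 0, width = 100, height = 100),
      target_left = c(x_center = -600, y_center = 0, width = 140, height = 140),
      target_right = c(x_center = 600, y_center = 0, width = 140, height = 140)
    ),
    "above"
  )
  # asymmetric beyond tolerance, then allowed by tolerance
  args <- list(
    start = c(x_center = 0, y_center = 0, width = 100, height = 100),
    target_left = c(x_center = -590, y_center = 500, width = 140, height = 140),
    target_right = c(x_center = 600, y_center = 500, width = 140, height = 140)
  )
  expect_error(do.call(display_geometry, args), "mirror-symmetric")
  expect_s3_class(do.call(display_geometry, c(args, tol = 15)),
                  "display_geometry")
  # missing field
  expect_error(
    display_geometry(
      start = c(x_center = 0, y_center = 0, width = 100),
      target_left = c(x_center = -600, y_center = 500, width = 140, height = 140),
      target_right = c(x_center = 600, y_center = 500, width = 140, height = 140)
    ),
    "start"
  )
})

test_that("screen-frame geometry canonicalizes to the equivalent y-up layout", {
  screen <- display_geometry(
    start        = c(x_center = 960, y_center = 940, width = 100, height = 100),
    target_left  = c(x_center = 360, y_center = 340, width = 140, height = 140),
    target_right = c(x_center = 1560, y_center = 340, width = 140, height = 140),
    frame = "screen"
  )
  canon <- display_geometry(
    start        = c(x_center = 0, y_center = 0, width = 100, height = 100),
    target_left  = c(x_center = -600, y_center = 600, width = 140, height = 140),
    target_right = c(x_center = 600, y_center = 600, width = 140, height = 140)
  )
  a <- as_canonical(screen)
  b <- as_canonical(canon)
  # hand transform of one rectangle: (360, 340) in a y-down frame with the
  # start centre at (960, 940) maps to (360-960, -(340-940)) = (-600, 600)
  expect_equal(a$target_left$x_center, -600)
  expect_equal(a$target_left$y_center, 600)
  for (nm in c("start", "target_left", "target_right")) {
    expect_equal(a[[nm]], b[[nm]])
  }
})

test_that("region membership is boundary-inclusive", {
  start <- test_geometry()$start
  expect_true(in_region(50, 0, start))   # on the right edge
  expect_true(in_region(0, -50, start))  # on the bottom edge
  expect_false(in_region(50.001, 0, start))
})

test_that("geometry configs round-trip through YAML and JSON", {
  geom <- rec_sim_geometry()
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_geometry(geom, path)
    back <- read_geometry(path)
    expect_equal(back[c("start", "target_left", "target_right", "frame")],
                 geom[c("start", "target_left", "target_right", "frame")])
  }
  # missing region is a configuration error
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(start = geom$start, target_left = geom$target_left,
                        frame = "screen"), path)
  expect_error(read_geometry(path), "target_right")
})

test_that("canonicalization translates, flips left trials, and is an isometry", {
  geom <- test_geometry()
  right <- make_trial(x = c(0, 10, 80), y = c(0, 5, 90))
  out <- canonicalize(right, geom)
  expect_equal(out$x, right$x_px) # start centre already at the origin
  expect_equal(out$y, right$y_px)
  expect_false(any(out$flipped))

  left <- make_trial(x = c(0, -30, -80), y = c(0, 5, 90),
                     correct_side = "left")
  out_l <- canonicalize(left, geom)
  expect_equal(out_l$x, c(0, 30, 80))
  expect_true(all(out_l$flipped))
  # mirroring is an involution: mirroring the mirrored coordinates
  # restores the input
  expect_equal(-out_l$x, left$x_px)

  # isometry: pairwise inter-sample distances preserved (property over
  # random trajectories on both sides)
  set.seed(101)
  for (side in c("left", "right")) {
    for (rep in 1:5) {
      tr <- make_trial(x = c(0, cumsum(rnorm(9, 0, 30))),
                       y = c(0, cumsum(rnorm(9, 0, 30))),
                       correct_side = side)
      ct <- canonicalize(tr, geom)
      expect_equal(dist(cbind(ct$x, ct$y)), dist(cbind(tr$x_px, tr$y_px)),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }

  # correct target at x > 0, wrong target at x < 0 in the flipped frame
  g <- as_canonical(geom)
  expect_gt(g$target_right$x_center, 0)
  expect_lt(g$target_left$x_center, 0)

  # first sample outside the start area violates the precondition
  bad <- make_trial(x = c(200, 210, 300), y = c(0, 50, 400))
  expect_error(canonicalize(bad, geom), "start area")
  expect_warning(out <- canonicalize(bad, geom, on_violation = "drop"),
                 "dropped")
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "rejections")$reason, "first_sample_outside_start")
})
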