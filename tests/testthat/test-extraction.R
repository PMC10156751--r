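test_that("smoothing is a centered moving average with shrunken edges", {
  expect_equal(smooth_series(c(0, 3, 0), 3), c(1.5, 1.0, 1.5))
  x <- rnorm(20)
  expect_equal(smooth_series(x, 1), x)                 # window 1: identity
  expect_equal(smooth_series(rep(4, 10), 5), rep(4, 10))  # constants fixed
  expect_error(smooth_series(numeric(0), 3), "frames")
  expect_error(smooth_series(1:5, 4), "odd")
})

test_that("rapid-motion flags follow the 150%-of-previous-frame rule", {
  expect_equal(flag_rapid_motion(c(10, 16, 16)), c(FALSE, TRUE, FALSE))
  expect_false(any(flag_rapid_motion(rep(7, 50))))
  # the epsilon floor guards ratios between near-zero angles
  expect_equal(flag_rapid_motion(c(0.1, 0.2)), c(FALSE, FALSE))
  expect_equal(flag_rapid_motion(c(0.1, 1.6)), c(FALSE, TRUE))
  # magnitudes are compared: sign crossings alone do not trigger
  expect_false(any(flag_rapid_motion(c(5, -5, 5, -5))))
})

test_that("facing-forward requires yaw gate, gaze, open eyes and no rapid motion", {
  cfg <- extraction_config()
  n <- 10
  base <- frame_stream(yaw_deg = rep(0, n), gaze_on_screen = rep(TRUE, n),
                       eyes_open = rep(TRUE, n), au45 = rep(0, n),
                       confidence = rep(1, n))
  expect_true(all(facing_forward_mask(base, cfg)))
  shut <- base; shut$eyes_open <- rep(FALSE, n)
  expect_false(any(facing_forward_mask(shut, cfg)))
  off <- base; off$gaze_on_screen <- rep(FALSE, n)
  expect_false(any(facing_forward_mask(off, cfg)))
  # yaw 10 deg for frames 1-5, then 30 deg: the second half fails the gate
  turn <- base; turn$yaw_deg <- c(rep(10, 5), rep(30, 5))
  expect_equal(facing_forward_mask(turn, cfg),
               oracle_facing(turn, cfg))
  expect_true(all(facing_forward_mask(turn, cfg)[1:4]))
  expect_false(any(facing_forward_mask(turn, cfg)[6:10]))
})

test_that("facing mask matches the brute-force oracle on random streams", {
  cfg <- extraction_config()
  set.seed(101)
  for (rep_i in 1:50) {
    st <- random_stream(sample(5:50, 1))
    expect_equal(facing_forward_mask(st, cfg), oracle_facing(st, cfg))
  }
})

test_that("TFF is the percent of facing frames", {
  expect_equal(total_facing_forward(rep(TRUE, 8)), 100)
  expect_equal(total_facing_forward(c(rep(TRUE, 5), rep(FALSE, 5))), 50)
  expect_true(is.na(total_facing_forward(logical(0))))
})

test_that("valid frames require facing plus confidence at or above 0.75", {
  expect_true(all(valid_frame_mask(rep(TRUE, 3), rep(0.9, 3))))
  # boundary: exactly 0.75 is valid
  expect_true(valid_frame_mask(TRUE, 0.75))
  expect_false(valid_frame_mask(TRUE, 0.7499))
  expect_false(any(valid_frame_mask(rep(FALSE, 3), rep(1, 3))))
  expect_error(valid_frame_mask(rep(TRUE, 3), rep(1, 2)), "length")
})

test_that("blink detection finds pulse apexes and enforces separation", {
  cfg <- extraction_config()
  expect_equal(detect_blinks(rep(0, 100), cfg), integer(0))
  # single triangular pulse: one blink at the apex
  pulse <- c(rep(0, 10), 1, 2, 3, 2, 1, rep(0, 10))
  expect_equal(detect_blinks(pulse, cfg), 13L)
  # 20 well-separated identical pulses -> 20 blinks
  many <- rep(c(rep(0, 10), 1, 3, 1, rep(0, 7)), 20)
  expect_equal(length(detect_blinks(many, cfg)), 20)
  # close pair: the higher apex wins
  close_pair <- c(0, 1, 3, 1, 4, 1, 0)
  got <- detect_blinks(close_pair, extraction_config(
    au45_smooth_window = 1, blink_min_separation = 3))
  expect_equal(got, 5L)
})

test_that("blink detection matches the brute-force oracle on random series", {
  cfg <- extraction_config()
  set.seed(202)
  for (rep_i in 1:50) {
    au <- pmax(0, rnorm(sample(5:50, 1), 0.8, 1.5))
    expect_equal(detect_blinks(au, cfg), oracle_blinks(au, cfg))
  }
})

test_that("blink rate normalizes by valid minutes and gates on apex validity", {
  # 20 blinks over one valid minute -> 20 blinks/min
  valid <- rep(TRUE, 1800)
  blinks <- seq(10, 1790, length.out = 20)
  expect_equal(blink_rate(round(blinks), valid, fps = 30), 20)
  # doubling valid time at the same event pattern halves the rate
  valid2 <- rep(TRUE, 3600)
  expect_equal(blink_rate(round(blinks), valid2, fps = 30), 10)
  expect_true(is.na(blink_rate(integer(0), rep(FALSE, 100))))
  # blinks only on invalid frames count zero
  v <- rep(c(TRUE, FALSE), each = 50)
  expect_equal(blink_rate(c(60L, 70L), v, fps = 30), 0)
})

test_that("gaze-percent-social respects side and excludes off-screen frames", {
  on <- rep(TRUE, 10)
  expect_equal(gaze_percent_social(on, rep(0.2, 10), "left"), 100)
  expect_equal(gaze_percent_social(on, rep(c(0.2, 0.8), 5), "left"), 50)
  # off-screen frames drop from the denominator
  half_off <- rep(c(TRUE, FALSE), 5)
  expect_equal(gaze_percent_social(half_off, rep(0.9, 10), "right"), 100)
  expect_true(is.na(gaze_percent_social(rep(FALSE, 5), rep(0.5, 5),
                                        "left")))
  expect_error(gaze_percent_social(on, rep(0.5, 10), "none"), "mixed")
})

test_that("raising yaw threshold never lowers TFF; raising the confidence floor never adds valid frames", {
  set.seed(303)
  st <- random_stream(200)
  thresholds <- c(5, 15, 25, 45, 90)
  tffs <- vapply(thresholds, function(th) {
    total_facing_forward(facing_forward_mask(
      st, extraction_config(yaw_threshold_deg = th)))
  }, numeric(1))
  expect_true(all(diff(tffs) >= 0))
  facing <- facing_forward_mask(st, extraction_config())
  nv <- vapply(c(0.5, 0.75, 0.9), function(ct) {
    sum(valid_frame_mask(facing, st$confidence, ct))
  }, numeric(1))
  expect_true(all(diff(nv) <= 0))
})

test_that("extraction config validates fields and round-trips YAML/JSON", {
  expect_error(extraction_config(yaw_smooth_window = 4), "odd")
  expect_error(extraction_config(blink_min_height = -1), ">= 0")
  cfg <- extraction_config(yaw_threshold_deg = 20, blink_min_height = 1.5)
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_extraction_config(cfg, path)
    expect_equal(read_extraction_config(path), cfg)
  }
})
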