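test_that("derivatives of constant and ramp images match hand computation", {
  const <- matrix(1, 6, 6)
  d <- compute_derivatives(const, const)
  expect_equal(dim(d$f_x), c(5, 5))
  expect_true(all(d$f_x == 0) && all(d$f_y == 0) && all(d$f_t == 0))

  # ramp f(x, y) = x: the 2-tap derivative filter (0.5, -0.5) on a unit
  # ramp gives 0.5 everywhere; no y-gradient, no temporal change
  ramp <- matrix(rep(1:6, each = 6), 6, 6)
  d <- compute_derivatives(ramp, ramp)
  expect_equal(d$f_x, matrix(0.5, 5, 5))
  expect_equal(d$f_y, matrix(0, 5, 5))
  expect_equal(d$f_t, matrix(0, 5, 5))

  # y-ramp by symmetry
  d <- compute_derivatives(t(ramp), t(ramp))
  expect_equal(d$f_y, matrix(0.5, 5, 5))
  expect_equal(d$f_x, matrix(0, 5, 5))
})

test_that("a uniform brightness step appears only in the temporal term", {
  base <- matrix(runif(36), 6, 6)
  d <- compute_derivatives(base + 0.2, base)
  d0 <- compute_derivatives(base, base)
  expect_equal(d$f_x, d0$f_x, tolerance = 1e-12)
  expect_equal(d$f_y, d0$f_y, tolerance = 1e-12)
  # temporal difference is half the frame difference, smoothed
  expect_equal(d$f_t, d0$f_t + 0.1, tolerance = 1e-12)
})

test_that("mismatched or degenerate frames are rejected", {
  expect_error(compute_derivatives(matrix(0, 3, 3), matrix(0, 4, 4)),
               class = "leaftrack_error_motion")
  expect_error(compute_derivatives(matrix(0, 1, 5), matrix(0, 1, 5)),
               class = "leaftrack_error_motion")
})

test_that("a zero derivative field is flagged as ill-conditioned", {
  d <- compute_derivatives(matrix(1, 8, 8), matrix(1, 8, 8))
  est <- estimate_translation(d)
  expect_false(est$condition_ok)
  expect_true(is.na(est$v_y))
})

test_that("translation estimates match the brute-force SSD oracle", {
  sc <- test_scene()
  cases <- list(c(0, 0.5), c(0.3, -0.4), c(-0.6, 0.2), c(0.9, 0.9))
  for (shift in cases) {
    pair <- shifted_pair(sc, shift[1], shift[2])
    est <- estimate_translation(compute_derivatives(pair$cur, pair$prev))
    expect_true(est$condition_ok)
    orc <- oracle_translation(sc, pair$cur)
    expect_equal(orc[1], shift[1], tolerance = 0.01)  # oracle sanity
    expect_equal(orc[2], shift[2], tolerance = 0.01)
    expect_lt(abs(est$v_x - orc[1]), 0.05)
    expect_lt(abs(est$v_y - orc[2]), 0.05)
  }
})

test_that("time reversal negates the estimate on noise-free pairs", {
  sc <- test_scene()
  pair <- shifted_pair(sc, 0.4, -0.7)
  fwd <- estimate_translation(compute_derivatives(pair$cur, pair$prev))
  rev <- estimate_translation(compute_derivatives(pair$prev, pair$cur))
  expect_lt(abs(fwd$v_x + rev$v_x), 0.02)
  expect_lt(abs(fwd$v_y + rev$v_y), 0.02)
})

test_that("transposing both frames swaps v_x and v_y exactly", {
  sc <- test_scene()
  pair <- shifted_pair(sc, 0.35, -0.15)
  est <- estimate_translation(compute_derivatives(pair$cur, pair$prev))
  est_t <- estimate_translation(
    compute_derivatives(t(pair$cur), t(pair$prev))
  )
  expect_identical(est_t$v_x, est$v_y)
  expect_identical(est_t$v_y, est$v_x)
})

test_that("a constant brightness offset leaves the estimate unchanged", {
  sc <- test_scene()
  pair <- shifted_pair(sc, 0.2, 0.6)
  est <- estimate_translation(compute_derivatives(pair$cur, pair$prev))
  est_off <- estimate_translation(
    compute_derivatives(pair$cur + 0.07, pair$prev + 0.07)
  )
  expect_lt(abs(est$v_x - est_off$v_x), 1e-10)
  expect_lt(abs(est$v_y - est_off$v_y), 1e-10)
})

test_that("error grows monotonically once shifts leave the linear regime", {
  sc <- test_scene()
  shifts <- c(0.5, 1, 2, 3, 4)
  errs <- vapply(shifts, function(s) {
    pair <- shifted_pair(sc, 0, s)
    est <- estimate_translation(compute_derivatives(pair$cur, pair$prev))
    abs(est$v_y - s)
  }, numeric(1))
  expect_lt(errs[1], 0.05)
  # degradation beyond the ~2 px small-motion regime
  expect_true(all(diff(errs[3:5]) > 0))
  expect_gt(errs[5], errs[2])
})

test_that("tracking a static scene gives an identically zero v_y", {
  st <- simulate_image_sequence(test_scene(amplitude = 0, duration_h = 3))
  tr <- track_stack(st)
  expect_equal(tr$v_y, rep(0, nrow(tr)), tolerance = 1e-9)
  expect_equal(tr$v_x, rep(0, nrow(tr)), tolerance = 1e-9)
  expect_false(any(tr$interpolated))
  # pair midpoints on the uniform grid
  expect_equal(tr$time_hr, (seq_len(nrow(tr)) - 0.5) / 3, tolerance = 1e-12)
})

test_that("reversing the frame order negates the motion trace", {
  st <- simulate_image_sequence(test_scene(duration_h = 12))
  tr <- track_stack(st)
  rev_st <- image_stack(rev(st$frames), st$sampling_interval_min)
  tr_rev <- track_stack(rev_st)
  expect_equal(tr_rev$v_y, -rev(tr$v_y), tolerance = 1e-8)
})

test_that("ill-conditioned pairs are interpolated and flagged", {
  sc <- test_scene(amplitude = 0)
  blob <- render_blob_frame(sc)
  flat <- matrix(sc$background, 64, 64)
  st <- image_stack(list(blob, flat, flat, blob), 20)
  tr <- track_stack(st)
  expect_identical(tr$interpolated, c(FALSE, TRUE, FALSE))
  expect_true(all(is.finite(tr$v_y)))
})

test_that("tracked oscillation reproduces the scene's analytic velocity", {
  sc <- test_scene(duration_h = 24)
  st <- simulate_image_sequence(sc)
  tr <- track_stack(st)
  # per-step displacement of the blob center between consecutive frames
  t_frames <- stack_times_hr(st)
  cy <- sc$oscillation_amplitude_px * cos(2 * pi * t_frames / sc$period_h)
  truth <- diff(cy)
  expect_lt(max(abs(tr$v_y - truth)), 0.05)
  expect_lt(max(abs(tr$v_x)), 0.05)
})

test_that("motion traces round-trip through the CSV format", {
  st <- simulate_image_sequence(test_scene(duration_h = 2))
  tr <- track_stack(st, plant_id = "p7")
  path <- withr::local_tempfile(fileext = ".csv")
  write_motion_trace(tr, path)
  expect_identical(
    readLines(path, n = 1),
    "plant_id,time_hours,v_x,v_y,interpolated_flag"
  )
  back <- read_motion_trace(path)
  expect_equal(back$v_y, tr$v_y, tolerance = 1e-9)
  expect_identical(back$plant_id[1], "p7")
  expect_identical(back$interpolated, tr$interpolated)
})
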