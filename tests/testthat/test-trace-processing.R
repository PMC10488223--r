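test_that("initial-rate extraction recovers exact slopes on linear traces", {
  t <- seq(0, 600, by = 10)
  ir <- extract_initial_rate(data.frame(time_s = t, signal = 2 + 0.5 * t))
  expect_equal(ir$v0, 0.5, tolerance = 1e-12)
  expect_equal(ir$r2, 1, tolerance = 1e-9)
  expect_equal(ir$window_end, 600) # full trace qualifies
  # flat trace: zero rate, r2 defined as 1 (no 0/0)
  ir0 <- extract_initial_rate(data.frame(time_s = t, signal = rep(7, length(t))))
  expect_equal(ir0$v0, 0)
  expect_equal(ir0$r2, 1)
})

test_that("the selected window tracks the curvature onset", {
  tr <- simulate_progress_trace(1, duration = 1800, n_points = 181,
                                curvature_onset = 300)
  # the default linearity criterion (r2 >= 0.99) tolerates a visible bend:
  # the window overruns a 300 s onset by a few samples and the slope sits
  # somewhat below truth
  ir <- extract_initial_rate(tr)
  expect_lte(ir$window_end, 700)
  expect_true(ir$v0 > 0.8 && ir$v0 <= 1)
  # a strict criterion confines the window to the linear portion
  ir_strict <- extract_initial_rate(tr, r2_threshold = 0.9999)
  expect_equal(ir_strict$v0, 1, tolerance = 0.01)
  expect_lte(ir_strict$window_end, 400)
  # capping the window inside the linear portion recovers v0 exactly
  ir_cap <- extract_initial_rate(tr, max_window = 300)
  expect_equal(ir_cap$v0, 1, tolerance = 1e-9)
  expect_lte(ir_cap$window_end, 300)
  # noise-free fully linear traces are recovered to high relative accuracy
  tr2 <- simulate_progress_trace(0.25, duration = 600, n_points = 121,
                                 curvature_onset = 600)
  expect_equal(extract_initial_rate(tr2)$v0, 0.25, tolerance = 1e-6)
})

test_that("rate extraction respects max_window and degenerate-trace errors", {
  tr <- simulate_progress_trace(1, duration = 1800, n_points = 181,
                                curvature_onset = 1800)
  ir <- extract_initial_rate(tr, max_window = 500)
  expect_lte(ir$window_end, 500)
  # a quadratic trace has no linear prefix at a strict threshold
  t <- 0:60
  quad <- data.frame(time_s = t, signal = t^2)
  err <- expect_error(
    extract_initial_rate(quad, r2_threshold = 0.9999),
    class = "inhibkin_degenerate_trace"
  )
  expect_true(is.finite(err$best_r2) && err$best_r2 < 0.9999)
  # the caller may accept the minimum window explicitly
  ir_fb <- extract_initial_rate(quad, r2_threshold = 0.9999,
                                fallback_min_window = TRUE)
  expect_equal(ir_fb$n_points, 5L)
  expect_true(isTRUE(attr(ir_fb, "accepted_min_window")))
})

test_that("rate extraction is shift-invariant and scale-equivariant", {
  tr <- simulate_progress_trace(0.8, duration = 900, n_points = 91,
                                curvature_onset = 450, noise_sd = 0.5,
                                seed = 5)
  base <- extract_initial_rate(tr)
  shifted <- tr; shifted$signal <- shifted$signal + 100
  scaled <- tr; scaled$signal <- scaled$signal * 3
  expect_equal(extract_initial_rate(shifted)$v0, base$v0, tolerance = 1e-9)
  expect_equal(extract_initial_rate(shifted)$r2, base$r2, tolerance = 1e-9)
  expect_equal(extract_initial_rate(scaled)$v0, 3 * base$v0, tolerance = 1e-9)
  expect_equal(extract_initial_rate(scaled)$r2, base$r2, tolerance = 1e-9)
})

test_that("plateau averaging selects a qualifying suffix window", {
  # constant scan: whole scan is the plateau
  flat <- data.frame(time_s = 0:300, signal = rep(600, 301))
  pv <- plateau_mean(flat)
  expect_equal(pv$mean, 600)
  expect_equal(pv$window_start, 0)
  expect_equal(pv$n_points, 301L)
  # rising steeply then flat at 600: the window sits in the flat segment,
  # up to one boundary sample (a single off-plateau point is never
  # individually significant under the zero-slope test)
  t <- 0:300
  y <- pmin(t * 40, 600)
  pv2 <- plateau_mean(data.frame(time_s = t, signal = y))
  expect_equal(pv2$mean, 600, tolerance = 1e-3)
  expect_gte(pv2$window_start, 14)
  # monotone drifting scan never plateaus
  err <- expect_error(
    plateau_mean(data.frame(time_s = t, signal = t)),
    class = "inhibkin_no_plateau"
  )
  expect_gt(err$terminal_slope, 0)
  expect_error(plateau_mean(flat[1:50, ], min_span = 120),
               class = "inhibkin_input_error")
})

test_that("plateau mean of a noisy constant scan is within the standard-error bound", {
  t <- 0:300
  y <- withr::with_seed(42, 600 + rnorm(301, 0, 5))
  pv <- plateau_mean(data.frame(time_s = t, signal = y))
  expect_lt(abs(pv$mean - 600), 3 * 5 / sqrt(120))
  expect_gte(pv$window_end - pv$window_start, 120)
})

test_that("percent residual normalizes, clamps and flags", {
  expect_equal(as.numeric(percent_residual(600, 1100, 100)), 50)
  expect_equal(as.numeric(percent_residual(1100, 1100, 100)), 100)
  expect_equal(as.numeric(percent_residual(100, 1100, 100)), 0)
  expect_equal(as.numeric(percent_residual(50, 1100, 100)), 0) # floored
  enh <- percent_residual(1300, 1100, 100)
  expect_gt(as.numeric(enh), 100)
  expect_true(attr(enh, "flagged"))
  expect_error(percent_residual(600, 100, 100),
               class = "inhibkin_normalization_error")
  # invariant under common affine rescaling of all three plateaus
  a <- as.numeric(percent_residual(600, 1100, 100))
  b <- as.numeric(percent_residual(600 * 2 + 30, 1100 * 2 + 30, 100 * 2 + 30))
  expect_equal(a, b, tolerance = 1e-12)
})
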