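test_that("truth constructors enforce the mechanism/Ki invariants", {
  expect_s3_class(make_truth("competitive", Ki_c = 10), "inhibition_truth")
  expect_error(inhibition_truth("competitive", Km = 100, Vmax = 10,
                                Ki_c = 10, Ki_u = 5),
               class = "inhibkin_config_error")
  expect_error(inhibition_truth("uncompetitive", Km = 100, Vmax = 10,
                                Ki_c = 10),
               class = "inhibkin_config_error")
  expect_error(inhibition_truth("noncompetitive", Km = 100, Vmax = 10,
                                Ki_c = 10, Ki_u = 12),
               class = "inhibkin_config_error")
  expect_error(inhibition_truth("mixed", Km = 100, Vmax = 10,
                                Ki_c = 10, Ki_u = 10),
               class = "inhibkin_config_error")
  # noncompetitive convenience: one constant sets both sites
  tr <- inhibition_truth("noncompetitive", Km = 100, Vmax = 10, Ki_u = 7)
  expect_identical(tr$Ki_c, 7)
  expect_error(tht_truth(IC50 = 100, F_control = 100, F_background = 100),
               class = "inhibkin_config_error")
})

test_that("noise-free velocities match the modifier-equation closed form", {
  # noncompetitive at S = Km, I = Ki halves then halves again: v = 2.5
  nc <- make_truth("noncompetitive", Ki_c = 10)
  expect_equal(modifier_velocity(nc, 100, 10), 2.5, tolerance = 1e-12)
  # I = 0 reduces to plain MM at half saturation
  co <- make_truth("competitive", Ki_c = 10)
  expect_equal(modifier_velocity(co, 100, 0), 5, tolerance = 1e-12)
  # uncompetitive large-S asymptote: v -> Vmax / (1 + I/Ki_u)
  un <- make_truth("uncompetitive", Ki_u = 10)
  expect_equal(modifier_velocity(un, 1e6, 10), 5, tolerance = 1e-3)
  # panel generation in noiseless mode returns exact model values
  pan <- simulate_velocity_panel(nc, n_replicates = 2)
  expect_equal(pan$v0, modifier_velocity(nc, pan$S_uM, pan$I_uM),
               tolerance = 1e-12)
  expect_equal(nrow(pan), length(S_GRID) * length(I_GRID) * 2)
})

test_that("velocity panels require an uninhibited reference and valid grids", {
  nc <- make_truth("noncompetitive", Ki_c = 10)
  expect_error(simulate_velocity_panel(nc, I_grid = c(2.5, 5)),
               class = "inhibkin_input_error")
  expect_error(simulate_velocity_panel(nc, S_grid = numeric()),
               class = "inhibkin_input_error")
  expect_error(simulate_velocity_panel(nc, S_grid = c(-80, 100)),
               class = "inhibkin_input_error")
})

test_that("panels are reproducible under a fixed seed and vary across seeds", {
  a <- simulate_velocity_panel(make_truth("mixed", Ki_c = 5, Ki_u = 20,
                                          noise_cv = 0.02, seed = 11))
  b <- simulate_velocity_panel(make_truth("mixed", Ki_c = 5, Ki_u = 20,
                                          noise_cv = 0.02, seed = 11))
  c <- simulate_velocity_panel(make_truth("mixed", Ki_c = 5, Ki_u = 20,
                                          noise_cv = 0.02, seed = 12))
  expect_identical(a, b)
  expect_false(identical(a, c))

  th <- tht_truth(100, scan_noise_cv = 0.02, seed = 11)
  expect_identical(simulate_tht_assay(th), simulate_tht_assay(th))
})

test_that("velocity is strictly decreasing in inhibitor dose for every mechanism", {
  truths <- list(
    make_truth("competitive", Ki_c = 10),
    make_truth("noncompetitive", Ki_c = 10),
    make_truth("uncompetitive", Ki_u = 10),
    make_truth("mixed", Ki_c = 5, Ki_u = 20)
  )
  I <- seq(0, 50, by = 2.5)
  for (tr in truths) {
    for (S in c(80, 200, 500)) {
      v <- modifier_velocity(tr, S, I)
      expect_true(all(diff(v) < 0), label = tr$mechanism)
    }
  }
})

test_that("progress traces are linear up to the curvature onset", {
  # zero-rate trace stays flat at the initial signal
  flat <- simulate_progress_trace(0, duration = 100, n_points = 11,
                                  signal0 = 3)
  expect_equal(flat$signal, rep(3, 11), tolerance = 1e-12)
  # fully linear trace: endpoint = start + duration at unit rate
  lin <- simulate_progress_trace(1, duration = 100, n_points = 101,
                                 curvature_onset = 100)
  expect_equal(lin$signal, lin$time_s, tolerance = 1e-9)
  # curvature after the onset drags the full-window least-squares slope down
  bent <- simulate_progress_trace(0.5, duration = 300, n_points = 301,
                                  curvature_onset = 100)
  pre <- bent$time_s <= 100
  slope_pre <- coef(lm(signal ~ time_s, bent[pre, ]))[[2]]
  slope_full <- coef(lm(signal ~ time_s, bent))[[2]]
  expect_equal(slope_pre, 0.5, tolerance = 1e-9)
  expect_lt(slope_full, 0.5)
  expect_error(simulate_progress_trace(1, duration = -1, n_points = 10),
               class = "inhibkin_input_error")
  expect_error(simulate_progress_trace(1, duration = 10, n_points = 1),
               class = "inhibkin_input_error")
})

test_that("ThT scans encode the logistic inhibition law exactly at zero noise", {
  th <- tht_truth(IC50 = 100, F_control = 1100, F_background = 100)
  scans <- simulate_tht_assay(th, I_grid = c(0, 100, 1000),
                              n_replicates = 1)
  level <- function(role, I) {
    mean(scans$signal[scans$role == role & scans$inhibitor_uM == I])
  }
  expect_equal(level("control", 0), 1100, tolerance = 1e-12)
  # at I = IC50 the background-subtracted plateau is half the control span
  expect_equal(level("sample", 100), 600, tolerance = 1e-12)
  # at I = 10 x IC50, hill 1: residual is 1/11 of the control span
  expect_equal((level("sample", 1000) - 100) / 1000, 1 / 11,
               tolerance = 1e-12)
  expect_equal(level("background", 0), 100, tolerance = 1e-12)
  # residual is strictly decreasing in dose
  th2 <- tht_truth(IC50 = 50, hill_slope = 1.3)
  sc <- simulate_tht_assay(th2, I_grid = c(0, 10, 30, 90, 270),
                           n_replicates = 1)
  lv <- tapply(sc$signal[sc$role != "background"],
               sc$inhibitor_uM[sc$role != "background"], mean)
  expect_true(all(diff(lv[order(as.numeric(names(lv)))]) < 0))
})

test_that("truth sidecars round-trip generative parameters as JSON", {
  tr <- make_truth("mixed", Ki_c = 5, Ki_u = 20, noise_cv = 0.02, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_sidecar(tr, path)
  got <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(got$kind, "inhibition_truth")
  expect_equal(got$Ki_c, 5)
  expect_equal(got$Ki_u, 20)
  expect_equal(got$seed, 3)
})
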