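test_that("the decision table maps parameter-shift patterns to labels", {
  mm0 <- mm_stub(100, 10)
  # Vmax halves, Km unchanged -> noncompetitive
  expect_identical(classify_mechanism(mm0, mm_stub(100, 5, I = 10))$label,
                   "noncompetitive")
  # Km and Vmax halve together, ratio preserved -> uncompetitive
  expect_identical(classify_mechanism(mm0, mm_stub(50, 5, I = 10))$label,
                   "uncompetitive")
  # Km doubles, Vmax unchanged -> competitive
  expect_identical(classify_mechanism(mm0, mm_stub(200, 10, I = 10))$label,
                   "competitive")
  # both shift with the ratio broken -> mixed
  expect_identical(classify_mechanism(mm0, mm_stub(150, 8, I = 10))$label,
                   "mixed")
  # Vmax rising matches no inhibition pattern -> undetermined
  expect_identical(classify_mechanism(mm0, mm_stub(100, 12, I = 10))$label,
                   "undetermined")
  # sub-tolerance shifts count as unchanged -> undetermined (no change at all)
  expect_identical(classify_mechanism(mm0, mm_stub(102, 9.8, I = 10))$label,
                   "undetermined")
  expect_error(classify_mechanism(mm0, mm_stub(100, 5, method = "lineweaver_burk")),
               class = "inhibkin_input_error")
})

test_that("apparent-Ki relations reproduce their arithmetic exactly", {
  mm0 <- mm_stub(100, 10)
  # relation 1: K'i = V'max I / (Vmax - V'max) = 5*10/5 = 10
  nc <- apparent_ki(mm0, mm_stub(100, 5), 10, "noncompetitive")
  expect_equal(nc$Ki, 10, tolerance = 1e-12)
  expect_identical(nc$equations_used, 1L)
  # relation 3: K'i = K'm I / (Km - K'm) = 50*10/50 = 10
  un <- apparent_ki(mm0, mm_stub(50, 5), 10, "uncompetitive")
  expect_equal(un$Ki, 10, tolerance = 1e-12)
  expect_identical(un$equations_used, 3L)
  # relation 2 as stated: K'i = K'm I / (K'm - Km) = 200*10/100 = 20 = Ki + I
  co <- apparent_ki(mm0, mm_stub(200, 10), 10, "competitive")
  expect_equal(co$Ki, 20, tolerance = 1e-12)
  expect_identical(co$equations_used, 2L)
  # classical mode substitutes Km in the numerator and recovers Ki = 10
  co_cl <- apparent_ki(mm0, mm_stub(200, 10), 10, "competitive",
                       equation_mode = "classical")
  expect_equal(co_cl$Ki, 10, tolerance = 1e-12)
  # mixed keys the relation pair to the sign of the Km shift
  up <- apparent_ki(mm0, mm_stub(150, 8), 10, "mixed")
  expect_identical(up$equations_used, c(1L, 2L))
  expect_equal(up$Ki, mean(c(8 * 10 / 2, 150 * 10 / 50)), tolerance = 1e-12)
  dn <- apparent_ki(mm0, mm_stub(60, 8), 10, "mixed")
  expect_identical(dn$equations_used, c(1L, 3L))
  expect_equal(dn$Ki, mean(c(40, 15)), tolerance = 1e-12)
  # inconsistent shift for the selected relation errors, naming it
  err <- expect_error(apparent_ki(mm0, mm_stub(100, 12), 10, "noncompetitive"),
                      class = "inhibkin_ki_inconsistent")
  expect_identical(err$equation, 1L)
})

test_that("the Ki relations are exact on noiseless truths at every dose", {
  doses <- c(2.5, 5, 10)
  # noncompetitive truth: relation 1 returns Ki exactly
  nc <- make_truth("noncompetitive", Ki_c = 12)
  mm0 <- fit_mm_lineweaver_burk(simulate_velocity_panel(nc, I_grid = 0))
  for (I in doses) {
    pan <- simulate_velocity_panel(nc, I_grid = c(0, I))
    mmI <- fit_mm_lineweaver_burk(pan[pan$I_uM == I, ])
    expect_equal(apparent_ki(mm0, mmI, I, "noncompetitive")$Ki, 12,
                 tolerance = 1e-9)
  }
  # uncompetitive truth: relation 3 returns Ki exactly
  un <- make_truth("uncompetitive", Ki_u = 8)
  mm0u <- fit_mm_lineweaver_burk(simulate_velocity_panel(un, I_grid = 0))
  for (I in doses) {
    pan <- simulate_velocity_panel(un, I_grid = c(0, I))
    mmI <- fit_mm_lineweaver_burk(pan[pan$I_uM == I, ])
    expect_equal(apparent_ki(mm0u, mmI, I, "uncompetitive")$Ki, 8,
                 tolerance = 1e-9)
  }
  # competitive truth: relation 2 as stated returns Ki + I exactly
  co <- make_truth("competitive", Ki_c = 10)
  mm0c <- fit_mm_lineweaver_burk(simulate_velocity_panel(co, I_grid = 0))
  for (I in doses) {
    pan <- simulate_velocity_panel(co, I_grid = c(0, I))
    mmI <- fit_mm_lineweaver_burk(pan[pan$I_uM == I, ])
    expect_equal(apparent_ki(mm0c, mmI, I, "competitive")$Ki, 10 + I,
                 tolerance = 1e-9)
    expect_equal(apparent_ki(mm0c, mmI, I, "competitive",
                             equation_mode = "classical")$Ki, 10,
                 tolerance = 1e-9)
  }
})

test_that("pooled Ki averages the per-concentration estimates", {
  flat <- pooled_ki(data.frame(I_uM = c(2.5, 5, 10), Ki = c(10, 10, 10)))
  expect_equal(flat$Ki_mean, 10)
  expect_equal(flat$Ki_sd, 0)
  expect_equal(flat$n, 3L)
  two <- pooled_ki(data.frame(I_uM = c(2.5, 5), Ki = c(8, 12)))
  expect_equal(two$Ki_mean, 10)
  expect_equal(two$Ki_sd, sd(c(8, 12)), tolerance = 1e-12)
  one <- pooled_ki(data.frame(I_uM = 5, Ki = 7))
  expect_true(is.na(one$Ki_sd))
  expect_error(pooled_ki(data.frame(I_uM = numeric(), Ki = numeric())),
               class = "inhibkin_input_error")
  expect_error(pooled_ki(data.frame(I_uM = 5, Ki = -1)),
               class = "inhibkin_input_error")
})

test_that("classification is invariant to replicate order and velocity rescaling", {
  tr <- make_truth("mixed", Ki_c = 5, Ki_u = 20, noise_cv = 0.02, seed = 31)
  pan <- simulate_velocity_panel(tr)
  base <- profile_inhibition(pan)
  perm <- pan[withr::with_seed(2, sample(nrow(pan))), ]
  scaled <- pan; scaled$v0 <- scaled$v0 * 40
  expect_identical(profile_inhibition(perm)$label, base$label)
  prof_sc <- profile_inhibition(scaled)
  expect_identical(prof_sc$label, base$label)
  expect_equal(prof_sc$ki$Ki_mean, base$ki$Ki_mean, tolerance = 1e-6)
})
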