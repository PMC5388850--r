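test_that("scatterer phantoms honour the count rule and are reproducible", {
  ph <- make_scatterer_phantom(10, 10, 12, seed = 1)
  expect_equal(nrow(ph$scatterer_positions), 1200)
  expect_true(all(ph$scatterer_positions[, "axial_mm"] >= 0 &
                  ph$scatterer_positions[, "axial_mm"] <= 10))
  expect_true(all(ph$scatterer_positions[, "lateral_mm"] >= 0 &
                  ph$scatterer_positions[, "lateral_mm"] <= 10))
  ph2 <- make_scatterer_phantom(10, 10, 12, seed = 1)
  expect_identical(ph$scatterer_positions, ph2$scatterer_positions)
  ph3 <- make_scatterer_phantom(10, 10, 12, seed = 2)
  expect_false(identical(ph$scatterer_positions, ph3$scatterer_positions))
  expect_equal(nrow(make_scatterer_phantom(5, 5, 0)$scatterer_positions), 0)
  expect_error(make_scatterer_phantom(-1, 10, 5), class = "qus_invalid_parameter")
  expect_error(make_scatterer_phantom(10, 10, -5), class = "qus_invalid_parameter")
})

test_that("pulse model validates its parameters", {
  expect_error(pulse_model(fractional_bandwidth = 2.5),
               class = "qus_invalid_parameter")
  expect_error(pulse_model(sampling_rate_hz = 20e6),
               class = "qus_invalid_parameter")
  expect_equal(pulse_band_mhz(pulse_model()), c(4.2, 7.8))
})

test_that("an empty phantom gives an all-zero frame", {
  ph <- make_scatterer_phantom(5, 5, 0)
  fr <- simulate_rf_frame(ph, default_pulse(), 4, 0.25)
  expect_true(all(fr$samples == 0))
})

test_that("a single scatterer echoes at the two-way delay", {
  ph <- make_scatterer_phantom(25, 1, 0, seed = 1)
  ph$scatterer_positions <- cbind(axial_mm = 20, lateral_mm = 0.5)
  fr <- simulate_rf_frame(ph, default_pulse(), 1, 1)
  env <- compute_bmode(fr)$pixels[, 1]
  # 0-based sample round(2 * 0.020 / 1540 * 40e6) = 1039
  expect_equal(which.max(env) - 1L, 1039L)
})

test_that("a frame too short for the deepest scatterer is a geometry error", {
  ph <- make_scatterer_phantom(20, 2, 1, seed = 1)
  expect_error(simulate_rf_frame(ph, default_pulse(), 2, 1, n_samples = 100),
               class = "qus_geometry_error")
})

test_that("dense phantoms produce fully developed (Rayleigh) speckle", {
  # envelope mean/sd -> sqrt(pi/4) / sqrt(1 - pi/4) = 1.9130 as density grows
  snr_at <- function(density) {
    ph <- make_scatterer_phantom(10, 8, density, effective_radius_um = 0,
                                 attenuation_slope_db_cm_mhz = 0, seed = 2)
    fr <- simulate_rf_frame(ph, default_pulse(), 32, 0.25)
    env <- apply(fr$samples, 2, function(col) Mod(qusresponse:::analytic_signal(col)))
    n <- nrow(env)
    roi <- env[round(n * 0.15):round(n * 0.85), ]
    mean(roi) / sd(roi)
  }
  lo <- snr_at(100); hi <- snr_at(400)
  expect_gt(hi, lo)                        # converges from below
  expect_lt(abs(hi - 1.913) / 1.913, 0.05) # within 5% when dense
})

test_that("simulation is deterministic given phantom and pulse", {
  ph <- make_scatterer_phantom(8, 4, 20, seed = 3)
  f1 <- simulate_rf_frame(ph, default_pulse(), 8, 0.25)
  f2 <- simulate_rf_frame(ph, default_pulse(), 8, 0.25)
  expect_identical(f1$samples, f2$samples)
})

test_that("spectrum-level oracle reproduces the backscatter model exactly", {
  # a_eff = 0: pure Rayleigh f^4 curve
  o <- synthesize_block_spectrum(0, 2, c(3, 8), noise_db = 0)
  expect_equal(o$s_db, 2 + 40 * log10(o$f_mhz))
  # fixed seed reproducibility of the noise
  n1 <- synthesize_block_spectrum(25, 0, c(3, 8), noise_db = 1, seed = 5)
  n2 <- synthesize_block_spectrum(25, 0, c(3, 8), noise_db = 1, seed = 5)
  expect_identical(n1$s_db, n2$s_db)
  expect_error(synthesize_block_spectrum(25, 0, c(5, 5)),
               class = "qus_invalid_parameter")
})

test_that("feature cohorts have the clinical class sizes and null behaviour", {
  coh <- separated_cohort(seed = 2)
  expect_equal(nrow(coh$features), 56)
  expect_equal(as.vector(table(coh$labels)), c(42, 14))
  coh2 <- separated_cohort(seed = 2)
  expect_identical(coh$features, coh2$features)
  # zero effect size: doubled one-tailed p-values approximately uniform
  p <- 60
  null_spec <- cohort_spec(100L, 100L, feature_names = paste0("f", 1:p),
                           mean_good = rep(0, p), mean_poor = rep(0, p),
                           covariance = diag(p), seed = 7)
  coh0 <- generate_feature_cohort(null_spec)
  rk <- rank_features(coh0$features, coh0$labels)
  ks <- suppressWarnings(ks.test(pmin(1, 2 * rk$p_value), "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_error(cohort_spec(42, 14, "f1", 0, 0, covariance = matrix(-1, 1, 1)),
               class = "qus_invalid_parameter")
})

test_that("survival cohorts respect censoring and reproducibility", {
  s0 <- generate_survival_cohort(c(20, 20), c(0.01, 0.05), censor_rate = 0,
                                 seed = 4)
  expect_true(all(s0$event == 1))
  s1 <- generate_survival_cohort(c(30, 30), c(0.01, 0.05), censor_rate = 0.3,
                                 seed = 4)
  expect_identical(s1, generate_survival_cohort(c(30, 30), c(0.01, 0.05),
                                                censor_rate = 0.3, seed = 4))
  expect_true(mean(s1$event == 0) > 0.05)  # some censoring realized
  expect_error(generate_survival_cohort(10, -1, 0, 1),
               class = "qus_invalid_parameter")
  expect_error(generate_survival_cohort(10, 1, 1, 1),
               class = "qus_invalid_parameter")
})
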