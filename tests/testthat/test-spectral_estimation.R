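test_that("block periodograms locate tones and satisfy Parseval", {
  fs <- 40e6
  t <- (0:511) / fs
  line <- sin(2 * pi * 6.25e6 * t)   # 6.25 MHz sits exactly on a 512-pt bin
  fr <- rf_frame(cbind(line, line, line), fs, 0.25)
  sp <- block_power_spectrum(fr, list(r0 = 1L, r1 = 512L, c0 = 1L, c1 = 3L),
                             nfft = 512L)
  expect_equal(sp$freq_mhz[which.max(sp$power)], 6.25)
  # Parseval: one-sided periodogram sums to the windowed-signal energy
  w <- qusresponse:::hann_window(512)
  expect_equal(sum(sp$power), sum((line * w)^2), tolerance = 1e-10)
  expect_error(block_power_spectrum(fr, list(r0 = 1L, r1 = 600L, c0 = 1L,
                                             c1 = 1L)),
               class = "qus_geometry_error")
  expect_error(block_power_spectrum(fr, list(r0 = 1L, r1 = 2L, c0 = 1L,
                                             c1 = 1L)),
               class = "qus_geometry_error")
})

test_that("averaged white-noise spectra are flat", {
  set.seed(42)
  fr <- rf_frame(matrix(rnorm(256 * 200), 256, 200), 40e6, 0.25)
  sp <- block_power_spectrum(fr, list(r0 = 1L, r1 = 256L, c0 = 1L, c1 = 200L),
                             nfft = 256L)
  band <- sp$freq_mhz >= 2 & sp$freq_mhz <= 18
  s_db <- 10 * log10(sp$power[band])
  expect_lt(diff(range(s_db)), 2)   # within +/- 1 dB of flat
})

test_that("normalization obeys the log identities", {
  f <- (0:128) * 40 / 256
  a <- structure(list(freq_mhz = f, power = rep(2, length(f)), n_lines = 1),
                 class = "raw_spectrum")
  ns <- normalize_spectrum(a, a, c(3, 8))
  expect_true(all(ns$s_db == 0))
  b <- a; b$power <- 4 * a$power
  ns2 <- normalize_spectrum(b, a, c(3, 8))
  expect_equal(ns2$s_db, rep(10 * log10(4), length(ns2$s_db)))
  bad <- a; bad$power[10] <- 0
  expect_error(normalize_spectrum(a, bad, c(0.5, 8)),
               class = "qus_invalid_parameter")
})

test_that("the linear spectral fit is exact on lines and constants", {
  f <- seq(3, 8, by = 0.05)
  ft <- fit_linear_spectrum(normalized_spectrum(f, 2 * f + 3, c(3, 8)))
  expect_equal(ft$ss, 2, tolerance = 1e-9)
  expect_equal(ft$si, 3, tolerance = 1e-9)
  expect_equal(ft$mbf, 2 * 5.5 + 3, tolerance = 1e-9)
  cst <- fit_linear_spectrum(normalized_spectrum(f, rep(-7, length(f)), c(3, 8)))
  expect_equal(cst$ss, 0, tolerance = 1e-9)
  expect_equal(cst$si, -7, tolerance = 1e-9)
  expect_equal(cst$mbf, -7, tolerance = 1e-9)
  expect_error(fit_linear_spectrum(normalized_spectrum(3, 1, c(3, 3))),
               class = "qus_invalid_parameter")
})

test_that("MBF = SS * f_c + SI identically, and SS is unbiased under noise", {
  f <- seq(4.2, 7.8, by = 0.1)
  set.seed(9)
  ss_hat <- replicate(200, {
    s <- -1.5 * f + 10 + rnorm(length(f), sd = 2)
    ft <- fit_linear_spectrum(normalized_spectrum(f, s, c(4.2, 7.8)))
    expect_equal(ft$mbf, ft$ss * 6 + ft$si, tolerance = 1e-12)
    ft$ss
  })
  se <- sd(ss_hat) / sqrt(length(ss_hat))
  expect_lt(abs(mean(ss_hat) + 1.5), 3 * se + 1e-12)
})

test_that("attenuation point compensation is the exact inverse of the decay", {
  f <- seq(4, 8, by = 0.1)
  base <- normalized_spectrum(f, -0.5 * f + 4, c(4, 8))
  # ace equal to the reference: unchanged
  same <- correct_attenuation(base, 0.5, 0.5, depth_cm = 2)
  expect_identical(same$s_db, base$s_db)
  # apply the 4*dalpha*f*z decay, then correct: identity
  att <- base
  att$s_db <- att$s_db - 4 * (1.2 - 0.5) * f * 1.5
  rec <- correct_attenuation(att, 1.2, 0.5, depth_cm = 1.5)
  expect_equal(rec$s_db, base$s_db, tolerance = 1e-12)
})

test_that("ACE equals the reference slope for the reference phantom itself", {
  ref <- reference_fixture()
  other <- fixture("ref2", simulate_reference_frame(default_pulse(), 40, 0.25,
                                                    16, 10, seed = 17))
  core <- interior_core(other)
  a <- estimate_ace(other, core, ref, band_fixture(), alpha_reference = 0.5,
                    min_depth_span_mm = 10)
  expect_lt(abs(a$ace - 0.5), 0.15)
})

test_that("ACE recovers a known attenuation contrast from simulated RF", {
  fr <- hom_frame(a_eff = 0, aac = 0, alpha = 1.0, seed = 11)
  a <- estimate_ace(fr, interior_core(fr), reference_fixture(), band_fixture(),
                    alpha_reference = 0.5, min_depth_span_mm = 10)
  expect_lt(abs(a$ace - 1.0), 0.15)
  # insufficient depth span is an estimation error
  dz <- axial_spacing_mm(fr)
  small <- matrix(FALSE, nrow(fr$samples), ncol(fr$samples))
  small[round(6 / dz):round(10 / dz), ] <- TRUE
  expect_error(estimate_ace(fr, roi_mask(small, "core"), reference_fixture(),
                            band_fixture(), min_depth_span_mm = 10),
               class = "qus_geometry_error")
})

test_that("attenuation correction flattens the MBF depth trend", {
  fr <- hom_frame(a_eff = 0, aac = 0, alpha = 1.0, seed = 11)
  ref <- reference_fixture()
  core <- interior_core(fr)
  px <- c(axial_spacing_mm(fr), fr$line_pitch_mm)
  blocks <- tile_blocks(core, px, overlap = 0.5)
  band <- band_fixture()
  a <- estimate_ace(fr, core, ref, band, min_depth_span_mm = 10)
  trend <- function(ace) {
    q <- compute_block_qus(fr, ref, blocks, ace, band, depth_origin_mm = 0)
    z <- blocks$centre_depth_mm / 10
    unname(stats::lm.fit(cbind(1, z), q$mbf)$coefficients[2])
  }
  raw_slope <- trend(0.5)          # no differential correction
  fix_slope <- trend(a$ace)
  expect_gt(abs(raw_slope), 5)     # ~ -4 * 0.5 * f_c dB/cm uncorrected
  expect_lt(abs(fix_slope), 1.5)   # restored homogeneity
})

test_that("normalization cancels the system response across pulses", {
  ph <- make_scatterer_phantom(16, 10, 30, effective_radius_um = 40,
                               acoustic_concentration_db = 5,
                               attenuation_slope_db_cm_mhz = 0.5, seed = 5)
  band <- c(4.4, 7.6)
  mean_norm <- function(pulse, ref_seed = 91) {
    fr <- simulate_rf_frame(ph, pulse, 40, 0.25)
    ref <- simulate_reference_frame(pulse, 40, 0.25, 16, 10, seed = ref_seed)
    core <- interior_core(fr)
    px <- c(axial_spacing_mm(fr), fr$line_pitch_mm)
    blocks <- tile_blocks(core, px, overlap = 0.5)
    cache <- new.env(parent = emptyenv())
    acc <- 0
    for (i in seq_len(nrow(blocks))) {
      b <- blocks[i, ]
      ns <- normalize_spectrum(
        block_power_spectrum(fr, b),
        qusresponse:::reference_spectrum(ref, b$r0, b$r1, cache = cache), band)
      acc <- acc + ns$s_db
    }
    list(f = ns$f_mhz, s = acc / nrow(blocks))
  }
  s1 <- mean_norm(pulse_model())
  s2 <- mean_norm(pulse_model(fractional_bandwidth = 0.8))
  expect_lt(max(abs(s1$s - s2$s)), 1)
  # cross-fidelity: mean normalized spectrum matches the model difference
  oracle <- backscatter_model_db(s1$f, 40, 5) - backscatter_model_db(s1$f, 0, 0)
  expect_lt(max(abs(s1$s - oracle)), 3)
})
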