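# Synthetic-data generators: scatterer phantoms, pulse-echo RF frames,
# spectrum-level oracles, two-class feature cohorts, censored survival cohorts.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are reproducible without clobbering the session.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Pulse model for a linear-array acquisition
#'
#' Gaussian-modulated sinusoid parameterized by its -6 dB fractional
#' bandwidth. Defaults match a 6 MHz linear probe sampled at 40 MHz.
#'
#' @param center_frequency_hz centre frequency (Hz).
#' @param fractional_bandwidth -6 dB fractional bandwidth, in (0, 2).
#' @param sampling_rate_hz RF sampling rate (Hz); must exceed 4x the centre
#'   frequency.
#' @param speed_of_sound_m_s assumed speed of sound (m/s).
#' @return An object of class `pulse_model`.
#' @export
pulse_model <- function(center_frequency_hz = 6e6, fractional_bandwidth = 0.6,
                        sampling_rate_hz = 40e6, speed_of_sound_m_s = 1540) {
  check_scalar(center_frequency_hz, "center_frequency_hz", positive = TRUE)
  check_scalar(fractional_bandwidth, "fractional_bandwidth", positive = TRUE)
  check_scalar(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  check_scalar(speed_of_sound_m_s, "speed_of_sound_m_s", positive = TRUE)
  if (fractional_bandwidth >= 2)
    stop_invalid("fractional_bandwidth must be < 2")
  if (sampling_rate_hz <= 4 * center_frequency_hz)
    stop_invalid("sampling_rate_hz must exceed 4 x center_frequency_hz")
  structure(list(center_frequency_hz = center_frequency_hz,
                 fractional_bandwidth = fractional_bandwidth,
                 sampling_rate_hz = sampling_rate_hz,
                 speed_of_sound_m_s = speed_of_sound_m_s),
            class = "pulse_model")
}

# Gaussian amplitude spectrum of the pulse; -6 dB (power) points at
# fc * (1 +/- bw/2).
pulse_amplitude_spectrum <- function(pulse, f_hz) {
  fc <- pulse$center_frequency_hz
  half <- pulse$fractional_bandwidth * fc / 2
  sigma <- half / sqrt(0.6 * log(10))        # |P|^2 = 10^-0.6 at fc +/- half
  exp(-(f_hz - fc)^2 / (2 * sigma^2))
}

#' Default -6 dB band of a pulse, in MHz
#' @param pulse a [pulse_model()].
#' @return numeric length-2 vector `c(f_lo, f_hi)` in MHz.
#' @export
pulse_band_mhz <- function(pulse) {
  fc <- pulse$center_frequency_hz / 1e6
  half <- pulse$fractional_bandwidth * fc / 2
  c(fc - half, fc + half)
}

#' Random point-scatterer phantom
#'
#' Uniformly random scatterer positions over a rectangular extent, with
#' ground-truth effective scatterer radius, acoustic concentration and
#' frequency-linear attenuation slope used by [simulate_rf_frame()].
#'
#' @param extent_axial_mm,extent_lateral_mm phantom extent (mm), > 0.
#' @param number_density_per_mm2 scatterer number density (1/mm^2), >= 0; the
#'   scatterer count is `round(density * area)`.
#' @param effective_radius_um ground-truth effective scatterer radius a_eff
#'   (micrometres); the effective scatterer diameter ASD is `2 * a_eff`.
#' @param acoustic_concentration_db ground-truth effective acoustic
#'   concentration (dB, reference-relative).
#' @param attenuation_slope_db_cm_mhz ground-truth attenuation slope alpha0
#'   (dB/cm/MHz), >= 0.
#' @param seed integer seed; fixed seed gives identical position lists.
#' @return An object of class `scatterer_phantom`.
#' @export
make_scatterer_phantom <- function(extent_axial_mm, extent_lateral_mm,
                                   number_density_per_mm2,
                                   effective_radius_um = 25,
                                   acoustic_concentration_db = 0,
                                   attenuation_slope_db_cm_mhz = 0.5,
                                   seed = 1L) {
  check_scalar(extent_axial_mm, "extent_axial_mm", positive = TRUE)
  check_scalar(extent_lateral_mm, "extent_lateral_mm", positive = TRUE)
  check_scalar(number_density_per_mm2, "number_density_per_mm2", nonneg = TRUE)
  check_scalar(effective_radius_um, "effective_radius_um", nonneg = TRUE)
  check_scalar(acoustic_concentration_db, "acoustic_concentration_db")
  check_scalar(attenuation_slope_db_cm_mhz, "attenuation_slope_db_cm_mhz",
               nonneg = TRUE)
  area <- extent_axial_mm * extent_lateral_mm
  n <- round(number_density_per_mm2 * area)
  pos <- if (n > 0) {
    with_seed(seed, cbind(axial_mm = stats::runif(n) * extent_axial_mm,
                          lateral_mm = stats::runif(n) * extent_lateral_mm))
  } else {
    cbind(axial_mm = numeric(0), lateral_mm = numeric(0))
  }
  structure(list(extent_axial_mm = extent_axial_mm,
                 extent_lateral_mm = extent_lateral_mm,
                 scatterer_positions = pos,
                 effective_radius_um = effective_radius_um,
                 acoustic_concentration_db = acoustic_concentration_db,
                 number_density_per_mm2 = number_density_per_mm2,
                 attenuation_slope_db_cm_mhz = attenuation_slope_db_cm_mhz,
                 seed = seed),
            class = "scatterer_phantom")
}

#' Gaussian form-factor, in dB
#'
#' `10*log10(exp(-0.827 k^2 a_eff^2))` with `k = 2*pi*f/c` (Insana-Hall
#' convention). Describes the departure of backscatter from Rayleigh (f^4)
#' behaviour as the scatterer size grows.
#'
#' @param f_mhz frequency grid (MHz).
#' @param a_eff_um effective scatterer radius (micrometres).
#' @param c_m_s speed of sound (m/s).
#' @return dB values on the grid (0 for `a_eff_um = 0`).
#' @export
gaussian_form_factor_db <- function(f_mhz, a_eff_um, c_m_s = 1540) {
  k <- 2 * pi * f_mhz * 1e6 / c_m_s         # 1/m
  a <- a_eff_um * 1e-6                      # m
  -0.827 * (k * a)^2 * 10 / log(10)
}

#' Gaussian form-factor backscatter model, in dB
#'
#' `M(f) = AAC + 10*log10(f^4) + 10*log10(exp(-0.827 k^2 a_eff^2))`, the model
#' fitted by [fit_gaussian_form_factor()].
#'
#' @inheritParams gaussian_form_factor_db
#' @param aac_db effective acoustic concentration (dB).
#' @export
backscatter_model_db <- function(f_mhz, a_eff_um, aac_db, c_m_s = 1540) {
  aac_db + 40 * log10(f_mhz) + gaussian_form_factor_db(f_mhz, a_eff_um, c_m_s)
}

#' Simulate a pulse-echo RF frame from a scatterer phantom
#'
#' Each scan line accepts the scatterers within +/- pitch/2 of its lateral
#' position, weighted by a Gaussian lateral beam profile. Lines are
#' synthesised in the frequency domain: each scatterer at depth z contributes
#' `A(f) * exp(-i 2 pi f (2 z / c))` where `A(f)` combines the pulse spectrum,
#' the square root of the f^4 x Gaussian-form-factor backscatter power model,
#' and cumulative round-trip attenuation of `4 * alpha0 * f * z` dB (f in MHz,
#' z in cm).
#'
#' @param phantom a [make_scatterer_phantom()].
#' @param pulse a [pulse_model()].
#' @param n_lines number of scan lines (>= 1).
#' @param line_pitch_mm element pitch (mm).
#' @param n_samples axial sample count; default covers the phantom extent
#'   plus a pulse guard. A frame too short to contain the deepest scatterer
#'   is a geometry error.
#' @param noise_sd standard deviation of additive white noise (same linear
#'   units as the echoes); 0 disables noise.
#' @param seed seed for the noise realization (ignored when `noise_sd = 0`).
#' @return An [rf_frame()].
#' @export
simulate_rf_frame <- function(phantom, pulse, n_lines, line_pitch_mm,
                              n_samples = NULL, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(phantom, "scatterer_phantom"), inherits(pulse, "pulse_model"))
  if (!is.numeric(n_lines) || n_lines < 1) stop_invalid("n_lines must be >= 1")
  n_lines <- as.integer(n_lines)
  check_scalar(line_pitch_mm, "line_pitch_mm", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  fs <- pulse$sampling_rate_hz
  c_ms <- pulse$speed_of_sound_m_s
  guard <- 64L
  need <- ceiling(2 * phantom$extent_axial_mm * 1e-3 / c_ms * fs) + guard
  if (is.null(n_samples)) n_samples <- as.integer(need)
  n_samples <- as.integer(n_samples)
  pos <- phantom$scatterer_positions
  if (nrow(pos) > 0) {
    deepest <- ceiling(2 * max(pos[, "axial_mm"]) * 1e-3 / c_ms * fs)
    if (deepest > n_samples)
      stop_geometry("frame of ", n_samples,
                    " samples cannot contain the deepest scatterer (needs ",
                    deepest, ")")
  }
  nfft <- 2^ceiling(log2(n_samples + guard))
  npos <- nfft / 2 + 1
  f_hz <- (seq_len(npos) - 1) * fs / nfft
  f_mhz <- f_hz / 1e6
  # shared frequency shaping: pulse x f^2 x sqrt(form factor)
  shape <- pulse_amplitude_spectrum(pulse, f_hz) * f_mhz^2 *
    10^(gaussian_form_factor_db(f_mhz, phantom$effective_radius_um, c_ms) / 20)
  dens <- phantom$number_density_per_mm2
  amp0 <- 10^(phantom$acoustic_concentration_db / 20) /
    sqrt(max(dens, .Machine$double.eps))
  alpha <- phantom$attenuation_slope_db_cm_mhz
  sigma_lat <- line_pitch_mm / 4
  rf <- matrix(0, n_samples, n_lines)
  lat_centers <- (seq_len(n_lines) - 0.5) * line_pitch_mm
  if (nrow(pos) > 0) {
    att_coef <- -4 * alpha * log(10) / 20          # per (MHz * cm), amplitude
    for (j in seq_len(n_lines)) {
      dx <- pos[, "lateral_mm"] - lat_centers[j]
      keep <- abs(dx) <= line_pitch_mm / 2
      if (!any(keep)) next
      z_mm <- pos[keep, "axial_mm"]
      w <- amp0 * exp(-dx[keep]^2 / (2 * sigma_lat^2))
      tau <- 2 * z_mm * 1e-3 / c_ms
      ex <- outer(f_mhz, z_mm / 10) * att_coef +
        outer(f_hz, tau) * (-2i * pi)
      spec_pos <- shape * as.vector(exp(ex) %*% w)
      full <- complex(length.out = nfft)
      full[seq_len(npos)] <- spec_pos
      full[1] <- Re(full[1]); full[npos] <- Re(full[npos])
      if (nfft > 2) full[nfft:(npos + 1)] <- Conj(spec_pos[2:(npos - 1)])
      line <- Re(stats::fft(full, inverse = TRUE)) / nfft
      rf[, j] <- line[seq_len(n_samples)]
    }
  }
  if (noise_sd > 0)
    rf <- rf + with_seed(seed, matrix(stats::rnorm(length(rf), sd = noise_sd),
                                      n_samples, n_lines))
  rf_frame(rf, sampling_rate_hz = fs, line_pitch_mm = line_pitch_mm,
           speed_of_sound_m_s = c_ms)
}

#' Simulate a reference-phantom frame
#'
#' Convenience wrapper producing the frame a physical reference phantom would
#' give: point (Rayleigh) scatterers (`a_eff = 0`), 0 dB concentration and a
#' known attenuation slope, dense enough for fully developed speckle.
#'
#' @inheritParams simulate_rf_frame
#' @param extent_axial_mm,extent_lateral_mm phantom extent (mm).
#' @param alpha_db_cm_mhz reference attenuation slope (dB/cm/MHz).
#' @param number_density_per_mm2 scatterer density (1/mm^2).
#' @param seed phantom seed.
#' @export
simulate_reference_frame <- function(pulse, n_lines, line_pitch_mm,
                                     extent_axial_mm, extent_lateral_mm,
                                     alpha_db_cm_mhz = 0.5,
                                     number_density_per_mm2 = 30,
                                     n_samples = NULL, seed = 99L) {
  ph <- make_scatterer_phantom(extent_axial_mm, extent_lateral_mm,
                               number_density_per_mm2,
                               effective_radius_um = 0,
                               acoustic_concentration_db = 0,
                               attenuation_slope_db_cm_mhz = alpha_db_cm_mhz,
                               seed = seed)
  simulate_rf_frame(ph, pulse, n_lines, line_pitch_mm, n_samples = n_samples)
}

#' Spectrum-level backscatter oracle
#'
#' Evaluates the Gaussian form-factor backscatter model on a frequency grid,
#' in dB, plus optional zero-mean Gaussian noise. An exact inverse-test
#' substrate for [fit_gaussian_form_factor()] that bypasses RF simulation.
#'
#' @param a_eff_um effective scatterer radius (micrometres).
#' @param aac_db acoustic concentration (dB).
#' @param band_mhz usable band `c(f_lo, f_hi)` (MHz), f_lo > 0.
#' @param noise_db standard deviation of additive dB noise.
#' @param seed seed for the noise realization.
#' @param freq_step_mhz grid spacing (MHz).
#' @param c_m_s speed of sound (m/s).
#' @param depth_mm nominal block depth (mm) carried on the result.
#' @return A [normalized_spectrum()].
#' @export
synthesize_block_spectrum <- function(a_eff_um, aac_db, band_mhz,
                                      noise_db = 0, seed = 1L,
                                      freq_step_mhz = 0.05, c_m_s = 1540,
                                      depth_mm = 0) {
  if (length(band_mhz) != 2 || !all(is.finite(band_mhz)) ||
      band_mhz[1] <= 0 || band_mhz[2] <= band_mhz[1])
    stop_invalid("band_mhz must be c(f_lo, f_hi) with 0 < f_lo < f_hi")
  f <- seq(band_mhz[1], band_mhz[2], by = freq_step_mhz)
  if (length(f) < 2) stop_invalid("band_mhz too narrow for freq_step_mhz")
  s <- backscatter_model_db(f, a_eff_um, aac_db, c_m_s)
  if (noise_db > 0)
    s <- s + with_seed(seed, stats::rnorm(length(f), sd = noise_db))
  normalized_spectrum(f, s, band_mhz, depth_mm = depth_mm)
}

#' Two-class cohort specification
#'
#' Describes a synthetic patient cohort: class sizes (default 42 good / 14
#' poor responders), feature names, class-conditional means and a common
#' covariance.
#'
#' @param n_good,n_poor class sizes.
#' @param feature_names character vector of feature names.
#' @param mean_good,mean_poor class mean vectors (length = #features).
#' @param covariance common covariance matrix (symmetric positive-definite).
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_good = 42L, n_poor = 14L, feature_names,
                        mean_good, mean_poor,
                        covariance = diag(length(feature_names)), seed = 1L) {
  if (n_good < 1 || n_poor < 1) stop_invalid("class sizes must be >= 1")
  p <- length(feature_names)
  if (length(mean_good) != p || length(mean_poor) != p)
    stop_invalid("class means must match feature_names in length")
  covariance <- as.matrix(covariance)
  if (!isTRUE(all.equal(covariance, t(covariance))))
    stop_invalid("covariance must be symmetric")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop_invalid("covariance must be positive-definite")
  structure(list(n_good = as.integer(n_good), n_poor = as.integer(n_poor),
                 feature_names = feature_names, mean_good = mean_good,
                 mean_poor = mean_poor, covariance = covariance,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a two-class feature cohort
#'
#' Draws patient feature rows from class-conditional multivariate normal
#' distributions per a [cohort_spec()].
#'
#' @param spec a [cohort_spec()].
#' @return list with `features` (data.frame, `patient_id` + feature columns)
#'   and `labels` (factor with levels good/poor, poor-first class order kept
#'   as `c("good","poor")`).
#' @export
generate_feature_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_good + spec$n_poor
  X <- with_seed(spec$seed, {
    xg <- MASS::mvrnorm(spec$n_good, spec$mean_good, spec$covariance)
    xp <- MASS::mvrnorm(spec$n_poor, spec$mean_poor, spec$covariance)
    rbind(matrix(xg, nrow = spec$n_good), matrix(xp, nrow = spec$n_poor))
  })
  colnames(X) <- spec$feature_names
  features <- data.frame(patient_id = sprintf("P%03d", seq_len(n)), X,
                         check.names = FALSE, stringsAsFactors = FALSE)
  labels <- factor(rep(c("good", "poor"), c(spec$n_good, spec$n_poor)),
                   levels = c("good", "poor"))
  list(features = features, labels = labels)
}

#' Generate a censored survival cohort
#'
#' Exponential event times with group-dependent hazards and independent
#' exponential censoring tuned to the requested expected censoring fraction.
#'
#' @param n_per_group integer vector of group sizes (recycled against
#'   `hazards`).
#' @param hazards per-group event hazards (1/month), > 0.
#' @param censor_rate expected fraction censored, in [0, 1).
#' @param seed integer seed.
#' @param group_names group labels (default good/poor).
#' @return data.frame with `patient_id`, `months`, `event` (1 = event,
#'   0 = censored) and `group`.
#' @export
generate_survival_cohort <- function(n_per_group, hazards, censor_rate = 0,
                                     seed = 1L,
                                     group_names = c("good", "poor")) {
  if (any(hazards <= 0)) stop_invalid("hazards must be > 0")
  if (censor_rate < 0 || censor_rate >= 1)
    stop_invalid("censor_rate must be in [0, 1)")
  k <- max(length(hazards), length(n_per_group))
  n_per_group <- rep_len(n_per_group, k)
  hazards <- rep_len(hazards, k)
  group_names <- rep_len(group_names, k)
  with_seed(seed, {
    rows <- lapply(seq_len(k), function(g) {
      n <- n_per_group[g]
      ev_t <- stats::rexp(n, rate = hazards[g])
      if (censor_rate > 0) {
        mu <- hazards[g] * censor_rate / (1 - censor_rate)
        cn_t <- stats::rexp(n, rate = mu)
      } else cn_t <- rep(Inf, n)
      data.frame(months = pmin(ev_t, cn_t),
                 event = as.integer(ev_t <= cn_t),
                 group = group_names[g], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- cbind(patient_id = sprintf("S%03d", seq_len(nrow(out))), out)
    out$patient_id <- as.character(out$patient_id)
    out
  })
}
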