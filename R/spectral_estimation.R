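# Per-block power spectra, reference-phantom normalization, attenuation
# estimation/correction, and linear spectral fits (MBF/SS/SI).

#' Averaged power spectrum of an analysis block
#'
#' Mean over the block's scan-line segments of Hann-windowed periodograms.
#' The one-sided periodogram uses the Parseval convention (interior bins
#' doubled), so its sum equals the windowed-signal energy.
#'
#' @param frame an [rf_frame()].
#' @param block one row of an `analysis_blocks` table (or any list with
#'   pixel ranges `r0`, `r1`, `c0`, `c1`).
#' @param nfft FFT length (zero-padded); must be >= the block sample length.
#' @return list of class `raw_spectrum`: `freq_mhz`, `power` (linear),
#'   `n_lines`.
#' @export
block_power_spectrum <- function(frame, block, nfft = 256L) {
  stopifnot(inherits(frame, "rf_frame"))
  r0 <- block$r0; r1 <- block$r1; c0 <- block$c0; c1 <- block$c1
  ns <- nrow(frame$samples); nl <- ncol(frame$samples)
  if (r0 < 1 || r1 > ns || c0 < 1 || c1 > nl || r1 < r0 || c1 < c0)
    stop_geometry("block pixel range outside the frame")
  len <- r1 - r0 + 1L
  if (len < 4L) stop_geometry("block shorter than the analysis window")
  if (nfft < len) stop_invalid("nfft must be >= block sample length")
  w <- hann_window(len)
  seg <- frame$samples[r0:r1, c0:c1, drop = FALSE] * w
  padded <- rbind(seg, matrix(0, nfft - len, ncol(seg)))
  P <- Mod(stats::mvfft(padded))^2 / nfft
  half <- nfft / 2 + 1
  Pone <- P[seq_len(half), , drop = FALSE]
  Pone[2:(half - 1), ] <- 2 * Pone[2:(half - 1), ]
  structure(list(freq_mhz = (seq_len(half) - 1) * frame$sampling_rate_hz /
                   nfft / 1e6,
                 power = rowMeans(Pone), n_lines = ncol(seg)),
            class = "raw_spectrum")
}

# Laterally averaged reference spectrum for an axial window, cached per
# (r0, r1) in `cache` (an environment) when given.
reference_spectrum <- function(ref_frame, r0, r1, nfft = 256L, cache = NULL) {
  key <- paste0(r0, "_", r1)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  sp <- block_power_spectrum(ref_frame,
                             list(r0 = r0, r1 = r1, c0 = 1L,
                                  c1 = ncol(ref_frame$samples)),
                             nfft = nfft)
  if (!is.null(cache)) cache[[key]] <- sp
  sp
}

#' Normalized power spectrum container
#'
#' @param f_mhz frequency grid (MHz).
#' @param s_db normalized power (dB) on the grid.
#' @param band_mhz usable band `c(f_lo, f_hi)` (MHz).
#' @param depth_mm block centre depth (mm).
#' @export
normalized_spectrum <- function(f_mhz, s_db, band_mhz, depth_mm = 0) {
  if (length(f_mhz) != length(s_db))
    stop_invalid("frequency grid and spectrum lengths differ")
  if (!all(is.finite(s_db)))
    stop_invalid("normalized spectrum must be finite on its band")
  structure(list(f_mhz = f_mhz, s_db = s_db, band_mhz = band_mhz,
                 depth_mm = depth_mm),
            class = "normalized_spectrum")
}

#' @export
print.normalized_spectrum <- function(x, ...) {
  cat(sprintf("Normalized spectrum: %d points on %.2f-%.2f MHz, depth %.1f mm\n",
              length(x$f_mhz), x$band_mhz[1], x$band_mhz[2], x$depth_mm))
  invisible(x)
}

#' Reference-phantom normalization
#'
#' `S_norm(dB) = 10*log10(S_sample / S_reference)` on the usable band. The
#' division cancels the system transfer function and diffraction effects
#' shared by the two acquisitions.
#'
#' @param sample_spec,reference_spec `raw_spectrum` objects on the same
#'   frequency grid.
#' @param band_mhz usable band `c(f_lo, f_hi)` (MHz).
#' @param depth_mm block centre depth (mm), carried through.
#' @return A [normalized_spectrum()].
#' @export
normalize_spectrum <- function(sample_spec, reference_spec, band_mhz,
                               depth_mm = 0) {
  if (length(sample_spec$freq_mhz) != length(reference_spec$freq_mhz) ||
      any(abs(sample_spec$freq_mhz - reference_spec$freq_mhz) > 1e-9))
    stop_invalid("sample and reference spectra must share a frequency grid")
  f <- sample_spec$freq_mhz
  keep <- f >= band_mhz[1] - 1e-9 & f <= band_mhz[2] + 1e-9
  if (sum(keep) < 2) stop_invalid("usable band contains < 2 frequency points")
  pr <- reference_spec$power[keep]
  if (any(pr <= 0))
    stop_invalid("reference power must be > 0 within the band")
  normalized_spectrum(f[keep],
                      10 * log10(sample_spec$power[keep] / pr),
                      band_mhz, depth_mm = depth_mm)
}

#' Point compensation for frequency-dependent attenuation
#'
#' Adds `4 * (ace - alpha_reference) * f * z` dB to the normalized spectrum
#' (f in MHz, z the overlying tissue path in cm), undoing the differential
#' round-trip attenuation between sample and reference phantom.
#'
#' @param spec a [normalized_spectrum()].
#' @param ace attenuation coefficient estimate (dB/cm/MHz).
#' @param alpha_reference reference-phantom attenuation slope (dB/cm/MHz).
#' @param depth_cm overlying tissue path (cm), >= 0.
#' @return The corrected [normalized_spectrum()].
#' @export
correct_attenuation <- function(spec, ace, alpha_reference, depth_cm) {
  stopifnot(inherits(spec, "normalized_spectrum"))
  check_scalar(ace, "ace")
  check_scalar(alpha_reference, "alpha_reference")
  check_scalar(depth_cm, "depth_cm", nonneg = TRUE)
  spec$s_db <- spec$s_db + 4 * (ace - alpha_reference) * spec$f_mhz * depth_cm
  spec
}

#' Linear fit of a normalized spectrum (MBF, SS, SI)
#'
#' Least-squares line over the usable band: spectral slope SS (dB/MHz),
#' 0-MHz intercept SI (dB) and midband fit MBF (dB), the fitted value at the
#' band centre. `MBF = SS * f_c + SI` holds exactly.
#'
#' @param spec a [normalized_spectrum()].
#' @return list of class `spectral_fit`: `mbf`, `ss`, `si`, `f_c_mhz`.
#' @export
fit_linear_spectrum <- function(spec) {
  stopifnot(inherits(spec, "normalized_spectrum"))
  if (length(spec$f_mhz) < 2 || diff(range(spec$f_mhz)) < 1e-9)
    stop_invalid("degenerate band: need >= 2 distinct frequency points")
  ft <- stats::lm.fit(cbind(1, spec$f_mhz), spec$s_db)
  si <- unname(ft$coefficients[1]); ss <- unname(ft$coefficients[2])
  f_c <- mean(spec$band_mhz)
  structure(list(mbf = ss * f_c + si, ss = ss, si = si, f_c_mhz = f_c),
            class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("Spectral fit: MBF %.2f dB, SS %.3f dB/MHz, SI %.2f dB (f_c %.2f MHz)\n",
              x$mbf, x$ss, x$si, x$f_c_mhz))
  invisible(x)
}

#' Attenuation coefficient estimate by the spectral difference method
#'
#' Tiles the core ROI into analysis blocks, forms the dB ratio of sample to
#' laterally-averaged reference spectra, regresses the ratio against depth at
#' each frequency, then regresses the per-frequency slopes against frequency.
#' With round-trip attenuation of `4 * alpha * f * z` dB the slope-of-slopes
#' is `-4 * (alpha - alpha_reference)`, giving
#' `ACE = alpha_reference - slope / 4`. One value per core ROI.
#'
#' @param frame sample [rf_frame()].
#' @param core_mask core [roi_mask()].
#' @param ref_frame reference-phantom [rf_frame()] (same geometry).
#' @param band_mhz usable band (MHz).
#' @param alpha_reference reference attenuation slope (dB/cm/MHz).
#' @param min_depth_span_mm minimum axial span of block centres (mm).
#' @param block_mm,overlap,min_inside tiling parameters.
#' @param nfft FFT length for block spectra.
#' @return list of class `ace_estimate`: `ace` (dB/cm/MHz), `delta_alpha`,
#'   `depth_span_mm`, `n_depths`, `residual_db_cm`.
#' @export
estimate_ace <- function(frame, core_mask, ref_frame, band_mhz,
                         alpha_reference = 0.5, min_depth_span_mm = 10,
                         block_mm = 2, overlap = 0.8, min_inside = 0.5,
                         nfft = 256L) {
  stopifnot(inherits(frame, "rf_frame"), inherits(ref_frame, "rf_frame"))
  px <- c(axial_spacing_mm(frame), frame$line_pitch_mm)
  blocks <- tile_blocks(core_mask, px, block_mm, overlap, min_inside)
  if (nrow(blocks) == 0) stop_geometry("core ROI yields no analysis blocks")
  ratio_by_depth(frame, ref_frame, blocks, band_mhz, nfft,
                 alpha_reference, min_depth_span_mm)
}

ratio_by_depth <- function(frame, ref_frame, blocks, band_mhz, nfft,
                           alpha_reference, min_depth_span_mm) {
  depths <- sort(unique(blocks$axial_start_mm))
  span <- diff(range(blocks$centre_depth_mm))
  if (span < min_depth_span_mm - 1e-9)
    stop_geometry(sprintf(
      "core depth span %.1f mm below the %.1f mm minimum for ACE estimation",
      span, min_depth_span_mm))
  cache <- new.env(parent = emptyenv())
  curves <- NULL; z_cm <- NULL
  for (d in depths) {
    rows <- blocks[abs(blocks$axial_start_mm - d) < 1e-9, , drop = FALSE]
    acc <- NULL
    for (i in seq_len(nrow(rows))) {
      b <- rows[i, ]
      sp <- block_power_spectrum(frame, b, nfft)
      rf <- reference_spectrum(ref_frame, b$r0, b$r1, nfft, cache)
      ns <- normalize_spectrum(sp, rf, band_mhz, depth_mm = b$centre_depth_mm)
      acc <- if (is.null(acc)) ns$s_db else acc + ns$s_db
      f_grid <- ns$f_mhz
    }
    curves <- cbind(curves, acc / nrow(rows))
    z_cm <- c(z_cm, (d + attr(blocks, "block_mm") / 2) / 10)
  }
  # slope of dB ratio vs depth, per frequency
  X <- cbind(1, z_cm)
  sl <- apply(curves, 1L, function(y) stats::lm.fit(X, y)$coefficients[2])
  # slope of those slopes vs frequency
  ft <- stats::lm.fit(cbind(1, f_grid), sl)
  slope2 <- unname(ft$coefficients[2])
  delta <- -slope2 / 4
  structure(list(ace = alpha_reference + delta, delta_alpha = delta,
                 depth_span_mm = span, n_depths = length(z_cm),
                 residual_db_cm = sqrt(mean(ft$residuals^2))),
            class = "ace_estimate")
}

#' @export
print.ace_estimate <- function(x, ...) {
  cat(sprintf("ACE: %.3f dB/cm/MHz (depth span %.1f mm, %d depths, resid %.3f dB/cm)\n",
              x$ace, x$depth_span_mm, x$n_depths, x$residual_db_cm))
  invisible(x)
}
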