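# Core containers and on-disk formats: RF frames, B-mode images, ROI masks,
# feature and label tables.

#' RF frame container
#'
#' Raw echo data with acquisition geometry. Columns are scan lines, rows are
#' axial samples; sample `i` (1-based) corresponds to depth
#' `axial_origin_mm + (i - 1) * c / (2 * fs)`.
#'
#' @param samples numeric matrix (axial samples x scan lines), finite.
#' @param sampling_rate_hz RF sampling rate (Hz).
#' @param line_pitch_mm lateral spacing between lines (mm).
#' @param speed_of_sound_m_s assumed speed of sound (m/s).
#' @param axial_origin_mm depth of the first sample (mm).
#' @return An object of class `rf_frame`.
#' @export
rf_frame <- function(samples, sampling_rate_hz, line_pitch_mm,
                     speed_of_sound_m_s = 1540, axial_origin_mm = 0) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop_format("samples must be a numeric matrix")
  if (ncol(samples) < 1L || nrow(samples) < 1L)
    stop_geometry("rf frame must have at least one sample and one line")
  if (!all(is.finite(samples))) stop_format("samples must be finite")
  check_scalar(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  check_scalar(line_pitch_mm, "line_pitch_mm", positive = TRUE)
  check_scalar(speed_of_sound_m_s, "speed_of_sound_m_s", positive = TRUE)
  check_scalar(axial_origin_mm, "axial_origin_mm", nonneg = TRUE)
  structure(list(samples = samples, sampling_rate_hz = sampling_rate_hz,
                 line_pitch_mm = line_pitch_mm,
                 speed_of_sound_m_s = speed_of_sound_m_s,
                 axial_origin_mm = axial_origin_mm),
            class = "rf_frame")
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("RF frame: %d samples x %d lines, fs = %.1f MHz, pitch = %.3f mm, c = %.0f m/s\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate_hz / 1e6,
              x$line_pitch_mm, x$speed_of_sound_m_s))
  invisible(x)
}

#' Axial sample spacing of a frame, in mm
#' @param frame an [rf_frame()].
#' @export
axial_spacing_mm <- function(frame) {
  frame$speed_of_sound_m_s / (2 * frame$sampling_rate_hz) * 1e3
}

rf_required_fields <- c("rf", "fs_hz", "pitch_mm", "c_m_s")

#' Write / read an RF frame container
#'
#' The container is a single-file named-array archive (R serialization of a
#' named list) with arrays/scalars `rf`, `fs_hz`, `pitch_mm`, `c_m_s` and
#' optional `axial_origin_mm`. `read_rf(write_rf(frame))` is the identity on
#' all fields; missing fields raise a format error naming the field.
#'
#' @param frame an [rf_frame()].
#' @param path file path.
#' @return `write_rf` returns `path` invisibly; `read_rf` returns an
#'   [rf_frame()].
#' @export
write_rf <- function(frame, path) {
  stopifnot(inherits(frame, "rf_frame"))
  payload <- list(rf = frame$samples, fs_hz = frame$sampling_rate_hz,
                  pitch_mm = frame$line_pitch_mm,
                  c_m_s = frame$speed_of_sound_m_s,
                  axial_origin_mm = frame$axial_origin_mm)
  saveRDS(payload, path, version = 2)
  invisible(path)
}

#' @rdname write_rf
#' @export
read_rf <- function(path) {
  payload <- tryCatch(readRDS(path),
                      error = function(e) stop_format("unreadable RF container: ",
                                                      conditionMessage(e)))
  if (!is.list(payload)) stop_format("RF container must hold a named list")
  missing <- setdiff(rf_required_fields, names(payload))
  if (length(missing))
    stop_format("RF container missing field(s): ", paste(missing, collapse = ", "))
  rf_frame(payload$rf, sampling_rate_hz = payload$fs_hz,
           line_pitch_mm = payload$pitch_mm,
           speed_of_sound_m_s = payload$c_m_s,
           axial_origin_mm = if (is.null(payload$axial_origin_mm)) 0
                             else payload$axial_origin_mm)
}

#' B-mode image from an RF frame
#'
#' Log-compressed analytic-signal envelope on the RF pixel grid (no scan
#' conversion; linear array, rectilinear grid). Pixels are
#' `20*log10(envelope / max envelope)`, so the maximum pixel is 0 dB.
#'
#' @param frame an [rf_frame()].
#' @return An object of class `bmode_image` with `pixels` (dB matrix),
#'   `axial_mm` and `lateral_mm` pixel sizes.
#' @export
compute_bmode <- function(frame) {
  stopifnot(inherits(frame, "rf_frame"))
  env <- envelope_matrix(frame$samples)
  m <- max(env)
  if (m == 0) stop_invalid("all-zero RF frame has no B-mode image")
  structure(list(pixels = 20 * log10(pmax(env, .Machine$double.xmin) / m),
                 axial_mm = axial_spacing_mm(frame),
                 lateral_mm = frame$line_pitch_mm),
            class = "bmode_image")
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf("B-mode image: %d x %d px (%.4f x %.3f mm)\n",
              nrow(x$pixels), ncol(x$pixels), x$axial_mm, x$lateral_mm))
  invisible(x)
}

#' ROI mask on the B-mode / RF pixel grid
#'
#' @param mask logical (or 0/1) matrix; rows index axial samples, columns
#'   scan lines.
#' @param region `"core"` or `"margin"`.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, region = c("core", "margin")) {
  region <- match.arg(region)
  if (!is.matrix(mask)) stop_format("mask must be a matrix")
  m <- mask
  storage.mode(m) <- "logical"
  if (anyNA(m)) stop_format("mask must be 0/1 with no NAs")
  if (region == "core" && !any(m))
    stop_invalid("core mask must contain at least one pixel")
  structure(list(mask = m, region = region), class = "roi_mask")
}

#' Read / write an ROI mask as a 0/1 PNG
#'
#' @param path PNG path.
#' @param region region tag for the returned mask.
#' @param mask an [roi_mask()] (for writing).
#' @export
read_mask_png <- function(path, region = "core") {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  roi_mask(img > 0.5, region = region)
}

#' @rdname read_mask_png
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  png::writePNG(mask$mask * 1, path)
  invisible(path)
}

#' Read a per-patient label table
#'
#' Validates a CSV with columns `patient_id`, `response_gp` (good/poor),
#' `response_ci` (complete/incomplete), `er`, `pr`, `her2` (0/1/NA),
#' `rfs_months` (>= 0) and `event` (0/1). Label case is normalized to lower
#' case; unknown values raise a validation error naming the row.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_labels <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "response_gp", "response_ci", "er", "pr", "her2",
            "rfs_months", "event")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop_format("label table missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(tab$patient_id))
    stop_format("duplicate patient_id in label table")
  tab$response_gp <- tolower(trimws(tab$response_gp))
  tab$response_ci <- tolower(trimws(tab$response_ci))
  check_levels <- function(x, levels, col) {
    bad <- which(!x %in% levels)
    if (length(bad))
      stop_format("invalid ", col, " value '", x[bad[1]], "' at row ", bad[1])
  }
  check_levels(tab$response_gp, c("good", "poor"), "response_gp")
  check_levels(tab$response_ci, c("complete", "incomplete"), "response_ci")
  for (col in c("er", "pr", "her2")) {
    v <- tab[[col]]
    bad <- which(!(is.na(v) | v %in% c(0, 1)))
    if (length(bad))
      stop_format("invalid ", col, " value at row ", bad[1])
  }
  bad <- which(!is.finite(tab$rfs_months) | tab$rfs_months < 0)
  if (length(bad)) stop_format("invalid rfs_months at row ", bad[1])
  bad <- which(!tab$event %in% c(0, 1))
  if (length(bad)) stop_format("invalid event flag at row ", bad[1])
  tab
}

#' Write / read a patient feature table as CSV
#'
#' @param features data.frame with `patient_id` plus numeric feature columns.
#' @param path CSV path.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"patient_id" %in% names(tab))
    stop_format("feature table missing column: patient_id")
  if (anyDuplicated(tab$patient_id))
    stop_format("duplicate patient_id in feature table")
  tab
}
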