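# Patient-level feature tables: per-region means/SDs and textures for each
# QUS parameter, core-to-margin comparison features, ACE, averaged over
# image planes, with optional molecular markers.

qus_params <- c("MBF", "SS", "SI", "ASD", "AAC")
qus_regions <- c("core", "margin")
qus_stats <- c("MEAN", "CON", "COR", "ENE", "HOM")

#' The QUS feature-name dictionary
#'
#' The full grid `{MBF,SS,SI,ASD,AAC} x {core,margin} x {MEAN,CON,COR,ENE,HOM}`
#' plus `{param}_CMR`, `{param}_CMCR` and `ACE_core_MEAN`: 61 QUS features.
#' With molecular markers, `ER`, `PR` and `HER2` are appended (64 columns).
#'
#' @param include_molecular append ER/PR/HER2 names.
#' @return character vector of column names.
#' @export
qus_feature_names <- function(include_molecular = FALSE) {
  grid <- as.vector(vapply(qus_params, function(p)
    as.vector(outer(paste(p, qus_regions, sep = "_"), qus_stats, paste,
                    sep = "_")), character(10)))
  cm <- as.vector(vapply(qus_params, function(p)
    paste(p, c("CMR", "CMCR"), sep = "_"), character(2)))
  out <- c(grid, cm, "ACE_core_MEAN")
  if (include_molecular) out <- c(out, "ER", "PR", "HER2")
  out
}

#' Region statistics of a parametric image
#'
#' Mean, sample standard deviation and Haralick texture vector over the valid
#' cells of a region. Statistics use valid cells only; an empty region gives
#' missing values.
#'
#' @param image a parametric image (see [assemble_parametric_image()]).
#' @param region region tag (`"core"` or `"margin"`), or `NULL` for all
#'   valid cells.
#' @param G gray levels for the texture computation.
#' @return named numeric vector `c(MEAN, SD, CON, COR, ENE, HOM)`.
#' @export
region_stats <- function(image, region = NULL, G = 16L) {
  v <- image$values
  if (!is.null(region)) v[!(image$region %in% region)] <- NA_real_
  v <- v[is.finite(v)]
  m <- if (length(v) >= 1) mean(v) else NA_real_
  s <- if (length(v) >= 2) stats::sd(v) else NA_real_
  tex <- if (length(v) >= 2) region_texture(image, region, G)
         else c(CON = NA_real_, COR = NA_real_, ENE = NA_real_, HOM = NA_real_)
  c(MEAN = m, SD = s, tex)
}

#' Core-to-margin ratio
#'
#' `CMR = core_mean / margin_mean`, an SNR-style image-quality feature
#' comparing parametric-image intensities between the tumour core and its
#' margin ring. Undefined (NA) when the margin mean is zero.
#'
#' @param core_mean,margin_mean region means of one parametric image.
#' @export
cmr <- function(core_mean, margin_mean) {
  if (!is.finite(core_mean) || !is.finite(margin_mean) || margin_mean == 0)
    return(NA_real_)
  core_mean / margin_mean
}

#' Core-to-margin contrast ratio
#'
#' `CMCR = |core_mean - margin_mean| / sqrt(core_sd^2 + margin_sd^2)`, the
#' CNR-style analogue that also accounts for bias. Undefined when both
#' standard deviations are zero. Invariant under common positive scaling of
#' all inputs.
#'
#' @param core_mean,core_sd,margin_mean,margin_sd region statistics.
#' @export
cmcr <- function(core_mean, core_sd, margin_mean, margin_sd) {
  if (!all(is.finite(c(core_mean, core_sd, margin_mean, margin_sd))))
    return(NA_real_)
  denom <- sqrt(core_sd^2 + margin_sd^2)
  if (denom == 0) return(NA_real_)
  abs(core_mean - margin_mean) / denom
}

#' Feature row of a single image plane
#'
#' Assembles the 61-feature QUS row from parametric images of the five
#' parameters (computed over a shared core+margin block grid) and the
#' ROI-level ACE.
#'
#' @param images named list of parametric images (`MBF`, `SS`, `SI`, `ASD`,
#'   `AAC`).
#' @param ace ROI-level attenuation estimate (dB/cm/MHz).
#' @param G gray levels for textures.
#' @return named numeric vector over [qus_feature_names()].
#' @export
plane_feature_row <- function(images, ace, G = 16L) {
  out <- stats::setNames(rep(NA_real_, 61), qus_feature_names())
  for (p in qus_params) {
    img <- images[[p]]
    if (is.null(img)) next
    st_core <- region_stats(img, "core", G)
    st_marg <- region_stats(img, "margin", G)
    for (s in qus_stats) {
      out[paste(p, "core", s, sep = "_")] <- st_core[[s]]
      out[paste(p, "margin", s, sep = "_")] <- st_marg[[s]]
    }
    out[paste0(p, "_CMR")] <- cmr(st_core[["MEAN"]], st_marg[["MEAN"]])
    out[paste0(p, "_CMCR")] <- cmcr(st_core[["MEAN"]], st_core[["SD"]],
                                    st_marg[["MEAN"]], st_marg[["SD"]])
  }
  out["ACE_core_MEAN"] <- ace
  out
}

#' Average per-plane feature rows into a patient row
#'
#' Unweighted mean across the 4-7 image planes covering the tumour volume,
#' missing-aware: a feature is missing only when missing in every plane.
#'
#' @param plane_rows list of named numeric vectors (identical names).
#' @return named numeric vector.
#' @export
aggregate_patient <- function(plane_rows) {
  if (length(plane_rows) == 0) stop_invalid("need at least one image plane")
  m <- do.call(rbind, plane_rows)
  out <- colMeans(m, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Build the patient feature matrix
#'
#' Stacks per-patient feature rows into the classification substrate, with
#' optional ER/PR/HER2 molecular markers (0/1).
#'
#' @param patient_rows named list: patient id -> feature vector from
#'   [aggregate_patient()].
#' @param molecular optional data.frame with `patient_id`, `er`, `pr`,
#'   `her2`.
#' @return data.frame with `patient_id` and feature columns.
#' @export
build_feature_matrix <- function(patient_rows, molecular = NULL) {
  ids <- names(patient_rows)
  if (is.null(ids) || anyDuplicated(ids))
    stop_invalid("patient_rows must be a uniquely named list")
  m <- do.call(rbind, patient_rows)
  out <- data.frame(patient_id = ids, m, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(molecular)) {
    i <- match(out$patient_id, molecular$patient_id)
    if (anyNA(i)) stop_invalid("molecular table missing patient(s): ",
                               paste(out$patient_id[is.na(i)], collapse = ", "))
    out$ER <- molecular$er[i]
    out$PR <- molecular$pr[i]
    out$HER2 <- molecular$her2[i]
  }
  out
}
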