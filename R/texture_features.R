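# GLCM-based Haralick texture features (CON, COR, ENE, HOM) computed from
# parametric images within a region mask.

#' Quantize a parametric image to G gray levels
#'
#' Linear min-max binning over the valid cells of a region into levels
#' `0 .. G-1`. Because binning is min-max, textures are invariant to affine
#' rescaling of the underlying parameter. A constant region cannot be
#' quantized and returns `NULL` (the degenerate-region signal; see
#' [region_texture()]).
#'
#' @param image a [assemble_parametric_image()] result, or a plain numeric
#'   matrix (NAs = invalid).
#' @param region optional region tag (`"core"`/`"margin"`) restricting the
#'   cells when `image` is a parametric image.
#' @param G number of gray levels (>= 2).
#' @return integer matrix of levels 0..G-1 with NAs outside the region, or
#'   `NULL` for a degenerate (constant) region.
#' @export
quantize <- function(image, region = NULL, G = 16L) {
  if (G < 2) stop_invalid("G must be >= 2")
  if (inherits(image, "parametric_image")) {
    v <- image$values
    if (!is.null(region)) v[!(image$region %in% region)] <- NA_real_
  } else v <- image
  ok <- is.finite(v)
  if (sum(ok) < 2) return(NULL)
  mn <- min(v[ok]); mx <- max(v[ok])
  if (mx <= mn) return(NULL)
  q <- floor((v - mn) / (mx - mn) * G)
  q[q == G] <- G - 1L
  q[!ok] <- NA_real_
  storage.mode(q) <- "integer"
  q
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurrences of gray levels at the given pixel offsets, pooled
#' over all offsets into a single matrix, symmetrized, and normalized to sum
#' 1. Both pixels of a pair must be valid (non-NA). The default offsets are
#' distance-1 neighbours in the four directions 0, 90, 45 and 135 degrees.
#'
#' @param q quantized integer matrix from [quantize()] (levels 0..G-1, NAs
#'   invalid).
#' @param G number of gray levels.
#' @param offsets list of `c(drow, dcol)` offsets.
#' @param symmetric add the transposed counts (default TRUE).
#' @return list of class `glcm`: `p` (G x G normalized matrix), `offsets`,
#'   `symmetric`, `n_pairs`; or `NULL` when no valid pair exists.
#' @export
compute_glcm <- function(q, G = 16L,
                         offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L),
                                        c(1L, -1L)),
                         symmetric = TRUE) {
  if (is.null(q)) return(NULL)
  nr <- nrow(q); nc <- ncol(q)
  counts <- matrix(0, G, G)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r_src <- seq_len(nr - abs(dr)) + max(0L, -dr)
    c_src <- seq_len(nc - abs(dc)) + max(0L, -dc)
    if (!length(r_src) || !length(c_src)) next
    a <- q[r_src, c_src, drop = FALSE]
    b <- q[r_src + dr, c_src + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- table(factor(a[ok], levels = 0:(G - 1)),
                 factor(b[ok], levels = 0:(G - 1)))
    counts <- counts + tab
  }
  if (symmetric) counts <- counts + t(counts)
  total <- sum(counts)
  if (total == 0) return(NULL)
  structure(list(p = counts / total, offsets = offsets,
                 symmetric = symmetric, n_pairs = total),
            class = "glcm")
}

#' Haralick texture features of a GLCM
#'
#' Contrast `CON = sum (i-j)^2 p`, correlation
#' `COR = sum (i-mu_i)(j-mu_j) p / (sigma_i sigma_j)`, energy
#' `ENE = sum p^2` and homogeneity `HOM = sum p / (1 + |i-j|)`, with i, j the
#' 0-based gray levels. COR is undefined (NA) when either marginal standard
#' deviation is zero.
#'
#' @param glcm a [compute_glcm()] result.
#' @return named numeric vector `c(CON, COR, ENE, HOM)`.
#' @export
haralick <- function(glcm) {
  stopifnot(inherits(glcm, "glcm"))
  p <- glcm$p
  G <- nrow(p)
  lv <- 0:(G - 1)
  I <- matrix(lv, G, G)       # row level i
  J <- matrix(lv, G, G, byrow = TRUE)
  con <- sum((I - J)^2 * p)
  ene <- sum(p^2)
  hom <- sum(p / (1 + abs(I - J)))
  pi_ <- rowSums(p); pj_ <- colSums(p)
  mu_i <- sum(lv * pi_); mu_j <- sum(lv * pj_)
  var_i <- sum((lv - mu_i)^2 * pi_); var_j <- sum((lv - mu_j)^2 * pj_)
  cor <- if (var_i > 0 && var_j > 0)
    sum((I - mu_i) * (J - mu_j) * p) / sqrt(var_i * var_j)
  else NA_real_
  c(CON = con, COR = cor, ENE = ene, HOM = hom)
}

#' Texture vector of a region of a parametric image
#'
#' Quantizes the region, pools the GLCM over the default offsets and returns
#' the four Haralick features. A degenerate (constant or too-small) region
#' returns the documented limits `CON = 0`, `ENE = 1`, `HOM = 1` and COR
#' missing.
#'
#' @inheritParams quantize
#' @inheritParams compute_glcm
#' @export
region_texture <- function(image, region = NULL, G = 16L,
                           offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L),
                                          c(1L, -1L)),
                           symmetric = TRUE) {
  degenerate <- c(CON = 0, COR = NA_real_, ENE = 1, HOM = 1)
  q <- quantize(image, region, G)
  if (is.null(q)) return(degenerate)
  g <- compute_glcm(q, G, offsets, symmetric)
  if (is.null(g)) return(degenerate)
  haralick(g)
}
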