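# Margin rings around core masks, overlapping analysis-block tiling, and
# parametric-image assembly.

#' Build a margin ring around a core mask
#'
#' The margin is the set of pixels whose Euclidean distance to the core, in
#' physical millimetres (anisotropic pixels supported), lies in
#' `(0, thickness_mm]`. It is disjoint from the core by construction and
#' clipped at the frame edges.
#'
#' @param core an [roi_mask()] with region `"core"`.
#' @param thickness_mm ring thickness (mm), > 0; the standard choices are 3,
#'   5 or 10 mm.
#' @param pixel_mm pixel sizes `c(axial, lateral)` in mm.
#' @return An [roi_mask()] with region `"margin"`.
#' @export
build_margin_mask <- function(core, thickness_mm, pixel_mm) {
  stopifnot(inherits(core, "roi_mask"))
  check_scalar(thickness_mm, "thickness_mm", positive = TRUE)
  if (length(pixel_mm) != 2 || any(pixel_mm <= 0))
    stop_invalid("pixel_mm must be c(axial, lateral) > 0")
  d <- distance_transform(core$mask, dy = pixel_mm[1], dx = pixel_mm[2])
  ring <- d > 0 & d <= thickness_mm
  if (!any(ring))
    stop_geometry("margin ring is empty (core touches all frame edges?)")
  structure(list(mask = ring, region = "margin"), class = "roi_mask")
}

#' Tile an ROI into overlapping analysis blocks
#'
#' Square blocks of side `block_mm` (default 2 mm) are laid on a regular
#' lattice anchored at the mask's bounding box with step
#' `block_mm * (1 - overlap)` (0.4 mm at the default 80% overlap) in both the
#' axial and lateral directions. A block is kept when at least `min_inside`
#' of its pixels lie inside the mask. Ordering is deterministic (axial-major
#' within each lateral position).
#'
#' @param mask an [roi_mask()].
#' @param pixel_mm pixel sizes `c(axial, lateral)` in mm.
#' @param block_mm block side (mm).
#' @param overlap fractional overlap of adjacent blocks, in [0, 1).
#' @param min_inside minimum fraction of block pixels inside the mask.
#' @return data.frame of class `analysis_blocks` with one row per kept block:
#'   grid indices `ax_idx`/`lat_idx`, physical starts and centre depth (mm),
#'   pixel ranges `r0:r1` x `c0:c1`, `frac_inside` and `region`; attributes
#'   `step_mm`, `block_mm`, `grid_dim` and `grid_origin_mm` describe the
#'   lattice. Empty (zero-row) with a warning when the mask is smaller than
#'   one block.
#' @export
tile_blocks <- function(mask, pixel_mm, block_mm = 2, overlap = 0.8,
                        min_inside = 0.5) {
  stopifnot(inherits(mask, "roi_mask"))
  tile_blocks_grid(list(mask), pixel_mm, block_mm, overlap, min_inside,
                   regions = mask$region)
}

#' Tile core and margin ROIs on a shared lattice
#'
#' Tiles the union bounding box of the two masks so that core and margin
#' blocks share one parametric-image grid. Each kept block is assigned
#' exclusively: core when the core mask satisfies `min_inside` (ties go to
#' the core), margin otherwise.
#'
#' @param core,margin [roi_mask()] objects.
#' @inheritParams tile_blocks
#' @export
tile_core_margin <- function(core, margin, pixel_mm, block_mm = 2,
                             overlap = 0.8, min_inside = 0.5) {
  stopifnot(inherits(core, "roi_mask"), inherits(margin, "roi_mask"))
  tile_blocks_grid(list(core, margin), pixel_mm, block_mm, overlap,
                   min_inside, regions = c("core", "margin"))
}

tile_blocks_grid <- function(masks, pixel_mm, block_mm, overlap, min_inside,
                             regions) {
  if (length(pixel_mm) != 2 || any(pixel_mm <= 0))
    stop_invalid("pixel_mm must be c(axial, lateral) > 0")
  check_scalar(block_mm, "block_mm", positive = TRUE)
  if (overlap < 0 || overlap >= 1) stop_invalid("overlap must be in [0, 1)")
  if (min_inside <= 0 || min_inside > 1)
    stop_invalid("min_inside must be in (0, 1]")
  dy <- pixel_mm[1]; dx <- pixel_mm[2]
  step <- block_mm * (1 - overlap)
  union <- Reduce(`|`, lapply(masks, `[[`, "mask"))
  nr <- nrow(union); nc <- ncol(union)
  empty <- function() {
    out <- data.frame(ax_idx = integer(0), lat_idx = integer(0),
                      axial_start_mm = numeric(0), lateral_start_mm = numeric(0),
                      r0 = integer(0), r1 = integer(0), c0 = integer(0),
                      c1 = integer(0), centre_depth_mm = numeric(0),
                      frac_inside = numeric(0), region = character(0),
                      stringsAsFactors = FALSE)
    structure(out, class = c("analysis_blocks", "data.frame"),
              step_mm = step, block_mm = block_mm, grid_dim = c(0L, 0L),
              grid_origin_mm = c(NA_real_, NA_real_))
  }
  if (!any(union)) { warning("mask is empty; no blocks"); return(empty()) }
  rows <- range(which(rowSums(union) > 0))
  cols <- range(which(colSums(union) > 0))
  y0 <- (rows[1] - 1) * dy; span_y <- (rows[2] - rows[1] + 1) * dy
  x0 <- (cols[1] - 1) * dx; span_x <- (cols[2] - cols[1] + 1) * dx
  eps <- 1e-9
  n_ax <- floor((span_y - block_mm) / step + eps) + 1
  n_lat <- floor((span_x - block_mm) / step + eps) + 1
  if (n_ax < 1 || n_lat < 1) {
    warning("mask smaller than one analysis block; no blocks")
    return(empty())
  }
  sats <- lapply(masks, function(m) summed_area(m$mask * 1))
  px_range <- function(start, size, d, n) {
    p0 <- ceiling(start / d + 0.5 - eps)
    p1 <- floor((start + size) / d + 0.5 - eps)
    c(max(1L, p0), min(n, p1))
  }
  recs <- vector("list", n_ax * n_lat)
  idx <- 0L
  for (kj in seq_len(n_lat)) {
    xs <- x0 + (kj - 1) * step
    cr <- px_range(xs, block_mm, dx, nc)
    for (ki in seq_len(n_ax)) {
      ys <- y0 + (ki - 1) * step
      rr <- px_range(ys, block_mm, dy, nr)
      npx <- (rr[2] - rr[1] + 1) * (cr[2] - cr[1] + 1)
      if (npx <= 0) next
      fracs <- vapply(sats, function(s)
        rect_sum(s, rr[1], rr[2] + 1L, cr[1], cr[2] + 1L) / npx, numeric(1))
      keep <- which(fracs >= min_inside - eps)
      if (!length(keep)) next
      reg <- regions[keep[1]]   # masks listed core-first: ties go to core
      idx <- idx + 1L
      recs[[idx]] <- data.frame(ax_idx = ki, lat_idx = kj,
                                axial_start_mm = ys, lateral_start_mm = xs,
                                r0 = rr[1], r1 = rr[2], c0 = cr[1], c1 = cr[2],
                                centre_depth_mm = ys + block_mm / 2,
                                frac_inside = fracs[keep[1]], region = reg,
                                stringsAsFactors = FALSE)
    }
  }
  if (idx == 0L) { warning("no block satisfies min_inside"); return(empty()) }
  out <- do.call(rbind, recs[seq_len(idx)])
  out <- out[order(out$lat_idx, out$ax_idx), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("analysis_blocks", "data.frame"),
            step_mm = step, block_mm = block_mm,
            grid_dim = c(n_ax, n_lat), grid_origin_mm = c(y0, x0))
}

#' Assemble block values into a parametric image
#'
#' Places one value per analysis block at its lattice node; nodes without a
#' block are invalid and excluded from all downstream statistics.
#'
#' @param blocks an `analysis_blocks` table from [tile_blocks()] or
#'   [tile_core_margin()].
#' @param values numeric vector, one value per block row.
#' @param parameter parameter name (e.g. `"SI"`).
#' @return An object of class `parametric_image` with `values` (matrix with
#'   NAs at invalid nodes), `valid`, `region` (character matrix), `parameter`
#'   and `step_mm`.
#' @export
assemble_parametric_image <- function(blocks, values, parameter) {
  stopifnot(inherits(blocks, "analysis_blocks"))
  if (length(values) != nrow(blocks))
    stop_invalid("need exactly one value per block (", nrow(blocks),
                 " blocks, ", length(values), " values)")
  gd <- attr(blocks, "grid_dim")
  vals <- matrix(NA_real_, gd[1], gd[2])
  regs <- matrix(NA_character_, gd[1], gd[2])
  ij <- cbind(blocks$ax_idx, blocks$lat_idx)
  vals[ij] <- values
  regs[ij] <- blocks$region
  structure(list(values = vals, valid = !is.na(vals), region = regs,
                 parameter = parameter, step_mm = attr(blocks, "step_mm"),
                 grid_origin_mm = attr(blocks, "grid_origin_mm")),
            class = "parametric_image")
}

#' @export
print.parametric_image <- function(x, ...) {
  cat(sprintf("Parametric image [%s]: %d x %d nodes (%d valid), step %.2f mm\n",
              x$parameter, nrow(x$values), ncol(x$values), sum(x$valid),
              x$step_mm))
  invisible(x)
}

#' Physical area of a mask, in mm^2
#' @param mask an [roi_mask()].
#' @param pixel_mm pixel sizes `c(axial, lateral)` in mm.
#' @export
mask_area_mm2 <- function(mask, pixel_mm) {
  sum(mask$mask) * pixel_mm[1] * pixel_mm[2]
}
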