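# Quantitative image analysis of stained cells: shape factors,
# stress-fiber density, vinculin:actin ratio, nuclei counting.
#
# Standard image operations (Otsu threshold, connected components,
# watershed, Gaussian filtering, erosion) are delegated to EBImage; the
# morphometric definitions themselves live here.

# best-fit ellipse of a pixel set from second-order moments.
# For a filled ellipse with semi-axes (A, B), the coordinate covariance
# eigenvalues are A^2/4 and B^2/4, so full axes are 4 sqrt(lambda).
.fit_ellipse <- function(xs, ys) {
  n <- length(xs)
  if (n < 3L) stop("degenerate mask: fewer than 3 pixels")
  cx <- mean(xs); cy <- mean(ys)
  cxx <- mean((xs - cx)^2); cyy <- mean((ys - cy)^2)
  cxy <- mean((xs - cx) * (ys - cy))
  tr <- cxx + cyy
  det_ <- cxx * cyy - cxy^2
  disc <- sqrt(max(tr^2 / 4 - det_, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (l1 <= 0) stop("degenerate mask: zero spatial extent")
  list(center = c(cx, cy),
       major = 4 * sqrt(l1), minor = 4 * sqrt(max(l2, 0)),
       orientation = 0.5 * atan2(2 * cxy, cxx - cyy),
       axis_ratio = sqrt(max(l2, 0) / l1))
}

.mask_indices_xy <- function(mask) {
  idx <- which(mask != 0)
  h <- nrow(mask)
  list(x = (idx - 1L) %/% h, y = (idx - 1L) %% h)  # 0-based (col, row)
}

# Otsu threshold robust to EBImage's [0, 1] range requirement
.otsu_threshold <- function(values) {
  rng <- range(values)
  if (diff(rng) == 0) return(Inf)
  norm <- (values - rng[1L]) / diff(rng)
  thr <- EBImage::otsu(matrix(norm, nrow = 1L), range = c(0, 1))
  rng[1L] + thr * diff(rng)
}

#' Segment cells from a single fluorescence channel
#'
#' Global Otsu threshold, connected-component labelling, removal of
#' components below `min_area`, and a best-fit ellipse from second-order
#' moments for each surviving component.
#'
#' @param img single-channel 2D matrix.
#' @param min_area smallest component kept, px^2.
#' @param pixel_size um per pixel (for areas and axes in physical units).
#' @param log_transform threshold log-intensities (default): with bright
#'   structures (stress fibers) on dim cytoplasm the linear-intensity Otsu
#'   threshold splits fibers from cytoplasm instead of cell from
#'   background; the log compresses that dynamic range so the cell body
#'   segments as one object.
#' @return list of `cell_mask` objects, each with `mask` (logical matrix),
#'   `cell_id`, `area_px`, `area_um2`, `major_um`, `minor_um`,
#'   `orientation`, `pixel_size`; empty list (with a warning) if nothing
#'   survives.
#' @export
segment_cells <- function(img, min_area = 200, pixel_size = 1,
                          log_transform = TRUE) {
  stopifnot(is.matrix(img))
  if (diff(range(img)) == 0) {
    warning("flat image: no cells segmented")
    return(list())
  }
  timg <- if (log_transform)
    log(img - min(img) + 1e-3 * diff(range(img))) else img
  thr <- .otsu_threshold(as.vector(timg))
  mask <- timg > thr
  lbl <- EBImage::bwlabel(mask)
  sizes <- table(lbl[lbl > 0])
  keep <- as.integer(names(sizes)[sizes >= min_area])
  if (length(keep) == 0L) {
    warning("no component of at least ", min_area, " px^2 found")
    return(list())
  }
  out <- lapply(seq_along(keep), function(i) {
    m <- lbl == keep[i]
    xy <- .mask_indices_xy(m)
    e <- .fit_ellipse(xy$x, xy$y)
    structure(list(mask = m, cell_id = i, area_px = sum(m),
                   area_um2 = sum(m) * pixel_size^2,
                   major_um = e$major * pixel_size,
                   minor_um = e$minor * pixel_size,
                   orientation = e$orientation,
                   axis_ratio = e$axis_ratio,
                   pixel_size = pixel_size),
              class = "cell_mask")
  })
  out
}

#' Build a cell mask from a manually drawn ROI polygon
#'
#' Supports the manual-outline workflow: a polygon of (x, y) vertices in
#' pixel coordinates (e.g. exported from ImageJ as plain text) is filled
#' by the even-odd rule.
#'
#' @param vertices data frame or 2-column matrix of polygon vertices
#'   (x, y), 0-based pixel coordinates.
#' @param dim image dimensions c(height, width) the mask should match.
#' @param pixel_size um per pixel.
#' @return a `cell_mask` object.
#' @export
roi_to_mask <- function(vertices, dim, pixel_size = 1) {
  v <- as.matrix(vertices)[, 1:2, drop = FALSE]
  h <- dim[1L]; w <- dim[2L]
  X <- matrix(rep(0:(w - 1L), each = h), h, w)
  Y <- matrix(rep(0:(h - 1L), times = w), h, w)
  nv <- nrow(v)
  inside <- matrix(FALSE, h, w)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]; xj <- v[j, 1L]; yj <- v[j, 2L]
    crosses <- ((yi > Y) != (yj > Y)) &
      (X < (xj - xi) * (Y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  xy <- .mask_indices_xy(inside)
  e <- .fit_ellipse(xy$x, xy$y)
  structure(list(mask = inside, cell_id = 1L, area_px = sum(inside),
                 area_um2 = sum(inside) * pixel_size^2,
                 major_um = e$major * pixel_size,
                 minor_um = e$minor * pixel_size,
                 orientation = e$orientation, axis_ratio = e$axis_ratio,
                 pixel_size = pixel_size),
            class = "cell_mask")
}

.as_mask_matrix <- function(mask) {
  if (inherits(mask, "cell_mask")) mask$mask else mask != 0
}

#' Cell shape factor (elongation)
#'
#' Ratio of the minor to major axis of the cell's best-fit ellipse: 1 for
#' a perfect circle, smaller for elongated cells.
#'
#' @param mask a `cell_mask` from [segment_cells()]/[roi_to_mask()], or a
#'   binary matrix.
#' @return dimensionless shape factor in (0, 1].
#' @export
cell_shape_factor <- function(mask) {
  if (inherits(mask, "cell_mask")) return(mask$axis_ratio)
  m <- .as_mask_matrix(mask)
  if (sum(m) == 0) stop("empty mask")
  xy <- .mask_indices_xy(m)
  .fit_ellipse(xy$x, xy$y)$axis_ratio
}

#' Nuclear shape factor
#'
#' Minor/major axis ratio of the nucleus's best-fit ellipse, the same
#' convention as [cell_shape_factor()]: 1 indicates a perfectly round
#' nucleus.  The perimeter-based circularity `4 pi A / P^2` (also 1 for a
#' circle) is available as an alternative.  Enforces the semi-automated
#' single-nucleus contract: the mask must contain exactly one connected
#' component.
#'
#' @param mask binary matrix containing a single nucleus.
#' @param method `"axis_ratio"` (default) or `"circularity"`.
#' @return dimensionless shape factor in (0, 1].
#' @export
nuclear_shape_factor <- function(mask, method = c("axis_ratio",
                                                  "circularity")) {
  method <- match.arg(method)
  m <- .as_mask_matrix(mask)
  if (sum(m) == 0) stop("empty nucleus mask")
  lbl <- EBImage::bwlabel(m)
  if (max(lbl) != 1)
    stop("nucleus mask must contain exactly one connected component; ",
         "found ", max(lbl))
  if (method == "axis_ratio") {
    xy <- .mask_indices_xy(m)
    return(.fit_ellipse(xy$x, xy$y)$axis_ratio)
  }
  feat <- EBImage::computeFeatures.shape(lbl)
  unname(min(4 * pi * feat[1L, "s.area"] / feat[1L, "s.perimeter"]^2, 1))
}

#' Stress-fiber factor: fiber pixel fraction of the cell area
#'
#' Detects linear actin structures with a Laplacian-of-Gaussian ridge
#' filter and reports the fraction of the cell area they occupy.  The
#' actin channel is normalized to its maximum (making the factor invariant
#' to uniform intensity scaling), filtered, and thresholded by Otsu's
#' method on the ridge response within the cell.  The response is
#' evaluated on a mask eroded by about twice the filter scale so the
#' cell-boundary step edge is not counted as fiber signal; because fibers
#' span the cell, the fiber fraction of the eroded interior estimates the
#' whole-cell fraction without bias.  A uniform (fiber-free) channel
#' yields exactly 0.
#'
#' @param actin actin channel, 2D matrix aligned with `mask`.
#' @param mask a `cell_mask` or binary matrix.
#' @param log_sigma_px Gaussian scale of the LoG filter, px (about half
#'   the expected fiber width).
#' @param use = `"pixel_count"` counts thresholded ridge pixels (default);
#'   `"response_sum"` sums the supra-threshold ridge response instead,
#'   normalized by the maximum response times area.
#' @return dimensionless factor in [0, 1].
#' @export
stress_fiber_factor <- function(actin, mask, log_sigma_px = 2.5,
                                use = c("pixel_count", "response_sum")) {
  use <- match.arg(use)
  m <- .as_mask_matrix(mask)
  if (sum(m) == 0) stop("empty cell mask")
  stopifnot(all(dim(actin) == dim(m)))
  img <- actin / max(actin)
  sm <- EBImage::imageData(EBImage::gblur(img, sigma = log_sigma_px))
  lap_kernel <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3L, 3L)
  ridge <- -EBImage::imageData(EBImage::filter2(sm, lap_kernel))
  er <- as.integer(ceiling(4 * log_sigma_px)) + 1L
  brush <- EBImage::makeBrush(2L * er + 1L, shape = "disc")
  core <- EBImage::imageData(EBImage::erode(m * 1, brush)) > 0
  if (sum(core) == 0) stop("cell mask vanished under erosion; ",
                           "mask too small for log_sigma_px = ", log_sigma_px)
  r_in <- ridge[core]
  r_in[r_in < 0] <- 0
  # a genuine fiber ridge responds at ~10% of the normalized contrast;
  # residual boundary/noise response sits orders of magnitude lower
  if (max(r_in) < 0.005 * diff(range(img))) return(0)
  thr <- max(.otsu_threshold(r_in), 0.05 * max(r_in))
  fiber <- r_in > thr
  if (use == "pixel_count") sum(fiber) / sum(core)
  else sum(r_in[fiber]) / (max(r_in) * sum(core))
}

#' Vinculin to actin intensity ratio within a cell
#'
#' Each channel is background-subtracted (median over pixels outside the
#' mask) with negatives clipped to zero; the ratio of the summed
#' background-corrected vinculin to actin intensity inside the mask is
#' returned.  Linear in the vinculin channel and scale-invariant only
#' jointly, matching a ratiometric readout.
#'
#' @param vinculin,actin aligned single-channel matrices.
#' @param mask a `cell_mask` or binary matrix.
#' @return dimensionless ratio >= 0.
#' @export
vinculin_actin_ratio <- function(vinculin, actin, mask) {
  m <- .as_mask_matrix(mask)
  if (sum(m) == 0) stop("empty cell mask")
  stopifnot(all(dim(vinculin) == dim(m)), all(dim(actin) == dim(m)))
  bg_v <- if (any(!m)) stats::median(vinculin[!m]) else 0
  bg_a <- if (any(!m)) stats::median(actin[!m]) else 0
  v <- sum(pmax(vinculin - bg_v, 0)[m])
  a <- sum(pmax(actin - bg_a, 0)[m])
  if (a == 0) stop("actin signal within the mask is zero")
  v / a
}

#' Count nuclei in a DAPI image
#'
#' Otsu threshold, removal of objects below `min_area`, and (optionally) a
#' distance-map watershed to split touching nuclei.  A blank image counts
#' zero.
#'
#' @param img single-channel matrix.
#' @param min_area smallest object counted, px^2.
#' @param split_touching apply a watershed split of touching objects.
#' @return integer count.
#' @export
count_nuclei <- function(img, min_area = 30, split_touching = FALSE) {
  stopifnot(is.matrix(img))
  if (diff(range(img)) == 0) return(0L)
  thr <- .otsu_threshold(as.vector(img))
  mask <- img > thr
  if (split_touching) {
    dm <- EBImage::distmap(mask * 1)
    lbl <- EBImage::imageData(EBImage::watershed(dm))
  } else {
    lbl <- EBImage::bwlabel(mask)
  }
  sizes <- table(lbl[lbl > 0])
  sum(sizes >= min_area)
}

#' Mean nuclei count over a batch of fields
#'
#' Transwell-migration readout: the average number of cells per image
#' over the acquired fields of view.
#'
#' @param images list of single-channel matrices.
#' @inheritParams count_nuclei
#' @return list with `mean_count`, `counts` and `n_fields`.
#' @export
count_nuclei_batch <- function(images, min_area = 30,
                               split_touching = FALSE) {
  counts <- vapply(images, count_nuclei, integer(1L), min_area = min_area,
                   split_touching = split_touching)
  list(mean_count = mean(counts), counts = counts,
       n_fields = length(images))
}

#' Maximum-intensity projection of an image stack
#'
#' Confocal stacks are projected before morphometry; this collapses a
#' height x width x slices array (or list of matrices) by the per-pixel
#' maximum.
#'
#' @param stack 3D array or list of matrices.
#' @return single 2D matrix.
#' @export
max_project <- function(stack) {
  if (is.list(stack)) stack <- simplify2array(stack)
  stopifnot(length(dim(stack)) == 3L)
  apply(stack, c(1L, 2L), max)
}

#' Morphometry record for one cell
#'
#' Bundles the per-cell metrics into one row: cell shape factor,
#' stress-fiber factor, nuclear shape factor, vinculin:actin ratio.
#'
#' @param cell_mask a `cell_mask` for the cell body.
#' @param actin,nucleus,vinculin aligned channel matrices (`nucleus` and
#'   `vinculin` optional).
#' @param nucleus_mask optional binary matrix of the (single) nucleus; if
#'   missing and `nucleus` is given, it is segmented by Otsu within the
#'   cell.
#' @param log_sigma_px LoG scale for [stress_fiber_factor()].
#' @return one-row data frame (`cell_id`, `cell_shape_factor`,
#'   `stress_fiber_factor`, `nuclear_shape_factor`,
#'   `vinculin_actin_ratio`); metrics without inputs are NA.
#' @export
morphometry_record <- function(cell_mask, actin, nucleus = NULL,
                               vinculin = NULL, nucleus_mask = NULL,
                               log_sigma_px = 2.5) {
  nsf <- NA_real_
  if (is.null(nucleus_mask) && !is.null(nucleus)) {
    thr <- .otsu_threshold(as.vector(nucleus))
    nucleus_mask <- (nucleus > thr) & .as_mask_matrix(cell_mask)
  }
  if (!is.null(nucleus_mask)) nsf <- nuclear_shape_factor(nucleus_mask)
  var_ <- if (!is.null(vinculin))
    vinculin_actin_ratio(vinculin, actin, cell_mask) else NA_real_
  data.frame(cell_id = cell_mask$cell_id,
             cell_shape_factor = cell_shape_factor(cell_mask),
             stress_fiber_factor = stress_fiber_factor(actin, cell_mask,
                                                       log_sigma_px),
             nuclear_shape_factor = nsf,
             vinculin_actin_ratio = var_)
}
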