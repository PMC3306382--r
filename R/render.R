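# Synthetic microscopy renderers.
#
# Image convention (shared with the tracking module): matrices are indexed
# m[row, col] with 0-based pixel coordinates x = col - 1, y = row - 1 and
# pixel centers at integer coordinates.  A physical position maps to pixels
# via x_px = x_um / pixel_size, retaining the sub-pixel offset.

# evaluate a Gaussian spot of total weight `photons` centred at (x, y) px,
# adding it in place to img over a +-5 sigma window
.stamp_spot <- function(img, x, y, sigma, photons) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(5 * sigma)
  cols <- max(1L, floor(x) - r + 1L):min(w, ceiling(x) + r + 1L)
  rows <- max(1L, floor(y) - r + 1L):min(h, ceiling(y) + r + 1L)
  gx <- exp(-((cols - 1L - x)^2) / (2 * sigma^2))
  gy <- exp(-((rows - 1L - y)^2) / (2 * sigma^2))
  img[rows, cols] <- img[rows, cols] +
    photons * (gy %o% gx) / (2 * pi * sigma^2)
  img
}

#' Offset trajectories to random positions inside a rendered field of view
#'
#' Trajectory generators start every particle at the origin; before
#' rendering, each particle's whole path must fit in the field.  This
#' draws an independent uniform offset for every particle such that its
#' bounding box stays at least `margin_px` from the field edge.
#'
#' @param trajectories a `trajectory_set` (um).
#' @param spec an [acquisition_spec()]; supplies `pixel_size` and
#'   `field_dim`.
#' @param margin_px margin kept free around every path, px.
#' @param min_separation_px minimum distance between path centres, px;
#'   overlapping point-spread functions corrupt centroid localization, so
#'   fields are drawn with separated particles (as an experimenter would
#'   select them).
#' @param seed optional integer seed.
#' @return the trajectory set with shifted coordinates.
#' @export
scatter_trajectories <- function(trajectories, spec, margin_px = 8,
                                 min_separation_px = 16, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- spec$field_dim[1L]; h <- spec$field_dim[2L]
  px <- spec$pixel_size
  out <- trajectories
  centers <- matrix(numeric(0), 0L, 2L)
  for (id in unique(out$particle_id)) {
    sel <- out$particle_id == id
    rx <- range(out$x_um[sel]) / px
    ry <- range(out$y_um[sel]) / px
    lo_x <- margin_px - rx[1L]; hi_x <- (w - 1L - margin_px) - rx[2L]
    lo_y <- margin_px - ry[1L]; hi_y <- (h - 1L - margin_px) - ry[2L]
    if (hi_x < lo_x || hi_y < lo_y)
      stop("particle ", id, " path does not fit in the field of view")
    ok <- FALSE
    for (attempt in seq_len(200L)) {
      ox <- stats::runif(1L, lo_x, hi_x)
      oy <- stats::runif(1L, lo_y, hi_y)
      cand <- c(mean(rx) + ox, mean(ry) + oy)
      if (nrow(centers) == 0L ||
          all(sqrt(rowSums(sweep(centers, 2L, cand)^2)) >=
              min_separation_px)) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place particle ", id, " at separation ",
           min_separation_px, " px; reduce n_particles or separation")
    centers <- rbind(centers, cand)
    out$x_um[sel] <- out$x_um[sel] + ox * px
    out$y_um[sel] <- out$y_um[sel] + oy * px
  }
  out
}

#' Render a fluorescence movie of probe particles
#'
#' Each frame is a sum of 2D Gaussian spots (sigma = `spec$psf_sigma`)
#' carrying `spec$photons_per_particle` photons, over a uniform background
#' of `spec$background_photons` photons/px, with optional shot noise.
#' Ground-truth sub-pixel positions are returned alongside the stack.
#'
#' @param trajectories a `trajectory_set` in um, already placed inside the
#'   field (see [scatter_trajectories()]).
#' @param spec an [acquisition_spec()].
#' @param noise_model `"poisson"` applies shot noise to the expected photon
#'   counts (after background addition); `"none"` returns the noiseless
#'   expectation; `"gaussian"` adds read noise of sd `read_noise_sd`.
#' @param read_noise_sd Gaussian read noise, photons (only for
#'   `noise_model = "gaussian"`).
#' @param seed optional integer seed.
#' @return list with `frames` (array height x width x n_frames, photons),
#'   `positions_px` (data frame particle_id, frame, x_px, y_px) and `spec`.
#' @export
render_particle_stack <- function(trajectories, spec,
                                  noise_model = c("poisson", "none",
                                                  "gaussian"),
                                  read_noise_sd = 2, seed = NULL) {
  noise_model <- match.arg(noise_model)
  if (!is.null(seed)) set.seed(seed)
  w <- spec$field_dim[1L]; h <- spec$field_dim[2L]
  pos <- data.frame(particle_id = trajectories$particle_id,
                    frame = trajectories$frame,
                    x_px = trajectories$x_um / spec$pixel_size,
                    y_px = trajectories$y_um / spec$pixel_size)
  bad <- pos$x_px < 0 | pos$x_px > w - 1L | pos$y_px < 0 | pos$y_px > h - 1L
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("particle %s leaves the field of view at frame %d",
                 pos$particle_id[i], pos$frame[i]))
  }
  frames <- unique(pos$frame)
  stack <- array(0, dim = c(h, w, length(frames)))
  for (k in seq_along(frames)) {
    img <- matrix(spec$background_photons, h, w)
    rows <- pos[pos$frame == frames[k], ]
    for (j in seq_len(nrow(rows)))
      img <- .stamp_spot(img, rows$x_px[j], rows$y_px[j], spec$psf_sigma,
                         spec$photons_per_particle)
    if (noise_model == "poisson")
      img <- matrix(stats::rpois(length(img), img), h, w)
    else if (noise_model == "gaussian")
      img <- img + matrix(stats::rnorm(length(img), sd = read_noise_sd), h, w)
    stack[, , k] <- img
  }
  list(frames = stack, positions_px = pos, spec = spec)
}

#' Geometry of a synthetic stained cell
#'
#' Describes an elliptical cell body with linear actin stress fibers, an
#' elliptical nucleus, and punctate vinculin adhesions, used to render
#' multi-channel fixtures with exact geometric ground truth.
#'
#' @param cell_major_axis,cell_minor_axis full cell axes, um.
#' @param cell_orientation major-axis angle, rad.
#' @param nucleus_major_axis,nucleus_minor_axis full nuclear axes, um.
#' @param n_fibers number of stress fibers.
#' @param fiber_width fiber width, um.
#' @param adhesion_count number of vinculin puncta.
#' @param intensity_levels named list of per-channel intensities
#'   (background, cytoplasm, fiber, nucleus, vinculin), arbitrary units.
#' @param noise_model `"none"`, `"poisson"` or `"gaussian"`.
#' @param pixel_size um per pixel of the rendered image.
#' @param seed integer seed.
#' @return an object of class `synthetic_cell_spec`.
#' @export
synthetic_cell_spec <- function(cell_major_axis = 40, cell_minor_axis = 20,
                                cell_orientation = 0,
                                nucleus_major_axis = 12,
                                nucleus_minor_axis = 9,
                                n_fibers = 12, fiber_width = 0.8,
                                adhesion_count = 30,
                                intensity_levels = list(background = 0.01,
                                                        cytoplasm = 0.2,
                                                        fiber = 1,
                                                        nucleus = 1,
                                                        vinculin = 1),
                                noise_model = c("none", "poisson",
                                                "gaussian"),
                                pixel_size = 0.2, seed = NULL) {
  noise_model <- match.arg(noise_model)
  if (cell_minor_axis > cell_major_axis)
    stop("cell minor axis must not exceed the major axis")
  if (nucleus_minor_axis > nucleus_major_axis)
    stop("nucleus minor axis must not exceed the major axis")
  if (n_fibers < 0) stop("n_fibers must be >= 0")
  structure(list(cell_major_axis = cell_major_axis,
                 cell_minor_axis = cell_minor_axis,
                 cell_orientation = cell_orientation,
                 nucleus_major_axis = nucleus_major_axis,
                 nucleus_minor_axis = nucleus_minor_axis,
                 n_fibers = as.integer(n_fibers),
                 fiber_width = fiber_width,
                 adhesion_count = as.integer(adhesion_count),
                 intensity_levels = intensity_levels,
                 noise_model = noise_model,
                 pixel_size = pixel_size, seed = seed),
            class = "synthetic_cell_spec")
}

# binary raster of an ellipse with full axes (major, minor) um, centred at
# (cx, cy) px, rotated by theta
.raster_ellipse <- function(h, w, cx, cy, major_px, minor_px, theta) {
  X <- matrix(rep(0:(w - 1L), each = h), h, w)
  Y <- matrix(rep(0:(h - 1L), times = w), h, w)
  u <- (X - cx) * cos(theta) + (Y - cy) * sin(theta)
  v <- -(X - cx) * sin(theta) + (Y - cy) * cos(theta)
  (u / (major_px / 2))^2 + (v / (minor_px / 2))^2 <= 1
}

.apply_noise <- function(img, noise_model, photon_scale = 1000,
                         gaussian_sd = 0.01) {
  switch(noise_model,
    none = img,
    poisson = matrix(stats::rpois(length(img), img * photon_scale),
                     nrow(img), ncol(img)) / photon_scale,
    gaussian = img + matrix(stats::rnorm(length(img), sd = gaussian_sd),
                            nrow(img), ncol(img)))
}

#' Render a synthetic multi-channel stained-cell image
#'
#' Produces aligned actin (cytoplasm + linear stress fibers), nucleus, and
#' vinculin (puncta) channels together with the exact geometric ground
#' truth: the cell and nuclear axis ratios, the fiber pixel fraction of
#' the cell area, and the puncta positions.  Fibers are chords roughly
#' parallel to the cell's major axis, as stress fibers align in elongated
#' cells.
#'
#' @param spec a [synthetic_cell_spec()].
#' @param seed optional integer seed; overrides `spec$seed`.
#' @return list with `channels` (named list of matrices: actin, nucleus,
#'   vinculin) and `truth` (cell/nuclear shape factors, fiber_fraction,
#'   masks, adhesion positions, pixel_size).
#' @export
render_cell_image <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_cell_spec"))
  seed <- if (!is.null(seed)) seed else spec$seed
  if (!is.null(seed)) set.seed(seed)
  px <- spec$pixel_size
  major_px <- spec$cell_major_axis / px
  minor_px <- spec$cell_minor_axis / px
  pad <- 10
  side <- ceiling(major_px) + 2L * pad
  h <- w <- as.integer(side)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  th <- spec$cell_orientation
  cell <- .raster_ellipse(h, w, cx, cy, major_px, minor_px, th)
  nucleus <- .raster_ellipse(h, w, cx, cy, spec$nucleus_major_axis / px,
                             spec$nucleus_minor_axis / px, th)
  if (any(nucleus & !cell))
    stop("nucleus is not contained in the cell body")

  lv <- spec$intensity_levels
  X <- matrix(rep(0:(w - 1L), each = h), h, w)
  Y <- matrix(rep(0:(h - 1L), times = w), h, w)
  # chords parallel-ish to the major axis at random perpendicular offsets
  fiber <- matrix(FALSE, h, w)
  half_w <- spec$fiber_width / px / 2
  for (i in seq_len(spec$n_fibers)) {
    phi <- th + stats::runif(1L, -0.2, 0.2)
    off <- stats::runif(1L, -0.85, 0.85) * minor_px / 2
    # signed perpendicular distance to the line through the offset point
    d <- -(X - (cx - off * sin(th))) * sin(phi) +
      (Y - (cy + off * cos(th))) * cos(phi)
    fiber <- fiber | (abs(d) <= half_w & cell)
  }
  actin <- matrix(lv$background, h, w)
  actin[cell] <- lv$cytoplasm
  actin[fiber] <- lv$fiber
  nuc_img <- matrix(lv$background, h, w)
  nuc_img[nucleus] <- lv$nucleus
  vinc <- matrix(lv$background, h, w)
  adhesions <- NULL
  if (spec$adhesion_count > 0) {
    inside <- which(cell & !nucleus)
    pick <- sample(inside, min(spec$adhesion_count, length(inside)))
    ax <- (pick - 1L) %/% h  # 0-based col = x
    ay <- (pick - 1L) %% h   # 0-based row = y
    for (j in seq_along(pick))
      vinc <- .stamp_spot(vinc, ax[j], ay[j], 1.5, lv$vinculin * 10)
    adhesions <- data.frame(x_px = ax, y_px = ay)
  }
  channels <- lapply(list(actin = actin, nucleus = nuc_img, vinculin = vinc),
                     .apply_noise, noise_model = spec$noise_model)
  list(channels = channels,
       truth = list(
         cell_shape_factor = spec$cell_minor_axis / spec$cell_major_axis,
         nuclear_shape_factor =
           spec$nucleus_minor_axis / spec$nucleus_major_axis,
         fiber_fraction = sum(fiber & cell) / sum(cell),
         cell_mask = cell, nucleus_mask = nucleus, fiber_mask = fiber,
         adhesions = adhesions, pixel_size = px,
         orientation = th, seed = seed))
}

#' Render a DAPI-like field of well-separated nuclei
#'
#' Places `n_nuclei` elliptical blobs with centres at least
#' `min_separation` px apart (and clear of the field edge) by rejection
#' sampling, then renders them with a slight Gaussian blur.  The true
#' count is returned with the image.
#'
#' @param n_nuclei number of nuclei (>= 0).
#' @param field_dim c(width, height) px.
#' @param nucleus_axes full (major, minor) axes of each nucleus, px.
#' @param min_separation minimum centre-to-centre distance, px.
#' @param seed optional integer seed.
#' @param max_attempts placement attempts before giving up.
#' @return list with `image` (matrix), `count` (true count) and `centers`.
#' @export
render_nuclei_field <- function(n_nuclei, field_dim = c(512L, 512L),
                                nucleus_axes = c(14, 10),
                                min_separation = 30, seed = NULL,
                                max_attempts = 500 * (n_nuclei + 1L)) {
  if (n_nuclei < 0) stop("n_nuclei must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  w <- as.integer(field_dim[1L]); h <- as.integer(field_dim[2L])
  img <- matrix(0, h, w)
  margin <- nucleus_axes[1L] / 2 + 2
  centers <- matrix(numeric(0), 0L, 2L)
  attempts <- 0L
  while (nrow(centers) < n_nuclei) {
    if (attempts >= max_attempts)
      stop("could not place ", n_nuclei, " nuclei at separation ",
           min_separation, " within ", max_attempts, " attempts")
    attempts <- attempts + 1L
    cand <- c(stats::runif(1L, margin, w - 1 - margin),
              stats::runif(1L, margin, h - 1 - margin))
    if (nrow(centers) == 0L ||
        all(sqrt(rowSums(sweep(centers, 2L, cand)^2)) >= min_separation))
      centers <- rbind(centers, cand)
  }
  if (n_nuclei > 0) {
    for (i in seq_len(n_nuclei)) {
      e <- .raster_ellipse(h, w, centers[i, 1L], centers[i, 2L],
                           nucleus_axes[1L], nucleus_axes[2L],
                           stats::runif(1L, 0, pi))
      img[e] <- 1
    }
    img <- EBImage::imageData(EBImage::gblur(img, sigma = 1))
  }
  rownames(centers) <- NULL
  list(image = img, count = as.integer(n_nuclei), centers = centers)
}
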