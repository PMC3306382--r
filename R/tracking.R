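# Particle localization and trajectory linking.
#
# Coordinates are 0-based with pixel centers at integer positions and
# order (x = column, y = row), matching the renderer.

#' Detection and linking parameters
#'
#' @param detection_threshold candidate local maxima must exceed this
#'   fraction of the frame's brightest background-subtracted pixel.
#' @param window_radius half-width of the square centroid window, px; must
#'   cover the PSF extent.
#' @param max_link_displacement largest allowed frame-to-frame jump, px.
#' @param min_length minimum trajectory length kept, frames (>= 10).
#' @param pixel_size um per pixel, used by [to_physical()].
#' @param saturation_level intensity at or above which a detection is
#'   flagged as saturated.
#' @return an object of class `tracking_config`.
#' @export
tracking_config <- function(detection_threshold = 0.3, window_radius = 6,
                            max_link_displacement = 5, min_length = 100,
                            pixel_size = 0.1, saturation_level = Inf) {
  if (detection_threshold <= 0 || window_radius <= 0 ||
      max_link_displacement <= 0 || min_length <= 0 || pixel_size <= 0)
    stop("all tracking_config parameters must be positive")
  if (min_length < 10) stop("min_length must be >= 10 frames")
  structure(list(detection_threshold = detection_threshold,
                 window_radius = as.integer(window_radius),
                 max_link_displacement = max_link_displacement,
                 min_length = as.integer(min_length),
                 pixel_size = pixel_size,
                 saturation_level = saturation_level),
            class = "tracking_config")
}

# logical matrix of strict-or-equal local maxima in the 8-neighbourhood
.local_maxima <- function(img) {
  h <- nrow(img); w <- ncol(img)
  pad <- matrix(-Inf, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- img
  res <- matrix(TRUE, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0L && dy == 0L) next
    res <- res & img >= pad[(2:(h + 1L)) + dy, (2:(w + 1L)) + dx]
  }
  res
}

#' Locate particles in one frame by intensity-weighted centroid
#'
#' The frame median is taken as the background estimate (robust to sparse
#' bright spots) and subtracted, with negative residuals clipped to zero.
#' Local maxima exceeding `detection_threshold` times the brightest
#' residual seed detections; maxima within one window radius of a brighter
#' seed are merged into it.  Each detection is the intensity-weighted
#' centroid of the residual over the window around its seed.
#'
#' @param img a 2D numeric matrix (one frame).
#' @param config a [tracking_config()].
#' @return data frame with columns `x_px`, `y_px`, `total_intensity`,
#'   `saturated`; zero rows for a blank or flat frame.
#' @export
locate_particles <- function(img, config = tracking_config()) {
  stopifnot(is.matrix(img))
  bg <- stats::median(img)
  sub <- pmax(img - bg, 0)
  peak <- max(sub)
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      total_intensity = numeric(0), saturated = logical(0))
  if (peak <= 0) return(empty)
  cand <- which(.local_maxima(sub) & sub > config$detection_threshold * peak)
  if (length(cand) == 0L) return(empty)
  h <- nrow(img); wd <- ncol(img)
  cy <- (cand - 1L) %% h          # 0-based row
  cx <- (cand - 1L) %/% h         # 0-based col
  ord <- order(sub[cand], decreasing = TRUE)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0L ||
        all(pmax(abs(cx[i] - cx[keep]), abs(cy[i] - cy[keep])) >
            config$window_radius))
      keep <- c(keep, i)
  }
  r <- config$window_radius
  out <- lapply(keep, function(i) {
    cols <- max(1L, cx[i] - r + 1L):min(wd, cx[i] + r + 1L)
    rows <- max(1L, cy[i] - r + 1L):min(h, cy[i] + r + 1L)
    win <- sub[rows, cols, drop = FALSE]
    tot <- sum(win)
    data.frame(
      x_px = sum(win * rep(cols - 1L, each = length(rows))) / tot,
      y_px = sum(win * rep(rows - 1L, times = length(cols))) / tot,
      total_intensity = tot,
      saturated = any(img[rows, cols] >= config$saturation_level))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Locate particles in every frame of a stack
#'
#' @param stack 3D array (height x width x frames) as returned by
#'   [render_particle_stack()], or a list of matrices.
#' @param config a [tracking_config()].
#' @return data frame of detections with a 0-based `frame` column.
#' @export
locate_stack <- function(stack, config = tracking_config()) {
  frames <- if (is.array(stack) && length(dim(stack)) == 3L)
    lapply(seq_len(dim(stack)[3L]), function(k) stack[, , k])
  else stack
  dets <- lapply(seq_along(frames), function(k) {
    d <- locate_particles(frames[[k]], config)
    if (nrow(d)) d$frame <- k - 1L
    d
  })
  dets <- dets[vapply(dets, nrow, 1L) > 0L]
  if (length(dets) == 0L)
    return(data.frame(frame = integer(0), x_px = numeric(0),
                      y_px = numeric(0), total_intensity = numeric(0),
                      saturated = logical(0)))
  out <- do.call(rbind, dets)
  out[, c("frame", "x_px", "y_px", "total_intensity", "saturated")]
}

#' Link per-frame detections into trajectories
#'
#' Greedy mutual-nearest-neighbour assignment between consecutive frames:
#' a link is made only if each detection is the other's nearest neighbour
#' and the jump does not exceed `max_link_displacement`; candidate links
#' are accepted in order of increasing distance, with exact ties broken
#' deterministically by the lower track id.  Unmatched detections start
#' new tracks; tracks shorter than `min_length` are discarded.  No gap
#' closing: a missed frame terminates the track.
#'
#' @param detections data frame with `frame`, `x_px`, `y_px` (e.g. from
#'   [locate_stack()]).
#' @param config a [tracking_config()].
#' @return data frame with `particle_id`, `frame`, `x_px`, `y_px`.
#' @export
link_detections <- function(detections, config = tracking_config()) {
  stopifnot(all(c("frame", "x_px", "y_px") %in% names(detections)))
  if (nrow(detections) == 0L)
    return(data.frame(particle_id = integer(0), frame = integer(0),
                      x_px = numeric(0), y_px = numeric(0)))
  frames <- sort(unique(detections$frame))
  next_id <- 0L
  per_frame <- vector("list", length(frames))
  active <- data.frame(id = integer(0), x = numeric(0), y = numeric(0))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    det <- detections[detections$frame == f, c("frame", "x_px", "y_px")]
    n_new <- nrow(det)
    ids <- rep(NA_integer_, n_new)
    if (nrow(active) > 0L && n_new > 0L) {
      dmat <- sqrt(outer(active$x, det$x_px, "-")^2 +
                   outer(active$y, det$y_px, "-")^2)
      repeat {
        dmin <- min(dmat)
        if (!is.finite(dmin) || dmin > config$max_link_displacement) break
        i <- which(dmat == dmin, arr.ind = TRUE)
        # ties: lowest track id wins
        i <- i[order(active$id[i[, 1L]]), , drop = FALSE][1L, ]
        ids[i[2L]] <- active$id[i[1L]]
        dmat[i[1L], ] <- Inf
        dmat[, i[2L]] <- Inf
      }
    }
    fresh <- is.na(ids)
    if (any(fresh)) {
      ids[fresh] <- next_id + seq_len(sum(fresh))
      next_id <- next_id + sum(fresh)
    }
    det$particle_id <- ids
    per_frame[[fi]] <- det
    # unmatched old tracks terminate (no gap closing)
    active <- data.frame(id = ids, x = det$x_px, y = det$y_px)
  }
  out <- do.call(rbind, per_frame)[, c("particle_id", "frame",
                                       "x_px", "y_px")]
  out <- out[order(out$particle_id, out$frame), ]
  len <- table(out$particle_id)
  keep <- names(len)[len >= config$min_length]
  out <- out[out$particle_id %in% as.integer(keep), ]
  rownames(out) <- NULL
  out
}

#' Convert pixel-unit tracks to physical units
#'
#' Lossless, invertible scaling: `x_um = x_px * pixel_size` and
#' `t_s = frame * frame_interval`.
#'
#' @param tracks data frame with `particle_id`, `frame`, `x_px`, `y_px`.
#' @param pixel_size um per pixel (> 0).
#' @param frame_interval seconds per frame (> 0).
#' @return a `trajectory_set` data frame (um, s).
#' @export
to_physical <- function(tracks, pixel_size, frame_interval) {
  if (pixel_size <= 0 || frame_interval <= 0)
    stop("pixel_size and frame_interval must be positive")
  out <- data.frame(particle_id = tracks$particle_id,
                    frame = tracks$frame,
                    t_s = tracks$frame * frame_interval,
                    x_um = tracks$x_px * pixel_size,
                    y_um = tracks$y_px * pixel_size)
  structure(out, class = c("trajectory_set", "data.frame"),
            frame_interval = frame_interval)
}

#' Calibrate static localization error from immobilized particles
#'
#' The standard calibration for particle-tracking resolution: track
#' particles immobilized on a coverslip and measure the apparent motion.
#' Returns the per-axis RMS deviation of positions about each trajectory's
#' mean, pooled across particles and axes, and the implied additive MSD
#' floor `4 sigma^2`.
#'
#' @param trajectories a `trajectory_set` (um) of immobilized particles;
#'   every trajectory must have at least `min_frames` positions.
#' @param min_frames minimum frames per trajectory for a stable mean.
#' @return list with `rms_nm` (per-axis RMS error, nm), `rms_um`, and
#'   `msd_floor_um2` (= 4 sigma^2, um^2).
#' @export
estimate_static_error <- function(trajectories, min_frames = 100) {
  parts <- split_trajectories(trajectories)
  if (length(parts) < 1L) stop("need at least one trajectory")
  short <- vapply(parts, nrow, 1L) < min_frames
  if (any(short))
    stop("every trajectory must have at least ", min_frames,
         " frames; shortest has ", min(vapply(parts, nrow, 1L)))
  sq <- unlist(lapply(parts, function(d)
    c((d$x_um - mean(d$x_um))^2, (d$y_um - mean(d$y_um))^2)))
  rms_um <- sqrt(mean(sq))
  list(rms_nm = rms_um * 1e3, rms_um = rms_um,
       msd_floor_um2 = 4 * rms_um^2)
}
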