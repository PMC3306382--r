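# Plain-text and TIFF interchange formats.

#' Write trajectories to CSV
#'
#' Columns: `particle_id`, `frame`, `t_s`, `x_um`, `y_um`.  The ground
#' truth (when attached) can be written to a JSON sidecar.
#'
#' @param trajectories a `trajectory_set`.
#' @param path output CSV path.
#' @param truth_path optional path for a JSON sidecar holding the
#'   simulation ground truth and frame interval.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path, truth_path = NULL) {
  utils::write.csv(as.data.frame(trajectories)[, c("particle_id", "frame",
                                                   "t_s", "x_um", "y_um")],
                   path, row.names = FALSE)
  if (!is.null(truth_path)) {
    truth <- unclass(attr(trajectories, "truth"))
    jsonlite::write_json(
      list(truth = truth,
           frame_interval = attr(trajectories, "frame_interval")),
      truth_path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read trajectories from CSV
#'
#' @param path CSV written by [write_trajectories()] (or any table with
#'   the same columns).
#' @param truth_path optional JSON sidecar restoring the ground truth.
#' @return a `trajectory_set`.
#' @export
read_trajectories <- function(path, truth_path = NULL) {
  d <- utils::read.csv(path)
  stopifnot(all(c("particle_id", "frame", "t_s", "x_um", "y_um") %in%
                  names(d)))
  fi <- if (!is.null(truth_path)) {
    side <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    attr(d, "truth") <- side$truth
    side$frame_interval
  } else if (nrow(d) > 1L) {
    ts <- sort(unique(d$t_s))
    if (length(ts) > 1L) min(diff(ts)) else NA_real_
  } else NA_real_
  structure(d, class = c("trajectory_set", "data.frame"),
            frame_interval = fi)
}

#' Write an image stack as a multi-frame TIFF
#'
#' Stored as 32-bit float so photon counts survive a round trip.
#'
#' @param stack 3D array (height x width x frames) or a single matrix.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  frames <- if (is.matrix(stack)) list(stack)
  else lapply(seq_len(dim(stack)[3L]), function(k) stack[, , k])
  # TIFF floats are stored in [0, 1]; keep the physical scale in the
  # image description so reads restore photon counts
  scale <- max(unlist(lapply(frames, max)), 1)
  frames <- lapply(frames, function(f) {
    f <- f / scale
    attr(f, "description") <- sprintf("mptrheo_scale=%.17g", scale)
    f
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a multi-frame TIFF as an image stack
#'
#' @param path TIFF path.
#' @return 3D array (height x width x frames).
#' @export
read_image_stack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  desc <- attr(frames[[1L]], "description")
  scale <- if (!is.null(desc) && grepl("mptrheo_scale=", desc))
    as.numeric(sub(".*mptrheo_scale=", "", desc)) else 1
  simplify2array(lapply(frames, function(f) f * scale))
}

#' Write a viscoelastic spectrum to CSV
#'
#' Columns: `omega`, `alpha`, `G1_Pa` (elastic), `G2_Pa` (viscous),
#' `delta_deg`.
#'
#' @param spectrum a `viscoelastic_spectrum` in Pa.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.csv(data.frame(omega = spectrum$omega,
                              alpha = spectrum$alpha,
                              G1_Pa = spectrum$G_prime,
                              G2_Pa = spectrum$G_double_prime,
                              delta_deg = spectrum$delta_deg),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write an ensemble MSD to CSV
#'
#' Columns: `lag_s`, `msd_um2`, `n`, `se_um2`.
#' @param ens an `ensemble_msd`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_msd <- function(ens, path) {
  utils::write.csv(data.frame(lag_s = ens$lag_s, msd_um2 = ens$msd_um2,
                              n = ens$n_particles, se_um2 = ens$se_um2),
                   path, row.names = FALSE)
  invisible(path)
}
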