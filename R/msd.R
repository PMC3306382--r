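# Mean-squared-displacement estimation.
#
# MSD(dt) = < [x(t+dt) - x(t)]^2 + [y(t+dt) - y(t)]^2 >, averaged over all
# overlapping pairs of a trajectory (time average), then over particles
# (ensemble average), each particle counting once regardless of length.

#' Time-averaged MSD of a single trajectory
#'
#' For each lag `tau = k * frame_interval` up to `max_lag_fraction` of the
#' trajectory length, averages the squared two-dimensional displacement
#' over all overlapping start times.  Overlapping pairs are correlated but
#' make maximal use of the data; uncertainty is therefore reported across
#' particles at the ensemble stage, not across pairs.
#'
#' @param traj single-particle data frame with `t_s`, `x_um`, `y_um`
#'   (e.g. one element of [split_trajectories()]).
#' @param max_lag_fraction largest lag as a fraction of the trajectory
#'   length (<= 0.5; default 0.25 limits estimator variance at long lags).
#' @return an `msd_curve` data frame with `lag_s`, `msd_um2`, `n_pairs`;
#'   lag 0 (identically zero) is excluded.
#' @export
time_averaged_msd <- function(traj, max_lag_fraction = 0.25) {
  stopifnot(is.data.frame(traj),
            all(c("t_s", "x_um", "y_um") %in% names(traj)))
  if (max_lag_fraction <= 0 || max_lag_fraction > 0.5)
    stop("max_lag_fraction must lie in (0, 0.5]")
  n <- nrow(traj)
  if (n < 8L) stop("trajectory too short for MSD estimation (", n, " frames)")
  dts <- diff(traj$t_s)
  dt <- stats::median(dts)
  if (dt <= 0 || any(abs(dts - dt) > 1e-9 * max(dt, 1)))
    stop("trajectory must be uniformly sampled in time")
  kmax <- max(1L, floor(max_lag_fraction * n))
  x <- traj$x_um; y <- traj$y_um
  msd <- vapply(seq_len(kmax), function(k) {
    dx <- x[(1L + k):n] - x[1L:(n - k)]
    dy <- y[(1L + k):n] - y[1L:(n - k)]
    mean(dx * dx + dy * dy)
  }, numeric(1L))
  out <- data.frame(lag_s = seq_len(kmax) * dt, msd_um2 = msd,
                    n_pairs = n - seq_len(kmax))
  structure(out, class = c("msd_curve", "data.frame"),
            particle_id = traj$particle_id[1L], frame_interval = dt)
}

#' Time-averaged MSDs for every particle in a trajectory set
#'
#' @param trajectories a `trajectory_set`.
#' @param max_lag_fraction see [time_averaged_msd()].
#' @return list of `msd_curve` objects.
#' @export
msd_curves <- function(trajectories, max_lag_fraction = 0.25) {
  lapply(split_trajectories(trajectories), time_averaged_msd,
         max_lag_fraction = max_lag_fraction)
}

#' Ensemble-averaged MSD across particles
#'
#' Per-lag unweighted mean of the individual time-averaged MSDs: each
#' particle counts once, independent of its trajectory length.  The
#' standard error at each lag is computed across particles.  Curves may
#' have different maximum lags (particles leave the focal plane); a lag's
#' average then uses the particles that reach it, recorded in
#' `n_particles`.  All curves must share the same frame interval, and each
#' must overlap the common lag grid.
#'
#' @param curves list of `msd_curve` objects (>= 1).
#' @return an `ensemble_msd` data frame with `lag_s`, `msd_um2`,
#'   `n_particles`, `se_um2`.
#' @export
ensemble_msd <- function(curves) {
  if (inherits(curves, "msd_curve")) curves <- list(curves)
  if (length(curves) == 0L) stop("need at least one MSD curve")
  dts <- vapply(curves, function(c) attr(c, "frame_interval"), numeric(1L))
  if (any(abs(dts - dts[1L]) > 1e-9 * dts[1L]))
    stop("curve ", which(abs(dts - dts[1L]) > 1e-9 * dts[1L])[1L],
         " has a different frame interval: lag grids are disjoint")
  dt <- dts[1L]
  ks <- lapply(curves, function(c) as.integer(round(c$lag_s / dt)))
  grid <- sort(unique(unlist(ks)))
  # a curve sharing no lags with the others indicates disjoint grids
  for (i in seq_along(curves)) {
    if (!any(ks[[i]] %in% unlist(ks[-i])) && length(curves) > 1L)
      stop("curve ", i, " shares no lags with the other curves")
  }
  acc_sum <- acc_sq <- acc_n <- numeric(length(grid))
  for (i in seq_along(curves)) {
    idx <- match(ks[[i]], grid)
    acc_sum[idx] <- acc_sum[idx] + curves[[i]]$msd_um2
    acc_sq[idx] <- acc_sq[idx] + curves[[i]]$msd_um2^2
    acc_n[idx] <- acc_n[idx] + 1
  }
  m <- acc_sum / acc_n
  v <- ifelse(acc_n > 1, (acc_sq - acc_n * m^2) / (acc_n - 1), NA_real_)
  v <- pmax(v, 0)
  out <- data.frame(lag_s = grid * dt, msd_um2 = m,
                    n_particles = as.integer(acc_n),
                    se_um2 = sqrt(v / acc_n))
  structure(out, class = c("ensemble_msd", "data.frame"),
            frame_interval = dt)
}

#' Ensemble MSD straight from a trajectory set
#'
#' Convenience wrapper: [msd_curves()] then [ensemble_msd()].
#' @inheritParams msd_curves
#' @return an `ensemble_msd`.
#' @export
compute_ensemble_msd <- function(trajectories, max_lag_fraction = 0.25) {
  ensemble_msd(msd_curves(trajectories, max_lag_fraction))
}
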