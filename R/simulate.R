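# Trajectory generators with known viscoelastic ground truth.
#
# Positions are in micrometres, times in seconds.  All generators return a
# tidy trajectory set (one row per particle per frame) carrying the ground
# truth as an attribute, so recovery tests can compare against the exact
# parameters that produced the data.

#' Boltzmann constant in J/K
#' @keywords internal
.kB <- 1.380649e-23

#' Ground-truth physical parameters for a simulated medium
#'
#' Describes the medium a probe particle is embedded in.  Exactly the
#' parameters of the chosen `medium_kind` must be supplied:
#' * `viscous`: diffusivity `D` (um^2/s); the two-dimensional MSD is
#'   `4 D dt`.
#' * `power_law`: exponent `alpha` in (0, 2] and prefactor `A`
#'   (um^2/s^alpha); the two-dimensional MSD is `A dt^alpha`.
#' * `trapped`: trap stiffness `kappa` (N/m) and drag coefficient `gamma`
#'   (N s/m); each axis is a stationary Ornstein-Uhlenbeck process with
#'   relaxation time `gamma/kappa` and the two-dimensional MSD plateaus at
#'   `4 kB T / kappa`.
#'
#' @param medium_kind one of `"viscous"`, `"power_law"`, `"trapped"`.
#' @param D diffusivity in um^2/s (viscous media).
#' @param alpha subdiffusive exponent in (0, 2] (power-law media).
#' @param A MSD prefactor in um^2/s^alpha (power-law media).
#' @param kappa trap stiffness in N/m (trapped media).
#' @param gamma drag coefficient in N s/m (trapped media).
#' @param temperature absolute temperature in K.
#' @param probe_radius probe particle radius in um (100 nm diameter beads
#'   by default).
#' @param seed integer seed recorded with every dataset generated from this
#'   truth.
#' @return an object of class `simulation_truth`.
#' @export
simulation_truth <- function(medium_kind = c("viscous", "power_law", "trapped"),
                             D = NULL, alpha = NULL, A = NULL,
                             kappa = NULL, gamma = NULL,
                             temperature = 310.15, probe_radius = 0.05,
                             seed = NULL) {
  medium_kind <- match.arg(medium_kind)
  if (temperature <= 0) stop("temperature must be positive (K)")
  if (probe_radius <= 0) stop("probe_radius must be positive (um)")
  truth <- list(medium_kind = medium_kind, temperature = temperature,
                probe_radius = probe_radius, seed = seed)
  switch(medium_kind,
    viscous = {
      if (is.null(D)) stop("viscous media require a diffusivity D")
      if (D < 0) stop("D must be non-negative (um^2/s)")
      if (!is.null(alpha) || !is.null(A) || !is.null(kappa) || !is.null(gamma))
        stop("viscous media take only D")
      truth$D <- D
    },
    power_law = {
      if (is.null(alpha) || is.null(A))
        stop("power-law media require alpha and A")
      if (alpha <= 0 || alpha > 2) stop("alpha must lie in (0, 2]")
      if (A <= 0) stop("A must be positive (um^2/s^alpha)")
      if (!is.null(D) || !is.null(kappa) || !is.null(gamma))
        stop("power-law media take only alpha and A")
      truth$alpha <- alpha
      truth$A <- A
    },
    trapped = {
      if (is.null(kappa) || is.null(gamma))
        stop("trapped media require kappa and gamma")
      if (kappa <= 0) stop("kappa must be positive (N/m)")
      if (gamma <= 0) stop("gamma must be positive (N s/m)")
      if (!is.null(D) || !is.null(alpha) || !is.null(A))
        stop("trapped media take only kappa and gamma")
      truth$kappa <- kappa
      truth$gamma <- gamma
    })
  structure(truth, class = "simulation_truth")
}

#' Video acquisition geometry for simulated or rendered movies
#'
#' Defaults mirror a standard live-cell acquisition: 20-second videos at
#' 33 ms temporal resolution (30 frames/s) with 15 probe particles per
#' video, 100 nm/px sampling and ~5 nm static localization error.
#'
#' @param n_frames frames per video (>= 2).
#' @param frame_interval seconds between frames.
#' @param n_particles particles per video.
#' @param pixel_size um per pixel.
#' @param psf_sigma point-spread-function standard deviation in px.
#' @param photons_per_particle expected photons collected per particle per
#'   frame.
#' @param background_photons expected background photons per pixel per
#'   frame.
#' @param localization_noise_sigma static localization error in um (5 nm by
#'   default); applied only by [add_localization_noise()].
#' @param field_dim rendered field of view, c(width, height) in px.
#' @return an object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(n_frames = 600, frame_interval = 0.033,
                             n_particles = 15, pixel_size = 0.1,
                             psf_sigma = 1.3, photons_per_particle = 5000,
                             background_photons = 10,
                             localization_noise_sigma = 0.005,
                             field_dim = c(128L, 128L)) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (frame_interval <= 0) stop("frame_interval must be positive (s)")
  if (n_particles < 1) stop("n_particles must be >= 1")
  if (pixel_size <= 0) stop("pixel_size must be positive (um/px)")
  if (psf_sigma <= 0) stop("psf_sigma must be positive (px)")
  if (photons_per_particle < 0 || background_photons < 0)
    stop("photon counts must be non-negative")
  if (localization_noise_sigma < 0)
    stop("localization_noise_sigma must be non-negative (um)")
  structure(list(n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 n_particles = as.integer(n_particles),
                 pixel_size = pixel_size, psf_sigma = psf_sigma,
                 photons_per_particle = photons_per_particle,
                 background_photons = background_photons,
                 localization_noise_sigma = localization_noise_sigma,
                 field_dim = as.integer(field_dim)),
            class = "acquisition_spec")
}

# assemble per-axis position matrices (n_frames x n_particles) into a tidy
# trajectory set
.trajectory_set <- function(x, y, spec, truth) {
  n_frames <- nrow(x)
  n_particles <- ncol(x)
  out <- data.frame(
    particle_id = rep(seq_len(n_particles), each = n_frames),
    frame = rep(seq_len(n_frames) - 1L, times = n_particles),
    t_s = rep((seq_len(n_frames) - 1L) * spec$frame_interval,
              times = n_particles),
    x_um = as.vector(x),
    y_um = as.vector(y))
  structure(out, class = c("trajectory_set", "data.frame"),
            truth = truth, frame_interval = spec$frame_interval)
}

#' Simulate Brownian probe trajectories in a purely viscous medium
#'
#' Per-axis increments are independent Gaussian draws with variance
#' `2 D frame_interval`, so the two-dimensional ensemble MSD is `4 D dt`
#' at every lag.
#'
#' @param truth a [simulation_truth()] with `medium_kind = "viscous"`.
#' @param spec an [acquisition_spec()].
#' @param seed integer seed; overrides `truth$seed` when given.
#' @return a `trajectory_set` data frame with columns `particle_id`,
#'   `frame`, `t_s`, `x_um`, `y_um` and the truth attached as attribute
#'   `"truth"`.
#' @export
simulate_brownian <- function(truth, spec = acquisition_spec(), seed = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (truth$medium_kind != "viscous")
    stop("simulate_brownian requires a viscous simulation_truth; got ",
         truth$medium_kind)
  seed <- .resolve_seed(seed, truth)
  n <- spec$n_frames
  p <- spec$n_particles
  step_sd <- sqrt(2 * truth$D * spec$frame_interval)
  dx <- matrix(stats::rnorm((n - 1L) * p, sd = step_sd), n - 1L, p)
  dy <- matrix(stats::rnorm((n - 1L) * p, sd = step_sd), n - 1L, p)
  x <- rbind(0, apply(dx, 2L, cumsum))
  y <- rbind(0, apply(dy, 2L, cumsum))
  truth$seed <- seed
  .trajectory_set(x, y, spec, truth)
}

#' Exact covariance of fractional Gaussian noise increments
#'
#' Covariance between increments j steps apart of a process whose per-axis
#' MSD is `sigma2 * t^(2H)`, sampled at interval dt.
#' @keywords internal
.fgn_cov <- function(j, H, sigma2, dt) {
  sigma2 * dt^(2 * H) / 2 *
    (abs(j + 1)^(2 * H) - 2 * abs(j)^(2 * H) + abs(j - 1)^(2 * H))
}

#' Simulate subdiffusive probe trajectories in a power-law medium
#'
#' Per-axis displacements are fractional Brownian motion with Hurst
#' exponent `H = alpha/2`, synthesized by Cholesky factorization of the
#' exact fractional-Gaussian-noise covariance so the target autocovariance
#' is realized exactly (no spectral approximation).  Scaled so the
#' two-dimensional MSD is `A dt^alpha`.  `alpha = 1` reduces to Brownian
#' motion with `A = 4D`; `alpha = 2` (singular fGn covariance) is generated
#' as exact ballistic motion with per-particle Gaussian velocities.
#'
#' @inheritParams simulate_brownian
#' @param truth a [simulation_truth()] with `medium_kind = "power_law"`.
#' @return a `trajectory_set`; see [simulate_brownian()].
#' @export
simulate_power_law <- function(truth, spec = acquisition_spec(), seed = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (truth$medium_kind != "power_law")
    stop("simulate_power_law requires a power_law simulation_truth; got ",
         truth$medium_kind)
  seed <- .resolve_seed(seed, truth)
  n <- spec$n_frames
  p <- spec$n_particles
  dt <- spec$frame_interval
  sigma2 <- truth$A / 2  # per-axis MSD prefactor
  H <- truth$alpha / 2
  if (truth$alpha == 2) {
    # ballistic limit: x(t) = v t with Var(v) = sigma2 per axis
    t <- (seq_len(n) - 1L) * dt
    vx <- stats::rnorm(p, sd = sqrt(sigma2))
    vy <- stats::rnorm(p, sd = sqrt(sigma2))
    x <- outer(t, vx)
    y <- outer(t, vy)
  } else {
    cov <- .fgn_cov(abs(outer(seq_len(n - 1L), seq_len(n - 1L), "-")),
                    H, sigma2, dt)
    L <- t(chol(cov))
    z <- matrix(stats::rnorm((n - 1L) * 2L * p), n - 1L, 2L * p)
    incr <- L %*% z
    x <- rbind(0, apply(incr[, seq_len(p), drop = FALSE], 2L, cumsum))
    y <- rbind(0, apply(incr[, p + seq_len(p), drop = FALSE], 2L, cumsum))
  }
  truth$seed <- seed
  .trajectory_set(x, y, spec, truth)
}

#' Simulate harmonically trapped (Hookean) probe trajectories
#'
#' Each axis is a stationary Ornstein-Uhlenbeck process with relaxation
#' time `gamma/kappa` and equilibrium variance `kB T / kappa`, advanced
#' with the exact discrete-time update (no Euler time-step bias):
#' `x[t+dt] = x[t] exp(-dt/tau) + sqrt(var_eq (1 - exp(-2 dt/tau))) z`.
#' The two-dimensional MSD rises as `4 (kB T / kappa)(1 - exp(-dt/tau))`
#' and plateaus at `4 kB T / kappa`.
#'
#' @inheritParams simulate_brownian
#' @param truth a [simulation_truth()] with `medium_kind = "trapped"`.
#' @return a `trajectory_set`; see [simulate_brownian()].
#' @export
simulate_trapped <- function(truth, spec = acquisition_spec(), seed = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (truth$medium_kind != "trapped")
    stop("simulate_trapped requires a trapped simulation_truth; got ",
         truth$medium_kind)
  seed <- .resolve_seed(seed, truth)
  n <- spec$n_frames
  p <- spec$n_particles
  tau <- truth$gamma / truth$kappa                    # relaxation time, s
  var_eq <- .kB * truth$temperature / truth$kappa * 1e12  # um^2 per axis
  rho <- exp(-spec$frame_interval / tau)
  innov_sd <- sqrt(var_eq * (1 - rho^2))
  x <- matrix(0, n, p)
  y <- matrix(0, n, p)
  x[1L, ] <- stats::rnorm(p, sd = sqrt(var_eq))
  y[1L, ] <- stats::rnorm(p, sd = sqrt(var_eq))
  for (i in seq_len(n - 1L)) {
    x[i + 1L, ] <- x[i, ] * rho + stats::rnorm(p, sd = innov_sd)
    y[i + 1L, ] <- y[i, ] * rho + stats::rnorm(p, sd = innov_sd)
  }
  truth$seed <- seed
  .trajectory_set(x, y, spec, truth)
}

#' Add static localization noise to trajectories
#'
#' Models the apparent motion of a particle caused by photon noise in
#' centroid localization: independent zero-mean Gaussian offsets of
#' standard deviation `sigma` are added to every coordinate.  In
#' expectation this raises the two-dimensional MSD by the additive floor
#' `4 sigma^2` at every lag.  The input is not modified.
#'
#' @param trajectories a `trajectory_set`.
#' @param sigma static localization error in um (>= 0).
#' @param seed optional integer seed.
#' @return a new `trajectory_set` with perturbed coordinates.
#' @export
add_localization_noise <- function(trajectories, sigma, seed = NULL) {
  stopifnot(is.data.frame(trajectories))
  if (sigma < 0) stop("sigma must be non-negative (um)")
  if (sigma == 0) return(trajectories)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(trajectories)
  out <- trajectories
  out$x_um <- out$x_um + stats::rnorm(n, sd = sigma)
  out$y_um <- out$y_um + stats::rnorm(n, sd = sigma)
  out
}

.resolve_seed <- function(seed, truth) {
  seed <- if (!is.null(seed)) seed else truth$seed
  if (!is.null(seed)) set.seed(seed)
  seed
}

#' Split a trajectory set into per-particle data frames
#'
#' @param trajectories a `trajectory_set`.
#' @return a named list of single-particle data frames, each carrying the
#'   parent's `frame_interval` attribute.
#' @export
split_trajectories <- function(trajectories) {
  stopifnot(is.data.frame(trajectories))
  fi <- attr(trajectories, "frame_interval")
  parts <- split(as.data.frame(trajectories), trajectories$particle_id)
  lapply(parts, function(d) {
    rownames(d) <- NULL
    attr(d, "frame_interval") <- fi
    d
  })
}
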