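# Independent oracles used across the suite.

kB <- 1.380649e-23

# Brute-force MSD by exhaustive pair enumeration (independent of the
# vectorized estimator in the package).
brute_force_msd <- function(traj, max_lag_fraction = 0.25) {
  n <- nrow(traj)
  kmax <- max(1L, floor(max_lag_fraction * n))
  dt <- traj$t_s[2] - traj$t_s[1]
  msd <- numeric(kmax)
  for (k in seq_len(kmax)) {
    acc <- 0
    cnt <- 0L
    for (i in seq_len(n - k)) {
      acc <- acc + (traj$x_um[i + k] - traj$x_um[i])^2 +
        (traj$y_um[i + k] - traj$y_um[i])^2
      cnt <- cnt + 1L
    }
    msd[k] <- acc / cnt
  }
  data.frame(lag_s = seq_len(kmax) * dt, msd_um2 = msd)
}

# Numerical Laplace-transform GSER: |G*(omega)| for a power-law MSD
# msd2d(t) = A t^alpha, via numeric integration of the transform
# (independent of the algebraic Mason estimator).
laplace_gser_magnitude <- function(omega, A, alpha, temperature = 310.15,
                                   probe_radius_um = 0.05,
                                   correction = 1.5) {
  a_m <- probe_radius_um * 1e-6
  vapply(omega, function(w) {
    # Laplace transform of the corrected MSD at s = omega, in m^2 s
    msd_laplace <- stats::integrate(
      function(t) correction * A * t^alpha * 1e-12 * exp(-w * t),
      0, Inf, rel.tol = 1e-10)$value
    kB * temperature / (pi * a_m * w * msd_laplace)
  }, numeric(1))
}

# Analytic per-axis OU MSD: 2 (kB T / kappa) (1 - exp(-kappa t / gamma))
ou_msd_2d <- function(t, kappa, gamma, temperature = 310.15) {
  4 * kB * temperature / kappa * 1e12 * (1 - exp(-kappa * t / gamma))
}

# Exact fGn increment covariance (mirrors the generator's target law but
# derived independently from the fBm covariance function)
fbm_increment_cov <- function(j, H, sigma2, dt) {
  fbm_cov <- function(s, t) sigma2 / 2 * (s^(2 * H) + t^(2 * H) -
                                            abs(s - t)^(2 * H))
  # cov(B((j+1)dt) - B(j dt), B(dt) - B(0)); B(0) = 0
  fbm_cov((j + 1) * dt, dt) - fbm_cov(j * dt, dt)
}

# quick trajectory builder
make_traj <- function(x, y, dt = 1) {
  data.frame(particle_id = 1L, frame = seq_along(x) - 1L,
             t_s = (seq_along(x) - 1L) * dt, x_um = x, y_um = y)
}
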