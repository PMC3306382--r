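# Trajectory generators: closed-form limits, exact covariance, seeding.

test_that("simulation_truth enforces medium-specific parameter sets", {
  expect_s3_class(simulation_truth("viscous", D = 0.1), "simulation_truth")
  expect_error(simulation_truth("viscous"), "diffusivity")
  expect_error(simulation_truth("viscous", D = -1), "non-negative")
  expect_error(simulation_truth("viscous", D = 0.1, kappa = 1), "only D")
  expect_error(simulation_truth("power_law", alpha = 2.5, A = 1), "0, 2")
  expect_error(simulation_truth("trapped", kappa = 0, gamma = 1),
               "kappa")
  expect_error(simulate_brownian(simulation_truth("trapped", kappa = 1,
                                                  gamma = 1)),
               "viscous")
  expect_error(simulate_power_law(simulation_truth("viscous", D = 1)),
               "power_law")
})

test_that("zero diffusivity leaves every particle stationary", {
  tr <- simulate_brownian(simulation_truth("viscous", D = 0),
                          acquisition_spec(n_frames = 50, n_particles = 3),
                          seed = 1)
  expect_true(all(tr$x_um == 0) && all(tr$y_um == 0))
})

test_that("Brownian ensemble MSD matches 4 D dt within 3 SE at all lags", {
  D <- 0.1
  tr <- simulate_brownian(simulation_truth("viscous", D = D),
                          acquisition_spec(n_particles = 200), seed = 1)
  ens <- compute_ensemble_msd(tr)
  expected <- 4 * D * ens$lag_s
  expect_true(all(abs(ens$msd_um2 - expected) <= 3 * ens$se_um2))
  # slope of a through-origin fit recovers 4D
  slope <- sum(ens$msd_um2 * ens$lag_s) / sum(ens$lag_s^2)
  expect_equal(slope, 4 * D, tolerance = 0.05)
})

test_that("generators are bit-reproducible under a fixed seed", {
  spec <- acquisition_spec(n_frames = 60, n_particles = 4)
  for (gen in list(
    function(s) simulate_brownian(simulation_truth("viscous", D = 0.05),
                                  spec, seed = s),
    function(s) simulate_power_law(
      simulation_truth("power_law", alpha = 0.5, A = 0.01), spec, seed = s),
    function(s) simulate_trapped(
      simulation_truth("trapped", kappa = 1e-6, gamma = 3e-7), spec,
      seed = s))) {
    expect_identical(gen(7L), gen(7L))
    expect_false(identical(gen(7L)$x_um, gen(8L)$x_um))
  }
})

test_that("fGn increments realize the exact target autocovariance", {
  # compare the generator's covariance helper against an independent
  # derivation from the fBm covariance function
  for (alpha in c(0.4, 1, 1.6)) {
    H <- alpha / 2
    got <- mptrheo:::.fgn_cov(0:10, H, sigma2 = 0.3, dt = 0.033)
    want <- fbm_increment_cov(0:10, H, sigma2 = 0.3, dt = 0.033)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # and empirically: increments of many short fGn paths reproduce it
  tr <- simulate_power_law(simulation_truth("power_law", alpha = 0.5,
                                            A = 0.01),
                           acquisition_spec(n_frames = 12,
                                            n_particles = 3000), seed = 2)
  inc <- sapply(split_trajectories(tr), function(d) diff(d$x_um))
  emp <- drop(inc[1, ] %*% t(inc)) / ncol(inc)
  want <- mptrheo:::.fgn_cov(0:10, 0.25, sigma2 = 0.005, dt = 0.033)
  expect_equal(unname(emp), want, tolerance = 0.1)
})

test_that("power-law MSD recovers alpha within 0.05 across exponents", {
  for (alpha in c(0.3, 0.5, 0.8, 1.0)) {
    tr <- simulate_power_law(
      simulation_truth("power_law", alpha = alpha, A = 0.01),
      acquisition_spec(n_particles = 200), seed = 11)
    ens <- compute_ensemble_msd(tr)
    fit <- stats::lm(log(msd_um2) ~ log(lag_s), data = ens)
    expect_equal(unname(stats::coef(fit)[2]), alpha, tolerance = 0.05)
  }
})

test_that("alpha = 1 fGn covariance degenerates to independent Brownian steps", {
  cov <- mptrheo:::.fgn_cov(abs(outer(1:20, 1:20, "-")), H = 0.5,
                            sigma2 = 2 * 0.1, dt = 0.033)
  expect_equal(cov, diag(2 * 0.1 * 0.033, 20), tolerance = 1e-12)
})

test_that("trapped MSD follows the OU closed form and plateaus at 4kBT/kappa", {
  kappa <- 1e-6
  gamma <- 3.3e-7
  tr <- simulate_trapped(simulation_truth("trapped", kappa = kappa,
                                          gamma = gamma),
                         acquisition_spec(n_particles = 200), seed = 3)
  ens <- compute_ensemble_msd(tr)
  want <- ou_msd_2d(ens$lag_s, kappa, gamma)
  expect_equal(ens$msd_um2, want, tolerance = 0.06)
  plateau <- 4 * kB * 310.15 / kappa * 1e12
  long <- ens$lag_s > 10 * gamma / kappa
  expect_equal(mean(ens$msd_um2[long]), plateau, tolerance = 0.05)
})

test_that("a very stiff trap freezes the particle", {
  tr <- simulate_trapped(simulation_truth("trapped", kappa = 1, gamma = 1e-7),
                         acquisition_spec(n_frames = 100, n_particles = 5),
                         seed = 4)
  # equilibrium sd = sqrt(kBT/kappa) ~ 6.5e-5 um: displacements vanish
  expect_lt(max(abs(tr$x_um)), 1e-3)
})

test_that("localization noise is additive 4 sigma^2 on the MSD and pure at sigma = 0", {
  tr <- simulate_brownian(simulation_truth("viscous", D = 0),
                          acquisition_spec(n_frames = 300,
                                           n_particles = 100), seed = 5)
  expect_identical(add_localization_noise(tr, 0), tr)
  expect_error(add_localization_noise(tr, -1), "non-negative")
  sigma <- 0.005
  noisy <- add_localization_noise(tr, sigma, seed = 6)
  ens <- compute_ensemble_msd(noisy)
  expect_equal(mean(ens$msd_um2), 4 * sigma^2, tolerance = 0.05)
  # additivity on a diffusing ensemble
  tr2 <- simulate_brownian(simulation_truth("viscous", D = 0.01),
                           acquisition_spec(n_frames = 300,
                                            n_particles = 150), seed = 7)
  noisy2 <- add_localization_noise(tr2, sigma, seed = 8)
  d <- compute_ensemble_msd(noisy2)$msd_um2 -
    compute_ensemble_msd(tr2)$msd_um2
  expect_equal(mean(d), 4 * sigma^2, tolerance = 0.15)
})
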