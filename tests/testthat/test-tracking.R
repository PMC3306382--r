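# Localization, linking, unit conversion and static-error calibration.

test_that("point-mass and blank images localize exactly", {
  img <- matrix(0, 20, 20)
  img[10, 8] <- 5  # 0-based (x = 7, y = 9)
  det <- locate_particles(img, tracking_config(window_radius = 3))
  expect_equal(nrow(det), 1L)
  expect_equal(det$x_px, 7)
  expect_equal(det$y_px, 9)
  expect_equal(nrow(locate_particles(matrix(0, 20, 20))), 0L)
  expect_equal(nrow(locate_particles(matrix(3, 20, 20))), 0L)  # flat
})

test_that("noiseless Gaussian spots localize within 0.05 px", {
  spec <- acquisition_spec(n_frames = 2, n_particles = 1,
                           background_photons = 5, field_dim = c(40, 40))
  tr <- simulate_brownian(simulation_truth("viscous", D = 0), spec, seed = 1)
  tr$x_um <- tr$x_um + 10.50 * spec$pixel_size
  tr$y_um <- tr$y_um + 20.25 * spec$pixel_size
  img <- render_particle_stack(tr, spec, noise_model = "none")$frames[, , 1]
  det <- locate_particles(img, tracking_config())
  expect_equal(nrow(det), 1L)
  expect_equal(det$x_px, 10.50, tolerance = 0.05)
  expect_equal(det$y_px, 20.25, tolerance = 0.05)
})

test_that("localization bias over random sub-pixel positions is below 0.02 px", {
  spec <- acquisition_spec(n_frames = 2, n_particles = 1,
                           background_photons = 10, field_dim = c(32, 32))
  cfg <- tracking_config()
  set.seed(99)
  err_x <- err_y <- numeric(60)
  for (i in 1:60) {
    x <- 15 + stats::runif(1)
    y <- 15 + stats::runif(1)
    tr <- data.frame(particle_id = 1L, frame = 0L, t_s = 0,
                     x_um = x * spec$pixel_size, y_um = y * spec$pixel_size)
    img <- render_particle_stack(tr, spec, noise_model = "none")$frames[, , 1]
    det <- locate_particles(img, cfg)
    err_x[i] <- det$x_px[1] - x
    err_y[i] <- det$y_px[1] - y
  }
  expect_lt(abs(mean(err_x)), 0.02)
  expect_lt(abs(mean(err_y)), 0.02)
})

test_that("linking: continuity, identity preservation, jump splitting", {
  cfg <- tracking_config(max_link_displacement = 3, min_length = 10)
  # one particle drifting slowly: a single full-length track
  det1 <- data.frame(frame = 0:29, x_px = 10 + 0.1 * (0:29), y_px = 10)
  tr <- link_detections(det1, cfg)
  expect_equal(length(unique(tr$particle_id)), 1L)
  expect_equal(nrow(tr), 30L)
  # two well-separated particles keep their identities
  det2 <- rbind(data.frame(frame = 0:29, x_px = 5, y_px = 5),
                data.frame(frame = 0:29, x_px = 50, y_px = 50))
  tr2 <- link_detections(det2, cfg)
  expect_equal(length(unique(tr2$particle_id)), 2L)
  by_id <- split(tr2, tr2$particle_id)
  expect_true(all(vapply(by_id, function(d) stats::sd(d$x_px) == 0,
                         logical(1))))
  # a jump beyond max_link_displacement splits the track
  det3 <- data.frame(frame = 0:29, x_px = c(rep(10, 15), rep(30, 15)),
                     y_px = 10)
  tr3 <- link_detections(det3, cfg)
  expect_equal(length(unique(tr3$particle_id)), 2L)
  # and sub-min_length fragments are dropped
  det4 <- data.frame(frame = 0:29, x_px = c(rep(10, 25), rep(30, 5)),
                     y_px = 10)
  tr4 <- link_detections(det4, cfg)
  expect_equal(length(unique(tr4$particle_id)), 1L)
  expect_equal(nrow(tr4), 25L)
})

test_that("linking fidelity >= 99% on well-separated simulated movies", {
  spec <- acquisition_spec(n_frames = 100, n_particles = 8,
                           field_dim = c(200, 200))
  tr <- simulate_brownian(simulation_truth("viscous", D = 0.005), spec,
                          seed = 11)
  placed <- scatter_trajectories(tr, spec, margin_px = 20, seed = 12)
  truth <- placed
  dets <- data.frame(frame = truth$frame,
                     x_px = truth$x_um / spec$pixel_size,
                     y_px = truth$y_um / spec$pixel_size)
  linked <- link_detections(dets, tracking_config(max_link_displacement = 5,
                                                  min_length = 50))
  expect_equal(length(unique(linked$particle_id)), 8L)
  # every linked track must follow a single ground-truth particle
  key <- paste(dets$frame, round(dets$x_px, 9))
  truth_id <- truth$particle_id[match(paste(linked$frame,
                                            round(linked$x_px, 9)), key)]
  agreement <- vapply(split(truth_id, linked$particle_id),
                      function(ids) max(table(ids)) / length(ids),
                      numeric(1))
  expect_true(all(agreement >= 0.99))
})

test_that("to_physical scales losslessly and validates input", {
  tracks <- data.frame(particle_id = 1L, frame = 0:9, x_px = 0:9 * 1.5,
                       y_px = 9:0)
  ph <- to_physical(tracks, pixel_size = 0.1, frame_interval = 0.033)
  expect_equal(ph$x_um, tracks$x_px * 0.1)  # 15 px at 0.1 um/px -> 1.5 um
  expect_equal(ph$t_s, (0:9) * 0.033)
  back_x <- ph$x_um / 0.1
  expect_equal(back_x, tracks$x_px, tolerance = 1e-12)
  ident <- to_physical(tracks, 1, 1)
  expect_equal(ident$x_um, tracks$x_px)
  expect_error(to_physical(tracks, 0, 1), "positive")
})

test_that("static error calibration recovers injected noise and flags short input", {
  tr <- simulate_brownian(simulation_truth("viscous", D = 0),
                          acquisition_spec(n_frames = 300,
                                           n_particles = 20), seed = 13)
  noisy <- add_localization_noise(tr, 0.010, seed = 14)
  est <- estimate_static_error(noisy)
  expect_equal(est$rms_nm, 10, tolerance = 0.1)
  expect_equal(est$msd_floor_um2, 4 * est$rms_um^2)
  short <- simulate_brownian(simulation_truth("viscous", D = 0),
                             acquisition_spec(n_frames = 50,
                                              n_particles = 2), seed = 15)
  expect_error(estimate_static_error(short), "100")
})

test_that("rendered immobilized particles localize below 0.5 nm noiseless", {
  spec <- acquisition_spec(n_frames = 12, n_particles = 4,
                           background_photons = 10, field_dim = c(64, 64))
  tr <- simulate_brownian(simulation_truth("viscous", D = 0), spec,
                          seed = 16)
  placed <- scatter_trajectories(tr, spec, seed = 17)
  movie <- render_particle_stack(placed, spec, noise_model = "none")
  dets <- locate_stack(movie$frames, tracking_config(min_length = 10))
  tracks <- link_detections(dets, tracking_config(min_length = 10))
  ph <- to_physical(tracks, spec$pixel_size, spec$frame_interval)
  est <- estimate_static_error(ph, min_frames = 10)
  expect_lt(est$rms_nm, 0.5)  # discretization only
})
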