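# End-to-end orchestration: simulate -> (render -> track) -> MSD ->
# rheology -> report, with seed capture and a provenance manifest.
#
# All randomness flows from one top-level seed: stage i uses
# seed + 1000 * i, so any stage can be re-run independently and a rerun
# with the same config and seed is bit-identical.

.stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 1L, render = 2L, track = 3L, msd = 4L,
               rheology = 5L)
  if (is.null(seed)) return(NULL)
  seed + 1000L * offsets[[stage]]
}

.default_run_config <- function() {
  list(
    stages = c("simulate", "msd", "rheology"),
    medium = list(kind = "viscous", D = 0.1),
    acquisition = list(n_frames = 600L, frame_interval = 0.033,
                       n_particles = 15L),
    n_videos = 1L,
    tracking = list(),
    rheology = list(temperature = 310.15, probe_radius = 0.05,
                    msd_dimension_correction = 1.5,
                    max_lag_fraction = 0.25, smoothing_halfwidth = 2L),
    delta_band = c(1, 10),
    units = "Pa")
}

.merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
      .merge_config(base[[k]], override[[k]]) else override[[k]]
  }
  base
}

.truth_from_config <- function(medium, rheo) {
  args <- medium
  names(args)[names(args) == "kind"] <- "medium_kind"
  args$temperature <- rheo$temperature
  args$probe_radius <- rheo$probe_radius
  do.call(simulation_truth, args)
}

#' Run the simulation-to-rheology pipeline
#'
#' Executes the requested stages in order, writing each artifact to
#' `outdir` together with a provenance manifest (config, seed, per-stage
#' derived seeds, file checksums).  With identical config and seed the
#' run is bit-identical.
#'
#' Config structure (a nested list, or the path of an equivalent YAML
#' file): `stages` (subset of `"simulate"`, `"render"`, `"track"`,
#' `"msd"`, `"rheology"` in that order), `medium` (`kind` plus its
#' parameters, see [simulation_truth()]), `acquisition` (see
#' [acquisition_spec()]), `n_videos`, `tracking` (see
#' [tracking_config()]), `rheology` (see [rheology_config()]),
#' `delta_band`, `units` (`"Pa"` or `"dyn/cm2"`).
#'
#' @param config nested list or YAML path; omitted entries fall back to
#'   defaults.
#' @param seed integer seed recorded in the manifest.
#' @param outdir output directory (created if needed).
#' @return the manifest, invisibly; artifacts land in `outdir`.
#' @export
run_pipeline <- function(config = list(), seed = 1L, outdir = tempdir()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(.default_run_config(), config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- cfg$stages
  known <- c("simulate", "render", "track", "msd", "rheology")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  stages <- known[known %in% stages]
  artifacts <- character(0)
  summary <- list()

  acq <- do.call(acquisition_spec, cfg$acquisition)
  rheo <- do.call(rheology_config, cfg$rheology)
  trajs <- NULL

  if ("simulate" %in% stages) {
    truth <- .truth_from_config(cfg$medium, cfg$rheology)
    sim_fun <- switch(cfg$medium$kind, viscous = simulate_brownian,
                      power_law = simulate_power_law,
                      trapped = simulate_trapped)
    sseed <- .stage_seed(seed, "simulate")
    videos <- lapply(seq_len(cfg$n_videos), function(v) {
      tr <- sim_fun(truth, acq, seed = if (is.null(sseed)) NULL
                    else sseed + v - 1L)
      tr$particle_id <- tr$particle_id + (v - 1L) * acq$n_particles
      tr
    })
    trajs <- structure(do.call(rbind, videos),
                       class = c("trajectory_set", "data.frame"),
                       truth = truth, frame_interval = acq$frame_interval)
    if (!is.null(cfg$localization_noise) && cfg$localization_noise > 0)
      trajs <- add_localization_noise(trajs, cfg$localization_noise,
                                      seed = .stage_seed(seed, "simulate"))
    p <- file.path(outdir, "trajectories.csv")
    write_trajectories(trajs, p, file.path(outdir, "trajectories_truth.json"))
    artifacts <- c(artifacts, p, file.path(outdir,
                                           "trajectories_truth.json"))
  }

  if ("render" %in% stages) {
    if (is.null(trajs)) stop("render stage requires the simulate stage")
    placed <- scatter_trajectories(trajs, acq,
                                   seed = .stage_seed(seed, "render"))
    movie <- render_particle_stack(placed, acq,
                                   seed = .stage_seed(seed, "render"))
    p <- file.path(outdir, "movie.tif")
    write_image_stack(movie$frames, p)
    artifacts <- c(artifacts, p)
    if ("track" %in% stages) {
      tcfg <- do.call(tracking_config,
                      c(cfg$tracking, list(pixel_size = acq$pixel_size)))
      dets <- locate_stack(movie$frames, tcfg)
      tracks <- link_detections(dets, tcfg)
      trajs <- to_physical(tracks, acq$pixel_size, acq$frame_interval)
      p <- file.path(outdir, "tracked_trajectories.csv")
      write_trajectories(trajs, p)
      artifacts <- c(artifacts, p)
    }
  } else if ("track" %in% stages) {
    stop("track stage requires the render stage")
  }

  ens <- NULL
  if ("msd" %in% stages) {
    if (is.null(trajs)) stop("msd stage requires trajectories from a ",
                             "simulate (or track) stage")
    ens <- compute_ensemble_msd(trajs, rheo$max_lag_fraction)
    p <- file.path(outdir, "msd.csv")
    write_msd(ens, p)
    artifacts <- c(artifacts, p)
  }

  if ("rheology" %in% stages) {
    if (is.null(ens)) stop("rheology stage requires the msd stage")
    spec <- gser_moduli(ens, rheo)
    if (identical(cfg$units, "dyn/cm2")) spec <- spectrum_in_dyn_cm2(spec)
    p <- file.path(outdir, "spectrum.csv")
    write_spectrum(spec, p)
    artifacts <- c(artifacts, p)
    pa <- phase_angle(spec, band = cfg$delta_band)
    summary$delta_median_deg <- pa$summary
    summary$delta_band <- cfg$delta_band
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mptrheo")),
    seed = seed,
    stage_seeds = lapply(stats::setNames(stages, stages),
                         function(s) .stage_seed(seed, s)),
    config = cfg,
    artifacts = stats::setNames(
      as.list(unname(tools::md5sum(artifacts))), basename(artifacts)),
    summary = summary)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}

#' Summarize pipeline artifacts into report tables and figures
#'
#' Pure formatting over existing artifacts: a summary CSV (and, for
#' spectra, a log-log figure of G', G'' and the MSD) with no further
#' computation.
#'
#' @param outdir directory holding the artifacts of [run_pipeline()].
#' @param figures write a PDF figure alongside the tables.
#' @return paths of the written report files, invisibly.
#' @export
make_report <- function(outdir, figures = TRUE) {
  spec_path <- file.path(outdir, "spectrum.csv")
  msd_path <- file.path(outdir, "msd.csv")
  if (!file.exists(spec_path) && !file.exists(msd_path))
    stop("no spectrum.csv or msd.csv artifacts found in ", outdir)
  written <- character(0)
  summ <- list()
  if (file.exists(msd_path)) {
    msd <- utils::read.csv(msd_path)
    summ$msd_at_min_lag_um2 <- msd$msd_um2[1L]
    summ$max_lag_s <- max(msd$lag_s)
  }
  if (file.exists(spec_path)) {
    sp <- utils::read.csv(spec_path)
    band <- sp$omega >= 1 & sp$omega <= 10
    if (any(band)) summ$delta_median_deg <- stats::median(sp$delta_deg[band])
    summ$alpha_median <- stats::median(sp$alpha)
  }
  tab <- data.frame(quantity = names(summ),
                    value = unlist(summ, use.names = FALSE))
  out_csv <- file.path(outdir, "report_summary.csv")
  utils::write.csv(tab, out_csv, row.names = FALSE)
  written <- c(written, out_csv)
  if (figures) {
    out_pdf <- file.path(outdir, "report.pdf")
    grDevices::pdf(out_pdf, width = 9, height = 4.5)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mfrow = c(1, 2))
    if (file.exists(msd_path)) {
      graphics::plot(msd$lag_s, msd$msd_um2, log = "xy", type = "b",
                     pch = 16, cex = 0.5, xlab = "lag time (s)",
                     ylab = expression(MSD ~ (mu * m^2)),
                     main = "Ensemble MSD")
    }
    if (file.exists(spec_path)) {
      pos <- sp$G1_Pa > 0 | sp$G2_Pa > 0
      ylim <- range(c(sp$G1_Pa[sp$G1_Pa > 0], sp$G2_Pa[sp$G2_Pa > 0]))
      graphics::plot(sp$omega[pos], pmax(sp$G1_Pa[pos], ylim[1L]),
                     log = "xy", type = "l", lty = 1, ylim = ylim,
                     xlab = expression(omega ~ (rad/s)),
                     ylab = "modulus (Pa)", main = "G' (solid), G'' (dashed)")
      graphics::lines(sp$omega[pos], pmax(sp$G2_Pa[pos], ylim[1L]),
                      lty = 2)
    }
    written <- c(written, out_pdf)
  }
  invisible(written)
}
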