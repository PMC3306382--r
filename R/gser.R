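# Generalized Stokes-Einstein conversion of the ensemble MSD to
# frequency-dependent viscoelastic moduli.
#
# The medium's Laplace-domain modulus is G(s) = kB T / (pi a s <MSD(s)>).
# Rather than transforming numerically, the local power-law (Mason)
# estimator projects this into the Fourier domain algebraically:
#
#   |G*(w)| = kB T / (pi a m(1/w) Gamma[1 + alpha(w)])
#   G'(w)  = |G*| cos(pi alpha / 2),   G''(w) = |G*| sin(pi alpha / 2)
#
# where alpha(w) is the local logarithmic slope of the MSD at t = 1/w and
# m is the (dimension-corrected) MSD.  For an exact power-law MSD this
# reproduces the analytic transform; a numerical-transform oracle lives in
# the test suite.

#' Parameters of the MSD-to-moduli conversion
#'
#' @param temperature absolute temperature, K.
#' @param probe_radius probe radius, um.
#' @param msd_dimension_correction factor applied to the measured 2D MSD
#'   before the GSER.  The `pi a` form of the relation presumes a
#'   3D-equivalent MSD; tracking is two-dimensional, so the default 3/2
#'   rescales `<dx^2 + dy^2>` to `<dx^2 + dy^2 + dz^2>` for an isotropic
#'   medium.  Affects only the modulus scale, never `alpha` or `delta`.
#' @param max_lag_fraction largest MSD lag used, as a fraction of
#'   trajectory length (<= 0.5).
#' @param smoothing_halfwidth half-width, in points of the log-spaced lag
#'   grid, of the local log-log fit that estimates alpha.
#' @param lags_per_decade density of the logarithmically spaced lag grid
#'   the spectrum is evaluated on.  Uniform lag spacing would make the
#'   local log-log slope window span a vanishing log-range at long lags,
#'   amplifying noise; log-spacing keeps the slope estimator's bandwidth
#'   constant across frequencies.  `NULL` uses every sampled lag.
#' @return an object of class `rheology_config`.
#' @export
rheology_config <- function(temperature = 310.15, probe_radius = 0.05,
                            msd_dimension_correction = 1.5,
                            max_lag_fraction = 0.25,
                            smoothing_halfwidth = 2L,
                            lags_per_decade = 16L) {
  if (temperature <= 0) stop("temperature must be positive (K)")
  if (probe_radius <= 0) stop("probe_radius must be positive (um)")
  if (msd_dimension_correction <= 0)
    stop("msd_dimension_correction must be positive")
  if (max_lag_fraction <= 0 || max_lag_fraction > 0.5)
    stop("max_lag_fraction must lie in (0, 0.5]")
  if (smoothing_halfwidth < 1) stop("smoothing_halfwidth must be >= 1")
  if (!is.null(lags_per_decade) && lags_per_decade < 4)
    stop("lags_per_decade must be >= 4 (or NULL for every lag)")
  structure(list(temperature = temperature, probe_radius = probe_radius,
                 msd_dimension_correction = msd_dimension_correction,
                 max_lag_fraction = max_lag_fraction,
                 smoothing_halfwidth = as.integer(smoothing_halfwidth),
                 lags_per_decade = lags_per_decade),
            class = "rheology_config")
}

#' Subsample an ensemble MSD onto a logarithmically spaced lag grid
#'
#' Picks the sampled lags closest to `lags_per_decade` points per decade
#' (always keeping the first and last lag); duplicates are dropped.
#'
#' @param ens an `ensemble_msd`.
#' @param lags_per_decade grid density; `NULL` returns the input.
#' @return an `ensemble_msd` on the reduced grid.
#' @export
subsample_log_lags <- function(ens, lags_per_decade = 16L) {
  if (is.null(lags_per_decade)) return(ens)
  lo <- log10(min(ens$lag_s))
  hi <- log10(max(ens$lag_s))
  targets <- 10^seq(lo, hi, by = 1 / lags_per_decade)
  idx <- unique(vapply(targets, function(t)
    which.min(abs(log(ens$lag_s) - log(t))), integer(1L)))
  idx <- sort(unique(c(idx, 1L, nrow(ens))))
  out <- ens[idx, ]
  rownames(out) <- NULL
  structure(out, class = class(ens),
            frame_interval = attr(ens, "frame_interval"))
}

#' Local logarithmic slope of the ensemble MSD
#'
#' alpha(w) = d ln MSD / d ln t evaluated at t = 1/w, estimated at each
#' lag by a least-squares line through (ln tau, ln MSD) over a window of
#' +- `smoothing_halfwidth` points (truncated at the boundaries).  Slopes
#' are clipped to the physical range [0, 2]; clip events are reported via
#' the `"n_clipped"` attribute and a message.
#'
#' @param ens an `ensemble_msd` (all `msd_um2` must be positive).
#' @param smoothing_halfwidth window half-width, points.
#' @return data frame with `omega` (rad/s, = 1/lag), `lag_s`, `alpha`.
#' @export
log_slope <- function(ens, smoothing_halfwidth = 2L) {
  stopifnot(is.data.frame(ens))
  n <- nrow(ens)
  if (n < 3L) stop("need at least 3 lags to estimate a log-slope")
  if (any(ens$msd_um2 <= 0))
    stop("MSD must be positive at every lag to take logarithms; ",
         "raise the minimum lag or drop empty lags")
  lt <- log(ens$lag_s)
  lm_ <- log(ens$msd_um2)
  h <- as.integer(smoothing_halfwidth)
  alpha <- vapply(seq_len(n), function(i) {
    w <- max(1L, i - h):min(n, i + h)
    x <- lt[w] - mean(lt[w])
    sum(x * lm_[w]) / sum(x * x)
  }, numeric(1L))
  clipped <- alpha < -1e-9 | alpha > 2 + 1e-9
  if (any(clipped))
    message(sum(clipped), " alpha value(s) clipped to [0, 2]")
  alpha <- pmin(pmax(alpha, 0), 2)
  alpha[abs(alpha) < 1e-12] <- 0  # snap float noise so sin(pi alpha/2) = 0
  structure(data.frame(omega = 1 / ens$lag_s, lag_s = ens$lag_s,
                       alpha = alpha),
            n_clipped = sum(clipped))
}

#' Viscoelastic moduli from the ensemble MSD (Mason estimator)
#'
#' Converts the ensemble MSD to `|G*|`, `G'`, `G''` and the phase angle
#' `delta` on the frequency grid `omega = 1/lag`.  Where `alpha > 1` the
#' algebraic estimator would give a (non-physical) negative `G'`; negative
#' moduli are clamped to zero (counted in attribute `"n_clamped"`) and
#' `|G*|` is recomputed as `sqrt(G'^2 + G''^2)` so the Pythagorean
#' relation holds exactly.  Output is in Pa; multiply by 10 for dyn/cm^2
#' (see [spectrum_in_dyn_cm2()]).
#'
#' @param ens an `ensemble_msd` (um^2 vs s).
#' @param config a [rheology_config()].
#' @param static_error_um optional static localization error sigma (um)
#'   whose floor `4 sigma^2` is subtracted from the MSD before conversion;
#'   off by default.
#' @return a `viscoelastic_spectrum` data frame with `omega`, `alpha`,
#'   `G_star`, `G_prime`, `G_double_prime` (Pa) and `delta_deg`, sorted by
#'   increasing omega.
#' @export
gser_moduli <- function(ens, config = rheology_config(),
                        static_error_um = 0) {
  stopifnot(is.data.frame(ens))
  ens <- subsample_log_lags(ens, config$lags_per_decade)
  msd <- ens$msd_um2 - 4 * static_error_um^2
  if (any(msd <= 0))
    stop("MSD must be positive at every lag (after any static-error ",
         "subtraction)")
  ens2 <- ens
  ens2$msd_um2 <- msd
  sl <- log_slope(ens2, config$smoothing_halfwidth)
  alpha <- sl$alpha
  a_m <- config$probe_radius * 1e-6
  m_m2 <- config$msd_dimension_correction * msd * 1e-12
  g_mag <- .kB * config$temperature / (pi * a_m * m_m2 * gamma(1 + alpha))
  g1 <- g_mag * cospi(alpha / 2)
  g2 <- g_mag * sinpi(alpha / 2)
  n_clamped <- sum(g1 < 0) + sum(g2 < 0)
  g1 <- pmax(g1, 0)
  g2 <- pmax(g2, 0)
  g_mag <- sqrt(g1^2 + g2^2)
  delta <- atan2(g2, g1) * 180 / pi
  out <- data.frame(omega = sl$omega, lag_s = sl$lag_s, alpha = alpha,
                    G_star = g_mag, G_prime = g1, G_double_prime = g2,
                    delta_deg = delta)
  out <- out[order(out$omega), ]
  rownames(out) <- NULL
  structure(out, class = c("viscoelastic_spectrum", "data.frame"),
            units = "Pa", n_clamped = n_clamped,
            n_alpha_clipped = attr(sl, "n_clipped"), config = config)
}

#' Express a viscoelastic spectrum in dyn/cm^2
#'
#' 1 Pa = 10 dyn/cm^2.
#' @param spectrum a `viscoelastic_spectrum` in Pa.
#' @return the spectrum with moduli multiplied by 10 and `units`
#'   attribute `"dyn/cm2"`.
#' @export
spectrum_in_dyn_cm2 <- function(spectrum) {
  stopifnot(inherits(spectrum, "viscoelastic_spectrum"))
  if (identical(attr(spectrum, "units"), "dyn/cm2")) return(spectrum)
  for (col in c("G_star", "G_prime", "G_double_prime"))
    spectrum[[col]] <- spectrum[[col]] * 10
  attr(spectrum, "units") <- "dyn/cm2"
  spectrum
}

#' Phase angle of a viscoelastic spectrum
#'
#' `delta = arctan(G''/G')` in degrees: 90 for a viscous liquid, 0 for a
#' Hookean solid, intermediate for a viscoelastic material.  Also reports
#' a scalar summary, the median delta over a frequency band.
#'
#' @param spectrum a `viscoelastic_spectrum`, or a data frame with
#'   `omega`, `G_prime`, `G_double_prime`.
#' @param band frequency band (rad/s) for the scalar summary.
#' @return list with `delta` (data frame omega, delta_deg) and `summary`
#'   (median delta over the band, degrees).
#' @export
phase_angle <- function(spectrum, band = c(1, 10)) {
  stopifnot(all(c("omega", "G_prime", "G_double_prime") %in%
                  names(spectrum)))
  g1 <- spectrum$G_prime
  g2 <- spectrum$G_double_prime
  if (any(g1 < 0) || any(g2 < 0)) stop("moduli must be non-negative")
  both0 <- g1 == 0 & g2 == 0
  if (any(both0))
    stop("delta undefined where G' = G'' = 0 (omega = ",
         paste(signif(spectrum$omega[both0], 3), collapse = ", "), ")")
  delta <- atan2(g2, g1) * 180 / pi
  in_band <- spectrum$omega >= band[1L] & spectrum$omega <= band[2L]
  if (!any(in_band))
    stop("no sampled frequencies in the summary band [", band[1L], ", ",
         band[2L], "] rad/s")
  list(delta = data.frame(omega = spectrum$omega, delta_deg = delta),
       summary = stats::median(delta[in_band]))
}
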