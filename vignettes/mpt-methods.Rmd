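---
title: "Particle-tracking microrheology and cell morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Particle-tracking microrheology and cell morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mptrheo)
```

## The measurement model

Multiple-particle-tracking microrheology (MPT) infers the viscoelasticity
of the medium surrounding thermally driven probe particles from their
mean squared displacement (MSD). The chain implemented here is

1. localize particles per frame by intensity-weighted centroid,
2. link detections into trajectories,
3. compute per-particle time-averaged MSDs and their ensemble average,
4. convert the ensemble MSD to frequency-dependent moduli with the
   generalized Stokes–Einstein relation (GSER),
5. summarize the mechanical state by the phase angle
   $\delta(\omega) = \arctan(G''/G')$.

The GSER states, in the Laplace domain,
$\tilde G(s) = k_B T / (\pi a s \langle\langle \Delta r^2(s)\rangle\rangle)$,
with $a$ the probe radius and $T$ absolute temperature. It assumes the
medium is a homogeneous, isotropic continuum at the probe scale, in
thermal equilibrium, and that probe inertia and fluid inertia are
negligible over the sampled frequencies. None of these hold exactly in a
cytoplasm (which is heterogeneous and actively driven); MPT treats the
result as an effective local rheology.

Rather than transforming the sampled MSD numerically, the package uses
the local power-law (Mason) projection: approximating the MSD near
$t = 1/\omega$ by $\Delta r^2 \propto t^{\alpha(\omega)}$ with
$\alpha(\omega) = \mathrm{d}\ln \langle\langle\Delta r^2\rangle\rangle /
\mathrm{d}\ln t$, the transform evaluates algebraically to

$$|G^*(\omega)| = \frac{k_B T}{\pi a\, m(1/\omega)\, \Gamma[1+\alpha(\omega)]},
\qquad G' = |G^*|\cos(\pi\alpha/2), \quad G'' = |G^*|\sin(\pi\alpha/2).$$

For an exact power-law MSD this equals the analytic transform; the test
suite carries an independent numerical Laplace-transform oracle and
checks agreement within 3% on $|G^*|$ at interior frequencies. The two
limiting cases anchor the scale: a Newtonian fluid
($\Delta r^2_{2D} = 4Dt$, $\alpha = 1$) maps to $G'' = \eta\omega$ and
$\delta = 90^\circ$; an arrested probe in a harmonic trap of stiffness
$\kappa$ (plateau $4 k_B T/\kappa$, $\alpha = 0$) maps to
$G' = \kappa/(6\pi a)$ and $\delta = 0^\circ$. The Mason identity
$\delta = \alpha \cdot 90^\circ$ holds exactly for power-law media.

## Parameters that matter

* `temperature` (K, default 310.15): enters $|G^*|$ linearly; live-cell
  incubation temperature.
* `probe_radius` (µm, default 0.05): 100 nm-diameter beads; enters
  $|G^*|$ inversely. Errors in $a$ or $T$ rescale the moduli but leave
  $\alpha$ and $\delta$ untouched (asserted numerically in the suite).
* `msd_dimension_correction` (default 3/2): the $\pi a$ form of the GSER
  presumes a 3D-equivalent MSD while tracking is 2D; for an isotropic
  medium $\langle\Delta r^2_{3D}\rangle = \tfrac{3}{2}\langle\Delta
  r^2_{2D}\rangle$. Without the correction a Newtonian fluid would read
  $G'' = \tfrac{3}{2}\eta\omega$. Whether published cytoplasmic moduli
  include this factor is often unstated, so it is a configuration knob,
  not a hard-wired constant; $\delta$ and $\alpha$ are unaffected either
  way.
* `max_lag_fraction` (default 0.25): for a diffusing particle the MSD
  estimator variance grows with lag, so standard practice discards lags
  beyond a quarter of the trajectory. For *bounded* (trapped) MSDs that
  rationale does not apply, and plateau readouts benefit from the longest
  accessible lags: analyses of Hookean media here use 0.5. This choice
  was made from the analytic Ornstein–Uhlenbeck MSD passed through the
  estimator: with a 10-frame relaxation time, the crossover tail still
  sits inside the lowest sampled frequency decade at the 1/4 cap
  (analytic median $\delta \approx 3.7^\circ$ where the plateau value is
  $\approx 0^\circ$), while at the 1/2 cap the lowest decade is clean.
* `lags_per_decade` (default 16) and `smoothing_halfwidth` (default 2
  points): $\alpha(\omega)$ is the slope of a local least-squares line
  through $(\ln\tau, \ln \mathrm{MSD})$. The spectrum is evaluated on a
  log-spaced lag grid because on a uniform grid the window spans a
  vanishing log-range at long lags, amplifying noise that the physical
  clip $\alpha \ge 0$ then rectifies into a positive $\delta$ bias.
* `ensemble averaging`: each particle contributes its time-averaged MSD
  with equal weight, regardless of trajectory length; uncertainty is the
  standard error across particles (overlapping displacement pairs within
  one trajectory are correlated, so per-pair errors would be too
  optimistic). Lags that only longer trajectories reach are averaged
  over the particles that reach them, with per-lag counts reported.

Tracking defaults: detections seed at local maxima above 30% of the
brightest background-subtracted pixel (background = frame median, robust
to sparse spots; negatives clipped); centroids are computed over an
11-px window (`window_radius = 6`, covering a PSF of σ ≈ 1.3 px);
linking is greedy nearest-neighbour with mutual-closest acceptance,
a 5 px/frame gate, deterministic tie-breaking by lower track id, no gap
closing; tracks shorter than 100 frames are dropped so each retained
particle supports lags to 25 frames at the quarter-length cap.
Global-optimal (Hungarian) assignment is deliberately not used: at
10–20 particles per field, greedy mutual-nearest linking is equivalent
in practice and easier to audit — a documented limitation at higher
densities.

## What the synthetic data emulate — and what they do not

The generators reproduce the acquisition geometry of a standard MPT
experiment: 20-second videos at 33 ms resolution (30 frames/s), 15
particles per video by default, 100 nm probes, ~5 nm static
localization error, and for rendered movies a Gaussian PSF (σ = 1.3 px
at 100 nm/px) with Poisson photon statistics over a uniform background.

* **Viscous**: independent Gaussian increments, variance $2D\Delta t$
  per axis.
* **Power-law (subdiffusive)**: per-axis fractional Brownian motion with
  Hurst exponent $H = \alpha/2$, synthesized by Cholesky factorization
  of the exact fractional-Gaussian-noise covariance — no spectral or
  wavelet approximation — so $\alpha$-recovery tests measure estimator
  error, not generator error. The singular edge $\alpha = 2$ is
  generated as exact ballistic motion with Gaussian per-particle
  velocities.
* **Trapped**: stationary Ornstein–Uhlenbeck process per axis with the
  exact discrete-time update, so plateau tests carry no time-step bias.

Deliberately not modelled: hydrodynamic or steric coupling between
particles, cytoplasmic heterogeneity (each dataset is one homogeneous
medium), active non-thermal forces, 3D (out-of-plane) motion and
defocus, photobleaching, and probe depth distributions. Passing tests
therefore demonstrate the *estimator chain* is correct and calibrated —
not that real cytoplasmic data satisfy GSER assumptions. Rendered cells
are geometric idealizations (elliptical bodies and nuclei, straight
fibers, Gaussian puncta) for calibrating the morphometric definitions,
not realistic texture models.

## Morphometry definitions

* **Cell shape factor** = minor/major axis of the best-fit ellipse from
  second-order moments of the segmented mask (1 = circle). For a filled
  ellipse the coordinate-covariance eigenvalues are
  $\lambda_{1,2} = (\text{semi-axes})^2/4$, so full axes are
  $4\sqrt{\lambda}$; the ratio is rotation-invariant by construction of
  the eigendecomposition (verified within 0.01 on rendered rotations).
* **Nuclear shape factor**: same axis-ratio convention, on a
  single-nucleus mask (the function enforces one connected component,
  matching a semi-automated one-nucleus-at-a-time workflow). A
  perimeter-based circularity $4\pi A/P^2$ is exposed as an alternative
  because the axis-ratio-vs-circularity choice is ambiguous in parts of
  the literature; both equal 1 for a circle.
* **Stress-fiber factor** = fiber-pixel fraction of cell area. Fibers
  are detected as ridges of the negative Laplacian-of-Gaussian response
  (σ ≈ half the fiber width, default 0.5 µm at 0.2 µm/px → 2.5 px),
  thresholded by Otsu within the cell. Two numerical guards: the
  response is evaluated on the mask eroded by ~4σ so the cell-boundary
  step edge is not counted as fiber (fibers span the cell, so the
  interior fraction is an unbiased whole-cell estimate), and a response
  floor of 0.5% of the image contrast returns exactly 0 for a uniform
  (fiber-free) channel instead of an Otsu split of numerical noise.
  Intensity normalization makes the factor invariant to uniform
  scaling. Thresholded pixel count is the default numerator; the summed
  supra-threshold response is available.
* **Vinculin:actin ratio**: each channel background-subtracted by the
  median outside the mask, clipped at zero, summed within the mask, and
  ratioed — linear in the vinculin channel.
* **Nuclei counting**: Otsu, minimum-area filter, optional distance-map
  watershed for touching nuclei; batch mode reports the mean count per
  field (the transwell-migration readout, typically 9 fields).
* **Segmentation**: cell bodies are segmented by Otsu thresholding of
  log-intensities. On linear intensities, a bright-fiber/dim-cytoplasm
  image makes Otsu separate fibers from cytoplasm rather than cell from
  background; the log compresses that dynamic range (exact recovery on
  rendered fibered cells). Manual ROI polygons (the workflow when
  borders are drawn by hand) are supported via even-odd polygon fill.

## Assay statistics

Adherent fraction = (post-spin − blank)/(pre-spin − blank), clipped at
0 and flagged above 1.05. ΔΔCt fold change: per-sample
$\Delta C_t = C_t^{gene} - C_t^{GAPDH}$, referenced to the mean
$\Delta C_t$ of a designated control group, reported as
$2^{-\Delta\Delta C_t}$ with mean ± SEM computed on per-sample fold
changes (the common reporting convention; SEM on the ΔΔCt scale with
delta-method transformation is available, and makes the reference
group's own fold change exactly 1). Group comparison uses Student's
t-test for two groups, one-way ANOVA for more, and two-way ANOVA with
interaction for cell-type × treatment designs, with the usual star
convention (*** p<0.001, ** p<0.01, * p<0.05). The two-factor report is
generic: no claim is made of replicating any particular published ANOVA
whose factor structure is not fully specified.

## Numerical choices and degenerate inputs

* Positions are µm, times s, moduli Pa (dyn/cm² = 10 × Pa available).
  Pixel coordinates are 0-based with pixel centers at integer
  coordinates, order (x = column, y = row), shared by renderer and
  tracker.
* $\alpha$ is clipped to $[0, 2]$ (clip events counted and messaged);
  values within $10^{-12}$ of 0 are snapped so $\sin(\pi\alpha/2)$ is
  exactly 0 at a plateau. Where $\alpha > 1$ makes the algebraic $G'$
  negative, moduli are clamped at 0 and $|G^*|$ recomputed as
  $\sqrt{G'^2 + G''^2}$, so $\delta$ saturates at 90° and the
  Pythagorean closure holds exactly.
* MSDs of zero (perfectly stationary input) are rejected before the
  logarithm with an actionable error; the optional static-error floor
  subtraction ($4\sigma^2$) is off by default.
* Linking ties (equal distances) break deterministically toward the
  lower track id. Empty images yield empty detection sets, not errors;
  flat images yield no cells/nuclei.
* All generators are bit-reproducible given a seed; the pipeline derives
  per-stage seeds from one top-level seed (`seed + 1000·stage_index`)
  so stages can be re-run independently.

## Problem sizes used in the shipped tests

Simulation-based checks use 200 particles × 600 frames (the standard
20 s acquisition) for pipeline limits, 100–200 particles for estimator
recovery, 4 rendered movies × 10 particles × 300 frames for the
tracking end-to-end check, and 2000 replicates for the type-I-error
check — sizes chosen so the whole suite runs in about a minute on one
core while keeping Monte-Carlo error far below the asserted tolerances.

## Known limitations

Greedy linking (no global assignment, no gap closing) limits use at
high particle density or with blinking probes. No drift correction is
applied. The GSER conversion reports effective moduli only over the
sampled frequency window (no extrapolation), and its accuracy degrades
within half a smoothing window of the band edges. Morphometry assumes
maximum-intensity-projected, single-cell fields of view; overlapping
cells must be separated upstream or outlined manually.
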