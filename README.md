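# mptrheo

Live-cell mechanics from multiple-particle-tracking microrheology (MPT),
plus the quantitative image metrics and plate-assay statistics that
typically accompany it in cell-mechanics studies.

MPT probes the viscoelasticity of the cytoplasm by embedding ~100 nm
fluorescent particles in cells, filming their thermal motion (typically
20-second videos at 30 frames/s), and converting the ensemble-averaged
mean squared displacement

    <<Δr²(Δt)>> = << [x(t+Δt) − x(t)]² + [y(t+Δt) − y(t)]² >>

into frequency-dependent moduli through the generalized Stokes–Einstein
relation (GSER), `G(s) = k_B T / (π a s <<Δr²(s)>>)`. The package
implements the local power-law (Mason) projection of that relation:

    α(ω)    = d ln <<Δr²(t)>> / d ln t  at  t = 1/ω
    |G*(ω)| = k_B T / (π a m(1/ω) Γ[1 + α(ω)])
    G′ = |G*| cos(πα/2),  G″ = |G*| sin(πα/2),  δ = arctan(G″/G′)

with `m` the dimension-corrected MSD. The phase angle δ summarizes the
mechanical state: 90° for a viscous liquid, 0° for a Hookean elastic
solid. Because no raw microscopy ships with a desk-scale analysis, the
package includes a first-class synthetic-data module — exact fractional
Brownian (Cholesky of the fGn covariance), exact discrete-time
Ornstein–Uhlenbeck traps, and a movie renderer with Poisson photon
statistics — so every stage is testable against known ground truth.

Who it is for: cell-mechanics and biophysics groups running MPT
experiments who want a scriptable, tested alternative to one-off
MATLAB/MetaMorph routines, covering tracking → MSD → moduli as well as
the morphometric readouts (shape factors, stress-fiber density,
vinculin:actin ratio, nuclei counting) and assay statistics
(centrifugal adhesion fractions, ΔΔCt fold changes, group comparisons).

## Worked example

Simulate probes in a viscous medium at the standard acquisition geometry
(600 frames at 33 ms), run the full pipeline, and read off the
mechanical state:

```r
library(mptrheo)

truth <- simulation_truth("viscous", D = 0.1)   # um^2/s
trajs <- simulate_brownian(truth, acquisition_spec(n_particles = 200),
                           seed = 7)
ens   <- compute_ensemble_msd(trajs)
spec  <- gser_moduli(ens, rheology_config())
phase_angle(spec, band = c(1, 10))$summary
#> [1] 90
band <- spec$omega >= 1 & spec$omega <= 10
median(spec$G_double_prime[band] / spec$omega[band])
#> [1] 0.0454
```

The median phase angle over 1–10 rad/s is 90° — a purely viscous
response — and the apparent viscosity `G″/ω` is 0.0454 Pa·s, matching
the viscosity implied by the simulated diffusivity through
Stokes–Einstein (`k_B T / (6 π a D)` = 0.0454 Pa·s at 310.15 K for a
50 nm-radius probe).

Morphometry on a rendered stained cell (40 × 20 µm body, four stress
fibers):

```r
out   <- render_cell_image(synthetic_cell_spec(
           cell_major_axis = 40, cell_minor_axis = 20,
           n_fibers = 4, seed = 8))
cells <- segment_cells(out$channels$actin, min_area = 500,
                       pixel_size = 0.2)
cell_shape_factor(cells[[1]])
#> [1] 0.5
stress_fiber_factor(out$channels$actin, cells[[1]], log_sigma_px = 2)
#> [1] 0.163   # rendered ground truth: 0.169
```

The shape factor (minor/major axis of the best-fit ellipse) recovers the
2:1 elongation exactly; the stress-fiber factor (fiber-pixel fraction of
the cell area from a Laplacian-of-Gaussian ridge filter) recovers the
rendered coverage within 0.01.

An end-to-end run with provenance manifest:

```r
run_pipeline(list(medium = list(kind = "viscous", D = 0.1)),
             seed = 1, outdir = "run1")
make_report("run1")
```

A thin command-line wrapper lives at `inst/scripts/mpt_pipeline.R`.

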