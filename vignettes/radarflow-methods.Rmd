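---
title: "Methods behind radarflow: reconstructing and visualizing migratory flow from weather-radar profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind radarflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radarflow)
```

## The measurement model

A weather radar running a bird-profiling algorithm yields, per scan and per
altitude bin, a bird density ρ_bird (birds km⁻³) and the horizontal
ground-speed components (u, v) of the birds aloft (m s⁻¹, east and north).
Density derives from linear reflectivity η (cm² km⁻³) through an assumed
per-bird radar cross section σ:

ρ_bird = η / σ,  σ = 11 cm² by default,

the cross-calibrated value for nocturnal passerine migration
(`reflectivity_to_density()`). A network of such radars samples a
time-varying, altitude-layered vector field (u, v) and scalar field ρ at a
few dozen points at most. Everything in this package is a consequence of
that sparsity: the fields must be reconstructed by interpolation before any
flow can be drawn.

### Preprocessing and its filtering rules

`filter_records()` and `aggregate_profiles()` implement the standard
pipeline (`preprocess_config()` holds the constants):

* The lowest altitude bin (floor < 200 m) is excluded: ground clutter
  dominates there. Bins at or above the sampling ceiling (4000 m EU-style,
  3000 m US-style) are dropped.
* Velocities are kept only where ρ_bird ≥ 1 bird km⁻³ (inclusive). At low
  densities the velocity estimate is easily contaminated by residual rain
  and insects; the density itself is retained.
* Scan timestamps are rounded to the nearest 5 minutes (relevant for
  networks whose scans fall off-grid), then records aggregate into
  half-open 20-minute windows [t, t + 20 min) anchored at the hour, crossed
  with altitude bands. Band means of density and velocity are **unweighted**
  over the altitude bins; a density-weighted velocity mean is available
  (`density_weighted = TRUE`) but off by default, since the standard
  pipeline takes plain means. The density mean includes bins whose velocity
  was filtered out — the velocity filter is about velocity quality, not
  about whether birds were present.
* **Zero-velocity convention.** If no bin in a window passed the velocity
  filter but at least one bin *had* a measured velocity, the aggregate is
  emitted with u = v = 0 and a flag: measurements were taken, no migration
  was detected. These records participate in interpolation and pull the
  reconstructed field toward zero — deliberately distinct from *missing*
  velocity (no measurement), which contributes nothing. I/O preserves the
  distinction: empty CSV fields are missing values and are never read as 0.

Altitude bins straddling a band boundary are assigned by bin floor. For
EU-style 200-m bins the default boundaries (200, 1600, 4000 m) align
exactly, so the rule only matters for 100-m US-style bins, where some rule
is needed and the floor rule is the simplest deterministic one.

## Field reconstruction

`flow_field()` indexes the aggregates by (interval, band);
`interpolate_vector()` / `interpolate_scalar()` evaluate the fields by
inverse squared distance weighting over the k nearest vector-bearing (or
density-bearing) samples:

V(x) = Σᵢ wᵢ Vᵢ / Σᵢ wᵢ,  wᵢ = dᵢ⁻²,  i over the k = 5 nearest radars.

Numerical choices:

* A query point coinciding with a sample (d = 0) returns that sample's
  value exactly, making the interpolant exact at the radars.
* Ties at the k-th distance are all included, so results never depend on
  sample order (k may effectively be exceeded at ties).
* With no vector-bearing sample in a snapshot the field is *undefined*: a
  typed condition (`radarflow_field_undefined`) that particle engines
  translate into frozen/truncated particles rather than NaNs.
* Temporal behaviour is piecewise-constant per 20-minute interval, matching
  the stepwise field updates of the animated visualization; optional
  linear-in-time blending (`time_blend = TRUE`) exists purely for smoother
  animation and is off by default.

Interpolation happens in a projected plane in kilometres (azimuthal equidistant on a
sphere, R = 6371.0088 km, centred on the radar centroid), not in screen pixels as
browser-based implementations of this visualization do. Pixel-space
interpolation ties results to a rendering resolution;
km-space results are reproducible and the renderer converts at draw time.
Distances from the projection centre are true great-circle distances, and
over the ≤ ~1000 km extent of a radar network the distortion between
stations is far smaller than the physical uncertainty of assigning a point
measurement a 75-km radius of validity. IDW weights therefore use planar
km distances.

The IDW interpolant is a convex combination, so reconstructed values stay
within the range of the contributing samples — no overshoot, but also no
extrapolation of gradients: far from all radars the field flattens toward
the average of the five nearest samples. This is an accepted property of
the method, not a defect to be fixed by tuning.

## The streamlet animation

`seed_streamlets()` / `step_streamlets()` maintain a fixed population
(450 by default) of short streamline segments. Per frame, each head moves
by V(head) × Δt × speed_scale; the previous head joins the trail; trail
segment opacities multiply by a fade factor; streamlets that reach their
lifespan are replaced by fresh uniform-random seeds (population size is
invariant); after a fixed number of frames the field advances to the next
20-minute interval. Density is intentionally unused here — the animation
encodes velocity only.

Parameters the method family does not pin down, fixed here as defaults:

| parameter | default | rationale |
|---|---|---|
| `n` | 450 | the conventional population size for this visualization |
| `max_age_range` | 30–90 frames, per-streamlet uniform | "varying lifespans"; staggered deaths avoid pulsing |
| `fade` | 0.95 per frame | trails vanish (< 1/255) after ~108 frames |
| `speed_scale` | 30 | animation exaggeration; measured speeds are visually static at map scale |
| `dt_frame_s` | 60 s simulated per frame | at a nominal 60 frames per animation-second, one simulated minute per frame keeps 20-minute intervals legible |
| `frames_per_interval` | 120 | two animation-seconds per data interval at the nominal frame rate |

Seeding of dying streamlets is uniform over the domain (biasing reseeding
toward inflow boundaries is conceivable; uniform is the assumption-free
choice). All randomness flows through a private RNG
stream stored in the state, so a given seed replays bit-identically
regardless of the caller's RNG use. Fully faded segments (< 1/255 opacity)
are trimmed; because opacity decays geometrically with segment age, this
only ever removes a prefix of the trail.

## TIMAMP

The static visualization answers "how many birds moved where" over a
window of 1–8 whole hours, split into 1–6 even altitude strata over
[0, ceiling].

1. **Lattice** (`build_lattice()`): square cells (10 km EU-style, 20 km
   US-style) are kept iff the cell centre lies within 75 km of the nearest
   radar — the chosen operationalization of "mostly within 75 km of a radar" —
   and crossed with the strata into volumes.
2. **Expected migrants** (`volume_migrants()`): per volume, the IDW density
   at the cell centre is averaged over the window's 20-minute intervals
   (sampled at interval midpoints) and multiplied by the volume
   (cell² × stratum thickness, km³), giving birds per volume.
3. **Anchoring** (`draw_anchors()`): each volume's expectation, divided by
   `migrants_per_path` and apportioned uniformly over the window's time
   steps, is the per-step anchor intensity λ. The count drawn is
   floor(λ) + Bernoulli(frac(λ)): unbiased for any λ, including λ > 1,
   where a plain per-volume Bernoulli anchoring probability would be
   undefined. Anchor positions are uniform within the cell footprint —
   cell centres would imprint the lattice on the map. Consequently,
   E[pathlines] × migrants_per_path = Σ expected migrants: the drawn map is
   a visual census. The uniform per-step apportionment is itself a choice;
   nothing in the method constrains the weighting.
4. **Integration** (`heun_step()`, `integrate_pathline()`): from each
   anchor at its step's midpoint, the trajectory is integrated with the
   explicit two-stage Runge–Kutta (Heun) scheme, k₁ = V(t, x),
   k₂ = V(t + h, x + h k₁), x ← x + (h/2)(k₁ + k₂), h = ±20 min. With
   n = duration/20 min steps, ⌈n/2⌉ go backward and ⌊n/2⌋ forward — the
   odd step goes backward, an arbitrary but fixed and documented tie-break. The
   scheme is exact in fields constant over a step and second-order
   otherwise (the test suite verifies the error ratio ≈ 4 under step
   halving on a rotating flow). Where the field is undefined — outside the
   case's time coverage, or in an interval with no vector-bearing radar —
   the pathline truncates on that side and is flagged, never silently
   extrapolated.
5. **Styling** (`smooth_and_style()`): an interpolating cardinal spline
   through the vertices, tangents mᵢ = c (Pᵢ₊₁ − Pᵢ₋₁)/2 with tension
   c ∈ [0, 1] (c = 1 is the Catmull–Rom spline; default 0.5 renders
   calmer curves with the same vertices); per-vertex thickness
   t_min + (t_max − t_min) ρ / ρ_scale clipped to [t_min, t_max] (defaults
   0.5–4 units, ρ_scale = 400 birds km⁻³, chosen so typical peak nocturnal
   densities of a few hundred birds km⁻³ span the range; only the
   proportionality is essential); a dot at the temporally last vertex marks
   travel direction. Single-vertex (zero-flow or fully truncated) pathlines
   degenerate to the dot alone. Integration, like interpolation, works in km-space, consistent with the
   field module.

## The synthetic-case generator

`generate_case()` writes complete case directories in the exact file
dialects, sampling an analytic `flow_spec()` at each site/bin/scan and
adding optional Gaussian noise. The flow kinds — uniform, rigid rotation,
shear, per-layer bearings (altitude layering, emulating nights when upper
strata carry denser, differently-directed migration) and a clockwise
nocturnal bearing drift — plus a layered density model with an optional
north–south gradient cover the phenomena the visualizations are meant to
reveal. The built-in layouts mirror the two network styles: `eu5_sites()`,
five stations over ~300 × 300 km with 200-m bins to 4000 m and
`us13_sites()`, thirteen stations over ~1000 × 800 km with 100-m bins to
3000 m. Coordinates are synthetic.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: beam geometry and range-dependent sensitivity,
rain/insect contamination (the density threshold's actual reason for
existing), missing scans and station outages, correlated (rather than
i.i.d. Gaussian) measurement error, and terrain effects on the surface
reference of altitude bins. Recovery results on synthetic cases bound the
pipeline's numerical error, not the measurement error of real radars.

## Determinism and problem sizes

Every stochastic step (case generation, streamlet seeding/reseeding,
anchor draws) takes an explicit integer seed, and replays are
bit-identical; renders (PNG frame sequences, the built-in GIF89a writer)
are byte-reproducible given (seed, config, style). The test suite and the
acceptance script use deliberately small cases — 5-station layouts, 1–6 h
windows, populations of tens to a few hundred pathlines, 10 000-draw Monte
Carlo for anchoring and 2 000-draw for the end-to-end ratio — sizes at
which all statistical checks have comfortable margins while the whole
suite runs in a couple of minutes on one core.

## Known limitations

* IDW with k = 5 produces plateaus beyond the network hull and cannot
  represent divergence/convergence between radars beyond what distance
  weighting implies; kriging or spline interpolation (with uncertainty)
  is out of scope by design.
* The 75-km validity radius and the cell-centre retention rule create a
  hard edge; migrants crossing the edge simply leave the census.
* Pathlines assume birds passively follow the interpolated ground-speed
  field; individual variation, landing and take-off within a window are
  not modelled — TIMAMP is a visualization of measured flow, not an
  agent-based migration model.
* The CSV/JSON dialects are this package's own (the deposited case-study
  format is not printed in full anywhere authoritative); readers validate
  strictly and writers emit exactly the documented headers, so round-trips
  are lossless, but foreign files may need a one-line rename of columns.
* MP4 export is not provided; animations are GIF or PNG frame sequences.
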