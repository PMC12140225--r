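---
title: "Methods: synthetic submesoscale flows, larval tracking and connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic submesoscale flows, larval tracking and connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Invasive corals with short-lived, weakly swimming larvae (such as sun corals,
whose planulae are effectively passive drifters) spread along continental
shelves through the interplay of wind-driven coastal currents and
submesoscale features — filaments and eddies a few hundred metres to a few
tens of kilometres wide, dynamically marked by order-one Rossby numbers
`Ro = zeta / f`. On shelves with alternating wind regimes, two contrasting
situations recur: prevailing northeasterly winds drive a southwestward
alongshore jet that sheds cyclonic cross-shelf filaments (opening export
pathways from the coast toward offshore structures such as oil platforms),
while passing cold fronts reverse the winds, reverse the alongshore flow, and
trap material near the coast in anticyclonic features.

Running a full primitive-equation hindcast to study this is expensive and not
reproducible without the original forcing archives. `larvadrift` instead
provides a desk-scale emulation: analytic velocity fields with the same
structural ingredients (jet, filaments, eddies, a mid-run reversal), a
faithful Lagrangian tracker, the standard submesoscale diagnostics, and the
dispersal statistics used to summarize connectivity between named sites. The
same statistics run unchanged on externally supplied gridded velocity fields
read from NetCDF, so the synthetic generator is a substitutable front end,
not a closed world.

## Synthetic velocity fields

Every synthetic feature derives from a scalar streamfunction
`psi(lon, lat)`, with velocities

    u = -(1/R) dpsi/dphi,    v = (1/(R cos phi)) dpsi/dlambda,

evaluated analytically on a spherical Earth of radius R = 6,371,000 m. This
makes the horizontal flow exactly non-divergent in the spherical flux sense
`(1/(R cos phi)) [du/dlambda + d(v cos phi)/dphi] = 0`; the discrete
divergence of a generated slice is pure truncation error and converges to
zero at second order in grid spacing, which the test suite measures over two
grid refinements. Feature geometry (distances, widths) uses metric offsets
taken at each feature's own reference latitude; the residual shape
distortion is O(tan(lat) · domain width) and does not affect the
non-divergence property.

The ingredients are:

* **Alongshore jet** — a Gaussian velocity profile in the cross-shore
  coordinate, centred `jet_offshore_km` from the (straight) coast with
  e-folding half-width `jet_width_km` and peak speed `jet_speed`. Direction
  is southwestward (negative `u`) under the northeast regime; in the
  `cold_front` scenario it reverses through a smooth `tanh` factor of
  time-scale `reversal_width_hours` centred on `reversal_day`, so the
  spatially averaged alongshore velocity changes sign exactly at the
  reversal instant.
* **Filaments** — elongated Gaussian streamfunction ridges anchored at a
  coastal origin and extending offshore (`length_km`), narrow alongshore
  (`width_km`). Peak relative vorticity is approximately `-2 A / w^2` for
  ridge amplitude A and width w, so the amplitude implied by a requested
  flank `peak_speed` V is `A = V w e^{1/2} / sqrt(2)` and the peak
  `|Ro|` is roughly `sqrt(2) e^{1/2} V / (w |f|)` — about 2.4 for
  V = 0.35 m/s and w = 5 km at 23°S, comfortably order one.
* **Eddies** — Rankine vortices: solid-body rotation inside `core_radius_km`
  (`zeta = 2 omega`), azimuthal speed decaying as `r_c / r` outside.

Polarity is specified dynamically, not visually: `cyclonic` means
`zeta / f > 0` at the feature's latitude, which in the southern hemisphere
is clockwise rotation. This keeps configurations portable across
hemispheres.

The source studies do not quantify filament geometry (width, offshore
extent, core speed); the demo configurations use values chosen once to land
in the observed dynamical regime — widths of ~5 km, offshore extents of
35–60 km, flank speeds of 0.2–0.35 m/s, giving peak `|Ro|` between 1.5 and
3 — and they are configuration, not asserted constants.

### What the generator emulates, and what it does not

It reproduces the *structural* conditions the dispersal arguments rest on:
a directional alongshore jet, O(1)-Rossby-number cross-shelf filaments,
eddies, a mid-run current reversal, 6-hourly output, and a no-slip-like
coast via mask-aware interpolation. It does not emulate primitive-equation
dynamics: no tides, no stratification or terrain-following vertical
structure (fields are vertically uniform; `w = 0`), no atmospheric forcing,
no transient submesoscale instabilities, and — importantly — steady
non-divergent features, so particles follow streamlines and cross-shelf
export happens through streamline deflection around filament ridges rather
than through the unsteady, divergent ageostrophic motions of a real
submesoscale field. Passing tests therefore demonstrate that the tracker
and statistics recover designed transport in controlled flows, not that the
synthetic fields reproduce any particular hindcast; the printed
connectivity values of the original high-resolution experiments depend on
an unavailable hindcast and are deliberately out of scope.

## Diagnostics

Relative vorticity `zeta = dv/dx - du/dy` and the strain-rate magnitude

    alpha = sqrt((du/dx - dv/dy)^2 + (dv/dx + du/dy)^2)

are computed with central differences on the cell-centred grid, with metric
factors `dx = R cos(phi) dlambda`, `dy = R dphi`, and normalized by the
planetary vorticity `f = 2 Omega sin(phi)` (Omega = 7.2921e-5 s⁻¹) to give
`Ro = zeta/f` and `alpha/|f|`. Design choices:

* **A-grid, not C-grid.** Synthetic fields are cell-centred; reproducing
  ocean-model staggering would add bookkeeping without testable value.
* **Undefined, not one-sided.** Cells whose 4-point stencil touches land or
  the boundary are undefined (`NA`) rather than one-sided-differenced,
  avoiding spurious coastal extrema in `|Ro| >= 1` feature masks; enlarging
  the land mask can only shrink the defined set.
* **f varies with latitude** by default; an `f_plane` mode exists for
  analytic tests. Normalization refuses latitudes where `f` vanishes.

On the sphere these differences are exact for fields linear in the
metric coordinates, and second-order accurate otherwise; the test suite
checks pure shear (`zeta = -gamma`, `alpha = gamma`), pure strain
(`alpha = 2 gamma`), solid-body rotation (`zeta = 2 omega`, `alpha ~ 0`)
and the error-ratio-of-4 under grid halving.

## Lagrangian tracking

Particles are passive: position only, no behaviour. The integrator is
classical RK4 in (lon, lat, z) with degree-metre conversion at the
instantaneous particle latitude. Velocity sampling is bilinear in lon/lat
(linear in z when the field has several levels, though synthetic fields are
vertically uniform) and linear in time between slices; land corners
contribute zero velocity with weights renormalized over ocean corners.
Choices and their rationale:

* **Internal step `dt = 60 s` by default**, configurable. The features the
  demo fields resolve are several kilometres wide and speeds are below
  0.5 m/s, so the advective displacement per step is metres; the RK4 orbit
  test shows closure errors far below the 1%-per-period target at this
  step, and the demo configurations use `dt = 120 s`, still two orders of
  magnitude inside that target.
* **Vertical random walk** `dz = sqrt(2 kappa_v dt) N(0,1)` applied after
  each advection step, reflected at the surface and the bottom. The source
  experiments specify a random-walk subroutine but not its diffusivity, so
  `kappa_v` is a parameter (default 1e-5 m²/s, a typical upper-ocean
  interior value); the constant-`kappa` (naive) scheme is used because no
  profile is specified, and this is a documented limitation — with
  spatially varying diffusivity a gradient correction term would be
  required to avoid artificial accumulation.
* **Beaching is terminal.** A candidate position whose containing cell is
  land freezes the particle there (interpreted as settlement at the shore);
  leaving the grid freezes it as exited. Status transitions are one-way,
  and the accounting identity `unreleased + active + beached + exited =
  total` holds at every output sample by construction and is asserted in
  every end-to-end test.
* **Releases**: uniform positions within the source region by rejection
  sampling, `particles_per_day` per day staggered daily — the default
  schedule is 1,000/day for 5 days (5,000 per site), the emission plan of
  the experiments this package emulates — at the surface (`z = 0`), since
  the release layer's exact mid-depth is unspecified.
* **No longitude wrapping**; domains are regional.
* **Determinism**: the scenario seed, release seed and walk seed fully
  determine a run; two runs with equal seeds are bit-identical, and with
  `kappa_v = 0` on vertically uniform fields the depth never changes.

## Dispersal statistics

* **Connectivity** is unidirectional, from emitting coastal sources to all
  destinations. The entry (S, D), S ≠ D, is the fraction of S's particles
  whose *sampled* position (6-hourly by default) lies inside D at any
  output time, counted at most once per particle per destination, with
  frozen positions of beached/exited particles still eligible. Sub-cadence
  crossings of small regions can be missed; that is a documented
  consequence of computing "reach" from sampled output. Whether the
  original matrices used any-time entry or final membership is not stated
  anywhere we could verify; the any-time rule is adopted and recorded in
  the outputs. The diagonal would be trivially 1 under the any-time rule,
  so it reports final-time retention instead, and the CSV/JSON outputs say
  so.
* **Density plume**: a 2-D histogram of all post-release particle-samples,
  frozen positions included — the integrated footprint of the dispersal.
* **Final population**: membership counts of final (or terminal) positions
  per region, with overlapping regions counted independently.

Circle membership uses great-circle (haversine) distance on the same
spherical Earth; polygons use even-odd ray casting in lon/lat with boundary
points counted inside. The bundled site set (four source circles AC, CI,
IGB, AH and two offshore destination polygons P1, P2) is illustrative: the
real sites' radii and platform-field vertices are not published, so the
demo geometry only mirrors their arrangement along a zonal coast with
offshore fields to the south-east.

## Problem sizes and numerical tolerances in the shipped tests

The package's own verification uses deliberately modest sizes chosen to
exercise every invariant: demo grids at 0.02° (~2 km) spacing over a
3.2° × 1.25° shelf strip, 20-day runs at 6-h output cadence (81 samples),
100/day × 5-day releases per site for the reduced demonstration (2,000
particles over four sites), 500-particle jet-capture experiments, and
10,000-member random-walk ensembles. Tolerances follow from theory, not
tuning: second-order ratios 4 (±15%), RK4 ratios 16 (asserted within
[8, 32]), orbit closure < 1% per period, ensemble variance within 5% of
`2 kappa t` (≈ 3.5 standard errors at n = 10,000), and binomial ±3 SE for
the half-capture recovery. The full-resolution configuration of the
original experiments (~600 m spacing, 5,000 particles per site) is
expressible with the same functions by changing `spacing_deg` and the
schedule.

## Known limitations

* Steady, non-divergent synthetic features: offshore export is bounded by
  streamline deflection; transient filament growth/decay and divergent
  frontal circulations are not represented.
* Vertically uniform fields with `w = 0`: depth matters only through the
  random walk, and vertical shear cannot disperse particles horizontally.
* Constant vertical diffusivity, no behaviour (swimming, mortality,
  temperature response), no horizontal random walk.
* Beaching has no re-suspension; reflective coasts are not implemented.
* Connectivity is sampled at the output cadence, not by continuous
  crossing detection.
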