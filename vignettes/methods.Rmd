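---
title: "Methods: weighted utilization distributions and MPA containment from Argos telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted utilization distributions and MPA containment from Argos telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpaud)
```

## The problem

Satellite transmitters on marine animals report positions through the
Argos system. Each fix carries a location class (LC) — 3, 2, 1, 0, A, B
or Z, ordered from most to least accurate — with mean positional errors
ranging from a few hundred meters (LC 3) to roughly ten kilometers
(LC B). Fixes are also strongly autocorrelated in time: transmitters
duty-cycle (here, 6 h on / 6 h off), and several fixes can arrive within
a single satellite pass. Both properties violate the assumptions of a
naive kernel home-range estimate. `mpaud` implements a pipeline that
confronts them directly for a small-extent question: *how much of a
resident population's activity space falls inside a marine protected
area (MPA)?* A separate branch smooths a migratory track into one
position per day and reports travel speeds.

## Filtering

Two LC filters are applied depending on the question:

* **home range** — retain {3, 2, 1, A}. Classes 0, B and Z carry errors
  comparable to the working extent itself and would dominate a
  fine-scale density.
* **migration** — retain everything but Z. Over hundreds of kilometers,
  coarse fixes still carry directional information, and the state-space
  model accounts for their error explicitly.

Class Z fixes are parsed and stored (never silently dropped at read
time) so exclusion percentages are auditable; `filter_fixes()` logs
per-class exclusion counts. Fixes with identical timestamps are kept,
ordered by LC accuracy — duplicate satellite passes are information, and
the likelihoods downstream tolerate near-zero time steps.

## Working projection

All density estimation happens in planar meters. The package uses a
spherical azimuthal equidistant projection centered on the centroid of
the filtered fixes (`project_track()`; the center can be pinned in the
run config when several runs must share a frame). The projection is
exactly invertible on the sphere, and across a ~30-km extent its
distance distortion is far below Argos error, which is why we prefer it
over a zoned system: any center is valid, and there is no zone-boundary
edge case. Great-circle distances use a 6371-km Earth radius throughout.

## Movement model and fix weights

Range residency is modeled per animal as an isotropic
Ornstein–Uhlenbeck (OU) process: attraction to a home center `mu`,
stationary variance `sigma2` per axis, autocorrelation timescale `tau`.
The exact Markov likelihood over irregular fix intervals is

    x[i+1] | x[i] ~ N(mu + phi_i (x[i] - mu), sigma2 (1 - phi_i^2)),
    phi_i = exp(-dt_i / tau),

with the first fix from the stationary distribution. `fit_ou()` profiles
`mu` (generalized-least-squares mean) and `sigma2` (closed-form ML) out
of the likelihood, leaving a one-dimensional search over `log(tau)`
(coarse log-grid bracket, golden-section refinement). A one-dimensional
profiled search was chosen over a joint 3-parameter optimizer because
tracks here can be as short as a handful of fixes, where joint
optimizers wander; the profile likelihood is smooth and unimodal in all
our simulations. Tracks with fewer than five fixes fall back to an IID
model (`tau = 0`).

Each fix then receives a two-part weight:

* **autocorrelation weight** — from the fitted OU correlation matrix
  `C[i,j] = exp(-|t_i - t_j|/tau)`, the minimum-variance weights
  `w ∝ C⁻¹·1` (the quadratic-program optimum for estimating a mean under
  correlation), negatives clipped to zero, renormalized to sum to one
  per animal. Clustered fixes share weight; isolated fixes keep it. The
  literature describing this weighting idea gives no closed formulas;
  the minimum-variance construction is our concrete choice because it is
  closed-form, testable against a 3×3 oracle, and reduces to uniform
  weights exactly in the IID limit.
* **Argos-error weight** — inverse of the LC's mean metric error,
  rescaled so the most accurate class present scores 1. The
  proportionality constant is arbitrary; max-scaling keeps combined
  weights interpretable.

The two are multiplied and the product renormalized per animal, so every
animal contributes total weight one to the population pool regardless of
how many fixes it produced. The two normalizations (before and after the
product) are our own assumptions — the method statement fixes only
"proportional to inverse error" and "multiplied" — and they are what
makes the two desired invariants (per-animal autocorrelation weights sum
to one; equal animal weight in the pool) hold simultaneously.

The per-class error magnitudes themselves are configurable
(`lc,error_m` CSV). The shipped table (0.5 km for LC 3 rising to
10.3 km for LC B, 30 km nominal for Z) is a literature-scale synthetic
default, not a reproduction of any published table.

## Utilization distributions

`weighted_kde()` evaluates the weighted isotropic-Gaussian mixture at
the centers of a fixed grid — by default 33.7 × 19.3 km with 100-m cells
— then renormalizes to integrate to exactly one. The fixed,
conservatively large extent makes every UD of a run comparable; 100-m
cells sit well below the smallest bandwidth the sweep can choose
(250 m), and halving the cell size moves a single-kernel 50% area by
under 1% (tested). Kernels are separable, so the grid evaluation is two
small matrix products, checked in the tests against a brute-force
double-loop mixture at 1e-10 relative tolerance.

Isopleths (`ud_contour()`) are highest-density regions: cells ranked by
density, accumulated until the requested mass `p` is reached. This makes
mass accounting exact (the enclosed mass exceeds `p` by at most one
cell) at the cost of a raster-polygon outline. Components are counted
under 8-connectivity; outlines are traced as rectilinear rings (outer
rings counterclockwise, holes clockwise).

### Bandwidth selection

Bandwidths descend in fixed 250-m decrements from a start value to a
floor (default 250 m); at each step the 50% isopleth is tested for
contiguity, and the chosen bandwidth is the last one before the contour
first splits. If nothing splits by the floor, the fallback selects the
smallest bandwidth yielding exactly two components, else the floor is
returned flagged. The start bandwidth defaults to the weighted Silverman
reference value rounded up to the next 250-m multiple — the sweep's
bounds are otherwise unspecified in the method's source, and the
Silverman value is a standard oversmoothed anchor that is always above
the split point in our fixtures. Contiguity ignores "slivers" —
components holding under 1% of contour mass — because raster contouring
can emit single-cell fragments that no analyst would read as a second
polygon off a map.

## Containment

`percent_contained()` reports `100 · area(contour ∩ MPA) /
area(contour)`, over the union of all contour components. Percentages
are area-based because the question is polygon containment; a
mass-based variant can be derived from the persisted grid if needed.
When the boundary is a single convex polygon the intersection is exact
(Sutherland–Hodgman clipping of each rectilinear ring, hole rings
subtracting by orientation). Non-convex or multi-part boundaries fall
back to subsampled cell integration (8×8 points per straddling cell;
full/empty cells decided by their corners), which resolves well below
the 0.1-percentage-point tolerance used in the tests. No landmass
correction is applied to the density — the containment statistic is
computed on the raw contour.

Boundaries are read from GeoJSON (Polygon/MultiPolygon, any nesting).
Overlapping features are treated with union semantics, never double
counted.

## Migration: daily correlated random walk

For the migratory branch, `fit_crw()` estimates one position per day
with a linear-Gaussian state-space model, per axis:

    x_t = x_{t-1} + v_t          (daily position)
    v_t = gamma v_{t-1} + eta_t  (velocity persistence, eta ~ N(0, sigma_p^2))
    y_i = (1-a) x_{t-1} + a x_t + eps_i   (fix at fractional day, a in (0,1])

Observation error is the fix's LC mean error times a single fitted
inflation factor `k` (nominal Argos errors are known to be optimistic;
one extra parameter keeps an 8-fix track identifiable). The state is
augmented with the previous day's position so interpolated observations
stay linear; `(gamma, sigma_p, k)` are fitted by maximum likelihood
through the Kalman filter (Nelder–Mead on transformed parameters), and
daily positions come from the Rauch–Tung–Striebel smoother, using an
SVD pseudo-inverse for the smoother gain because the augmentation makes
the prediction covariance rank-deficient by construction.

The daily step matches the sparse fix schedule of migratory Argos data
(mean interval near 1.3 days in the motivating application;
`mean_fix_interval()` reports it). Speeds are great-circle distances
between consecutive smoothed daily positions; `speed_stats()` returns
their sample mean and SD (n−1). Because a "mean travel speed" can also
be computed from raw fixes (displacement over elapsed time between
consecutive fixes), both statistics are reported — the raw version is
strongly inflated by positional error over short gaps, which is visible
in the synthetic scenario and is precisely why the smoothed version is
the headline number.

## Residency classification

The pipeline must decide which animals enter the home-range branch. The
default rule calls an animal a migrant iff its net displacement from
the first fix exceeds 50 km *and* the displacement is monotone
non-decreasing over the final third of its fixes, allowing up to 25 km
of apparent backtracking per step. The tolerance is set by measurement
error, not behavior: a difference of two consecutive displacements
combines two positional errors, roughly `sqrt(2) × 9 km` for classes
0/B, so 25 km is about two such standard deviations. Classification
runs on Z-filtered fixes. An explicit id list in the config overrides
the rule, which is the recommended path when the analyst has inspected
the tracks.

## Synthetic scenario: what it emulates, and what it does not

`make_island_scenario()` generates the full desk-scale study: nine
residents and one migrant, all seeded from a single generator.

* Residents move as exact OU processes (transition sampling, no Euler
  error — verified by standardized-residual tests) with home centers a
  couple of kilometers offshore of the island center (scatter 1.2 km),
  `sigma = 1.5 km`, `tau = 12 h`. Durations are uniform on 10–170 days
  and per-animal raw fix totals uniform on 8–156, emulating the spread
  of real deployments; fix times fall only inside the on-halves of a
  6-h duty cycle.
* The LC mix is class-B dominated (61% B, 3% Z, 26% across {3,2,1,A}),
  so the home-range filter excludes roughly three quarters of raw fixes
  — the regime the pipeline is designed for.
* Positional error is isotropic Normal per LC with axis SD
  `mean_error × sqrt(2/pi)`, so the mean radial error matches the error
  table. Real Argos errors are heavier-tailed and anisotropic; the
  Normal keeps every downstream oracle closed-form. Consequently,
  passing tests demonstrate correctness of the estimators under the
  stated error model, not robustness to Argos pathologies such as
  mirror-image fixes.
* The MPA is a 28 × 22 km rectangle (616 km²) centered on the island;
  resident home centers sit well inside it, so the population 50% UD is
  fully contained by construction — that is the geometric invariant the
  end-to-end test asserts.
* The migrant departs due south at 18 km/d with 10°/day heading jitter
  and fixes at exponential intervals (mean 1.3 d) over 10 days.

## Numerical choices and degenerate inputs

* OU: `tau` is bracketed on a log grid from 1/100 of the finest fix
  interval to 100× the track span; duplicate fix times are floored at
  1e-6 s in the likelihood; zero-variance tracks are flagged
  `degenerate` with `sigma2` at its 1e-12 floor.
* Weights: a singular correlation matrix (duplicate times) gets 1e-8
  diagonal jitter, logged via a message.
* KDE: points outside the extent are permitted with a warning carrying
  a mass-leak estimate; an all-outside point set is an error.
* CRW: innovation variances are floored at 1e-12 so noise-free tracks
  remain finite during optimization; non-finite likelihood evaluations
  return a large penalty.
* Contours: ties at the inclusion threshold follow the stable
  cell-ranking order; `p` outside (0,1) is an error.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at desk scale: tracks of tens to a few hundred fixes, a 337 × 193
grid, sweeps of up to 20 bandwidth candidates, 100-replicate
parameter-recovery studies for the OU timescale (n = 400 fixes) and CRW
persistence (60-day tracks). The full suite completes in about a minute
on one core.

## Known limitations

* The KDE treats fixes as exact points; Argos error enters only through
  the weights, not as kernel convolution.
* The OU model is isotropic; elongated coastlines would benefit from an
  anisotropic variant.
* Shapefile boundaries are not read; convert to GeoJSON first.
* Exact polygon intersection is implemented for convex boundaries;
  non-convex boundaries use high-resolution integration rather than a
  general clipping algorithm.
* The migrant/resident rule is a displacement heuristic intended for
  screening; ambiguous animals should be assigned explicitly in the
  config.
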