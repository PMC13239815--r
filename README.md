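# mpaud

Utilization distributions and protected-area containment from Argos
satellite telemetry.

`mpaud` is for movement ecologists asking a concrete conservation
question: **how much of a tracked population's activity space falls
inside a marine protected area?** It was built around the archetypal
small-MPA study — a handful of animals (e.g., juvenile sea turtles at an
insular foraging ground) tracked with Argos transmitters on a 6-h duty
cycle, most fixes in the coarse location classes, one animal leaving on
a migration — and turns that analysis into a tested, reusable pipeline
that runs end-to-end on synthetic data with known ground truth.

## What it computes

**Residency branch.** Argos fixes are filtered by location class (LC):
home-range analyses retain {3, 2, 1, A}; migration analyses drop only Z.
Fixes are projected to planar meters (azimuthal equidistant, centroid
center). Each animal's track is fitted with an isotropic
Ornstein–Uhlenbeck model by maximum likelihood over irregular intervals,

    x(t+dt) | x(t) ~ N(mu + e^(-dt/tau) (x(t) - mu), sigma^2 (1 - e^(-2 dt/tau))),

and every fix receives a two-part weight: a minimum-variance
autocorrelation weight `w ∝ C⁻¹·1` from the fitted correlation matrix
`C_ij = exp(-|t_i - t_j|/tau)` (summing to one per animal), times an
Argos-error weight proportional to the inverse mean metric error of its
LC. The population utilization distribution (UD) is a weighted Gaussian
kernel density estimate on a fixed 33.7 × 19.3 km extent,

    f(u) = Σ_i (w_i / W) (2π h²)⁻¹ exp(-‖u - x_i‖² / 2h²),

with the bandwidth `h` selected by an ad hoc contiguity sweep: descend
in 250-m decrements and keep the last bandwidth before the 50% isopleth
splits into disjoint polygons (smallest two-polygon bandwidth as the
fallback). The 50% and 90% highest-density isopleths are overlaid on the
MPA boundary polygon and containment is reported as
`100 · area(isopleth ∩ MPA) / area(isopleth)`.

**Migration branch.** A daily-step correlated random walk state-space
model (`x_t = x_{t-1} + v_t`, `v_t = γ v_{t-1} + η_t`, observations at
fractional days by linear interpolation with LC-scaled error) is fitted
by maximum likelihood through a Kalman filter; smoothed daily positions
give travel speed mean ± SD.

See `vignettes/methods.Rmd` for the full model account, parameter
defaults, numerical choices and limitations.

## Worked example

Simulate the bundled island scenario (nine Ornstein–Uhlenbeck residents
inside a 616-km² rectangular MPA plus one southward migrant at 18 km/d,
class-B-dominated LC mix, 6-h duty cycle), then run both branches:

```r
library(mpaud)

cfg    <- synthetic_config(seed = 1)
scen   <- make_island_scenario(cfg, "mpaud-demo/data")
config <- run_config(fixes = scen$fixes, boundary = scen$boundary,
                     outdir = "mpaud-demo/run", seed = 1)

report <- run_residency(config)
print(report)
#> <mpaud_report> 9 residents, 169/715 fixes kept (76% excluded), h = 750 m (last_contiguous)
#>   50% UD: 19.81 km^2, 100.0% inside MPA
#>   90% UD: 73.58 km^2, 100.0% inside MPA

migration <- run_migration(config, "T10")
print(migration)
#> <mpaud_migration_report> T10: 8 fixes (mean interval 1.14 d), speed 18.17 +/- 0.45 km/d (smoothed), 35.74 +/- 34.39 km/d (raw)
```

Reading the output: of 715 raw fixes from the nine residents, the
home-range LC filter keeps 169 (the class-B-dominated mix is why ~3/4
are excluded). The contiguity sweep settles on a 750-m bandwidth; at
that bandwidth the core (50%) activity area is 19.8 km² and lies
entirely inside the MPA, as does the broader 90% area. The migrant's
smoothed daily path recovers its constructed 18 km/d speed almost
exactly, while the raw-fix speed (35.7 km/d) is inflated by Argos error
over short gaps — the reason the state-space estimate is the one to
report. Every intermediate (filtered fixes, OU fits, weights, UD grid,
contour GeoJSON, containment table, report JSON) is persisted under
`outdir`.

A thin CLI wrapper is installed at `inst/scripts/mpaud`
(`mpaud simulate|run|migrate|report --config run.json`).

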