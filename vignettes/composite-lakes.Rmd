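---
title: "Composite lake hypsography: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite lake hypsography: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakecomposer)
```

## The problem

Lakes respond to climate and geochemical forcing collectively, but most
quantitative descriptions stop at the individual lake. The quantity that
controls how a population of lakes partitions water volume and sediment
surface across depth — and therefore how area-based processes (benthic
respiration, sediment nutrient flux, gas exchange) trade off against
volume-based ones (pelagic respiration, heat storage) — is hypsography, the
depth–area relationship. `lakecomposer` aggregates per-lake hypsography
into a *composite lake*: a conceptual basin whose area at every depth is
the sum of the member areas at that depth. Any collection works: a lake
district, a 1×1-degree grid cell, a climate zone, a continent.

## The per-lake model

Each basin is reduced to three numbers — surface area SA, maximum depth
$Z_{max}$ and mean depth $Z_{mean}$ — through the Imboden form

$$A(z) = \mathrm{SA}\,(1 - z/Z_{max})^q, \qquad q = Z_{max}/Z_{mean} - 1 .$$

$q$ captures the 2-D basin shape: $q = 2$ is a perfect cone, $q < 2$ more
convex (bowl-like), $q > 2$ more concave (shelf plus deep pit), $q = 0$ a
cylinder. Volume below a depth has the closed form
$V(z) = \mathrm{SA}\,(Z_{max}-z)(1-z/Z_{max})^q/(q+1)$, so the total volume
is $\mathrm{SA}\,Z_{max}/(q+1) = \mathrm{SA}\,Z_{mean}$ — an identity the
test suite checks both algebraically and against trapezoidal quadrature of
$A(z)$.

Assumptions worth keeping in mind: the model is monotone (area never
increases with depth), smooth, and single-basined. Multi-basin lakes,
shelves with abrupt breaks, and very irregular shorelines are represented
only in an averaged sense. `validate_curve()` quantifies the residual
against a measured curve as $(measured - modelled)/measured$ per depth.

## Aggregation

The composite is built on a uniform depth grid from the surface to the
deepest member (`dz = 0.5` m by default, the conventional discretization
interval for this kind of analysis; configurable). Member curves are
evaluated *analytically* on the composite grid rather than resampled from
per-lake grids — the closed forms make interpolation unnecessary, so
aggregation introduces no numerical error beyond floating point, and
surface areas and volumes are exactly additive over any partition of the
collection (a property the tests assert). Layer differentials
$dA_z, dV_z$ telescope, so layer sums reproduce SA and V exactly whatever
`dz`.

The composite mean depth $Z_{meanC} = V_C/\mathrm{SA}_C$ is the
area-weighted mean of member mean depths, and generally differs from their
arithmetic mean — the reason composite metrics cannot be obtained by
averaging lake attributes. The dynamic ratio
$DR_C = \sqrt{\mathrm{SA}_C\,[\mathrm{km^2}]}/Z_{meanC}$ indexes
shallow-area dominance.

## Thermal structure and the mixed-layer partition

Functional metrics need to know, for every depth, how much of the year it
spends out of contact with the atmosphere. From daily depth-resolved
temperature and ice series:

* **Thermocline**: the shallowest depth where the water density gradient
  exceeds 0.1 kg m⁻⁴. Gradients are forward differences scaled per metre,
  making the threshold independent of the profile grid spacing. A column
  whose maximum gradient stays at or below the threshold counts as fully
  mixed and the thermocline is assigned at $Z_{max}$.
* **Density**: the Martin & McCutcheon temperature-only freshwater
  polynomial (maximum near 3.9863 °C). The function is an argument of the
  thermocline routines, so another equation of state can be substituted.
* **Ice**: any day with ice thickness above zero isolates *all* depths.
  Ice caps the air–water interface entirely, so even depths above the
  (undefined) thermocline are out of atmospheric contact. This is a
  modelling choice; partial ice cover is not resolved.
* **fIso_atmZ**: per depth, the fraction of days isolated (below the
  thermocline or under ice), in [0, 1]. The year is 365 days; leap days
  are dropped by the reader.

Isolated layer sums $dA_{IsoC,z} = \sum_i fIso_{z,i}\,dA_{z,i}$ (and the
volume analogue) yield the epilimnetic fractions
$fA_{EpiC}, fV_{EpiC}$ and the mean epilimnion thickness
$V_{EpiC}/A_{EpiC}$. For depth-constant isolation profiles these fractions
are exactly the dA- and dV-weighted means of the per-lake values, which the
property tests exploit. Temperatures aggregate volume-weighted per depth;
layers with zero total volume are flagged undefined and excluded from the
vertical mean $wT_{meanC}$.

Process-rate scaling is linear: `rate_v * epi_ratio` per m² of epilimnetic
sediment, times $fA_{EpiC}$ per m² of lake surface. The "respiration
ratio" of a volumetric to an areal rate is implemented exactly as the
first-order comparison it is, and its result carries a
`unit_consistent = FALSE` flag because the operands' units differ.

## Gridding and clustering

Lakes map to 1×1-degree cells by the floor of their centroid coordinates
(south/west edges inclusive; lat 90 and lon 180 fold into the last valid
cell; antimeridian cells are not merged). Composite features
($Z_{meanC}$, $DR_C$, $fA_{EpiC}$ — descriptive of shape and mutually
weakly correlated) are standardized to zero mean and unit SD and clustered
by Ward's ward.D2 criterion (`stats::hclust`); the cluster count is chosen
by the maximum mean silhouette width (`cluster::silhouette`) over k = 2–10,
ties to the smallest k. The tests cross-check the ward.D2 merge heights
against an independent Lance–Williams implementation on small instances.
A practical note on the silhouette floor: a single Gaussian blob — no real
structure — still yields mean silhouettes around 0.3–0.35, inside the
conventional "weak, possibly artificial" band; genuinely separated groups
sit around 0.7+. The `weak` flag therefore uses a conservative default
threshold of 0.25, and users should treat anything below ~0.5 with
suspicion.

## Uncertainty propagation

Morphometric prediction errors are close to normal in cube-root space, so
perturbations are applied there:
$Z_{max}' = (Z_{max}^{1/3} + \varepsilon_1)^3$,
$q' = \max(0, (q^{1/3} + \varepsilon_2)^3)$, with $Z_{mean}$ recomputed
from the identity. Draws pushing $Z_{max}$ non-positive are rejected and
redrawn (rejection preserves the distribution shape near zero, unlike
truncation); $q$ is clamped at zero, where the model degenerates gracefully
to a cylinder. Error draws for the two parameters are independent by
default with a correlation knob. Error SDs are user inputs; the defaults
(0.1 on each cube root) produce roughly 30% relative error in a single
lake's area at depth, a realistic magnitude for depths predicted from
terrain, and are used for demonstration rather than as estimates of any
particular prediction model.

The stream for iteration $t$ is seeded from (base seed, $t$) and draws are
made in lake-id order, so results are reproducible and independent of row
order. `propagate()` reports 2.5/50/97.5% quantiles of the composite
metrics and the per-depth relative error SD/mean of $A_{C,z}$;
`error_vs_aggregation()` traces that relative error across nested
collection sizes. Two behaviours emerge on any Pareto-style population:
the near-surface relative error declines as lakes are added (aggregated
area grows faster than its error), and at fixed n the error near the
deepest depth exceeds the near-surface error, because the Pareto law sends
few lakes deep.

## The synthetic population generator

The generator emulates the statistical structure the framework assumes so
that every stage is testable without downloads:

* **Areas**: truncated Pareto via inverse CDF; exceedance-count slope
  $-\alpha$ on log–log axes. Default $\alpha = 0.98$, the slope typical of
  formerly glaciated regions (0.92 for non-glaciated); bounds 1 ha–1000 km²
  keep populations in the size range where the power law is observed.
* **Depths**: $Z_{max} = c\,\mathrm{SA}^{b}\,e^{\sigma\varepsilon}$ with
  defaults $c = 0.2$, $b = 0.25$, $\sigma = 0.4$ — an increasing depth–area
  scaling with realistic scatter that puts a 1-ha lake near 2 m and a
  1000-km² lake near 60 m.
* **Shape**: $q$ lognormal with median 2 (cone-like on average) and log-SD
  0.5, spanning convex to concave basins.
* **Thermal series**: deliberately schematic — a sinusoidal surface
  temperature (mean 12 °C, amplitude 10 °C), a two-layer profile (warm
  epilimnion over a 4 °C hypolimnion at a thermocline of 0.3 × $Z_{max}$,
  clipped to $Z_{max}$) for a stratified season centred on the warm peak,
  an isothermal column otherwise, and an ice season of constant thickness
  centred on the cold trough. Its only contract is producing valid,
  exactly countable inputs for the stratification stage; it does not
  emulate seiches, partial mixing, inverse stratification under ice, or
  inter-annual variability. Passing tests therefore demonstrate the
  *aggregation machinery*, not fidelity to any real lake's thermal regime.

The exceedance-curve slope estimator regresses
$\log_{10}(\#\{A \ge a\})$ on $\log_{10} a$ over the central 5–95% of the
sample — the limnological convention, with the quantile window avoiding
truncation bias at both ends — and bootstraps its CI. Recovery holds to
±0.05 at $n = 10^5$ for the slope and ±0.02 at $n = 10^4$ for the depth
exponent (both asserted in the tests at exactly those sizes).

One qualitative expectation deserves a caveat. Making the size law steeper
(more small, shallow lakes) reliably drags the composite mean depth down
and concentrates volume near the surface — the shallow-dominance mechanism
— but it does *not* necessarily raise $DR_C$: with depth scaling
$b = 0.25$, $\sqrt{\mathrm{SA}_C}$ shrinks faster than $Z_{meanC}$ as the
tail loses big lakes, so the ratio can fall. Contrasts in DR between real
regions reflect differences in depth–area scaling as much as in the Pareto
slope. The property tests assert the mechanism (mean depth and volume
concentration), not a DR direction.

## Numerical choices and degenerate inputs

* Depth grids run from 0 to the smallest multiple of `dz` at or beyond
  $Z_{max}$; layers are half-open $[z, z+dz)$ with the final layer
  truncated at the bottom. How a partial last layer is closed is a
  convention; telescoping makes the totals exact under any choice.
* Depths at or beyond a lake's bottom return zero area/volume rather than
  erroring, so composite grids can exceed any member's depth; cells below
  every lake are retained with zero weights.
* $q = 0$ (cylinder) needs care because R evaluates $0^0 = 1$; bottom
  cells are masked explicitly.
* Consistency between supplied $q$ and depths is *checked* (tolerance
  1e−9), never silently recomputed.
* Fully isolated composites have an undefined epilimnion thickness,
  reported as `NA`, which propagates through the rate conversions.
* Units are SI (m, m², m³) internally; `composite_metrics()` converts to
  km²/km³ only at the reporting layer.

## Problem sizes

The shipped tests and the acceptance script use populations of 10³–10⁵
lakes, Monte Carlo runs of 60–100 iterations over collections up to 10³,
and silhouette scans over a few hundred points — sizes at which every
stochastic recovery above is comfortably inside its stated tolerance while
the whole suite runs in well under a minute on a laptop core. All
generators and Monte Carlo streams are seed-deterministic.

## Limitations

* The hypsographic family is single-parameter in shape; no sigmoid or
  piecewise basins, and no bathymetric raster ingestion.
* The thermal generator is schematic (see above); real mixed-layer
  climatologies should come from a hydrodynamic model or observations via
  `read_thermal_series()`.
* Isolation under partial ice cover is all-or-nothing.
* Cluster labels are arbitrary up to permutation; comparisons should use
  partition-equivalence, as the tests do.
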