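---
title: "Locating predation pressure on drifting herring larvae: models and methods"
author: "predquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating predation pressure on drifting herring larvae: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predquant)
```

## The problem

Norwegian spring-spawning (NSS) herring hatch on coastal spawning grounds
between about 63 and 68 degrees N and drift north in the Norwegian Coastal
Current (NCC) toward their nursery areas. Atlantic mackerel now feed along
the same corridor in early summer, and predation on the drifting larvae is
a candidate explanation for years of weak recruitment despite a large
spawning stock. Measuring that predation is hard: larvae are soft-bodied
and digest quickly, so visual stomach inspection under-counts them, while
spatial overlap alone says nothing about realized feeding.

predquant implements the computational chain that links three independent
lines of evidence:

1. **Where the larvae should be** — a Lagrangian individual-based model
   (IBM) of larval drift forced by gridded daily-mean currents.
2. **What the predator actually ate** — a droplet digital PCR (ddPCR)
   chain that converts droplet counts from stomach-content assays into
   mitochondrial 16S (mt16S) gene copies per gram of stomach content.
3. **How the two line up in space** — survey statistics joining larval
   densities, swept-area predator biomass and the molecular signal.

Because the field data behind such studies are rarely deposited, a
synthetic-data module generates every input with the statistical structure
the analysis assumes. All results in this vignette and in the test suite
are computed from those generators; nothing is fetched from outside.

## The drift model

Particles representing newly hatched larvae are released at four spawning
grounds (Møre, Haltenbanken, Sklinna, Røst) with release fractions 0.5,
0.2, 0.1 and 0.2, allocated by largest-remainder rounding so per-ground
counts always sum to the configured total (198,580 by default). Hatch
times follow a Gaussian intensity truncated to the 15 March – 20 April
window. The window is the only published constraint, so the package sets
the mean to the window midpoint and the standard deviation to one sixth
of the window length (about 6.2 days): the window then spans roughly
±3 sd, which keeps truncation mild while using the full window.

Each active particle is advected by a 4th-order Runge–Kutta step (default
`dt` = 3600 s) over velocities interpolated trilinearly in space and
linearly in time between daily means, with the cos(lat) metric converting
metres to degrees. Against closed-form oracles this integrator reproduces
uniform-flow displacement to machine precision and closes a solid-body
rotation orbit to well under 1% of the radius per period.

Behaviour follows three rules:

* **Growth.** Length is 9 mm at hatch and increases at exactly
  0.4 mm day⁻¹; the invariant `length = 9 + 0.4 * age` is enforced by
  recomputing length from age, so it holds to machine precision at every
  step.
* **Diel vertical migration (DVM).** Larvae move toward 5 m at night and
  40 m by day, swimming vertically at 0.1 body lengths s⁻¹. The published
  swim speed is attached to the migration clause, so the package applies
  it to vertical migration only; there is no horizontal swimming.
* **Night definition.** Night is solar elevation below 0 degrees,
  computed from standard solar geometry (Fourier-series declination and
  equation of time, accurate to well within half a degree). At the study
  latitudes in June the sun may never set; the model is silent on this
  case in the sources it draws on, so the package defines night under the
  midnight sun as ±3 h around local solar midnight (the daily elevation
  minimum). This keeps the migration rhythm continuous across the Arctic
  circle instead of pinning particles at the day depth all summer.

Particles whose updated position falls on a land cell revert to the last
wet position and are irreversibly beached; particles leaving the domain
are frozen as exited. The conservation invariant — hatched = active +
beached + exited — holds at every snapshot by bookkeeping and is tested.

The vertical coordinate is plain z-levels (depth positive down), not
terrain-following sigma layers: synthetic fields carry no bathymetry
worth following, and the seabed is taken as the deepest model level.
Flow fields are exchanged as documented delimited text (a long-format
velocity table plus a mask table) rather than a binary gridded format,
keeping every artefact in the repository human-readable.

## The ddPCR quantification chain

Template partitions into roughly 20,000 droplets of 0.85 nL (the QX200
convention; the droplet volume is configurable because instruments
differ). With positive fraction *p*, the reaction concentration is

> c = −ln(1 − p) / v_droplet  [copies µl⁻¹]

The chain to copies per gram of stomach content multiplies by the
template-to-reaction ratio (22 µl / 5.5 µl = 4), the template dilution
(1, 10, 40 or 100), and the elution volume (150 µl default, the midpoint
of the 100–200 µl used in practice), then divides by the tissue weight of
the subsample. Wet weights include the 1:3 homogenization buffer, so
tissue is `wet_weight / (1 + pbs_ratio)` — volumes treated as
weight-equivalent at buffer density ≈ 1 g mL⁻¹. Stomachs recorded as
empty use the 0.01 g convention so residual DNA still yields a defined
value. The five replicate subsamples per stomach are averaged
arithmetically on the copies-per-gram scale.

Quality control mirrors laboratory practice: wells with fewer than
13,000 or more than 21,000 accepted droplets are flagged for repetition
(boundaries inclusive); wells with fewer than 30 negative droplets are
flagged saturated and reported as a lower bound evaluated at that
threshold; wells with zero positives are flagged below detection and
enter the replicate mean as 0 (configurable to exclusion — the field
convention is not settled). Plate controls (no-template, positive,
negative, blanks) gate whole runs: more than 2 positive droplets in any
control marks contamination, and a dead positive control invalidates the
run.

The in-silico PCR checker locates the herring-specific primer pair
(forward `CGCCCACCAATCACGAA`, reverse `ACGTTTGTGCCAGTATCACGTT`) on both
strands of a reference, IUPAC-aware, and reports amplicons inclusive of
both primer footprints. Against the packaged reference the pair yields a
single 69 bp product — the assay's diagnostic fragment of the mt16S gene.
The packaged reference is a synthetic stand-in (flanks are generated
sequence around the real primer sites and a 30 nt insert), so the check
exercises coordinates, strand logic and degeneracy handling, not sequence
identity to the GenBank record.

## Survey statistics

* **Larval density** is `10 * count / filtered_volume` (individuals per
  10 m³), and **predator biomass** is the swept-area estimate
  `catch / (tow_distance * effective_width)` in kg NM⁻², with the
  effective trawl width a per-gear configuration value.
* **Station effects** on the molecular signal are tested by one-way
  ANOVA with Tukey HSD on `log10(copies + 1)` — raw copies span orders
  of magnitude and violate normality; the +1 offset keeps
  below-detection stomachs defined and is negligible at signal level.
  The log base does not affect F or p. The response is the per-stomach
  replicate mean, matching the df bookkeeping (k − 1, n − k) of
  per-stomach analyses. Stations with fewer than two stomachs are
  excluded with a warning. Residual normality and homoscedasticity
  summaries ride along.
* **Predator covariates** (fish weight, stomach-content weight) are
  tested by Pearson correlation with df = n − 2.
* **Visual vs molecular** comparisons attach hat-matrix leverages
  (`h = 1/n + (x − x̄)²/Σ(x − x̄)²`; Σh = 2 for a simple regression);
  points above twice the average leverage are flagged. Outliers and
  high-leverage points are always reported and never dropped — a single
  stomach stuffed with larvae can dominate a station, and hiding it
  would misstate the evidence.
* **Overlap** is summarized per station (larval density, predator
  biomass, mean copies), with Schoener's D on normalized grids available
  as a clearly labelled extension.

## The synthetic generators

`genFlowField()` builds a northward coastal jet with a cross-shore
Gaussian profile (core 0.35 m s⁻¹ by default, within the 0.15–0.40 m s⁻¹
band typical of the NCC and capped at its 1 m s⁻¹ maximum) west of an
idealized meridional coastline, with optional rotational eddies derived
from a streamfunction by central differences so the discrete horizontal
divergence vanishes in the interior.

`genStomachSurvey()` draws per-station log10 copies Normal around a base
of 7.3 (≈ 2 × 10⁷ copies g⁻¹, mid-range of reported predation signals)
with a between-station sd of 0.6 decades, then fish-level sd 0.5 and
replicate-level sd 0.2. The variance components are conventions — the
sources report only that variability was "high" — and are exposed in
`scenarioConfig()`. Droplet counts are generated by inverting the exact
normalization chain and auto-selecting the dilution from the printed
1/10/40/100 series that keeps wells out of saturation, which reproduces
the laboratory's dilution ladder behaviour. Empty stomachs (7% default)
keep a weak residual signal (10⁻³ of their station level), emulating
visually empty stomachs that still test positive. Visual counts are
Poisson with a detection mean saturating in true copies, capturing the
imperfect visual–molecular correspondence without asserting its
parameters.

What the generators do **not** emulate: mesoscale realism of a hindcast
ocean model, temperature-dependent growth or mortality, otolith digestion
kinetics, or secondary predation. Tests passing on synthetic data
therefore demonstrate the correctness of the estimators and bookkeeping
under the stated statistical assumptions, not oceanographic or trophic
realism.

## Calibration and verification choices

* The truth tables record *realized* per-replicate copies; station truth
  is the geometric mean over fish of per-fish mean replicate copies.
  Recovery checks therefore measure measurement error (droplet partition
  noise), which sits well under 1%; at 8 fish per station with 0.5
  decades of fish-level noise, comparing instead against the configured
  station parameter would be dominated by sampling noise, not estimator
  quality. The recovery scenario also sets the empty-stomach probability
  to zero so detection-limit censoring does not contaminate the
  measurement-error estimate; rank-recovery checks run at full defaults,
  empties included.
* The brute-force droplet oracle drops a Poisson-distributed number of
  molecules uniformly into droplets; this is the exact generative match
  to per-droplet Poisson occupancy, so the two simulation modes agree in
  distribution and either can stand as the independent check of the
  estimator.
* ANOVA size and power are verified by direct Monte-Carlo: type-I error
  at the nominal 5% under the null, and power above 0.9 under a
  one-decade spread of station means at sd 0.5 with 10 stations × 8
  fish.
* Problem sizes used by the checks are chosen to keep full verification
  runs comfortably interactive: the DVM/growth invariants run on a
  5,000-particle, 60-day jet simulation in the test suite, and the
  acceptance script reports drift invariants from a 2,000-particle,
  30-day run, estimator recovery from 200 wells per concentration, and
  ANOVA calibration from 1,000 null simulations.

## Known limitations

* Daily-mean forcing with linear time interpolation smooths inertial and
  tidal motion; the integrator is exact for the fields supplied but the
  physics is as coarse as its forcing.
* Beaching is irreversible and grid-resolution dependent (nearest-cell
  land test).
* Saturated wells report lower bounds; surveys with most wells saturated
  need the dilution ladder, not this estimator.
* The ANOVA treats stomachs as independent within stations; shared-haul
  dependence would need a mixed model, deliberately out of scope.
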