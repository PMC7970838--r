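# predquant

Quantifying predation pressure on drifting fish larvae by combining a
larval drift model, molecular diet quantification and survey statistics.

## The problem

Norwegian spring-spawning herring larvae hatch on coastal spawning
grounds and drift north in the Norwegian Coastal Current; Atlantic
mackerel now feed along the same corridor. Because larvae digest beyond
visual recognition within hours, stomach inspection under-counts
predation, and spatial overlap alone does not demonstrate feeding.
predquant implements the full computational chain for locating predation
pressure with a quantitative molecular signal:

* **drift model** — a Lagrangian individual-based model: particles
  released at weighted spawning grounds with a truncated-Gaussian hatch
  schedule, advected by RK4 over gridded daily-mean currents, with diel
  vertical migration between 5 m (night) and 40 m (day) at
  0.1 body lengths s⁻¹ and linear growth (9 mm at hatch,
  0.4 mm day⁻¹);
* **ddPCR quantification** — droplet counts to mitochondrial 16S gene
  copies per gram of stomach content via Poisson partition statistics,
  `c = −ln(1 − p)/v_droplet`, the dilution/volume chain, the
  1:3-buffer tissue correction and the 0.01 g empty-stomach convention,
  with droplet-count QC (13,000–21,000 band), saturation and
  below-detection flags, plate-control checks, and an in-silico PCR
  verification of the herring-specific primer pair (one 69 bp mt16S
  amplicon);
* **survey statistics** — larval densities (per 10 m³), swept-area
  predator biomass (kg NM⁻²), one-way station ANOVA with Tukey HSD on
  `log10(copies + 1)`, Pearson correlations against predator covariates,
  leverage diagnostics for the visual-vs-molecular comparison, and
  per-station overlap summaries (Schoener's D as an extension);
* **synthetic data** — generators for coastal-jet flow fields, droplet
  partition data at known concentration, and a two-year multi-station
  stomach survey with lognormal station/fish/replicate effects, so the
  whole pipeline runs and is testable offline.

## Worked example

Quantify one stomach from raw droplet counts:

```r
library(predquant)
w  <- data.frame(well_id = "A1", stomach_id = "s1", replicate = 1,
                 n_total = 18000, n_positive = 2600, dilution = 10)
s  <- data.frame(stomach_id = "s1", replicate = 1, wet_weight = 0.21)
st <- data.frame(stomach_id = "s1", station_id = "A", year = 2017,
                 fish_weight = 412, content_weight = 3.8, empty = FALSE)
copiesPerGram(w, s, st)
#>   stomach_id station_id year copies_per_ul_reaction copies_per_g n_replicates flags
#> 1         s1          A 2017               183.5344     20975361            1
```

2600 positive of 18,000 droplets is 183.5 copies µl⁻¹ in the reaction;
after the ×4 template ratio, ×10 dilution, ×150 µl elution and the
0.0525 g tissue weight (0.21 g wet at 1:3 buffer), the stomach carries
about 2.1 × 10⁷ mt16S gene copies per gram of content — a strong
predation signal.

Check the primer assay in silico:

```r
inSilicoPCR(PrimerAssay(), syntheticHerringReference())[, 1:4]
#>   start end length strand
#> 1   211 279     69      +
```

Run the whole synthetic pipeline:

```r
rep <- runPipeline(pipelineConfig(seed = 1))
rep$anova[["2018"]]
#> One-way station ANOVA [2018]: F(8, 63) = 6.626, p = 2.968e-06
#>   Tukey HSD: 8 of 36 pairs significant at 0.05
rep$anova[["2017"]]
#> One-way station ANOVA [2017]: F(10, 77) = 1.51, p = 0.1521
#>   Tukey HSD: 0 of 55 pairs significant at 0.05
head(rep$overlap, 4)
#>   station_id larval_density predator_density mean_copies_per_g n_stomachs
#> 1          A      3.1612372       2251.77805           8837911          8
#> 2          B      0.7506576       2226.40783          52019179          8
#> 3          C      4.6830485         53.53721          17762102          8
#> 4          D     61.1348448       2116.65674         155281183          8
```

With this draw the 2018 survey shows a clear station effect on the
molecular signal (stations P and O carry two decades more copies than
station N), while in 2017 the between-station differences drown in
within-station noise — empty stomachs with residual DNA inflate the
residual variance, exactly the behaviour that motivates keeping them in
the analysis rather than dropping them. The overlap table lines up
larval density, predator biomass and the mean molecular signal per
station; station D combines a dense larval patch with high predator
biomass and the strongest predation signal.

A thin CLI over the same functions ships in `inst/cli/predquant.R`
(subcommands `make-synthetic`, `simulate-drift`, `quantify-ddpcr`,
`insilico-pcr`, `survey-stats`, `run-all`).

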