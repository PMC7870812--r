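# cluesdm

Climate change reaches species along two pathways: **directly**, by
shifting the biophysical conditions that bound their climatic niches,
and **indirectly**, through the economy — changing yields move commodity
production and land requirements, which materialize as land-use change
and habitat conversion. `cluesdm` is an R package for ecologists and
land-system modellers that implements, at desk scale, an integrated
assessment chain separating and comparing the two pathways for a cohort
of species.

The chain has four layers:

1. **Demand downscaling.** Sector-level relative changes in land
   requirements (the output surface of an economy-wide equilibrium
   model, which this package consumes but does not contain) become an
   absolute cropland demand via harvested-area-share weighting,
   `D_t = D_0 (1 + Σ_s w_s δ_{s,t})`; urban demand scales with
   population at constant density; the remaining classes absorb the
   residual in proportion to their mean predicted suitability.
2. **Land-use change.** Per-class suitability comes from one-vs-rest
   logistic regressions on sampled pixels, after a |Spearman ρ| ≥ 0.7
   redundancy filter and cross-validated Lasso predictor selection. A
   CLUE-S style allocator then realizes the demands in decadal steps:
   each cell takes the class maximizing
   `suitability + elasticity stay-bonus + price_u`, where per-class
   prices are adjusted iteratively until every class's allocated area
   meets demand (within 0.1% or one cell), under a transition matrix,
   conversion elasticities and a frozen protected-area mask.
3. **Species distribution models.** Presence-only records (filtered to
   1950–2018, ≥ 20 records per species) are modelled against background
   points drawn proportional to an estimated observer-effort surface —
   cancelling sampling bias — with an elastic-net logistic regression on
   linear + quadratic features. Models are gated on fivefold
   cross-validated AUC ≥ 0.7, pruned of predictors with permutation
   importance < 1%, and binarized at the MaxSSS threshold (maximum
   sensitivity + specificity).
4. **Impact assessment.** Each retained species is re-predicted under
   three treatments — *direct* (future climate, present land use),
   *indirect* (present climate, future land use), *combined* (both
   future) — inside a dispersal mask of occupied-plus-adjacent
   bioregions. Range change is the ratio of suitable-cell counts,
   summarized per cohort and mapped as per-cell loss proportions.

Every input the chain needs — autocorrelated covariate fields, land use
with known multinomial-logistic truth, pseudo-GCM ensembles,
effort-biased occurrences, sector demand trajectories — is produced by
a first-class synthetic-data module with stored ground truth, so the
whole pipeline is testable by parameter recovery and brute-force
oracles without any downloads.

## Worked example

The shipped demo study (`inst/extdata/demo_config.yaml`) is a 100 × 100
landscape, 8 land-use classes, 20 synthetic species and two climate
scenarios (severity 0.3 vs 1.0, decadal steps 2020–2070):

```r
library(cluesdm)
cfg <- validate_config(system.file("extdata", "demo_config.yaml",
                                   package = "cluesdm"))
run <- run_scenario(cfg, "high")
print(run)
#> <scenario_run> high (severity 1.00)
#>   species retained: 20 / 20
print(run$cohort$summary, row.names = FALSE, digits = 3)
#>  scenario treatment n_species mean_ratio n_loss_ge50 n_loss_ge10 n_loss_ge95
#>      high    direct        20      0.644           0          20           0
#>      high  indirect        20      1.002           0           0           0
#>      high  combined        20      0.645           0          20           0
```

All 20 species supported an informative model (CV AUC ≥ 0.7). Under
the severe scenario the **direct** treatment shrinks the mean suitable
range to 0.644 of its present extent, with all 20 species losing at
least 10% — while the **indirect** (land-use-only) treatment leaves
ranges essentially unchanged (mean ratio 1.002), and the combined
treatment tracks the direct one. Land-use change itself still scales
with severity:

```r
run_low <- run_scenario(cfg, "low")
sum(run$change_intensity, na.rm = TRUE)      # 48.7
sum(run_low$change_intensity, na.rm = TRUE)  # 16.0
```

Per-species records underlying the summary:

```r
head(run$records[run$records$treatment == "direct",
                 c("species_id", "n_present", "n_future", "ratio")], 4)
#>    species_id n_present n_future     ratio
#> 1        sp01      3528     2093 0.5932540
#> 4        sp02      4188     3270 0.7808023
#> 7        sp03      3613     2819 0.7802380
#> 10       sp04      3137     1655 0.5275741
```

Each scenario writes its land-use maps (`landuse_<year>.asc`), demand
and audit tables, per-species QC, range-change records, loss-proportion
maps and a checksummed manifest under `output_dir/<scenario>/`. A thin
command-line wrapper is installed at
`system.file("scripts", "run_pipeline.R", package = "cluesdm")`.

The methods — model assumptions, parameter defaults and their
rationale, numerical choices, and what the synthetic data do and do not
emulate — are documented in
`vignettes/integrated-impact-assessment.Rmd`.

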