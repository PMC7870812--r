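---
title: "Separating direct and indirect climate impacts on species ranges: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating direct and indirect climate impacts on species ranges: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cluesdm)
```

## The problem

Climate change reaches species through two pathways. The *direct*
pathway alters the biophysical covariates — temperature, rainfall and
their derivatives — that delimit a species' climatic niche. The
*indirect* pathway runs through the economy: changing yields shift
commodity production and land requirements, which are realized on the
ground as land-use change, which in turn alters habitat. Assessments
that consider only one pathway cannot say which dominates, nor where
they interact.

`cluesdm` implements a desk-scale version of an integrated assessment
chain that quantifies both pathways in one consistent framework:

1. **Demand downscaling** converts sector-level relative changes in land
   requirements (the output surface of a computable-general-equilibrium
   model, which is *not* part of this package) into absolute per-class
   land-area demands.
2. **Land-use suitability and allocation** turns those demands into
   decadal land-use maps with a CLUE-S style competitive allocator under
   suitability, transition, elasticity and protection constraints.
3. **Species distribution models (SDMs)** fitted to presence-only
   occurrence data with effort-corrected background points are
   re-predicted under recombined futures and thresholded to suitable
   ranges.
4. **Impact assessment** contrasts three treatments per species:
   *direct* (future climate, present land use), *indirect* (present
   climate, future land use) and *combined* (future both).

Because the real inputs (occurrence archives, downscaled climate
ensembles, licensed economic databases) are not reproducible at desk
scale, a synthetic-data module generates every input with known ground
truth, so that each stage can be validated by parameter-recovery and
oracle tests rather than by eyeballing maps.

## The synthetic landscape and what it does (not) emulate

Covariate layers are Gaussian white noise smoothed by a Gaussian kernel
of scale `correlation_length` (cells) via toroidal FFT convolution, then
standardized. This reproduces the single most important property of
real environmental rasters — spatial autocorrelation with a known decay
scale, checked against a brute-force Moran's I — while remaining exactly
reproducible from a seed. Land use is drawn cellwise from a multinomial
logistic (softmax) model over those covariates; the coefficients are
retained as recoverable truth. Protected areas are the clumped top
decile of a smooth latent field; bioregions are quantile slices of two
independent smooth fields.

Species are given Gaussian niches on the logit scale: linear plus
negative quadratic terms in two randomly chosen climate layers, with an
optional positive association with a land-use indicator layer (the
hook through which the indirect pathway can reach a species). Niche
width defaults to 0.45 covariate standard deviations with peak
suitability between `plogis(1)` and `plogis(2)`; these defaults were
chosen so the synthetic cohort resembles the occurrence data quality of
regional avian archives — most species support a cross-validated AUC in
the 0.75–0.9 range, with a small fraction discarded by the 0.7 gate —
rather than producing mostly unmodelable species.

Observer effort is log-linear in accessibility and elevation,
emulating the roadside bias of opportunistic recording. Presences are
drawn with probability proportional to truth suitability times effort.

The generator deliberately does **not** emulate: measurement error in
coordinates, taxonomic misidentification, temporal trends in effort,
dispersal limitation within bioregions, mechanistic links between land
use and microclimate, or real bioclim variable definitions. Passing
tests therefore demonstrate that the *chain of methods* is implemented
correctly and recovers known truth under its own assumptions — not that
any particular real-world prediction is accurate.

Pseudo-GCM ensembles add to each present-day climate layer a shared
smooth anomaly (the forced signal) plus member-specific smooth
perturbations, both scaled by a scenario `severity` scalar. Severity 0
reproduces the present exactly — making the null scenario an exact
fixed point of the whole chain, which the acceptance suite asserts.
The low/high forcing contrast is emulated as severity 0.3 vs 1.0.
Cell-wise ensemble quartiles use linear interpolation between closest
ranks (the default sample-quantile convention); the convention matters
because real ensembles have even member counts.

## Demand downscaling

Cropland demand applies the harvested-area-share-weighted mean of the
sector relative land-requirement changes to the *base-year* cropland
area: `demand_t = base * (1 + sum_s share_s * d_land_req_{s,t})`.
Anchoring to the base year (rather than chaining multiplicatively)
keeps the direct proportional link between land-requirement change and
agricultural area; chaining is available as an option. Urban demand
scales base urban area by relative population growth, i.e. urban
population density is held constant. Wetlands and barren land are
static by default (the class list, and which classes are static, are
configurable — classifications differ on whether wetlands and barren
form one class or two; the default keeps them separate, eight classes
in all).

The remaining (residual) classes — herbaceous vegetation, shrubland
and the two forest classes — absorb whatever area the fixed demands do
not claim. A pure proportional-to-suitability split of the residual
total would move large areas between residual classes even under a
zero-change scenario, so the table builder anchors each residual class
at its base-year area and distributes only the *change* in the residual
total proportionally to mean predicted suitability across the
landscape. Under zero change the demand table is constant, and class
totals sum to the fixed land area at every timestep (checked to 1e-6
relative).

## Land-use suitability

Per-class suitability is a one-vs-rest binomial logistic regression
(the source framework fits one logistic model per land use, not a
single multinomial model) on pixels sampled uniformly without
replacement — 15,000 by convention; the shipped demo uses 8,000 on its
10,000-cell grid. Two predictor-selection stages precede the final
fit:

* **Rank-correlation filter.** While any predictor pair has absolute
  Spearman correlation at or above 0.7, the pair with the largest
  correlation is examined and the member whose highest correlation with
  the *other remaining* predictors is larger is dropped — keeping the
  predictor carrying more independent information. Ties are broken by
  column order (earlier kept); constant predictors have undefined rank
  correlation and are treated as zero with a warning. The filter is
  idempotent, which the tests assert.
* **Cross-validated Lasso.** An L1 path is scored by k-fold
  cross-validated deviance and the minimum-deviance penalty chosen (not
  the one-standard-error rule; the choice is recorded in the model
  metadata). Predictors with zero coefficient at that penalty are
  discarded.

The surviving predictors enter an unpenalized `glm` refit, so
coefficients and standard errors are directly interpretable; the
parameter-recovery acceptance check uses those standard errors. That
check runs on a two-class landscape because with class 1 as a zero
reference the one-vs-rest logistic truth is exactly the generator's
class-2 coefficient vector; with more classes one-vs-rest recovers
contrasts only approximately.

Future suitability surfaces interpolate the climate layers linearly
between the base year and the 2070 ensemble quantile before predicting.

## CLUE-S style allocation

Each cell is assigned the class maximizing

```
score_u(cell) = suitability_u(cell) + stay_bonus(cell, u) + term_u
```

where the stay bonus equals the current class's conversion elasticity
(in [0, 1]; 1 = hardest to convert away from) scaled by the spread of
suitability values, and the per-class iteration terms `term_u` act as
competitive prices that equilibrate allocation with demand. Transitions
are restricted by a boolean matrix, protected cells never change, and
static classes sit entirely outside the competition (their cells are
frozen; no cell may convert into them).

The price update is the one genuinely open design point. A classic
fixed-step relaxation (`term_u += eta * relative deviation`) and
several adaptive-step variants all failed to converge on realistic
inputs: the cell-count response to a price is a step function, and
where many cells share nearly the same score gap, classes end up
exchanging the same marginal cells indefinitely. The implementation
therefore adjusts, each pass, the price of the worst-deviating class by
the *exact* margin that flips the needed number of cells — the midpoint
between the k-th and (k+1)-th sorted score margins, so exactly k cells
flip and exchange cycles cannot form. This converges in roughly 10–40
passes on every random landscape in the test battery (50 seeded
100x100 problems) and preserves the CLUE-S semantics: iterate until
"estimated land area demands are met".

Numerical contract: convergence requires every class's allocation
within `tol` (default 0.001, i.e. 0.1%) of its demand, with an absolute
floor of one cell; ties in the per-cell argmax are broken by a seeded
random permutation of class order fixed per run, making the allocator
deterministic given inputs and seed. Demands infeasible in either
direction — exceeding a class's reachable cells, or below the count of
its immovable cells — are rejected before iterating. Because of the
one-cell tolerance floor, demand shifts of at most one cell per class
are treated as already satisfied and return the input map unchanged;
this also makes the zero-change scenario an exact fixed point.

Change between two maps is summarized by block-aggregated change
intensity: the fraction of cells per `factor x factor` block (default
3) whose class differs; edge blocks use their actual cell counts.

## Species distribution models

The SDM is an elastic-net-penalized logistic regression of presences
against background points on linear plus quadratic features of the
predictors — the standard re-expression of a maximum-entropy model
restricted to those feature classes (hinge, product and threshold
features are out of scope). Predictions are used as relative
likelihoods: every downstream quantity (AUC ranking, MaxSSS
thresholding, range membership) is invariant to monotone rescaling, so
no attempt is made to replicate any particular output transformation.

* **Record filter:** observations outside 1950–2018 are dropped;
  species with fewer than 20 remaining records are excluded (exactly 20
  is retained).
* **Effort surface:** pooled per-cell record counts are regressed on
  demographic/topographic drivers with a log-link Poisson model; the
  fitted mean surface, normalized to sum to one, is the relative
  sampling effort.
* **Background:** 10,000 points by default (2,000 in the demo),
  sampled with replacement proportional to effort. Sampling background
  where observers actually looked cancels the effort term that
  contaminates presence locations; the acceptance suite verifies the
  mechanism end to end (effort-proportional background beats uniform
  background on truth-correlation across 20 biased species, one-sided
  sign test).
* **Penalty:** the elastic-net penalty (alpha 0.5) is chosen by
  internal fivefold cross-validation at the conservative
  one-standard-error value, scaled by a user multiplier. The
  conservative choice suppresses uninformative features, which keeps
  the permutation-importance stage decisive.
* **Permutation importance:** importance is the mean drop in training
  AUC over `n_perm` permutations of a predictor's raw column (linear
  and quadratic features move together, since permutation happens
  before feature expansion), floored at zero and normalized to sum to
  100. Predictors under 1% are dropped and the model refit once. If
  every predictor falls under the threshold the single most important
  one is kept with a warning. AUC-drop is used as the importance
  metric; importance computed from training gain would be an
  alternative, and the choice is flagged here.
* **Cross-validation:** presences are split into five random folds;
  background is shared across folds. Mean test AUC below 0.7 discards
  the species from impact assessment; the final model is refit on all
  records. AUC is the normalized Mann–Whitney U with ties counted one
  half, tested against brute-force pair enumeration.
* **MaxSSS:** the binarization threshold maximizes sensitivity plus
  specificity over the observed scores, with background standing in for
  absences; among tied candidates the smallest (most inclusive)
  threshold is returned. Training scores are used (whether held-out
  scores should be used instead is unspecified in the source
  framework; training data is the common default). Cells at or above
  the threshold count as suitable.

## Impact assessment

For each retained species the same fitted model and the same MaxSSS
threshold are applied to three covariate recombinations (direct,
indirect, combined). Suitable-cell counts are taken inside a dispersal
mask: either the whole grid ("unlimited") or the union of bioregions
containing records plus bioregions in 8-neighbour (queen) contact with
those ("bioregion_adjacent"; rook contact is a config option). Range
change is reported as the multiplicative ratio future/present alongside
its natural log; a species whose future count is zero is flagged
extirpated and carries ratio 0 rather than log ratio negative infinity,
so cohort means stay finite. Species with an empty present range are
excluded from change estimation with a logged reason.

Cohort summaries give the mean multiplicative change per scenario and
treatment plus counts of species losing at least 50%, 10% and 95% of
their present range (an extirpated species falls in every tier). The
per-cell loss-proportion map divides, cellwise, the number of species
suitable at present but not in the future by the number suitable at
present; cells with no present-suitable species are no-data. Using all
retained species as the denominator instead is a config option.

Two exact consistency properties pin the treatment logic down: if the
future equals the present for the climate layers, combined equals
indirect; if it equals the present for the land-use layers, combined
equals direct. Both are asserted in the tests.

## Orchestration, formats, reproducibility

`validate_config()` overlays a YAML document on documented defaults,
rejects unknown keys with the offending path, and cross-checks classes,
transitions, elasticities (bounds [0, 1]), scenario severities and the
demand timestep. `run_scenario()` executes the stages in dependency
order, writes every output under `output_dir/<scenario>/`, and records
a manifest with the config hash, per-stage seeds (derived
deterministically from one master seed) and MD5 checksums of every
output file. Re-running with the same config reproduces identical
checksums, which the test suite asserts; `resume = TRUE` short-circuits
a scenario whose manifest is already complete and matches the config
hash. Two scenarios never share an output path.

Rasters are stored as ESRI ASCII grids — a plain-text, GIS-readable,
version-control-friendly raster format — with integer codes for
categorical layers; tables are CSV with fixed documented columns;
fitted SDMs serialize to JSON. Coordinates are planar: 0-based
row/column indices, cell centres at half-integers, no projection.

## Problem sizes

The shipped demo study — also the configuration the acceptance script
runs — uses a 100 x 100 grid, 8 classes, 20 species with 300 records
each, 2,000 background points, a 15-member pseudo-ensemble and decadal
steps 2020–2070 for two scenarios. Suitability recovery checks run at
the conventional 15,000-pixel sample on an 18,000-cell landscape over
20 seeds; the allocator battery runs 50 seeded random 100 x 100
problems. These sizes keep the full validation suite in the minutes
range on a single core while leaving every statistical check adequately
powered.

## Known limitations

* One-vs-rest suitability models do not sum to one across classes; the
  allocator consumes them as independent scores, as CLUE-S does.
* The allocator optimizes cellwise scores under demand constraints; it
  does not implement neighbourhood interaction terms or
  multi-resolution allocation.
* MaxEnt hinge/product/threshold features are not implemented; species
  whose true response is strongly non-quadratic on the logit scale will
  be approximated.
* The economic stage is an emulator with qualitative realism (output
  declines up to ~20% at high severity, land requirements flat to
  slightly positive, shares fixed); it carries no price equilibria and
  no substitution structure.
* Resumability is at scenario granularity (a completed scenario is
  skipped); individual stages are cheap enough at desk scale that
  finer-grained checkpointing was not worth its complexity.
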