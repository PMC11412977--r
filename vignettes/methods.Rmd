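---
title: "Methods: prioritization and corridor models in prioconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prioritization and corridor models in prioconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`prioconn` chains five analyses that are usually run in separate tools —
occurrence cleaning, collinearity screening, ensemble distribution
modeling, spatial prioritization, and least-cost corridor design — into one
deterministic R pipeline over a single raster data model. This vignette
describes each model, its assumptions, the parameters that matter, and the
design decisions taken where the methodology is conventionally
underspecified.

## The raster data model

All layers are `GridRaster` objects: a numeric matrix (row 1 = north) on a
shared projected grid with square cells, a cell size in meters, a top-left
origin, and an opaque CRS tag. Every operation that combines layers asserts
shape/cell-size/origin equality first. Distances are measured center to
center in meters; areas are reported in km². Rasters are exchanged on disk
as plain-text ESRI ASCII grids with a `.prj` sidecar, a format every GIS
reads, and the write–read round trip preserves values exactly.

Fragment labeling uses 8-connectivity (queen moves), the common
remote-sensing convention; labels are assigned in row-major scan order so
they are reproducible. Connectivity is a genuine free choice here —
4-connectivity would split diagonally-touching patches — and tests pin the
8-connected behavior.

## Occurrence cleaning

Records pass a fixed cascade of filters, each removed record carrying the
first-triggered reason: missing coordinates; outside the study grid or
study-area mask; on non-vegetated land cover (water or bare/urban);
coordinate precision coarser than 1000 m; individual count outside 1–99;
collected before 1945; within one cell of a user-supplied exclusion point;
geographic outlier. All boundary comparisons are strict ("before 1945"
removes 1944 and keeps 1945; "larger than 99" keeps 99). The exclusion-point
mechanism generically replaces gazetteer tests (political centroids,
institutions) that need external reference data. The outlier rule is a
distance-MAD heuristic: a record is flagged when its median distance to all
other surviving records of the taxon exceeds five times the taxon-level
median of those medians; it needs at least three survivors, and captures the
"isolated far-away record" intent without a gazetteer.

Spatial thinning is stated in the literature as a goal ("delete coordinates
within 1 km, prioritizing the most recent") rather than an algorithm. The
implementation is deterministic greedy acceptance: sort by year descending
(ties: stable input order), accept a record only if it is at least 1000 m
from every accepted record. Exact spatial duplicates collapse first (the
0-m degenerate case of the same rule). This is idempotent, order-insensitive
when years are distinct, and keeps two records exactly 1000 m apart. Taxa
retaining fewer than five records are excluded (exactly five passes).

## Predictor screening

`derivePredictors()` builds the standard stack: distances to forest edge,
large fragments (≥ 1 km² by default), roads, watercourses and protected
areas; moving-window percentages of agropastoral and forest cover (square
window, default 5 cells, truncated at edges rather than padded); and the
continuous passthroughs (tree cover %, elevation m, temperature range °C,
human modification in [0, 1]).

Screening happens once on the whole landscape, not per taxon, so every
taxon is modeled on the same predictor set. Pairwise pruning removes layers
until no retained pair exceeds |r| = 0.7: at each step the layer with the
highest mean |r| against the remaining layers is dropped, considering only
layers that participate in a violating pair (this restriction guarantees
progress and leaves untangled layers alone); ties break alphabetically.
Multicollinearity pruning then iteratively removes the layer with the
largest VIF (1/(1−R²) from regressing it on the others) until all VIF < 5;
non-finite VIFs from exact collinearity or zero variance count as infinite
and go first. Both statistics are computed on a seeded random sample of
complete cells (default 10,000) for speed; tests recompute them on the full
grid to verify the postconditions.

## Ensemble distribution models

Pseudo-absences are background points drawn uniformly over non-nodata
cells, in independent sets (default 3 × 10,000) with a 1-km minimum
point-to-point spacing; when the grid cannot host the request the set is
returned short with a warning rather than failing.

Candidates are one model per (pseudo-absence set × learner × replicate),
so the full design instantiates 3 × 5 × 100 = 1500 models per taxon. Each
replicate splits presences and background 80/20, stratified by class, and
weights records so each class contributes half the total weight (the
prevalence-0.5 convention). The built-in roster holds analogs of the
conventional algorithms — ridge-regularized logistic regression,
gradient-boosted shallow trees, a single classification tree, and a small
one-hidden-layer neural network — plus a constant-score baseline; the
roster is pluggable (any `fit`/`predict` pair), because the contract is
the ensemble machinery, not algorithm-for-algorithm parity with any
particular toolbox. A learner failure on a replicate is recorded and
skipped, never fatal.

Evaluation uses the True Skill Statistic, TSS = sensitivity + specificity −
1, maximized over every observed score as cutoff, plus the ROC AUC.
Candidates with holdout TSS strictly above 0.8 become ensemble members
(demo-scale configurations lower this cutoff since four-replicate TSS
estimates are noisy); weights are proportional to TSS and the ensemble
suitability is the weighted member mean, hence a convex combination. The
ensemble's own binarization threshold is the max-TSS cutoff of its scores on
the pooled member holdouts. Variable importance is permutation-based: 1
minus the correlation between ensemble predictions before and after
permuting one variable on the evaluation sample, averaged over a few
permutations and clamped to [0, 1]. Response curves are median-conditioned
evaluation strips: the focal variable sweeps its observed range while the
others sit at their landscape medians.

## Core-area zonation

Each taxon contributes an occurrence-value layer: ensemble suitability with
cells below the taxon's binary threshold zeroed, weighted by conservation
status (DD = 1, VU = 2, EN = 3, CR = 4). An ecological-condition layer
multiplies every feature by (1 − gHM), penalizing human-modified cells; a
protected-area mask adds a hierarchy level so all unprotected cells are
removed before any protected cell.

Ranking removes cells one at a time. Among cells of the lowest hierarchy
level still present, the removed cell minimizes the core-area marginal loss

δ_i = max_j [ w_j · a_ij / Σ_{k ∈ remaining} a_kj ],

i.e. the worst-case weighted share the cell holds of any taxon's remaining
distribution, with unit cell cost. A taxon whose remaining total reaches
zero contributes zero loss thereafter. Ties break at the lowest (row,
column) position, which makes the ranking fully deterministic; an all-zero
feature stack therefore degenerates to mask level plus scan order. The rank
of a cell is the fraction of analyzed cells removed at or before it, so
ranks are exactly {1/n, ..., 1} and protected cells always occupy the top
block. The implementation updates the remaining totals incrementally but is
tested for exact agreement with a naive oracle that recomputes every δ from
scratch each iteration. Per-taxon performance curves (fraction of weighted
distribution remaining vs fraction of landscape removed) are recorded;
they start at 1, end at 0, and never increase.

Conservation priority areas are the cells with rank above 1 − f for a
user-chosen top fraction f; no conventional default exists for f, so it is
a required configuration parameter. Conservation priority fragments (CPFs)
are forest fragments strictly larger than 1 km² whose unweighted mean rank
strictly exceeds 0.95.

## Resistance and corridors

The landscape resistance surface is the mean of five [0, 1] layers: (1)
forest 0 / non-forest 1; (2) the rescaled inverse of tree canopy cover;
(3) the Euclidean distance to forest rescaled to [0, 1]; (4) a
riparian-restoration layer that is 0 in unforested riparian
permanent-preservation (APP) cells and 1 everywhere else, steering
corridors through legally restorable land; (5) barriers, 1 on roads and
watercourses. Taxon resistance reflects each suitability layer between its
own extremes, r = (max(hs) − hs) + min(hs), so the best habitat gets the
layer's minimum resistance; layers are averaged over taxa and a constant
layer passes through unchanged (the reflection is the identity there). The
final surface is exactly the mean of the landscape and taxon components.

Cost distance is single-source-set Dijkstra over the 8-connected grid
graph: a step between adjacent cells costs the center distance (cell size,
or √2 × cell size diagonally) times the mean of the two cells' resistance.
Zero-resistance steps are legal; nodata cells are impassable; negative
resistance is an error. The Rcpp implementation is verified exactly against
a general-purpose shortest-path routine and against exhaustive simple-path
search on small grids.

Corridor pair selection follows cost allocation: every cell is assigned to
the CPF it can reach at least cost-weighted distance, and CPF pairs whose
allocation regions touch (8-adjacency) are linked — reproducing the
"connect each patch to its cost-space neighbors" behavior of standard
corridor toolboxes and yielding sparse corridor networks rather than all
pairs (an all-pairs mode exists for small fragment counts). The least-cost
path between two fragments treats their full cell sets as sources and
targets and meets at the cell minimizing the summed cost distances. Each
corridor reports CWD (accumulated cost, meters × resistance), CL (geometric
path length along the corridor, center to center), and CWD/CL, the mean
effective resistance en route; on a uniform surface of resistance r the
ratio equals r to floating-point accuracy, which the tests use as a closed
form.

## The synthetic landscape generator

`makeLandscape()` emulates the statistical structure the analysis assumes,
not any real region: spatially autocorrelated continuous predictors
(Gaussian-smoothed white noise with a chosen correlation range, in cells);
forest grown from seeded patches with right-skewed (lognormal) target sizes
so that most fragments are small and a few are large, with the realized
forest cell count exact; straight road and watercourse transects; a
human-modification layer blending road proximity with agropastoral density;
a one-cell riparian APP buffer; and a protected subset limited to two or
three mid-sized reserves capped near 4% of the landscape, because
protection is sparse in heavily deforested regions — at desk scale a
protected block spanning much more than the top-rank window could never
clear the 0.95 CPF cutoff, which would misrepresent the system being
emulated.

`makeVirtualTaxon()` gives each taxon a logistic suitability truth on
standardized predictors, exactly recomputable from its response
specification, and samples presences without replacement with probability
proportional to suitability, restricted to vegetated cells
(threshold-free sampling preserves the continuous gradient that
response-curve and importance recovery need). Generated records pass the
cleaning filters by construction; dirty records (missing coordinates, year
1900, count 0, 5-km precision, off-grid points) are injected only on
request. All draws come from one seeded stream: equal seeds give
byte-identical bundles and occurrence tables.

What the generator does **not** emulate: realistic topography or climate
surfaces, sampling bias and spatial clustering of real occurrence data,
registration error between layers, or the enormous cell counts of real
analyses. Passing tests therefore demonstrate that the algorithms implement
their contracts and recover known truth under clean conditions, not that
any particular real dataset would yield particular maps.

For the parameter-recovery experiments the "strong signal" taxon is a
habitat specialist — logistic intercept −2.5 and slope 5 on one predictor,
about 10–15% prevalence. The choice matters: a generalist occupying half
the landscape has a TSS ceiling near 0.5 (one minus prevalence) no matter
how strong the signal, because background points fall in suitable habitat
half the time; a specialist is what "strong, recoverable signal" means for
presence/background evaluation.

## Numerical and scale choices

Problem sizes are chosen so the full suite and the acceptance script run in
minutes on one core: demo landscapes are 40 × 40 to 50 × 50 cells at 1 km,
demo rosters use two learners with a handful of replicates, and oracle
comparisons use grids of at most 6 × 6 (exact removal-order and
shortest-path agreement) or 4 × 4 (exhaustive path enumeration). The
full-scale defaults (10,000 background points, 100 replicates, 5 learners)
remain the package defaults and are exercised structurally (the 1500-model
count) with the constant baseline learner standing in for expensive fits.

Other conventions worth knowing: a constant raster rescales to all zeros
(resistance-neutral) with a warning instead of erroring, so degenerate
synthetic layers do not kill a run; ensemble weights fall back to equal
when all member TSS values are zero; suitability stays on [0, 1] end to
end; and every stochastic stage takes an explicit seed, with pipeline stage
seeds derived from the single global seed.

## Known limitations

- No reprojection or resampling: all inputs must share one grid.
- The cleaning stage replaces gazetteer-based tests with the generic
  exclusion-point mechanism; name/synonym resolution is out of scope.
- The corridor planner produces single least-cost paths, not corridor
  swaths or circuit-theory current maps, and does not prune corridors that
  pass through a third fragment.
- The zonation stage implements the core-area removal rule with a
  multiplicative condition layer and hierarchical mask only — no
  additive-benefit rule, retention layers, or feature interactions.
- TSS-based evaluation uses random holdouts, not spatially blocked
  cross-validation, so autocorrelation inflates apparent skill exactly as
  it does in the conventional workflow.
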