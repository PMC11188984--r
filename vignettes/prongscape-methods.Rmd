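---
title: "Methods: multiscale climate and habitat consensus modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale climate and habitat consensus modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`prongscape` implements a multiscale workflow for mapping where a
wide-ranging arid-grassland ungulate (the motivating case is pronghorn,
*Antilocapra americana*, in a region that has seen extreme range collapse)
could live now and under future climate. The workflow stacks two kinds of
inference: coarse climate suitability models under two competing historical
hypotheses, and three independent fine-scale habitat models. Their agreement
— a 0–3 consensus count per cell — is the management product. Because the
real inputs (range-wide occurrence archives, GPS collar deployments,
30-arc-second climate normals, 25-member future climate ensembles) cannot be
bundled or downloaded in a test environment, the package ships a
synthetic-landscape generator with known ground truth; every stage of the
pipeline is exercised, and where possible inverted, against that truth.

## The data model

All spatial layers live on a `pg_grid`: a regular grid with square cells,
cell-center registration, row 1 at the north edge, and Euclidean distances in
a projected equal-area CRS (units m). Nodata is `NA` in memory and an
explicit sentinel in the single-band float32 GeoTIFFs the package reads and
writes. The GeoTIFF codec is deliberately minimal (uncompressed baseline
TIFF + ModelPixelScale/ModelTiepoint/GDAL_NODATA); it exists because the
target environment ships no GIS raster library, and it round-trips its own
output bit-exactly at float32 precision.

Predictor construction follows the conventions of the field's terrain tools:
slope by Horn's 3x3 weighted differences (edges by one-sided differences via
linear edge extrapolation, so a plane keeps its slope at the margin), TPI as
cell elevation minus the mean of neighbors within a radius, road distance as
exact Euclidean nearest-feature distance between cell centers, road density
as the unitless fraction of road cells in a circular window, and land-cover
fractions as the share of fine cells of a class within a coarse cell. Focal
operations renormalize over valid cells; point operations propagate nodata.
The density/TPI radius defaults to 1 km — the source material names the
predictors but not the window — and is configurable.

## Climate suitability (Maxent-style)

The presence/background model is a lasso-penalized logistic regression on
min–max-scaled covariates expanded into linear + quadratic features (hinge
features with both orientations are available; they carry half penalty
weight, mirroring maxnet's class defaults). This is the maxnet
parameterization of Maxent; the regularization multiplier scales a base
penalty (`lambda_base = 0.01` at multiplier 1) and is swept over
0.5–3.0 in steps of 0.5. Each candidate is scored with `AIC = 2k − 2 logL`,
where `k` counts nonzero penalized coefficients and `logL` is the
*unpenalized* binomial log-likelihood at the fitted coefficients; the AIC
argmin is selected, ties resolved toward the larger (more parsimonious)
multiplier. Predictions are logistic in [0, 1]; since every downstream
binary is an occurrence-percentile threshold, any monotone output transform
would produce identical maps.

Seasonal ("migration hypothesis") models are fitted separately for winter
(Nov–Feb, monthly minimum temperature + slope) and summer (May–Sep, monthly
maximum temperature, annual precipitation, slope), with month-matched
extraction: each record reads the climate layer of its own month, and
background points draw a month uniformly from the season. March, April and
October are excluded as movement months. The "niche reduction" model instead
uses records up to a historical cutoff (default 1950) plus a small
supplement (default 20) of later records carrying an arid-adapted subspecies
tag, with climate-summary covariates. At desk scale those summaries are
winter-mean minimum temperature, summer-mean maximum temperature, annual
precipitation and slope rather than the 19 bioclimatic variables of the real
analysis — the synthetic climate generator has no quarterly structure worth
summarizing, and the module contract (any named covariate layers) is
unchanged.

Spatial cross-validation uses the checkerboard partition: aggregation blocks
labeled by the parity of block row + column. A checkerboard natively yields
two folds; the source material simultaneously mentions five-fold CV, which
cannot both hold, so two-fold checkerboard is the default and random k-fold
remains available. Projection clamps covariates to the training range
(clamp counts are reported) rather than masking, with the MOP surface as the
companion extrapolation diagnostic: per projection cell, the mean
standardized Euclidean distance to the nearest `ceil(fraction × n)`
calibration rows (defaults: fraction 0.10, calibration subsampled to 2000
rows), rescaled to similarity `1 − d/d_max` so the in-region minimum is 0,
plus a strict min–max extrapolation flag. Future projection produces both
the mean-over-ensemble surface (thresholded at the contemporary threshold
for the future climate clip) and the per-member binary-sum count map.

## Habitat models

*Ensemble RSF.* Presences (thinned to one per cell) against an equal count
of background points drawn uniformly within 25 km of any presence — the
radius of the largest reported home range — fitted identically by four
learners: the Maxent-style model above, a 500-tree bagged random forest, a
single CART, and a plain logistic GLM. CART and the forest are implemented
in-package (Gini splits, class-probability leaves, per-split feature
subsampling `floor(sqrt(p))`) because the environment ships no tree
learner. Members are combined by an unweighted mean, and a member that
cannot be fitted raises rather than being dropped. Perfectly separable
input is tolerated for the GLM (separation yields a perfectly ranking fit;
only undefined coefficients are treated as failure). The default predictor
set is the reduced road + land-cover set; the full set is a config choice,
reflecting the overfitting concern that motivated the reduction.

*Step-selection function.* Tracks are filtered to individuals with at least
100 fixes at a uniform rate (nearest of 1/2/4/13 h; uniformity = median
absolute interval deviation within 10% of the rate; larger gaps split tracks
into bursts instead of fabricating long steps). Each observed step is paired
with K = 15 random steps sharing its start point, lengths drawn from the
individual's maximum-likelihood gamma and turns from its von Mises (mean 0)
relative to the previous bearing — uniform where a first step has none.
Covariates are read at step endpoints. The stratified conditional logistic
likelihood is maximized by Newton iteration with step halving; standard
errors come from the inverse observed information; complete separation is
detected (likelihood at its supremum) and raised; covariates without
within-stratum variation are reported as zero with a warning. The fit is
cross-checked against `survival::clogit` in the tests. The projected
surface is the logistic of the habitat linear predictor, min–max rescaled.
Because the six cover fractions sum to one within a stratum-centered model,
the default SSF covariate set drops one cover class (desert) as the
baseline.

*Expert HSI.* Road-distance suitability times slope suitability times the
summed fraction of four open-cover classes (barren, desert, grass, shrub),
then cells whose urban + agriculture fraction exceeds 0.5 are zeroed. The
curve breakpoints (road: 0 at 0 m rising to 1 at 1 km; slope: 1 up to 10°
falling to 0 at 30°) are declared package defaults, not literature facts —
the source figure is graphical only — and are fully overridable; the module
enforces only the structural contract (monotone piecewise-linear curves in
[0, 1], multiplicative combination, conflict zeroing).

## Evaluation and consensus

AUC is the Mann–Whitney probability that a presence outranks a background
score, ties half-weighted. The Boyce index is the continuous form: 101
overlapping windows of width 10% of the score range, P/E = presence share
over cell share per window, Spearman correlation of P/E against window
midpoint, consecutive duplicate P/E values removed before correlating (the
reference implementations do the same; without it, presences concentrated in
top-ranked cells cannot reach the nominal 1.0 because zero-P windows tie).
A constant surface is flagged rather than scored. Because the windows
overlap heavily, a *single* uniform-null draw of the index has a standard
deviation near 0.38; the package's null tests therefore check the mean over
replicates against the ±0.3 band rather than pretending one draw is that
precise. Cross-evaluation refuses to score a model on data carrying its own
training-source tag unless explicitly overridden: collar-trained surfaces
are scored on observation records, the expert surface on collar points.

Thresholding uses the type-1 (lower-interpolation) quantile of surface
values at occurrence points, which makes the retention guarantee exact: at
least the stated fraction of occurrence values is ≥ the threshold, and the
threshold is itself an observed value. Two stringencies (retain 0.85 "HSS"
and 0.95 "LSS") binarize the climate models; habitat surfaces use retain
0.99. Habitat binaries are clipped (cellwise AND) to the niche-reduction
climate binary — contemporary and future separately — summed into a 0–3
consensus, masked to 0 where the urban + agriculture fraction exceeds 0.5,
and accounted as cells × cell area per class. The migration-hypothesis
combined binary is the AND of winter and summer (both seasons must be
suitable), configurable to OR.

## The synthetic world

The generator is a stated world, not a tuning dial. Defaults: a 10 × 10 km
landscape at 100 m cells; Gaussian random fields with exponential covariance
synthesized by circulant embedding (elevation mean 800 m, sd 150 m, range
2 km; winter-centered seasonal temperature cycle with −6.5 °C/km lapse;
~400 mm precipitation); land cover from a latent field cut at
empirical-prevalence quantiles (grass 30%, shrub 25%, barren 15%, desert
12%, agriculture 12%, urban 6%), which makes class shares exact per
realization while preserving spatial structure; one west–east major road and
one minor road as smooth connected paths; occurrences sampled proportional
to suitability with jitter, era/month/precision/basis attributes, and a
contemporary surface truncated below its 0.6 quantile to emulate range
collapse (historical records sample the full surface — the signal the
niche-reduction model is meant to detect); movement by gamma(2, 150 m) step
lengths and von Mises (κ = 0.5) turns, with the chooser selecting one of
K_gen = 50 candidates with probability ∝ exp(βᵀx) — K_gen is deliberately
different from the analysis K = 15 so fitting does not mirror generation;
pseudo-GCMs as contemporary climate + (+2.8 °C min, +3.2 °C max, −50 mm)
plus per-member smooth noise (sd 0.5).

What a green test establishes is therefore: the estimators invert this
generative family (SSF coefficient recovery within ±0.15 with ~nominal CI
coverage; Maxent-style ranking recovery at Spearman ≥ 0.6 on held-out
cells; Boyce calibration on surfaces sampled from themselves), and the
deterministic algebra (thresholds, clips, sums, areas, distances, AUC, MOP)
matches independent brute-force oracles exactly. What it does not establish
is realism of any specific landscape: no climate physics, no calibration to
real climate normals, no fences or water (excluded in the source analysis
too), and land-cover classes that border each other in latent-field order.

## Numerical and reproducibility choices

Every stochastic stage derives its seed from one master seed via an LCG-style
mix (`derive_seed`), so `run_pipeline` is bit-reproducible — rerunning with
the same config yields byte-identical consensus GeoTIFFs — while stages stay
independently perturbable. glmnet and the k-nearest-neighbour searches are
deterministic. The pipeline default forest is 200 trees (the `fit_ensemble`
default stays at 500) so the end-to-end 100 × 100 determinism check fits
comfortably in its runtime budget; at these sample sizes the ensemble mean
is insensitive to the difference. Degenerate inputs fail loudly: all-zero
suitability, empty feature masks, grids under 3 × 3 for slope or 50 × 50
for track simulation, gamma fits on constant lengths, single-class samples,
misaligned grids.

## Known limitations

The Maxent implementation is the penalized-logistic core only — no threshold
or product features, no bias files. MOP similarity is normalized by the
projection-region maximum distance, so it is comparable within one
projection, not across projections. The expert curves are placeholders with
a structural contract, pending real expert elicitation. The SSF is a plain
(not integrated) step-selection fit, evaluated at endpoints. Area accounting
assumes the projected CRS is equal-area, as stated by the grid contract.
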