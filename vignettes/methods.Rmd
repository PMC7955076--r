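---
title: "Morphometric similarity networks and their transcriptomic correlates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric similarity networks and their transcriptomic correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the models and procedures implemented in `msntx`:
what each stage computes, the assumptions behind it, the tunable parameters
and their defaults, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely open.
It states no empirical result that the package's tests and acceptance script
do not themselves compute.

## The morphometric similarity network (MSN)

A subject's cortex is parcellated into regions (the package's synthetic
atlas stands in for a ~300-parcel subdivision of a standard anatomical
atlas, with equal numbers of parcels per hemisphere). Each region carries a
vector of `F` morphometric features drawn from structural and
diffusion-weighted MRI — surface area, cortical thickness, gray-matter
volume, two curvature measures, fractional anisotropy and mean diffusivity
in the canonical seven-feature setting.

Features live in incommensurate units, so each feature is first
*z-normalized across regions* within subject (`zscore_features()`; sample
SD with denominator n−1 — the convention is stated because nothing forces
either choice). The MSN is then the region × region matrix of Pearson
correlations between regions' z-scored feature vectors, correlating over
the `F` features (`build_msn()`). The diagonal is set to zero. With `F = 7`
these correlations are individually noisy; no significance filtering is
applied, matching how the statistic is used in the MSN literature.

The per-region statistic is the **regional strength**: the signed sum of a
region's correlation weights to all other regions (`regional_strength()`).
Negative weights are included and nothing is normalized. Optional density
thresholding (`threshold_msn()`) retains the top fraction of off-diagonal
entries ranked by *signed* value. Ranking by signed rather than absolute
value is a deliberate choice: the strength statistic sums signed weights
and the decoupling/dedifferentiation interpretation depends on negative
weights, so "strongest edges" means largest correlations. An
`mode = "absolute"` switch is provided because the convention is not
universal. Ties break by (row, column) lexicographic order of the
upper-triangle pair, which makes thresholding deterministic and kept-edge
sets nested across densities.

## Case-control statistics

For each region, strength is regressed on an intercept, a case/control
indicator, and covariates (age, sex, education by default; total
intracranial volume can be added for sensitivity analysis) by ordinary
least squares, and the two-sided t-statistic of the group coefficient
(case − control, n − k residual degrees of freedom) is extracted
(`fit_tmap()`). P-values are adjusted by Benjamini–Hochberg FDR across
regions; every FDR call in the package states its family (regions, systems,
or a named gene set) in its output metadata, because overlap and FDR
statistics are family-sensitive. Sex is coded 0/1; the coding affects only
the intercept.

Regions are classified into quadrants by crossing the sign of the t-value
with the sign of the control-group mean strength (`classify_regions()`):
negative t with positive mean strength is *decoupling* (a well-connected
region becoming less similar to the rest of cortex in cases), positive t
with negative mean is *dedifferentiation*, and the two remaining strict
quadrants are labelled `coupled_increase` and `differentiated_decrease`.
Exact zeros are mapped to `null`: the two named quadrants leave boundaries
undefined, and an explicit rule beats silent ties.

System-level analysis (`aggregate_by_system()`) averages each subject's
strengths within labelled systems (functional-network or cytoarchitectonic
schemes carried by the atlas) and refits the same model per system, with
FDR across systems. Symptom analysis (`correlate_symptoms()`) computes
per-region Pearson correlations with a clinical score; whether such
correlations should pool groups or use cases only is not standardized, so
both modes exist and case-only is the default.

## Spatial permutation ("spin") inference

Regional maps are spatially autocorrelated, so naive permutation nulls are
anti-conservative. The spin engine (`generate_spins()`) draws uniform
random 3D rotations by the normalized-quaternion method, rotates the
left-hemisphere parcel centroids, and re-assigns rotated centroids to
original parcels by one-to-one greedy matching in ascending distance order
(ties toward the lower region index; the tie-break is our addition, since
the cited matching approach leaves it unspecified). For whole-cortex maps
the x-mirrored rotation is applied to the right hemisphere so the two
hemispheres spin coherently. Spun maps preserve the multiset of values and
the autocorrelation structure while breaking alignment with other maps.

Permutation p-values use the add-one correction
`p = (1 + #extreme) / (n + 1)` rather than a raw percentile rule: raw
zero p-values would poison downstream FDR. The percentile rule arises as a
special case. By convention the engine spins the *first* map; callers pass
the MSN-derived map there, so gene maps stay fixed.

## Expression preprocessing

`build_region_gene_matrix()` runs the canonical six-step microarray
pipeline, in fixed order, on a multi-donor bundle in the AHBA CSV dialect:

1. **Probe re-annotation** against an external probe-to-gene mapping;
   probes with missing, ambiguous or contradicted annotations are dropped.
2. **Intensity filtering**: a probe survives if it is called "present" in
   at least 50% of samples, pooled across donors (the pooling is
   configurable to per-donor because the convention is ambiguous; pooled is
   the default).
3. **Probe selection**: one probe per gene, the one whose
   structure-averaged profile best Spearman-correlates with an
   RNA-seq-like reference; genes missing from the reference fall back to
   highest mean intensity; ties go to the lowest probe id. Spearman rather
   than Pearson follows the cited preprocessing convention and is
   configurable.
4. **Sample assignment**: each tissue sample maps to the nearest parcel
   representative point within 2.0 distance units, else stays unassigned;
   right-hemisphere samples are excluded by default because expression
   coverage is effectively left-hemisphere-only.
5. **Scaled robust sigmoid (SRS) normalization** per donor and gene:
   `1 / (1 + exp(-(x - median) / IQR))`, then min-max rescaling to [0, 1].
   Zero-IQR genes become the constant 0.5 and are flagged, not fatal.
6. **Differential stability (DS) filtering**: a gene's DS is its mean
   pairwise inter-donor Spearman correlation of regional profiles over
   shared regions; genes are retained either above a DS floor (`ds_min`,
   for compatibility with the DS > 0.1 convention) or as a top fraction
   (`top_fraction`, the default). The exact cut-off that published analyses
   used to arrive at their gene count is not stated anywhere we can verify,
   so it is exposed as configuration and never hard-coded.

Donors are normalized first and averaged second (simple mean across donors
within region; regions with no donor coverage are dropped and logged).
Every stage logs counts into a provenance record, and a noise-free bundle
round-trips exactly: SRS is monotone, so each gene's regional profile keeps
Spearman correlation 1 with its generating profile — this is the
conservation property the acceptance suite checks.

## PLS1 and bootstrap gene ranking

With a univariate response, the first partial-least-squares component has a
closed form: center (and, by default, z-score) the predictor columns,
center the response, and take the unit-norm weight vector proportional to
`t(X) %*% y` (`fit_pls1()`). This equals what iterative NIPALS yields at
component 1; the test suite verifies the identity against an independent
NIPALS implementation. Predictor standardization defaults to on because
SRS outputs live on [0, 1] with unequal variances. The component sign is
fixed so regional scores correlate positively with the response; "PLS1−"
then reproducibly means expression high where the map is low.
`var_explained` is the squared correlation between scores and response
(response variance, the primary reading of "variance explained"; the
predictor-block share could be reported alongside but is not the headline
number).

Significance comes from a spin test on the response map
(`pls_spin_test()`, alternative = greater). Gene-level inference uses a
bootstrap over *regions* — the observational units of this regression —
with replacement (`bootstrap_gene_weights()`): each replicate refits PLS1,
aligns its sign to the original weights (all signs flip when the dot
product is negative), and each gene gets `z = weight / bootstrap SE`, with
BH-FDR over two-sided normal p-values. Gene lists (`extract_gene_lists()`)
apply both a |Z| threshold (default 5) and an FDR threshold (default
0.005); with many bootstrap replicates the two nearly coincide, and both
are applied because both conventions are in circulation.

## Gene-list statistics

- `dge_spearman_test()` correlates PLS gene weights with published
  differential-expression effects over the genes common to one direction
  ("up" or "down"). The null relabels direction assignments across all
  differentially expressed genes, preserving per-direction counts (the
  alternative that does not preserve counts is noted in metadata but not
  default). Spearman is used because DGE effect sizes carry outliers.
- `celltype_overlap_test()` counts genes shared with each cell-class set
  and compares to size-matched random sets drawn from the background
  universe — the cell set is resampled, matching the wording of the
  procedure it reproduces; resampling the gene list instead is available
  behind a flag for sensitivity analysis. The background defaults to the
  post-filtering gene universe of the expression stage, and is explicitly
  configurable because overlap statistics are background-sensitive.
- `list_overlap_or()` summarizes the overlap of two gene lists over a
  background universe as the sample odds ratio `ad/bc` (Haldane 0.5
  correction when a cell is zero) with a two-sided Fisher exact p.

## The synthetic-data generator

Every input the pipeline consumes can be generated with known planted
structure, so parameter recovery and null calibration are testable end to
end. All spatial structure uses Gaussian random fields with a
squared-exponential kernel on great-circle distance between parcel
centroids (`sample_smooth_fields()`); the `smoothness` parameter is the
kernel length-scale in radians. Spin tests are only meaningful on
autocorrelated maps, so every generated map is smooth at a controllable
scale. The real spatial autocorrelation structure of MSN maps is unknown;
the kernel is a modelling stand-in, not an inference about data.

**Cohorts.** Each region carries a latent alignment `rho` in (−1, 1) with a
shared "hub" feature-profile direction; a region's feature vector is
`rho * u + sqrt(1 - rho^2) * idio_sd * w + noise`, where the idiosyncratic
texture `w` is fixed across subjects (morphometric profiles are largely
stable across people) and per-subject measurement noise has SD `noise_sd`
(default 0.2). Between-region correlations are then approximately
`rho_i * rho_j`, so MSN strength increases monotonically with alignment.
The group effect is planted by shifting the Fisher-z alignment in effect
regions for cases by `effect_size * noise_sd * direction`: a latent
feature-profile rotation whose strength consequence is emergent and
sign-controlled, keeping the MSN computation honest — strengths are never
shifted directly. Two design details matter and were found the hard way:

- A naive "shift toward a common profile" plant is *exactly cancelled* by
  the z-score + Pearson double centering and produces no strength response;
  the rank-1 alignment model is the simplest latent structure that
  survives it.
- The baseline alignment field is mean-centred before scaling, because a
  smooth field on the sphere has few effective degrees of freedom and its
  random spatial mean would otherwise occasionally null the global
  alignment level that the strength response depends on. With the field
  centred, `align_mean` (default 0.6 on the Fisher-z scale) really is the
  mean alignment.

Because strength sums over all regions, a planted perturbation propagates
into non-effect regions (and does so in real data too — similarity is a
global statistic). Specificity of the t-map is therefore not a design
target; recovery criteria are stated over planted regions only.

Covariates (age, sex, education) act through their own smooth regional
maps with standardized effect sizes, so covariate adjustment is exercised
rather than decorative. Defaults: `align_sd = 0.5`, `idio_sd = 0.5`,
`smoothness = 0.6` rad; the participant table carries plausible
demographics plus depression/anxiety scores and intracranial volume.

**Expression.** Gene profiles are smooth fields (baseline SD 1.5 on a
log2-like scale around 7); planted genes add `signal_strength * loading`
times the standardized signal map on the left hemisphere, with per-gene
signed loadings drawn once (magnitudes 0.5–1.5) so planted genes vary in
effect. One probe per gene is high-fidelity; extra probes mix in a decoy
gene's profile with probe-specific bias and noise, a configurable fraction
are generated far below background (to exercise the intensity filter) or
with broken annotations (to exercise re-annotation). Samples sit at
donor-jittered positions near `radius * centroid` (radius 75, jitter SD
0.5 — the same "mm-like" units as the 2.0 assignment distance); small
fractions are placed in the right hemisphere or beyond the assignment
distance on purpose. Detection calls are absent below the donor-specific
20th-percentile intensity by default; any monotone background rule
suffices for testing the 50% filter, and the quantile is configurable.

The pipeline plants the expression signal along the *kernel-smoothed*
effect map (length-scale 0.15 rad) rather than the raw indicator: a sparse
indicator would concentrate the PLS cross-covariance on a handful of
regions and explode the bootstrap SEs, which no realistic transcriptomic
gradient does. Postmortem differential-expression tables are generated
with effects *anti*-rank-correlated with planted loadings (strength
`corr_strength`), mirroring the direction convention in which genes
upregulated in cases pair with decreased similarity; cell-type sets draw a
configurable fraction of each class from the planted genes and are not
forced to be disjoint, since real marker compilations overlap.

What the generator does **not** emulate: realistic cortical geometry or
surface meshes, realistic gene–gene co-expression topology beyond smooth
fields plus a planted signal, batch structure between donors beyond an
additive shift, or site effects. Passing tests therefore demonstrate the
statistical machinery is correct and calibrated on data with known truth —
not that any particular biological finding would replicate.

## Problem sizes and reproducibility

Two shipped configurations define the study conditions. `demo_config()`:
40 parcels per hemisphere, 24+24 subjects, 400 genes (40 planted), 4
donors, 199 spins, 200 bootstrap replicates — it exercises every stage in
a few seconds. `strong_signal_config()`: 154 parcels per hemisphere, 60+60
subjects, 2000 genes with 5% planted, 6 donors × 400 samples, 999 spins,
1000 bootstrap replicates, planted effect size 4 in 32 regions — the
documented strong-signal scenario under which the recovery checks in the
test suite run (≥90% of planted regions at FDR < 0.05, ≥80% of planted
genes in the correct PLS1 list at |Z| > 5, spin p ≤ 0.01). Null
calibration in the acceptance tests uses 200 replicates for each
permutation test and 100 null cohorts for the regional FDR check.

Every stochastic stage takes an explicit seed; `run_pipeline()` derives
per-stage seeds from the master seed in its configuration, refuses configs
without one, and writes a manifest with a configuration hash. Two runs of
the same configuration are byte-identical, which the test suite asserts
file by file.

There is deliberately no shell command-line wrapper: this package is an
analysis library whose natural interface is R, and orchestration is
covered by the exported stage functions plus `run_pipeline()` and
`validate_inputs()` with YAML configurations. A shell wrapper would add a
surface without adding capability.

## Known limitations

- The rank-1 alignment model yields realistic-looking strength maps but a
  single latent dimension; real morphometric similarity has richer
  structure that the generator does not attempt.
- Greedy matching after rotation only approximates a true rotation of the
  parcellation; calibration of the resulting null is checked empirically
  (uniform p-values on smooth nulls) rather than guaranteed analytically.
- The DS cut-off, intensity-pooling convention, and symptom-correlation
  cohort are genuinely underdetermined by the sources this design follows;
  all three are configuration, with defaults documented above.
- Bootstrap SEs assume regions are exchangeable units; spatial
  autocorrelation makes the effective number of regions smaller than the
  nominal one, so gene Z-scores should be read as rankings more than as
  calibrated test statistics — which is how they are used.
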