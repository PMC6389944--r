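---
title: "Penetrance-weighted tractometry: model, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penetrance-weighted tractometry: model, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penetract)
```

## The problem

Pathogenic copy number variants (CNVs) are among the most penetrant genetic
risk factors for schizophrenia and developmental delay, but individual CNVs
are rare: a single-variant neuroimaging study rarely exceeds a handful of
carriers. `penetract` implements a *penetrance-weighted* analysis that pools
carriers of many different CNVs and regresses brain features on each
variant's *penetrance* — the probability that a carrier manifests
schizophrenia (P~Sz~) or intellectual disability / developmental delay /
autism (P~DD~) — rather than on a binary carrier label. Penetrance acts as a
continuous dose, so convergent neurodevelopmental effects shared across
variants become detectable in a cohort of realistic size (the reference
design has 21 carriers across 12 CNV classes and 15 controls).

The imaging features are tractography-derived: per-bundle streamline *shape
descriptors*, bundle *volumes* from voxel traversal, and bundle *medians* of
scalar microstructure maps (FA, MD, AD, RD from the diffusion tensor; R1 and
T1 from relaxometry; ICVF, ISOF, ODI from the NODDI tissue model).

## The model, stage by stage

### Streamline shape descriptors

1. Subject tractograms are affinely normalised to a common template space
   (`apply_affine()`), preserving shape while removing positional and
   orientational variance.
2. Each streamline is re-parameterised to 30 knot points at equal arc-length
   spacing along a natural cubic spline through its points
   (`reparameterize()`). Arc length is measured on a 10x-oversampled
   polyline along the spline; endpoints are preserved.
3. Streamlines are canonically oriented (`canonical_orient()`): a streamline
   is reversed when its endpoint displacement projects negatively on the
   anterior axis (0, 1, 0), with ties broken by the superior axis then the
   left–right axis. The orientation convention is our choice — the
   alternative of letting clustering absorb orientation flips doubles the
   number of shape modes spent on mirror pairs, and a deterministic
   convention makes concatenated coordinates comparable across subjects.
4. The knot centroid is subtracted (translation invariance) and coordinates
   are concatenated knot-major into a 90-vector (`to_feature_vector()`).
   Any consistent concatenation order is statistically equivalent; knot-major
   is frozen for reproducibility.
5. PCA of the pooled feature vectors (`fit_shape_pca()`) yields a common
   orthonormal *shape basis* across all subjects. By default the first seven
   eigenvectors are retained, which in the reference design capture about
   95% of shape variance; `variance_target` alternatively selects the
   smallest basis reaching a variance fraction. Eigenvector signs are fixed
   (largest-magnitude element positive) so runs are comparable; descriptor
   signs remain arbitrary up to this convention and all tests are two-sided.
6. Projection weights are clustered with k-means (`cluster_weights()`;
   k-means++ initialisation, 10 restarts, best inertia kept, Lloyd
   iterations). The faithful setting is K = 800; desk-scale runs default to
   K = 100 so that clusters remain populated with hundreds rather than
   hundreds of thousands of streamlines. Cluster membership histograms per
   subject are available (`membership_histogram()`); the default tested
   descriptors are per-bundle mean weights (below), with histograms exposed
   for completeness since the two summaries coincide in expectation for
   well-separated bundles.
7. Clusters take bundle labels by majority vote over a labelled reference
   set (`train_bundle_map()`), and new streamlines inherit the label of
   their nearest centroid (`segment_bundles()`), restricted to a 19-bundle
   vocabulary (bilateral arcuate, uncinate, inferior/superior longitudinal
   and fronto-occipital fasciculi, dorsal and parahippocampal cingulum,
   fornix branches, corpus callosum splenium/body/genu) plus "unassigned".
8. The *shape descriptor* of bundle b, component j, for one subject is the
   mean projection weight j over the subject's streamlines in b
   (`shape_descriptors()`). Bundles with fewer than `min_streamlines`
   (default 5) members give missing values, never zeros. With 19 bundles and
   7 components the default configuration yields 133 shape descriptors; the
   descriptor count is configuration-determined (bundles x components) and
   is exposed as such rather than hard-coded.

### Tractometry

Bundle volume is the number of distinct voxels traversed by the bundle's
streamlines times the voxel volume (`bundle_volume()`). Traversal is
approximated by dense point sampling at steps no larger than a quarter of
the smallest voxel edge — halving the step changes volumes by under 2% on
smooth bundles, which is the accuracy regime that matters here, at far lower
cost than exact segment–box intersection. Microstructure is summarised as
the median of trilinear map samples pooled over all streamline points of the
bundle (`sample_bundle_median()`); the median of pooled points (rather than
a median of per-streamline medians) is frozen and documented. Up to 10% of
points may fall outside a map and are dropped with a logged count; more is
an error.

The feature matrix (`assemble_features()`) tags every column with a family
(`shape`, `tract_volume`, `microstructure`) and two covariate-policy flags
(volumetric, diffusion-derived). The default configuration yields
19 x (9 metrics + volume) = 190 microstructural variables. The source
material names only eight microstructural measures while counting nine; we
default the ninth to T1 and leave it configurable.

### Penetrance scores

The built-in table ships the penetrance scores of the 12 study CNVs
(percent) for both phenotypes, keyed by CNV label and hg19 locus. Two
entries are typographically ambiguous in the source material and are flagged
`transcription_uncertain` in the resource; the shipped values are the unique
reading under which the per-CNV rows reproduce the printed carrier-weighted
summary means (5.4 and 36.7) and gender totals exactly.
`compute_penetrance()` implements the underlying Bayes rate: the CNV rate in
cases times disease prevalence over the rate in the general population,
clamped at 100%. Prevalence is an explicit parameter (the cited derivation
includes it; setting it to 1 recovers the plain frequency ratio sometimes
quoted).

### Statistics

Each feature is regressed on a penetrance score by OLS with the study's
covariate policy: age and gender always, total brain volume for volumetric
features, motion for diffusion-derived features (`fit_glm()`). Family-wise
error within a variable family — one family per microstructural metric
across the 19 bundles, tract volumes as one family, shape descriptors as one
family — is controlled by max-|t| permutation (`permutation_correct()`,
B = 5000 faithful / 1000 desk) with the Freedman–Lane scheme: residuals of
the nuisance-only model are permuted so exchangeability respects the
covariates. Freedman–Lane is our choice where the source is silent on the
exchangeability scheme; it is the standard choice with nuisance covariates.
The corrected p uses the +1 estimator, `(1 + #{max|t|_b >= |t|}) / (B + 1)`,
and is floored at the parametric p so the contract `p_corr >= p` holds
exactly.

Supporting analyses: the binary carrier model (`binary_model()`) verifies
that effects track dose rather than CNV presence; leave-one-CNV-out
refitting (`loo_cnv_sensitivity()`) quantifies which variants drive an
effect; a global PCA of all imaging variables with per-component tests
(`global_pca_test()`, first min(34, n-2) components, z-scored columns,
mean-imputation flagged) finds multivariate patterns; and a post-hoc test on
the corpus callosum body/splenium volume ratio (`cc_ratio_test()`) probes
volumetric interrelationships — the ratio is dimensionless, so total brain
volume is dropped from its covariates while motion is kept. The Spearman
correlation between the two scores (`score_correlation()`) uses midranks,
an exact permutation p for n <= 10 and the t-approximation otherwise, and is
reported both for the full cohort and carriers only, since either convention
is defensible.

Degenerate fits (zero residual variance) are flagged and given the minimum
representable p rather than zero; permutation p-values are reproducible
bit-exact given (seed, B).

## The synthetic cohort generator

No individual MRI is distributable, so the package ships a generator
(`simulation_design()`, `simulate_study()`) that emulates the statistical
structure the analysis assumes, making every downstream stage testable:

* **Cohort**: CNV class counts as in the reference table (21 carriers, 15
  controls); gender matched to the printed per-CNV counts; age ~ N(38, 12^2)
  years truncated to 18–65; total brain volume ~ N(1.1e6, 1e5^2) mm^3;
  motion index half-normal. These covariate distributions are our choice at
  the scale of the printed demographics.
* **Bundles**: parametric arcs `p(t) = (1-t)p0 + t p1 + bow * amp * sin(pi t)`
  for all 19 vocabulary bundles, in template-space mm. The default
  three-bundle set (left dorsal cingulum, CC splenium, CC body) is the
  smallest that exercises segmentation and the corpus-callosum analyses. The
  cingulum is a sagittal-plane arc whose superior bow amplitude is
  `a0 + beta_a * P + noise` with a0 = 15 mm, beta_a = 0.05 mm per penetrance
  percent, between-subject amplitude noise 1 mm — higher penetrance, greater
  anterior–posterior curvature. Streamlines get a constant cross-sectional
  offset (sd 2 mm) and per-point jitter (sd 0.5 mm).
* **Maps**: background at the metric's base value; voxels traversed by the
  bundle (dilated by one voxel so trilinear samples at streamline points are
  interior to the effect region) hold `base + slope * P` plus one
  subject-level draw (sd 0.02 for ICVF) and per-voxel noise (sd 0.01),
  truncated to the metric's physical range. The default dose effect is on
  ICVF only: slope -0.002 per percent, so P = 88 shifts the bundle median
  from 0.60 to about 0.42.
* **Seeds**: one master seed; per-subject and per-stage streams are derived
  by a fixed hash, so identical seeds give bit-identical cohorts, bundles
  and maps.

What the generator does *not* emulate: MRI physics and acquisition noise,
tractography errors (spurious or premature streamlines), registration
imperfections, anatomical variability of real bundle geometry, and
correlated multi-metric microstructure. Passing tests therefore demonstrate
that the pipeline's inference machinery is correct and well calibrated under
the designed data-generating process — not that the biological effects would
be detectable in any particular real acquisition.

## Validation and problem sizes

The test suite validates the package at desk scale on one CPU:

* **Oracle equivalence**: PCA against a dense eigendecomposition of the
  covariance; k-means against exhaustive Lloyd iterations from the identical
  initialisation; the GLM against explicit normal equations; Spearman
  against rank-then-Pearson — all to 1e-8 on fixtures of at most 50 rows.
* **Calibration**: the family-wise error of the max-|t| Freedman–Lane
  procedure over a 19-feature family at alpha = 0.05, measured on 200 null
  cohorts (all effect slopes zero) at B = 1000, must lie in the central 95%
  binomial band around 0.05.
* **Recovery**: on 50 simulated cohorts of n = 36 at the default effect
  sizes and noise, the cingulum shape descriptor family and the cingulum
  ICVF median must each reach p_corr <= 0.05 for P_DD in at least 80% of
  cohorts, and the penetrance model must out-rank the binary carrier model
  by |t| in at least 80% — the qualitative dose-response contrast the design
  is built around. Recovery runs use the generator's true bundle labels for
  descriptor grouping; segmentation itself is validated separately (>= 95%
  accuracy on the three-bundle fixture; in practice ~100%).
* **End-to-end**: the desk profile (19 bundles, 10 streamlines per bundle,
  K = 100, B = 1000, 3 mm maps) runs the full pipeline in under a minute and
  reproduces the structural contract of 190 microstructural variables, with
  bit-identical outputs on re-runs with the same seed.

`scripts/acceptance.R` recomputes all of these quantities from scratch.

## Numerical choices and edge cases

* Cubic splines use natural end conditions; chord-length parameterisation;
  equal-arc inversion by linear interpolation on the oversampled polyline.
* Voxel indices are 0-based and affines map voxel *centres* to mm (the
  NIfTI convention) everywhere, including the TRK reader/writer, which
  converts TrackVis voxel-mm storage through the header affine on the fly.
* k-means restarts that lose a cluster are discarded; ties in the
  cluster-to-bundle majority vote break alphabetically.
* Zero-length streamlines, singular affines, empty cluster maps, empty
  feature families, rank-deficient designs and zero splenium volumes are
  errors; missing bundle cells are NA (with warnings), never silent zeros.
* `K` is clamped to the number of pooled streamlines in desk runs; the
  faithful K = 800 assumes whole-brain tractogram sizes.

## Known limitations

* The shape-descriptor count of the original analysis (194) is not exactly
  reproducible from the published description; the package makes the count
  configuration-determined (bundles x components) and documents it.
* Penetrance scores enter as fixed known constants; uncertainty in the
  penetrance estimates themselves is not propagated.
* The GLM is OLS with two-sided t tests; no mixed models or Bayesian
  alternatives.
* Segmentation quality on real tractograms depends on the labelled
  reference set; the shipped machinery learns the cluster-to-bundle map
  from whatever labelled streamlines it is given and will faithfully
  propagate their biases.
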