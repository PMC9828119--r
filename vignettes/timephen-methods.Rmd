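---
title: "Methods: immune phenotyping, spatial metrics and relapse modelling in timephen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune phenotyping, spatial metrics and relapse modelling in timephen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timephen)
```

## The problem

Low-grade, early-stage (FIGO I–II, G1–G2) endometrioid endometrial carcinomas
mostly have a good prognosis, yet a small fraction of patients relapse, and the
standard risk factors (FIGO stage, tumor grade, lymphovascular space invasion)
identify them poorly. The tumor immune microenvironment (TIME) — how many
CD8+ T-cells, CD68+ macrophages and FOXP3+ regulatory T-cells infiltrate the
tumor, how much PD-1/PD-L1 they and the tumor cells express, and how these
cells are arranged in space — carries additional prognostic signal.

`timephen` implements the full analysis chain for this question on
tissue-microarray (TMA) cohorts profiled by multiplex immunofluorescence:

1. **cell tables → per-core profiles** (densities in cells/mm², marker
   fractions, tumor–stroma gradients);
2. **profiles → immune phenotypes** (hierarchical clustering, bootstrap
   Jaccard stability, rule-based naming);
3. **cells → spatial interaction metrics** (radius neighbor counts);
4. **cores → patients → relapse models** (carriage aggregation, exhaustive
   feature-subset logistic regression with repeated cross-validation,
   ROC/Youden stratification, bootstrap model comparison, Kaplan–Meier
   curves);
5. **a CART surrogate** mapping intra-tumoral single-marker densities to
   phenotypes, emulating what single-marker IHC could recover.

A seeded synthetic cohort generator with known ground truth makes every stage
testable without access to patient data.

## Data model

A cohort is three tables. `cells` has one row per segmented cell: `core_id`,
`x_um`/`y_um` (micrometers, origin at the top-left corner of the core's
bounding box, y increasing downward — the image convention), a
`tumor`/`stroma` compartment label, and six boolean marker channels (CK, CD8,
CD68, FOXP3, PD-1, PD-L1). At most one of the four lineage markers
(CK/CD8/CD68/FOXP3) may be positive per cell; PD-1 and PD-L1 may co-occur with
any lineage. Lineage co-positive cells are a hard validation error by default
because upstream phenotyping should already have resolved them; since real
exports sometimes contain them anyway, `validate_cohort(resolve_lineage =
TRUE)` resolves by the priority CK > CD8 > CD68 > FOXP3 (epithelial identity
dominates, then the more abundant immune lineages).

`cores` records `patient_id`, diameter (default 1.2 mm) and area (default
π·0.6² ≈ 1.13097 mm²); at most two cores per patient. `patients` holds the
clinical covariates (FIGO stage, grade, LVSI, adjuvant radiotherapy,
MMRP/POLE/CTNNB1 status with explicit `unknown` levels), the relapse indicator
and type, and follow-up in months.

Readers are dialect-driven (`canonical_dialect()`, `inform_dialect()`,
`read_dialect()` for YAML): a dialect maps source headers and value encodings
(0/1, true/false, +/−) onto this schema, and malformed rows are rejected with
row-level diagnostics rather than silently dropped.

## Per-core features

`population_density()` divides the count of cells matching a marker
conjunction within a scope (tumor, stroma, whole) by the scope's area.
Compartment areas are not part of a per-cell export, so they are approximated
as (compartment cell count / total cell count) × core area, with an override
for supplied mask areas. This keeps counts additive (tumor + stroma = whole)
and is adequate for between-core contrasts; it does bias per-compartment
densities when cellularity differs strongly between compartments, which is
one reason the package reports whole-core OMDs for cluster characterization.

`marker_fraction()` returns the conditional positive fraction (e.g. PD-1
among CD8+ cells in the tumor compartment); an empty base population yields
`NA`, never 0 — absence of evidence is missing information.
`compartment_gradient()` is 100·(tumor fraction − stroma fraction) percentage
points, positive when expression is higher inside the tumor.

The canonical feature matrix (`build_feature_matrix()`) has 17 variables:
densities of CD8, CD68, FOXP3, CD8+PD-1+ and CD68+PD-L1+ in tumor and stroma
scope, CK and CK+PD-L1+ densities in tumor scope (CK+ cells define the tumor
compartment, so stromal CK densities are not meaningful), plus the five
conditional fractions. The reference clustering pipeline uses the 12 density
variables only (`include_fractions = FALSE`): the fractions have undefined
values on cores lacking the base population, and clustering on densities
avoids putting imputed values into the distance. When fractions are requested,
missing values are imputed with the across-core median of the variable.

## Phenotype discovery

Features are z-scaled column-wise (`scale_features()`, population-SD
convention, zero-variance columns zeroed with a warning) and clustered with
Ward linkage (`ward.D2`) on Euclidean distances. Neither the linkage nor the
metric nor a k-selection criterion is uniquely standard in this setting; Ward
on z-scaled densities is the common choice for density heatmap clustering and
is pinned for determinism. k is pinned to 5 in the reference pipeline;
`choose_k()` is available for sensitivity analysis and selects k by maximum
mean silhouette, reporting mean bootstrap Jaccard per k as a secondary
diagnostic, and flags "no support for k > 1" when the best silhouette is
below 0.25 (the conventional weak-structure threshold).

Stability (`bootstrap_jaccard()`) follows the clusterboot recipe: resample
rows with replacement B = 100 times, recluster, match each original cluster to
the bootstrap cluster maximizing |A∩B|/|A∪B| over the distinct resampled
points, score 0 when a cluster vanishes from a resample, and average per
original cluster. Means above 0.5 are read as fair robustness.

`name_clusters()` applies ordered rules to the per-cluster whole-core OMD
(overall median density) table: the cluster with the highest CD8 OMD is
**TIL-rich**; among the rest, highest CK+PD-L1+ OMD is **immune-exclusion**;
then highest CD68 OMD is **macrophage-rich**; then highest FOXP3 OMD is
**FOXP3-rich**; the remainder is **immune-desert** provided it also has the
lowest total immune OMD (CD8 + CD68 + FOXP3), otherwise it stays unnamed with
a warning. Ties break toward the larger cluster. The rule order puts the two
outcome-relevant phenotypes first so they are claimed by their defining
feature before the greedier CD68/FOXP3 rules run.

## Spatial metrics

Two cells are "in close contact" when their Euclidean distance is at most a
radius r (closed ball, so a pair exactly at r is adjacent — pinned so the
grid implementation can be checked against brute force exactly). The default
r = 20 µm approximates one-to-two cell diameters, the scale at which membrane
contact and short-range signalling are plausible; the radius is stamped into
every result and is configurable. Neighbor search hashes cells into a uniform
grid with bucket size r and scans the 3×3 bucket neighborhood; results are
exactly those of the O(n²) scan, which the tests assert on random instances.

`mean_neighbor_count()` reports, for a source/target population pair, the
mean number of target cells within r of each source cell (`NA` with no source
cells; a cell matching both predicates never counts itself). CD8 "spatial
clustering" is the reflexive query (CD8 around CD8). `interaction_matrix()`
assembles all pairs; it is not symmetric (normalization differs by source),
but edge counts are conserved: M[a,b]·n_a = M[b,a]·n_b.

## Patient aggregation and outcome modelling

`aggregate_patients()` turns core assignments into patient-level **carriage**
(≥ 1 core of a phenotype) and **purity** (all analyzed cores share the
phenotype; single-core patients have purity = carriage). Patients losing
follow-up before 36 months without relapse are excluded
(`filter_followup()`); relapsed patients are always retained.

Covariates are encoded as FIGO ∈ {IA = 0, IB = 1, II = 2} (ordered severity),
grade as a G2 indicator, LVSI as 0/1; immune variables enter as carriage (and
optionally purity) indicators.

`fit_logistic()` is a plain IRLS maximum-likelihood fit (convergence when the
largest coefficient change is below 1e-8, at most 100 iterations). With rare
events and small strata, quasi-separation is routine; non-convergence or
runaway coefficients trigger a refit with a tiny ridge (1e-6) and the fit is
flagged. The ridge is small enough to leave identifiable coefficients
untouched (the tests compare against `glm()` to 1e-8) while keeping separated
fits finite.

`exhaustive_search()` scores every non-empty subset of up to 20 candidate
features by mean misclassification error under 20 repeats of stratified
2-fold cross-validation, with held-out patients classified at probability
0.5. Fold assignments are drawn once per repeat and shared across subsets, so
subset comparisons are paired. Ties go to fewer features, then lexicographic
order. The classification cut-off stays at 0.5 during selection; the Youden
cut-off is applied only afterwards, for risk stratification of the selected
model — mixing the two would leak the stratification objective into
selection.

`roc_auc()` uses the Mann–Whitney identity with half-credit for ties;
`youden_stratify()` scans every distinct score, maximizes
sensitivity + specificity − 1 and breaks ties toward higher specificity (in a
low-relapse-rate population, specificity is the scarce resource).
`ppv_npv_from_rates()` is the Bayes conversion from sensitivity, specificity
and prevalence. `bootstrap_compare()` draws B = 10,000 paired patient
resamples (redrawing any replicate that loses an outcome class) and counts
strict AUC wins; exact AUC ties count for neither model. Kaplan–Meier curves
and the log-rank test are delegated to the survival package; Fisher exact
enrichment tests to `fisher.test()` (with a seeded Monte-Carlo fallback for
large tables, flagged in the output). `subgroup_evaluate()` scores already
fitted models within strata (no refitting), flagging strata with fewer than
5 events as low-power and skipping single-class strata.

## The CART surrogate

`fit_cart()` wraps rpart (Gini impurity, minimum leaf 5, maximum depth 5,
growth threshold cp = 0.01) and then applies 1-SE cost-complexity pruning
against the internal 10-fold cross-validation, with a fixed internal fold
seed so the fit is deterministic given the data. On label-free noise this
collapses the large majority of fits to a stump, though chance
cross-validation dips retain some structure in a minority of replicates —
complexity control on pure noise is a majority property, not a guarantee.
`simplified_tree()` restricts the features to intra-tumoral CD8 and PD-L1,
the two-marker panel; by construction its resubstitution performance cannot
exceed the full tree's. `per_class_precision()` reports TP/(TP+FP) per
phenotype on the fitting data (resubstitution, as appropriate for a screening
analysis; the mode is stamped in the object) and flags classes the tree never
predicts.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults are the study
conditions the rest of the package is validated under.

**Archetypes.** Five immune archetypes carry whole-core density targets and
conditional marker rates (`default_archetypes()`). The four published
whole-core OMD anchors are used verbatim as density targets: immune-desert
CD8 109.63 and CD68 134.32, TIL-rich CD8 695.45, immune-exclusion CD8 106.87
cells/mm², plus the immune-exclusion CK+PD-L1+ density 6445.38 cells/mm²
(realized as CK density 6445.38/0.8 with PD-L1|CK = 0.8). Every other number
is an invented default — chosen once to reproduce the qualitative contrasts
the phenotypes are defined by (TIL-rich has the highest PD-1|CD8 and a
positive tumor–stroma PD-1 gradient; FOXP3-rich is the exception with a
stromal-leaning gradient; immune-exclusion has the strongest PD-L1|CD68
tumor–stroma polarization; macrophage-rich has the highest CD68) — and
flagged `invented` in `archetype_provenance()`.

**Core geometry.** A core is a 1.2-mm disc. Tumor (CK+) cells follow a
Thomas-type parent–offspring process: Poisson parents uniform in the disc,
Gaussian offspring truncated to a circular nest around each parent; the nest
union is the tumor mask, and nest radii are solved so summed nest area
(overlap ignored) matches the archetype's tumor area fraction. The
immune-exclusion archetype gets more parents (22 vs 10) and therefore
tighter nests at a higher tumor fraction (0.60 vs 0.40–0.45), planting the
higher tumor-cell packing that the spatial module must detect. Immune cells
are homogeneous Poisson over the disc at whole-core target intensity and
inherit the compartment of the mask region containing them; truncated
redrawing keeps every population's expected count equal to density × area
exactly, which the Poisson-sanity tests exploit.

**Patients and outcome.** Default 235 patients; each contributes two cores
with probability 169/235 (expected 404 cores). Core archetypes are drawn from
the mixture (279, 18, 78, 14, 15)/404; a second core repeats the first's
archetype with probability 0.7, mirroring the observation that desert and
exclusion patients are usually "pure" while the rarer phenotypes co-occur
with others. Relapse follows
logit p = β₀ + β_c·carriage + β_p·purity (immune-exclusion), with
β₀ = logit(0.012), mixed-carrier probability 0.25, and the purity increment
solved in closed form (`solve_purity_beta()`) so the **average** relapse
probability among exclusion carriers is exactly 0.48 under the default
mixture and carriage geometry. The purity term reflects the reported
dose–response (relapse more likely when both cores are immune-exclusion) and
is also what makes model selection by misclassification error well-posed: a
carriage-only model's carrier probability (0.48) never crosses the 0.5
classification cut-off, whereas pure carriers (p ≈ 0.58) do. Relapse times
are lognormal(log 31, 0.72) months (median 31, interquartile range ≈ 18–50);
non-relapse follow-up is 120-capped normal(125, 30) with a 6.7% short
(< 36 months) fraction to exercise the follow-up filter. Clinical covariates
are drawn at the cohort's reported margins (FIGO IA 80%, G1 70%, LVSI 12%,
adjuvant RT none 64.3%/unknown 9%, MMRP-deficient 15.8%, POLE-mutated 2.3%)
and — deliberately — carry no planted effect on relapse, so the reference
model is an honest baseline.

`simulate_patient_features()` exposes the patient-level margin of the same
model (archetype draws, covariates, outcome) without cell placement, for
studies that need many replicate cohorts cheaply; with the same seed it
reproduces exactly the patient table of `generate_cohort()`.

**What the generator does not emulate.** Segmentation and classification
errors, staining batch effects, continuous marker intensities, within-core
immune hotspots or peritumoral gradients (immune cells are spatially
homogeneous per compartment), correlation between populations beyond the
archetype structure, and competing-risk censoring. Passing the recovery tests
therefore shows the pipeline is correct and well-calibrated under a
realistic-scale, cleanly separated data-generating process — not that
real-cohort effect sizes or error rates will be matched.

## Problem sizes and seeds used in the tests

The acceptance-style checks run on the default 235-patient/≈404-core cohort
for clustering recovery, naming, stability (B = 100), coefficient recovery
and the 10,000-replicate bootstrap model comparison; selection consistency
uses 50 replicate patient-level cohorts of n = 1000; the spatial contrast
uses 50 core pairs; oracle-equivalence suites use 150–500-point random
instances. Module tests use smaller cohorts (4–150 patients) where the
property under test does not need cohort scale. All stochastic tests fix
their seeds.

## Known limitations

* Compartment areas are approximated from cell counts unless mask areas are
  supplied; per-compartment densities inherit that approximation.
* The spatial layer implements radius counts only — no Ripley's K, pair
  correlation, or permutation-based interaction enrichment.
* `exhaustive_search()` is exponential in the candidate count (guarded at
  20) and refits every subset 40 times; it is meant for the small curated
  candidate sets used here.
* The outcome layer models relapse as a binary endpoint with a follow-up
  filter, plus Kaplan–Meier description; it is not a time-to-event
  (Cox) model.
* Phenotype naming assumes the five canonical archetypes; partitions of
  different biology will be partially named or left unnamed.
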