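# timephen

Tumor immune microenvironment (TIME) phenotyping and relapse modelling for
tissue-microarray (TMA) cohorts profiled by multiplex immunofluorescence.

Low-grade, early-stage (FIGO I–II, G1–G2) endometrioid endometrial carcinomas
mostly follow a benign course, but 5–10% of patients relapse and the standard
clinicopathological risk factors — FIGO stage, tumor grade, lymphovascular
space invasion (LVSI) — identify them poorly. The immune contexture of the
tumor carries additional signal: how densely CD8+ T-cells, CD68+ macrophages
and FOXP3+ regulatory T-cells infiltrate tumor and stroma, how much
PD-1/PD-L1 they and the CK+ tumor cells express, and how those cells are
arranged in space. `timephen` is for pathology/immuno-oncology groups who
have per-cell tables from a multiplex-IF imaging pipeline and want to go from
those tables to immune phenotypes, spatial metrics and an immune-optimized
relapse model, with every step testable against a synthetic cohort of known
ground truth.

## What it computes

Starting from three tables (cells, cores, patients; tidyverse-style, every
function takes a data frame or cohort and returns a tibble):

* **Per-core profiles** — population densities `n / A` in cells/mm² per
  compartment scope, conditional marker fractions such as
  `P(PD-1+ | CD8+, tumor)`, and tumor–stroma gradients
  `100·(f_tumor − f_stroma)` percentage points.
* **Immune phenotypes** — Ward (`ward.D2`) hierarchical clustering of
  z-scaled density profiles; per-cluster stability as the mean bootstrap
  Jaccard coefficient `|A∩B| / |A∪B|` over B = 100 resamples
  (clusterboot-style matching); rule-based naming into immune-desert,
  TIL-rich, immune-exclusion, FOXP3-rich and macrophage-rich from the
  per-cluster overall median densities (OMDs).
* **Spatial interaction metrics** — for populations a, b and contact radius
  r (default 20 µm, closed ball), the mean number of b-cells within r of
  each a-cell, via exact grid-hash neighbor search; edge counts satisfy
  `M[a,b]·n_a = M[b,a]·n_b`.
* **Relapse models** — patient-level carriage/purity aggregation; a
  follow-up filter (non-relapsers with < 36 months excluded); IRLS logistic
  regression with a 1e-6 ridge fallback under separation; exhaustive
  feature-subset search scored by mean misclassification under 20× stratified
  2-fold cross-validation; AUC by the Mann–Whitney identity; Youden-index
  risk stratification (`J = sens + spec − 1`); PPV/NPV from
  sensitivity/specificity/prevalence by Bayes' rule; paired bootstrap model
  comparison over 10,000 resamples; Kaplan–Meier curves with log-rank tests;
  Fisher exact enrichment tests.
* **A CART surrogate** — an rpart tree (Gini, min leaf 5, max depth 5,
  cp 0.01 with 1-SE cross-validated pruning) mapping intra-tumoral CD8,
  CD68, FOXP3 and PD-L1 densities to phenotypes, plus a simplified
  CD8/PD-L1-only tree, with per-class precision reporting — a screen for how
  much of the multiplex phenotype single-marker IHC could recover.
* **A synthetic TMA generator** — seeded cohorts with tumor nests from a
  Thomas-type clustered point process, Poisson immune placement at published
  density anchors, five immune archetypes, within-patient phenotype
  correlation, and a logistic relapse model driven by immune-exclusion
  carriage/purity (`?default_archetypes`, `?synthetic_config`). Ground truth
  is returned alongside, so recovery is measurable.

## Worked example

A full pipeline run on the default synthetic cohort (235 patients, ~404
cores, ~2.1M cells; a couple of minutes on one core):

```r
library(timephen)
library(dplyr)

co <- generate_cohort(synthetic_config())      # seeded; truth attached
ph <- phenotype_cohort(co, k = 5, B = 100, seed = 1)
glance(ph)
#>   cluster_index semantic_name    n_cores mean_jaccard   cd8  cd68 foxp3    ck ck_pdl1
#> 1             1 immune_desert        286            1  110.  134.  15.0 3504.    69.9
#> 2             2 immune_exclusion      64            1  109.  201.  19.5 8079.  6452.
#> 3             3 macrophage_rich       28            1  294.  683.  40.7 3494.   864.
#> 4             4 foxp3_rich            15            1  302.  246. 185.  3522.   878.
#> 5             5 til_rich              12            1  706.  248.  39.8 3505.   351.
```

Each row is one discovered phenotype: its core count, bootstrap Jaccard
stability (1 = perfectly stable), and whole-core OMDs in cells/mm². The
immune-desert cluster shows the low densities it is defined by (CD8 110,
CD68 134); immune-exclusion combines low CD8 with a high CK+PD-L1+ density
(6452); TIL-rich has the highest CD8 OMD (706).

```r
pf <- aggregate_patients(tidy(ph), co) |> filter_followup() |> encode_covariates()
#> 216 patients analyzable; 24 relapses

reference <- fit_logistic(pf, "relapse", c("figo_num", "grade_num", "lvsi_num"))
search <- exhaustive_search(pf, "relapse",
  c("figo_num", "grade_num", "lvsi_num",
    "carriage_immune_exclusion", "purity_immune_exclusion"), seed = 1)
search
#> <timephen_search> 31 subsets; best: grade_num + purity_immune_exclusion (CV error 0.0947)

opt <- predict(search$model, pf); ref <- predict(reference, pf)
roc_auc(opt, pf$relapse)$auc   # 0.809
roc_auc(ref, pf$relapse)$auc   # 0.595

bootstrap_compare(opt, ref, pf$relapse, B = 10000, seed = 2)
#> <timephen_boot> A > B in 9994 / 10000 replicates (0 ties)

ys <- youden_stratify(opt, pf$relapse)
#>   cutoff sensitivity specificity   ppv   npv
#>    0.488       0.667       0.938 0.571 0.957

km_estimate(pf$followup_months, pf$relapse,
            ifelse(opt >= ys$cutoff, "high risk", "low risk"))
#> <timephen_km> 2 group(s); log-rank chi-square = 88.521 (p = 5.03e-21)
```

The subset search keeps the immune-exclusion purity indicator, the
immune-optimized model clearly outperforms the clinicopathological reference
(AUC 0.81 vs 0.60; winner in 9,994 of 10,000 paired bootstrap resamples), and
the Youden cut-off yields a high-specificity stratification whose
Kaplan–Meier curves separate sharply.

`autoplot()` methods exist for phenotype tables, ROC curves and KM curves;
`plot_spatial_panel()` shows per-phenotype spatial interaction summaries.

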