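# pyropattern

Pyroptosis — inflammasome/gasdermin-mediated lytic cell death — leaves a
transcriptional footprint in acute myeloid leukemia (AML). Bulk AML
cohorts separate into two reproducible *pyroptosis patterns* over a fixed
40-gene panel: **C1 (ELANE-high)**, with favorable survival, and **C2
(ELANE-low)**, with higher expression of most panel genes (inflammasome
sensors, caspases, granzymes, ESCRT-III members) and worse outcome.
`pyropattern` implements that analysis as a tested, reusable R pipeline
for computational hematologists: subtype discovery, a cross-platform
subtype classifier, projection onto single-cell samples, immune gene-set
enrichment contrasts, and prognostic gene-set selection — exercised end
to end on a bundled synthetic-data generator, so everything runs and is
verified without external downloads.

## Methods at the core

- **Consensus NMF subtyping.** For expression matrix *V* (panel genes ×
  samples), repeated non-negative factorizations *V ≈ WH* (Lee–Seung
  multiplicative updates, Frobenius loss) from random restarts define a
  consensus co-clustering matrix; average-linkage clustering of
  1 − consensus gives the assignment, the cluster number is chosen by
  mean silhouette width *s(i) = (b − a)/max(a, b)*, and C1 is anchored to
  the ELANE-high cluster.
- **Rank-pair classification.** Binary features *x(i,j) = 1{expr_i >
  expr_j}* over all p(p−1)/2 = 780 panel pairs feed a random forest with
  out-of-bag permutation and Gini importance. Because the features
  depend only on within-sample rankings, the trained model transfers
  unchanged across monotone platform distortions (microarray vs
  RNA-seq).
- **Pseudobulk projection.** Malignant-cell counts are summed per
  single-cell sample, CPM-normalized (each column sums to 10⁶), and
  classified with the same rank-pair model.
- **Enrichment and prognosis.** Single-sample gene-set scores use an
  ssGSEA-form weighted Kolmogorov–Smirnov running sum; pattern contrasts
  use a moderated t with empirical-Bayes variance shrinkage and BH FDR;
  prognostic sets are selected by LASSO-Cox at the cross-validated
  deviance minimizer; classical statistics (Mann–Whitney DE, Pearson
  correlation, Wald Cox with Breslow ties, Kaplan–Meier/log-rank, Fisher
  exact, parallel-analysis factor extraction) round out the toolkit.

## Worked example

```r
library(pyropattern)

# a synthetic two-pattern cohort: 40 panel genes x (77 + 55) samples
co <- generate_cohort(cohort_params(), seed = 1)
dim(co$expr)
#> [1]  40 132

# consensus NMF at k = 2: sizes, cohesion, survival split
fit <- nmf_factorize(co$expr, k = 2, n_restarts = 30, seed = 1)
table(fit$assignment$subtype)
#> C1 C2
#> 76 56
round(fit$mean_silhouette, 3)
#> [1] 0.947
sum(mannwhitney_de(co$expr, fit$assignment)$q < 0.05)
#> [1] 19
signif(km_logrank(co$surv, fit$assignment)$p, 3)
#> [1] 0.0139

# train the rank-pair forest, transfer across a noisy monotone platform
model <- train_classifier(pair_features(co$expr, pyroptosis_panel()),
                          fit$assignment, seed = 1)
new <- generate_cohort(cohort_params(), seed = 2)
shifted <- platform_shift(new$expr,
                          platform_spec("monotone-nonlinear", gain = 1.5,
                                        curvature = 1.3, pernoise_sd = 0.3),
                          seed = 2)
pred <- predict(model, pair_features(shifted, pyroptosis_panel()))
round(pair_auc(pred$score, new$truth$subtype), 3)
#> [1] 1
```

The cohort splits 76/56 with mean silhouette 0.947; the Mann–Whitney
screen recovers the 19-gene differential signature; the ELANE-low
pattern shows significantly worse survival (log-rank p = 0.014); and the
classifier keeps AUC 1.0 on an independent cohort pushed through a noisy
nonlinear platform shift.

## The analysis workflow

Numbered drivers under `analysis/` replay the full study on simulated
inputs and write their tables under `results/`:

| script | stage |
|---|---|
| `01_simulate_cohorts.R` | discovery/validation cohorts, single-cell data, gene sets |
| `02_subtype_discovery.R` | k selection, consensus assignment, KM and Fisher contrasts |
| `03_panel_statistics.R` | DE signature, correlations, Cox, factor analysis |
| `04_rank_pair_classifier.R` | forest training, importance, cross-platform AUC |
| `05_single_cell_projection.R` | pseudobulk CPM, pattern assignment, cell-type contrasts |
| `06_immune_enrichment.R` | ssGSEA scores, moderated-t contrasts, intersection, LASSO, ORA |
| `07_hub_genes.R` | degree-based hub ranking in PPI clusters |

Run them in order from the repository root:
`for f in analysis/0*.R; do Rscript "$f"; done`

A single-call alternative is `run_full(list(seed = 1))`, which executes
the same stages from one configuration and writes a `summary.json` of
headline numbers.

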