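# panspecies

Cross-species transfer evaluation and spatial immune prognostics for
single-cell H&E pathology.

AI cell classifiers for histology are almost always trained on human tumours.
Veterinary pathologists and comparative-oncology researchers who want to use
them on dogs, Tasmanian devils, reptiles or birds face two questions this
package answers with code:

1. **Will the classifier transfer?** Nuclear morphology is partly conserved
   across species. The package extracts 27 morphometric and staining features
   per nucleus, embeds them in a 2-D *morphospace* (exact t-SNE, perplexity
   50), and scores how much of an animal cell class's morphospace lies inside
   its human counterpart's — the *morphospace overlap* (`port_overlap()`), a
   quantile-ladder interval-intersection score multiplied across the two
   embedding dimensions. High counterpart overlap predicts high balanced
   classification accuracy (BCAcc), so the score can triage samples before
   any classification is attempted.

2. **Is the classifier's output prognostic?** From classified cell positions
   the package computes lymphocyte relative abundance and the quadrat-based
   Morisita–Horn colocalisation between cancer cells and lymphocytes,

   MH = 2 Σᵢ xᵢyᵢ / [(Σᵢ xᵢ²/X² + Σᵢ yᵢ²/Y²) · X · Y],

   and feeds the ×100-scaled score into multivariate Cox
   proportional-hazards models (with age and lymphocyte %, VIF < 5 screen),
   lower-quartile dichotomisation and Kaplan–Meier curves.

Evaluation follows the balanced-accuracy convention: per class,
BCAcc = (sensitivity + specificity)/2 one-vs-rest; *overall* BCAcc is the
mean over cancer, lymphocyte and stromal cells. Annotations are matched to
detected centroids greedily within 1.824 µm (4 px at 20X).

Because whole-slide images are not redistributable, a first-class synthetic
module generates every input with known ground truth: labelled nuclear
images, classifier predictions with a specified confusion matrix, clustered
point patterns with a tunable colocalisation parameter θ, and survival
cohorts drawn from a known proportional-hazards model. A bundled 20-species
table of published per-species accuracies supports the cohort statistics.

## Worked example

Simulate a labelled image, featurise it, and score simulated predictions:

```r
library(panspecies)

img <- gen_cell_image(n_per_class = c(cancer = 40, lymphocyte = 40, stromal = 40),
                      canvas = c(220, 220), seed = 4)
feats <- extract_features(img$mask, img$intensity, scale = img$spec$scale)
feats[1:3, c("cell_id", "area", "eccentricity", "solidity", "int_mean")]
#>  cell_id   area eccentricity solidity int_mean
#>        1 58.638        0.890        1  149.011
#>        2 76.105        0.762        1  138.104
#>        3 32.022        0.502        1   88.734

cm <- matrix(c(.9,.05,.05, .05,.9,.05, .05,.05,.9), 3, byrow = TRUE)
preds <- gen_predictions(img$truth,
                         confusion_spec(cm, jitter_sd = 0.5, miss_rate = 0.05),
                         seed = 5)
score_predictions(img$truth, preds)
#> Single-cell classification metrics
#>         cls n_annotated sensitivity specificity precision    f1 bcacc
#>      cancer          40        0.90       0.963     0.923 0.911 0.931
#>  lymphocyte          40        0.85       0.963     0.919 0.883 0.906
#>     stromal          40        0.90       0.950     0.900 0.900 0.925
#> Overall BCAcc: 0.921
```

Areas are in µm², intensities on the 0–255 grayscale. The recovered
per-class sensitivities sit near the 0.90 diagonal of the generating
confusion matrix; misses (5%) count against sensitivity.

Spatial immune score and survival:

```r
pp <- gen_point_pattern(coloc_spec(theta = 0.8), seed = 2)
colocalization_score(pp$cancer, pp$lymph)
#>          mh coloc100 quadrat_width n_quadrats
#>   0.9459174 94.59174           250         64

d <- gen_survival(survival_spec(n = 88), seed = 3)   # HR 0.98 per coloc100 unit
fit_cox(d)
#> Cox proportional-hazards fit (efron ties): n = 88, events = 62
#>            term estimate      se    hr hr_low hr_high p.value
#>        coloc100  -0.0170 0.00791 0.983  0.968   0.999 0.03196
#>             age   0.1451 0.05591 1.156  1.036   1.290 0.00946
#>  lymphocyte_pct  -0.0291 0.01111 0.971  0.950   0.993 0.00880
```

A melanoma-sized cohort (n = 88) recovers a protective colocalisation effect
(HR 0.983 per unit, true 0.98). `tidy()`/`glance()` extract tibbles;
`autoplot()` draws overlap heatmaps, forest plots and KM curves.

Cohort statistics from the bundled 20-species table:

```r
table1_summaries()
#> Pan-species cohort summary (n = 20 species)
#>   overall BCAcc: mean 0.815, range 0.57-0.94
#>   species with BCAcc >= 0.70: 19/20; >= 0.80: 12/20
#>   Kruskal-Wallis by tumour type: H(4) = 0.393, p = 0.983, eta^2 = -0.240
#>   Spearman annotations vs BCAcc: rho = -0.122, p = 0.607
```

The bundled table stores accuracies at two decimals; rank statistics on 20
observations are sensitive to the induced ties (see the methods vignette).

A configuration-driven run chaining all stages:

```r
run_pipeline(list(stages = c("simulate", "featurize", "morphospace",
                             "evaluate", "colocalize", "survive"),
                  seed = 12, out = "out/"))
```

A thin command-line wrapper is provided in `inst/scripts/panspecies.R`.

## Package layout

- `R/` — cell-table and image IO, synthetic generators, morphometry,
  morphospace overlap, evaluation statistics, spatial immune scores,
  survival models, pipeline, plotting, tidiers.
- `inst/extdata/` — the 20-species accuracy table and the canine-prostate
  per-class accuracies.
- `vignettes/methods.Rmd` — the model and every numerical convention, with
  the design decisions and known limitations.
- `tests/testthat/` — unit, property and acceptance tests (oracle-based
  expected values computed independently of the implementation).
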