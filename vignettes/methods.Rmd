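---
title: "Methods: cross-species transfer evaluation and spatial immune prognostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species transfer evaluation and spatial immune prognostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panspecies)
```

## Scope and scientific setting

Single-cell classifiers for H&E histology are usually trained on human tumours.
When such a classifier is applied to tumours of other species, two questions
arise: *how accurately does it transfer*, and *can its output be turned into a
clinically useful score*? This package implements the computational chain for
both questions:

1. **Morphometry** — 27 shape and staining descriptors per nucleus, from a
   labelled mask and a paired grayscale image.
2. **Morphospace overlap** — a 2-D t-SNE embedding of the feature vectors and
   a quantile-ladder overlap score (`port_overlap()`) between cell-class
   groups, quantifying how much of one class's morphological range lies
   inside another's.
3. **Evaluation** — annotation-to-detection matching, confusion matrices,
   per-class and overall balanced accuracy (BCAcc), and cohort-level rank
   statistics.
4. **Spatial immune scoring** — lymphocyte relative abundance and the
   quadrat-based Morisita-Horn colocalisation between cancer cells and
   lymphocytes.
5. **Survival modelling** — multivariate Cox proportional-hazards fits with a
   VIF collinearity screen, lower-quartile dichotomisation of the
   colocalisation score, and (adjusted) Kaplan-Meier curves.
6. **Synthetic data** — generators for every input, so the full chain is
   testable without whole-slide images.

The deep cell detector/classifier itself is out of scope; its behaviour
enters only through annotation tables, prediction tables and a confusion
specification.

## Balanced accuracy

For each annotated class $c$ (cancer, lymphocyte, stromal), one-vs-rest
sensitivity and specificity are computed from the confusion matrix and

$$\mathrm{BCAcc}_c = \tfrac12(\mathrm{sensitivity}_c + \mathrm{specificity}_c),
\qquad \mathrm{BCAcc} = \tfrac13 \sum_c \mathrm{BCAcc}_c .$$

Two conventions needed fixing because they are under-determined for matched
annotation/prediction data:

* Annotations with no detection within the matching threshold count as a
  `missed` outcome of their true class — they reduce that class's
  sensitivity but are not positive predictions of any class.
* `other` predictions on annotated cells are errors of the true class
  (annotations cover only the three core classes).

Annotation-to-centroid matching is greedy by ascending distance with
one-to-one use of centroids, thresholded at 1.824 µm — four pixels at the
0.456 µm/px working resolution of a 20X slide (scanners at 40X/228 nm
down-scaled by 2). Both the threshold and the convention are configurable.

## The 27-feature registry

The exact published feature list lives in supplementary material that is not
redistributable here, so the registry is a documented reconstruction: a
14-feature regionprops-style shape block (area, convex area, filled area,
perimeter, equivalent diameter, major/minor axis lengths, eccentricity,
orientation, solidity, extent, Euler number, circularity $4\pi A/P^2$, aspect
ratio) and a 13-feature intensity block (mean, median, min, max, SD, median
absolute deviation, range, 25th/75th percentiles, IQR, skewness, kurtosis,
256-bin Shannon entropy). The registry is data: reordering or substituting it
changes the output without code changes, and a hash of the registry travels
with every feature table.

Numerical conventions, each chosen to match a widely used implementation:

* Second central moments include the $1/12\,\mathrm{px}^2$ variance of a unit
  pixel (the MATLAB regionprops convention), so one-pixel-wide regions keep
  eccentricity $< 1$ and a finite aspect ratio.
* Perimeter uses the weighted border-pixel approximation with weights $1$,
  $\sqrt2$ and $(1+\sqrt2)/2$ for straight, diagonal and corner
  configurations. On a 2:1 ellipse it overestimates the true perimeter by
  roughly 4%, which is why the test bounds on circularity are asymmetric.
* Convex area counts pixel centres on or inside the convex hull of the
  region's pixel centres (scanline count), so solidity is always $\le 1$.
* The Euler number is connected components minus holes, computed by hole
  filling and component labelling (EBImage).
* Skewness and kurtosis follow the e1071 defaults (type 3, excess kurtosis);
  entropy uses $\log_2$ over 256 intensity bins.

Labels with fewer than 3 pixels are skipped with a warning — their axis
moments are not meaningful.

## Morphospace and the overlap score

Features are z-scored per dimension before embedding (raw areas would
otherwise dominate every distance), then reduced to two dimensions with exact
t-SNE (`theta = 0`, perplexity 50, fixed seed). Perplexity must satisfy
$3p + 2 \le n$; smaller samples are an error, not a silent re-parametrisation.

The overlap score between groups $A$ and $B$ is computed per embedding
dimension over a quantile ladder $\alpha \in \{0, 0.01, \ldots, 0.49\}$: at
each level the group interval is $[Q_\alpha, Q_{1-\alpha}]$, the
per-dimension score is the mean over $\alpha$ of
$|I_\alpha(A) \cap I_\alpha(B)| / |I_\alpha(A)|$, and the final score is the
product across the two dimensions. It is therefore *asymmetric* —
`port_overlap(A, B)` is the fraction of A's morphospace inside B's — and
invariant under affine maps applied jointly to both samples. The ladder is
configurable and reported; the default spans the full quantile range below
the median in 1% steps. Zero-length intervals (a group constant in one
dimension) fall back to a point-membership rule with a warning rather than a
0/0.

Per-sample embeddings are computed jointly over the human reference cells
and that sample's animal cells so that overlaps live in one space. The
per-sample summary, `mean_sample_overlap()`, averages the counterpart-class
overlaps (animal vs human cancer, animal vs human lymphocyte) in both
directions; all-pairs averaging is available by passing a different pair
list.

## Cohort statistics

Kruskal-Wallis tests use the tie-corrected statistic; when every observation
is identical the tie-correction denominator vanishes and $H$ is defined as 0.
The rank effect size is $\eta^2 = (H - k + 1)/(N - k)$, which is negative for
$H < k - 1$; its 95% CI comes from a seeded percentile bootstrap (2000
resamples within groups by default). Post-hoc pairwise contrasts are
rank-based $z$ contrasts — mean-rank differences with the tie-corrected
pooled-rank variance — adjusted by Benjamini-Hochberg, with significance
defined as the CI excluding zero. This is a deliberate approximation: mixing
rank tests with normal-theory contrasts mirrors the common applied practice
the package emulates, and the contrast scale (mean ranks) is stated in the
output rather than implied.

## Spatial immune scores

Lymphocyte relative abundance is the percentage of lymphocytes among
classified cells, with `other` cells excluded from the denominator.

Colocalisation discretises both point patterns on a shared grid of square
quadrats (default width 250 µm — an order of magnitude above single-cell
spacing and an order below slide extent; no published convention exists, so
the width is a reported parameter and `coloc_width_sweep()` exposes the
sensitivity instead of hiding it). The grid anchors at the joint bounding-box
minimum with half-open cells, so boundary points are counted exactly once.
The Morisita-Horn index

$$MH = \frac{2\sum_i x_i y_i}{\left(\sum_i x_i^2/X^2 + \sum_i y_i^2/Y^2\right) XY}$$

is symmetric in the two patterns, translation invariant, 1 for
proportionally identical quadrat occupancies and 0 for disjoint ones. For
survival modelling the score is multiplied by 100 (`coloc100`), putting a
hazard ratio per unit on a readable scale.

## Survival modelling

Cox models are fitted by partial likelihood with Efron tie handling (the
common default; the choice is exposed). Covariates are screened by variance
inflation factor, retaining VIF $< 5$; exact collinearity reports an infinite
VIF. The colocalisation score enters per unit of `coloc100` (i.e. per 0.01 of
MH). Dichotomisation uses the lower quartile with the linear-interpolation
quantile (type 7) — "lower quartile" is convention-dependent, so the type is
a parameter and the cutoff is attached to the result. Covariate-adjusted
Kaplan-Meier curves are derived from the multivariate fit either at the
cohort covariate means or at reference (zero) values; both are offered
because the reference point for "adjusted" curves is genuinely
under-specified in applied reports. For the melanoma-style design, an
`event_cause` column recodes deaths unrelated to the tumour as censored.

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions for every test:

* `gen_cell_image()` draws non-overlapping nuclei as ellipses with 2nd-4th
  harmonic radial perturbations; per-class log-normal areas, aspect ratios,
  boundary irregularity and stain intensities come from
  `morphology_profile()`. The defaults (lymphocytes: 35 µm² median, nearly
  round, dark; cancer: 110 µm², pleomorphic; stromal: 55 µm², elongated)
  encode the qualitative H&E structure a pathologist would describe; no
  species-specific quantitative distributions are published, so these are
  free parameters of the simulation, not calibrated claims.
* `gen_predictions()` emulates a classifier by a row-stochastic confusion
  matrix, Gaussian positional jitter, a miss rate and uniformly placed
  spurious detections whose class is uniform over the three core classes (no
  false-positive class profile is published).
* `gen_point_pattern()` is a Thomas-type cluster process: uniform parents,
  Gaussian offspring (toroidal wrap keeps counts exact and margins uniform).
  The mixing parameter $\theta$ is the probability that a lymphocyte attaches
  to a cancer parent rather than an independent one; expected Morisita-Horn
  increases monotonically in $\theta$, which the tests verify by simulation.
* `gen_survival()` realises the proportional-hazards model forward:
  exponential baseline (rate $\log 2 / 370$ per day, a 370-day median
  survival as in a melanoma-sized cohort of n = 88), log-hazards per unit of
  coloc100 (default $-0.02$, i.e. HR 0.98), age and lymphocyte percentage,
  with independent censoring.

What passing tests on these data do **not** show: robustness to real H&E
texture, stain variation, segmentation error beyond positional jitter,
non-ellipsoidal nuclear shapes, tissue-mask effects on quadrats, or
non-proportional hazards. The generators are deliberately simple enough that
every expected value can be computed independently.

## The transfer-cohort simulation

`simulate_transfer_cohort()` reproduces, at desk scale, the cohort-level
relationship between morphospace overlap and transfer accuracy. Each
synthetic species draws human and animal cells from class-conditional
Gaussians in the 27-dimensional feature space; the animal class centroids
drift from their human counterparts by a specified number of within-class
standard deviations. The drift direction is drawn **inside the subspace
spanned by the class centroids**, one direction per class: displacement
orthogonal to that discriminative subspace neither confuses a classifier nor
should it, whereas drift inside it emulates an animal cell class coming to
resemble a different human class — the failure mode actually observed when
models transfer poorly. A nearest-centroid classifier trained on the human
cells provides the measured BCAcc; the same cells are jointly embedded and
scored with `mean_sample_overlap()`. With 20 species, separations 0-4 SD,
120 human and 100 animal cells per class (sizes chosen so the full cohort
runs in about a minute), the Pearson correlation between mean overlap and
BCAcc is reliably around +0.7.

## Reproducibility conventions

Every stochastic function takes an explicit seed and restores the RNG state
(`withr::with_seed`); generators attach their specification to their output;
`run_pipeline()` derives all stage seeds from one configuration seed and
records them in its JSON report, so identical configurations yield identical
reports.

## Known limitations

* The Kruskal-Wallis $H$ and the Spearman coefficient recomputed from the
  bundled 20-species table differ from some published cohort values: the
  bundled accuracies are 2-decimal roundings, and rank statistics on 20
  observations are sensitive to the induced ties. The package reports what
  the printed table implies.
* The morphometry registry is a reconstruction (see above); swapping in an
  exact list is a data change, not a code change.
* Quadrat width and the quantile ladder are reported parameters with
  sensible defaults, not published constants.
* The `other` morphology class is not simulated; it appears only as a
  prediction outcome.
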