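---
title: "Methods: information-theoretic glioma diagnostic workflows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: information-theoretic glioma diagnostic workflows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(gliodx)
```

This vignette documents the models implemented in gliodx, the parameters
they expose, the numerical conventions behind them, and the scope and
limitations of the synthetic data generators that ground-truth every stage.
The package targets a concrete clinical question: in IDH-mutant diffuse
gliomas, which combinations of cheap bench observations (patient age,
nuclear morphometry on Olig2 or H&E sections, p53 and ATRX
immunohistochemistry) carry enough information about 1p/19q codeletion
status to decide *whether and which* confirmatory molecular test to order.

## 1. The discrete information engine

All information quantities are plug-in (maximum-likelihood) estimates in
bits. For a sample of a discrete variable with observed level frequencies
$\hat p_i$,

$$H(X) = -\sum_i \hat p_i \log_2 \hat p_i, \qquad
I(X;Y) = H(X) + H(Y) - H(X,Y),$$
$$I(X;Y\mid Z) = H(X,Z) + H(Y,Z) - H(X,Y,Z) - H(Z).$$

Design decisions:

* **Joint coding.** A biomarker *panel* enters as a single joint variable
  formed by the cartesian product of member level sets
  (`mutual_information(list(a, b), label)`). Internally variables are
  mapped to integer codes and combined positionally; when the running
  level-space would overflow `.Machine$integer.max`, the accumulated code
  is re-factored to its observed support first. This keeps entropy
  computation a single `tabulate()` pass — no string keys, no hashing.
* **Clamping.** MI and CMI are clamped at zero. The identities hold to
  1e-12 before clamping; tiny negative values can only arise from float
  rounding.
* **Percent of maximum.** A panel's value is reported as
  $100 \cdot I(\text{panel};\text{label}) / H(\text{label})$
  (`percent_of_max_info()`). The label entropy is the supremum of
  information any feature set can supply, and the percentage is invariant
  to the logarithm base.
* **Continuous inputs** (age, percent positivity, morphometry) are binned
  by `discretize()`, default 5 equal-frequency bins: quantile edges keep
  every cell populated at modest cohort sizes, which matters because the
  plug-in estimator is biased upward on sparse tables. Ties always land in
  the same bin, so heavily tied variables may yield fewer bins.
* **Significance** is by label permutation with the add-one rule
  $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(n_{\text{perm}}+1)$, which
  never reports zero. Under planted independence (n = 200, 999
  permutations) the rejection rate at $\alpha = 0.05$ is calibrated
  (acceptance suite: 0.045 over 200 replicates). `incremental_gain()`
  scores a candidate biomarker's addition to a panel; for the plug-in
  estimator on a fixed sample this is non-negative by construction, so its
  *significance*, not its sign, is the interesting output.

```{r xor}
# two markers individually useless, jointly decisive (1 bit):
a <- c(0, 0, 1, 1); b <- c(0, 1, 0, 1)
label <- as.integer(xor(a, b))
c(I_a = mutual_information(a, label),
  I_ab = mutual_information(list(a, b), label))
```

## 2. Stain physics and segmentation

Bright-field stains follow Beer–Lambert absorption, so images are analyzed
in optical density, $OD_c = -\log_{10}((p_c + 1)/256)$ per channel — the
+1 offset makes a pure-white pixel exactly zero OD. `color_deconvolve()`
inverts the standard stain OD matrix (hematoxylin, eosin or DAB rows, with
the residual third vector as cross product; rows unit-normalized) to
per-stain concentration maps, and `forward_stain_synthesis()` is its exact
inverse, which is how the synthetic generators make images whose
deconvolution is known by construction.

Three unsupervised segmenters share one contract (integer label matrix,
0 = background):

* **`segment_deconv_otsu()`** — the reference pipeline, in fixed order:
  deconvolve, median filter (radius 2), Otsu threshold (256 bins) on the
  target stain channel, fill holes, remove border-touching objects
  (incomplete nuclei must not contribute morphometry), distance-transform
  watershed (tolerance 1) to split touching nuclei, drop objects under
  `min_size` (20 px). The `min_od` floor (0.15) stops Otsu from
  hallucinating nuclei on blank tiles, where it would otherwise split
  background noise. The target channel defaults to the stain that marks
  nuclei (DAB for immunostains, hematoxylin for H&E); `"HD"` sums both
  densities for counterstained immunostains.
* **`segment_kmeans()`** — k-means on raw RGB pixels (k = 3: nuclei,
  counterstain/cytoplasm, background), foreground = the cluster whose
  centroid carries maximal nuclear-stain OD. MacQueen's algorithm is used
  because Hartigan–Wong emits Quick-TRANSfer warnings on the large
  near-duplicate pixel sets these images produce.
* **`segment_ccc()`** — cut–cluster–classify: 5×5 gray patches; a kNN
  density *cut* drops the sparsest patches (quantile 0.85, k = 4, against
  a 2000-patch reference subsample); 2-means *clusters* the survivors;
  nearest-centroid *classifies* every patch; pixels vote by patch
  majority and the darker cluster is the nucleus class. The reference
  subsample must be large enough that nucleus cores look dense — with a
  few hundred reference patches, genuine nuclei are sparsely represented
  and get cut.

`evaluate_segmentation()` scores binarized masks by pixel accuracy and
foreground IoU, with empty-vs-empty defined as IoU 1.

## 3. Nuclear morphometry

`extract_nucleus_features()` computes, per labeled nucleus and per RGB
channel, the full basic-intensity + shape + image-moment + Haralick
texture feature set, then drops columns that repeat identically across
channels (shape does not depend on the channel). Border nuclei are
excluded first. Downstream:

* **`pca_reduce()`** standardizes columns and keeps the minimal number of
  principal components reaching a cumulative explained-variance target
  (default 0.9).
* **`density_features()`** samples a *fixed* number of nuclei (default
  350) so cellularity does not leak into the statistic, computes each
  nucleus's distance to its k-th nearest neighbor in PC space
  (k = 10/20/40/60), and summarizes by mean/median/SD. Monomorphic
  (oligodendroglioma-like) nuclei pack tightly — small distances;
  pleomorphic (astrocytoma-like) nuclei spread — large distances. The
  features are homogeneous of degree 1 in the embedding coordinates.
* **`histogram_features()`** gives mean/SD/moment-skewness/excess-kurtosis
  of major axis, eccentricity and area; constant features report zero
  skewness and kurtosis by convention and are flagged.
* **`select_features_by_information()`** ranks case-level features by MI
  with the diagnosis and keeps those significant under label permutation.

## 4. The stain-colored noise assay

Arbitrary RGB noise is trivially rejected by color deconvolution; the hard
case is noise *on the stain's own color manifold*.
`fit_noise_color_model()` learns G and B as functions of R by
support-vector regression on the stain pixels; `inject_noise()` replaces
exactly `round(pct/100 * H * W)` uniformly sampled pixel positions with
colors drawn from that manifold (R uniform over the observed stain range).
`run_noise_assay()` traces accuracy/IoU over the grid
{0, 5, 10, 15, 25, 50, 75, 90}%.

A finding worth stating plainly: the deconvolution–Otsu accuracy curve is
**not monotone** on this assay. At intermediate noise the Otsu foreground
fuses into one border-touching component which the (mandatory)
border-removal step deletes wholesale; the resulting empty prediction
scores `1 − foreground fraction` — a floor that can exceed the score of a
prediction with a few false clumps. Pixel accuracy is bounded below by
the trivial empty prediction, so a thresholding segmenter that collapses
under noise can *appear* to recover. The acceptance suite pins this
behavior (its monotonicity check fails, deliberately left at tolerance).

## 5. Self-normalizing p53 quantification

Chromogenic IHC intensity varies by batch, so a fixed intensity cutoff
does not transfer between slides. The workflow instead trains a fresh
classifier *per slide* on that slide's own on-slide controls:

1. `build_control_training_set()` segments the positive control (a
   diffusely positive tissue, fraction 1.0) and negative control (e.g.
   lymphocytes, fraction 0.0) on the **hematoxylin counterstain channel**
   — the counterstain marks every nucleus regardless of DAB status, which
   is precisely why counterstains are used; segmenting on DAB (or even
   H+D summed) loses faint negative nuclei when positives dominate the
   intensity histogram. Control nuclei are labeled wholesale by tile of
   origin, and only intensity/texture features are kept: positivity must
   not depend on nuclear shape.
2. `train_slide_classifier()` fits an ensemble of trees with an internal
   80/20 stratified split for a per-slide accuracy report.
3. `compute_p53_positivity()` applies the model to the pooled tumor
   nuclei and reports percent positive.

Because the classifier is re-learned from controls that experienced the
same staining batch, a global ±20% intensity change moves the readout by
0 points on the synthetic assay (acceptance bound: ≤ 5). Planted
fractions {0, 10, 30, 50, 80, 100}% are recovered with regression slope
1.01 (bound [0.9, 1.1]). The continuous percentage is binarized at 80%
(`binarize_p53()`) when a hard call is needed, and agreement between
readers/methods is scored by Lin's concordance correlation (`lin_ccc()`,
population moments, Fisher-z CI with Lin's asymptotic variance).

## 6. The composite codeletion model and triage rule

* `naive_bayes_codel_prob()` — Gaussian naive Bayes posterior of
  codeletion from age (optionally gender), the simplest usable prior:
  codeleted patients skew older.
* `fit_atrx_age_model()` / `predict_codel_prob()` — an ensemble-of-trees
  probability of codeletion from ATRX status + age, fitted on a global
  cohort; ATRX mutation and codeletion are essentially mutually
  exclusive, so this feature is strong.
* `impute_atrx()` / `complete_atrx()` — missing or equivocal ATRX calls
  are imputed from age + binarized p53 (p53 and ATRX are coupled through
  the astrocytoma genotype); observed calls are never overwritten.
* `train_codeletion_model()` — the composite classifier over per-case
  density features, continuous percent p53, and the ATRX/age probability,
  with a stratified 70/30 split for held-out accuracy.
* `recommend_test()` — the decision rule: predicted probability < 0.5
  means no confirmatory testing (diagnose astrocytoma); otherwise a
  low-grade, non-recurrent tumor is confirmed by FISH, while high-grade
  or recurrent tumors go to chromosomal microarray or sequencing, which
  FISH's false-positive mode makes preferable there.

## 7. Synthetic generators: scope and limits

All ground truth is generated, never stored:

* `make_slide()` paints non-overlapping ellipse nuclei (rejection-sampled
  placement; optional planted touching pairs and border-straddlers) into
  stain concentration maps and renders through the forward stain model
  with Gaussian pixel noise. Pleomorphism is one knob multiplying the SDs
  of radius, axis ratio and stain intensity. DAB-positive nuclei carry
  DAB *plus* a hematoxylin counterstain component; negative nuclei carry
  counterstain only — the generator realism the p53 workflow depends on.
  `positive_fraction` plants an exact count, `round(f * n)`.
* `make_slide_set()` assembles the on-slide-control setting: positive and
  negative control tiles plus tumor tiles, all sharing one
  `intensity_scale` batch factor.
* `make_cohort()` draws (codeletion, age, p53, ATRX, gender) by ancestral
  sampling with the documented couplings (codeleted: older, p53-low,
  ATRX-wildtype); ages truncate at 18 by resampling.
* `make_entity_spec_fixture()` writes a small 8-entity CSV specification
  (two entities deliberately overlap so classifier confusion is
  realistic) for the population simulator; `simulate_population()` +
  `classify_diagnosis()` + `scramble_importance()` then quantify which
  features carry diagnostic signal at the population level.
* `make_case_features()` runs the *real* image pipeline (slide → feature
  table → pooled PCA → density features) per case with planted
  class-conditional pleomorphism, and adds p53/ATRX/age features drawn
  from the cohort model.

Limits, honestly: nuclei are ellipses without chromatin texture; the
color model is the ideal Beer–Lambert forward model the deconvolution
inverts, so deconvolution-based methods face no model mismatch here;
tiles are hundreds of pixels, not gigapixel slides; and all problem sizes
(tile 192–288 px, 20–55 nuclei, cohorts of 1–2 thousand) were chosen so
the full suite runs on one CPU in minutes. These sizes are package
choices, not estimates of clinical scale.

## 8. A worked example

```{r example, eval = FALSE}
# segment a synthetic Olig2-like tile and score against ground truth
slide <- make_slide(n_nuclei = 20, stain_kind = "DAB", seed = 3)
mask <- segment_deconv_otsu(slide$image)
evaluate_segmentation(mask, slide$mask)

# p53 positivity with on-slide controls
set <- make_slide_set(tumor_fraction = 0.3, seed = 42)
compute_p53_positivity(set, seed = 1)

# composite codeletion model end to end
cases <- make_case_features(n_cases = 60, seed = 11)
fit <- train_codeletion_model(cases, seed = 11)
fit$accuracy
recommend_test(predict_codeletion(fit, cases[1, ]), grade = "high")
```
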