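---
title: "slidefuse: methods, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{slidefuse: methods, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the two-tier whole-slide-image (WSI) classification model, its assumptions,
the parameters that matter, what the synthetic generator does and does not
emulate, and the design choices made where the design was genuinely open.
It states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. The model

Histopathological diagnosis and prognosis from H&E-stained WSIs is a
weakly supervised problem: labels exist per case (diagnosis; recurrence
within follow-up) while the gigapixel image decomposes into thousands of
512 × 512 px tiles, most of which are individually ambiguous. The package
implements a two-tier pipeline:

1. **Patch tier.** Tiles at 0.5 μm/pixel are cleaned (background removal,
   Macenko stain normalization, per-channel z-scoring), and a convolutional
   classifier — trained with SGD on softmax cross-entropy, each patch
   inheriting its slide's label — emits per-patch class probabilities.
2. **Fusion tier (the core).** Per *document* (a case pooling all its
   slides, or one representative slide) the patch likelihoods are collapsed
   into a fixed-length feature vector by two parallel pipelines:
   * *Patch-likelihood histogram (PLH)*: likelihoods are discretized to a
     fixed decimal precision and histogrammed; features are relative
     frequencies over the full token vocabulary (names `hist_-0.39`, …).
   * *Bag of words (BoW)*: the same tokens are treated as words and
     TF-IDF-weighted against the training corpus (names `bow_039`, …).
   Features pass a Welch t-test filter and a grid-searched conventional
   classifier produces the document-level prediction.

The two tasks differ only in configuration: the diagnostic (3-class)
setup uses one-decimal tokens with predicted labels entering the histogram
only (`diagnostic_config()`, 11 + K PLH + 11 BoW columns, i.e. 25 for
K = 3); the prognostic (binary) setup uses two-decimal tokens with labels
and probabilities in both pipelines (`prognostic_config()`,
(101 + 2) × 2 = 206 columns).

### Assumptions

* Patch appearance carries class signal often enough that the *distribution*
  of patch likelihoods characterizes the document; spatial arrangement is
  ignored (a histogram/bag is order-free). Attention-based or spatial MIL is
  deliberately out of scope.
* Patches are exchangeable within a document; multi-slide cases are pooled
  because a single slide of a large resected lesion under-samples it.
* The patch classifier need only be *better than chance and consistent*:
  fusion tolerates weak patch-level AUC, which is precisely the regime the
  method targets.

## 2. Key parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `tile_size`, `mpp` | 512 px, 0.5 μm/px | tessellation contract; partial edge tiles dropped; resolution honored within 10%, else area-average resampling from the finer source |
| `sat_threshold`, `tissue_fraction_min` | 0.07, 0.25 | HSV-saturation background rule replacing the original proprietary deep-learning tool |
| Macenko `od_floor`, angle percentiles, concentration quantile | 0.15, 1%/99%, 99% | the original method's robust-estimation constants |
| `eta_min`, `eta_max`, `T_i` | 0, 0.01, 8 | cosine-decay schedule; backbone frozen for `T_cur ≤ T_i/2`, then fine-tuned under the same decay |
| `batch_size` | 128 | SGD batch size |
| `decimals` | 1 (diagnostic) / 2 (prognostic) | token precision, half-up rounding |
| TF-IDF | smoothed idf `ln((1+N)/(1+df))+1`, L2 norm | the most common convention; fitted on training documents only |
| t-test filter `alpha` | 0.05 | two-sided Welch; no multiplicity correction (configurable; a BH column is always emitted by the findings screen) |
| Tree grids | n_estimators 10–50 step 5 × max_depth 2–5 | 36 configurations; five-fold stratified CV selects on mean AUC |
| SVM | RBF kernel, C = 1, gamma = "scale" | other settings default |
| MLP | hidden 128/64/32 | fixed fully connected perceptron |
| Operating threshold | 0.5 (`"youden"` optional) | the original report does not state its threshold; its printed sensitivity/specificity imply a non-0.5 choice |

Noted discrepancy: the stated tree grid enumerates 9 × 4 = 36
configurations, although the source text says the search "forms 40" models;
the stated ranges are implemented and the count surfaced here rather than
silently adjusted.

The schedule equations with their defaults are asserted to 1e-12 against
independent numeric evaluation in the acceptance suite. One textual
ambiguity is resolved in favor of the displayed equation: the backbone
learning rate is 0 for `T_cur ≤ T_i/2` (boundary inclusive), although the
prose says fine-tuning begins "when `T_cur = T_i/2`".

## 3. The synthetic cohort generator

`synthetic_spec()` states a world; it is not a tuning dial:

* **Structure** mirrors a multi-slide clinical cohort: 2–4 slides per case,
  50–200 kept tiles per slide (uniform draws), case-level 7:3 train/test
  splits (the split operation reproduces the published 519 → 363/156 and
  400 → 280/120 sizes exactly, using half-up rounding with largest-remainder
  stratification).
* **Likelihoods**: each tile's positive-class likelihood is i.i.d.
  Beta(α, β) given (class, recurrence); multi-class rows complete the
  simplex uniformly. The well-separated default (Beta(8,2) vs Beta(2,8))
  expresses *controlled separability* so that downstream failures are
  attributable to the pipeline, not the world. A single value instead of
  (α, β) is a point mass (variance-zero law).
* **Recurrence**: prevalence 0.2 by default — the reported recurrence range
  for these lesions is 14–20% — and recurrent cases shift the Beta mean by
  `recurrence_effect` (+0.15) at fixed concentration.
* **Tiles**: two synthetic stain concentration fields — nuclei-scale
  Gaussian blobs (hematoxylin-like) and smooth background plus optional
  stripes (eosin-like) — mixed through Beer–Lambert optical density with
  the published H&E stain directions, jittered per tile by at most 5°. The
  eosin field is attenuated where the blob field is dense (nuclei displace
  cytoplasm), which also guarantees near-pure-stain pixels for the
  extreme-angle Macenko estimate. Stain weights (0, 0) produce a
  near-white tile that the background rule removes.
* **Findings**: each binary pathological finding is drawn from a logistic
  model on one designated fusion feature (the case's relative frequency of
  a chosen likelihood token, standardized), with the intercept calibrated
  to the stated prevalence — a planted truth for the association screen.

**What a green test does not establish.** The generator produces
exchangeable, i.i.d.-given-class patches with stylized textures. It does
not emulate spatial tissue architecture, scanner or staining batch effects,
label noise, class imbalance drift, or nuclei-level morphology — so green
end-to-end tests certify the pipeline's mechanics and statistics, not
clinical performance. The published clinical AUCs (0.935 diagnostic, 0.840
prognostic) depend on a private 519-case cohort and are explicitly not
reproduction targets.

## 4. Numerical choices

* **Discretization** is half-up on decimal-safe arithmetic
  (`signif(p·10^d, 12)` before the floor), not banker's rounding —
  deterministic across platforms; tokens render with trailing zeros
  stripped ("0.90" → `0.9`), matching the published feature names.
* **Histogram normalization**: counts are divided by document length so
  documents with different patch counts are comparable (the source does not
  state this; relative frequencies are the scale-invariant choice).
* **AUC** is the tie-aware Mann–Whitney statistic (ties count ½), computed
  via midranks; confidence intervals and the paired two-model test both use
  the DeLong structural-component estimator, keeping one estimator family
  (the original report names no CI method). Degenerate comparisons
  (identical predictors) return z = 0, p = 1.
* **Macenko**: pixels with OD *magnitude* below 0.15 are discarded. A
  per-channel floor would also discard near-pure-stain pixels — each stain
  is optically faint in some channel — and bias the extreme-angle
  estimates; this was verified on the synthetic tiles. Tiles with fewer
  than 100 pixels above the floor are returned unchanged with a
  `degenerate` flag.
* **Argmax ties** (patch labels, document predictions) resolve to the
  lowest class index; single-slide document selection breaks patch-count
  ties by lexicographically smallest slide id.
* **`T_cur` granularity**: advanced per iteration (continuous fractional
  epochs), logged per epoch — standard cosine-schedule practice; the source
  does not state step granularity.
* **Scalar "likelihood" of a patch**: the positive-class probability in
  binary tasks; for 3-class tasks the probability of the document's
  majority predicted label (configurable to a designated class or the
  per-patch maximum) — the source shows a single scalar per patch in its
  heatmaps without naming the convention.

## 5. Design decisions on open ground

* **Native classifier engines.** The deployment environment provides no
  SVM, random-forest, boosting or neural-network packages, so the model zoo
  is implemented natively at desk scale: exhaustive-split CART (gini),
  bagged forests, extremely randomized trees (no bootstrap, random
  thresholds), second-order Newton gradient boosting — level-wise growth
  standing in for XGBoost and leaf-wise best-first growth capped at
  `2^max_depth` leaves standing in for LightGBM — a simplified-SMO RBF
  SVM with Platt-scaled probabilities (Platt fit on training decision
  values; score order, hence every AUC, is unaffected), and a 128/64/32
  Adam-trained MLP. These are compact reimplementations, not bindings; the
  module surface and every contract test are unchanged.
* **CNN backbone.** The published pipeline used Inception_v3 on >2.5M
  patches; the method is architecture-parametric downstream, so the default
  backbone is a 3-conv-block network on 32 px inputs that trains on a CPU
  in seconds. At desk scale the paper-scale schedule (T_i = 8, batch 128)
  amounts to ~16 SGD updates and cannot learn anything, so CNN tests use an
  explicitly desk-scale configuration (epochs 20, batch 32, eta_max 0.1)
  under identical schedule semantics — frozen backbone for the first half,
  cosine decay throughout. ImageNet pretraining is out of scope; the
  transfer-learning contract is honored by initializing the backbone from
  any previously trained model (`pretrained = TRUE, init_from = …`).
* **Input formats.** No pyramidal TIFF/NDPI reader exists in the target R
  environment; `tile_slide()` accepts in-memory rasters with an `mpp`
  attribute, PNG files, or pre-tiled `<col>_<row>.png` directories.
  Proprietary slide formats are a non-goal.
* **Background removal** replaces the original proprietary deep-learning
  tool with the transparent HSV-saturation rule above (thresholds
  configurable).
* **Micro vs macro AUC.** Macro (unweighted mean of one-vs-rest AUCs)
  reduces exactly to the binary AUC on two classes; micro under the
  standard pooled construction does not in general — pooling mixes p and
  1 − p into one ranking — and the tests assert the reduction only where it
  genuinely holds (macro always; micro under perfect separation).
* **t-SNE** is delegated to `Rtsne` (exact mode, seeded) as plumbing.

## 6. Known limitations

* The CNN is intentionally small; it demonstrates and tests the training
  contract (two LR groups, weak supervision, Grad-CAM) rather than
  competing with modern backbones.
* SMO and the native tree ensembles are O(n²)-ish and sized for hundreds of
  documents / thousands of patches — adequate for the package's scope, not
  for production-scale cohorts.
* DeLong p-values are asymptotic; at n = 40 they agree with a
  10,000-permutation oracle to ~0.01–0.03 (the acceptance suite asserts the
  median deviation over five draws < 0.02).
* Grad-CAM resolution is bounded by the final 4 × 4 conv map; localization
  tests therefore operate at quadrant granularity.
* The findings screen reports raw p-values by design (matching the original
  analysis); the emitted Benjamini–Hochberg column should be preferred for
  any reuse.
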