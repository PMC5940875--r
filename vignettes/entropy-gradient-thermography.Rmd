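---
title: "Entropy-gradient classification of neck thermograms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-gradient classification of neck thermograms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egsvm)
```

## The problem

Infrared thermography images the surface-temperature field of the body
passively, in the 8–14 μm band. In healthy subjects the temperature
distribution of the neck is bilaterally symmetric; a metastatic cervical
lymph node and the abnormal vasculature it recruits add heat on one side,
producing an asymmetric pattern — a unilateral warm focus, dilated or
tortuous vessel tracks, or a left–right temperature difference of more than
about 1 °C. `egsvm` implements an automatic classifier for frontal-neck
thermograms built on this premise, together with the diagnostic-accuracy
statistics used to evaluate a binary medical test, and a synthetic phantom
generator so that the entire pipeline can be exercised and validated
without patient data.

## Feature extraction

The unit of analysis is a single-channel gray image $g(x, y) \in
\{0,\dots,255\}$, obtained either directly (8-bit PNG/TIFF) or from a
radiometric temperature matrix by a linear min–max map to $[0, 255]$
(rounded half-up; per-image bounds by default). A rectangular neck region
of interest may be cropped first; coordinates are 0-based and half-open
throughout.

Irregularity of the thermal pattern is summarized by how the gray-level
entropy changes as a centered window expands over the image:

1. **Expanding windows.** For a window count $n$ (default 50), window $k$
   is centered on the image and spans $\mathrm{round}(kH/n) \times
   \mathrm{round}(kW/n)$ pixels, so the window grows in steps of $1/n$ of
   each dimension from $H/n \times W/n$ to the full image. Windows are
   nested, and with an odd leftover border the extra row/column goes to the
   bottom/right.
2. **Window normalization.** The sub-image under window $k$ is rescaled by
   its own maximum, $g'(x,y) = \mathrm{round}\!\left(g(x,y) \cdot 255 /
   \max_{(x',y') \in \mathrm{win}_k} g(x',y')\right)$, so every window uses
   the full gray range regardless of its local dynamic range.
3. **Histogram equalization.** A second branch applies the standard
   cumulative-histogram remapping $v \mapsto \mathrm{round}(255 \cdot
   (\mathrm{cdf}(v) - \mathrm{cdf}_{\min}) / (N - \mathrm{cdf}_{\min}))$ to
   each normalized sub-image. Equalization stretches gray values
   non-linearly and emphasizes contrast; the normalized branch preserves
   the linear structure. The two branches carry complementary information,
   which is why both are kept.
4. **Entropy series and gradients.** Each sub-image yields a Shannon
   entropy $h_k = -\sum_i p_i \log_2 p_i$ over its gray-level proportions
   $p_i$, giving series $H = [h_1, \dots, h_n]$ per branch. The feature
   vector is the concatenation of the first differences of both series,
   $[\,h_2 - h_1, \dots, h_n - h_{n-1}\,]$ for the normalized and the
   equalized branch: length $2(n-1)$, i.e. 98 at the default $n = 50$.

A symmetric, smoothly varying field produces entropy series that change
little from window to window; a unilateral warm focus or vessel track
entering the expanding window at some scale perturbs the gradient sequence
at that scale, which is what the classifier picks up.

```{r}
ph <- generate_phantom(phantom_params(hotspot_amplitude = 2,
                                      hotspot_side = "right", seed = 42))
fv <- extract_features(ph$gray)
length(fv)
plot_feature_vector(fv)
```

### Numerical conventions

These choices are stated explicitly because the feature values depend on
them:

* **Entropy base**: base 2 (bits), so $h_k \in [0, 8]$. Any fixed base only
  rescales all features uniformly, which a linear SVM absorbs into its
  weights.
* **All 256 levels** participate in the entropy sum. Level 0 occurs in
  normalized images and carries real probability mass; terms with
  $p_i = 0$ contribute zero either way.
* **Per-window sub-images**: normalization and entropy are computed on the
  window's own sub-image, not on the full image rescaled by a window
  maximum (which could push values past 255).
* **Rounding**: half-up to integer gray levels after every rescaling step,
  because entropy is defined over discrete levels. Real-valued binning
  would shift $h_k$ slightly.
* **Degenerate windows**: an all-zero window normalizes to zeros; a
  constant image equalizes to itself and has zero entropy, so a constant
  image yields an all-zero feature vector.

## The classifier

Features feed a soft-margin linear SVM: minimize $\tfrac12 w^\top w + C
\sum_i c_{y_i}\,\varepsilon_i$ subject to $y_i(w^\top x_i + b) \ge 1 -
\varepsilon_i$, with penalty $C = 0.5$ and per-class weights $c_{+1} =
1.2$, $c_{-1} = 1.0$, favouring sensitivity over specificity — the
asymmetry appropriate for a screening test where a missed metastasis costs
more than a false alarm. The quadratic program is solved by libsvm (via
**e1071**); the package stores the explicit hyperplane $(w, b)$ and
predicts by $\mathrm{sign}(w^\top x + b)$, with a decision value of exactly
zero classified as negative. Features are deliberately not re-scaled
before training, so $C$ keeps its meaning on the raw entropy gradients.

Evaluation uses stratified nine-fold cross-validation: samples are
randomly partitioned into nine label-balanced subsets under a fixed seed,
each subset serves once as the test set, and the reported sensitivity,
specificity, accuracy, PPV and NPV are across-fold averages (pooled
confusion counts are returned as well). Stratification is a deliberate
strengthening of a plain random split: at 90 samples an unstratified fold
can end up single-class, leaving fold metrics undefined. An unstratified
mode and other fold counts (e.g. five) remain available. With identical
data and seed the whole procedure is bit-reproducible.

Two details of the original protocol description are ambiguous and were
resolved as follows, configurably: the up-weighted class is taken to be
the metastasis-positive one (the study contains no lymphoma cases, so the
"lymphoma" wording is read as referring to metastatic-node images), and
averages are taken over all nine folds rather than five (the protocol
mentions both nine folds and an average of five results; averaging over
every held-out fold is the standard convention).

## Diagnostic-accuracy statistics

`confusion_metrics()` computes the five standard ratios as percentages
with 95% confidence intervals; `youden_lr()` adds Youden's index
($\mathrm{sens} + \mathrm{spec} - 1$) and likelihood ratios
($LR^+ = \mathrm{sens}/(1-\mathrm{spec})$,
$LR^- = (1-\mathrm{sens})/\mathrm{spec}$); `prevalence()` the positive
fraction; and `noninferiority_paired()` the paired comparison of two tests
on the same patients.

* **Interval method.** The default is the Wald interval $\hat p \pm
  z_{0.975}\sqrt{\hat p(1-\hat p)/n}$, clipped to $[0,100]$, because it is
  the form under which reported interval bounds in this setting reproduce
  exactly from their counts. Wilson and Clopper–Pearson exact intervals
  are available behind the `method` argument for users who prefer better
  small-sample coverage.
* **Reporting arithmetic.** Rounding is half-up and happens only at the
  reporting boundary (one decimal for percentages, three for Youden's
  index, four for likelihood ratios). Youden's index and the likelihood
  ratios are computed *from the rounded percentages*, matching how such
  tables are assembled from their printed rows; computing them from the
  raw fractions gives visibly different fourth decimals.
* **Noninferiority.** Correctness of each test on each patient (call
  matches true status) turns the paired table into discordant counts: $b$
  = patients only the new test gets right, $c$ = patients only the
  reference gets right. With margin $\delta$ the Wald statistic for paired
  proportions is $z = (d + \delta)/SE$, $d = (b-c)/n$, $SE =
  \sqrt{(b+c) - (b-c)^2/n}\,/\,n$, one-sided $p = 1 - \Phi(z)$. When $b =
  c = 0$ the standard error degenerates and the conclusion is reported
  directly from the sign of $d + \delta$. The test form is a design
  choice: descriptions of noninferiority analyses in this setting are
  often citation-only, and other forms (or a different correction) can
  yield somewhat smaller p-values than this statistic; the package
  documents its formula precisely so its output is reproducible. A power
  calculation is intentionally not implemented.
* Metrics with zero denominators are reported as `NA` (undefined), never
  as 0.

```{r}
confusion_metrics(tp = 39, fp = 10, tn = 34, fn = 7)
noninferiority_paired(paired_outcomes(positive = c(29, 10, 5, 2),
                                      negative = c(1, 9, 6, 28)))
```

## The phantom generator

`generate_phantom()` emulates the statistical structure the method
assumes, not neck anatomy:

* a baseline field (33 °C) plus Gaussian noise (default sd 0.3 °C, box-blur
  smoothed, radius 3 px) **mirrored about the vertical midline**, so
  negatives genuinely satisfy the bilateral-symmetry premise;
  `mirrored_noise = FALSE` gives independent noise per side, the harder,
  more realistic case;
* positives add, on one side only, a Gaussian-profile hotspot (peak 2 °C by
  default, scale `hotspot_radius`, kept a full radius away from the
  midline and the border) and/or vertical-biased random-walk vessel tracks
  with a Gaussian cross-section — the simplest structures producing the
  unilateral warm-focus and tortuous-vessel gradient content the entropy
  features respond to;
* fields are clamped to a physiologic 15–45 °C band, and every sample is
  bit-reproducible from its seed (per-sample seeds derive from a master
  seed in `generate_dataset()`).

The default study conditions used across the test suite are 45 + 45
phantoms at 128 × 128 px, 2 °C hotspot, 0.3 °C noise — a size at which the
full pipeline (generation, feature extraction, nine-fold cross-validation,
and a 20-permutation label-shuffle null) runs in seconds on one core.

What phantoms do **not** model: anatomy and perspective, camera noise
statistics, emissivity and calibration drift, bilateral disease, and any
physics-based (bioheat) temperature structure. Passing the phantom study
therefore shows that the implementation separates the signal structure it
targets from symmetric backgrounds at realistic noise; it does not certify
clinical performance, which can only come from patient data.

`asymmetry_screen()` automates the >1 °C symmetry criterion: after 3 × 3
mean smoothing (part of the screen's definition — it suppresses
single-pixel excursions), the temperature field is compared with its
mirror image and flagged when the maximum absolute difference strictly
exceeds the threshold. The visual criteria of qualitative thermogram
reading (vessel morphology judgments) have no stated operator and are out
of scope.

## Known limitations

* The linear min–max grayscale conversion ties gray statistics to the
  per-image temperature extremes; a single hot pixel compresses the rest
  of the range. Fixed bounds can be supplied where cross-image
  comparability matters.
* Entropy features are global over the window sequence: they detect *that*
  structure differs between scales, not *where* it lies, so the method is
  a per-image (per-patient) screen, not a localizer.
* With 90 samples, cross-validated metrics have wide sampling variability;
  the averaged-fold protocol reports that variability only through the
  per-fold table (`tidy()` on the CV result).
* The solver's convergence tolerance (default `1e-4`) bounds the
  reproducibility of the hyperplane across sample orderings; tighten it
  via `egsvm_config(tolerance = )` when exact agreement matters.
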