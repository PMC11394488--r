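---
title: "Dual-attention multiple-instance learning for recurrence risk: methods and design notes"
author: "damil authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-attention multiple-instance learning for recurrence risk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

After surgical resection of lung adenocarcinoma, a substantial fraction of
patients recur within five years. Histologic grading predicts outcome only
coarsely, so there is clinical interest in learning recurrence risk directly
from the resection slides. A whole-slide image (WSI) is a gigapixel scan; the
only supervision available is a per-patient binary outcome (recurrence within
five years, RC, vs none, NRC) plus the recurrence-free time in months. This
is the classic weakly supervised, multiple-instance learning (MIL) regime:
each slide is a *bag* of thousands of patch embeddings, and the label
attaches to the bag, not to any patch.

`damil` implements the full pipeline for this problem — slide preprocessing,
tumor-bulk restriction, representative-key selection, a dual-attention MIL
aggregator with its training protocol, patient-level cross-validation, and
survival-based evaluation — together with a synthetic-data module that makes
every stage testable on a laptop with no external data.

# Pipeline stages and their models

## Tissue detection and patching

Foreground is detected on a slide thumbnail by HSV saturation thresholding:
stained tissue is strongly saturated while the glass background is nearly
grey. The saturation channel (0–255) is median-filtered (radius 2, i.e. a
5×5 window) and thresholded at 8 by default. Both values are config-exposed;
they are the common defaults for this thresholding approach, not claims about
any particular cohort. Patches are non-overlapping 896×896 tiles at the
highest pyramid level (40×), enumerated row-major, and kept when their
area-weighted tissue coverage is at least `min_tissue_frac` (default 0.5 — a
coverage rule has to exist, and half-coverage is the neutral choice).
Coverage is computed exactly by area-weighting mask pixels under the patch
footprint, so the selection is stable across mask raster resolutions.

Patch encoding sits behind a small interface (`$dim`, `$encode`): any model
mapping a 224×224 RGB patch to a fixed-length vector can be plugged in.
Patches are resized 896→224 before encoding, so a 40× crop is encoded at an
effective 10×. The bundled `toy_encoder()` projects a joint 8×8×8 RGB
histogram through a fixed seeded Gaussian matrix; it is deterministic and
color-sensitive, which is all the tests require. The pretrained
histopathology foundation encoder used in production settings is deliberately
not bundled (it is large, licensed, and orthogonal to the pipeline logic);
its output dimension, 768, is the package default for `D`.

## Tumor-bulk restriction

Recurrence signal is expected in the primary tumor region, so bags are
restricted to tumor-bulk patches before aggregation. Patch-level tumor
probabilities come from a pluggable classifier (the bundled toy classifier
thresholds mean patch color; a trained CNN honoring the same contract can be
loaded). Scores are rasterized to a binary mask *at patch-grid resolution* —
one cell per 896-px patch — which keeps the subsequent morphology scale-free.
The mask is refined by binary closing (disc radius 1 cell), removal of
8-connected components smaller than 8 cells, and a per-component convex hull
fill. The hull is per component rather than global so that multifocal tumors
are not merged across the slide. A slide whose bag empties out after masking
is flagged for exclusion rather than silently passed through.

## Key-set construction (categorical representation learning)

Each training slide contributes its `m` highest-leverage patch embeddings
(default m = 4). For a bag matrix `E` (n×D) the leverage score of instance i
at rank r is the i-th diagonal entry of the projection onto the top-r left
singular subspace, `sum_{j<=r} U[i,j]^2`; scores lie in [0,1] and sum to r.
The selection rank is the smallest r whose singular values capture 90% of
squared spectral mass, capped at 32 — an energy rule makes r data-adaptive
and cheap to test against the dense hat matrix. Selections from **all**
training slides, RC and NRC alike, are concatenated in slide order into one
joint key set `K ∈ R^{D×τ}`; a single joint key set (rather than one per
class) is what makes the aggregator parameter-efficient. Key-set provenance
(slide id and row per key) is recorded and used as a hard leakage guard:
training refuses to start if a validation or test slide appears in it.

## The dual-attention aggregator

Given a bag `Q = [q_1..q_n] ∈ R^{D×n}` and the key set `K`, three linear
maps embed them: `K~ = W_k K`, `Q~ = W_q Q`, `V~ = W_v Q`, all in `R^{Dh×·}`.
Cross-attention is computed as a transformer decoder attends over its input
sequence:

    H = softmax(K~ᵀ Q~ / sqrt(Dh)) V~ᵀ ,  H ∈ R^{τ×Dh}

Two choices here were genuinely open and are worth recording:

* **Softmax axis.** The softmax normalizes over the *patch* axis (each of
  the τ rows is a distribution over the n patches), so every key slot
  aggregates a convex combination of patch values. This is the only reading
  consistent with "as a transformer decoder does" — decoder cross-attention
  weights normalize over the attended sequence — and it makes the output
  exactly invariant to patch order, which the test suite asserts end to end.
* **Scale factor.** The scores are scaled by `1/sqrt(Dh)`, the standard
  decoder scaling, rather than `1/Dh`.

Gated attention then pools the τ fused vectors: the weight of row `h_i` is

    a_i ∝ exp{ w (tanh(V h_iᵀ) ⊙ sigm(U h_iᵀ)) },   z = Σ_i a_i h_i

with `V, U ∈ R^{L×Dh}` and `w ∈ R^{1×L}` carrying no bias (matching the
standard gated-attention formulation; the three embeddings and the head do
carry biases). No nonlinearity is applied to `H` before the gate — nothing in
the architecture requires one, and adding one would be an undeclared degree
of freedom. The head is a single affine map from `z` to two logits.

The whole model is plain matrix code with an analytic backward pass, verified
in the tests against central finite differences (atol 1e-5) and against a
pure-loop scalar implementation of the three equations. Complexity is
`O(τ·n·Dh)` — linear in bag size at fixed τ, never `O(n²)` — which the MAC
counter asserts by exact second differences.

At the reference budget configuration (D = 1024, Dh = 512, L = 256, biases on
embeddings and head only) the model has

    3·(1024·512 + 512) + 2·(256·512) + 256 + (512·2 + 2) = 1,837,826

trainable parameters, under the published 2.10M budget for this architecture.
The published budget is treated as an upper bound: the exact hidden sizes
behind it are not published, so equality is not asserted.

## Training protocol

Adam with learning rate 8e-5 and weight decay 1e-5 (L2 added to the
gradient, as in the common Adam implementation), batch size one (bags have
varying shapes), and inverse-class-frequency weighted sampling with
replacement so RC and NRC are drawn equally often per epoch — imbalance is
handled entirely by the sampler, the loss itself is unweighted cross-entropy.
An epoch is as many draws as there are training bags. Early stopping: 5
initial epochs always run; afterwards training stops once the validation
loss has gone 5 consecutive epochs without a *strict* improvement over the
best value seen, capped at 50 epochs; the best-validation checkpoint is
returned. Under this reading a validation trace that is flat from epoch 1
stops at epoch 10 (5 warm-up + 5 patience), which the unit tests pin down
with scripted traces.

## Cross-validation and evaluation

Splitting is stratified five-fold at *patient* level: per class, patients are
shuffled and dealt into five test folds whose sizes differ by at most one;
within each fold the remaining patients are split per class into validation
(1/6 by default — the published train/validation/test sizes imply roughly
this ratio, which is otherwise unstated) and training. All slides of a
patient travel together. For a 71-RC/118-NRC cohort this yields test folds of
{15,14,14,14,14} RC and {24,24,24,23,23} NRC patients — modal 14 RC / 24 NRC.

Slide-level scores are evaluated with AUROC (pair-probability definition,
ties half), accuracy, specificity and sensitivity on the 0–100 scale,
reported fold-wise as mean ± sd. Patients are scored by their most
suspicious slide (max rule; switchable to mean — the aggregation rule is
unstated in the source setting, and the max rule matches how a pathologist
would read multiple blocks). Risk groups at the 0.5 threshold feed a
univariate Cox proportional-hazards model — Newton–Raphson on the Breslow
partial likelihood to |Δβ| < 1e-8, Wald 95% CI — and a Kaplan–Meier
product-limit table per group. Times are administratively censored at 60
months before fitting, matching the five-year framing. Breslow (not Efron)
tie handling is used because it is the simplest well-defined choice and ties
are measure-zero in the continuous synthetic times; the implementation is
tested to 1e-6 against an independent reference fitter. The Cox model is fit
at patient level (the natural unit for survival), a choice the source setting
leaves open.

# The synthetic world

The generator states one fixed world; its defaults are not tuned per test.

* **Cohort scale**: 71 RC / 118 NRC patients, 1–3 slides per patient
  (~2.4 on average), 40–80 instances per bag. Bag size is exposed as a range
  because no per-slide patch-count distribution is published (the n = 120 in
  the budget table is a budgeting convention, not data).
* **Instance model**: background instances are standard isotropic Gaussians
  in `R^D` (D = 64 by default at test scale); in RC bags,
  `ceil(witness_rate·n)` instances (witness rate 0.2) are shifted by
  `effect_size` (default 4) along one fixed random unit direction per
  cohort. This is the simplest controllable MIL signal: a minority witness
  population that low-rank leverage selection and attention should find.
* **Survival model**: recurrence-free times are exponential with rate
  λ_nrc = −log(0.65)/60 for NRC — i.e. ~35% of NRC patients event within 60
  months, keeping both events and censoring present — and λ_nrc·HR for RC
  with true HR 2.3; administrative censoring at 60 months.
* **Toy slides**: flat background, textured "normal tissue" region, circular
  tumor blobs with known centers/radii — exact ground truth for tissue
  detection, patching, and tumor-bulk masking.

What a green test does establish: the pipeline's stages compose correctly,
selection and attention find a planted minority signal, training descends,
no leakage occurs, and the survival machinery recovers a known hazard ratio.
What it does not establish: performance on real histology. The generator
makes no attempt to mimic stain statistics, texture, spatial correlation of
patches, or the geometry of real foundation-model embeddings, and a real
cohort's signal is far weaker than a 4-sigma witness shift. The published
real-data numbers (HR ≈ 2.3 at AUROC ≈ 65 on a private cohort) are therefore
out of scope here and are not asserted by any test.

# Numerical choices

* Softmax is computed with max-subtraction everywhere; attention rows and
  gate weights sum to 1 to 1e-6 by construction, asserted in tests.
* Leverage scores: `svd()` on the bag matrix; the trace identity Σs = r is
  asserted to 1e-6. Scores are rounded to 9 decimals before ranking so that
  duplicated rows tie-break deterministically by row index.
* Cox Newton steps are clamped to |step| ≤ 5 and |β| > 15 is flagged as a
  monotone likelihood rather than iterated to overflow.
* Per-stage seeds are derived from one global seed by fixed integer offsets
  (kept below 2³¹), so each stage is independently reproducible and reruns
  are bitwise identical.
* The working model width for the D = 64 synthetic regime is Dh = 16, L = 8:
  at a 4-sigma witness shift the problem does not need more capacity (test
  AUROC is already saturated), and the narrow model keeps the full five-fold
  CPU run well inside its time budget. The reference budget configuration
  (Dh = 512, L = 256) is used only for parameter accounting.

# Known limitations

* No stain normalization; slides lacking a 40× level are rejected, not
  rescaled.
* The bundled encoder and tumor classifier are toys; results on real slides
  depend entirely on the plugged-in models.
* Serialization uses plain-text containers (CSV/JSON, ASCII netpbm) rather
  than HDF5; adequate at test scale, not for production-size cohorts.
* The Cox utility handles a single binary covariate only — risk-group
  stratification — not multivariable adjustment.
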