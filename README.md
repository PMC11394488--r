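# damil

Dual-attention multiple-instance learning (MIL) for predicting five-year
cancer recurrence from whole-slide images (WSIs), with Cox
proportional-hazards risk stratification.

## What problem this solves, and for whom

After surgical resection of lung adenocarcinoma, recurrence within five
years is common, and histologic grading predicts it only coarsely. The only
supervision routinely available is per-patient: did the patient recur (RC)
or not (NRC), and how long were they recurrence-free. `damil` is for
computational-pathology researchers who want a complete, testable, pure-R
reference implementation of the weakly supervised pipeline for this setting:

1. **Preprocess** — tissue detection by HSV-saturation thresholding,
   non-overlapping 896×896 patch enumeration at 40×, patch encoding behind a
   pluggable encoder interface (resized to 224×224, i.e. effective 10×).
2. **Tumor bulk** — patch-level tumor/normal scoring (pluggable classifier),
   rasterization to a patch-grid mask, morphological refinement (closing,
   small-object removal, per-component convex hull), bag restriction.
3. **Key set** — each training slide contributes its `m` highest statistical
   *leverage* patch embeddings (diagonal of the hat matrix onto the top-r
   singular subspace, r chosen by a 90% spectral-energy rule); selections
   from all training slides form one joint key set `K ∈ R^{D×τ}`.
4. **Aggregator** — cross-attention of the key set against the bag,
   `H = softmax(K̃ᵀQ̃ / √Dh) Ṽᵀ`, followed by gated attention
   `a_i ∝ exp{w(tanh(Vh_iᵀ) ⊙ sigm(Uh_iᵀ))}`, `z = Σ a_i h_i`, and an
   affine head to RC/NRC probabilities. Pure matrix code with analytic
   backprop; O(τ·n·Dh), permutation-invariant in the instances.
5. **Training / CV** — Adam (lr 8e-5, weight decay 1e-5), batch size one,
   inverse-frequency weighted sampling, early stopping (5 warm-up epochs,
   patience 5, cap 50), patient-level stratified five-fold cross-validation
   with a hard key-set leakage guard.
6. **Evaluation** — AUROC/accuracy/specificity/sensitivity (0–100 scale,
   mean ± sd over folds), max-slide patient aggregation, univariate Cox
   (Newton–Raphson, Breslow ties, Wald CI) and Kaplan–Meier tables with
   administrative censoring at 60 months.

A first-class synthetic module generates embedding bags with a planted
minority "witness" signal in RC slides, exponential survival with a
configurable true hazard ratio, and toy slide images with ground-truth tumor
blobs — so the entire pipeline runs and is tested without any external data.

## Worked example

```r
library(damil)

# a small synthetic cohort: 30 RC / 40 NRC patients, 1-2 slides each,
# 20% witness instances in RC bags at 4-sigma separation, true HR 2.3
cfg <- pipeline_config(
  synthetic_data = list(n_rc = 30, n_nrc = 40, slides_per_patient = c(1, 2),
                        n_instances = c(30, 50), dim = 32),
  model = list(d_hidden = 8, l_gate = 4),
  seed = 42, out_dir = "run42"
)
run_pipeline(cfg)   # ~1 minute on one CPU

metrics <- jsonlite::read_json("run42/metrics.json", simplifyVector = TRUE)
cox     <- jsonlite::read_json("run42/cox.json", simplifyVector = TRUE)
metrics[, c("metric", "mean", "sd")]
#>        metric      mean         sd
#> 1       auroc  99.71429  0.6388766
#> 2    accuracy  90.93996  6.8982108
#> 3 specificity  83.52814 12.2835259
#> 4 sensitivity 100.00000  0.0000000
sprintf("HR %.2f (95%% CI %.2f-%.2f, p = %.3g)",
        cox$hr, cox$ci_low, cox$ci_high, cox$p)
#> [1] "HR 2.07 (95% CI 1.01-4.26, p = 0.0471)"
```

Reading the output: the metrics are mean ± sd over the five test folds of
slide-level predictions. The aggregator ranks held-out slides nearly
perfectly (AUROC 99.7 — the planted witness signal is strong and the
key-set + attention machinery finds it); every RC slide is called at the 0.5
threshold (sensitivity 100) at the cost of some false alarms (specificity
83.5). Aggregating slides to patients by the max rule and fitting the Cox
model on predicted risk groups estimates that high-risk patients recur about
2.1× faster (CI just excluding 1) — the generator's ground truth for this
draw is HR 2.3, and a 70-patient cohort estimates it about that coarsely.

Per-slide predictions are in `run42/predictions.csv`, the Kaplan–Meier
table in `run42/km.csv`, and the run manifest (stages, seeds, digests) in
`run42/manifest.json`.

## Command line

```sh
damil simulate  --config cfg.json --out DIR --seed 3     # bags + cohort CSV
damil segment   --slide slide.ppm --out DIR              # tumor-bulk mask
damil keyset    --bags DIR/bags --out keyset             # leverage key set
damil run       --config cfg.json --out DIR --seed 3     # full pipeline
damil evaluate  --pred pred.csv --cohort cohort.csv --out report/
```

(`exec/damil` is installed with the package; invoke it via
`Rscript $(Rscript -e 'cat(system.file("exec","damil",package="damil"))') ...`
or put it on your PATH.)

## Layout

- `R/` — implementation (synthetic data, preprocessing, tumor bulk, key set,
  model, training/CV, survival evaluation, pipeline/config)
- `tests/testthat/` — unit, property and acceptance tests; all fixtures are
  generated in code
- `vignettes/damil-methods.Rmd` — the model, its assumptions, tunable
  parameters, synthetic-world rationale, numerical choices, limitations
- `scripts/acceptance.R` — the acceptance report
- `exec/damil` — command-line entry point
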