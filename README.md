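# hbimage

Non-invasive hemoglobin estimation from eyelid and fingernail
photographs, with rule-based clinical corridor triage.

## What it is for

Patients with hematologic malignancies need hemoglobin (Hb) checked one
to two times a week, which today means repeated venipuncture and
hospital visits. Tissue without melanocytes — the palpebral conjunctiva
and the nail bed — shows blood color directly, so an ordinary RGB
photograph carries an Hb signal. `hbimage` is a complete, tested R
implementation of the corresponding analysis pipeline for researchers
working on image-based digital biomarkers:

- **Synthetic study generator** — a 551-entry cohort (184 healthy
  donors, 101 anemic and 266 non-anemic patients, anemia threshold
  6.21 mmol/L), repeat visits, EORTC QLQ-C30 Global Health / Fatigue
  scores linked to Hb, clinician triage labels, and rendered image
  patches with known ground truth. No data download is needed; every
  downstream stage is testable against construction-time truth.
- **ROI refinement** — iterative 4-connected mask erosion to ~30% pixel
  retention (fingernails); gradient-edge map + Hough circle transform,
  keeping the lower circle segment (eyelids).
- **Chromatic features** — HSV hue extraction, normalized 36-bin hue
  histograms, PCA compression (fitted inside training folds only).
- **Predictors** — closed-form ridge regression and gradient-boosted
  regression trees (exact-split least-squares boosting in C++), each
  also as a one-vs-rest three-class corridor classifier.
- **Evaluation** — 10-fold cross-validation grouped by patient ID with
  a hard leakage assertion, median aggregation of per-image predictions
  per (patient, visit), and the full metric suite: residual SD, MSE,
  R², weighted/macro F1, corridor confusion matrices, Type-1/Type-2
  corridor error rates.
- **Corridor decision layer** — Hb discretized into Red (< 4.5 mmol/L),
  Yellow (4.5–6.0) and Green (> 6.0); EORTC scores mapped to corridor
  strata; deterministic equal-weight majority vote with a conservative
  tie-break (Red > Yellow > Green); concordance against clinician
  labels.

The statistic at the core is the cross-validated regression of Hb
(mmol/L) on PCA-compressed hue-histogram features,
`R² = 1 − SSres/SStot`, plus the deterministic vote
`label = majority(Hb corridor, GH corridor, Fatigue corridor)`.

## Worked example

```r
library(hbimage)

# corridor primitives
hb_to_corridor(c(4.2, 5.1, 7.3))
#> [1] "Red"    "Yellow" "Green"
majority_vote("Yellow", "Red", "Red")   # Yellow Hb, both QoL strata Red
#> [1] "Red"

# erosion refinement on a 10x10 solid square: snapshots retain
# 1.00 / 0.64 / 0.36 / 0.16 of the pixels; 0.36 is closest to the
# 30% target
erode_mask(matrix(TRUE, 10, 10))$retained_fraction
#> [1] 0.36

# end-to-end demo: 60-entry synthetic cohort, combined eyelid +
# fingernail GBM arm, 5-fold patient-grouped CV
out <- file.path(tempdir(), "demo")
run_pipeline(demo_config(seed = 1, out_dir = out))
ev <- jsonlite::read_json(file.path(out, "evaluation.json"))
ev$pooled$r2
#> [1] 0.8292077
```

The demo writes `cohort.csv`, rendered patches (`images/*.ppm` with
coarse/refined masks and ground-truth sidecars), `features.csv`,
`model.json`, `evaluation.json` (pooled R² 0.829, residual SD
0.671 mmol/L, MSE 0.444 for this seed — per-fold values included),
`decision.csv`, `concordance.json` (agreement 0.667 over the 12
QoL-complete entries against the synthetic clinician labels) and a
`manifest.json` with content hashes. At full scale (551 entries,
default noise), the combined GBM arm reaches pooled cross-validated
R² ≈ 0.96 — the strong-signal analogue computed by the acceptance
suite.

A command-line front end mirrors the stages:

```sh
Rscript -e 'hbimage::hbimage_cli()' all --seed 1 --out run1
Rscript -e 'hbimage::hbimage_cli()' decide --input preds.csv --out dec1
```

## Limits

The synthetic renderer has no melanin, illumination physics or camera
processing; green tests establish that the machinery recovers a signal
present by construction and invents none when absent — not accuracy on
real photographs. The decision layer contextualizes estimates; it is
not a treatment recommendation system.
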