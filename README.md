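# lonesense

Momentary loneliness — "How lonely do you feel right now?" on a 0–100
slider, prompted five times a day — fluctuates too fast for retrospective
questionnaires. `lonesense` implements a fully objective pipeline that
detects it from passively sensed smart-device data: wrist-PPG heart-rate
variability, nightly ring sleep summaries, and phone behavior (GPS
mobility, calls, messages, app notifications, screen use). It is built
for researchers in digital phenotyping / mobile mental-health sensing who
want a tested, end-to-end reference implementation of this kind of
analysis, exercised entirely on a synthetic cohort with known ground
truth (no such dataset is publicly deposited).

## What the pipeline does

1. **Synthetic cohort** (`simulate_cohort()`): a latent loneliness process
   per participant (day-level AR(1) + within-day drift) drives, with
   configurable standardized effect sizes, the generated streams:
   heart rate up, HRV down, home-stay up, visited places down,
   communication down, Social-app notifications up. Ground truth (true
   beats, noise masks, homes, visits, couplings) is retained.
2. **PPG chain**: per 12-minute segment — signal-quality assessment on
   30-s windows (five features: IQR, PSD spread, cycle-energy range,
   template distance and correlation), reconstruction of interior noisy
   runs shorter than 15 s by template tiling at the local IBI, systolic
   peak detection (band-pass, adaptive threshold, 300-ms refractory,
   parabolic refinement), IBI screening ([300, 2000] ms, 30% jump rule),
   and HR/HRV features (meanNN, SDNN, RMSSD, CVSD, CVNN, LF, HF, LFn,
   HFn, SDANN1/5).
3. **Behavior**: stay-point places, home = dominant night-time place, the
   ten standard location features, call/message/notification/screen
   features over an 18-category app map.
4. **Assembly** (`assemble_features()`): per-feature optimum look-back
   window from {4, …, 48} h by correlation with the scores, >30%
   missingness drop, imputation method A (local neighbours) vs B
   (participant mean) chosen by majority vote, per-participant
   median-split labels, per-participant z-normalization from training
   rows.
5. **Modeling** (`evaluate_all()`, `evaluate_ablation()`): one
   random-forest detector per participant — trained on that participant's
   earliest 50% plus everyone else, tested on their most recent 50% —
   with confusion counts pooled over all test rows:
   accuracy, precision, recall, F1, MSE = (FP+FN)/n (so accuracy+MSE=1),
   rank-statistic AUC; repeated per device subset.
6. **Explainability** (`tree_shap()`, `aggregate_importance()`): native
   path-dependent TreeSHAP on the vote-fraction output, validated against
   an exhaustive Shapley oracle, aggregated to a participant × feature
   mean-|SHAP| matrix and signed summaries.

## Worked example

The numbered scripts under `analysis/` run the whole study on a
30-participant × 56-day strong-coupling cohort plus a zero-coupling
control:

```sh
Rscript analysis/01_simulate.R 11
Rscript analysis/02_extract_features.R
Rscript analysis/03_assemble.R
Rscript analysis/04_model.R
Rscript analysis/05_explain.R
```

With seed 11 this prints, along the way:

```
EMA responses: 7539 | PPG segments: 20160 | GPS fixes: 929047 | phone events: 289522
segments with usable HRV: 18605/18612 (100.0%)
records: 7539 | features kept: 59 | dropped (>30% missing): 2 | imputation method: A
            devices  accuracy precision    recall        f1       mse       auc
               ring 0.8170699 0.8137890 0.7877924 0.8005797 0.1829301 0.8985719
              watch 0.8391385 0.8257662 0.8300057 0.8278805 0.1608615 0.9224934
              phone 0.7428875 0.7222851 0.7284655 0.7253621 0.2571125 0.8209620
   phone+ring+watch 0.8457857 0.8361032 0.8322875 0.8341910 0.1542143 0.9287678
null-cohort pooled accuracy 0.457 (chance band)
```

Reading this: the planted couplings are recovered — the all-device
detector reaches pooled accuracy 0.846 (AUC 0.93) over 3,761 held-out
records, beats every single-device model (multimodality gain), and the
identity accuracy + MSE = 1 holds row by row; on the zero-coupling
control the same pipeline stays at chance (0.457), so the accuracy is
signal, not leakage. The SHAP ranking puts the strongly coupled HRV and
nocturnal-ring features at the top (`hrv_rmssd`, `hrv_sdnn`, `hrv_cvsd`,
…) and uncoupled channels at the bottom. Outputs land in `results/`
(`features.csv`, `ablation.csv`, `model_report.json`, `shap_matrix.csv`,
`top_features.json`).

## Design notes

The methods vignette
(`vignettes/loneliness-detection-pipeline.Rmd`) documents the model and
its assumptions, every tunable parameter with units and defaults, what
the synthetic generator does and does not emulate, numerical conventions
(population SDs, tie rules, degenerate-input handling) and known
limitations.
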