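# semgwfm

Lower-limb action recognition from multichannel surface electromyography
(sEMG), built around two ideas: a **weighted feature method** (WFM) that
scales each channel's features by that muscle's share of the signal energy,
and an **improved genetic algorithm** (IGA) that tunes an RBF-SVM's penalty
`c` and kernel parameter `g` with championship-plus-sorted-tier selection.
The package is aimed at researchers in myoelectric pattern recognition and
rehabilitation robotics who want a tested, fully reproducible reference
implementation of this pipeline.

A trial is an 8-channel recording (rectus femoris, biceps femoris, tibialis
anterior, gastrocnemius of both legs; 2000 Hz; 10 s) labelled with one of
six actions `y1..y6` (raise/lower right/left leg, sit-to-stand,
stand-to-sit). The pipeline:

1. **Onset detection** — frames of `L = 64` samples advancing by `I = 32`;
   frame energy `En(i) = Σ x²`; adaptive threshold `th = Σ En(i) / M`; the
   onset is the first frame with `En > th` in that frame and the next three.
   The **main feature segment** is the 2 s starting 0.5 s after the onset
   sample `SN = (FS−1)·I + 1`.
2. **Features per channel** over 64/32 sliding windows: MAV, RMS, Willison
   amplitude (threshold 10 µV), and EC1 = `log10(mean |S_j|²)` with `S_j`
   the window's wavelet-packet coefficients (db4, depth 3).
3. **WFM** — channel weights `C_i = n · sumabsX_i / sumabsX` (n = number of
   channels), applied to the per-channel feature vectors before fusion.
4. **IGA-SVM** — fitness = stratified k-fold CV accuracy of the RBF-SVM at
   `(c, g)`; the population is sorted into bad/medium/well/good tiers,
   selected with probabilities `P, P+σ, P+2σ, P+3σ`, recombined and
   mutated, and refilled with intact elites from the good tier.

No public dataset covers these six actions, so the package includes a
synthetic generator (`generate_recording()`, `generate_dataset()`) producing
8-channel band-limited (10–500 Hz) surrogate sEMG with known onsets and
per-action muscle gain profiles, plus the published worked-example energy
and weight tables as fixtures (`table2_fixture()`, `table3_fixture()`).

## Worked example

Channel weights from the packaged energy table — action 1 (raise right leg),
eight channels:

```r
library(semgwfm)
round(channel_weights(table2_fixture()["action1", ]), 4)
#>    CH1    CH2    CH3    CH4    CH5    CH6    CH7    CH8
#> 0.8208 1.3780 0.6304 0.5641 0.4664 1.8686 1.1319 1.1397
```

The weights sum to 8 (the channel count) by construction; CH6 (left biceps
femoris) contributes most energy to this action and is up-weighted, CH5
(left rectus femoris) least. The same computation over all six actions
reproduces the published correlation table to its printed 4 decimals.

End-to-end on synthetic data:

```r
cfg <- pipeline_config(
  sim = sim_config(n_per_class = 20, duration = 5),
  profiles = default_action_profiles(burst_onset = 1, burst_duration = 3),
  ga = ga_config(pop_size = 16, max_generations = 4, cv_folds = 3),
  use_wfm = "both", seed = 101)
report <- run_pipeline(cfg)
report$wfm$accuracy   # test accuracy with channel weighting
report$raw$accuracy   # unweighted ablation on the same split
report$wfm$best_c; report$wfm$best_g
```

On this 6×20 problem, seed 101 gives a weighted test accuracy of 0.950
against 0.933 for the unweighted ablation, with the GA selecting a large
penalty (`best_c ≈ 7.8e3`) and `best_g ≈ 0.11`. `report_json(report, path)`
writes the full report — counts, exclusions, best `(c, g)`, fitness
history, per-class accuracy, confusion matrix — as byte-stable JSON.

A thin command-line wrapper is included at `inst/cli/semgwfm.R`
(`run --config run.yaml --out report.json`, `simulate --n-per-class 10
--outdir data/`).

## Package layout

- `R/recording.R` — recording/manifest containers, CSV I/O, splits
- `R/segmentation.R` — framing, frame energy, adaptive threshold, onset,
  main-segment extraction, denoising
- `R/wavelet.R` — periodized DWT/WPT filter banks (db4, Haar), soft
  thresholding
- `R/features.R` — MAV/RMS/WA/EC1, windowing, (−1, 1) normalisation
- `R/wfm.R` — channel energies, weights, fusion, dataset assembly
- `R/iga_svm.R` — tiered GA, tournament baseline, SVM training/evaluation
- `R/synthetic.R`, `R/tables.R` — generator and reference fixtures
- `R/pipeline.R` — orchestration and JSON reports
- `vignettes/weighted-feature-method.Rmd` — models, parameters, design
  rationale, limitations
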