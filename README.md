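# gazedx

Dynamic visual attention analysis for autism screening from eye tracking.

Preschool children on the autism spectrum often show a visual preference for
dynamic geometric motion over social motion when the two are shown side by
side (the preferential-looking / "GeoPref" paradigm). `gazedx` implements a
complete computational pipeline that turns raw gaze recordings from such a
split-screen video task into a diagnostic classifier and a symptom-severity
predictor:

1. **Fixation processing** — a velocity-threshold (I-VT) filter with the
   standard post-processing chain: adjacent fixations ≤ 75 ms and ≤ 0.5°
   apart are merged, fixations < 100 ms are discarded, and recordings with
   < 15 s of total fixation time are excluded. All angular constants are
   converted through explicit screen/stimulus geometry.
2. **Difference-of-fixation (DoF) maps** — per video frame, each group's
   fixations are overlaid in a binary map, smoothed with a 1° Gaussian and
   sum-normalised into heatmaps *I⁻* (reference group, e.g. TD) and *I⁺*
   (contrast group, e.g. ASD). The DoF map is the logistic transform of the
   SD-normalised difference *I = I⁻ − I⁺*:

   D = 1 / (1 + exp(−I / σ_I))

   so cells where the groups attend equally sit at 0.5, white regions mark
   reference-group attention and black regions contrast-group attention.
3. **Video saliency network** — a compact convolutional encoder with a
   static attention gate, a convolutional recurrence over frames, and a
   sigmoid decoder predicts the per-frame DoF map. It is fine-tuned with
   Adam (learning rate 1e-4, 20 epochs) on the combined saliency loss

   L = L_KL + 0.1·L_LCC + 0.1·L_NSS,   L_d = Σ_t L(Y_t, Q_t)

   where L_KL is the KL divergence between renormalised maps, L_LCC the
   negative Pearson correlation and L_NSS the negative target-weighted
   standardised prediction. Backpropagation (through the recurrence) is
   implemented analytically and verified against finite differences.
4. **Feature cascading + SVM** — per fixation, a C-dimensional feature
   vector is read from the (4× bilinearly upsampled) recurrent feature
   volume at the fixated location; the first K fixation-stage vectors are
   concatenated in temporal order and zero-padded to length K·C. A linear
   SVM (C = 1) with per-fold Platt probability calibration is evaluated by
   leave-one-out cross-validation; pooled per-fold probabilities yield the
   ROC AUC.
5. **Baselines and statistics** — the %Geo preferential-looking statistic
   (share of fixation time on the geometric half), the published
   %Geo > 69 % threshold rule, random-forest / decision-tree baselines on
   handcrafted features, pooled-variance t tests from group summaries, and
   confusion-matrix arithmetic.
6. **Synthetic cohorts** — a generator for split-screen stimuli (drifting
   grating vs. moving blobs, alternating sides) and group-conditional gaze
   with known ground-truth %Geo, so the whole pipeline is testable without
   any recorded data.

## Worked example

```r
library(gazedx)

# geometry of the reference setup: 1281x720 stimulus on a 22" monitor at 60 cm
screen_geometry()
#> <screen_geometry> screen 1680x1050 px (47.6 cm wide) at 60 cm
#>   stimulus 1281x720 px, display scale 1.3115; 1 deg = 36.96 px

# group comparison of %Geo from published summary statistics
pooled_t_test(49.37, 24.14, 57, 35.97, 18.58, 17)
#> t(72) = 2.106, p = 0.0387

# diagnostic metrics from confusion counts
metrics_from_confusion(tp = 57, fn = 0, tn = 13, fp = 4)
#> accuracy 94.59%, sensitivity 100.00%, specificity 76.47%  (tp=57 fp=4 tn=13 fn=0)

# end-to-end synthetic run: simulate -> I-VT -> DoF -> train -> SVM -> evaluate
res <- run_pipeline(list(task = "diagnosis", seed = 42, out_dir = "run",
                         n_asd = 10, n_td = 10, n_moderate = 5,
                         geo_mean_asd = 85, geo_sd_asd = 8,
                         geo_mean_td = 15, geo_sd_td = 8))
str(res$metrics)
#> List of 7
#>  $ task       : chr "diagnosis"
#>  $ K          : num 16
#>  $ n_folds    : int 20
#>  $ accuracy   : num 100
#>  $ sensitivity: num 100
#>  $ specificity: num 100
#>  $ auc        : num 1
```

The t statistic says the ASD group's mean %Geo (49.37 %) sits about two
pooled standard errors above the TD group's (35.97 %). The pipeline run
simulates a 20-child cohort whose groups prefer opposite screen halves
(85 % vs 15 % mean %Geo) and recovers that separation perfectly under
leave-one-out cross-validation; the run directory contains the per-fold
probabilities, fixation tables, loss trace and a checksummed manifest.

A thin command-line front-end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/gazedx.R", package="gazedx"))')" \
    run --config run.yaml --seed 42
```

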