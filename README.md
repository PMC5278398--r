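# chewsense

Automatic monitoring of ingestive behavior from a pair of sensor-equipped
glasses. Contraction of the temporalis muscle during mastication presses the
glasses temple outward; a load cell embedded in each hinge senses that force
after mechanical amplification by the temple's natural lever action. From
the two hinge-force channels (left and right), this package classifies six
facial behaviors: natural head movement (NHM), left chewing (LC), right
chewing (RC), left wink (LW), right wink (RW) and talking (TK).

The package is aimed at researchers prototyping wearable chewing/eating
detectors: it provides the full processing chain plus a synthetic-signal
generator, so every stage is testable without human recordings.

## The model

**Lever mechanics.** The temple pivots about the hinge joint. With the
muscle contact at distance *L*<sub>temple</sub> from the joint and the hinge
load cell at *L*<sub>hinge</sub>, moment equilibrium gives

  *F*<sub>hinge</sub> = (*L*<sub>temple</sub> / *L*<sub>hinge</sub>) · *F*<sub>temple</sub>

so the weak muscle force is amplified by the dimensionless lever-arm ratio
(7.67 for the default 69 mm / 9 mm geometry). `simulate_bench()` reproduces
the bench validation: a linear stage loads the temple in 50 µm steps and the
amplification factor is recovered as the slope of the
*F*<sub>hinge</sub>-on-*F*<sub>temple</sub> regression.

**Classification chain.** Recordings are segmented into consecutive 3-s
single-label windows (a window spans several mastication cycles at
0.94–2.17 Hz). Each window is median-centered per channel (removing the
subject-specific pre-load), low-pass filtered (zero-phase 5th-order
Butterworth, 10 Hz), Hann-tapered and Fourier-transformed into a
single-sided periodogram PSD with 1/3 Hz resolution. An 84-dimensional
feature vector is extracted per window: 20 temporal statistics per side, 20
spectral statistics of the 0–10 Hz PSD per side (including 0.94–2.17 Hz
chewing-band power), and 4 cross-channel features (Pearson correlation,
signal magnitude area, log left/right RMS ratio, cross-correlation lag).
Features are z-scored with scalers fitted on training subjects only, and a
multiclass RBF-kernel SVM (one-vs-one) is selected by a two-step exponential
(C, γ) grid search under leave-one-subject-out (LOSO) cross-validation.
Evaluation reports the 6×6 confusion matrix with per-class precision,
recall, F1 and their arithmetic-average F1.

## Worked example

The numbered drivers under `analysis/` run the whole study on a synthetic
cohort (10 subjects, 60 windows per class per subject, 100 Hz):

```sh
Rscript analysis/01_simulate.R   # cohort CSVs -> results/data/
Rscript analysis/02_mechanics.R  # bench-sweep validation of the lever model
Rscript analysis/03_features.R   # 3600-window x 84-feature table
Rscript analysis/04_train.R      # two-step LOSO grid search
Rscript analysis/05_evaluate.R   # confusion matrix and metrics
```

`02_mechanics.R` prints (seed 1):

```
Theoretical amplification factor (69/9 mm): 7.67
Experimental slope 7.646 (R^2 = 0.9962, p = 2.77e-120)
Displacement slopes: temple 0.440 N/mm, hinge 3.374 N/mm (ratio 7.68)
```

i.e. with 2% measurement noise the regression slope recovers the geometric
factor to within 0.3%. `05_evaluate.R` prints the held-out-subject metrics
of the selected model:

```
Synthetic cohort, LOSO at (C = 11.31, gamma = 0.0009766):
    precision recall    f1
NHM      99.8   99.7  99.7
LC      100.0  100.0 100.0
...
average F1: 99.9%   accuracy: 99.9%   n = 3600
```

The default synthetic classes are deliberately well separated; the
`confusability` parameter of `generate_recording()` shrinks the left/right
chewing asymmetry and the talking-vs-head-movement amplitude gap to produce
harder cohorts. The same script also evaluates the packaged reference
confusion matrix of 20,700 real-study windows, for which the metric code
reproduces the reported per-class values and the 94.0% average F1.

Equivalently in R:

```r
library(chewsense)
res <- run_pipeline(pipeline_config(n_subjects = 10, per_class_windows = 60,
                                    seed = 1))
res$metrics
```

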