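# rimest

Surrogate-based estimation of liver respiratory-induced motion.

During percutaneous liver procedures (biopsy, tumor ablation) the liver
moves with breathing, mainly along the superior–inferior (SI) axis.
`rimest` implements a non-contact estimation pipeline for that motion: the
abdominal surface, observed as a sequence of depth-camera point clouds, is
reduced to a scalar **surrogate signal**, and a polynomial
**correspondence model** maps the surrogate to the internal liver
displacement measured by a ground-truth modality (an electromagnetic
tracker inside a robotic phantom, or ultrasound liver segmentation masks
in human sessions).

It is aimed at researchers in image-guided interventions who want to
study surrogate-driven motion models without hardware: a built-in
simulator generates phantom and multi-session clinical-style datasets
(surface clouds, displacement traces, segmentation masks) with the
statistical structure the pipeline assumes.

## The model

The surrogate at frame *t* is the mean nearest-neighbor distance between
the current surface cloud and a reference cloud taken at maximum
inhalation:

    x(t) = (1/N) * sum_i  min_j || p_i(t) − r_j ||_2     [mm]

The correspondence model is a polynomial fitted by ordinary least
squares,

    y(x) = b0 + b1 x + b2 x^2 + … + bn x^n,

minimizing the squared-residual cost over a training set, with three
training regimes for multi-session recordings:

* **single** — train on all of session 1, test on the other sessions
  (inter-session generalization);
* **specific** — train on the first 70 % of one session, test on its
  last 30 %;
* **combined** — pool the 70 % train parts of all sessions, fit once,
  test on each held-out 30 %.

Performance is reported as mean absolute error (MAE, mm) and coefficient
of determination (R², %). Ground truth from ultrasound comes from binary
liver masks: largest 8-connected component, hole filling, morphological
closing, boundary extraction, then mean edge column inside an ROI,
converted at the isotropic pixel spacing (0.027 cm/px) and low-pass
filtered with a zero-phase Butterworth filter. Streams are synchronized
by timestamps or by aligning the end of the leading breath-hold.

## Worked example

A phantom experiment end-to-end — simulate the breathing phantom (30 mm
SI, 10 mm AP peak-to-trough at 0.25 Hz), render the deforming surface,
compute the cloud surrogate, corrupt it with 1 mm noise, and fit a
degree-3 specific model per motion axis:

```r
library(rimest)
rep <- runPhantomExperiment(list(seed = 0, surrogateNoiseSd = 1))
rep$si
#> ModelReport (specific regime, degree 3)
#>   train: MAE 1.83 mm, R2 94.8%
#>   test:  MAE 1.82 mm, R2 94.9%
```

Held-out SI error below 2 mm with ~95 % of the motion variance
explained; the AP axis gives `test MAE 0.57 mm, R2 95.7%`. A
multi-session cohort with inter-session drift (amplitude scales
0.9–1.1, baseline shifts up to 3 mm) exercises the three regimes:

```r
res <- runClinicalExperiment(list(seed = 0))
subset(res$overall, partition == "test")
#>    regime partition metric  mean   sd
#>    single      test MAE_mm  3.31 0.71
#>    single      test R2_pct 89.04 4.46
#>  specific      test MAE_mm  1.97 0.10
#>  specific      test R2_pct 95.26 1.84
#>  combined      test MAE_mm  2.71 0.60
#>  combined      test R2_pct 92.28 2.41
```

The ordering — single worst, specific best, combined between — is the
expected signature of inter-session drift: models that never see the
current session absorb its baseline and amplitude changes as error.

A command-line front end (`inst/scripts/rimest`) exposes the same steps
as subcommands (`simulate`, `surrogate`, `track`, `sync`, `fit`,
`report`, `phantom-demo`, `clinical-demo`).

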