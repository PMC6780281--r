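# svwave

Stroke-volume estimation from the radial arterial pressure waveform with a
1-D convolutional network and a jointly trained per-patient calibration,
plus the full method-comparison toolbox used to validate cardiac-output
monitors — and a Windkessel-based synthetic cohort generator so the entire
pipeline runs, end to end, without any clinical data.

## Who this is for

Researchers in hemodynamic monitoring and physiological signal processing
who want a reproducible, fully synthetic testbed for waveform-to-stroke-
volume estimators: the estimator itself, the data plumbing around it
(windowing, patient-level splits), and the statistics used to compare any
two SV monitors (correlation with CIs, Steiger's dependent-correlation
test, Bland–Altman, four-quadrant trend concordance, MDPE/MDAPE/RMSE),
stratified by surgical phase.

## The model

An input record is 10.24 s of arterial pressure sampled at 100 Hz (1024
samples, long enough to cover one ventilator cycle), slid every 2 s. Eight
blocks of convolution + factor-2 max pooling — each block consuming the
concatenation of the previous block's pooled output and its pooled input —
reduce the window to a length-4 feature map; a fully connected head yields
one scalar, SV<sub>CNN</sub>. Because patients of different body size map
the same waveform shape to different true SV, a per-patient affine pair
(the *individual scale coefficient*, ISC) completes the estimate:

> SV<sub>scaled</sub> = SV<sub>CNN</sub> · w<sub>i</sub> + b<sub>i</sub>

with (w<sub>i</sub>, b<sub>i</sub>) initialized at (1, 0) and optimized
jointly with the network under an RMS loss (Adam). For a patient never seen
in training, the calibration is either left at the identity (`fixed`) or
fitted by least squares on an initial segment of reference measurements
(`calibrate`); reports always name the mode used.

The synthetic cohort drives a two-element Windkessel with half-sine
ejection beats whose volumes follow phase-structured liver-transplant
hemodynamics (four phases, respiration-coupled SV oscillation, AR(1) heart
rate, SVR swings concentrated in reperfusion), distorts the waveform-to-SV
relation by a hidden per-patient affine, and emits a noisy, smoothed
thermodilution-like reference plus a deliberately crude pulse-pressure
competitor. See `vignettes/svwave-methods.Rmd` for every assumption and
default.

## A worked example

```r
library(svwave)

cfg <- default_config(work_dir = "svwave_demo", seed = 1)
res <- run_pipeline(cfg)   # simulate -> dataset -> train -> predict -> evaluate
res$report[res$report$phase %in% c("reperfusion", "overall"),
           c("phase", "n", "r", "bias", "concordance_rate", "mdape")]
```

On the default desk-scale configuration (16 simulated patients — 12
training / 4 test — two hours each, ~57,000 windows, 10 epochs, a few
minutes on one CPU core) this prints, for the trained model against the
thermodilution-like reference:

```
        phase     n         r     bias concordance_rate      mdape
3 reperfusion   256 0.9317219 3.234954         46.66667 0.04129136
5     overall 14380 0.9074929 2.229437         82.47625 0.04275181
```

So overall the model tracks the reference at r = 0.907 with a +2.2 mL bias
and a 4.3% median absolute performance error; during reperfusion — the most
unstable phase — it holds r = 0.932 while `res$report_competitor` shows the
crude pulse-pressure competitor collapsing exactly where conventional
contour methods do (r = 0.519 there). The reperfusion concordance cell is
noisy by construction: a ~130-s phase contains only a few dozen usable
60-s trend pairs. `res$comparison` gives Steiger p-values for the
correlation differences, and `res$r_vs_true` the correlations against the
simulator's hidden true SV (0.892 model vs 0.847 competitor at seed 1). The run directory contains the per-case CSVs, the windowed dataset,
the checkpoint, predictions, the JSON/CSV report and the scatter /
Bland–Altman / four-quadrant figures.

A thin command-line front-end over the same pipeline lives at
`inst/cli/svwave.R`:

```sh
Rscript inst/cli/svwave.R pipeline --seed 1 --out run_dir
Rscript inst/cli/svwave.R evaluate --config run.yaml --isc-mode calibrate
```

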