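---
title: "Methods: calibrated waveform-to-stroke-volume estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated waveform-to-stroke-volume estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

Stroke volume (SV, mL per beat) is the flow-side quantity anesthesiologists
steer by during major surgery, but the gold-standard measurement — pulmonary
artery thermodilution — is invasive, sparse and slow. The radial arterial
pressure waveform, by contrast, is continuously available. Classical
pulse-contour analysis maps waveform features (pulse pressure, systolic
area) to SV through a calibrated vascular model and is known to degrade
exactly when monitoring matters most: under rapid swings of systemic
vascular resistance (SVR), as in liver-transplant reperfusion.

`svwave` estimates SV directly from 10.24 s of raw waveform (1024 samples
at 100 Hz — long enough to span at least one ventilator cycle) with a 1-D
convolutional network, and resolves the patient-specific scale between
waveform shape and true SV with an *individual scale coefficient* (ISC): a
per-patient affine pair applied to the network output,

$$\mathrm{SV}_{scaled} = \mathrm{SV}_{CNN} \cdot w_i + b_i,$$

initialized at the identity $(w_i, b_i) = (1, 0)$ and optimized jointly
with the network weights on the training patients. Two scalars per patient
cannot memorize waveforms; they can only resize the shared model's output,
which is exactly the degree of freedom that differs between patients of
different body size and vascular state.

## Network architecture

Eight blocks, each a same-padded convolution (kernel 5, ReLU) followed by a
factor-2 max pool, reduce the 1024-sample input to a spatial length of 4.
Each block consumes the channel concatenation of the previous block's
pooled output and the previous block's *input*; because the two differ in
length by the pool factor, the skip path passes through the same factor-2
max pool before concatenation. This keeps the strict halving schedule while
letting every block see all coarser representations of the raw pressure. A
two-layer fully connected head (64 hidden units, ReLU) maps the flattened
activations to one scalar per window.

Choices the architecture statement leaves open were fixed as package
defaults: kernel 5; channels (4, 4, 8, 8, 8, 8, 16, 16); one hidden layer
of 64 units; Adam with learning rate $10^{-3}$, batch 256 (the end-to-end
pipeline default trains 10 epochs at $2\times10^{-3}$). The
channel widths are deliberately modest so that the default desk-scale
experiment (below) trains in a few minutes on one CPU core; the
configuration object exposes all of them. Two further engine details
matter for reproducibility and convergence:

* the network predicts a **residual around the training-set mean SV**
  (`out_center`), because an output bias starting at zero cannot travel to
  ~85 mL within desk-scale step counts under Adam;
* inputs are standardized by the fixed map $(x - 80)/40$ mmHg — no
  per-window normalization, since absolute pressure level carries
  information about vascular state.

The loss is the RMS error between the calibrated prediction and the
reference SV. The ISC parameters share the optimizer but use a 10× larger
learning rate (two scalars per patient versus thousands of shared weights);
the gain is clamped to $[0.2, 5]$. Validation RMS is recorded every epoch
and the best-validation-epoch parameters are kept. Validation patients are
held out at the patient level (default 20% of the training group) and do
not own trained coefficients, so their RMS is computed after per-patient
ordinary-least-squares calibration of their predictions; without this, epoch
selection would be dominated by scale mismatch rather than waveform skill.

For a patient never seen in training, two modes exist and every report
names the one used: `fixed` applies the identity $(1, 0)$; `calibrate` fits
$(w, b)$ by OLS of the reference on the prediction over an initial segment.
The segment must span enough reference variation to identify a slope: the
reference is itself a ~60-s average, so a one-minute segment carries almost
no SV range and OLS degenerates toward a zero gain. The pipeline therefore
calibrates on the first 300 prediction/reference pairs (ten minutes of
records), comparable to the settling period of thermodilution-calibrated
monitors. With a single pair, $w = 1$ and $b$ is the offset.

## The synthetic cohort

No public recordings exist for the intraoperative setting the estimator
targets, so the package ships a generator that reproduces the statistical
structure the method relies on, with known ground truth.

**Hemodynamic state.** A case follows the four liver-transplant phases
(pre-anhepatic, anhepatic, reperfusion, post-reperfusion) with default
duration shares 43.0/12.7/1.8/42.5% and per-phase targets — SV 88.5, 75.3,
85.7, 83.8 mL; HR 82.8, 88.2, 86.5, 83.4 bpm; SVR 850, 910, 750, 857
dyne·s/cm⁵ — matching an intraoperative liver-transplant cohort's phase
summary statistics. Around its phase target, beat-to-beat true SV follows a
bounded Ornstein–Uhlenbeck walk (marginal SD = 0.3 × the phase spread,
correlation time 45 s: slow enough to be a hemodynamic trend, fast enough
that a two-hour case explores the range) multiplied by a
ventilation-coupled modulation $1 + a\,\sin(2\pi t/T_{resp})$ with
$T_{resp} \approx 5{-}6$ s. The default amplitude $a = 0.045$ follows from
the cohort's reported stroke-volume variation of ~9%, since SVV is
approximately twice the modulation amplitude. Heart rate jitters as a
bounded AR(1) (±5 bpm), so the input is never perfectly periodic.

**Waveform.** Each beat's pressure is the response of a two-element
Windkessel, $\dot P = Q(t)/C - P/(RC)$, to a half-sine ejection flow whose
integral equals the beat's *waveform* SV; integration is fixed-step RK4 at
1 kHz, decimated to 100 Hz. Crucially, the waveform SV is the affine
inverse $(\mathrm{SV}_{true} - b_i^\ast)/w_i^\ast$ of the true SV through a
per-patient pair $(w_i^\ast, b_i^\ast)$ drawn per patient — so the waveform
alone under-determines true SV and the estimator must learn a per-patient
calibration, which is the point of the ISC.

**Reference and competitor.** The reference mimics continuous
thermodilution: a causal 60-s moving average of true SV plus 3 mL Gaussian
noise, sampled every 2 s. (The averaging window of the clinical reference
device is unpublished; 60 s is this package's configurable choice.) The
competitor is a deliberately crude pulse-contour surrogate — pulse pressure
scaled by an initial self-calibration, distorted by a factor
$(\mathrm{SVR}/858.8)^{0.6}$ and multiplicative AR(1) noise, then smoothed
over 10 s — so its error grows when SVR departs from the cohort mean,
as conventional contour analysis does. It models no commercial device; it
exists to exercise the comparison statistics.

**What the generator does not emulate.** No wave reflection, no
three-element Windkessel, no arterial-tree transmission, no arrhythmia, no
measurement artifacts (damping, flushes), and within-patient SV ranges
narrower than a real transplant (where SV spans 30–220 mL). Passing the
recovery experiments therefore shows the pipeline is correct and the
calibration identifiable under the stated structure — not that the trained
weights transfer to clinical waveforms.

## Window construction

Records are built exactly as the estimator consumes them: a window is 1024
consecutive samples whose interval is half-open, $(t_0 - 10.24, t_0]$, with
$t_0$ the last sample's timestamp; windows slide by 2 s. Each window pairs
with the reference sample nearest $t_0$ within ±1 s (half the stride, so a
stale reference can never be paired); unpaired windows are dropped and
counted. Runs of missing or flat-line samples longer than 0.5 s split a
recording into independent segments — windows never span a gap — while
shorter missing runs are linearly interpolated. Cohorts are always split at
the patient level.

## Evaluation statistics

The comparison suite mirrors standard cardiac-output method-comparison
practice, stratified by surgical phase and pooled:

* Pearson r with a Fisher-z CI (SE $1/\sqrt{n-3}$);
* Steiger's test for two dependent overlapping correlations, used to
  compare two estimators against the shared reference (the correlation
  between the two estimators is computed from the data);
* Bland–Altman bias and 95% limits of agreement (sample SD, $n-1$);
* four-quadrant trend concordance: changes over a 60-s interval (a
  configurable choice — consecutive 2-s records differ mostly by noise —
  always stated in reports), with a central exclusion square of half-width
  10% of the mean reference SV; by default a pair is excluded only when
  *both* changes fall inside the zone, with the either/or variant available
  as a flag;
* performance errors with the prediction as denominator,
  $\mathrm{PE} = (\mathrm{SV}_{ref} - \mathrm{SV}_{pred})/\mathrm{SV}_{pred}$:
  MDPE (median PE), MDAPE (median |PE|), and RMSE in mL.

Per-phase cells with too few records for a statistic are reported as NA;
trend deltas never span a phase boundary (the overall concordance pools
per-phase delta pairs). Report tables round r to 3 decimals and mL/%
quantities to 2, and contain no timestamps, so identical runs produce
byte-identical files.

## Numerical and reproducibility choices

* RK4 at 1 kHz on a time constant of ~1 s has global error far below
  waveform noise; the zero-inflow decay matches the closed form to 1e-9.
* Max-pool tie-breaks take the earlier sample; convolution padding is
  zero-valued; all floating-point accumulation is sequential, so a fixed
  parameter set gives bit-identical predictions.
* Every random process (cohort draws, beat innovations, initialization,
  shuffling, splits) derives from one master seed through fixed child
  seeds; regenerating any artifact with the same configuration is
  bit-identical, and two full pipeline runs with the same configuration
  yield byte-identical reports.
* OLS calibration clamps the gain to $[0.2, 5]$; degenerate calibration
  sets (constant predictions) fall back to a pure offset.

## Desk-scale experiment sizes

The default configuration simulates 16 patients (12 train / 4 test), two
hours each: ~57,000 windows, of which ~36,000 train after the patient-level
validation split. Training runs 10 epochs in a few minutes on one CPU core;
the identifiability experiment uses 6 patients × 40 minutes and more epochs
(35), since the per-patient coefficients converge more slowly than the
shared weights. These sizes are the package's defaults, chosen so the whole
suite runs comfortably on a laptop; all of them scale up through the
configuration.

## Known limitations

* Intercepts $b_i$ are intrinsically harder to identify than gains: within
  a desk-scale case, SV varies over a limited range around its mean, so the
  (gain, offset) pair is nearly collinear and the offset converges slowly.
  The identifiability experiment aligns fitted and true coefficient sets up
  to one global affine before comparing, because a global affine can always
  be absorbed by the network head — only the relative ISC geometry is
  testable.
* Training against a smoothed, lagged reference means the estimator learns
  the smoothed SV: beat-scale respiratory modulation is deliberately not
  recovered, and correlation against instantaneous true SV is bounded by
  the smoothing, not only by network skill.
* The engine is single-threaded CPU code sized for the default
  architecture; much wider channel stacks will train slowly.
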