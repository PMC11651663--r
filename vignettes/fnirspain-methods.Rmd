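---
title: "Decoding pain from fNIRS under analgesia: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding pain from fNIRS under analgesia: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Functional near-infrared spectroscopy (fNIRS) measures cortical hemodynamics
through scalp optodes: pairs of light sources and detectors at two
wavelengths whose attenuation changes track oxygenated (ΔHbO) and
deoxygenated (ΔHbR) hemoglobin. Because painful stimulation evokes
stereotyped hemodynamic responses — activation over sensorimotor cortex,
deactivation over the medial frontopolar cortex — single-trial fNIRS epochs
can be classified into painful versus non-painful states. The scientific
question this package operationalizes is whether a decoder trained on
pre-drug recordings transfers to brain states altered by an analgesic
(morphine) or a placebo at several times post-administration, and which
cortical regions carry the decision.

`fnirspain` implements the full pipeline as testable components:

1. a **session simulator** producing raw two-wavelength intensity with known
   ground truth,
2. the **preprocessing chain** (optical density, wavelet and PCA motion
   correction, zero-phase band-pass, modified Beer–Lambert law,
   short-channel regression),
3. **trial extraction**, pooling, 60/20/20 splitting and time-domain
   augmentation,
4. a **1D-convolutional decoder** with transfer of its convolutional stack
   to post-drug conditions,
5. a **DeepLIFT-rescale Shapley explainer** aggregated per cortical ROI, and
6. the **run-level statistics layer** (Shapiro–Wilk screening,
   Kruskal–Wallis with Dunn/Bonferroni post hocs, Box–Cox +
   repeated-measures 2×3 ANOVA).

# The simulator

## Design

The default study design is 14 subjects, two pre-drug sessions each, and
one session per post-drug condition (morphine or placebo at 30/60/90 min).
A session presents six painful and six non-painful stimuli in seeded random
order; each stimulus lasts 5 s and is followed by 25 s of rest. Epoched at
1 Hz with a 1-s pre-stimulus and 30-s post-onset window, this yields the
canonical trial arrays: 336 pre-drug trials and 168 trials per post-drug
condition of size 31 time points × 24 channels.

## Signal model

Each long channel receives an evoked response: the stimulus boxcar
convolved with a canonical double-gamma HRF (peak 6 s, undershoot 16 s,
ratio 1/6 — the paper-independent standard choice that keeps recovery tests
interpretable), scaled by a per-(class, ROI, condition) amplitude table in
µM. The default table encodes frontopolar *deactivation* under pain
(−0.8 µM) and activation over SI/MI/PMC/DLPFC (+0.3 to +1.0 µM), with
non-painful stimulation evoking the same spatial pattern at roughly a
quarter of the amplitude. Morphine multiplies the FPA pain amplitude by
0.4 at all three post-drug timings; placebo changes nothing. These
magnitudes are configuration, not claims about pharmacology.

Nuisance structure mirrors what the preprocessing chain is designed to
remove:

* **systemic physiology** — cardiac (≈1.1 Hz, 0.4 µM), respiration
  (≈0.25 Hz, 0.3 µM) and Mayer waves (≈0.1 Hz, 0.4 µM) sharing one time
  course across channels with channel-specific gains;
* **drift** — a low-frequency random walk (1 µM);
* **white measurement noise** (0.3 µM per sample at 10 Hz);
* **motion artifacts** — Poisson-thinned exponential spikes and step
  offsets at a default rate of 1 per 100 s per channel.

Short-separation channels carry the systemic components (scaled by a
coupling coefficient) and noise but no evoked response, which is what makes
them valid nuisance regressors. Hemoglobin changes map to intensity through
the modified Beer–Lambert forward model (760/850 nm extinction
coefficients, DPF 6, separations 3 cm long / 0.8 cm short), so the whole
measurement chain can be inverted by the preprocessing module; a noiseless
ΔHbO sidecar is attached to every scan for recovery tests.

The native sampling rate is 10 Hz: it supports the 0.01–0.1 Hz analysis
band and leaves cardiac pulsation below the Nyquist frequency. Scans are
serialized to a self-describing JSON container (17 significant digits, so
write/read round trips are exact) with a CSV-compatible event table; a
plain-text container keeps fixtures portable and diffable.

## What the simulator does not emulate

Photon transport, anatomy, wavelength-dependent scattering, habituation of
responses over trials, and inter-subject response variability beyond
channel gains. Passing tests on synthetic sessions therefore demonstrate
that the pipeline recovers what the generative model put in — not that real
data meet the model's assumptions.

# Preprocessing

The stage order is fixed and refused if permuted: optical density → wavelet
motion correction → PCA motion correction → band-pass → Beer–Lambert →
short-channel regression.

* **Optical density** uses the whole-scan mean intensity as baseline
  (`OD = −ln(I / mean I)`), the common convention.
* **Wavelet correction** decomposes each series with a periodized
  Daubechies-5 transform (depth `ceiling(log2 fs)` = 4 at 10 Hz, so the
  entire sub-0.3 Hz hemodynamic band sits in the unthresholded
  approximation) and zeroes detail coefficients outside the Tukey fences
  `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]` of their level. The series is extended by
  odd (point-symmetric) reflection before decomposition so the periodic
  wrap-around creates no spurious coefficients; on a clean tone the stage
  changes the signal by less than 1e-11 RMS while removing ≥90 % of an
  injected spike's amplitude.
* **PCA correction** removes principal components that *individually*
  explain at least 80 % of the variance across channels × wavelengths. A
  genuine motion event shared across the array dominates the decomposition
  and is removed; on ordinary data no component reaches the threshold and
  the stage is an identity. A cumulative-variance criterion was rejected
  deliberately: on event-related data it removes the global component and
  with it the common mode of the evoked response. For the same reason the
  clean-scan recovery test disables this stage — a scan without motion
  artifacts gives the stage nothing it is designed to remove.
* **Band-pass**: order-3 Butterworth, 0.01–0.1 Hz, applied forward and
  backward (zero phase, so epoch latencies are undistorted). Measured
  gains: ≥0.95 at 0.03 Hz, ≤1e-5 at 1 Hz.
* **Beer–Lambert inversion** solves the per-channel 2×2 extinction system;
  it is linear and exact to machine precision, and is the numerical inverse
  of the simulator's forward model.
* **Short-channel regression** implements the scalar no-intercept estimator
  `beta = (S'S)^{-1} S'L` and `L' = L − beta·S` per long channel against
  its nearest short channel, exactly as printed; band-passed series are
  near zero-mean, so the missing intercept is immaterial. Only ΔHbO is
  regressed; downstream decoding uses ΔHbO only.

**Known limitation.** With a strictly periodic 30-s stimulus train, the
third stimulus harmonic falls exactly on the 0.1 Hz Mayer band. The part of
the evoked response coherent with the short-channel signal is then removed
by the regression, which caps clean-scan recovery correlations near
0.96–0.99 per channel rather than 1.0. This is a property of the design
(fixed inter-stimulus interval), not of the estimator; jittered designs
avoid it.

# Trials, splits, augmentation

Epochs are decimated to 1 Hz after the 0.1 Hz low-pass (no extra
anti-aliasing is needed), windowed from 1 s before to 30 s after onset
(31 samples), and labelled +1 (pain) / −1 (non-pain). Pooled sets are split
by a seeded shuffle into train/validation/test with floor-rounded 20 %
validation and test partitions and the remainder to training, reproducing
the printed test sizes 67 (336 trials) and 33 (168 trials); the shuffle is
redrawn (bounded retries) until all partitions contain both classes.

Training-set augmentation appends 25 copies of each trial (originals
retained; "augmented 25 times" is read as 25 additional copies, and the
factor is configurable). Each copy applies exactly one procedure, chosen
with equal probability per copy: a linear trend `slope·(0…30)` added to
every channel with slope drawn from {0.01, 0.05, 0.1} (per-sample at 1 Hz,
equivalently per second), or zero-mean Gaussian noise with variance drawn
from {0.01, 0.05, 0.1}, i.i.d. per sample and channel. The slope/variance
draw is made once per copy and applied to all channels. Validation and
test partitions are never augmented, and the API refuses to.

# The decoder

Three 1D convolutional blocks along the time axis (kernel length 2, "same"
padding, ReLU, max-pooling of width 2 with "valid" padding, dropout 0.4)
with 32/64/128 filters, then flatten → dense 256 + ReLU → dropout 0.4 →
dense 1 + sigmoid; with T = 31 the time axis shrinks 31 → 15 → 7 → 3.
Training uses Adam (learning rate 1e-4), binary cross-entropy (the only
consistent standard loss for a sigmoid output), batch 16, up to 100 epochs,
and a plateau schedule: when the validation loss fails to improve by more
than 1e-4 for 10 consecutive epochs the learning rate is multiplied by
0.01, bounded below at 1e-6. Dropout is active only during training;
evaluation is deterministic.

The network, Adam and the schedule are implemented in vectorized base R
(im2col convolutions through BLAS). At this network size a training run
takes seconds to minutes on one CPU, and the backward pass is verified
against finite differences to ~1e-9 relative error in the test suite.

Transfer to a post-drug condition copies the weights from the first
convolution through the last max-pooling into a fresh model, freezes them
(a configuration switch allows fine-tuning; frozen is the default reading
of retraining "adjusted" new head layers only), reinitializes the
flatten/dense/sigmoid head, and trains the head on the post-condition's own
60/20/20 split and augmentation with the same optimizer schedule.
Evaluation reports accuracy, sensitivity (pain = positive class),
specificity and rank-statistic AUC. The experiment harness repeats the
whole procedure (re-split, re-augment, retrain base, transfer to each
post condition) per run — the repetition includes base retraining, the
fuller reading of the repeated-randomization protocol.

Labels are stored as ±1 and mapped to {0, 1} at the decoder boundary to
match the sigmoid output.

# Attribution

The explainer backpropagates DeepLIFT rescale multipliers from the sigmoid
probability output (not the logit, so signs match the probability scale) to
the inputs, averaging contributions over a background of 100 trials drawn
(seeded) from the run's training set. Elementwise nonlinearities use the
rescale slope `(f(x) − f(r))/(x − r)` with the derivative as fallback when
`x ≈ r`; max-pooling is decomposed as `max(a, b) = a + relu(b − a)` so the
rescale rule applies there too. A consequence worth stating: the
local-accuracy identity `sum(phi) = f(x) − mean_r f(r)` holds to machine
precision for every attributed trial, not merely within a tolerance.

Per run, attributions are averaged (signed, over test trials × time points
× channels) within each ROI, giving a runs × ROIs Shapley matrix per
model; ROIs whose across-run mean is strictly positive are listed as
positive contributors. Signed averaging is interpretation-sensitive: for a
balanced two-class test set, contributions of a symmetrically informative
channel largely cancel, so positive means reflect asymmetries (e.g.
one-sided responses, sigmoid curvature), which is why the localization
test drives only the pain class.

# Statistics layer

Per metric and model, run-level values are screened with Shapiro–Wilk
(constant groups are noted and skipped). The pre-drug model is compared
with each drug family's three post-drug models by Kruskal–Wallis (df = 3
per family), followed by Dunn-type pairwise rank z tests with Bonferroni
correction sized by the number of pairs in the family — the specific post
hoc is our choice; only the correction is inherited. Under a 1000-rep null
at n = 30 per group the wrapper's type-I error is ≈0.05.

The 2×3 comparison of post-drug models transforms the metric by Box–Cox
(maximum-likelihood λ on a ±5 grid, automatic all-positive shift when
needed) and fits `value ~ drug * time + Error(run)` — a repeated-measures
ANOVA with the run index as the error stratum, our reading of "repeated
measures over runs". The report labels its own statistics explicitly.

# Problem sizes in the test and acceptance suites

The packaged experiments run on one CPU, so the suites use a reduced
operating point chosen once: a scaled-down network (8/16/32 filters, dense
64), learning rate 1e-3 with 15 epochs, augmentation factor 5, and —
depending on the check — 4 to 14 simulated subjects. The full-size
configuration (32/64/128, dense 256, 1e-4, 100 epochs, factor 25) remains
the package default for real use. The drug-contrast experiment additionally
raises white noise to 0.6 µM so decoding operates off ceiling, where the
frontopolar information loss is measurable; at default noise all models
saturate near perfect accuracy and the contrast is invisible — the same
reason the morphine/placebo gap is small when overall performance is high.

# Degenerate inputs and numerical conventions

Non-positive intensities, all-zero short channels, singular extinction
matrices, single-class test sets, constant PCA input, stage-order
permutations and augmentation of non-training partitions are all refused
with specific errors rather than silently repaired. Max-pooling ties break
toward the earlier time step. Seeds: every stochastic operation takes an
explicit seed and restores the caller's RNG state; derived seeds are hashed
from (parent seed, stream label) and stay below 2^31.
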