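# fnirspain

Simulation, preprocessing, decoding and explanation of fNIRS pain
responses under pharmacological conditions.

## What this package is for

Functional near-infrared spectroscopy (fNIRS) records cortical hemodynamics
through scalp optodes. Painful stimulation produces stereotyped responses —
ΔHbO increases over sensorimotor cortex, decreases over the medial
frontopolar cortex — so single-trial epochs can be classified as painful
vs. non-painful. `fnirspain` is for researchers who want a tested, fully
reproducible pipeline for the transfer-learning question: does a decoder
trained on pre-drug sessions still decode pain after morphine or placebo
administration, and which cortical regions drive its decisions?

The package provides:

* a **session simulator**: event-related ΔHbO/ΔHbR responses (double-gamma
  HRF, per-ROI amplitude tables, morphine-attenuated frontopolar pain
  responses), systemic physiology (cardiac, respiration, Mayer waves),
  drift, motion artifacts and paired short-separation channels, mapped to
  raw two-wavelength intensity through the modified Beer–Lambert forward
  model, with a noiseless ground-truth sidecar;
* the **preprocessing chain**: optical density, db5 wavelet and PCA motion
  correction, zero-phase 0.01–0.1 Hz Butterworth band-pass, Beer–Lambert
  inversion, and short-channel regression
  `beta = (S'S)^(-1) S'L`, `L' = L − beta·S`;
* **trial handling**: 31-sample × 24-channel epochs at 1 Hz, pooling
  (336 pre-drug / 168 post-drug trials under the default design), seeded
  60/20/20 splits (test sizes 67 / 33), and ×25 time-domain augmentation
  (random linear trends or Gaussian noise);
* a **1D-CNN decoder** (conv 32/64/128, kernel 2, pooling 2, dropout 0.4,
  dense 256, sigmoid; Adam 1e-4 with a ×0.01 plateau schedule down to
  1e-6, batch 16, 100 epochs) with frozen-conv transfer to post-drug
  conditions — implemented in vectorized base R and verified against
  finite differences;
* a **DeepLIFT-rescale Shapley explainer** with exact per-trial local
  accuracy, aggregated into runs × ROIs contribution matrices and
  positive-contributor sign tables;
* the **statistics layer**: Shapiro–Wilk screening, Kruskal–Wallis per drug
  family with Dunn/Bonferroni post hocs, and a 2×3 (drug × time)
  repeated-measures ANOVA after Box–Cox transformation.

## Worked example

Simulate a small two-condition study, preprocess, decode, transfer and
explain:

```r
library(fnirspain)

layout <- make_layout()                      # 24 long + 8 short channels, 10 ROIs
config <- simulation_config(n_subjects = 6, conditions = c("pre", "MM30"))
study  <- simulate_study(config, layout, seed = 11)

pool <- function(scans)
  pool_sessions(lapply(scans, function(s) extract_trials(preprocess_scan(s))))
datasets <- lapply(study, pool)
datasets$pre
#> <trial_set> N=144 trials x T=31 x C=24 (72 pain / 72 non-pain)

res <- run_experiment(
  datasets, n_runs = 2, seed = 42,
  mc = model_config(filters = c(8, 16, 32), dense = 64),
  tc = train_config(lr = 1e-3, epochs = 15),
  ac = augmentation_config(factor = 5),
  explain = TRUE, background_size = 30, layout = layout
)
summarize_metrics(res$metrics)[, 1:3]
#>   condition accuracy_mean accuracy_sd
#> 1       pre     0.8928571  0.05050763
#> 2      MM30     0.7142857  0.10101525

positive_contributors(res$shapley)
#>   model L PMC R PMC L DLPFC R DLPFC L FPA R FPA L IFG R SMG R SI R MI
#> 1   pre     +                           +     +                +
#> 2  MM30     +                     +     +     +           +    +    +
```

Read: the base (pre-drug) decoder reaches 0.89 mean test accuracy over two
runs at this reduced problem size, and the model transferred to the
post-morphine condition drops to 0.71 — the simulator attenuates the
frontopolar pain response under morphine, so there is genuinely less
class information. The sign table lists, per model, the ROIs whose mean
Shapley contribution across runs is strictly positive. (Output shown is
from this exact code; small-sample runs vary with the seed you pass.)

The full-size settings (`model_config()`, `train_config()`,
`augmentation_config()` defaults) reproduce the complete architecture and
schedule; the reduced settings above fit interactive use.

## Layout

```
R/                  simulator, preprocessing, trials, decoder, explainer, stats
tests/testthat/     unit, property and acceptance suites
scripts/acceptance.R
vignettes/fnirspain-methods.Rmd   models, parameters, design choices, limits
```
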