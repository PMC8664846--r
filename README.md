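# smtrace

Single-molecule TIRF trace analysis for oligomerizing RNA-binding
proteins: simulation, idealization, counting, kinetics and two-colour
pathway classification.

## What it is for

In surface-immobilized single-molecule TIRF assays of an RNA helicase that
oligomerizes through its disordered N-terminus and strips cleaved target
RNA off an RNA-guided effector complex, the raw data are per-spot
fluorescence intensity time series. Everything the experiment reports is
derived from those traces:

* the **single-fluorophore intensity unit** `μ₁`, calibrated from
  photobleaching step sizes (`I_step ~ N(μ₁, σ₁²)`, with
  `μ₁ ≈ 178.2 ± 58.6` camera counts in the reference condition);
* **integer molecule counts** per spot or per step,
  `n = round(I / μ₁)`, and their population summaries from Gaussian fits
  to integer histograms;
* **dwell-time constants** from single-exponential fits
  `F(t) = 1 − e^(−t/τ)` to empirical cumulative dwell distributions, with
  right-censoring at the recording window, and ensemble decays
  `A·e^(−t/τ) + B`;
* **dissociation pathway fractions** of colocalized protein/RNA spot
  pairs: simultaneous release, sequential release, or no RNA release
  within the window.

`smtrace` implements this pipeline end to end — spot detection and ROI
trace extraction from image stacks, hidden-Markov-model trace
idealization, calibration and counting, censored exponential kinetics,
two-colour classification — together with a seeded synthetic-data
generator that reproduces the study conditions, so every estimator is
validated by parameter recovery against known ground truth. It is aimed
at single-molecule biophysicists who want a tested, scriptable R
implementation of this analysis chain.

## Worked example

Simulate a two-dye photobleaching calibration trace, idealize it with the
monotone HMM, and count molecules per step:

```r
library(smtrace)

cfg <- sim_config("CALIBRATION", seed = 11, n_frames = 400)
sim <- simulate_bleach_trace(cfg, n_dyes = 2)
id  <- idealize_trace(sim$trace, max_states = 6,
                      config = idealize_config(loss_only = TRUE))
id$segments
#>   start_frame end_frame    level
#> 1           0        26 335.4285
#> 2          26        51 169.7069
#> 3          51       400   0.5317

st <- extract_steps(id)
st
#>   trace_id time frame  delta from_level to_level direction
#> 1    calib  2.6    26 -165.7      335.4 169.7069      loss
#> 2    calib  5.1    51 -169.2      169.7   0.5317      loss

count_molecules(abs(st$delta), list(mean = 178.2))
#> [1] 1 1
```

The two bleaching transitions (at 2.6 s and 5.1 s) each lose about one
single-dye unit of intensity, so both count as single molecules. Pooling
such steps over hundreds of traces and fitting a Gaussian to their
histogram calibrates the unit itself:

```r
cal <- experiment_calibration(n_traces = 200, seed = 1101)
cal
#> <gaussian_fit> mean 179.61, sd 15.89 (n = 277, R^2 = 0.878)
```

The recovered mean (179.6 ± 0.9) agrees with the configured single-dye
intensity of 178.2 counts. The other `experiment_*()` functions run the
remaining recovery experiments (event stoichiometry, dwell and ensemble
kinetics, RNA survival, pathway classification, partial-step fractions);
the vignette in `vignettes/trace-analysis-methods.Rmd` explains the models
and all tunable parameters.

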