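---
title: "Models and methods behind smtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smtrace)
```

`smtrace` is an analysis pipeline for surface-immobilized single-molecule
TIRF experiments on an oligomerizing RNA helicase interacting with an
RNA-loaded effector complex. It covers the whole chain from raw image
stacks (or per-spot intensity traces) to the quantities such experiments
report: the single-fluorophore intensity unit, integer molecule counts and
oligomer-size distributions, dwell-time constants with right-censoring,
ensemble decay constants, and two-colour dissociation-pathway fractions.
Because the reference experiments' raw movies are not deposited, the
package pairs every analysis step with a synthetic-data generator that
reproduces the study conditions, so each estimator can be validated as a
parameter-recovery experiment against known ground truth.

## The measurement model

A camera frame integrates the emission of the fluorophores in a
diffraction-limited spot. The generator assumes:

* each active dye contributes Gaussian counts with mean $\mu_1 = 178.2$
  and SD $\sigma_1 = 58.6$ per frame, independently across dyes and
  frames, so a spot with $k$ dyes emits
  $\mathcal{N}(k\mu_1, \sqrt{k}\,\sigma_1)$;
* additive Gaussian camera read noise (default SD 20 counts) on every
  sample;
* acquisition intervals of 0.1 s (calibration movies), 0.6 s (oligomer
  dynamics) or 0.4 s (RNA and two-colour movies), 1000 frames per movie;
* for rendered stacks, an isotropic Gaussian PSF (default $\sigma$ =
  1.1 px at 108 nm/px on a 256 x 256 px field, i.e. a 27.648 um field
  edge) over a constant background, with the PSF amplitude normalized so
  the 8 x 8 px ROI sum equals the trace value.

The study only reports the overall spread of single-dye steps
($178.2 \pm 58.6$); its decomposition into emission versus camera noise is
a generator choice. Blinking and other photophysics beyond single-step
bleaching are deliberately excluded: passing tests therefore say nothing
about blinking-dominated data.

Kinetic structure per condition (see `sim_config()`):

| Condition | Process | Defaults |
|---|---|---|
| `CALIBRATION` | per-dye geometric bleaching | 0.02/frame |
| `DYNAMICS` | alternating association/dissociation of multi-molecule units | $\tau_a = 465.3$ s, $\tau_d = 385.1$ s; event-size mixtures with means 2.13 / 2.48 |
| `RNA_1MM_ATP` | single-step RNA release | $\tau = 49.8$ s; ensemble decay $\tau = 46.5$ s |
| `RNA_10UM_ATP` | single-step RNA release | $\tau = -400/\ln 0.716 \approx 1197$ s |
| `TWO_COLOR` | three dissociation pathways | class probabilities 14/72, 31/72, 27/72 |

Two of these defaults deserve comment. First, the low-ATP time constant is
not reported directly; it is fixed by inverting the reported 71.6 %
survival at 400 s under a single exponential. The same source also
describes the low-ATP dwell as about five times the high-ATP dwell, which
is numerically inconsistent with that survival (it would imply roughly
24x); the generator follows the survival figure, and the 5x alternative is
available by overriding `kinetics$tau_rna`. Second, the association
event-size mixture is {1: 0.10, 2: 0.70, 3: 0.17, 4: 0.03} (mean 2.13),
and the dissociation mixture {1: 0.10, 2: 0.41, 3: 0.41, 4: 0.07, 5: 0.01}
(mean 2.48). The dissociation weights were chosen near-symmetric about
their mean because the reported population means are Gaussian fits to
integer histograms, and a least-squares Gaussian tracks the mode: a
strongly skewed mixture with the same arithmetic mean would not reproduce
its own nominal value under the study's own fitting procedure.

The two-colour generator has three free parameters the source does not
pin: the waiting time between partial protein-channel losses
(`tau_partial` = 150 s, chosen so a spot loses material roughly twice per
400 s window, matching the reported ~1.9 partial events per colocalized
spot), the minimum separation between an RNA step and any protein step in
SEQUENTIAL pairs (6 frames, three times the classifier tolerance, so the
class is defined well beyond the idealizer's timing jitter), and the size
of non-single partial steps (2 molecules). Partial dissociation proceeds
only while at least three molecules remain — the dimer-scale core is
treated as stable — which makes every partial step size an unconditioned
Bernoulli(0.85) draw and keeps the single-molecule fraction exactly
calibrated.

## Trace idealization

Traces are segmented with a hidden Markov model with Gaussian emissions:
states are intensity levels, and transitions carry a sticky prior (0.99
self-transition, 50 pseudo-observations per row) that suppresses
single-frame excursions. For each candidate state count $k = 1..12$ the
model is fitted by EM (10 k-means++-seeded restarts, best final
likelihood), and $k$ is selected by BIC with ties broken toward fewer
states. The decoded Viterbi path is collapsed into segments, and step
events are emitted at segment boundaries; by construction the step deltas
telescope exactly to the last-minus-first level.

Three numerical choices matter and were made deliberately:

* **Per-state emission variances** (default; a single shared variance is
  available via `idealize_config(emission_var = "shared")`). Under the
  noise model above the variance grows with the number of active dyes,
  while most frames of a bleaching movie sit at the empty level. A shared
  variance collapses toward the read noise of that long tail and then
  fragments the upper levels; per-state variances (with a floor, and one
  regularizing pseudo-observation) keep both regimes honest.
* **BIC counts emission and initial-state parameters only.** The
  transition matrix is pinned by its sticky prior and is not an effective
  free parameter; charging $k(k-1)$ parameters for it makes short
  segments unaffordable and merges real steps.
* **Segment levels are per-segment frame means**, recomputed after
  decoding, rather than the EM state means. When adjacent levels are only
  ~2 combined SD apart, value-based state means suffer tail-truncation
  bias (measured at up to +20 counts on the brightest state); segment
  means are contiguous in time and free of it.

For calibration movies the decoder can be constrained to monotone
(loss-only) paths, reflecting that bleaching never adds intensity.

A brute-force oracle (`idealize_oracle()`) enumerates every segmentation
of a short trace into at most three segments, scores it by the same
shared-SD Gaussian likelihood (`segmentation_loglik()`), and is used in
the tests to confirm that the HMM's segmentation attains the optimum on
traces where enumeration is feasible.

The changepoint information limit is worth stating: with levels one unit
apart and per-dye noise, a segment shorter than about 5-6 frames cannot
justify its own BIC cost under any estimator. At the calibration preset's
bleach rate about a fifth of inter-bleach gaps fall below this limit and
fuse into double steps. The calibration therefore reports the Gaussian
curve fitted to the step histogram — the fit follows the single-step mode
and is insensitive to the merge tail — with a median +/- 2.5 MAD trim
available on top.

## Counting molecules

The single-dye unit from the calibration converts intensities to integer
molecule counts by `round(intensity / unit)` (half away from zero, floored
at zero). Nearest-integer rounding was chosen over flooring because at the
calibration noise level flooring undercounts systematically; flooring
remains available. Population summaries of integer histograms
(association/dissociation event sizes, per-spot stoichiometries) are
reported as the mean of a least-squares Gaussian fitted to the histogram,
which is how the non-integer population means of the reference experiments
(2.13, 2.48) are defined; moment summaries are available as an option.

## Kinetics

Dwell times are extracted from idealized step events: association dwells
from the previous event (or movie start; configurable), dissociation
dwells from the preceding gain, RNA-release dwells from the movie start to
the single loss. Traces with no qualifying event contribute a censored
dwell equal to the window; sub-frame dwells are below the detection limit
and are dropped.

Single-exponential fitting offers two estimators. `cdf_lsq` (default)
least-squares fits $1 - e^{-t/\tau}$ to the empirical CDF of uncensored
dwells at Hazen plotting positions $(i - 0.5)/n$ — the direct analogue of
fitting a cumulative dwell histogram with an exponential curve, and exact
on exponential quantiles. `mle` is the censoring-aware maximum-likelihood
estimate $\hat\tau = \sum_i t_i / n_\mathrm{uncensored}$, provided as the
statistically preferred cross-check; the tests require the two to agree
within 10 % on uncensored samples. Ensemble decays are fitted as
$A e^{-t/\tau} + B$ with all three parameters free. Survival fractions
count censored-at-or-beyond-$t$ traces as surviving. Welch's
unequal-variance $t$-test (via `stats::t.test`) checks that dwell times do
not depend on oligomer size.

One statistical caveat is recorded rather than hidden: at $n = 282$
events, the sampling SD of any unbiased $\hat\tau$ is at least
$\tau/\sqrt{n} \approx 6\,\%$, so recovery "within two printed SE" is not
a 95 %-coverage statement for the dissociation constant (printed SE
$\approx 4\,\%$ of $\tau$); the replicate tests assert coverage where it
is attainable and unbiasedness where it is not.

## Spot detection and ensemble intensity

Spots are detected on a single frame as strict 8-neighbourhood local
maxima whose prominence over the local background (median of the 1-px
ring around the 8 x 8 ROI) exceeds a tolerance, followed by non-maximum
suppression at twice the ROI half-width and deterministic (y, x)
ordering. The tolerance is expressed in camera counts on the peak pixel;
because the reference analysis's ImageJ "noise tolerance ~1500" is not
reconciled with its intensity scale (peak versus ROI-summed counts,
unknown gain), the threshold is a parameter, with about five read-noise
SDs a sensible default on simulated stacks. Spots are detected once and
held fixed — an immobilized-molecule assay, with no tracking or drift
correction. Trace extraction subtracts ring-median background times ROI
area per frame; ensemble intensity sums a region, subtracts its median
background, and normalizes to the first frame.

## Pathway classification

Channels are matched by mutual nearest neighbours within 2 px (about
216 nm, under the diffraction-limited spacing detection enforces). Each
colocalized pair is classified from its two idealized traces over a 400-s
window: `NO_DISSOCIATION` when the RNA channel shows no loss in the
window (a right-censored observation, not a claim that release never
happens); otherwise `SIMULTANEOUS` when the RNA step is within the
simultaneity tolerance (2 frames by default, not stated by the source) of
the nearest protein-channel loss (`nearest`/`final` configurable);
otherwise `SEQUENTIAL`. Classification compares step times only, so it is
invariant to channel-wide intensity scaling. Partial-step statistics
convert every protein-channel loss that leaves at least one molecule
behind into a molecule count and report the fraction equal to one.

## Problem sizes and what the tests show

The test-suite and the acceptance script run every experiment at the
reference sample sizes: 200 calibration traces of 1000 frames, 388/439
stoichiometry events, 282-event dwell samples, 300 RNA traces per ATP
condition, a 500-trace ensemble field, 72 stratified two-colour pairs,
and at least 96 partial steps. Property-style tests use sizes chosen to
keep the whole suite within a coffee break (for example 150 pairs for the
classifier confusion matrix and 12 000 pairs — cheap, as only ground
truth is needed — for the Bernoulli step-size law); each such size is a
package choice stated in the test.

Passing these tests shows that the estimators recover the parameters of
data generated under the package's own assumptions (Gaussian noise,
memoryless kinetics, fixed spots, no blinking). They do not validate the
assumptions themselves against real movies, nor detection on crowded or
drifting fields, nor multi-exponential kinetics, all of which are outside
the package's scope.
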