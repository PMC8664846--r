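# Parameter-recovery experiments: each function simulates one of the study's
# experimental conditions at its printed sample size, runs the full analysis
# on the synthetic data, and returns the recovered quantity. These are the
# workflows exercised by scripts/acceptance.R and the acceptance tests.

#' Single-dye calibration experiment
#'
#' Simulates photobleaching calibration movies, idealizes every trace with
#' the monotone (loss-only) HMM, pools the loss-step magnitudes and fits the
#' single-dye Gaussian with the robust trim (which suppresses unresolved
#' double steps).
#'
#' @param n_traces Number of traces (default 200).
#' @param seed Integer seed.
#' @param n_frames Movie length in frames (default the preset's 1000).
#' @return A `gaussian_fit` for the single-dye intensity unit.
#' @export
experiment_calibration <- function(n_traces = 200, seed = 1,
                                   n_frames = 1000) {
  cfg <- sim_config("CALIBRATION", seed = seed, n_frames = n_frames)
  sims <- simulate_calibration_set(cfg, n_traces)
  steps <- do.call(rbind, lapply(sims$traces, function(tr) {
    extract_steps(idealize_trace(tr, max_states = 6,
                                 config = idealize_config(loss_only = TRUE)))
  }))
  fit_single_dye(steps, trim = TRUE)
}

#' Event stoichiometry experiment
#'
#' Generates association or dissociation step events from the configured
#' size mixture at calibration noise, converts the intensity deltas to
#' molecule counts with the calibrated unit, and fits the integer histogram
#' with a single Gaussian.
#'
#' @param direction `"gain"` (association) or `"loss"` (dissociation).
#' @param n Number of events (388 association / 439 dissociation in the
#'   reference condition).
#' @param seed Integer seed.
#' @return A `count_distribution`.
#' @export
experiment_event_sizes <- function(direction = c("gain", "loss"), n,
                                   seed = 1) {
  direction <- match.arg(direction)
  cfg <- sim_config("DYNAMICS", seed = seed)
  ev <- simulate_step_events(cfg, direction, n)
  event_size_distribution(ev$steps, list(mean = cfg$unit_mean), direction)
}

#' Dwell-time constant experiment
#'
#' Draws dwell times from the oligomer-dynamics kinetics and fits the
#' empirical CDF with a single exponential.
#'
#' @param kind `"association"` or `"dissociation"`.
#' @param n Number of dwells (default 282).
#' @param seed Integer seed.
#' @return An `exp_fit`.
#' @export
experiment_dwell_tau <- function(kind = c("association", "dissociation"),
                                 n = 282, seed = 1) {
  kind <- match.arg(kind)
  cfg <- sim_config("DYNAMICS", seed = seed)
  fit_exponential(simulate_dwell_sample(cfg, kind, n))
}

#' Ensemble decay experiment
#'
#' Simulates a field of RNA traces disappearing at the ensemble decay rate,
#' sums them, normalizes to the first frame and fits `A exp(-t/tau) + B`.
#'
#' @param n_traces Number of traces in the field (default 500).
#' @param seed Integer seed.
#' @return An `exp_fit` with baseline.
#' @export
experiment_ensemble_decay <- function(n_traces = 500, seed = 1) {
  cfg <- sim_config("RNA_1MM_ATP", seed = seed)
  field <- simulate_ensemble_field(cfg, n_traces)
  fit_ensemble_decay(ensemble_intensity(field$traces), cfg$frame_interval)
}

# Shared helper: simulate an RNA condition, idealize, extract release dwells.
rna_release_dwells <- function(condition, n_traces, seed) {
  cfg <- sim_config(condition, seed = seed)
  sims <- simulate_rna_set(cfg, n_traces)
  events <- lapply(sims$traces, function(tr)
    extract_steps(idealize_trace(tr, max_states = 3)))
  extract_dwells(events, window = cfg$n_frames * cfg$frame_interval,
                 kind = "rna_release", condition = condition)
}

#' Single-molecule RNA release experiment (1 mM ATP)
#'
#' @param n_traces Number of traces (default 300).
#' @param seed Integer seed.
#' @return An `exp_fit` of the release dwell CDF.
#' @export
experiment_rna_release <- function(n_traces = 300, seed = 1) {
  fit_exponential(rna_release_dwells("RNA_1MM_ATP", n_traces, seed))
}

#' RNA survival experiment (10 uM ATP)
#'
#' @param n_traces Number of traces (default 300).
#' @param t Survival time point in seconds (default 400).
#' @param seed Integer seed.
#' @return Fraction of traces surviving past `t`.
#' @export
experiment_rna_survival <- function(n_traces = 300, t = 400, seed = 1) {
  survival_fraction(rna_release_dwells("RNA_10UM_ATP", n_traces, seed), t)
}

#' Two-colour pathway classification experiment
#'
#' Generates stratified colocalized pairs, idealizes both channels and
#' classifies each pair into its dissociation pathway.
#'
#' @param n_pairs Number of pairs (default 72).
#' @param seed Integer seed.
#' @return List with `percents` (per class), `counts`, `calls`,
#'   `true_classes`, `n_misclassified`.
#' @export
experiment_pathways <- function(n_pairs = 72, seed = 1) {
  cfg <- sim_config("TWO_COLOR", seed = seed)
  res <- simulate_two_color_pairs(cfg, n_pairs, stratified = TRUE)
  unit <- list(mean = cfg$unit_mean)
  calls <- lapply(seq_along(res$pairs), function(i) {
    p <- res$pairs[[i]]
    classify_pathway(idealize_trace(p$trace_a, max_states = 8),
                     idealize_trace(p$trace_b, max_states = 3),
                     window = 400, unit = unit,
                     pair_id = sprintf("pair_%03d", i))
  })
  fr <- pathway_fractions(calls)
  pred <- vapply(calls, `[[`, character(1), "class")
  list(percents = fr$percents, counts = fr$counts, calls = calls,
       true_classes = res$classes,
       n_misclassified = sum(pred != res$classes))
}

#' Partial-dissociation step experiment
#'
#' Generates two-colour pairs until at least `min_events` partial
#' channel-A losses have been observed in the idealized traces, converts
#' each loss to molecules and reports the single-molecule fraction.
#'
#' @param min_events Minimum number of partial losses (default 96).
#' @param seed Integer seed.
#' @return List with `fraction_single`, `n_events`, `n_spots`.
#' @export
experiment_partial_steps <- function(min_events = 96, seed = 1) {
  cfg <- sim_config("TWO_COLOR", seed = seed)
  unit <- list(mean = cfg$unit_mean)
  steps_by_spot <- list()
  n_partial <- 0
  batch <- 0
  while (n_partial < min_events && batch < 40) {
    batch <- batch + 1
    cfg$seed <- seed + 7919L * batch
    res <- simulate_two_color_pairs(cfg, 24)
    for (p in res$pairs) {
      st <- extract_steps(idealize_trace(p$trace_a, max_states = 8))
      losses <- st[st$direction == "loss" &
                     st$to_level >= 0.5 * unit$mean &
                     abs(st$delta) >= 0.5 * unit$mean, , drop = FALSE]
      steps_by_spot <- c(steps_by_spot, list(st))
      n_partial <- n_partial + nrow(losses)
    }
  }
  out <- partial_step_fraction(steps_by_spot, unit, min_events = min_events)
  out[c("fraction_single", "n_events", "n_spots")]
}
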