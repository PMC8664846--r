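# Trace generators. Every generator returns (trace, ground_truth) so that the
# downstream analysis (idealization, counting, kinetics, pathway calls) can be
# tested as parameter-recovery experiments against known truth.

ground_truth <- function(event_times = numeric(), event_sizes = numeric(),
                         dye_counts = integer(), censored = FALSE, ...) {
  if (is.unsorted(event_times, strictly = TRUE) && length(event_times) > 1)
    stop("ground-truth event times must be strictly increasing", call. = FALSE)
  if (any(dye_counts < 0))
    stop("ground-truth dye counts must be non-negative", call. = FALSE)
  structure(list(event_times = event_times, event_sizes = event_sizes,
                 dye_counts = dye_counts, censored = censored, ...),
            class = "sm_ground_truth")
}

# Per-frame camera intensity for a dye-count series: each active dye emits
# Gaussian(unit_mean, unit_sd) counts per frame independently, so k dyes give
# N(k * mean, sqrt(k) * sd); additive Gaussian read noise on top.
emit_intensity <- function(counts, cfg) {
  n <- length(counts)
  signal <- ifelse(counts > 0,
                   stats::rnorm(n, counts * cfg$unit_mean,
                                sqrt(pmax(counts, 0)) * cfg$unit_sd),
                   0)
  signal + stats::rnorm(n, 0, cfg$read_noise_sd)
}

#' Simulate a single-spot photobleaching calibration trace
#'
#' Each of `n_dyes` fluorophores emits independently until it photobleaches;
#' per-dye frame lifetimes are geometric with per-frame probability
#' `config$bleach_rate` (a rate of 0 means no bleaching). The trace is the
#' summed emission of the surviving dyes plus camera read noise. These movies
#' calibrate the single-fluorophore intensity unit from the downward step
#' sizes.
#'
#' @param config A [sim_config()] with `condition = "CALIBRATION"`.
#' @param n_dyes Number of fluorophores on the spot (>= 1).
#' @return A list with elements `trace` ([sm_trace()]) and `truth`
#'   (`sm_ground_truth` with bleach event times, sizes of -1 per dye merged
#'   by frame, and the per-frame true dye count).
#' @export
#' @examples
#' sim <- simulate_bleach_trace(sim_config("CALIBRATION", seed = 1,
#'                                         n_frames = 200), n_dyes = 2)
#' plot(sim$trace$values, type = "l")
simulate_bleach_trace <- function(config, n_dyes) {
  validate_sim_config(config)
  if (config$condition != "CALIBRATION")
    stop("simulate_bleach_trace requires the CALIBRATION preset", call. = FALSE)
  if (!is.numeric(n_dyes) || length(n_dyes) != 1L || n_dyes < 1)
    stop("n_dyes must be a positive integer", call. = FALSE)
  maybe_seed(config)
  n_dyes <- as.integer(n_dyes)
  nf <- config$n_frames
  dt <- config$frame_interval

  # frames alive per dye; geometric lifetime, at least one frame
  life <- if (config$bleach_rate > 0) {
    stats::rgeom(n_dyes, config$bleach_rate) + 1L
  } else {
    rep(nf, n_dyes)
  }
  life <- pmin(life, nf)
  counts <- vapply(seq_len(nf), function(f) sum(life >= f), integer(1))

  bleach_frames <- life[life < nf]          # dye bleached inside the movie
  ev <- sort(unique(bleach_frames))
  sizes <- -vapply(ev, function(f) sum(bleach_frames == f), integer(1))
  trace <- sm_trace(emit_intensity(counts, config), dt,
                    trace_id = "calib", channel = "A")
  truth <- ground_truth(event_times = ev * dt, event_sizes = sizes,
                        dye_counts = counts, n_dyes = n_dyes)
  list(trace = trace, truth = truth)
}

#' Simulate a set of calibration traces
#'
#' @param config A CALIBRATION [sim_config()]; its seed (if any) is applied
#'   once for the whole set.
#' @param n_traces Number of traces.
#' @param n_dyes_range Integer vector the per-trace dye count is drawn from
#'   (uniformly). Default 1:4.
#' @return List with `traces` and `truths` (parallel lists).
#' @export
simulate_calibration_set <- function(config, n_traces,
                                     n_dyes_range = 1:4) {
  validate_sim_config(config)
  maybe_seed(config)
  config <- strip_seed(config)
  n_dyes <- sample(rep(n_dyes_range, length.out = max(n_traces,
                                                      length(n_dyes_range))),
                   n_traces, replace = TRUE)
  sims <- lapply(seq_len(n_traces), function(i) {
    s <- simulate_bleach_trace(config, n_dyes[i])
    s$trace$trace_id <- sprintf("calib_%03d", i)
    s
  })
  list(traces = lapply(sims, `[[`, "trace"),
       truths = lapply(sims, `[[`, "truth"))
}

#' Simulate an oligomer association/dissociation trace
#'
#' Kinetic Monte Carlo trace of a surface-immobilized cluster exchanging
#' dimer-scale units with solution: waiting times alternate between
#' Exponential(`tau_assoc`) before a gain and Exponential(`tau_dissoc`)
#' before a loss, independent of the current cluster size. Event sizes
#' (molecules) are drawn from the configured association and dissociation
#' mixtures; losses are truncated so the size never goes below zero. The
#' cluster starts at a size drawn from the association mixture.
#'
#' @param config A [sim_config()] with `condition = "DYNAMICS"` whose
#'   `kinetics` holds `tau_assoc` and `tau_dissoc` (seconds).
#' @return List with `trace` and `truth`; `truth$event_sizes` are signed
#'   molecule-count changes and `truth$waits` the drawn waiting times
#'   (named by event direction).
#' @export
simulate_oligomer_dynamics_trace <- function(config) {
  validate_sim_config(config)
  if (config$condition != "DYNAMICS")
    stop("simulate_oligomer_dynamics_trace requires the DYNAMICS preset",
         call. = FALSE)
  kin <- config$kinetics
  if (is.null(kin$tau_assoc) || is.null(kin$tau_dissoc))
    stop("DYNAMICS config must provide kinetics$tau_assoc and tau_dissoc",
         call. = FALSE)
  mixes <- config$size_distribution
  if (is.null(mixes$association) || is.null(mixes$dissociation))
    stop("DYNAMICS config must provide association/dissociation size mixtures",
         call. = FALSE)
  maybe_seed(config)
  nf <- config$n_frames
  dt <- config$frame_interval
  window <- nf * dt

  size <- draw_sizes(mixes$association, 1)
  t_now <- 0
  gain_next <- TRUE
  ev_t <- numeric()
  ev_s <- numeric()
  waits <- numeric()
  repeat {
    tau <- if (gain_next) kin$tau_assoc else kin$tau_dissoc
    w <- stats::rexp(1, 1 / tau)
    # every draw is recorded (including the final overshoot), so the wait
    # sample in the ground truth is iid exponential, free of window bias
    waits <- c(waits, stats::setNames(w, if (gain_next) "gain" else "loss"))
    t_now <- t_now + w
    if (t_now >= window) break
    if (gain_next) {
      d <- draw_sizes(mixes$association, 1)
    } else {
      d <- -min(draw_sizes(mixes$dissociation, 1), size)
    }
    if (d != 0) {
      ev_t <- c(ev_t, t_now)
      ev_s <- c(ev_s, d)
      size <- size + d
    }
    gain_next <- !gain_next
  }
  counts <- dye_count_series(ev_t, ev_s, start = size - sum(ev_s),
                             nf = nf, dt = dt)
  trace <- sm_trace(emit_intensity(counts, config), dt,
                    trace_id = "dynamics", channel = "A")
  truth <- ground_truth(event_times = ev_t, event_sizes = ev_s,
                        dye_counts = counts, waits = waits)
  list(trace = trace, truth = truth)
}

# Piecewise-constant molecule count per frame from signed events at
# continuous times; an event lands in the frame containing its time, i.e. the
# count changes from the frame floor(t/dt) onward.
dye_count_series <- function(event_times, event_sizes, start, nf, dt) {
  counts <- rep(as.integer(start), nf)
  if (length(event_times)) {
    for (i in seq_along(event_times)) {
      f <- floor(event_times[i] / dt) + 1L  # 1-based frame index
      if (f <= nf) counts[f:nf] <- counts[f:nf] + as.integer(event_sizes[i])
    }
  }
  if (any(counts < 0)) stop("internal: negative dye count", call. = FALSE)
  counts
}

#' Simulate a single-RNA disappearance trace
#'
#' One fluorophore is present from the first frame and disappears in a single
#' step at an Exponential(`tau_rna`) time; the trace is truncated at the
#' recording window (`n_frames * frame_interval`) and marked censored when
#' the disappearance falls outside it.
#'
#' @param config A [sim_config()] with condition `"RNA_1MM_ATP"` or
#'   `"RNA_10UM_ATP"`.
#' @return List with `trace` and `truth` (`truth$true_time` is the continuous
#'   disappearance time, `truth$censored` whether it exceeded the window).
#' @export
simulate_rna_trace <- function(config) {
  validate_sim_config(config)
  if (!config$condition %in% c("RNA_1MM_ATP", "RNA_10UM_ATP"))
    stop("simulate_rna_trace requires an RNA_*_ATP preset", call. = FALSE)
  tau <- config$kinetics$tau_rna
  if (is.null(tau))
    stop("RNA config must provide kinetics$tau_rna", call. = FALSE)
  maybe_seed(config)
  nf <- config$n_frames
  dt <- config$frame_interval
  window <- nf * dt
  td <- stats::rexp(1, 1 / tau)
  censored <- td >= window
  present <- min(floor(td / dt), nf)   # whole frames with the dye present
  counts <- c(rep(1L, present), rep(0L, nf - present))
  trace <- sm_trace(emit_intensity(counts, config), dt,
                    trace_id = "rna", channel = "B")
  truth <- ground_truth(
    event_times = if (censored) numeric() else present * dt,
    event_sizes = if (censored) numeric() else -1,
    dye_counts = counts, censored = censored, true_time = td)
  list(trace = trace, truth = truth)
}

#' Simulate a set of RNA traces
#' @inheritParams simulate_calibration_set
#' @param config An RNA-preset [sim_config()].
#' @export
simulate_rna_set <- function(config, n_traces) {
  validate_sim_config(config)
  maybe_seed(config)
  config <- strip_seed(config)
  sims <- lapply(seq_len(n_traces), function(i) {
    s <- simulate_rna_trace(config)
    s$trace$trace_id <- sprintf("rna_%04d", i)
    s
  })
  list(traces = lapply(sims, `[[`, "trace"),
       truths = lapply(sims, `[[`, "truth"))
}

#' Simulate a field of RNA traces decaying at the ensemble rate
#'
#' Convenience generator for the field-of-view ensemble decay experiment:
#' identical to [simulate_rna_set()] but using `kinetics$tau_ensemble`
#' as the disappearance time constant.
#' @inheritParams simulate_rna_set
#' @export
simulate_ensemble_field <- function(config, n_traces) {
  tau <- config$kinetics$tau_ensemble
  if (is.null(tau))
    stop("config must provide kinetics$tau_ensemble", call. = FALSE)
  config$kinetics$tau_rna <- tau
  simulate_rna_set(config, n_traces)
}

#' Draw dwell times directly from the configured kinetics
#'
#' Samples waiting times from the exponential law of the requested event kind
#' without rendering traces; this is the generator's kinetic core, used for
#' dwell-time parameter-recovery experiments free of window truncation.
#'
#' @param config A [sim_config()] whose `kinetics` holds the matching rate
#'   (`tau_assoc`, `tau_dissoc` or `tau_rna`).
#' @param kind Event kind.
#' @param n Number of draws.
#' @param window Optional right-censoring window in seconds; draws beyond it
#'   are recorded as censored at `window`.
#' @return A [dwell_sample()].
#' @export
simulate_dwell_sample <- function(config, kind = c("association",
                                                   "dissociation",
                                                   "rna_release"),
                                  n, window = NULL) {
  kind <- match.arg(kind)
  validate_sim_config(config)
  tau <- switch(kind,
                association = config$kinetics$tau_assoc,
                dissociation = config$kinetics$tau_dissoc,
                rna_release = config$kinetics$tau_rna)
  if (is.null(tau))
    stop(sprintf("config has no rate parameter for kind '%s'", kind),
         call. = FALSE)
  maybe_seed(config)
  d <- stats::rexp(n, 1 / tau)
  cens <- rep(FALSE, n)
  if (!is.null(window)) {
    cens <- d >= window
    d[cens] <- window
  }
  dwell_sample(d, cens, condition = config$condition, event_kind = kind)
}

#' Generate step events from a size mixture at measurement noise
#'
#' Draws `n` event sizes (molecules) from the configured association or
#' dissociation mixture and converts them to intensity deltas
#' `k * unit_mean + N(0, sqrt(k) * unit_sd)`, i.e. at the per-dye intensity
#' spread of the calibration. Used for event-stoichiometry recovery
#' experiments.
#'
#' @param config A DYNAMICS [sim_config()].
#' @param direction `"gain"` (association) or `"loss"` (dissociation).
#' @param n Number of events.
#' @return List with `steps` (a step-event data frame, see [extract_steps()])
#'   and `true_sizes` (integer molecule counts).
#' @export
simulate_step_events <- function(config, direction = c("gain", "loss"), n) {
  direction <- match.arg(direction)
  validate_sim_config(config)
  mix <- config$size_distribution[[
    if (direction == "gain") "association" else "dissociation"]]
  if (is.null(mix))
    stop("config lacks the size mixture for this direction", call. = FALSE)
  maybe_seed(config)
  k <- draw_sizes(mix, n)
  mag <- k * config$unit_mean + stats::rnorm(n, 0, sqrt(k) * config$unit_sd)
  mag <- pmax(mag, 0)
  sgn <- if (direction == "gain") 1 else -1
  steps <- data.frame(
    trace_id = sprintf("ev_%05d", seq_len(n)),
    time = seq_len(n) * config$frame_interval,
    frame = seq_len(n),
    delta = sgn * mag,
    from_level = if (direction == "gain") 0 else mag,
    to_level = if (direction == "gain") mag else 0,
    direction = if (direction == "gain") "gain" else "loss",
    stringsAsFactors = FALSE)
  list(steps = steps, true_sizes = k)
}
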