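# Dwell-time extraction, single-exponential fitting (empirical-CDF least
# squares mirroring curve-fitting practice, plus censoring-aware MLE),
# survival fractions, ensemble decay and the Welch group test.

#' Extract dwell times from per-trace step events
#'
#' * `association`: time from the previous event (default) or the movie
#'   start to each gain.
#' * `dissociation`: time from the preceding gain (or the movie start) to
#'   each loss.
#' * `rna_release`: time from the movie start to the single (first) loss.
#'
#' Traces with no qualifying event contribute one right-censored duration
#' equal to `window`. Dwells shorter than one frame are below the detection
#' limit and are dropped.
#'
#' @param events List of step-event data frames (one per trace, time-sorted;
#'   see [extract_steps()]).
#' @param window Observation window in seconds (> 0).
#' @param kind Dwell kind (see above).
#' @param origin For `association`: `"previous"` (default) measures from the
#'   previous event of any direction, `"start"` from the movie start.
#' @param condition Condition label stored on the sample.
#' @return A [dwell_sample()].
#' @export
extract_dwells <- function(events, window,
                           kind = c("association", "dissociation",
                                    "rna_release"),
                           origin = c("previous", "start"),
                           condition = NA_character_) {
  kind <- match.arg(kind)
  origin <- match.arg(origin)
  if (!is.numeric(window) || window <= 0)
    stop("window must be positive", call. = FALSE)
  if (is.data.frame(events)) events <- list(events)

  durations <- numeric()
  censored <- logical()
  for (ev in events) {
    ev <- ev[ev$time <= window, , drop = FALSE]
    d <- switch(kind,
      association = {
        gains <- which(ev$direction == "gain")
        if (!length(gains)) numeric() else {
          ref <- if (origin == "start") {
            rep(0, length(gains))
          } else {
            c(0, ev$time)[gains]        # previous event of any kind, or 0
          }
          ev$time[gains] - ref
        }
      },
      dissociation = {
        losses <- which(ev$direction == "loss")
        if (!length(losses)) numeric() else {
          vapply(losses, function(i) {
            prev_gain <- which(ev$direction[seq_len(i - 1)] == "gain")
            ref <- if (length(prev_gain)) ev$time[max(prev_gain)] else 0
            ev$time[i] - ref
          }, numeric(1))
        }
      },
      rna_release = {
        losses <- which(ev$direction == "loss")
        if (!length(losses)) numeric() else ev$time[losses[1]]
      })
    if (!length(d)) {
      durations <- c(durations, window)
      censored <- c(censored, TRUE)
    } else {
      d <- d[d > 0]                       # one-frame detection limit
      durations <- c(durations, d)
      censored <- c(censored, rep(FALSE, length(d)))
    }
  }
  dwell_sample(durations, censored, condition = condition, event_kind = kind)
}

#' Fit a single exponential to a dwell-time sample
#'
#' `method = "cdf_lsq"` (default) least-squares fits `1 - exp(-t / tau)` to
#' the empirical CDF of the uncensored durations (Hazen plotting positions
#' `(i - 0.5) / n`), the direct analogue of fitting a cumulative dwell-time
#' distribution with a single-exponential curve. `method = "mle"` is the
#' censoring-aware maximum-likelihood estimate
#' `tau = sum(all durations) / n_uncensored` with `SE = tau /
#' sqrt(n_uncensored)`.
#'
#' @param sample A [dwell_sample()].
#' @param method `"cdf_lsq"` or `"mle"`.
#' @param min_events Minimum number of uncensored durations (default 10).
#' @return An `exp_fit`: list with `tau`, `tau_se`, `r_squared`, `n_events`,
#'   `method`.
#' @export
fit_exponential <- function(sample, method = c("cdf_lsq", "mle"),
                            min_events = 10L) {
  method <- match.arg(method)
  d <- sample$duration_s
  cens <- sample$censored
  n_unc <- sum(!cens)
  if (n_unc == 0) stop("insufficient data: all durations censored",
                       call. = FALSE)
  if (n_unc < min_events)
    stop(sprintf("insufficient data: %d uncensored durations (need >= %d)",
                 n_unc, min_events), call. = FALSE)

  if (method == "mle") {
    tau <- sum(d) / n_unc
    return(structure(list(tau = tau, tau_se = tau / sqrt(n_unc),
                          r_squared = NA_real_, n_events = n_unc,
                          method = "mle", baseline = NA_real_),
                     class = "exp_fit"))
  }
  t_sorted <- sort(d[!cens])
  F_emp <- (seq_len(n_unc) - 0.5) / n_unc
  fit <- minpack.lm::nlsLM(F_emp ~ 1 - exp(-t_sorted / tau),
                           start = list(tau = mean(t_sorted)),
                           lower = c(tau = 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- summary(fit)$coefficients
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((F_emp - mean(F_emp))^2)
  structure(list(tau = unname(cf["tau", "Estimate"]),
                 tau_se = unname(cf["tau", "Std. Error"]),
                 r_squared = r2, n_events = n_unc, method = "cdf_lsq",
                 baseline = NA_real_),
            class = "exp_fit")
}

#' Fraction of molecules surviving past a time point
#'
#' Fraction of traces whose duration exceeds `t`; durations censored at or
#' beyond `t` count as surviving.
#'
#' @param sample A [dwell_sample()].
#' @param t Time in seconds (>= 0).
#' @return Fraction in `[0, 1]`; monotone non-increasing in `t`, equal to 1
#'   at `t = 0` (durations are positive).
#' @export
survival_fraction <- function(sample, t) {
  if (!is.numeric(t) || t < 0) stop("t must be >= 0", call. = FALSE)
  if (!nrow(sample)) stop("insufficient data: empty sample", call. = FALSE)
  surv <- sample$duration_s > t | (sample$censored & sample$duration_s >= t)
  mean(surv)
}

#' Fit an exponential decay with baseline to an ensemble time course
#'
#' Least-squares fit of `A * exp(-t / tau) + B` to a normalized ensemble
#' intensity series (first value 1).
#'
#' @param series Numeric vector starting at 1 (see [ensemble_intensity()]),
#'   length >= 10.
#' @param frame_interval Seconds per frame.
#' @return An `exp_fit` with `baseline` set to the fitted B.
#' @export
fit_ensemble_decay <- function(series, frame_interval) {
  if (length(series) < 10) stop("series too short", call. = FALSE)
  if (abs(series[1] - 1) > 1e-6)
    stop("series must be normalized to 1 at t = 0", call. = FALSE)
  tt <- (seq_along(series) - 1) * frame_interval
  if (stats::sd(series) == 0 || series[length(series)] >= series[1])
    stop("fit failure: series does not decay", call. = FALSE)
  b0 <- min(series)
  a0 <- 1 - b0
  # crude initial tau: time to fall to b0 + a0/e
  idx <- which(series <= b0 + a0 / exp(1))
  tau0 <- if (length(idx)) max(tt[idx[1]], frame_interval) else
    tt[length(tt)] / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(series ~ A * exp(-tt / tau) + B,
                      start = list(A = a0, tau = tau0, B = b0),
                      lower = c(A = 0, tau = 1e-9, B = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("fit failure: ", conditionMessage(e),
                             call. = FALSE))
  cf <- summary(fit)$coefficients
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((series - mean(series))^2)
  structure(list(tau = unname(cf["tau", "Estimate"]),
                 tau_se = unname(cf["tau", "Std. Error"]),
                 r_squared = r2, n_events = length(series),
                 method = "ensemble",
                 baseline = unname(cf["B", "Estimate"])),
            class = "exp_fit")
}

#' Welch's unequal-variance t-test between two dwell groups
#'
#' Two-sided Welch test with Welch-Satterthwaite degrees of freedom; used to
#' check that dwell times do not depend on oligomer size.
#'
#' @param group_a,group_b Numeric vectors (each >= 2 values; not both with
#'   zero variance).
#' @return List with `t_statistic`, `p_value`, `df`.
#' @export
welch_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(t_statistic = 0, p_value = 1, df = NA_real_))
    stop("zero variance in both groups", call. = FALSE)
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t_statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}
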