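#' Construct an intensity trace
#'
#' A trace is one spot's intensity time series: the fundamental unit handed
#' between the simulator, the spot extractor, the idealizer and the kinetics
#' layer.
#'
#' @param values Numeric vector of per-frame intensities (camera counts).
#' @param frame_interval Frame interval in seconds (> 0).
#' @param trace_id Character label.
#' @param channel Channel label, e.g. `"A"` (protein) or `"B"` (RNA).
#' @param origin Optional [detect_spots()] row (a one-row data frame) the
#'   trace was extracted from; `NULL` for simulated or directly loaded traces.
#' @return An object of class `sm_trace`.
#' @export
sm_trace <- function(values, frame_interval, trace_id = "trace",
                     channel = "A", origin = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a trace needs at least 2 frames", call. = FALSE)
  if (!all(is.finite(values)))
    stop("trace values must all be finite", call. = FALSE)
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      frame_interval <= 0)
    stop("frame_interval must be a single positive number", call. = FALSE)
  structure(
    list(values = values, frame_interval = as.numeric(frame_interval),
         trace_id = as.character(trace_id), channel = as.character(channel),
         origin = origin),
    class = "sm_trace")
}

#' @export
print.sm_trace <- function(x, ...) {
  cat(sprintf("<sm_trace %s> channel %s, %d frames @ %.3g s, range [%.1f, %.1f]\n",
              x$trace_id, x$channel, length(x$values), x$frame_interval,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.sm_trace <- function(x) length(x$values)

#' Frame times of a trace
#'
#' Time origin is the first recorded frame (t = 0).
#' @param trace An [sm_trace()].
#' @return Numeric vector of times in seconds, one per frame.
#' @export
trace_times <- function(trace) {
  (seq_along(trace$values) - 1) * trace$frame_interval
}

#' Construct a dwell-time sample
#'
#' Durations with right-censoring flags, ready for exponential fitting.
#' A censored entry means the recording window ended before the event.
#'
#' @param durations Non-negative durations in seconds.
#' @param censored Logical vector, same length as `durations`.
#' @param condition Condition label carried along for bookkeeping.
#' @param event_kind One of `"association"`, `"dissociation"`, `"rna_release"`.
#' @return A `dwell_sample` data frame with columns `duration_s`, `censored`.
#' @export
dwell_sample <- function(durations, censored = rep(FALSE, length(durations)),
                         condition = NA_character_,
                         event_kind = c("association", "dissociation",
                                        "rna_release")) {
  event_kind <- match.arg(event_kind)
  durations <- as.numeric(durations)
  censored <- as.logical(censored)
  if (length(durations) != length(censored))
    stop("durations and censored must have the same length", call. = FALSE)
  if (any(durations < 0))
    stop("durations must be non-negative", call. = FALSE)
  out <- data.frame(duration_s = durations, censored = censored)
  attr(out, "condition") <- condition
  attr(out, "event_kind") <- event_kind
  class(out) <- c("dwell_sample", "data.frame")
  out
}

# Empty step-event table with the canonical columns.
empty_steps <- function() {
  data.frame(trace_id = character(), time = numeric(), frame = integer(),
             delta = numeric(), from_level = numeric(), to_level = numeric(),
             direction = character(), stringsAsFactors = FALSE)
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> mean %.2f, sd %.2f (n = %d, R^2 = %s)\n",
              x$mean, x$sd, x$n,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared))))
  invisible(x)
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit %s> tau %.2f +/- %.2f s (n = %d, R^2 = %s)\n",
              x$method, x$tau, x$tau_se, x$n_events,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared))))
  if (!is.null(x$baseline) && !is.na(x$baseline))
    cat(sprintf("  baseline %.4f\n", x$baseline))
  invisible(x)
}

#' @export
print.count_distribution <- function(x, ...) {
  cat(sprintf("<count_distribution> n = %d, fitted mean %.2f +/- %.2f\n",
              x$n, x$mean, x$se))
  print(x$histogram)
  invisible(x)
}

#' @export
print.ideal_trace <- function(x, ...) {
  cat(sprintf("<ideal_trace %s> %d segment(s), %d state(s), logLik %.1f\n",
              x$trace_id, nrow(x$segments), x$n_states, x$log_likelihood))
  invisible(x)
}

#' @export
print.pathway_call <- function(x, ...) {
  cat(sprintf("<pathway_call %s> %s; RNA step %s s; %d Vasa-channel loss(es)\n",
              x$pair_id, x$class,
              ifelse(is.na(x$rna_step_time), "none",
                     sprintf("%.1f", x$rna_step_time)),
              length(x$vasa_step_times)))
  invisible(x)
}
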