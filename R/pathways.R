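# Two-colour pair matching, dissociation pathway classification and
# partial-step statistics.

#' Match spots between two channels
#'
#' Mutual-nearest-neighbour matching within a radius: A and B spots are
#' paired when each is the other's closest partner and their distance is at
#' most `radius`. The colocalization fraction is matched B spots over total
#' B spots.
#'
#' @param spots_a,spots_b Data frames with `x`, `y` (0-based pixels), e.g.
#'   from [detect_spots()].
#' @param radius Matching radius in pixels (> 0). Default 2 px, below the
#'   diffraction-limited spot spacing enforced by detection.
#' @return List with `pairs` (data frame: `pair_id`, `a_index`, `b_index`,
#'   `ax`, `ay`, `bx`, `by`, `distance`), `unmatched_a`, `unmatched_b`
#'   (row indices), `colocalization_fraction`.
#' @export
match_channels <- function(spots_a, spots_b, radius = 2) {
  if (!is.numeric(radius) || radius <= 0)
    stop("radius must be positive", call. = FALSE)
  na <- nrow(spots_a)
  nb <- nrow(spots_b)
  empty <- data.frame(pair_id = character(), a_index = integer(),
                      b_index = integer(), ax = numeric(), ay = numeric(),
                      bx = numeric(), by = numeric(), distance = numeric())
  if (!na || !nb)
    return(list(pairs = empty, unmatched_a = seq_len(na),
                unmatched_b = seq_len(nb),
                colocalization_fraction = if (nb) 0 else NA_real_))
  dmat <- sqrt(outer(spots_a$x, spots_b$x, "-")^2 +
               outer(spots_a$y, spots_b$y, "-")^2)
  nn_a <- apply(dmat, 1, which.min)     # nearest B for each A
  nn_b <- apply(dmat, 2, which.min)     # nearest A for each B
  ai <- which(nn_b[nn_a] == seq_len(na) &
              dmat[cbind(seq_len(na), nn_a)] <= radius)
  bi <- nn_a[ai]
  pairs <- data.frame(pair_id = sprintf("pair_%03d", seq_along(ai)),
                      a_index = ai, b_index = bi,
                      ax = spots_a$x[ai], ay = spots_a$y[ai],
                      bx = spots_b$x[bi], by = spots_b$y[bi],
                      distance = dmat[cbind(ai, bi)],
                      stringsAsFactors = FALSE)
  list(pairs = pairs,
       unmatched_a = setdiff(seq_len(na), ai),
       unmatched_b = setdiff(seq_len(nb), bi),
       colocalization_fraction = nrow(pairs) / nb)
}

#' Classify a colocalized pair into a dissociation pathway
#'
#' Rules, applied to the idealized traces of one pair over a common window:
#'
#' * `NO_DISSOCIATION` if channel B (RNA) shows no loss within the window;
#' * otherwise `SIMULTANEOUS` if the RNA step time is within
#'   `sim_tolerance` of the nearest (default) or final channel-A loss;
#' * otherwise `SEQUENTIAL`.
#'
#' Classification is invariant to channel-wide intensity scaling (only step
#' times are compared).
#'
#' @param ideal_a,ideal_b `ideal_trace` objects for the protein (A) and RNA
#'   (B) channels over the same window.
#' @param window Window in seconds (default 400).
#' @param sim_tolerance Simultaneity tolerance in seconds; default 2 frames
#'   of channel B.
#' @param match Compare the RNA step to the `"nearest"` (default) or
#'   `"final"` channel-A loss.
#' @param unit Optional calibrated `gaussian_fit`; when given, the residual
#'   channel-A level after the last loss is converted to molecules.
#' @param pair_id Label.
#' @return A `pathway_call`: list with `class`, `rna_step_time` (NA when
#'   absent), `vasa_step_times` (sorted), `vasa_residual_level`,
#'   `vasa_residual_count` (NA without `unit`), `pair_id`.
#' @export
classify_pathway <- function(ideal_a, ideal_b, window = 400,
                             sim_tolerance = NULL,
                             match = c("nearest", "final"), unit = NULL,
                             pair_id = "pair") {
  match <- match.arg(match)
  stopifnot(inherits(ideal_a, "ideal_trace"), inherits(ideal_b, "ideal_trace"))
  for (id in list(ideal_a, ideal_b)) {
    if (window > id$n_frames * id$frame_interval + 1e-9)
      stop("window exceeds the idealized trace length", call. = FALSE)
  }
  if (is.null(sim_tolerance)) sim_tolerance <- 2 * ideal_b$frame_interval

  steps_a <- extract_steps(ideal_a)
  steps_b <- extract_steps(ideal_b)
  a_losses <- steps_a[steps_a$direction == "loss" & steps_a$time <= window, ,
                      drop = FALSE]
  b_losses <- steps_b[steps_b$direction == "loss" & steps_b$time <= window, ,
                      drop = FALSE]

  rna_time <- if (nrow(b_losses)) b_losses$time[1] else NA_real_
  a_times <- sort(a_losses$time)
  residual_level <- if (nrow(a_losses)) a_losses$to_level[nrow(a_losses)]
                    else ideal_a$segments$level[1]

  cls <- if (is.na(rna_time)) {
    "NO_DISSOCIATION"
  } else {
    ref <- if (!length(a_times)) Inf else if (match == "final")
      abs(rna_time - a_times[length(a_times)]) else
      min(abs(rna_time - a_times))
    if (ref <= sim_tolerance) "SIMULTANEOUS" else "SEQUENTIAL"
  }
  structure(list(class = cls, rna_step_time = rna_time,
                 vasa_step_times = a_times,
                 vasa_residual_level = residual_level,
                 vasa_residual_count = if (is.null(unit)) NA_integer_ else
                   count_molecules(residual_level, unit),
                 pair_id = pair_id),
            class = "pathway_call")
}

#' Pathway class counts and percentages
#'
#' @param calls List of `pathway_call` objects.
#' @return List with `counts` (named integer vector over the three classes),
#'   `fractions`, `percents` (rounded to integers), `n`.
#' @export
pathway_fractions <- function(calls) {
  if (!length(calls)) stop("insufficient data: no calls", call. = FALSE)
  cls <- factor(vapply(calls, `[[`, character(1), "class"),
                levels = PATHWAY_CLASSES)
  counts <- table(cls)
  n <- length(calls)
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       fractions = as.numeric(counts) / n,
       percents = stats::setNames(round(100 * as.numeric(counts) / n),
                                  names(counts)),
       n = n)
}

#' Fraction of partial protein-channel losses that are single molecules
#'
#' A partial loss is a channel-A loss that does not empty the spot (the
#' post-step level still holds at least one molecule). Each partial loss is
#' converted to a molecule count with the calibrated unit; the statistic is
#' the fraction counted as exactly 1. Losses counting to zero molecules
#' (magnitude below half a unit) are segmentation noise rather than
#' molecular dissociation events and are excluded.
#'
#' @param steps_by_spot List of channel-A step-event data frames, one per
#'   colocalized spot.
#' @param unit Calibrated `gaussian_fit`.
#' @param min_events Minimum number of partial losses (default 20).
#' @return List with `fraction_single`, `n_events`, `n_spots`,
#'   `counts` (per-event molecule counts).
#' @export
partial_step_fraction <- function(steps_by_spot, unit, min_events = 20L) {
  if (is.data.frame(steps_by_spot)) steps_by_spot <- list(steps_by_spot)
  per_spot <- lapply(steps_by_spot, function(st) {
    losses <- st[st$direction == "loss", , drop = FALSE]
    losses <- losses[losses$to_level >= 0.5 * unit$mean, , drop = FALSE]
    # keep molecular events only: at least one molecule lost
    losses[abs(losses$delta) >= 0.5 * unit$mean, , drop = FALSE]
  })
  n_events <- sum(vapply(per_spot, nrow, integer(1)))
  if (n_events < min_events)
    stop(sprintf("insufficient data: %d partial losses (need >= %d)",
                 n_events, min_events), call. = FALSE)
  counts <- unlist(lapply(per_spot, function(st)
    count_molecules(abs(st$delta), unit)))
  list(fraction_single = mean(counts == 1),
       n_events = n_events,
       n_spots = sum(vapply(per_spot, nrow, integer(1)) > 0),
       counts = counts)
}
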