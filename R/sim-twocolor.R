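# Two-colour (protein channel A / RNA channel B) pair generator for the
# colocalized dissociation-pathway experiment.

PATHWAY_CLASSES <- c("SIMULTANEOUS", "SEQUENTIAL", "NO_DISSOCIATION")

#' Simulate one colocalized two-colour trace pair
#'
#' Channel B carries a single RNA fluorophore with at most one disappearance
#' step; channel A starts at an oligomer size drawn from the colocalized size
#' mixture (support 2-10) and loses molecules in partial steps whose sizes
#' are 1 with probability `pathway_single_prob` (default 0.85) and 2
#' otherwise, with Exponential(`tau_partial`) waits between losses. Partial
#' dissociation continues only while at least three molecules remain, so the
#' residual oligomer never drops below the stable dimer-scale core and every
#' partial step size is an unconditioned Bernoulli draw. The pair belongs to
#' one of three dissociation classes:
#'
#' * `SIMULTANEOUS`: the RNA step and the final (complete) channel-A loss
#'   fall in the same frame.
#' * `SEQUENTIAL`: the RNA step occurs inside the window but every channel-A
#'   loss is separated from it by at least `min_sep_frames` frames.
#' * `NO_DISSOCIATION`: the RNA survives the whole window (right-censored);
#'   channel A still loses molecules partially.
#'
#' @param config A [sim_config()] with `condition = "TWO_COLOR"`.
#' @param class Optional forced class label (used by the stratified mode);
#'   `NULL` draws from `config$pathway_probs`.
#' @return List with `trace_a`, `trace_b` ([sm_trace()]) and `truth`
#'   (class, RNA step time, channel-A event times/sizes, start size).
#' @export
simulate_two_color_pair <- function(config, class = NULL) {
  validate_sim_config(config)
  if (config$condition != "TWO_COLOR")
    stop("simulate_two_color_pair requires the TWO_COLOR preset",
         call. = FALSE)
  if (is.null(config$pathway_probs))
    stop("TWO_COLOR config must provide pathway_probs", call. = FALSE)
  check_weights(config$pathway_probs, "pathway_probs")
  maybe_seed(config)

  nf <- config$n_frames
  dt <- config$frame_interval
  window <- nf * dt
  kin <- config$kinetics
  min_sep <- (if (is.null(config$min_sep_frames)) 6L else
                config$min_sep_frames) * dt
  if (is.null(class))
    class <- sample(PATHWAY_CLASSES, 1, prob = config$pathway_probs)
  class <- match.arg(class, PATHWAY_CLASSES)

  s0 <- draw_sizes(config$size_distribution$colocalized, 1)

  # RNA disappearance time: exponential truncated to lie inside the window
  # (with a margin so the step is resolvable) for the two dissociating
  # classes; absent for NO_DISSOCIATION.
  t_b <- NA_real_
  if (class != "NO_DISSOCIATION") {
    lo <- 3 * dt
    hi <- window - 3 * dt
    u <- stats::runif(1, stats::pexp(lo, 1 / kin$tau_rna),
                      stats::pexp(hi, 1 / kin$tau_rna))
    t_b <- stats::qexp(u, 1 / kin$tau_rna)
  }

  # Channel-A partial losses: exponential waits; each step loses 1 molecule
  # with probability p_single, else 2. Partial dissociation proceeds only
  # while at least 3 molecules remain (the dimer is the stable unit), so
  # both step sizes are always feasible and every emitted step is an
  # unconditioned Bernoulli(p_single) draw.
  p1 <- if (is.null(config$pathway_single_prob)) 0.85 else
    config$pathway_single_prob
  a_t <- numeric()
  a_s <- integer()
  size <- s0
  t_now <- 0
  limit <- if (class == "SIMULTANEOUS") t_b - min_sep else window
  repeat {
    t_now <- t_now + stats::rexp(1, 1 / kin$tau_partial)
    if (t_now >= limit || size <= 2L) break
    d <- if (stats::runif(1) < p1) 1L else 2L
    a_t <- c(a_t, t_now)
    a_s <- c(a_s, -d)
    size <- size - d
  }

  if (class == "SIMULTANEOUS") {
    # final complete channel-A loss in the same frame as the RNA step
    a_t <- c(a_t, t_b)
    a_s <- c(a_s, -size)
    size <- 0L
  } else if (class == "SEQUENTIAL" && length(a_t)) {
    # keep every A loss clear of the RNA step by at least min_sep
    bad <- abs(a_t - t_b) < min_sep
    if (any(bad)) {
      for (i in which(bad)) {
        a_t[i] <- if (t_b + min_sep + dt < window) t_b + min_sep + dt
                  else t_b - min_sep - dt
      }
      ord <- order(a_t)
      a_t <- a_t[ord]
      a_s <- a_s[ord]
    }
  }
  # guard against equal times after adjustment
  if (length(a_t) > 1 && any(diff(a_t) <= 0)) {
    keep <- !duplicated(a_t)
    a_s <- a_s[keep]
    a_t <- a_t[keep]
  }

  counts_a <- dye_count_series(a_t, a_s, start = s0, nf = nf, dt = dt)
  trace_a <- sm_trace(emit_intensity(counts_a, config), dt,
                      trace_id = "pair_A", channel = "A")
  present_b <- if (is.na(t_b)) nf else min(floor(t_b / dt), nf)
  counts_b <- c(rep(1L, present_b), rep(0L, nf - present_b))
  trace_b <- sm_trace(emit_intensity(counts_b, config), dt,
                      trace_id = "pair_B", channel = "B")
  truth <- ground_truth(event_times = a_t, event_sizes = a_s,
                        dye_counts = counts_a,
                        censored = is.na(t_b),
                        class = class, rna_time = t_b, start_size = s0,
                        dye_counts_b = counts_b)
  list(trace_a = trace_a, trace_b = trace_b, truth = truth)
}

#' Simulate a set of two-colour pairs
#'
#' In stratified mode the class counts are fixed exactly by largest-remainder
#' apportionment of `config$pathway_probs` over `n` (so the default
#' probabilities give exactly 14/31/27 for n = 72), and the class sequence is
#' shuffled; otherwise each pair draws its class independently.
#'
#' @param config A TWO_COLOR [sim_config()]; its seed seeds the whole set.
#' @param n Number of pairs.
#' @param stratified Logical; exact class counts (default `FALSE`).
#' @return List with `pairs` (list of [simulate_two_color_pair()] results)
#'   and `classes` (character vector of true classes).
#' @export
simulate_two_color_pairs <- function(config, n, stratified = FALSE) {
  validate_sim_config(config)
  check_weights(config$pathway_probs, "pathway_probs")
  maybe_seed(config)
  config <- strip_seed(config)
  if (stratified) {
    classes <- rep(PATHWAY_CLASSES, apportion_counts(config$pathway_probs, n))
    classes <- sample(classes)
  } else {
    classes <- sample(PATHWAY_CLASSES, n, replace = TRUE,
                      prob = config$pathway_probs)
  }
  pairs <- lapply(seq_len(n), function(i) {
    p <- simulate_two_color_pair(config, class = classes[i])
    p$trace_a$trace_id <- sprintf("pair_%03d_A", i)
    p$trace_b$trace_id <- sprintf("pair_%03d_B", i)
    p
  })
  list(pairs = pairs, classes = classes)
}

# Largest-remainder (Hamilton) apportionment of n among categorical weights;
# always sums to n exactly.
apportion_counts <- function(probs, n) {
  quota <- probs * n
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
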