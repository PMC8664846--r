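# Single-fluorophore calibration and molecule counting.

#' Calibrate the single-fluorophore intensity unit from bleaching steps
#'
#' Summarizes the absolute magnitudes of photobleaching loss steps with a
#' single Gaussian. The default method fits a Gaussian curve to the
#' Freedman-Diaconis histogram of the magnitudes by least squares — the way
#' calibration step histograms are fitted in practice, and robust to a
#' right tail of unresolved double steps because the fit follows the mode.
#' `method = "moments"` returns the sample mean and (maximum-likelihood)
#' SD instead.
#'
#' @param steps Step-event data frame (see [extract_steps()]).
#' @param loss_only Use only loss steps (default); otherwise all steps by
#'   absolute magnitude.
#' @param trim If `TRUE`, discard magnitudes outside median +/- 2.5 MAD
#'   before fitting; robust against occasional double (two-dye) steps.
#' @param method `"hist_lsq"` (default) or `"moments"`.
#' @param min_steps Minimum number of usable steps (default 30).
#' @return A `gaussian_fit`: list with `mean`, `sd`, `se` (standard error
#'   of the mean), `n`, `r_squared`, `method`.
#' @export
fit_single_dye <- function(steps, loss_only = TRUE, trim = FALSE,
                           method = c("hist_lsq", "moments"),
                           min_steps = 30L) {
  method <- match.arg(method)
  mags <- abs(steps$delta[if (loss_only) steps$direction == "loss"
                          else rep(TRUE, nrow(steps))])
  if (trim && length(mags)) {
    med <- stats::median(mags)
    s <- stats::mad(mags)
    if (s == 0) {
      mags <- mags[mags == med]
    } else {
      mags <- mags[abs(mags - med) <= 2.5 * s]
    }
  }
  n <- length(mags)
  if (n < min_steps)
    stop(sprintf("insufficient data: %d steps (need >= %d)", n, min_steps),
         call. = FALSE)
  m <- mean(mags)
  s <- stats::sd(mags) * sqrt((n - 1) / n)   # MLE sd
  if (s == 0) {
    return(structure(list(mean = m, sd = 0, se = 0, n = n, r_squared = 1,
                          method = method), class = "gaussian_fit"))
  }
  hist_fit <- hist_gaussian_fit(mags, stats::median(mags),
                                max(stats::mad(mags), s / 2))
  if (method == "hist_lsq" && !is.null(hist_fit)) {
    return(structure(list(mean = hist_fit$mu, sd = hist_fit$sg,
                          se = hist_fit$mu_se, n = n,
                          r_squared = hist_fit$r2, method = "hist_lsq"),
                     class = "gaussian_fit"))
  }
  structure(list(mean = m, sd = s, se = s / sqrt(n), n = n,
                 r_squared = if (is.null(hist_fit)) NA_real_ else
                   hist_fit$r2,
                 method = "moments"),
            class = "gaussian_fit")
}

# Least-squares Gaussian curve fit to the Freedman-Diaconis histogram of x,
# seeded at (m, s); NULL when the histogram is too coarse or the fit fails.
hist_gaussian_fit <- function(x, m, s) {
  hh <- graphics::hist(x, breaks = "FD", plot = FALSE)
  xs <- hh$mids
  ys <- hh$counts
  if (length(xs) < 4) return(NULL)
  fit <- tryCatch(
    minpack.lm::nlsLM(ys ~ A * exp(-(xs - mu)^2 / (2 * sg^2)),
                      start = list(A = max(ys), mu = m, sg = s),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- summary(fit)$coefficients
  list(mu = unname(cf["mu", "Estimate"]),
       mu_se = unname(cf["mu", "Std. Error"]),
       sg = abs(unname(cf["sg", "Estimate"])),
       r2 = 1 - sum(stats::residuals(fit)^2) / sum((ys - mean(ys))^2))
}

#' Convert an intensity to an integer molecule count
#'
#' Divides the measured intensity by the calibrated single-fluorophore mean
#' and rounds to the nearest integer (half away from zero), floored at zero.
#' `rounding = "floor"` gives the truncating alternative.
#'
#' @param intensity Numeric vector of intensities (camera counts).
#' @param unit A `gaussian_fit` from [fit_single_dye()] (or any list with a
#'   positive `mean`).
#' @param rounding `"nearest"` (default) or `"floor"`.
#' @return Integer vector of molecule counts (>= 0). Monotone non-decreasing
#'   in `intensity`.
#' @export
#' @examples
#' unit <- list(mean = 178.2)
#' count_molecules(356.4, unit)  # 2
#' count_molecules(430, unit)    # 2 (ratio 2.413 rounds down)
count_molecules <- function(intensity, unit, rounding = c("nearest",
                                                          "floor")) {
  rounding <- match.arg(rounding)
  if (!is.numeric(unit$mean) || unit$mean <= 0)
    stop("unit mean must be positive", call. = FALSE)
  ratio <- intensity / unit$mean
  n <- if (rounding == "nearest") floor(ratio + 0.5) else floor(ratio)
  as.integer(pmax(n, 0))
}

#' Distribution of molecule counts per step event
#'
#' Converts each event's intensity delta to a molecule count and summarizes
#' the integer histogram with a single-Gaussian fit, reporting the fitted
#' mean and its standard error (the "2.13 +/- 0.17"-style summary).
#' `fit_method = "lsq"` (default) fits the histogram by binned least
#' squares; `"moments"` reports the moment mean/SE of the counts instead.
#'
#' @param events Step-event data frame.
#' @param unit Calibrated `gaussian_fit`.
#' @param direction `"gain"` or `"loss"`.
#' @param fit_method `"lsq"` or `"moments"`.
#' @param min_events Minimum number of events of the requested direction.
#' @return A `count_distribution`: list with `histogram` (named integer
#'   table), `mean`, `se`, `r_squared`, `n`.
#' @export
event_size_distribution <- function(events, unit,
                                    direction = c("gain", "loss"),
                                    fit_method = c("lsq", "moments"),
                                    min_events = 10L) {
  direction <- match.arg(direction)
  fit_method <- match.arg(fit_method)
  sel <- events$direction == direction
  if (sum(sel) < min_events)
    stop(sprintf("insufficient data: %d %s events (need >= %d)",
                 sum(sel), direction, min_events), call. = FALSE)
  counts <- count_molecules(abs(events$delta[sel]), unit)
  count_summary(counts, fit_method)
}

count_summary <- function(counts, fit_method = "lsq") {
  tab <- table(factor(counts, levels = min(counts):max(counts)))
  n <- length(counts)
  if (length(unique(counts)) == 1L) {
    return(structure(list(histogram = tab, mean = counts[1], se = 0,
                          r_squared = 1, n = n),
                     class = "count_distribution"))
  }
  m0 <- mean(counts)
  s0 <- stats::sd(counts)
  if (fit_method == "moments" || length(tab) < 3) {
    return(structure(list(histogram = tab, mean = m0, se = s0 / sqrt(n),
                          r_squared = NA_real_, n = n),
                     class = "count_distribution"))
  }
  xs <- as.numeric(names(tab))
  ys <- as.numeric(tab)
  fit <- tryCatch(
    minpack.lm::nlsLM(ys ~ A * exp(-(xs - mu)^2 / (2 * sg^2)),
                      start = list(A = max(ys), mu = m0, sg = max(s0, 0.3)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(histogram = tab, mean = m0, se = s0 / sqrt(n),
                          r_squared = NA_real_, n = n),
                     class = "count_distribution"))
  }
  cf <- summary(fit)$coefficients
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ys - mean(ys))^2)
  structure(list(histogram = tab, mean = unname(cf["mu", "Estimate"]),
                 se = unname(cf["mu", "Std. Error"]), r_squared = r2, n = n),
            class = "count_distribution")
}

#' Oligomer-size distribution over spots
#'
#' Counts the molecules on each spot from the initial idealized level of its
#' trace (the pre-bleaching level in immobilized-molecule movies) and
#' summarizes the histogram as in [event_size_distribution()].
#'
#' @param traces List of [sm_trace()], or a list of `ideal_trace` objects if
#'   idealization has been run already.
#' @param unit Calibrated `gaussian_fit`.
#' @param max_states Passed to [idealize_trace()] when raw traces are given.
#' @param config Idealization settings for raw traces.
#' @param fit_method See [event_size_distribution()].
#' @return A `count_distribution` over spots.
#' @export
spot_stoichiometry <- function(traces, unit, max_states = 12L,
                               config = idealize_config(),
                               fit_method = c("lsq", "moments")) {
  fit_method <- match.arg(fit_method)
  if (!length(traces)) stop("insufficient data: no traces", call. = FALSE)
  levels0 <- vapply(traces, function(tr) {
    ideal <- if (inherits(tr, "ideal_trace")) tr
             else idealize_trace(tr, max_states = max_states, config = config)
    ideal$segments$level[1]
  }, numeric(1))
  counts <- count_molecules(levels0, unit)
  count_summary(counts, fit_method)
}
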