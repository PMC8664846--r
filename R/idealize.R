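# Trace idealization: piecewise-constant segmentation via a Gaussian-emission
# hidden Markov model with shared emission variance and a sticky transition
# prior, with the state count selected by BIC.

#' Idealization settings
#'
#' @param n_restarts EM restarts per state count (k-means++-seeded; the best
#'   final likelihood wins).
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @param self_prior Sticky self-transition prior probability.
#' @param prior_strength Pseudo-observations backing the transition prior.
#' @param seed Seed for the restart initializations (makes the fit
#'   deterministic).
#' @param bic_patience Stop scanning state counts after this many consecutive
#'   BIC increases.
#' @param loss_only If `TRUE`, Viterbi decoding only allows transitions to
#'   states with equal or lower mean (photobleaching movies are monotone).
#' @param emission_var `"per_state"` (default) fits one emission SD per
#'   state, appropriate when noise grows with the number of active
#'   fluorophores; `"shared"` fits a single SD across states.
#' @return A list of settings for [idealize_trace()].
#' @export
idealize_config <- function(n_restarts = 10L, max_iter = 100L, tol = 1e-6,
                            self_prior = 0.99, prior_strength = 50,
                            seed = 1L, bic_patience = 2L, loss_only = FALSE,
                            emission_var = c("per_state", "shared")) {
  emission_var <- match.arg(emission_var)
  list(n_restarts = n_restarts, max_iter = max_iter, tol = tol,
       self_prior = self_prior, prior_strength = prior_strength,
       seed = seed, bic_patience = bic_patience, loss_only = loss_only,
       emission_var = emission_var)
}

#' Idealize an intensity trace with a hidden Markov model
#'
#' Fits HMMs with k = 1..`max_states` states (Gaussian emissions; per-state
#' or shared SD, see [idealize_config()]; sticky transition prior), selects
#' k by BIC (ties broken toward fewer states), and returns the Viterbi
#' segmentation. Segment levels are the means of the frames in each segment
#' (time-contiguous averages, robust to emission overlap between adjacent
#' states). The fit is deterministic given `config$seed`.
#'
#' @param trace An [sm_trace()] (length >= 2, finite values).
#' @param max_states Maximum number of states to consider (>= 1). The
#'   default 12 spans the 2-10 oligomers seen in colocalized spots plus the
#'   empty level.
#' @param config An [idealize_config()].
#' @return An `ideal_trace`: list with `segments` (data frame of
#'   `start_frame` inclusive, `end_frame` exclusive, 0-based; `level`),
#'   `n_states` (distinct states used), `log_likelihood`, `sigma`,
#'   `trace_id`, `frame_interval`.
#' @export
#' @examples
#' tr <- sm_trace(c(rep(400, 40), rep(0, 40)) + rnorm(80, 0, 20), 0.1)
#' idealize_trace(tr, max_states = 3)
idealize_trace <- function(trace, max_states = 12L,
                           config = idealize_config()) {
  stopifnot(inherits(trace, "sm_trace"))
  y <- trace$values
  if (!all(is.finite(y))) stop("non-finite trace values", call. = FALSE)
  if (max_states < 1L) stop("max_states must be >= 1", call. = FALSE)
  T_ <- length(y)

  if (stats::sd(y) == 0) {
    return(new_ideal_trace(
      data.frame(start_frame = 0L, end_frame = T_, level = y[1]),
      n_states = 1L, log_likelihood = 0, sigma = 0, trace = trace))
  }

  sigma_floor <- max(1e-8, 1e-4 * diff(range(y)))
  shared <- config$emission_var == "shared"
  n_unique <- length(unique(y))
  best <- NULL
  best_bic <- Inf
  worse_run <- 0L
  for (k in seq_len(min(max_states, n_unique))) {
    fit_k <- NULL
    for (r in seq_len(config$n_restarts)) {
      mu0 <- kmeanspp_centers(y, k, seed = config$seed + 1000L * k + r)
      sigma0 <- pmax(init_sigma(y, mu0, per_state = !shared), sigma_floor)
      f <- hmm_em_cpp(y, mu0, sigma0, shared, config$self_prior,
                      config$prior_strength, config$max_iter, config$tol,
                      sigma_floor)
      if (is.null(fit_k) || f$loglik > fit_k$loglik) fit_k <- f
      if (k == 1L) break              # single state has a closed form
    }
    # free parameters: means, SD(s), initial distribution, plus one for the
    # overall switching rate (the transition matrix itself is pinned to the
    # sticky kernel by its prior, so its entries are not free parameters)
    p <- k + (if (shared) 1 else k) + (k - 1) + 1
    bic <- -2 * fit_k$loglik + p * log(T_)
    if (bic < best_bic - 1e-9) {          # ties go to fewer states
      best_bic <- bic
      best <- c(fit_k, list(k = k))
      worse_run <- 0L
    } else {
      worse_run <- worse_run + 1L
      if (worse_run >= config$bic_patience) break
    }
  }

  A <- best$A
  if (config$loss_only && best$k > 1) {
    # forbid transitions toward brighter states, renormalize rows
    for (j in seq_len(best$k)) {
      up <- best$mu > best$mu[j] + 1e-12
      A[j, up] <- 1e-300
      A[j, ] <- A[j, ] / sum(A[j, ])
    }
  }
  path <- hmm_viterbi_cpp(y, best$mu, best$sigma, A, best$pi)
  segs <- path_to_segments(path, best$mu)
  # Levels are re-estimated as per-segment frame means: segment membership
  # is contiguous in time, so unlike the value-based EM state means the
  # segment means do not suffer tail-truncation bias when adjacent emission
  # distributions overlap.
  segs$level <- vapply(seq_len(nrow(segs)), function(i) {
    mean(y[(segs$start_frame[i] + 1):segs$end_frame[i]])
  }, numeric(1))
  if (nrow(segs) > 1) {
    segs <- path_to_segments(rep(seq_len(nrow(segs)),
                                 segs$end_frame - segs$start_frame),
                             segs$level)
  }
  new_ideal_trace(segs, n_states = length(unique(path)),
                  log_likelihood = best$loglik, sigma = best$sigma,
                  trace = trace)
}

new_ideal_trace <- function(segments, n_states, log_likelihood, sigma,
                            trace) {
  structure(list(segments = segments, n_states = n_states,
                 log_likelihood = log_likelihood, sigma = sigma,
                 trace_id = trace$trace_id,
                 frame_interval = trace$frame_interval,
                 n_frames = length(trace$values)),
            class = "ideal_trace")
}

# 1-D k-means++ seeding followed by a few Lloyd iterations.
kmeanspp_centers <- function(y, k, seed) {
  set.seed(seed)
  centers <- numeric(k)
  centers[1] <- y[sample.int(length(y), 1)]
  if (k > 1) {
    for (j in 2:k) {
      d2 <- vapply(y, function(v) min((v - centers[1:(j - 1)])^2), numeric(1))
      if (sum(d2) == 0) {
        centers[j] <- y[sample.int(length(y), 1)]
      } else {
        centers[j] <- y[sample.int(length(y), 1, prob = d2)]
      }
    }
  }
  for (it in 1:5) {
    assign <- apply(outer(y, centers, function(a, b) (a - b)^2), 1,
                    which.min)
    for (j in seq_len(k))
      if (any(assign == j)) centers[j] <- mean(y[assign == j])
  }
  sort(centers)
}

init_sigma <- function(y, centers, per_state = TRUE) {
  assign <- apply(outer(y, centers, function(a, b) (a - b)^2), 1, which.min)
  pooled <- sqrt(mean((y - centers[assign])^2))
  if (!per_state) return(pooled)
  vapply(seq_along(centers), function(j) {
    v <- y[assign == j]
    if (length(v) > 2) sqrt(mean((v - centers[j])^2)) else pooled
  }, numeric(1))
}

# Collapse a Viterbi state path into contiguous segments; merge neighbours
# whose levels coincide numerically so adjacent segment levels always differ.
path_to_segments <- function(path, mu) {
  r <- rle(path)
  ends <- cumsum(r$lengths)
  segs <- data.frame(start_frame = c(0L, ends[-length(ends)]),
                     end_frame = ends,
                     level = mu[r$values])
  if (nrow(segs) > 1) {
    keep <- c(TRUE, abs(diff(segs$level)) > 1e-9)
    if (!all(keep)) {
      grp <- cumsum(keep)
      segs <- do.call(rbind, lapply(split(segs, grp), function(g) {
        data.frame(start_frame = g$start_frame[1],
                   end_frame = g$end_frame[nrow(g)], level = g$level[1])
      }))
      rownames(segs) <- NULL
    }
  }
  segs
}

#' Convert an idealized trace into step events
#'
#' Emits one event per adjacent-segment boundary; the event time is the first
#' frame of the new level times the frame interval, and the sum of all deltas
#' equals the last level minus the first level exactly.
#'
#' @param ideal An `ideal_trace` from [idealize_trace()] or
#'   [idealize_oracle()].
#' @param frame_interval Seconds per frame; defaults to the value stored on
#'   the idealized trace.
#' @return Data frame with columns `trace_id`, `time` (s), `frame` (0-based
#'   boundary frame), `delta`, `from_level`, `to_level`, `direction`
#'   (`"gain"`/`"loss"`). A single-segment trace gives zero rows.
#' @export
extract_steps <- function(ideal, frame_interval = ideal$frame_interval) {
  stopifnot(inherits(ideal, "ideal_trace"))
  segs <- ideal$segments
  n <- nrow(segs)
  if (n < 2) return(empty_steps())
  delta <- diff(segs$level)
  data.frame(trace_id = ideal$trace_id,
             time = segs$start_frame[-1] * frame_interval,
             frame = segs$start_frame[-1],
             delta = delta,
             from_level = segs$level[-n],
             to_level = segs$level[-1],
             direction = ifelse(delta > 0, "gain", "loss"),
             stringsAsFactors = FALSE)
}

#' Exhaustive segmentation oracle for short traces
#'
#' Enumerates every segmentation of the trace into at most `n_states`
#' segments (changepoint placements), assigns each segment its mean as the
#' level, and returns the segmentation maximizing the shared-SD Gaussian
#' log-likelihood (see [segmentation_loglik()]). Intended as an independent
#' test oracle for [idealize_trace()]; limited to traces of <= 50 frames and
#' <= 3 states.
#'
#' @param trace An [sm_trace()] of at most 50 frames.
#' @param n_states Maximum number of segments (1-3).
#' @return An `ideal_trace`.
#' @export
idealize_oracle <- function(trace, n_states) {
  stopifnot(inherits(trace, "sm_trace"))
  y <- trace$values
  T_ <- length(y)
  if (T_ > 50L) stop("oracle limited to traces of <= 50 frames",
                     call. = FALSE)
  if (n_states > 3L || n_states < 1L)
    stop("oracle limited to 1-3 states", call. = FALSE)

  best_cp <- integer()
  best_ll <- segmentation_loglik(y, integer())
  if (n_states > 1) {
    for (m in 1:(n_states - 1)) {
      cps <- utils::combn(T_ - 1L, m)
      for (j in seq_len(ncol(cps))) {
        ll <- segmentation_loglik(y, cps[, j])
        if (ll > best_ll + 1e-12) {
          best_ll <- ll
          best_cp <- cps[, j]
        }
      }
    }
  }
  bounds <- c(0L, best_cp, T_)
  segs <- data.frame(
    start_frame = bounds[-length(bounds)],
    end_frame = bounds[-1],
    level = vapply(seq_len(length(bounds) - 1), function(i) {
      mean(y[(bounds[i] + 1):bounds[i + 1]])
    }, numeric(1)))
  # merge equal-level neighbours for invariant consistency
  segs <- path_to_segments(rep(seq_len(nrow(segs)),
                               segs$end_frame - segs$start_frame),
                           segs$level)
  new_ideal_trace(segs, n_states = nrow(segs), log_likelihood = best_ll,
                  sigma = sqrt(seg_rss(y, best_cp) / T_), trace = trace)
}

#' Gaussian log-likelihood of a segmentation
#'
#' Scores a changepoint placement by the log-likelihood of the trace under
#' per-segment mean levels and the shared maximum-likelihood SD
#' (`sqrt(RSS / T)`). This is the common scale on which the exhaustive
#' oracle and the HMM segmentation are compared.
#'
#' @param y Numeric vector, or an [sm_trace()].
#' @param changepoints Integer vector of boundary frames (an event at
#'   changepoint c means frames 1..c and c+1.. belong to different
#'   segments); empty for a single segment.
#' @return Log-likelihood (a degenerate zero-RSS segmentation gets a large
#'   finite value via an SD floor).
#' @export
segmentation_loglik <- function(y, changepoints) {
  if (inherits(y, "sm_trace")) y <- y$values
  T_ <- length(y)
  rss <- seg_rss(y, changepoints)
  sigma <- max(sqrt(rss / T_), 1e-8)
  -T_ / 2 * log(2 * pi) - T_ * log(sigma) - rss / (2 * sigma^2)
}

seg_rss <- function(y, changepoints) {
  bounds <- c(0L, sort(as.integer(changepoints)), length(y))
  rss <- 0
  for (i in seq_len(length(bounds) - 1)) {
    seg <- y[(bounds[i] + 1):bounds[i + 1]]
    rss <- rss + sum((seg - mean(seg))^2)
  }
  rss
}

# Boundary frames (counts, not 0-based indices) of an ideal_trace: frame f
# means the changepoint sits between frames f and f+1 (1-based).
ideal_changepoints <- function(ideal) {
  segs <- ideal$segments
  if (nrow(segs) < 2) return(integer())
  as.integer(segs$end_frame[-nrow(segs)])
}
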