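# Spot detection and trace extraction on image stacks.
#
# Coordinates follow the simulator convention: 0-based pixel indices, spot
# centre at (x, y), analysis ROI the half-open square
# [x - h, x + h) x [y - h, y + h) with h = roi_halfwidth (default 4 px,
# giving the 8 x 8 px ROI of the assay).

#' Detect fluorescent spots in a single frame
#'
#' Finds local maxima whose prominence over the local background (median of
#' the 1-px border ring around the ROI) exceeds `tolerance`, then applies
#' non-maximum suppression so that no two detections lie within
#' `2 * roi_halfwidth` pixels (Chebyshev distance), keeping the brighter one.
#' Spots whose ROI (including the ring) would leave the image are discarded.
#'
#' The tolerance is a prominence threshold in camera counts on the peak
#' pixel; a sensible default for simulated stacks is about five times the
#' read-noise SD.
#'
#' @param frame 2-D numeric matrix (one image frame, rows = y).
#' @param tolerance Positive prominence threshold (camera counts).
#' @param roi_halfwidth ROI half-width in pixels (>= 1).
#' @return Data frame with columns `x`, `y` (0-based), `peak`, `prominence`,
#'   ordered by (y, x).
#' @export
detect_spots <- function(frame, tolerance, roi_halfwidth = 4L) {
  if (!is.matrix(frame)) stop("frame must be a 2-D matrix", call. = FALSE)
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("tolerance must be positive", call. = FALSE)
  h <- as.integer(roi_halfwidth)
  if (h < 1L) stop("roi_halfwidth must be >= 1", call. = FALSE)
  nr <- nrow(frame)
  nc <- ncol(frame)
  if (nr < 2 * h + 3 || nc < 2 * h + 3)
    stop("image smaller than the ROI", call. = FALSE)

  # strict local maxima over the 8-neighbourhood, away from the border
  inner_r <- (h + 2):(nr - h - 1)   # 1-based rows where ROI + ring fit
  inner_c <- (h + 2):(nc - h - 1)
  cand <- NULL
  core <- frame[inner_r, inner_c]
  is_max <- rep(TRUE, length(core))
  dim(is_max) <- dim(core)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    shifted <- frame[inner_r + dy, inner_c + dx]
    is_max <- is_max & (core >= shifted)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(x = integer(), y = integer(), peak = numeric(),
                      prominence = numeric()))
  rows <- inner_r[idx[, 1]]
  cols <- inner_c[idx[, 2]]

  prom <- vapply(seq_along(rows), function(i) {
    frame[rows[i], cols[i]] -
      ring_median(frame, cols[i] - 1L, rows[i] - 1L, h)
  }, numeric(1))
  keep <- prom > tolerance
  if (!any(keep))
    return(data.frame(x = integer(), y = integer(), peak = numeric(),
                      prominence = numeric()))
  rows <- rows[keep]
  cols <- cols[keep]
  prom <- prom[keep]
  peak <- frame[cbind(rows, cols)]

  # non-maximum suppression, brightest first
  ord <- order(peak, decreasing = TRUE)
  sel <- logical(length(ord))
  for (i in ord) {
    if (any(sel & pmax(abs(rows - rows[i]), abs(cols - cols[i])) < 2 * h))
      next
    sel[i] <- TRUE
  }
  out <- data.frame(x = cols[sel] - 1L, y = rows[sel] - 1L,
                    peak = peak[sel], prominence = prom[sel])
  out[order(out$y, out$x), , drop = FALSE]
}

# Median of the 1-px border ring around the ROI centred at 0-based (x, y).
ring_median <- function(frame, x, y, h) {
  r0 <- y - h       # 0-based inclusive ring bounds
  r1 <- y + h
  c0 <- x - h
  c1 <- x + h
  ring <- c(frame[r0 + 1, (c0:c1) + 1], frame[r1 + 1, (c0:c1) + 1],
            frame[((r0 + 1):(r1 - 1)) + 1, c0 + 1],
            frame[((r0 + 1):(r1 - 1)) + 1, c1 + 1])
  stats::median(ring)
}

#' Extract a background-corrected intensity trace at a spot
#'
#' Per frame, the trace value is the sum over the 8 x 8 ROI minus the local
#' background estimate (median of the 1-px border ring around the ROI) times
#' the ROI area.
#'
#' @param stack Numeric array `height x width x n_frames`.
#' @param spot One row of [detect_spots()] output, or any list/data frame
#'   with 0-based `x`, `y`.
#' @param frame_interval Frame interval in seconds.
#' @param roi_halfwidth ROI half-width in pixels.
#' @param trace_id,channel Labels for the resulting trace.
#' @return An [sm_trace()] with `origin` set to the spot.
#' @export
extract_trace <- function(stack, spot, frame_interval, roi_halfwidth = 4L,
                          trace_id = "spot", channel = "A") {
  stopifnot(length(dim(stack)) == 3)
  h <- as.integer(roi_halfwidth)
  x <- spot$x
  y <- spot$y
  nr <- dim(stack)[1]
  nc <- dim(stack)[2]
  if (x - h < 1 || y - h < 1 || x + h > nc - 2 || y + h > nr - 2)
    stop("spot ROI (plus background ring) outside image bounds",
         call. = FALSE)
  rows <- (y - h):(y + h - 1) + 1   # ROI rows, 1-based
  cols <- (x - h):(x + h - 1) + 1
  area <- length(rows) * length(cols)
  nf <- dim(stack)[3]
  vals <- vapply(seq_len(nf), function(f) {
    fr <- stack[, , f]
    sum(fr[rows, cols]) - roi_ring_median(fr, rows, cols) * area
  }, numeric(1))
  sm_trace(vals, frame_interval, trace_id = trace_id, channel = channel,
           origin = as.data.frame(spot)[, c("x", "y"), drop = FALSE])
}

# Median of the 1-px ring just outside the given ROI rows/cols (1-based).
roi_ring_median <- function(frame, rows, cols) {
  r0 <- min(rows) - 1
  r1 <- max(rows) + 1
  c0 <- min(cols) - 1
  c1 <- max(cols) + 1
  stats::median(c(frame[r0, c0:c1], frame[r1, c0:c1],
                  frame[rows, c0], frame[rows, c1]))
}

#' Ensemble (field-of-view) intensity time course
#'
#' Computes the per-frame total background-subtracted intensity over a
#' rectangular region (or the summed values of a list of traces) and
#' normalizes it to the first frame.
#'
#' @param x Either a `height x width x n_frames` array or a list of
#'   [sm_trace()] objects of equal length.
#' @param region For arrays: `c(x0, y0, x1, y1)` 0-based inclusive bounds;
#'   `NULL` uses the full frame. The per-frame background is the region's
#'   median pixel value (spots are assumed sparse).
#' @return Numeric vector of relative intensities with the first frame at 1.
#' @export
ensemble_intensity <- function(x, region = NULL) {
  if (is.array(x) && length(dim(x)) == 3) {
    nr <- dim(x)[1]
    nc <- dim(x)[2]
    if (is.null(region)) region <- c(0, 0, nc - 1, nr - 1)
    if (region[1] < 0 || region[2] < 0 || region[3] >= nc || region[4] >= nr)
      stop("region outside image", call. = FALSE)
    cols <- (region[1]:region[3]) + 1
    rows <- (region[2]:region[4]) + 1
    series <- vapply(seq_len(dim(x)[3]), function(f) {
      px <- x[rows, cols, f]
      sum(px) - stats::median(px) * length(px)
    }, numeric(1))
  } else if (is.list(x) && length(x) && inherits(x[[1]], "sm_trace")) {
    series <- rowSums(vapply(x, function(tr) tr$values,
                             numeric(length(x[[1]]$values))))
  } else {
    stop("x must be an image stack or a list of traces", call. = FALSE)
  }
  if (!is.finite(series[1]) || series[1] <= 0)
    stop("cannot normalize: ensemble intensity at t = 0 is not positive",
         call. = FALSE)
  series / series[1]
}
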