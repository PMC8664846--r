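#' Render traces into a synthetic TIRF image stack
#'
#' Places each trace at a fixed (x, y) position and renders every frame as a
#' sum of 2-D Gaussian point-spread functions over a constant background with
#' per-pixel Gaussian read noise. The PSF amplitude is scaled per spot so
#' that the intensity summed over the analysis ROI (a square of side
#' `2 * roi_halfwidth` centred on the spot) equals the trace value, making
#' [extract_trace()] the inverse of rendering up to PSF tail loss.
#'
#' Coordinates are 0-based pixel indices of the spot centre. The default
#' geometry (256 x 256 px at 108 nm/px) corresponds to a 27.648 um field
#' edge.
#'
#' @param traces List of [sm_trace()] objects, all the same length.
#' @param positions Data frame with columns `x`, `y` (0-based pixel centres),
#'   one row per trace.
#' @param config A [sim_config()]; uses `image` geometry and
#'   `read_noise_sd`.
#' @param roi_halfwidth ROI half-width in pixels used for amplitude
#'   normalization (default 4, i.e. the 8 x 8 px analysis ROI).
#' @return Numeric array `height x width x n_frames` (camera counts).
#' @export
render_stack <- function(traces, positions, config, roi_halfwidth = 4L) {
  validate_sim_config(config)
  img <- config$image
  w <- img$width
  h <- img$height
  sigma <- img$psf_sigma_px
  if (sigma <= 0) stop("PSF sigma must be positive", call. = FALSE)
  if (length(traces)) {
    if (nrow(positions) != length(traces))
      stop("positions must have one row per trace", call. = FALSE)
    if (any(positions$x < roi_halfwidth) ||
        any(positions$x >= w - roi_halfwidth) ||
        any(positions$y < roi_halfwidth) ||
        any(positions$y >= h - roi_halfwidth))
      stop("spot ROI falls outside image bounds", call. = FALSE)
    if (nrow(positions) > 1) {
      dmat <- as.matrix(stats::dist(positions[, c("x", "y")]))
      if (any(dmat[upper.tri(dmat)] < 2 * roi_halfwidth))
        warning("spots closer than 2 x ROI: ground truth is ambiguous",
                call. = FALSE)
    }
    nf <- length(traces[[1]]$values)
    if (!all(vapply(traces, function(tr) length(tr$values), 1L) == nf))
      stop("all traces must have the same number of frames", call. = FALSE)
  } else {
    nf <- config$n_frames
  }
  maybe_seed(config)

  stack <- array(img$background, dim = c(h, w, nf))
  support <- roi_halfwidth + 4L  # render PSF a little beyond the ROI
  for (i in seq_along(traces)) {
    x0 <- positions$x[i]
    y0 <- positions$y[i]
    xs <- max(0, floor(x0) - support):min(w - 1, floor(x0) + support)
    ys <- max(0, floor(y0) - support):min(h - 1, floor(y0) + support)
    kern <- outer(exp(-(ys - y0)^2 / (2 * sigma^2)),
                  exp(-(xs - x0)^2 / (2 * sigma^2)))
    in_roi <- outer(ys >= y0 - roi_halfwidth & ys < y0 + roi_halfwidth,
                    xs >= x0 - roi_halfwidth & xs < x0 + roi_halfwidth,
                    FUN = "&")
    kern <- kern / sum(kern[in_roi])   # ROI-summed intensity == trace value
    vals <- traces[[i]]$values
    for (f in seq_len(nf))
      stack[ys + 1, xs + 1, f] <- stack[ys + 1, xs + 1, f] + vals[f] * kern
  }
  if (config$read_noise_sd > 0)
    stack <- stack + array(stats::rnorm(length(stack), 0,
                                        config$read_noise_sd), dim = dim(stack))
  stack
}
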