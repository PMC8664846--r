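# Plain-text / TIFF interchange: trace and step-event CSV, multi-page TIFF
# stacks, YAML configs.

#' Write traces to CSV
#'
#' Long format with columns `trace_id`, `channel`, `frame` (0-based),
#' `time_s`, `intensity`.
#' @param traces List of [sm_trace()].
#' @param path Output file.
#' @export
write_traces_csv <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    data.frame(trace_id = tr$trace_id, channel = tr$channel,
               frame = seq_along(tr$values) - 1L,
               time_s = trace_times(tr), intensity = tr$values,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read traces from CSV
#'
#' Expects the format written by [write_traces_csv()]; the frame interval is
#' inferred from the `time_s` column per trace.
#' @param path CSV file.
#' @return List of [sm_trace()].
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$trace_id), function(g) {
    g <- g[order(g$frame), ]
    dt <- if (nrow(g) > 1) stats::median(diff(g$time_s)) else 1
    sm_trace(g$intensity, dt, trace_id = g$trace_id[1],
             channel = g$channel[1])
  })
}

#' Write step events to CSV
#' @param steps Step-event data frame (possibly row-bound across traces).
#' @param path Output file.
#' @export
write_events_csv <- function(steps, path) {
  utils::write.csv(steps, path, row.names = FALSE)
  invisible(path)
}

#' Read step events from CSV
#' @param path CSV file written by [write_events_csv()].
#' @return Step-event data frame.
#' @export
read_events_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write an image stack as multi-page 16-bit grayscale TIFF
#'
#' Values are rounded and clipped to the 16-bit range.
#' @param stack Numeric array `height x width x n_frames`.
#' @param path Output file.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3)
  pages <- lapply(seq_len(dim(stack)[3]), function(f) {
    pmin(pmax(round(stack[, , f]), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a multi-page TIFF stack
#' @param path TIFF file.
#' @return Numeric array `height x width x n_frames` in camera counts.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

#' Write a simulation config as YAML
#' @param config A [sim_config()].
#' @param path Output file.
#' @export
write_sim_config <- function(config, path) {
  raw <- unclass(config)
  # named numeric vectors serialize as YAML maps so names survive
  if (!is.null(raw$pathway_probs)) raw$pathway_probs <- as.list(raw$pathway_probs)
  raw$size_distribution <- lapply(raw$size_distribution, as.list)
  yaml::write_yaml(raw, path, precision = 15)
  invisible(path)
}

#' Read a simulation config from YAML
#' @param path YAML file written by [write_sim_config()].
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  extra <- raw[setdiff(names(raw), "condition")]
  # YAML loses the name attributes on scalar lists; restore numeric vectors
  for (nm in c("pathway_probs")) {
    if (!is.null(extra[[nm]])) extra[[nm]] <- unlist(extra[[nm]])
  }
  if (!is.null(extra$size_distribution))
    extra$size_distribution <- lapply(extra$size_distribution, unlist)
  do.call(sim_config, c(list(condition = raw$condition), extra))
}
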