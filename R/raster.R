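#' Spike rasters
#'
#' A spike raster records spike times (ms) per source or cell index over a
#' simulation window.  Used both for generated input spike trains and for
#' network output.
#'
#' @param times numeric vector of spike times (ms).
#' @param sources integer vector, same length, of 1-based source indices.
#' @param n_sources total number of sources (may exceed `max(sources)` when
#'   some sources are silent).
#' @param window numeric `c(t0, t1)` (ms) containing all spike times.
#' @return An object of class `spike_raster`.
#' @export
spike_raster <- function(times, sources, n_sources, window) {
  times <- as.numeric(times)
  sources <- as.integer(sources)
  stopifnot(length(times) == length(sources), length(window) == 2,
            window[1] <= window[2], n_sources >= 0)
  if (length(times)) {
    if (any(times < window[1] - 1e-9) || any(times > window[2] + 1e-9))
      stop("spike times outside window")
    if (any(sources < 1L) || any(sources > n_sources))
      stop("source index out of range")
    ord <- order(sources, times)
    times <- times[ord]
    sources <- sources[ord]
    if (any(diff(times)[diff(sources) == 0L] <= 0))
      stop("spike times must be strictly increasing per source")
  }
  structure(list(times = times, sources = sources,
                 n_sources = as.integer(n_sources),
                 window = as.numeric(window)),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("Spike raster: %d spikes from %d sources on [%g, %g] ms\n",
              length(x$times), x$n_sources, x$window[1], x$window[2]))
  invisible(x)
}

#' @export
plot.spike_raster <- function(x, pch = ".", cex = 2, ...) {
  plot(x$times, x$sources, pch = pch, cex = cex, xlab = "time (ms)",
       ylab = "source", xlim = x$window, ylim = c(0.5, x$n_sources + 0.5),
       ...)
  invisible(x)
}

#' @export
as.data.frame.spike_raster <- function(x, ...) {
  data.frame(source_id = x$sources, time_ms = x$times)
}

#' Count spikes in a raster
#'
#' @param raster a [spike_raster()].
#' @param window optional `c(t0, t1)` restriction (ms).
#' @return Total spike count (all sources).
#' @export
spike_count <- function(raster, window = raster$window) {
  sum(raster$times >= window[1] & raster$times < window[2])
}

#' Restrict a raster to a sub-window or subset of sources
#'
#' @param raster a [spike_raster()].
#' @param window `c(t0, t1)` (ms).
#' @param sources optional integer vector of source indices to keep
#'   (renumbered 1..k in order given).
#' @return A [spike_raster()].
#' @export
raster_subset <- function(raster, window = raster$window, sources = NULL) {
  keep <- raster$times >= window[1] & raster$times <= window[2]
  times <- raster$times[keep]
  src <- raster$sources[keep]
  if (!is.null(sources)) {
    sources <- as.integer(sources)
    keep2 <- src %in% sources
    times <- times[keep2]
    src <- match(src[keep2], sources)
    n <- length(sources)
  } else {
    n <- raster$n_sources
  }
  spike_raster(times, src, n_sources = n, window = window)
}

#' Read and write rasters as two-column CSV (source_id, time_ms)
#'
#' @param raster a [spike_raster()].
#' @param path file path.
#' @export
write_raster_csv <- function(raster, path) {
  utils::write.csv(as.data.frame(raster), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @param n_sources,window raster geometry (not stored in the CSV).
#' @export
read_raster_csv <- function(path, n_sources = NULL, window = NULL) {
  d <- utils::read.csv(path)
  if (is.null(n_sources)) n_sources <- if (nrow(d)) max(d$source_id) else 0L
  if (is.null(window)) window <- c(0, if (nrow(d)) max(d$time_ms) else 0)
  spike_raster(d$time_ms, d$source_id, n_sources = n_sources,
               window = window)
}
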