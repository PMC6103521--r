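#' Instantaneous population firing rate by Gaussian kernel regression
#'
#' The iFR is the sum of unit-mass Gaussian kernels centred on all population
#' spike times, divided by the population size: units are spikes/s per cell.
#' A 6 ms kernel is conventional for visualization and a 2 ms kernel for
#' spectral analysis.  "Kernel width" is interpreted as the Gaussian standard
#' deviation (set `width_is_fwhm = TRUE` for the full-width-half-maximum
#' convention).
#'
#' @param raster a [spike_raster()] of population spikes.
#' @param n_cells population size (must be positive; the raster's source
#'   count is used when omitted).
#' @param sigma kernel width (ms).
#' @param window `c(t0, t1)` (ms) over which to evaluate the trace.
#' @param dt_out output sampling step (ms); 1 ms gives the 1 kHz sampling
#'   assumed by [population_frequency()].
#' @param width_is_fwhm if `TRUE`, `sigma` is a full width at half maximum
#'   and is converted to a standard deviation.
#' @param label population label carried through to summaries.
#' @return An object of class `ifr_trace` with fields `t` (ms), `rate`
#'   (spikes/s per cell), `sigma`, `n_cells`, `label`.
#' @export
compute_ifr <- function(raster, n_cells = raster$n_sources, sigma = 6,
                        window = raster$window, dt_out = 1,
                        width_is_fwhm = FALSE, label = "pop") {
  stopifnot(inherits(raster, "spike_raster"), sigma > 0, dt_out > 0)
  if (n_cells < 1) stop("population size must be positive")
  if (width_is_fwhm) sigma <- sigma / (2 * sqrt(2 * log(2)))
  tg <- seq(window[1], window[2], by = dt_out)
  keep <- raster$times >= window[1] - 6 * sigma &
    raster$times <= window[2] + 6 * sigma
  st <- raster$times[keep]
  if (length(st) == 0) {
    rate <- numeric(length(tg))
  } else {
    d <- stats::density(st, bw = sigma, from = window[1], to = window[2],
                        n = length(tg))
    # density() integrates to 1 over all spikes; rescale to a sum of
    # unit-mass kernels (per ms), then to spikes/s and per cell
    rate <- d$y * length(st) * 1000 / n_cells
  }
  structure(list(t = tg, rate = rate, sigma = sigma,
                 n_cells = as.integer(n_cells), label = label),
            class = "ifr_trace")
}

#' @export
print.ifr_trace <- function(x, ...) {
  cat(sprintf(
    "iFR trace '%s': %d cells, kernel sd %g ms, [%g, %g] ms, mean %.2f sp/s\n",
    x$label, x$n_cells, x$sigma, min(x$t), max(x$t), mean(x$rate)))
  invisible(x)
}

#' @export
plot.ifr_trace <- function(x, ...) {
  plot(x$t, x$rate, type = "l", xlab = "time (ms)",
       ylab = "iFR (sp/s per cell)", ...)
  invisible(x)
}

#' @export
as.data.frame.ifr_trace <- function(x, ...) {
  data.frame(time_ms = x$t, ifr = x$rate)
}

#' Time-averaged population firing rate
#'
#' Averages an iFR trace over the analysis window; up to kernel edge effects
#' this equals spike count / (population size x window length).
#'
#' @param ifr an `ifr_trace` from [compute_ifr()].
#' @param window `c(t0, t1)` (ms); defaults to the whole trace.
#' @return Mean rate (spikes/s per cell).
#' @export
mean_rate <- function(ifr, window = range(ifr$t)) {
  stopifnot(inherits(ifr, "ifr_trace"))
  keep <- ifr$t >= window[1] & ifr$t <= window[2]
  if (!any(keep)) stop("window outside trace")
  mean(ifr$rate[keep])
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: Hann-windowed segments of `seg_len`
#' samples with fractional `overlap`, mean removed per segment.  When the
#' series is shorter than `seg_len` a single full-length segment is used.
#'
#' @param x numeric series.
#' @param fs sampling frequency (Hz).
#' @param seg_len segment length in samples (1024 at 1 kHz gives ~1 Hz
#'   resolution).
#' @param overlap fractional overlap between segments.
#' @return A data.frame with columns `freq` (Hz) and `power`, with the
#'   segment metadata in attributes.
#' @export
welch_psd <- function(x, fs = 1000, seg_len = 1024, overlap = 0.5) {
  n <- length(x)
  seg <- min(seg_len, n)
  step <- max(1, floor(seg * (1 - overlap)))
  starts <- seq(1, n - seg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg - 1) / (seg - 1))  # Hann
  norm <- sum(w^2) * fs
  nf <- floor(seg / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg_x <- x[s:(s + seg - 1)]
    seg_x <- (seg_x - mean(seg_x)) * w
    X <- stats::fft(seg_x)[seq_len(nf)]
    p <- (Mod(X)^2) / norm
    # one-sided: double all bins except DC (and Nyquist when seg is even)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (seg %% 2 == 0) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  out <- data.frame(freq = (seq_len(nf) - 1) * fs / seg,
                    power = acc / length(starts))
  attr(out, "seg_len") <- seg
  attr(out, "overlap") <- overlap
  attr(out, "window") <- "hann"
  attr(out, "n_segments") <- length(starts)
  out
}

#' Population frequency of a network oscillation
#'
#' The dominant frequency of the iFR oscillation: the spectral frequency with
#' peak power in Welch's spectrum of the iFR, searched within `band`.  Ties
#' are broken toward the lower frequency.  Use the 2 ms kernel iFR and a
#' window of at least ~1 s for a stable estimate.
#'
#' @param ifr an `ifr_trace` (2 ms kernel recommended).
#' @param band search band `c(lo, hi)` in Hz.
#' @param seg_len,overlap Welch parameters, see [welch_psd()].
#' @return A list with `f_pop` (Hz, `NA` with a `reason` attribute when no
#'   spiking/flat spectrum) and `spectrum` (the full Welch spectrum, for
#'   nested-oscillation diagnostics).
#' @export
population_frequency <- function(ifr, band = c(5, 100), seg_len = 1024,
                                 overlap = 0.5) {
  stopifnot(inherits(ifr, "ifr_trace"))
  dt <- ifr$t[2] - ifr$t[1]
  fs <- 1000 / dt
  if (all(ifr$rate == 0) || stats::sd(ifr$rate) == 0) {
    f <- NA_real_
    attr(f, "reason") <- "no spiking / flat iFR"
    return(list(f_pop = f, spectrum = NULL))
  }
  spec <- welch_psd(ifr$rate, fs = fs, seg_len = seg_len, overlap = overlap)
  in_band <- spec$freq >= band[1] & spec$freq <= band[2]
  if (!any(in_band) || max(spec$power[in_band]) <= 0) {
    f <- NA_real_
    attr(f, "reason") <- "flat spectrum in search band"
    return(list(f_pop = f, spectrum = spec))
  }
  fb <- spec$freq[in_band]
  pb <- spec$power[in_band]
  list(f_pop = fb[which.max(pb)], spectrum = spec)
}

#' Flag nested-oscillation spectra
#'
#' Strong, low-frequency, low-synchrony periodic drives can produce nested
#' internal oscillations whose spectral peak rivals the driving frequency;
#' such trials are excluded from population-frequency resonance extraction.
#' A trial is flagged when the spectrum has a secondary local peak of at
#' least `ratio` times the primary peak power and the primary peak lies above
#' `factor` times the input frequency.
#'
#' @param spectrum a Welch spectrum from [population_frequency()].
#' @param f_inp driving input frequency (Hz).
#' @param band search band (Hz).
#' @param ratio secondary/primary power threshold.
#' @param factor primary-frequency/input-frequency threshold.
#' @return Logical flag.
#' @export
nested_oscillation_flag <- function(spectrum, f_inp, band = c(5, 100),
                                    ratio = 0.5, factor = 1.5) {
  if (is.null(spectrum)) return(FALSE)
  in_band <- spectrum$freq >= band[1] & spectrum$freq <= band[2]
  f <- spectrum$freq[in_band]
  p <- spectrum$power[in_band]
  if (length(p) < 3 || max(p) <= 0) return(FALSE)
  # local maxima strictly above both neighbours
  i <- which(diff(sign(diff(p))) == -2) + 1L
  if (!length(i)) return(FALSE)
  prim <- i[which.max(p[i])]
  sec <- setdiff(i, prim)
  has_secondary <- length(sec) > 0 && max(p[sec]) >= ratio * p[prim]
  has_secondary && f[prim] > factor * f_inp
}

#' Natural frequency of a network
#'
#' The population frequency elicited by an equal-strength asynchronous drive:
#' runs one trial per seed with a constant-rate Poisson input and reports the
#' median PC-population frequency across seeds.
#'
#' @param spec a network specification (see [control_network()]).
#' @param r_inp asynchronous input rate (spikes/s).
#' @param seeds integer vector of trial seeds.
#' @param duration,onset trial timing (ms); analysis starts 500 ms after
#'   onset.
#' @param dt integration step (ms).
#' @param population which output population's iFR to analyse.
#' @return A list with `f_N` (Hz; `NA` with diagnostic when no rhythm),
#'   per-seed `f_pop`, and the mean PC/IN rates for reference.
#' @export
natural_frequency <- function(spec, r_inp = 1000, seeds = 1:3,
                              duration = 1500, onset = 400, dt = 0.01,
                              population = "PC") {
  fs <- numeric(0)
  rates <- NULL
  for (s in seeds) {
    rp <- rate_program("asynchronous", r_inp = r_inp, onset = onset,
                       duration = duration, dt = dt)
    tr <- run_trial(spec, signal = rp, seed = s, duration = duration,
                    onset = onset, dt = dt)
    m <- trial_measures(tr, population = population)
    fs <- c(fs, m$f_pop)
    rates <- rbind(rates, m$rates)
  }
  ok <- !is.na(fs)
  f_N <- if (any(ok)) stats::median(fs[ok]) else {
    x <- NA_real_
    attr(x, "reason") <- "no natural oscillation detected"
    x
  }
  list(f_N = f_N, f_pop = fs, rates = colMeans(rates))
}
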