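#' Rate programs: deterministic instantaneous-rate trajectories for Poisson inputs
#'
#' A rate program describes the instantaneous rate \eqn{\lambda(t)} (spikes/s)
#' of an inhomogeneous Poisson source population, sampled on the simulation
#' grid.  Four source states are supported:
#'
#' \describe{
#'   \item{`asynchronous`}{constant rate \eqn{\lambda(t) = r_{inp}} after onset.}
#'   \item{`sine`}{sinusoidal rate modulation at frequency `f_inp`.  With
#'     `sine_mean = "matched"` (default) \eqn{\lambda(t) = r_{inp}(1 +
#'     \sin(2\pi f t))}, so the time-averaged rate equals `r_inp` and the drive
#'     is equal-strength to an asynchronous input at the same `r_inp`.  With
#'     `sine_mean = "half"` \eqn{\lambda(t) = r_{inp}(1 + \sin(2\pi f t))/2},
#'     whose time average is `r_inp/2`.  The two conventions differ only by a
#'     factor of two in overall strength; see the methods vignette for why both
#'     are provided.}
#'   \item{`square_fixed_mean`}{periodic rectangular pulses of width
#'     `delta_inp` (ms) at inter-pulse frequency `f_inp` (Hz), with pulse
#'     amplitude \eqn{r_{inp} / (f_{inp} \delta_{inp})} (`delta_inp` in
#'     seconds) so that the time-averaged rate over whole periods is exactly
#'     `r_inp` regardless of `f_inp`.  Smaller `delta_inp` means more
#'     synchronous pulse packets.}
#'   \item{`square_fixed_amplitude`}{rectangular pulses of fixed amplitude
#'     `r_p`; the time-averaged rate then grows as
#'     \eqn{r_p f_{inp} \delta_{inp}} with input frequency.}
#' }
#'
#' The first pulse (and sine phase zero) begins at `onset`; \eqn{\lambda(t) =
#' 0} for `t < onset`.
#'
#' @param kind one of `"asynchronous"`, `"sine"`, `"square_fixed_mean"`,
#'   `"square_fixed_amplitude"`.
#' @param r_inp time-averaged rate in spikes/s (required except for
#'   `square_fixed_amplitude`).
#' @param f_inp modulation frequency (Hz); required for periodic kinds.
#' @param delta_inp pulse width (ms); square kinds only.  The duty cycle
#'   `f_inp * delta_inp / 1000` must not exceed 1.
#' @param r_p pulse amplitude in spikes/s; `square_fixed_amplitude` only.
#' @param onset signal start time (ms).
#' @param duration total program length (ms).
#' @param dt sampling step (ms); must divide `duration`.
#' @param sine_mean `"matched"` or `"half"`; see Details.
#'
#' @return An object of class `rate_program` with the sampled `lambda`
#'   trajectory (spikes/s, one value per `dt` bin, sampled at bin start).
#' @examples
#' rp <- rate_program("square_fixed_mean", r_inp = 1000, f_inp = 25,
#'                    delta_inp = 10, duration = 200)
#' pulse_amplitude(rp)  # 4000 sp/s
#' @export
rate_program <- function(kind = c("asynchronous", "sine", "square_fixed_mean",
                                  "square_fixed_amplitude"),
                         r_inp = NULL, f_inp = NULL, delta_inp = NULL,
                         r_p = NULL, onset = 0, duration = 1000, dt = 0.01,
                         sine_mean = c("matched", "half")) {
  kind <- match.arg(kind)
  sine_mean <- match.arg(sine_mean)
  if (duration <= 0 || dt <= 0)
    stop("duration and dt must be positive")
  n_steps <- round(duration / dt)
  if (abs(n_steps * dt - duration) > 1e-8)
    stop("dt must divide duration")
  if (onset < 0 || onset > duration)
    stop("onset must lie in [0, duration]")

  if (kind != "square_fixed_amplitude") {
    if (is.null(r_inp)) stop("r_inp is required for kind ", kind)
    if (r_inp < 0) stop("r_inp must be nonnegative")
  }
  if (kind != "asynchronous") {
    if (is.null(f_inp) || f_inp <= 0)
      stop("f_inp > 0 is required for periodic kinds")
  }
  if (kind %in% c("square_fixed_mean", "square_fixed_amplitude")) {
    if (is.null(delta_inp) || delta_inp <= 0)
      stop("delta_inp > 0 is required for square kinds")
    if (f_inp * delta_inp / 1000 > 1 + 1e-12)
      stop("duty cycle f_inp * delta_inp exceeds 1")
  }
  if (kind == "square_fixed_amplitude") {
    if (is.null(r_p) || r_p < 0) stop("r_p >= 0 is required")
  }

  t <- (seq_len(n_steps) - 1L) * dt   # bin start times
  ts <- t - onset                     # time since signal onset
  lambda <- numeric(n_steps)
  on <- ts >= 0
  lambda[on] <- switch(kind,
    asynchronous = r_inp,
    sine = {
      base <- 1 + sin(2 * pi * f_inp * ts[on] / 1000)
      if (sine_mean == "matched") r_inp * base else r_inp * base / 2
    },
    square_fixed_mean = {
      amp <- r_inp / (f_inp * delta_inp / 1000)
      period <- 1000 / f_inp
      phase <- ts[on] %% period
      ifelse(phase < delta_inp, amp, 0)
    },
    square_fixed_amplitude = {
      period <- 1000 / f_inp
      phase <- ts[on] %% period
      ifelse(phase < delta_inp, r_p, 0)
    })

  structure(list(kind = kind, r_inp = r_inp, f_inp = f_inp,
                 delta_inp = delta_inp, r_p = r_p, onset = onset,
                 duration = duration, dt = dt, sine_mean = sine_mean,
                 lambda = lambda),
            class = "rate_program")
}

#' Pulse amplitude of a sampled rate program
#'
#' The maximal instantaneous rate of \eqn{\lambda(t)} after signal onset.  For
#' `square_fixed_mean` programs this is the pulse amplitude
#' \eqn{r_{inp}/(f_{inp}\delta_{inp})} implied by holding the time-averaged
#' rate fixed across frequencies.
#'
#' @param rp a [rate_program()].
#' @return Amplitude in spikes/s.
#' @export
pulse_amplitude <- function(rp) {
  stopifnot(inherits(rp, "rate_program"))
  idx <- which((seq_along(rp$lambda) - 1L) * rp$dt >= rp$onset)
  max(rp$lambda[idx])
}

#' Time-averaged rate of a sampled rate program
#'
#' Mean of \eqn{\lambda(t)} over whole modulation periods following onset
#' (falls back to the whole post-onset window for asynchronous programs or
#' when no complete period fits).
#'
#' @param rp a [rate_program()].
#' @return Mean rate in spikes/s.
#' @export
mean_lambda <- function(rp) {
  stopifnot(inherits(rp, "rate_program"))
  t <- (seq_along(rp$lambda) - 1L) * rp$dt
  post <- rp$lambda[t >= rp$onset]
  if (!is.null(rp$f_inp)) {
    period_steps <- round(1000 / rp$f_inp / rp$dt)
    n_full <- floor(length(post) / period_steps)
    if (n_full >= 1) post <- post[seq_len(n_full * period_steps)]
  }
  mean(post)
}

#' @export
print.rate_program <- function(x, ...) {
  cat("Rate program:", x$kind, "\n")
  cat(sprintf("  duration %g ms, onset %g ms, dt %g ms\n",
              x$duration, x$onset, x$dt))
  if (!is.null(x$r_inp)) cat(sprintf("  r_inp   %g sp/s\n", x$r_inp))
  if (!is.null(x$f_inp)) cat(sprintf("  f_inp   %g Hz\n", x$f_inp))
  if (!is.null(x$delta_inp)) cat(sprintf("  delta   %g ms\n", x$delta_inp))
  if (!is.null(x$r_p)) cat(sprintf("  r_p     %g sp/s\n", x$r_p))
  cat(sprintf("  mean lambda %.1f sp/s, peak %.1f sp/s\n",
              mean_lambda(x), max(x$lambda)))
  invisible(x)
}

#' @export
plot.rate_program <- function(x, decimate = 100L, ...) {
  i <- seq(1L, length(x$lambda), by = decimate)
  t <- (i - 1L) * x$dt
  plot(t, x$lambda[i], type = "l", xlab = "time (ms)",
       ylab = expression(lambda(t) ~ "(sp/s)"), ...)
  invisible(x)
}

#' Serialize a rate program to JSON (parameters only)
#'
#' The sampled trajectory is reconstructed on read, so files stay small.
#'
#' @param rp a [rate_program()].
#' @param path file to write.
#' @export
write_rate_program <- function(rp, path) {
  stopifnot(inherits(rp, "rate_program"))
  fields <- rp[c("kind", "r_inp", "f_inp", "delta_inp", "r_p", "onset",
                 "duration", "dt", "sine_mean")]
  fields <- fields[!vapply(fields, is.null, logical(1))]
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rate_program
#' @export
read_rate_program <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(rate_program, p)
}

#' Draw inhomogeneous Poisson spike trains from a rate program
#'
#' One independent realization per source, generated by thinning on the `dt`
#' grid: each bin emits at most one spike with probability
#' \eqn{\lambda(t)\,dt}, which is exact to \eqn{O(\lambda dt)} (at the default
#' `dt` = 0.01 ms the bin occupancy probability is \eqn{\ll 1} for all rates
#' used here).  Spike times are grid-aligned at bin starts.
#'
#' Reproducibility: each source draws from its own RNG stream derived
#' deterministically from (`seed`, source index), so rasters are
#' bit-reproducible and the first `k` sources of an `n`-source raster equal
#' the sources of a `k`-source raster at the same seed.
#'
#' @param rp a [rate_program()].
#' @param n_sources number of independent source cells.
#' @param seed master seed (integer, required; no hidden global state).
#' @return A [spike_raster()].
#' @export
draw_poisson_spikes <- function(rp, n_sources, seed) {
  stopifnot(inherits(rp, "rate_program"), n_sources >= 0)
  if (missing(seed) || is.null(seed)) stop("seed must be given explicitly")
  p <- rp$lambda * rp$dt / 1000
  t_grid <- (seq_along(rp$lambda) - 1L) * rp$dt
  src_seeds <- derive_seeds(seed, n_sources)
  times <- vector("list", n_sources)
  sources <- vector("list", n_sources)
  for (i in seq_len(n_sources)) {
    st <- with_seed(src_seeds[i], t_grid[stats::runif(length(p)) < p])
    times[[i]] <- st
    sources[[i]] <- rep.int(i, length(st))
  }
  spike_raster(unlist(times), unlist(sources), n_sources = n_sources,
               window = c(0, rp$duration))
}

#' Uncorrelated background drive
#'
#' Preset for background activity: `n_cells` independent asynchronous Poisson
#' sources at `rate` spikes/s each (defaults model 100 cells in other brain
#' areas spiking at 1 sp/s).
#'
#' @param n_cells number of background cells.
#' @param rate per-cell rate (spikes/s).
#' @param duration window length (ms).
#' @param seed master seed.
#' @param dt sampling step (ms).
#' @return A [spike_raster()] with `n_cells` sources.
#' @export
background_drive <- function(n_cells = 100, rate = 1, duration = 1000, seed,
                             dt = 0.01) {
  if (n_cells == 0) {
    return(spike_raster(numeric(0), integer(0), n_sources = 0L,
                        window = c(0, duration)))
  }
  rp <- rate_program("asynchronous", r_inp = rate, duration = duration,
                     dt = dt)
  draw_poisson_spikes(rp, n_sources = n_cells, seed = seed)
}

# Per-source RNG streams derived from one master seed.  Uses a throwaway
# Mersenne-Twister stream seeded by the master to draw child seeds.
derive_seeds <- function(master, n) {
  if (n == 0) return(integer(0))
  with_seed(master, sample.int(2147483646L, n))
}

# Evaluate expr with the RNG temporarily seeded; restores prior RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
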