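#' Sweep specifications
#'
#' Describes a frequency (or synchrony/strength) sweep: the swept parameter
#' and grid, the input waveform and its fixed parameters, the number of
#' realizations per grid point, the base seed, and the network preset.  The
#' full-scale protocol sweeps `f_inp` from 1 to 50 Hz in 1 Hz steps with 10
#' realizations of 2500 ms trials; [scaled_sweep_spec()] is the desk-scale
#' preset (16-32 Hz in 2 Hz steps, 3 realizations, 1500 ms) used throughout
#' the test suite.
#'
#' @param param swept parameter; currently `"f_inp"`.
#' @param grid numeric grid of swept values (Hz).
#' @param kind input waveform kind, see [rate_program()].
#' @param r_inp time-averaged input rate (spikes/s).
#' @param delta_inp pulse width (ms) for square waveforms.
#' @param r_p pulse amplitude (spikes/s) for `square_fixed_amplitude`.
#' @param sine_mean sine normalization convention, see [rate_program()].
#' @param n_realizations trials per grid point.
#' @param base_seed seed from which all trial seeds are derived.
#' @param network a `network_spec`.
#' @param duration,onset trial timing (ms).
#' @param dt integration step (ms).
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(param = "f_inp", grid = 1:50,
                       kind = "square_fixed_mean", r_inp = 1000,
                       delta_inp = 1, r_p = NULL, sine_mean = "matched",
                       n_realizations = 10, base_seed = 1,
                       network = control_network(), duration = 2500,
                       onset = 400, dt = 0.01) {
  stopifnot(param == "f_inp", length(grid) >= 1, n_realizations >= 1)
  structure(list(param = param, grid = grid, kind = kind, r_inp = r_inp,
                 delta_inp = delta_inp, r_p = r_p, sine_mean = sine_mean,
                 n_realizations = n_realizations, base_seed = base_seed,
                 network = network, duration = duration, onset = onset,
                 dt = dt),
            class = "sweep_spec")
}

#' @rdname sweep_spec
#' @param ... overrides passed to [sweep_spec()].
#' @export
scaled_sweep_spec <- function(...) {
  args <- list(...)
  defaults <- list(grid = seq(16, 32, by = 2), n_realizations = 3,
                   duration = 1500)
  defaults[names(args)] <- args
  do.call(sweep_spec, defaults)
}

# deterministic trial seed for (grid index i, realization j)
trial_seed <- function(base_seed, i, j) {
  as.integer((base_seed + 7919 * (i - 1) + 104729 * (j - 1)) %% 2147483647L)
}

sweep_program <- function(sw, f) {
  switch(sw$kind,
    asynchronous = rate_program("asynchronous", r_inp = sw$r_inp,
                                onset = sw$onset, duration = sw$duration,
                                dt = sw$dt),
    sine = rate_program("sine", r_inp = sw$r_inp, f_inp = f,
                        onset = sw$onset, duration = sw$duration,
                        dt = sw$dt, sine_mean = sw$sine_mean),
    square_fixed_mean = rate_program("square_fixed_mean", r_inp = sw$r_inp,
                                     f_inp = f, delta_inp = sw$delta_inp,
                                     onset = sw$onset,
                                     duration = sw$duration, dt = sw$dt),
    square_fixed_amplitude = rate_program("square_fixed_amplitude",
                                          r_p = sw$r_p, f_inp = f,
                                          delta_inp = sw$delta_inp,
                                          onset = sw$onset,
                                          duration = sw$duration,
                                          dt = sw$dt))
}

#' Input frequency-dependent response profile
#'
#' Runs one trial per (grid point x realization), measures the
#' time-averaged PC and IN population rates and the population frequency,
#' and aggregates them as mean and standard deviation across realizations.
#' An equal-strength asynchronous reference (same `r_inp`, same number of
#' realizations) provides the natural response: the reference rates and the
#' natural frequency f_N.
#'
#' @param sw a [sweep_spec()].
#' @param population population measured for `f_pop` (default the first
#'   signal population).
#' @param reference if `FALSE` the asynchronous reference is skipped.
#' @param band spectral search band (Hz).
#' @return A data.frame of class `response_profile` with one row per grid
#'   point (`f_inp`, `rate_PC`, `rate_PC_sd`, `rate_IN`, `rate_IN_sd`,
#'   `f_pop`, `f_pop_sd`, `nested_frac`, plus per-realization argmax data in
#'   attributes) and attributes `f_N`, `ref_rates`, `sweep`.
#' @export
frequency_sweep <- function(sw, population = NULL, reference = TRUE,
                            band = c(5, 100)) {
  stopifnot(inherits(sw, "sweep_spec"))
  net <- sw$network
  if (is.null(population)) population <- net$signal_pops[1]
  pop_names <- names(net$populations)
  in_pop <- if ("IN" %in% pop_names) "IN" else pop_names[length(pop_names)]

  n_f <- length(sw$grid)
  rate_pc <- rate_in <- fpop <- matrix(NA_real_, n_f, sw$n_realizations)
  nested <- matrix(FALSE, n_f, sw$n_realizations)
  for (i in seq_len(n_f)) {
    rp <- sweep_program(sw, sw$grid[i])
    for (j in seq_len(sw$n_realizations)) {
      tr <- tryCatch(
        run_trial(net, signal = rp, seed = trial_seed(sw$base_seed, i, j),
                  duration = sw$duration, onset = sw$onset, dt = sw$dt),
        error = function(e) {
          warning(sprintf("trial (f=%g, rep %d) aborted: %s", sw$grid[i], j,
                          conditionMessage(e)))
          NULL
        })
      if (is.null(tr)) next
      m <- trial_measures(tr, population = population, band = band)
      rate_pc[i, j] <- m$rates[[population]]
      rate_in[i, j] <- m$rates[[in_pop]]
      fpop[i, j] <- m$f_pop
      nested[i, j] <- nested_oscillation_flag(m$spectrum, sw$grid[i],
                                              band = band)
    }
  }

  out <- data.frame(
    f_inp = sw$grid,
    rate_PC = rowMeans(rate_pc, na.rm = TRUE),
    rate_PC_sd = apply(rate_pc, 1, stats::sd, na.rm = TRUE),
    rate_IN = rowMeans(rate_in, na.rm = TRUE),
    rate_IN_sd = apply(rate_in, 1, stats::sd, na.rm = TRUE),
    f_pop = rowMeans(fpop, na.rm = TRUE),
    f_pop_sd = apply(fpop, 1, stats::sd, na.rm = TRUE),
    nested_frac = rowMeans(nested))

  if (reference) {
    ref <- natural_frequency(net, r_inp = sw$r_inp,
                             seeds = vapply(seq_len(sw$n_realizations),
                                            function(j)
                                              trial_seed(sw$base_seed, 0, j),
                                            numeric(1)),
                             duration = sw$duration, onset = sw$onset,
                             dt = sw$dt, population = population)
    attr(out, "f_N") <- ref$f_N
    attr(out, "ref_rates") <- ref$rates
  }
  attr(out, "per_real") <- list(rate_PC = rate_pc, rate_IN = rate_in,
                                f_pop = fpop)
  attr(out, "sweep") <- sw
  attr(out, "population") <- population
  class(out) <- c("response_profile", "data.frame")
  out
}

#' @export
print.response_profile <- function(x, ...) {
  cat("Response profile (", attr(x, "population"), "):\n", sep = "")
  print.data.frame(round(as.data.frame(x), 2))
  if (!is.null(attr(x, "f_N")))
    cat(sprintf("Natural frequency f_N = %.1f Hz; reference rates: %s\n",
                attr(x, "f_N"),
                paste(sprintf("%s %.1f", names(attr(x, "ref_rates")),
                              attr(x, "ref_rates")), collapse = ", ")))
  invisible(x)
}

#' @export
plot.response_profile <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::matplot(x$f_inp, cbind(x$rate_PC, x$rate_IN), type = "b",
                    pch = 16, lty = 1, col = c("blue", "red"),
                    xlab = "input frequency (Hz)", ylab = "mean rate (sp/s)")
  if (!is.null(attr(x, "ref_rates")))
    graphics::abline(h = attr(x, "ref_rates"), lty = 2,
                     col = c("blue", "red"))
  graphics::legend("topright", c("PC", "IN"), col = c("blue", "red"),
                   pch = 16, bty = "n")
  plot(x$f_inp, x$f_pop, type = "b", pch = 16,
       xlab = "input frequency (Hz)", ylab = "population frequency (Hz)")
  graphics::abline(0, 1, lty = 3)
  if (!is.null(attr(x, "f_N")))
    graphics::abline(h = attr(x, "f_N"), lty = 2)
  invisible(x)
}

argmax_lower <- function(grid, value) {
  ok <- is.finite(value)
  if (!any(ok)) return(NA_real_)
  g <- grid[ok]; v <- value[ok]
  g[which.max(v)]   # which.max takes the first (lowest-frequency) maximum
}

#' Extract resonance statistics from a response profile
#'
#' The firing-rate resonant frequencies are the input frequencies at which
#' the global maxima of the mean PC and IN rate profiles occur; the
#' population-frequency resonance is the argmax of the mean `f_pop` profile
#' after excluding grid points whose trials were predominantly flagged as
#' nested-oscillation regimes; the natural frequency comes from the
#' asynchronous reference.  Ties break toward the lower frequency, and the
#' dispersion of each resonance across realizations is the standard
#' deviation of the per-realization argmax.
#'
#' @param profile a `response_profile` from [frequency_sweep()].
#' @param nested_threshold exclude a grid point from f_R^pop extraction when
#'   more than this fraction of its realizations were flagged nested.
#' @return An object of class `resonance_summary` with fields `f_R_PC`,
#'   `f_R_IN`, `f_R_pop`, `f_N` and `*_sd` dispersions (Hz).
#' @export
extract_resonances <- function(profile, nested_threshold = 0.5) {
  stopifnot(inherits(profile, "response_profile"))
  per <- attr(profile, "per_real")
  grid <- profile$f_inp
  arg_sd <- function(m) {
    a <- apply(m, 2, function(col) argmax_lower(grid, col))
    stats::sd(a, na.rm = TRUE)
  }
  fpop_mean <- profile$f_pop
  fpop_mean[profile$nested_frac > nested_threshold] <- NA
  structure(list(
    f_R_PC = argmax_lower(grid, profile$rate_PC),
    f_R_PC_sd = arg_sd(per$rate_PC),
    f_R_IN = argmax_lower(grid, profile$rate_IN),
    f_R_IN_sd = arg_sd(per$rate_IN),
    f_R_pop = argmax_lower(grid, fpop_mean),
    f_R_pop_sd = arg_sd(per$f_pop),
    f_N = attr(profile, "f_N"),
    grid = range(grid)), class = "resonance_summary")
}

#' @export
print.resonance_summary <- function(x, ...) {
  cat("Resonance summary (grid", x$grid[1], "-", x$grid[2], "Hz):\n")
  cat(sprintf("  f_R_PC  = %5.1f Hz (sd %.1f)\n", x$f_R_PC, x$f_R_PC_sd))
  cat(sprintf("  f_R_IN  = %5.1f Hz (sd %.1f)\n", x$f_R_IN, x$f_R_IN_sd))
  cat(sprintf("  f_R_pop = %5.1f Hz (sd %.1f)\n", x$f_R_pop, x$f_R_pop_sd))
  if (!is.null(x$f_N)) cat(sprintf("  f_N     = %5.1f Hz\n", x$f_N))
  invisible(x)
}

#' Serialize a resonance summary to JSON
#'
#' @param x a `resonance_summary`.
#' @param path file to write.
#' @export
write_resonance_summary <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Knockout and applied-current modulation experiments
#'
#' Re-runs a firing-rate sweep for each condition: the control network, each
#' single-channel knockout, and/or each applied-current level, and extracts
#' the PC firing-rate resonant frequency per condition.  PC silence (mean
#' rate below `silence_floor` at every grid point) is reported as a distinct
#' outcome with `silent = TRUE`.
#'
#' @param knockouts character vector of channel names (subset of `NaF`,
#'   `KDR`, `NaP`, `Ks`, `Ca`, `KCa`); each is knocked out in the PCs one at
#'   a time.
#' @param I_app numeric vector of applied currents (uA/cm2) to the PCs,
#'   each a separate condition.
#' @param sweep template [sweep_spec()]; its network field is rebuilt per
#'   condition via [control_network()] arguments `network_args`.
#' @param network_args extra arguments passed to [control_network()] for
#'   every condition.
#' @param silence_floor rate floor (sp/s per cell) below which the PC
#'   population counts as silenced.
#' @return A data.frame of class `modulation_result`: one row per condition
#'   with `condition`, `f_R_PC`, `f_R_PC_sd`, `max_rate`, `silent`.
#' @export
modulation_experiment <- function(knockouts = character(), I_app = numeric(),
                                  sweep = scaled_sweep_spec(),
                                  network_args = list(),
                                  silence_floor = 0.5) {
  conds <- list(list(label = "control", knockout = character(), I_app = 0))
  for (k in knockouts) {
    if (!k %in% names(.pc_channels))
      stop("unknown current name: ", k)
    conds[[length(conds) + 1]] <- list(label = paste0("-", k), knockout = k,
                                       I_app = 0)
  }
  for (ia in I_app)
    conds[[length(conds) + 1]] <- list(label = sprintf("I_app=%+g", ia),
                                       knockout = character(), I_app = ia)
  rows <- lapply(conds, function(cd) {
    net <- do.call(control_network,
                   c(list(knockout = cd$knockout, I_app_pc = cd$I_app),
                     network_args))
    sw <- sweep
    sw$network <- net
    prof <- frequency_sweep(sw, reference = FALSE)
    silent <- all(prof$rate_PC < silence_floor, na.rm = TRUE)
    res <- extract_resonances(prof)
    data.frame(condition = cd$label,
               f_R_PC = if (silent) NA_real_ else res$f_R_PC,
               f_R_PC_sd = if (silent) NA_real_ else res$f_R_PC_sd,
               max_rate = max(prof$rate_PC, na.rm = TRUE),
               silent = silent)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("modulation_result", "data.frame")
  out
}

#' Competition between a target and a distractor pathway
#'
#' Two PC populations share one IN pool ([competition_network()]).  The
#' target pathway (`PC_T`) receives `target`, the distractor (`PC_D`)
#' receives `distractor`; unless overridden, both inputs have the same mean
#' strength.  The suppression index compares the distractor's rate under
#' competition with its natural (no-competition) response, obtained by
#' re-running the distractor pathway alone with identical seeds:
#' \deqn{SI = 1 - \bar r_{PC_D}(competition) / \bar r_{PC_D}(alone).}
#'
#' @param target,distractor [rate_program()]s for the two pathways.
#' @param network a two-pathway `network_spec`.
#' @param seeds integer vector of trial seeds (one trial per seed).
#' @param duration,onset,dt trial timing (ms).
#' @return An object of class `competition_result`: per-pathway mean rates
#'   and population frequencies (averaged over seeds), the suppression
#'   index, and the per-trial iFR traces of both pathways.
#' @export
competition_experiment <- function(target, distractor,
                                   network = competition_network(),
                                   seeds = 1:3, duration = 1500,
                                   onset = 400, dt = 0.01) {
  rates_T <- rates_D <- rates_D_alone <- fpop_T <- fpop_D <- numeric(0)
  ifr_T <- ifr_D <- list()
  for (s in seeds) {
    tr <- run_trial(network, signal = list(PC_T = target, PC_D = distractor),
                    seed = s, duration = duration, onset = onset, dt = dt)
    mT <- trial_measures(tr, population = "PC_T")
    mD <- trial_measures(tr, population = "PC_D")
    rates_T <- c(rates_T, mT$rates[["PC_T"]])
    rates_D <- c(rates_D, mT$rates[["PC_D"]])
    fpop_T <- c(fpop_T, mT$f_pop)
    fpop_D <- c(fpop_D, mD$f_pop)
    ifr_T[[length(ifr_T) + 1]] <- mT$ifr
    ifr_D[[length(ifr_D) + 1]] <- mD$ifr
    # natural reference: the distractor pathway alone, identical seed
    ref <- run_trial(network, signal = list(PC_D = distractor), seed = s,
                     duration = duration, onset = onset, dt = dt)
    mR <- trial_measures(ref, population = "PC_D")
    rates_D_alone <- c(rates_D_alone, mR$rates[["PC_D"]])
  }
  si <- 1 - mean(rates_D) / mean(rates_D_alone)
  structure(list(rate_T = mean(rates_T), rate_D = mean(rates_D),
                 rate_D_alone = mean(rates_D_alone),
                 f_pop_T = stats::median(fpop_T, na.rm = TRUE),
                 f_pop_D = stats::median(fpop_D, na.rm = TRUE),
                 suppression_index = si, seeds = seeds,
                 ifr_T = ifr_T, ifr_D = ifr_D),
            class = "competition_result")
}

#' @export
print.competition_result <- function(x, ...) {
  cat("Competition result:\n")
  cat(sprintf("  target     rate %5.1f sp/s, f_pop %5.1f Hz\n", x$rate_T,
              x$f_pop_T))
  cat(sprintf("  distractor rate %5.1f sp/s (alone %5.1f), f_pop %5.1f Hz\n",
              x$rate_D, x$rate_D_alone, x$f_pop_D))
  cat(sprintf("  suppression index %.2f\n", x$suppression_index))
  invisible(x)
}

#' Single-cell and minimal-network resonance ladder
#'
#' Reproduces the isolated-cell experiments: with background noise removed,
#' (i) the subthreshold voltage-fluctuation amplitude (Vmax - Vmin) of one
#' PC under weak sinusoidal Poisson drive, (ii) the firing-rate profile
#' under suprathreshold drive strengths, and (iii) the same rate profiles in
#' a minimal 1 PC + 1 IN network whose PC-to-IN synapse is strong enough for
#' a single PC spike to recruit the IN.  The sine inputs follow the printed
#' half-mean convention, under which 0.1 kHz is subthreshold and 0.3 kHz
#' slightly suprathreshold for the calibrated cell.
#'
#' @param freqs input frequency grid (Hz).
#' @param r_sub subthreshold input rate (spikes/s).
#' @param r_supra suprathreshold input rates (spikes/s).
#' @param seeds trial seeds.
#' @param duration,onset trial timing (ms).
#' @param minimal include the minimal-network rung.
#' @return A list with data.frames `subthreshold` (f_inp, v_amp),
#'   `suprathreshold` (f_inp, r_inp, rate), and `minimal` (same, for the
#'   1 PC + 1 IN network; `NULL` if skipped).
#' @export
single_cell_ladder <- function(freqs = 1:10, r_sub = 100,
                               r_supra = c(300, 800, 1000), seeds = 1:3,
                               duration = 2900, onset = 400,
                               minimal = TRUE) {
  spc <- single_pc_network()
  win0 <- onset + 500
  vamp <- sapply(freqs, function(f) mean(sapply(seeds, function(s) {
    rp <- rate_program("sine", r_inp = r_sub, f_inp = f, onset = onset,
                       duration = duration, sine_mean = "half")
    tr <- run_trial(spc, rp, seed = s, duration = duration, onset = onset)
    v <- tr$v[tr$v_time >= win0, 1]
    max(v) - min(v)
  })))
  sub <- data.frame(f_inp = freqs, v_amp = vamp)

  rate_profile <- function(net, r, pop = "PC") {
    sapply(freqs, function(f) mean(sapply(seeds, function(s) {
      rp <- rate_program("sine", r_inp = r, f_inp = f, onset = onset,
                         duration = duration, sine_mean = "half")
      tr <- run_trial(net, rp, seed = s, duration = duration, onset = onset)
      spike_count(tr$rasters[[pop]], c(win0, duration)) /
        ((duration - win0) / 1000)
    })))
  }
  supra <- do.call(rbind, lapply(r_supra, function(r)
    data.frame(f_inp = freqs, r_inp = r, rate = rate_profile(spc, r))))

  minimal_df <- NULL
  if (minimal) {
    mn <- minimal_network()
    minimal_df <- do.call(rbind, lapply(r_supra, function(r)
      data.frame(f_inp = freqs, r_inp = r, rate = rate_profile(mn, r))))
  }
  list(subthreshold = sub, suprathreshold = supra, minimal = minimal_df)
}

#' Classify the filter regime of a firing-rate profile
#'
#' Labels a PC rate profile as band-pass, low-pass, high-pass, or all-pass
#' (with or without a resonant peak) from which grid points respond above a
#' floor.  Thresholds are documented choices: a point is "active" when its
#' mean PC rate exceeds `floor`; the profile is all-pass when at least
#' `all_pass_frac` of points are active, low/high-pass when the active
#' points form a run anchored at the low/high end, and band-pass when they
#' form an interior band.  A "+peak" suffix marks a resonant peak (profile
#' maximum at least `peak_ratio` times the profile edge mean).
#'
#' @param profile a `response_profile` (or data.frame with `f_inp`,
#'   `rate_PC`).
#' @param floor activity floor (sp/s per cell).
#' @param all_pass_frac fraction of active grid points that counts as
#'   all-pass.
#' @param peak_ratio peak-to-edge ratio for the "+peak" suffix.
#' @return A character label: one of `"band-pass"`, `"low-pass"`,
#'   `"high-pass"`, `"all-pass"`, optionally suffixed `"+peak"`.
#' @export
classify_filter_regime <- function(profile, floor = 1, all_pass_frac = 0.9,
                                   peak_ratio = 1.3) {
  r <- profile$rate_PC
  active <- r > floor
  n <- length(r)
  edges <- mean(r[c(1, n)])
  has_peak <- max(r) >= peak_ratio * max(edges, 1e-9) &&
    which.max(r) != 1 && which.max(r) != n
  label <- if (mean(active) >= all_pass_frac) {
    "all-pass"
  } else if (!any(active)) {
    "band-pass"   # degenerate: nothing passes; narrowest label
  } else {
    runs <- rle(active)
    first_active <- active[1]
    last_active <- active[n]
    if (first_active && !last_active) "low-pass"
    else if (!first_active && last_active) "high-pass"
    else "band-pass"
  }
  if (has_peak && label != "band-pass") paste0(label, "+peak") else label
}

#' Concatenate two rate programs into a two-period schedule
#'
#' Builds a composite program whose first period follows `a` and whose
#' second follows `b` (shifted to start when `a` ends); used for schedules
#' such as asynchronous-then-oscillatory drive.
#'
#' @param a,b [rate_program()]s with equal `dt`.
#' @return A composite `rate_program` spanning both durations.
#' @export
concat_rate_programs <- function(a, b) {
  stopifnot(inherits(a, "rate_program"), inherits(b, "rate_program"),
            abs(a$dt - b$dt) < 1e-12)
  structure(list(kind = "composite", r_inp = a$r_inp, f_inp = b$f_inp,
                 delta_inp = b$delta_inp, r_p = b$r_p, onset = a$onset,
                 duration = a$duration + b$duration, dt = a$dt,
                 sine_mean = b$sine_mean,
                 lambda = c(a$lambda, b$lambda)),
            class = "rate_program")
}

#' Export a response profile as CSV
#'
#' @param profile a `response_profile`.
#' @param path file to write.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Find the input rate that produces a target natural frequency
#'
#' Coarse bisection on the monotone relation between asynchronous drive
#' strength and natural frequency; used e.g. to give a distractor pathway a
#' natural rhythm matching a target's population frequency.
#'
#' @param network a `network_spec`.
#' @param f_target desired natural frequency (Hz).
#' @param lower,upper bracketing input rates (spikes/s).
#' @param seeds trial seeds per evaluation.
#' @param iters bisection iterations.
#' @param duration,onset trial timing (ms).
#' @return A list with `r_inp` and the achieved `f_N`.
#' @export
tune_r_inp_to_f_N <- function(network, f_target, lower = 500, upper = 3000,
                              seeds = 1:2, iters = 5, duration = 1500,
                              onset = 400) {
  fN <- function(r) natural_frequency(network, r_inp = r, seeds = seeds,
                                      duration = duration, onset = onset)$f_N
  lo <- lower; hi <- upper
  f_lo <- fN(lo); f_hi <- fN(hi)
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    f_mid <- fN(mid)
    if (is.na(f_mid)) { lo <- mid; next }
    if (f_mid < f_target) { lo <- mid; f_lo <- f_mid }
    else { hi <- mid; f_hi <- f_mid }
  }
  mid <- (lo + hi) / 2
  list(r_inp = mid, f_N = fN(mid))
}
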