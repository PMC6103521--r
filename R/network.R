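#' Network specifications
#'
#' A network specification lists populations (cell model and size), all-to-all
#' synaptic connection blocks, and input wiring (which populations receive an
#' external signal and the input/noise coupling conductances).  Presets are
#' provided for the standard configurations:
#'
#' \describe{
#'   \item{[control_network()]}{20 PCs reciprocally connected to 5 INs:
#'     PC to IN by AMPA (g = 1 mS/cm2), IN to PC by GABA-A onto the soma
#'     (g = 0.1 mS/cm2); no PC-PC or IN-IN coupling.  External signal and
#'     background noise target the PC dendrites.}
#'   \item{[competition_network()]}{two PC populations (target `PC_T` and
#'     distractor `PC_D`), each driven by its own input pathway, reciprocally
#'     connected to one shared IN pool.}
#'   \item{[minimal_network()]}{1 PC and 1 IN with the PC-to-IN synapse
#'     strong enough that a single PC spike recruits the IN.}
#'   \item{[single_pc_network()]}{one isolated PC, no interneurons.}
#'   \item{[lif_network()]}{25 leaky integrate-and-fire PCs and 5 LIF INs
#'     with double-exponential synaptic conductances.}
#' }
#'
#' Block conductances are normalized by the number of source cells, so the
#' total maximal conductance onto a target cell equals `g`; this keeps
#' dynamics invariant when population sizes are scaled up at fixed synaptic
#' strength (e.g. `control_network(n_pc = 100, n_in = 37)`).
#'
#' @param n_pc,n_in population sizes.
#' @param g_ampa PC-to-IN AMPA maximal conductance (mS/cm2).
#' @param g_gaba IN-to-PC GABA-A maximal conductance (mS/cm2).
#' @param gaba_tau_d GABA-A decay time constant (ms), the duration of
#'   feedback inhibition.
#' @param g_inp signal synapse maximal conductance (mS/cm2).
#' @param g_noise background synapse maximal conductance (mS/cm2); defaults
#'   to `g_inp` for the conductance-based networks.
#' @param knockout channel knockout mask applied to the PCs (see
#'   [pc_cell()]).
#' @param I_app_pc applied current to PCs (uA/cm2).
#' @param pc,inh cell models from [pc_cell()] / [in_cell()].
#' @param background_rate aggregate background rate per PC (sp/s); the
#'   default models 100 uncorrelated cells at 1 sp/s.
#' @param init_jitter amplitude (mV) of uniform per-cell jitter applied to
#'   initial voltages.
#' @return An object of class `network_spec`.
#' @export
control_network <- function(n_pc = 20, n_in = 5, g_ampa = 1, g_gaba = 0.1,
                            gaba_tau_d = 5, g_inp = 0.0015, g_noise = 0.004,
                            knockout = character(), I_app_pc = 0,
                            pc = pc_cell(knockout = knockout,
                                         I_app = I_app_pc),
                            inh = in_cell(), background_rate = 100,
                            init_jitter = 1) {
  ampa <- ampa_synapse(g = g_ampa)
  gaba <- gaba_synapse(g = g_gaba, tau_d = gaba_tau_d)
  new_network_spec(
    model_class = "hh",
    populations = list(
      PC = list(model = "pc", n = n_pc, params = pc$params,
                I_app = pc$I_app),
      IN = list(model = "in", n = n_in, params = inh$params,
                I_app = inh$I_app)),
    connections = list(
      conn("PC", "IN", "soma", ampa),
      conn("IN", "PC", "soma", gaba)),
    signal_pops = "PC", g_inp = g_inp, g_noise = g_noise,
    input_target = "dend", background_rate = background_rate,
    init_jitter = init_jitter)
}

#' @rdname control_network
#' @export
competition_network <- function(n_pc = 20, n_in = 5, g_ampa = 1,
                                g_gaba = 0.1, gaba_tau_d = 5,
                                g_inp = 0.0015, g_noise = 0.004,
                                pc = pc_cell(), inh = in_cell(),
                                background_rate = 100, init_jitter = 1) {
  ampa <- ampa_synapse(g = g_ampa)
  gaba <- gaba_synapse(g = g_gaba, tau_d = gaba_tau_d)
  new_network_spec(
    model_class = "hh",
    populations = list(
      PC_T = list(model = "pc", n = n_pc, params = pc$params,
                  I_app = pc$I_app),
      PC_D = list(model = "pc", n = n_pc, params = pc$params,
                  I_app = pc$I_app),
      IN = list(model = "in", n = n_in, params = inh$params,
                I_app = inh$I_app)),
    connections = list(
      conn("PC_T", "IN", "soma", ampa),
      conn("PC_D", "IN", "soma", ampa),
      conn("IN", "PC_T", "soma", gaba),
      conn("IN", "PC_D", "soma", gaba)),
    signal_pops = c("PC_T", "PC_D"), g_inp = g_inp, g_noise = g_noise,
    input_target = "dend", background_rate = background_rate,
    init_jitter = init_jitter)
}

#' @rdname control_network
#' @export
minimal_network <- function(g_ampa = 1, g_gaba = 0.1, gaba_tau_d = 5,
                            g_inp = 0.0015, g_noise = g_inp, pc = pc_cell(),
                            inh = in_cell(), background_rate = 0,
                            init_jitter = 1) {
  control_network(n_pc = 1, n_in = 1, g_ampa = g_ampa, g_gaba = g_gaba,
                  gaba_tau_d = gaba_tau_d, g_inp = g_inp, g_noise = g_noise,
                  pc = pc, inh = inh, background_rate = background_rate,
                  init_jitter = init_jitter)
}

#' @rdname control_network
#' @export
single_pc_network <- function(g_inp = 0.0015, g_noise = g_inp,
                              pc = pc_cell(), background_rate = 0,
                              init_jitter = 0) {
  new_network_spec(
    model_class = "hh",
    populations = list(
      PC = list(model = "pc", n = 1L, params = pc$params,
                I_app = pc$I_app)),
    connections = list(),
    signal_pops = "PC", g_inp = g_inp, g_noise = g_noise,
    input_target = "dend", background_rate = background_rate,
    init_jitter = init_jitter)
}

#' @rdname control_network
#' @param params LIF parameter set from [lif_params()].
#' @export
lif_network <- function(n_pc = 25, n_in = 5, params = lif_params(),
                        background_rate = 100, init_jitter = 1) {
  cell <- params$cell
  new_network_spec(
    model_class = "lif",
    populations = list(
      PC = c(list(model = "lif", n = n_pc), cell),
      IN = c(list(model = "lif", n = n_in), cell)),
    connections = list(
      conn("PC", "IN", "soma", params$syn_onto_in),
      conn("IN", "PC", "soma", params$syn_onto_pc)),
    signal_pops = "PC", g_inp = params$g_inp, g_noise = params$g_noise,
    input_target = "soma", background_rate = background_rate,
    init_jitter = init_jitter)
}

conn <- function(src, dst, target, syn) {
  list(src = src, dst = dst, target = target, g = syn$g, E = syn$E,
       tau_r = syn$tau_r, tau_d = syn$tau_d)
}

new_network_spec <- function(...) {
  structure(list(...), class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("Network spec (", x$model_class, "):\n", sep = "")
  for (nm in names(x$populations))
    cat(sprintf("  %-5s %3d cells (%s)\n", nm, x$populations[[nm]]$n,
                x$populations[[nm]]$model))
  for (cn in x$connections)
    cat(sprintf("  %s -> %s (%s): g=%g E=%g tau_r=%g tau_d=%g\n",
                cn$src, cn$dst, cn$target, cn$g, cn$E, cn$tau_r, cn$tau_d))
  cat(sprintf("  signal -> %s (g_inp=%g, g_noise=%g, target=%s)\n",
              paste(x$signal_pops, collapse = ", "), x$g_inp, x$g_noise,
              x$input_target))
  invisible(x)
}

#' Assemble and validate a simulator from a network specification
#'
#' Checks cell models, connection endpoints, input wiring, and parameter
#' signs, and computes the directed synapse count (sum over all-to-all blocks
#' of n_source x n_target).
#'
#' @param spec a `network_spec`.
#' @return An object of class `network_sim` wrapping the validated spec with
#'   derived quantities (`synapse_count`, population offsets).
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  pops <- spec$populations
  if (!length(pops)) stop("network has no populations")
  for (nm in names(pops)) {
    m <- pops[[nm]]$model
    if (!m %in% c("pc", "in", "lif")) stop("unknown cell model: ", m)
    if (pops[[nm]]$n < 0) stop("negative population size")
  }
  for (cn in spec$connections) {
    if (!cn$src %in% names(pops) || !cn$dst %in% names(pops))
      stop("connection references unknown population: ", cn$src, "->", cn$dst)
    if (cn$g < 0) stop("negative synaptic conductance")
  }
  missing_pops <- setdiff(spec$signal_pops, names(pops))
  if (length(missing_pops))
    stop("input wiring targets unknown population(s): ",
         paste(missing_pops, collapse = ", "))
  if (spec$g_inp < 0 || spec$g_noise < 0) stop("negative input conductance")
  syn <- sum(vapply(spec$connections, function(cn)
    pops[[cn$src]]$n * pops[[cn$dst]]$n, numeric(1)))
  structure(list(spec = spec, synapse_count = syn,
                 pop_names = names(pops),
                 pop_sizes = vapply(pops, function(p) as.integer(p$n), integer(1))),
            class = "network_sim")
}

#' @export
print.network_sim <- function(x, ...) {
  cat("Simulator:", sum(x$pop_sizes), "cells,", x$synapse_count,
      "directed synapses\n")
  invisible(x)
}

#' Run one network trial
#'
#' Composes input sampling, integration, and raster extraction.  The network
#' runs with background noise from `t = 0`, the external signal is delivered
#' at `onset`, and the analysis window starts 500 ms after onset.  Fully
#' reproducible from (`spec`, `seed`): the master seed deterministically
#' derives one stream for the initial-voltage jitter and one per input
#' pathway.
#'
#' @param spec a `network_spec` (or `network_sim` from [build_network()]).
#' @param signal a [rate_program()] applied to every signal population, a
#'   named list of per-population rate programs or [spike_raster()]s, or
#'   `NULL` for background only.
#' @param seed master seed (integer).
#' @param duration trial length (ms).
#' @param onset signal delivery time (ms).
#' @param dt integration step (ms).
#' @param rec_dt voltage recording step (ms); traces are stored decimated.
#' @param settle_exclude response time excluded from analysis after onset
#'   (ms).
#' @return An object of class `sim_result` with per-population spike
#'   rasters, decimated somatic voltage traces, and timing metadata.
#' @export
run_trial <- function(spec, signal = NULL, seed, duration = 2500,
                      onset = 400, dt = 0.01, rec_dt = 0.1,
                      settle_exclude = 500) {
  if (inherits(spec, "network_sim")) spec <- spec$spec
  sim <- build_network(spec)
  if (missing(seed)) stop("seed must be given explicitly")
  pops <- spec$populations
  sig_pops <- spec$signal_pops

  # normalize `signal` to a named list over signal populations
  if (inherits(signal, "rate_program") || inherits(signal, "spike_raster")) {
    signal <- stats::setNames(rep(list(signal), length(sig_pops)), sig_pops)
  }
  if (!is.null(signal)) {
    extra <- setdiff(names(signal), sig_pops)
    if (length(extra))
      stop("signal given for population(s) without input wiring: ",
           paste(extra, collapse = ", "))
  }

  n_path <- length(sig_pops)
  seeds <- derive_seeds(seed, 1L + 2L * n_path)
  jitter_seed <- seeds[1]
  sig_seeds <- seeds[1 + seq_len(n_path)]
  bg_seeds <- seeds[1 + n_path + seq_len(n_path)]

  target_code <- if (identical(spec$input_target, "dend")) 1L else 0L
  streams <- list()
  for (i in seq_along(sig_pops)) {
    pop <- sig_pops[i]
    n <- pops[[pop]]$n
    sg <- signal[[pop]]
    if (!is.null(sg)) {
      if (inherits(sg, "rate_program")) {
        sg <- match_trial_grid(sg, duration, dt, onset)
        sg <- draw_poisson_spikes(sg, n_sources = n, seed = sig_seeds[i])
      }
      if (!inherits(sg, "spike_raster"))
        stop("signal must be a rate_program or spike_raster")
      if (sg$n_sources != n)
        stop("signal raster has ", sg$n_sources, " sources but population ",
             pop, " has ", n, " cells")
      ord <- order(sg$times)   # engine consumes streams in time order
      streams[[length(streams) + 1]] <- list(
        dst = which(names(pops) == pop) - 1L, target = target_code,
        g = spec$g_inp, E = 0, tau_d = 2,
        times = sg$times[ord], cells = sg$sources[ord])
    }
    if (spec$background_rate > 0 && n > 0) {
      rp_bg <- rate_program("asynchronous", r_inp = spec$background_rate,
                            onset = 0, duration = duration, dt = dt)
      bg <- draw_poisson_spikes(rp_bg, n_sources = n, seed = bg_seeds[i])
      ord <- order(bg$times)
      streams[[length(streams) + 1]] <- list(
        dst = which(names(pops) == pop) - 1L, target = target_code,
        g = spec$g_noise, E = 0, tau_d = 2,
        times = bg$times[ord], cells = bg$sources[ord])
    }
  }

  # initial voltages: rest with small per-cell jitter
  n_cells <- sum(vapply(pops, function(p) as.integer(p$n), integer(1)))
  rest <- unlist(lapply(pops, function(p) {
    V0 <- if (spec$model_class == "lif") p$E_l else p$params[["E_L"]]
    rep(V0, p$n)
  }))
  jit <- if (spec$init_jitter > 0)
    with_seed(jitter_seed,
              stats::runif(n_cells, -spec$init_jitter, spec$init_jitter))
  else numeric(n_cells)
  v_init <- rest + jit

  raw <- integrate_network(sim, streams, duration = duration, dt = dt,
                           rec_dt = rec_dt, v_init = v_init)
  if (isTRUE(raw$diverged))
    stop(sprintf(
      "numerical divergence (|V| > 200 mV) at t = %.2f ms [seed %d, dt %g]",
      raw$t_diverged, seed, dt))

  rasters <- list()
  for (p in seq_along(pops)) {
    sp <- raw$spikes[[p]]
    rasters[[names(pops)[p]]] <- spike_raster(
      sp$t, sp$cell, n_sources = pops[[p]]$n, window = c(0, duration))
  }
  structure(list(rasters = rasters, v = raw$v, v_time = raw$v_time,
                 pop_sizes = vapply(pops, function(p) as.integer(p$n), integer(1)),
                 dt = dt, duration = duration, onset = onset,
                 analysis_start = min(onset + settle_exclude, duration),
                 seed = seed, model_class = spec$model_class),
            class = "sim_result")
}

# re-sample a rate program onto the trial grid when it was built for a
# different duration/step/onset
match_trial_grid <- function(rp, duration, dt, onset) {
  if (rp$duration == duration && abs(rp$dt - dt) < 1e-12 &&
      rp$onset == onset) return(rp)
  if (is.null(rp$kind) || rp$kind == "composite")
    stop("composite rate program does not match the trial grid")
  rate_program(rp$kind, r_inp = rp$r_inp, f_inp = rp$f_inp,
               delta_inp = rp$delta_inp, r_p = rp$r_p, onset = onset,
               duration = duration, dt = dt, sine_mean = rp$sine_mean)
}

#' Low-level integration entry point
#'
#' Runs the fixed-step integrator on a built simulator with fully-specified
#' exogenous input streams and initial voltages.  Deterministic given its
#' arguments.  HH networks use 4th-order Runge-Kutta; LIF populations use the
#' grid-aligned event-based update.
#'
#' @param sim a `network_sim` from [build_network()].
#' @param streams list of input streams (`dst` 0-based population index,
#'   `target` 0 = soma / 1 = dendrite, `g`, `E`, `tau_d`, `times`, `cells`).
#' @param duration,dt,rec_dt timing (ms).
#' @param v_init initial voltage per cell.
#' @return Raw engine output (spike lists, decimated voltage matrix).
#' @export
integrate_network <- function(sim, streams, duration, dt = 0.01,
                              rec_dt = 0.1, v_init = NULL) {
  stopifnot(inherits(sim, "network_sim"))
  spec <- sim$spec
  pops <- spec$populations
  if (is.null(v_init))
    v_init <- unlist(lapply(pops, function(p) {
      V0 <- if (spec$model_class == "lif") p$E_l else p$params[["E_L"]]
      rep(V0, p$n)
    }))
  pop_idx <- function(nm) which(names(pops) == nm) - 1L
  # per-source-cell conductance: the block maximum g is shared across all
  # afferents of the same type (reversal) onto the target population, so a
  # target's total maximal conductance is independent of how many source
  # populations feed it (e.g. two PC pools sharing one IN pool)
  conns <- lapply(spec$connections, function(cn) {
    same_type <- Filter(function(x) identical(x$dst, cn$dst) &&
                          isTRUE(all.equal(x$E, cn$E)), spec$connections)
    n_tot <- sum(vapply(same_type, function(x) pops[[x$src]]$n, numeric(1)))
    list(src = pop_idx(cn$src), dst = pop_idx(cn$dst),
         target = if (identical(cn$target, "dend")) 1L else 0L,
         g_per = cn$g / n_tot, E = cn$E, tau_r = cn$tau_r,
         tau_d = cn$tau_d)
  })
  if (spec$model_class == "lif") {
    cpp_pops <- lapply(pops, function(p)
      list(n = p$n, g_l = p$g_l, E_l = p$E_l, v_thresh = p$v_thresh,
           v_reset = p$v_reset, t_ref = p$t_ref))
    .sim_lif_network(unname(cpp_pops), conns, streams, duration, dt, rec_dt,
                     v_init)
  } else {
    cpp_pops <- lapply(pops, function(p)
      list(model = p$model, n = p$n, params = p$params, I_app = p$I_app))
    .sim_hh_network(unname(cpp_pops), conns, streams, duration, dt, rec_dt,
                    v_init)
  }
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Simulation: %g ms (dt not stored in raster), onset %g ms,",
              x$duration, x$onset),
      sprintf("analysis from %g ms\n", x$analysis_start))
  for (nm in names(x$rasters)) {
    r <- x$rasters[[nm]]
    win <- c(x$analysis_start, x$duration)
    n <- x$pop_sizes[[nm]]
    rate <- spike_count(r, win) / n / (diff(win) / 1000)
    cat(sprintf("  %-5s %6d spikes, %6.2f sp/s per cell in window\n",
                nm, length(r$times), rate))
  }
  invisible(x)
}

#' @export
plot.sim_result <- function(x, population = names(x$rasters)[1],
                            sigma = 6, ...) {
  r <- x$rasters[[population]]
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(r, main = population)
  graphics::abline(v = x$onset, col = "grey", lty = 2)
  ifr <- compute_ifr(r, n_cells = x$pop_sizes[[population]], sigma = sigma,
                     window = c(x$onset, x$duration))
  plot(ifr)
  invisible(x)
}

#' Standard output measures of one trial
#'
#' Computes, over the analysis window, the 2 ms kernel iFR and population
#' frequency of one population and the time-averaged population rates (6 ms
#' kernel iFR) for all populations.
#'
#' @param trial a `sim_result`.
#' @param population population for spectral analysis.
#' @param band spectral search band (Hz).
#' @param sigma_spec kernel width for the spectral iFR (ms).
#' @return A list: `f_pop`, `spectrum`, `rates` (named vector, sp/s per
#'   cell), `ifr` (the 2 ms kernel trace).
#' @export
trial_measures <- function(trial, population = "PC", band = c(5, 100),
                           sigma_spec = 2) {
  win <- c(trial$analysis_start, trial$duration)
  r <- trial$rasters[[population]]
  if (is.null(r)) stop("no population named ", population)
  ifr2 <- compute_ifr(r, n_cells = trial$pop_sizes[[population]],
                      sigma = sigma_spec, window = win,
                      label = population)
  pf <- population_frequency(ifr2, band = band)
  rates <- vapply(names(trial$rasters), function(nm) {
    mean_rate(compute_ifr(trial$rasters[[nm]],
                          n_cells = trial$pop_sizes[[nm]], sigma = 6,
                          window = win, label = nm))
  }, numeric(1))
  list(f_pop = pf$f_pop, spectrum = pf$spectrum, rates = rates, ifr = ifr2)
}

#' Read and write network specifications as JSON config files
#'
#' The whole specification - populations with their kinetic parameter
#' vectors, connection blocks, and input wiring - round-trips through a
#' single JSON document.
#'
#' @param spec a `network_spec`.
#' @param path file path.
#' @export
write_network_spec <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  x <- unclass(spec)
  # parameter vectors as named objects so JSON keeps their names
  x$populations <- lapply(x$populations, function(p) {
    if (!is.null(p$params)) p$params <- as.list(p$params)
    p
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$populations <- lapply(x$populations, function(p) {
    if (!is.null(p$params)) p$params <- unlist(p$params)
    p
  })
  x$connections <- if (length(x$connections))
    lapply(seq_len(nrow(x$connections)), function(i)
      as.list(x$connections[i, ])) else list()
  do.call(new_network_spec, x)
}
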