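#' Kinetics registry for the principal-cell model
#'
#' Named parameter set for the two-compartment (soma + dendrite)
#' Hodgkin-Huxley principal cell (PC).  The soma carries spike-generating
#' fast sodium (NaF) and delayed-rectifier potassium (KDR) currents, a
#' persistent sodium current (NaP), and a slow M-type potassium current (Ks);
#' the dendrite carries a high-threshold calcium current (Ca) and a
#' calcium-dependent potassium current (KCa) fed by a first-order
#' intracellular calcium pool.  Conductances are in mS/cm2, potentials in mV,
#' times in ms, capacitance in uF/cm2.
#'
#' The registry is swappable: any entry can be overridden via `...`, and a
#' whole alternative registry can be passed to [pc_cell()].  Defaults are
#' calibrated so that (i) the isolated PC is regular spiking with a
#' subthreshold resonance near 2 Hz, (ii) a dendritic AMPA drive of
#' `g_inp = 0.0015` mS/cm2 at 1000 sp/s elicits somatic spiking, and (iii)
#' the 20 PC / 5 IN control network generates a beta-band natural rhythm;
#' see the methods vignette.
#'
#' @param ... named overrides of individual registry entries.
#' @return Named numeric vector of PC kinetic parameters.
#' @export
pc_kinetics <- function(...) {
  p <- c(
    cm = 1, g_L = 0.006, E_L = -53, g_c = 0.15, p_soma = 0.4,
    g_NaF = 100, g_KDR = 80, g_NaP = 0.003, g_Ks = 0.02,
    g_Ca = 0.1, g_KCa = 1,
    E_Na = 50, E_K = -90, E_Ca = 120,
    naf_shift = 12, naf_h_shift = 12, kdr_shift = 12,
    nap_vhalf = -52, nap_slope = 10,
    ks_vhalf = -50, ks_slope = 7, ks_tau_scale = 1,
    ca_vhalf = -20, ca_slope = 4,
    kca_kd = 10, ca_tau = 15, ca_alpha = 5
  )
  override_params(p, ...)
}

#' Kinetics registry for the fast-spiking interneuron model
#'
#' Single-compartment interneuron (IN) with spike-generating NaF and KDR
#' currents whose kinetics are hyperpolarized relative to the PC and whose
#' sodium inactivation is faster (rates scaled by `phi`), giving
#' fast-spiking behaviour with a higher maximal sustained rate than the PC.
#'
#' @param ... named overrides.
#' @return Named numeric vector of IN kinetic parameters.
#' @export
in_kinetics <- function(...) {
  p <- c(cm = 1, g_L = 0.1, E_L = -65, g_NaF = 35, g_KDR = 9,
         E_Na = 55, E_K = -90, phi = 5)
  override_params(p, ...)
}

override_params <- function(p, ...) {
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  p
}

# channel key -> conductance parameter, per cell model
.pc_channels <- c(NaF = "g_NaF", KDR = "g_KDR", NaP = "g_NaP",
                  Ks = "g_Ks", Ca = "g_Ca", KCa = "g_KCa")
.in_channels <- c(NaF = "g_NaF", KDR = "g_KDR")

#' Cell model constructors
#'
#' Build a PC or IN cell description from a kinetics registry, an optional
#' knockout mask, and an applied current.  Knockouts are named by the
#' standard channel key (`NaF`, `KDR`, `NaP`, `Ks`, `Ca`, `KCa` for the PC;
#' `NaF`, `KDR` for the IN) and zero the corresponding maximal conductance
#' only, leaving all other parameters untouched.
#'
#' @param kinetics named parameter vector from [pc_kinetics()] or
#'   [in_kinetics()].
#' @param knockout character vector of channel names to disable.
#' @param I_app applied (injected) current, uA/cm2, positive depolarizing.
#' @return A list with elements `model`, `params`, `knockout`, `I_app`.
#' @export
pc_cell <- function(kinetics = pc_kinetics(), knockout = character(),
                    I_app = 0) {
  make_cell("pc", kinetics, knockout, I_app, .pc_channels)
}

#' @rdname pc_cell
#' @export
in_cell <- function(kinetics = in_kinetics(), knockout = character(),
                    I_app = 0) {
  make_cell("in", kinetics, knockout, I_app, .in_channels)
}

make_cell <- function(model, kinetics, knockout, I_app, channels) {
  bad <- setdiff(knockout, names(channels))
  if (length(bad))
    stop("unknown current name(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(names(channels), collapse = ", "), ")")
  params <- kinetics
  params[channels[knockout]] <- 0
  list(model = model, params = params, knockout = knockout, I_app = I_app)
}

#' Membrane equation right-hand side
#'
#' Time-derivative of the membrane state under the conductance-based
#' framework: \eqn{C_m dV/dt = -I_{inp} - \sum I_{int} - \sum I_{syn} +
#' I_{app}} per compartment, with gating-variable and calcium derivatives
#' given by the cell's kinetics.  Input currents follow the outward-positive
#' convention \eqn{I = g s (V - E)}.
#'
#' @param cell a cell from [pc_cell()] or [in_cell()].
#' @param state named numeric state: `c(Vs, Vd, h, n, q, ca)` for a PC,
#'   `c(V, h, n)` for an IN.
#' @param I_inp exogenous input current (uA/cm2, outward positive); applied
#'   to the dendrite of a PC and the soma of an IN.
#' @param I_syn synaptic current (uA/cm2, outward positive), applied to the
#'   soma.
#' @return Named numeric vector of state derivatives (per ms).
#' @export
membrane_rhs <- function(cell, state, I_inp = 0, I_syn = 0) {
  if (any(!is.finite(state)))
    stop("non-finite membrane state: ",
         paste(sprintf("%s=%g", names(state), state), collapse = ", "))
  if (cell$model == "pc") {
    stopifnot(length(state) == 6)
    .pc_rhs_cpp(unname(state), cell$params, cell$I_app, I_syn, I_inp)
  } else {
    stopifnot(length(state) == 3)
    .in_rhs_cpp(unname(state), cell$params, cell$I_app, I_inp + I_syn)
  }
}

#' Resting state of a cell model
#'
#' Gating variables at their voltage steady state for a given membrane
#' potential; used to initialize simulations.
#'
#' @param cell a cell from [pc_cell()] or [in_cell()].
#' @param V initial potential (mV).
#' @return Named numeric state vector.
#' @export
cell_init_state <- function(cell, V = cell$params[["E_L"]]) {
  if (cell$model == "pc") {
    Vh <- V - cell$params[["naf_h_shift"]]
    Vn <- V - cell$params[["kdr_shift"]]
    ah <- 0.128 * exp(-(Vh + 50) / 18)
    bh <- 4 / (1 + exp(-(Vh + 27) / 5))
    an <- 0.032 * linoid_r(Vn + 52, 5)
    bn <- 0.5 * exp(-(Vn + 57) / 40)
    q <- 1 / (1 + exp(-(V - cell$params[["ks_vhalf"]]) /
                        cell$params[["ks_slope"]]))
    c(Vs = V, Vd = V, h = ah / (ah + bh), n = an / (an + bn), q = q,
      ca = 0.05)
  } else {
    ah <- 0.07 * exp(-(V + 58) / 20)
    bh <- 1 / (1 + exp(-(V + 28) / 10))
    an <- 0.01 * linoid_r(V + 34, 10)
    bn <- 0.125 * exp(-(V + 44) / 80)
    c(V = V, h = ah / (ah + bh), n = an / (an + bn))
  }
}

linoid_r <- function(x, k) ifelse(abs(x) < 1e-6, k, x / (1 - exp(-x / k)))

#' Synaptic gating and current primitives
#'
#' First-order kinetic synapse: the gating variable obeys
#' \eqn{ds/dt = H(V_{pre})(1-s)/\tau_r - s/\tau_d} with
#' \eqn{H(V) = 1 + \tanh(V/4)} a sigmoidal approximation to the Heaviside
#' function, and the current is \eqn{I = g s (V_{post} - E)}.
#'
#' @param s gating variable in `[0, 1]`.
#' @param V_pre presynaptic membrane potential (mV).
#' @param tau_r,tau_d rise and decay time constants (ms).
#' @return `syn_gate_rhs`: ds/dt (per ms); `syn_current`: current (uA/cm2,
#'   outward positive); `syn_H`: the release sigmoid.
#' @export
syn_gate_rhs <- function(s, V_pre, tau_r = 0.4, tau_d = 2) {
  stopifnot(tau_r > 0, tau_d > 0)
  syn_H(V_pre) * (1 - s) / tau_r - s / tau_d
}

#' @rdname syn_gate_rhs
#' @param V_post postsynaptic membrane potential (mV).
#' @param g_syn maximal conductance (mS/cm2).
#' @param E_syn reversal potential (mV).
#' @export
syn_current <- function(s, V_post, g_syn, E_syn) {
  g_syn * s * (V_post - E_syn)
}

#' @rdname syn_gate_rhs
#' @param V membrane potential (mV).
#' @export
syn_H <- function(V) 1 + tanh(V / 4)

#' Standard synapse parameter sets
#'
#' AMPA: \eqn{E = 0} mV, \eqn{\tau_r = 0.4} ms, \eqn{\tau_d = 2} ms.
#' GABA-A: \eqn{E = -75} mV, \eqn{\tau_r = 0.4} ms, \eqn{\tau_d = 5} ms.
#'
#' @param g maximal conductance (mS/cm2), shared across the all-to-all block
#'   and normalized by the number of source cells.
#' @param tau_d decay time constant (ms); the GABA-A decay sets the duration
#'   of feedback inhibition and hence the natural rhythm period.
#' @return A list of synapse parameters.
#' @export
ampa_synapse <- function(g = 1, tau_d = 2) {
  list(g = g, E = 0, tau_r = 0.4, tau_d = tau_d)
}

#' @rdname ampa_synapse
#' @export
gaba_synapse <- function(g = 0.1, tau_d = 5) {
  list(g = g, E = -75, tau_r = 0.4, tau_d = tau_d)
}

#' Leaky integrate-and-fire parameter set
#'
#' Parameters of the LIF control network: leak `g_l = 0.1`, rest and reset
#' at -65 mV, 3 ms refractory hold; double-exponential
#' synaptic conductances (onto PCs: inhibitory, g = 0.1, E = -80 mV, 2 ms
#' decay, 0.4 ms rise; onto INs: excitatory, g = 0.03, E = 0 mV, 10 ms
#' decay, 0.2 ms rise); input couplings `g_inp = 0.00375`,
#' `g_noise = 0.0056` mS/cm2.
#'
#' The dynamical spike threshold defaults to -58 mV: with these input
#' couplings the drive saturates roughly 10 mV above rest, so a 0 mV
#' threshold (the spike-detection level used when plotting full spike
#' waveforms) can never be reached by the subthreshold dynamics; -58 mV
#' places the network in the regime where pulse packets recruit cells and
#' feedback inhibition paces a natural rhythm.  Override via `cell`.
#'
#' @param ... named overrides of top-level entries.
#' @return A list of LIF cell, synapse, and input-coupling parameters.
#' @export
lif_params <- function(...) {
  p <- list(
    cell = list(g_l = 0.1, E_l = -65, v_thresh = -58, v_reset = -65,
                t_ref = 3),
    syn_onto_pc = list(g = 0.1, E = -80, tau_r = 0.4, tau_d = 2),
    syn_onto_in = list(g = 0.03, E = 0, tau_r = 0.2, tau_d = 10),
    g_inp = 0.00375, g_noise = 0.0056
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  stopifnot(p$cell$v_reset <= p$cell$E_l, p$cell$E_l < p$cell$v_thresh)
  p
}
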