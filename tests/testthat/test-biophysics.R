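test_that("synaptic gate follows the first-order kinetic scheme", {
  # H(0) = 1 + tanh(0) = 1: ds/dt = (1 - 0)/0.4 = 2.5 per ms
  expect_equal(syn_gate_rhs(0, 0, tau_r = 0.4, tau_d = 2), 2.5)
  # hyperpolarized presynaptic cell: pure decay (H(-80) ~ 0)
  expect_equal(syn_gate_rhs(0.6, -80, tau_r = 0.4, tau_d = 2), -0.3,
               tolerance = 1e-6)
  # equilibrium under sustained release H = 2: s* = H tau_d/(H tau_d + tau_r)
  s_star <- 4 / 4.4
  expect_equal(syn_gate_rhs(s_star, 1e6, tau_r = 0.4, tau_d = 2), 0,
               tolerance = 1e-9)
  expect_equal(syn_H(0), 1)
})

test_that("gating variable stays in [0, 1) for bounded presynaptic input", {
  # forward-Euler integration of the gate under erratic bounded V_pre
  set.seed(3)
  s <- 0
  v <- runif(5000, -90, 60)
  trace <- vapply(v, function(vi) {
    s <<- s + 0.01 * syn_gate_rhs(s, vi)
    s
  }, numeric(1))
  expect_true(all(trace >= 0 & trace < 1))
})

test_that("synaptic current follows g s (V - E)", {
  expect_equal(syn_current(0, -60, 1, 0), 0)
  expect_equal(syn_current(0.7, 0, 1, 0), 0)   # at reversal
  expect_equal(syn_current(0.5, -75, 1, 0), -37.5)
})

test_that("membrane equation has the stated sign convention", {
  # fully passive cell: all channels knocked out, V displaced from E_L
  cell <- pc_cell(pc_kinetics(g_L = 0.05, g_c = 0),
                  knockout = c("NaF", "KDR", "NaP", "Ks", "Ca", "KCa"))
  st <- cell_init_state(cell, V = -53)
  st["ca"] <- 0
  d0 <- membrane_rhs(cell, st)
  expect_equal(unname(d0[["Vs"]]), 0, tolerance = 1e-9)  # at rest
  # constant outward current I: dV/dt = -I / Cm
  d1 <- membrane_rhs(cell, st, I_syn = 2)
  expect_equal(unname(d1[["Vs"]]) - d0[["Vs"]], -2, tolerance = 1e-9)
  # displaced: dV/dt = -g_L (V - E_L)
  st2 <- st
  st2["Vs"] <- -43
  d2 <- membrane_rhs(cell, st2)
  expect_equal(unname(d2[["Vs"]]),
               -0.05 * (-43 - (-53)) - 0.3 * 0, tolerance = 1e-6)
  expect_error(membrane_rhs(cell, replace(st, 1, NaN)), "non-finite")
})

test_that("knocked-out cell relaxes like the passive RC oracle", {
  # simulate a single fully-knocked-out PC from a displaced voltage with no
  # input; compare against V(t) = E_L + (V0 - E_L) exp(-t g_L / Cm)
  kin <- pc_kinetics(g_L = 0.05, g_c = 0)
  cell <- pc_cell(kin, knockout = c("NaF", "KDR", "NaP", "Ks", "Ca", "KCa"))
  spec <- single_pc_network(pc = cell, background_rate = 0)
  spec$init_jitter <- 0
  sim <- build_network(spec)
  raw <- integrate_network(sim, streams = list(), duration = 100,
                           v_init = -33)
  tau <- 1 / 0.05   # Cm / g_L = 20 ms
  expected <- -53 + (-33 - (-53)) * exp(-raw$v_time / tau)
  expect_lt(max(abs(raw$v[, 1] - expected)), 0.05)
})

test_that("knockout masks zero only the named conductance", {
  cell <- pc_cell(knockout = "NaP")
  expect_equal(unname(cell$params[["g_NaP"]]), 0)
  ref <- pc_kinetics()
  same <- setdiff(names(ref), "g_NaP")
  expect_equal(cell$params[same], ref[same])
  expect_error(pc_cell(knockout = "Ih"), "unknown current")
  expect_error(in_cell(knockout = "NaP"), "unknown current")
})

test_that("interneuron is fast-spiking with a higher maximal rate than PC", {
  count_spikes <- function(cell_kind, I) {
    spec <- if (cell_kind == "pc") {
      single_pc_network(pc = pc_cell(I_app = I), background_rate = 0)
    } else {
      s <- single_pc_network(background_rate = 0)
      s$populations$PC <- list(model = "in", n = 1L,
                               params = in_kinetics(), I_app = I)
      s
    }
    spec$init_jitter <- 0
    raw <- integrate_network(build_network(spec), streams = list(),
                             duration = 500)
    length(raw$spikes[[1]]$t)
  }
  r_in <- count_spikes("in", 2)
  r_pc <- count_spikes("pc", 2)
  expect_gt(r_in, r_pc)
  expect_gt(r_in, 25)   # > 50 sp/s sustained: fast spiking
})

test_that("LIF parameter invariants hold and are validated", {
  p <- lif_params()
  expect_true(p$cell$v_reset <= p$cell$E_l)
  expect_lt(p$cell$E_l, p$cell$v_thresh)
  expect_error(lif_params(cell = list(g_l = 0.1, E_l = -65, v_thresh = -70,
                                      v_reset = -65, t_ref = 3)))
})
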