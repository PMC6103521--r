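// Fixed-step network integration engine.
//
// Hodgkin-Huxley network: two-compartment principal cells (PC) and
// single-compartment fast-spiking interneurons (IN) coupled all-to-all by
// first-order kinetic synapses, driven by exogenous Poisson spike trains
// integrated into exponentially-decaying conductance gates.  Integration is
// 4th-order Runge-Kutta with a fixed time step; exogenous input gates are
// held piecewise-constant within a step.
//
// A leaky integrate-and-fire network with double-exponential synaptic
// conductances is provided as a separate event-based update on the same
// fixed grid.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

static inline double linoid(double x, double k) {
  // x / (1 - exp(-x/k)), continuous at x = 0
  if (std::fabs(x) < 1e-6) return k;
  return x / (1.0 - std::exp(-x / k));
}

// ---------------------------------------------------------------------------
// Cell models
// ---------------------------------------------------------------------------

struct PCParams {
  double cm, g_L, E_L, g_c, p_soma;
  double g_NaF, g_KDR, g_NaP, g_Ks, g_Ca, g_KCa;
  double E_Na, E_K, E_Ca;
  double naf_shift, naf_h_shift, kdr_shift;
  double nap_vhalf, nap_slope;
  double ks_vhalf, ks_slope, ks_tau_scale;
  double ca_vhalf, ca_slope;
  double kca_kd, ca_tau, ca_alpha;
  double I_app;
};

struct INParams {
  double cm, g_L, E_L, g_NaF, g_KDR, E_Na, E_K, phi, I_app;
};

static PCParams parse_pc(const NumericVector& p, double I_app) {
  PCParams P;
  P.cm = p["cm"]; P.g_L = p["g_L"]; P.E_L = p["E_L"];
  P.g_c = p["g_c"]; P.p_soma = p["p_soma"];
  P.g_NaF = p["g_NaF"]; P.g_KDR = p["g_KDR"]; P.g_NaP = p["g_NaP"];
  P.g_Ks = p["g_Ks"]; P.g_Ca = p["g_Ca"]; P.g_KCa = p["g_KCa"];
  P.E_Na = p["E_Na"]; P.E_K = p["E_K"]; P.E_Ca = p["E_Ca"];
  P.naf_shift = p["naf_shift"]; P.naf_h_shift = p["naf_h_shift"];
  P.kdr_shift = p["kdr_shift"];
  P.nap_vhalf = p["nap_vhalf"]; P.nap_slope = p["nap_slope"];
  P.ks_vhalf = p["ks_vhalf"]; P.ks_slope = p["ks_slope"];
  P.ks_tau_scale = p["ks_tau_scale"];
  P.ca_vhalf = p["ca_vhalf"]; P.ca_slope = p["ca_slope"];
  P.kca_kd = p["kca_kd"]; P.ca_tau = p["ca_tau"]; P.ca_alpha = p["ca_alpha"];
  P.I_app = I_app;
  return P;
}

static INParams parse_in(const NumericVector& p, double I_app) {
  INParams P;
  P.cm = p["cm"]; P.g_L = p["g_L"]; P.E_L = p["E_L"];
  P.g_NaF = p["g_NaF"]; P.g_KDR = p["g_KDR"];
  P.E_Na = p["E_Na"]; P.E_K = p["E_K"]; P.phi = p["phi"];
  P.I_app = I_app;
  return P;
}

// PC state: [Vs, Vd, h, n, q, ca]; I_ext_* are outward-positive current
// densities added to each compartment (synaptic + input).
static const int PC_DIM = 6;
static inline void pc_rhs(const PCParams& P, const double* y, double* dy,
                          double I_ext_soma, double I_ext_dend) {
  const double Vs = y[0], Vd = y[1], h = y[2], n = y[3], q = y[4],
               ca = y[5];
  // fast sodium (activation instantaneous); spike-current kinetics are
  // shifted depolarized so the subthreshold range is window-current free
  const double Vm = Vs - P.naf_shift, Vn = Vs - P.kdr_shift;
  const double Vh = Vs - P.naf_h_shift;
  double am = 0.32 * linoid(Vm + 54.0, 4.0);
  double bm = 0.28 * linoid(-(Vm + 27.0), 5.0);
  double minf = am / (am + bm);
  double ah = 0.128 * std::exp(-(Vh + 50.0) / 18.0);
  double bh = 4.0 / (1.0 + std::exp(-(Vh + 27.0) / 5.0));
  double an = 0.032 * linoid(Vn + 52.0, 5.0);
  double bn = 0.5 * std::exp(-(Vn + 57.0) / 40.0);
  double I_NaF = P.g_NaF * minf * minf * minf * h * (Vs - P.E_Na);
  double I_KDR = P.g_KDR * n * n * n * n * (Vs - P.E_K);
  // persistent sodium (instantaneous)
  double pinf = 1.0 / (1.0 + std::exp(-(Vs - P.nap_vhalf) / P.nap_slope));
  double I_NaP = P.g_NaP * pinf * (Vs - P.E_Na);
  // slow (M-type) potassium
  double qinf = 1.0 / (1.0 + std::exp(-(Vs - P.ks_vhalf) / P.ks_slope));
  double tq = P.ks_tau_scale * 1000.0 /
    (3.3 * (std::exp((Vs + 35.0) / 20.0) + std::exp(-(Vs + 35.0) / 20.0)));
  double I_Ks = P.g_Ks * q * (Vs - P.E_K);
  // high-threshold calcium (somatic, spike-gated, activation instantaneous)
  double uinf = 1.0 / (1.0 + std::exp(-(Vs - P.ca_vhalf) / P.ca_slope));
  double I_Ca = P.g_Ca * uinf * uinf * (Vs - P.E_Ca);
  // calcium-dependent potassium (somatic; saturating activation gives a
  // hold-then-release AHP that sets the post-volley refractory wall)
  double I_KCa = P.g_KCa * (ca / (ca + P.kca_kd)) * (Vs - P.E_K);

  double I_c_s = (P.g_c / P.p_soma) * (Vs - Vd);
  double I_c_d = (P.g_c / (1.0 - P.p_soma)) * (Vd - Vs);

  dy[0] = (-(P.g_L * (Vs - P.E_L) + I_NaF + I_KDR + I_NaP + I_Ks + I_Ca +
             I_KCa) - I_c_s - I_ext_soma + P.I_app) / P.cm;
  dy[1] = (-(P.g_L * (Vd - P.E_L)) - I_c_d - I_ext_dend) / P.cm;
  dy[2] = ah * (1.0 - h) - bh * h;
  dy[3] = an * (1.0 - n) - bn * n;
  dy[4] = (qinf - q) / tq;
  dy[5] = -P.ca_alpha * I_Ca - ca / P.ca_tau;
}

static inline void pc_init(const PCParams& P, double V, double* y) {
  y[0] = V; y[1] = V;
  const double Vh = V - P.naf_h_shift, Vn = V - P.kdr_shift;
  double ah = 0.128 * std::exp(-(Vh + 50.0) / 18.0);
  double bh = 4.0 / (1.0 + std::exp(-(Vh + 27.0) / 5.0));
  double an = 0.032 * linoid(Vn + 52.0, 5.0);
  double bn = 0.5 * std::exp(-(Vn + 57.0) / 40.0);
  y[2] = ah / (ah + bh);
  y[3] = an / (an + bn);
  y[4] = 1.0 / (1.0 + std::exp(-(V - P.ks_vhalf) / P.ks_slope));
  y[5] = 0.05;
}

// IN state: [V, h, n]  (Wang-Buzsaki style fast-spiking kinetics:
// hyperpolarized relative to the PC, fast sodium inactivation)
static const int IN_DIM = 3;
static inline void in_rhs(const INParams& P, const double* y, double* dy,
                          double I_ext) {
  const double V = y[0], h = y[1], n = y[2];
  double am = 0.1 * linoid(V + 35.0, 10.0);
  double bm = 4.0 * std::exp(-(V + 60.0) / 18.0);
  double minf = am / (am + bm);
  double ah = 0.07 * std::exp(-(V + 58.0) / 20.0);
  double bh = 1.0 / (1.0 + std::exp(-(V + 28.0) / 10.0));
  double an = 0.01 * linoid(V + 34.0, 10.0);
  double bn = 0.125 * std::exp(-(V + 44.0) / 80.0);
  double I_NaF = P.g_NaF * minf * minf * minf * h * (V - P.E_Na);
  double I_KDR = P.g_KDR * n * n * n * n * (V - P.E_K);
  dy[0] = (-(P.g_L * (V - P.E_L) + I_NaF + I_KDR) - I_ext + P.I_app) / P.cm;
  dy[1] = P.phi * (ah * (1.0 - h) - bh * h);
  dy[2] = P.phi * (an * (1.0 - n) - bn * n);
}

static inline void in_init(const INParams& P, double V, double* y) {
  y[0] = V;
  double ah = 0.07 * std::exp(-(V + 58.0) / 20.0);
  double bh = 1.0 / (1.0 + std::exp(-(V + 28.0) / 10.0));
  double an = 0.01 * linoid(V + 34.0, 10.0);
  double bn = 0.125 * std::exp(-(V + 44.0) / 80.0);
  y[1] = ah / (ah + bh);
  y[2] = an / (an + bn);
}

// sigmoidal approximation to the Heaviside function driving synaptic release
static inline double H_rel(double V) { return 1.0 + std::tanh(V / 4.0); }

// ---------------------------------------------------------------------------
// Exposed single-cell right-hand sides (for oracle tests and membrane_rhs)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".pc_rhs_cpp")]]
NumericVector pc_rhs_cpp(NumericVector state, NumericVector params,
                         double I_app, double I_ext_soma, double I_ext_dend) {
  PCParams P = parse_pc(params, I_app);
  double y[PC_DIM], dy[PC_DIM];
  for (int i = 0; i < PC_DIM; i++) y[i] = state[i];
  pc_rhs(P, y, dy, I_ext_soma, I_ext_dend);
  NumericVector out(PC_DIM);
  for (int i = 0; i < PC_DIM; i++) out[i] = dy[i];
  out.names() = CharacterVector::create("Vs", "Vd", "h", "n", "q", "ca");
  return out;
}

// [[Rcpp::export(name = ".in_rhs_cpp")]]
NumericVector in_rhs_cpp(NumericVector state, NumericVector params,
                         double I_app, double I_ext) {
  INParams P = parse_in(params, I_app);
  double y[IN_DIM], dy[IN_DIM];
  for (int i = 0; i < IN_DIM; i++) y[i] = state[i];
  in_rhs(P, y, dy, I_ext);
  NumericVector out(IN_DIM);
  for (int i = 0; i < IN_DIM; i++) out[i] = dy[i];
  out.names() = CharacterVector::create("V", "h", "n");
  return out;
}

// ---------------------------------------------------------------------------
// HH network simulator
// ---------------------------------------------------------------------------

struct Stream {       // exogenous Poisson drive, single-exponential gate
  int dst_pop, target;              // target: 0 soma, 1 dendrite
  double g, E, decay;               // decay factor exp(-dt/tau) per step
  std::vector<double> t_spk;
  std::vector<int> cell;            // 0-based target cell within pop
  std::vector<double> s;            // gate per target cell
  size_t ptr;
};

struct Block {        // all-to-all chemical synapse block
  int src_pop, dst_pop, target;
  double g_per, E, tau_r, tau_d;    // g_per = g / n_src
};

// [[Rcpp::export(name = ".sim_hh_network")]]
List sim_hh_network(List pops, List conns, List streams_in, double duration,
                    double dt, double rec_dt, NumericVector v_init,
                    double spike_thresh = 0.0, double spike_refrac = 2.0) {
  int n_pops = pops.size();
  std::vector<int> pop_model(n_pops), pop_n(n_pops), pop_dim(n_pops),
      pop_off(n_pops), cell_off(n_pops);
  std::vector<PCParams> pcp(n_pops);
  std::vector<INParams> inp(n_pops);

  int state_len = 0, n_cells = 0;
  for (int p = 0; p < n_pops; p++) {
    List pop = pops[p];
    std::string model = as<std::string>(pop["model"]);
    int n = as<int>(pop["n"]);
    double I_app = as<double>(pop["I_app"]);
    NumericVector pars = pop["params"];
    pop_n[p] = n;
    pop_off[p] = state_len;
    cell_off[p] = n_cells;
    if (model == "pc") {
      pop_model[p] = 0; pop_dim[p] = PC_DIM; pcp[p] = parse_pc(pars, I_app);
    } else if (model == "in") {
      pop_model[p] = 1; pop_dim[p] = IN_DIM; inp[p] = parse_in(pars, I_app);
    } else {
      stop("unknown cell model: " + model);
    }
    state_len += n * pop_dim[p];
    n_cells += n;
  }

  // synapse blocks: one gate per source cell per block, appended to state
  int n_blocks = conns.size();
  std::vector<Block> blocks(n_blocks);
  std::vector<int> gate_off(n_blocks);
  for (int b = 0; b < n_blocks; b++) {
    List cn = conns[b];
    Block B;
    B.src_pop = as<int>(cn["src"]); B.dst_pop = as<int>(cn["dst"]);
    B.target = as<int>(cn["target"]);
    B.g_per = as<double>(cn["g_per"]);   // per-source-cell conductance
    B.E = as<double>(cn["E"]);
    B.tau_r = as<double>(cn["tau_r"]); B.tau_d = as<double>(cn["tau_d"]);
    blocks[b] = B;
    gate_off[b] = state_len;
    state_len += pop_n[B.src_pop];
  }

  // exogenous input streams
  int n_streams = streams_in.size();
  std::vector<Stream> streams(n_streams);
  for (int s = 0; s < n_streams; s++) {
    List st = streams_in[s];
    Stream S;
    S.dst_pop = as<int>(st["dst"]); S.target = as<int>(st["target"]);
    S.g = as<double>(st["g"]); S.E = as<double>(st["E"]);
    double tau = as<double>(st["tau_d"]);
    S.decay = std::exp(-dt / tau);
    S.t_spk = as<std::vector<double> >(st["times"]);
    IntegerVector cl = st["cells"];
    S.cell.assign(cl.begin(), cl.end());
    for (size_t i = 0; i < S.cell.size(); i++) S.cell[i] -= 1;
    S.s.assign(pop_n[S.dst_pop], 0.0);
    S.ptr = 0;
    streams[s] = S;
  }

  // initial state
  std::vector<double> y(state_len, 0.0);
  for (int p = 0; p < n_pops; p++) {
    for (int c = 0; c < pop_n[p]; c++) {
      double* yc = &y[pop_off[p] + c * pop_dim[p]];
      double V = v_init[cell_off[p] + c];
      if (pop_model[p] == 0) pc_init(pcp[p], V, yc);
      else in_init(inp[p], V, yc);
    }
  }

  int n_steps = (int)std::lround(duration / dt);
  int rec_every = std::max(1, (int)std::lround(rec_dt / dt));
  int n_rec = n_steps / rec_every + 1;
  NumericMatrix v_out(n_rec, n_cells);
  NumericVector v_time(n_rec);

  std::vector<std::vector<double> > spk_t(n_pops);
  std::vector<std::vector<int> > spk_c(n_pops);
  std::vector<double> last_spk(n_cells, -1e9);
  std::vector<double> prev_V(n_cells);

  std::vector<double> k1(state_len), k2(state_len), k3(state_len),
      k4(state_len), yt(state_len);
  std::vector<double> ext_s(n_cells), ext_d(n_cells);  // per-stage currents
  std::vector<double> gsum(n_blocks);

  bool diverged = false;
  double t_div = NA_REAL;
  int rec_i = 0;

  // right-hand side over the full state vector
  auto rhs = [&](const std::vector<double>& yy, std::vector<double>& dyy) {
    // per-block summed gates
    for (int b = 0; b < n_blocks; b++) {
      const Block& B = blocks[b];
      double sum = 0.0;
      const double* g = &yy[gate_off[b]];
      for (int i = 0; i < pop_n[B.src_pop]; i++) sum += g[i];
      gsum[b] = sum;
    }
    // external currents per cell/compartment (stream gates held constant)
    std::fill(ext_s.begin(), ext_s.end(), 0.0);
    std::fill(ext_d.begin(), ext_d.end(), 0.0);
    for (int s = 0; s < n_streams; s++) {
      const Stream& S = streams[s];
      int off = cell_off[S.dst_pop];
      int dim = pop_dim[S.dst_pop];
      int yoff = pop_off[S.dst_pop];
      bool dend = (S.target == 1) && (pop_model[S.dst_pop] == 0);
      for (int c = 0; c < pop_n[S.dst_pop]; c++) {
        double V = dend ? yy[yoff + c * dim + 1] : yy[yoff + c * dim];
        double I = S.g * S.s[c] * (V - S.E);
        if (dend) ext_d[off + c] += I; else ext_s[off + c] += I;
      }
    }
    // synaptic currents
    for (int b = 0; b < n_blocks; b++) {
      const Block& B = blocks[b];
      int off = cell_off[B.dst_pop];
      int dim = pop_dim[B.dst_pop];
      int yoff = pop_off[B.dst_pop];
      bool dend = (B.target == 1) && (pop_model[B.dst_pop] == 0);
      double gtot = B.g_per * gsum[b];
      for (int c = 0; c < pop_n[B.dst_pop]; c++) {
        double V = dend ? yy[yoff + c * dim + 1] : yy[yoff + c * dim];
        double I = gtot * (V - B.E);
        if (dend) ext_d[off + c] += I; else ext_s[off + c] += I;
      }
    }
    // cell dynamics
    for (int p = 0; p < n_pops; p++) {
      int dim = pop_dim[p];
      for (int c = 0; c < pop_n[p]; c++) {
        const double* yc = &yy[pop_off[p] + c * dim];
        double* dyc = &dyy[pop_off[p] + c * dim];
        int gc = cell_off[p] + c;
        if (pop_model[p] == 0) pc_rhs(pcp[p], yc, dyc, ext_s[gc], ext_d[gc]);
        else in_rhs(inp[p], yc, dyc, ext_s[gc]);
      }
    }
    // synaptic gate dynamics (driven by presynaptic somatic voltage)
    for (int b = 0; b < n_blocks; b++) {
      const Block& B = blocks[b];
      int dim = pop_dim[B.src_pop];
      for (int i = 0; i < pop_n[B.src_pop]; i++) {
        double Vpre = yy[pop_off[B.src_pop] + i * dim];
        double sg = yy[gate_off[b] + i];
        dyy[gate_off[b] + i] =
            H_rel(Vpre) * (1.0 - sg) / B.tau_r - sg / B.tau_d;
      }
    }
  };

  // record initial
  for (int p = 0; p < n_pops; p++)
    for (int c = 0; c < pop_n[p]; c++) {
      double V = y[pop_off[p] + c * pop_dim[p]];
      v_out(0, cell_off[p] + c) = V;
      prev_V[cell_off[p] + c] = V;
    }
  v_time[0] = 0.0;
  rec_i = 1;

  for (int step = 0; step < n_steps; step++) {
    double t = step * dt;
    // deliver exogenous spikes falling in [t, t+dt)
    for (int s = 0; s < n_streams; s++) {
      Stream& S = streams[s];
      while (S.ptr < S.t_spk.size() && S.t_spk[S.ptr] < t + dt) {
        S.s[S.cell[S.ptr]] += 1.0;
        S.ptr++;
      }
    }

    rhs(y, k1);
    for (int i = 0; i < state_len; i++) yt[i] = y[i] + 0.5 * dt * k1[i];
    rhs(yt, k2);
    for (int i = 0; i < state_len; i++) yt[i] = y[i] + 0.5 * dt * k2[i];
    rhs(yt, k3);
    for (int i = 0; i < state_len; i++) yt[i] = y[i] + dt * k3[i];
    rhs(yt, k4);
    for (int i = 0; i < state_len; i++)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);

    // decay exogenous gates to end of step
    for (int s = 0; s < n_streams; s++) {
      Stream& S = streams[s];
      for (size_t c = 0; c < S.s.size(); c++) S.s[c] *= S.decay;
    }

    double t_now = t + dt;
    // spike detection: upward crossing of threshold at the soma
    for (int p = 0; p < n_pops; p++) {
      int dim = pop_dim[p];
      for (int c = 0; c < pop_n[p]; c++) {
        int gc = cell_off[p] + c;
        double V = y[pop_off[p] + c * dim];
        if (prev_V[gc] < spike_thresh && V >= spike_thresh &&
            t_now - last_spk[gc] >= spike_refrac) {
          spk_t[p].push_back(t_now);
          spk_c[p].push_back(c + 1);
          last_spk[gc] = t_now;
        }
        prev_V[gc] = V;
      }
    }

    if ((step + 1) % rec_every == 0 && rec_i < n_rec) {
      for (int p = 0; p < n_pops; p++)
        for (int c = 0; c < pop_n[p]; c++)
          v_out(rec_i, cell_off[p] + c) = y[pop_off[p] + c * pop_dim[p]];
      v_time[rec_i] = t_now;
      rec_i++;
    }

    if ((step & 127) == 0) {
      for (int gc = 0; gc < n_cells; gc++)
        if (!std::isfinite(prev_V[gc]) || std::fabs(prev_V[gc]) > 200.0) {
          diverged = true; t_div = t_now; break;
        }
      if (diverged) break;
    }
  }

  List spikes(n_pops);
  for (int p = 0; p < n_pops; p++)
    spikes[p] = List::create(_["t"] = wrap(spk_t[p]),
                             _["cell"] = wrap(spk_c[p]));

  return List::create(_["spikes"] = spikes, _["v"] = v_out,
                      _["v_time"] = v_time, _["diverged"] = diverged,
                      _["t_diverged"] = t_div);
}

// ---------------------------------------------------------------------------
// LIF network simulator (event-based update on the fixed grid)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".sim_lif_network")]]
List sim_lif_network(List pops, List conns, List streams_in, double duration,
                     double dt, double rec_dt, NumericVector v_init) {
  int n_pops = pops.size();
  std::vector<int> pop_n(n_pops), cell_off(n_pops);
  std::vector<double> g_l(n_pops), E_l(n_pops), v_th(n_pops), v_re(n_pops),
      t_ref(n_pops);
  int n_cells = 0;
  for (int p = 0; p < n_pops; p++) {
    List pop = pops[p];
    pop_n[p] = as<int>(pop["n"]);
    cell_off[p] = n_cells;
    n_cells += pop_n[p];
    g_l[p] = as<double>(pop["g_l"]); E_l[p] = as<double>(pop["E_l"]);
    v_th[p] = as<double>(pop["v_thresh"]); v_re[p] = as<double>(pop["v_reset"]);
    t_ref[p] = as<double>(pop["t_ref"]);
  }

  // double-exponential synapse blocks; two decaying states per source cell
  int n_blocks = conns.size();
  std::vector<Block> blocks(n_blocks);
  std::vector<std::vector<double> > A(n_blocks), B2(n_blocks);
  std::vector<double> decA(n_blocks), decB(n_blocks), norm(n_blocks);
  for (int b = 0; b < n_blocks; b++) {
    List cn = conns[b];
    Block Bk;
    Bk.src_pop = as<int>(cn["src"]); Bk.dst_pop = as<int>(cn["dst"]);
    Bk.g_per = as<double>(cn["g_per"]);
    Bk.E = as<double>(cn["E"]);
    Bk.tau_r = as<double>(cn["tau_r"]); Bk.tau_d = as<double>(cn["tau_d"]);
    blocks[b] = Bk;
    A[b].assign(pop_n[Bk.src_pop], 0.0);
    B2[b].assign(pop_n[Bk.src_pop], 0.0);
    decA[b] = std::exp(-dt / Bk.tau_d);
    decB[b] = std::exp(-dt / Bk.tau_r);
    double tr = Bk.tau_r, td = Bk.tau_d;
    double tp = (td * tr / (td - tr)) * std::log(td / tr);
    norm[b] = 1.0 / (std::exp(-tp / td) - std::exp(-tp / tr));
  }

  int n_streams = streams_in.size();
  std::vector<Stream> streams(n_streams);
  for (int s = 0; s < n_streams; s++) {
    List st = streams_in[s];
    Stream S;
    S.dst_pop = as<int>(st["dst"]); S.target = 0;
    S.g = as<double>(st["g"]); S.E = as<double>(st["E"]);
    S.decay = std::exp(-dt / as<double>(st["tau_d"]));
    S.t_spk = as<std::vector<double> >(st["times"]);
    IntegerVector cl = st["cells"];
    S.cell.assign(cl.begin(), cl.end());
    for (size_t i = 0; i < S.cell.size(); i++) S.cell[i] -= 1;
    S.s.assign(pop_n[S.dst_pop], 0.0);
    S.ptr = 0;
    streams[s] = S;
  }

  std::vector<double> V(n_cells);
  for (int i = 0; i < n_cells; i++) V[i] = v_init[i];
  std::vector<double> ref_until(n_cells, -1.0);

  int n_steps = (int)std::lround(duration / dt);
  int rec_every = std::max(1, (int)std::lround(rec_dt / dt));
  int n_rec = n_steps / rec_every + 1;
  NumericMatrix v_out(n_rec, n_cells);
  NumericVector v_time(n_rec);
  for (int i = 0; i < n_cells; i++) v_out(0, i) = V[i];
  v_time[0] = 0.0;
  int rec_i = 1;

  std::vector<std::vector<double> > spk_t(n_pops);
  std::vector<std::vector<int> > spk_c(n_pops);
  std::vector<double> gsum(n_blocks);

  for (int step = 0; step < n_steps; step++) {
    double t = step * dt;
    for (int s = 0; s < n_streams; s++) {
      Stream& S = streams[s];
      while (S.ptr < S.t_spk.size() && S.t_spk[S.ptr] < t + dt) {
        S.s[S.cell[S.ptr]] += 1.0;
        S.ptr++;
      }
    }
    for (int b = 0; b < n_blocks; b++) {
      double sum = 0.0;
      for (size_t i = 0; i < A[b].size(); i++) sum += A[b][i] - B2[b][i];
      gsum[b] = norm[b] * sum;
    }

    double t_now = t + dt;
    for (int p = 0; p < n_pops; p++) {
      for (int c = 0; c < pop_n[p]; c++) {
        int gc = cell_off[p] + c;
        if (t_now <= ref_until[gc]) { V[gc] = v_re[p]; continue; }
        double I = g_l[p] * (V[gc] - E_l[p]);
        for (int b = 0; b < n_blocks; b++)
          if (blocks[b].dst_pop == p)
            I += blocks[b].g_per * gsum[b] * (V[gc] - blocks[b].E);
        for (int s = 0; s < n_streams; s++)
          if (streams[s].dst_pop == p)
            I += streams[s].g * streams[s].s[c] * (V[gc] - streams[s].E);
        V[gc] += dt * (-I);
        if (V[gc] >= v_th[p]) {
          spk_t[p].push_back(t_now);
          spk_c[p].push_back(c + 1);
          V[gc] = v_re[p];
          ref_until[gc] = t_now + t_ref[p];
          for (int b = 0; b < n_blocks; b++)
            if (blocks[b].src_pop == p) {
              A[b][c] += 1.0;
              B2[b][c] += 1.0;
            }
        }
      }
    }

    for (int b = 0; b < n_blocks; b++)
      for (size_t i = 0; i < A[b].size(); i++) {
        A[b][i] *= decA[b];
        B2[b][i] *= decB[b];
      }
    for (int s = 0; s < n_streams; s++) {
      Stream& S = streams[s];
      for (size_t c = 0; c < S.s.size(); c++) S.s[c] *= S.decay;
    }

    if ((step + 1) % rec_every == 0 && rec_i < n_rec) {
      for (int i = 0; i < n_cells; i++) v_out(rec_i, i) = V[i];
      v_time[rec_i] = t_now;
      rec_i++;
    }
  }

  List spikes(n_pops);
  for (int p = 0; p < n_pops; p++)
    spikes[p] = List::create(_["t"] = wrap(spk_t[p]),
                             _["cell"] = wrap(spk_c[p]));
  return List::create(_["spikes"] = spikes, _["v"] = v_out,
                      _["v_time"] = v_time, _["diverged"] = false,
                      _["t_diverged"] = NA_REAL);
}
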