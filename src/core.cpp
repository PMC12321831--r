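// Forward-Euler engine for the resource-dependent heterosynaptic STDP network.
//
// State layout: recurrent synapses arrive sorted by (target, dendritic
// position); per-neuron afferent blocks are therefore contiguous and a
// synapse's dendritic neighbors are its adjacent (alive) entries. Synaptic
// drive is accumulated per neuron (the current ODEs are linear, so the sum
// over afferents obeys the same two-exponential dynamics as each synapse).
//
// Per-step phase order (mirrored exactly by the R reference oracle in the
// test suite):
//   A  deliver queued arrivals (impulse s' += gain*w, then acausal pairing ->
//      depression, then record arrival time)
//   B  generate/collect input spikes for this step, enqueue their arrivals
//   C  Euler-update v, r, s, s' per neuron (v clamped during absolute
//      refractory period)
//   D  threshold test; spikes reset v, r, start refractory period, trigger
//      causal pairing -> potentiation over afferents in ascending dendritic
//      position, and enqueue efferent deliveries
//   E  resource-pool decay
//   F  scheduled synapse deletions (degeneration protocol)
//   G  snapshots / checkpoints / cessation check

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct EventLog {
  std::vector<double> time, syn, tau, dir, requested, granted, from_nb, from_pool;
  double min_request;
  R_xlen_t cap;
  bool enabled;
  R_xlen_t n_total_pot = 0, n_total_dep = 0, n_partial_pot = 0;

  void record(double t, int j, double tv, int direction, double req,
              double gr, double fnb, double fpl) {
    if (direction > 0) {
      ++n_total_pot;
      if (req > 0 && gr < req * (1.0 - 1e-9)) ++n_partial_pot;
    } else {
      ++n_total_dep;
    }
    if (!enabled || req < min_request ||
        (R_xlen_t)time.size() >= cap) return;
    time.push_back(t); syn.push_back(j + 1.0); tau.push_back(tv);
    dir.push_back(direction); requested.push_back(req); granted.push_back(gr);
    from_nb.push_back(fnb); from_pool.push_back(fpl);
  }
};

} // namespace

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(IntegerVector src, IntegerVector tgt, IntegerVector pos,
              IntegerVector delay, NumericVector w0,
              IntegerVector isrc, IntegerVector itgt, IntegerVector idelay,
              NumericVector iw, NumericVector pools0,
              int n_exc, int n_in, List neuron, List stdp, List ctrl) {
  const int n_syn = src.size();
  const int n_isyn = isrc.size();

  const double dt = as<double>(ctrl["dt"]);
  const long long n_steps = (long long)as<double>(ctrl["n_steps"]);
  const double input_rate = as<double>(ctrl["input_rate"]);
  const long long input_end = (long long)as<double>(ctrl["input_end_step"]);
  const bool stdp_on = as<bool>(ctrl["stdp_on"]);
  const double quiet_ms = as<double>(ctrl["quiet_window_ms"]);
  const bool stop_at_cess = as<bool>(ctrl["stop_at_cessation"]);
  const long long snap_every = (long long)as<double>(ctrl["snapshot_every"]);
  const long long chk_every = (long long)as<double>(ctrl["checkpoint_every"]);
  IntegerVector chk_extra = ctrl["checkpoint_extra"]; // sorted step indices

  const double deg_start_ms = as<double>(ctrl["deg_start_ms"]);
  const double del_interval_ms = as<double>(ctrl["deletion_interval_ms"]);
  IntegerVector del_order = ctrl["deletion_order"]; // 1-based synapse ids
  const bool replenish = as<bool>(ctrl["replenish"]);

  const double tau_v = as<double>(neuron["tau_v"]);
  const double tau_r = as<double>(neuron["tau_r"]);
  const double tau_sr = as<double>(neuron["tau_sr"]);
  const double tau_sf = as<double>(neuron["tau_sf"]);
  const double theta = as<double>(neuron["theta"]);
  const double t_abs = as<double>(neuron["t_abs"]);
  const double gain = as<double>(neuron["syn_gain"]);
  const double r_reset = as<double>(neuron["r_reset"]);

  const double tau_stdp = as<double>(stdp["tau_stdp"]);
  const double dep_mult = as<double>(stdp["depression_multiple"]);
  const int max_dist = as<int>(stdp["max_neighbor_distance"]);
  const double tau_p_ms = as<double>(stdp["tau_pool"]) * 1000.0;

  EventLog log;
  log.enabled = as<bool>(ctrl["log_events"]);
  log.min_request = as<double>(ctrl["log_min_request"]);
  log.cap = (R_xlen_t)as<double>(ctrl["log_max_events"]);

  // scripted input: list of integer vectors of 0-based spike steps per train
  bool scripted = !Rf_isNull(ctrl["scripted_input"]);
  std::vector<std::vector<long long>> script;
  std::vector<size_t> script_ptr;
  if (scripted) {
    List sl = ctrl["scripted_input"];
    if (sl.size() != n_in) stop("scripted_input must have one entry per train");
    script.resize(n_in);
    script_ptr.assign(n_in, 0);
    for (int k = 0; k < n_in; ++k) {
      IntegerVector v = sl[k];
      script[k].assign(v.begin(), v.end());
    }
  }

  // ---- index structures -------------------------------------------------
  // afferent blocks by target (requires sorted-by-(target,pos) input)
  std::vector<int> tgt_ptr(n_exc + 1, 0);
  for (int j = 0; j < n_syn; ++j) {
    if (j > 0 && (tgt[j] < tgt[j - 1] ||
                  (tgt[j] == tgt[j - 1] && pos[j] <= pos[j - 1])))
      stop("recurrent synapse table must be sorted by (target, pos)");
    tgt_ptr[tgt[j]]++; // tgt is 1-based: counts shifted by one slot
  }
  for (int n = 0; n < n_exc; ++n) tgt_ptr[n + 1] += tgt_ptr[n];
  // tgt_ptr[n-1]..tgt_ptr[n] is the block of neuron n (1-based n)

  // efferent lists by source neuron (ascending synapse index)
  std::vector<int> eff_ptr(n_exc + 1, 0), eff_idx(n_syn);
  for (int j = 0; j < n_syn; ++j) eff_ptr[src[j]]++;
  for (int n = 0; n < n_exc; ++n) eff_ptr[n + 1] += eff_ptr[n];
  {
    std::vector<int> fill(n_exc, 0);
    for (int j = 0; j < n_syn; ++j) {
      int s = src[j] - 1;
      eff_idx[eff_ptr[s] + fill[s]++] = j;
    }
  }
  // input efferent lists by train
  std::vector<int> ieff_ptr(n_in + 1, 0), ieff_idx(n_isyn);
  for (int j = 0; j < n_isyn; ++j) ieff_ptr[isrc[j]]++;
  for (int k = 0; k < n_in; ++k) ieff_ptr[k + 1] += ieff_ptr[k];
  {
    std::vector<int> fill(n_in, 0);
    for (int j = 0; j < n_isyn; ++j) {
      int s = isrc[j] - 1;
      ieff_idx[ieff_ptr[s] + fill[s]++] = j;
    }
  }

  int max_delay = 1;
  for (int j = 0; j < n_syn; ++j) max_delay = std::max(max_delay, delay[j]);
  for (int j = 0; j < n_isyn; ++j) max_delay = std::max(max_delay, idelay[j]);
  const int ring_n = max_delay + 1;
  std::vector<std::vector<int>> ring(ring_n); // rec syn j; input syn n_syn+j

  // ---- state ------------------------------------------------------------
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> pool(pools0.begin(), pools0.end());
  std::vector<char> alive(n_syn, 1);
  std::vector<double> v(n_exc, 0.0), r(n_exc, 1.0),
      SP(n_exc, 0.0), SS(n_exc, 0.0);
  std::vector<int> refrac(n_exc, 0);
  std::vector<double> last_post(n_exc, -HUGE_VAL), last_pre(n_syn, -HUGE_VAL);

  const int n_abs = (int)std::llround(t_abs / dt);
  const double p_spike = input_rate * dt * 1e-3;
  if (p_spike >= 1.0) stop("input rate * dt >= 1: time step too coarse");

  std::vector<double> spike_t; std::vector<int> spike_n;
  std::vector<double> del_t; std::vector<int> del_syn;
  std::vector<double> tr_t, tr_wsum, tr_psum, tr_nnz, tr_nalive,
      tr_mnw, tr_spacing, tr_decay, tr_discard;
  List checkpoints;

  double cum_decay = 0.0, cum_discard = 0.0;
  double last_spike_ms = -HUGE_VAL;
  double cessation_ms = NA_REAL;
  int n_alive = n_syn;
  size_t del_idx = 0;
  double next_del_ms = deg_start_ms + del_interval_ms;
  int chk_extra_i = 0;

  // scratch for dendritic-spacing snapshot metric
  std::vector<int> posbuf;

  auto snapshot = [&](double t_ms) {
    double wsum = 0, psum = 0; int nnz = 0;
    for (int j = 0; j < n_syn; ++j) {
      if (alive[j]) { wsum += w[j]; if (w[j] > 0) ++nnz; }
    }
    for (int n = 0; n < n_exc; ++n) psum += pool[n];
    // mean nonfilopodia weight and nearest-neighbor spacing
    double mnw = 0; int nspine = 0;
    double sp_sum = 0; int sp_neurons = 0;
    for (int n = 0; n < n_exc; ++n) {
      posbuf.clear();
      for (int j = tgt_ptr[n]; j < tgt_ptr[n + 1]; ++j) {
        if (alive[j] && w[j] > 0) { posbuf.push_back(pos[j]); mnw += w[j]; ++nspine; }
      }
      int m = posbuf.size();
      if (m >= 2) {
        double acc = 0;
        for (int i = 0; i < m; ++i) {
          double dl = (i > 0) ? posbuf[i] - posbuf[i - 1] : HUGE_VAL;
          double dr = (i < m - 1) ? posbuf[i + 1] - posbuf[i] : HUGE_VAL;
          acc += std::min(dl, dr);
        }
        sp_sum += acc / m;
        ++sp_neurons;
      }
    }
    tr_t.push_back(t_ms);
    tr_wsum.push_back(wsum);
    tr_psum.push_back(psum);
    tr_nnz.push_back(nnz);
    tr_nalive.push_back(n_alive);
    tr_mnw.push_back(nspine ? mnw / nspine : NA_REAL);
    tr_spacing.push_back(sp_neurons ? sp_sum / sp_neurons : NA_REAL);
    tr_decay.push_back(cum_decay);
    tr_discard.push_back(cum_discard);
  };

  auto checkpoint = [&](long long step, double t_ms) {
    checkpoints.push_back(List::create(
        _["step"] = (double)step, _["time_ms"] = t_ms,
        _["weights"] = NumericVector(w.begin(), w.end()),
        _["pools"] = NumericVector(pool.begin(), pool.end()),
        _["alive"] = LogicalVector(alive.begin(), alive.end())));
  };

  // neighbor-funded potentiation; neighbors in ascending dendritic position.
  // exp(-d) for the (integer) dendritic distances is tabulated once.
  if (max_dist > 8) stop("max_neighbor_distance > 8 not supported");
  double exp_tab[9];
  for (int d = 0; d <= max_dist; ++d) exp_tab[d] = std::exp(-(double)d);
  int nb_idx[8]; int nb_d[8];
  auto do_potentiate = [&](int j, double t_ms, double tau) {
    double requested = std::exp(-tau / tau_stdp);
    int n1 = tgt[j]; // 1-based
    int p0 = tgt_ptr[n1 - 1], p1 = tgt_ptr[n1];
    int nnb = 0;
    int k = j - 1;
    while (k >= p0 && pos[j] - pos[k] <= max_dist) {
      if (alive[k]) nb_idx[nnb++] = k;
      --k;
    }
    std::reverse(nb_idx, nb_idx + nnb);
    k = j + 1;
    while (k < p1 && pos[k] - pos[j] <= max_dist) {
      if (alive[k]) nb_idx[nnb++] = k;
      ++k;
    }
    double norm = 0.0;
    for (int i = 0; i < nnb; ++i) {
      nb_d[i] = std::abs(pos[nb_idx[i]] - pos[j]);
      norm += exp_tab[nb_d[i]];
    }
    double from_nb = 0.0;
    for (int i = 0; i < nnb; ++i) {
      double share = exp_tab[nb_d[i]] / norm;
      double take = std::min(w[nb_idx[i]], requested * share);
      w[nb_idx[i]] -= take;
      from_nb += take;
    }
    double shortfall = requested - from_nb;
    double from_pool = std::min(pool[n1 - 1], shortfall);
    pool[n1 - 1] -= from_pool;
    double granted = from_nb + from_pool;
    w[j] += granted;
    log.record(t_ms, j, tau, 1, requested, granted, from_nb, from_pool);
  };

  auto do_depress = [&](int j, double t_ms, double tau) {
    double requested = dep_mult * std::exp(tau / tau_stdp) * w[j];
    double moved = std::min(requested, w[j]);
    w[j] -= moved;
    pool[tgt[j] - 1] += moved;
    log.record(t_ms, j, tau, -1, requested, moved, 0.0, moved);
  };

  GetRNGstate();
  long long end_step = n_steps;
  snapshot(0.0);
  checkpoint(0, 0.0);

  for (long long t = 0; t < n_steps; ++t) {
    const double t_ms = (double)t * dt;
    const int slot = (int)(t % ring_n);

    // A: deliveries scheduled for this step
    {
      std::vector<int> &q = ring[slot];
      for (size_t qi = 0; qi < q.size(); ++qi) {
        int id = q[qi];
        if (id >= n_syn) { // input synapse
          int j = id - n_syn;
          SP[itgt[j] - 1] += gain * iw[j];
        } else {
          int j = id;
          if (!alive[j]) continue;
          SP[tgt[j] - 1] += gain * w[j];
          if (stdp_on) {
            double tp = last_post[tgt[j] - 1];
            if (tp != -HUGE_VAL && tp - t_ms < 0) do_depress(j, t_ms, tp - t_ms);
          }
          last_pre[j] = t_ms;
        }
      }
      q.clear();
    }

    // B: input spikes emitted this step
    if (scripted) {
      for (int kk = 0; kk < n_in; ++kk) {
        std::vector<long long> &st = script[kk];
        while (script_ptr[kk] < st.size() && st[script_ptr[kk]] == t) {
          for (int e = ieff_ptr[kk]; e < ieff_ptr[kk + 1]; ++e) {
            int j = ieff_idx[e];
            ring[(t + idelay[j]) % ring_n].push_back(n_syn + j);
          }
          ++script_ptr[kk];
        }
      }
    } else if (t < input_end && p_spike > 0) {
      for (int kk = 0; kk < n_in; ++kk) {
        if (unif_rand() < p_spike) {
          for (int e = ieff_ptr[kk]; e < ieff_ptr[kk + 1]; ++e) {
            int j = ieff_idx[e];
            ring[(t + idelay[j]) % ring_n].push_back(n_syn + j);
          }
        }
      }
    }

    // C: Euler updates
    for (int n = 0; n < n_exc; ++n) {
      double ss_o = SS[n], sp_o = SP[n], r_o = r[n], v_o = v[n];
      if (refrac[n] > 0) {
        --refrac[n];
        v[n] = 0.0;
      } else {
        v[n] = v_o + dt / tau_v * (-v_o + r_o * ss_o);
      }
      r[n] = r_o + dt / tau_r * (1.0 - r_o);
      SS[n] = ss_o + dt / tau_sf * (-ss_o + sp_o);
      SP[n] = sp_o * (1.0 - dt / tau_sr);
      if (!std::isfinite(v[n]) || !std::isfinite(SS[n])) {
        PutRNGstate();
        stop("non-finite state at t = %.1f ms (neuron %d): v=%g s=%g",
             t_ms, n + 1, v[n], SS[n]);
      }
    }

    // D: threshold, reset, plasticity, efferent enqueue
    for (int n = 0; n < n_exc; ++n) {
      if (refrac[n] == 0 && v[n] >= theta) {
        spike_t.push_back(t_ms);
        spike_n.push_back(n + 1);
        last_spike_ms = t_ms;
        v[n] = 0.0;
        refrac[n] = n_abs;
        r[n] = r_reset;
        if (stdp_on) {
          for (int j = tgt_ptr[n]; j < tgt_ptr[n + 1]; ++j) {
            if (alive[j] && last_pre[j] != -HUGE_VAL) {
              do_potentiate(j, t_ms, t_ms - last_pre[j]);
            }
          }
        }
        last_post[n] = t_ms;
        for (int e = eff_ptr[n]; e < eff_ptr[n + 1]; ++e) {
          int j = eff_idx[e];
          ring[(t + delay[j]) % ring_n].push_back(j);
        }
      }
    }

    // E: pool decay
    for (int n = 0; n < n_exc; ++n) {
      double d = pool[n] * (dt / tau_p_ms);
      pool[n] -= d;
      cum_decay += d;
    }

    // F: scheduled deletions
    if (del_order.size() > 0) {
      while (del_idx < (size_t)del_order.size() && t_ms >= next_del_ms) {
        int j = del_order[del_idx] - 1;
        if (alive[j]) {
          alive[j] = 0;
          if (replenish) pool[tgt[j] - 1] += w[j];
          else cum_discard += w[j];
          w[j] = 0.0;
          --n_alive;
          del_t.push_back(t_ms);
          del_syn.push_back(j + 1);
        }
        ++del_idx;
        next_del_ms = deg_start_ms + del_interval_ms * (double)(del_idx + 1);
      }
    }

    // G: snapshots, checkpoints, cessation
    const long long t1 = t + 1;
    const double t1_ms = (double)t1 * dt;
    if (snap_every > 0 && t1 % snap_every == 0) snapshot(t1_ms);
    bool chk = (chk_every > 0 && t1 % chk_every == 0);
    while (chk_extra_i < chk_extra.size() && chk_extra[chk_extra_i] < t1)
      ++chk_extra_i;
    if (chk_extra_i < chk_extra.size() && chk_extra[chk_extra_i] == t1) chk = true;
    if (chk) checkpoint(t1, t1_ms);
    if (stop_at_cess && t1_ms >= quiet_ms && t1_ms - last_spike_ms >= quiet_ms) {
      cessation_ms = last_spike_ms == -HUGE_VAL ? t1_ms : last_spike_ms + quiet_ms;
      end_step = t1;
      if (!(snap_every > 0 && t1 % snap_every == 0)) snapshot(t1_ms);
      if (!chk) checkpoint(t1, t1_ms);
      break;
    }
    if (t1 == n_steps) {
      if (!(snap_every > 0 && t1 % snap_every == 0)) snapshot(t1_ms);
      if (!chk) checkpoint(t1, t1_ms);
    }
  }
  PutRNGstate();

  NumericMatrix trace(tr_t.size(), 9);
  for (size_t i = 0; i < tr_t.size(); ++i) {
    trace(i, 0) = tr_t[i]; trace(i, 1) = tr_wsum[i]; trace(i, 2) = tr_psum[i];
    trace(i, 3) = tr_nnz[i]; trace(i, 4) = tr_nalive[i]; trace(i, 5) = tr_mnw[i];
    trace(i, 6) = tr_spacing[i]; trace(i, 7) = tr_decay[i];
    trace(i, 8) = tr_discard[i];
  }
  colnames(trace) = CharacterVector::create(
      "time_ms", "weight_sum", "pool_sum", "n_nonzero", "n_alive",
      "mean_nonfil_weight", "mean_nonfil_spacing", "cum_pool_decay",
      "cum_discarded");

  R_xlen_t ne = log.time.size();
  NumericMatrix events(ne, 8);
  for (R_xlen_t i = 0; i < ne; ++i) {
    events(i, 0) = log.time[i]; events(i, 1) = log.syn[i];
    events(i, 2) = log.tau[i]; events(i, 3) = log.dir[i];
    events(i, 4) = log.requested[i]; events(i, 5) = log.granted[i];
    events(i, 6) = log.from_nb[i]; events(i, 7) = log.from_pool[i];
  }
  colnames(events) = CharacterVector::create(
      "time_ms", "synapse", "tau", "direction", "requested", "granted",
      "from_neighbors", "from_pool");

  return List::create(
      _["spike_t"] = NumericVector(spike_t.begin(), spike_t.end()),
      _["spike_n"] = IntegerVector(spike_n.begin(), spike_n.end()),
      _["weights"] = NumericVector(w.begin(), w.end()),
      _["pools"] = NumericVector(pool.begin(), pool.end()),
      _["alive"] = LogicalVector(alive.begin(), alive.end()),
      _["v"] = NumericVector(v.begin(), v.end()),
      _["r"] = NumericVector(r.begin(), r.end()),
      _["s"] = NumericVector(SS.begin(), SS.end()),
      _["s_rise"] = NumericVector(SP.begin(), SP.end()),
      _["trace"] = trace,
      _["checkpoints"] = checkpoints,
      _["events"] = events,
      _["n_pot_events"] = (double)log.n_total_pot,
      _["n_dep_events"] = (double)log.n_total_dep,
      _["n_partial_pot_events"] = (double)log.n_partial_pot,
      _["deletion_t"] = NumericVector(del_t.begin(), del_t.end()),
      _["deletion_syn"] = IntegerVector(del_syn.begin(), del_syn.end()),
      _["cessation_ms"] = cessation_ms,
      _["end_step"] = (double)end_step,
      _["cum_pool_decay"] = cum_decay,
      _["cum_discarded"] = cum_discard);
}
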