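// Compiled simulation engine.
//
// This file re-implements the per-interaction mechanics of the R reference
// engine (R/rng.R documents the shared draw discipline) on top of R's RNG
// stream (unif_rand()). Bit-identical trajectories with the R engine for a
// given seed are a package invariant, so every random draw and floating-
// point reduction here mirrors its R counterpart:
//   - one uniform per categorical draw (inverse CDF over normalized weights,
//     cumulative sums accumulated in long double like R's cumsum/sum);
//   - winner-take-all picks uniformly among entries within 1e-12 of the max;
//   - raw-count draws (inhibition, memory deletion) scale one uniform by the
//     long-double total;
//   - contexts are partial Fisher-Yates shuffles, sorted ascending;
//   - population CA accumulates per ordered pair (speaker-major), each pair
//     summed column-major in long double, divided by |M| per pair.
// Stores are column-major |M| x |S| integer count matrices.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

static const double WTA_TOL = 1e-12;

// --- draw helpers -----------------------------------------------------------

static inline int unif_index0(int n) {
  // R: floor(runif(1) * n) + 1, clipped to n; returned 0-based here.
  double k = std::floor(unif_rand() * n);
  int ki = (int)k;
  if (ki >= n) ki = n - 1;
  return ki;
}

static inline int invcdf_normalized0(const std::vector<double>& w, int n) {
  double u = unif_rand();
  long double acc = 0.0L;
  int last_pos = -1;
  for (int j = 0; j < n; ++j) {
    acc += w[j];
    if (w[j] > 0) last_pos = j;
    if ((double)acc >= u) return j;
  }
  return last_pos;
}

static inline int invcdf_raw0(const std::vector<double>& w, int n) {
  long double tot = 0.0L;
  for (int j = 0; j < n; ++j) tot += w[j];
  double u = unif_rand() * (double)tot;
  long double acc = 0.0L;
  int last_pos = -1;
  for (int j = 0; j < n; ++j) {
    acc += w[j];
    if (w[j] > 0) last_pos = j;
    if ((double)acc >= u) return j;
  }
  return last_pos;
}

static inline double ld_sum(const std::vector<double>& w, int n) {
  long double acc = 0.0L;
  for (int j = 0; j < n; ++j) acc += w[j];
  return (double)acc;
}

// --- engine state -----------------------------------------------------------

struct Params {
  int M, S, regime, weighting, selection;
  bool learn_speaker, learn_hearer;
  bool pun_speaker_own, pun_hearer_own, pun_sphc;
  int sphc_target, inh_kind, inh_strength, memory_limit, context_size;
  std::vector<double> dist;
  int dynamic, learner_interactions, learner_role;
  int max_interactions, check_interval;
};

typedef std::vector<int> Store;  // column-major M x S

static inline int cell(int m, int s, int M) { return s * M + m; }

// --- weights ----------------------------------------------------------------

static void production_weights(const Store& st, int t, const Params& P,
                               std::vector<double>& w) {
  int M = P.M, S = P.S;
  if (P.weighting == 0) {  // standard
    for (int s = 0; s < S; ++s) w[s] = (double)st[cell(t, s, M)];
    double tot = ld_sum(w, S);
    if (tot > 0) for (int s = 0; s < S; ++s) w[s] /= tot;
    else for (int s = 0; s < S; ++s) w[s] = 1.0 / S;
  } else {  // obverter
    for (int s = 0; s < S; ++s) {
      long double cs = 0.0L;
      for (int m = 0; m < M; ++m) cs += st[cell(m, s, M)];
      double csd = (double)cs;
      w[s] = (csd == 0) ? 0.0 : (double)st[cell(t, s, M)] / csd;
    }
    double tot = ld_sum(w, S);
    if (tot > 0) for (int s = 0; s < S; ++s) w[s] /= tot;
    else for (int s = 0; s < S; ++s) w[s] = 1.0 / S;
  }
}

static void reception_weights(const Store& st, int u,
                              const std::vector<int>& ctx, const Params& P,
                              std::vector<double>& w) {
  int M = P.M, S = P.S, k = (int)ctx.size();
  if (P.weighting == 0) {  // standard
    for (int j = 0; j < k; ++j) w[j] = (double)st[cell(ctx[j], u, M)];
    double tot = ld_sum(w, k);
    if (tot > 0) for (int j = 0; j < k; ++j) w[j] /= tot;
    else for (int j = 0; j < k; ++j) w[j] = 1.0 / k;
  } else {  // obverter
    for (int j = 0; j < k; ++j) {
      long double rs = 0.0L;
      for (int s = 0; s < S; ++s) rs += st[cell(ctx[j], s, M)];
      double rsd = (double)rs;
      w[j] = (rsd == 0) ? 0.0 : (double)st[cell(ctx[j], u, M)] / rsd;
    }
    double tot = ld_sum(w, k);
    if (tot > 0) for (int j = 0; j < k; ++j) w[j] /= tot;
    else for (int j = 0; j < k; ++j) w[j] = 1.0 / k;
  }
}

static inline int select0(const std::vector<double>& w, int n, int rule) {
  if (rule == 0) return invcdf_normalized0(w, n);
  double mx = w[0];
  for (int j = 1; j < n; ++j) if (w[j] > mx) mx = w[j];
  static thread_local std::vector<int> set;
  set.clear();
  for (int j = 0; j < n; ++j) if (w[j] >= mx - WTA_TOL) set.push_back(j);
  return set[unif_index0((int)set.size())];
}

// --- store operators --------------------------------------------------------

static inline void dec_floor(Store& st, int& total, int m, int s, int M) {
  int& c = st[cell(m, s, M)];
  if (c > 0) { --c; --total; }
}

static void inhibit_pass_col(Store& st, int& total, int focal_m, int s,
                             const Params& P) {
  // competitors: rows != focal_m in column s, ascending
  int M = P.M;
  if (P.inh_strength == 0) {  // minimal
    static thread_local std::vector<double> vals;
    static thread_local std::vector<int> rows;
    vals.clear(); rows.clear();
    long double tot = 0.0L;
    for (int m = 0; m < M; ++m) {
      if (m == focal_m) continue;
      vals.push_back((double)st[cell(m, s, M)]);
      rows.push_back(m);
      tot += st[cell(m, s, M)];
    }
    if ((double)tot > 0) {
      int k = invcdf_raw0(vals, (int)vals.size());
      dec_floor(st, total, rows[k], s, M);
    }
  } else if (P.inh_strength == 1) {  // broad
    for (int m = 0; m < M; ++m)
      if (m != focal_m) dec_floor(st, total, m, s, M);
  } else {  // maximal
    for (int m = 0; m < M; ++m) {
      if (m == focal_m) continue;
      int& c = st[cell(m, s, M)];
      total -= c; c = 0;
    }
  }
}

static void inhibit_pass_row(Store& st, int& total, int m, int focal_s,
                             const Params& P) {
  int M = P.M, S = P.S;
  if (P.inh_strength == 0) {
    static thread_local std::vector<double> vals;
    static thread_local std::vector<int> cols;
    vals.clear(); cols.clear();
    long double tot = 0.0L;
    for (int s = 0; s < S; ++s) {
      if (s == focal_s) continue;
      vals.push_back((double)st[cell(m, s, M)]);
      cols.push_back(s);
      tot += st[cell(m, s, M)];
    }
    if ((double)tot > 0) {
      int k = invcdf_raw0(vals, (int)vals.size());
      dec_floor(st, total, m, cols[k], M);
    }
  } else if (P.inh_strength == 1) {
    for (int s = 0; s < S; ++s)
      if (s != focal_s) dec_floor(st, total, m, s, M);
  } else {
    for (int s = 0; s < S; ++s) {
      if (s == focal_s) continue;
      int& c = st[cell(m, s, M)];
      total -= c; c = 0;
    }
  }
}

// add + lateral inhibition + memory enforcement (the learn_exemplar path)
static void learn_exemplar(Store& st, int& total, int t, int u,
                           const Params& P) {
  int M = P.M;
  ++st[cell(t, u, M)];
  ++total;
  if (P.inh_kind == 1 || P.inh_kind == 3) inhibit_pass_col(st, total, t, u, P);
  if (P.inh_kind == 2 || P.inh_kind == 3) inhibit_pass_row(st, total, t, u, P);
  if (P.memory_limit > 0 && total > P.memory_limit) {
    // uniform draw over all tokens excluding one instance of (t, u)
    int n = M * P.S;
    static thread_local std::vector<double> w;
    w.resize(n);
    for (int j = 0; j < n; ++j) w[j] = (double)st[j];
    w[cell(t, u, M)] -= 1.0;
    int k = invcdf_raw0(w, n);
    --st[k];
    --total;
  }
}

// --- updates (mirrors apply_updates) ---------------------------------------

static void apply_updates(Store& spk, int& spk_total, bool spk_learning,
                          Store& hear, int& hear_total, bool hear_learning,
                          int t, int u, int i, bool success, const Params& P) {
  bool fb = (P.regime == 1 || P.regime == 2);
  bool sphc = fb && P.pun_sphc;
  if (spk_learning) {
    if (!success) {
      if (P.pun_speaker_own) dec_floor(spk, spk_total, t, u, P.M);
      if (sphc && P.sphc_target == 0) dec_floor(spk, spk_total, i, u, P.M);
    }
    bool adds = (P.regime <= 1) ? (success && P.learn_speaker)
              : (P.regime == 2) ? P.learn_speaker : false;
    if (adds) learn_exemplar(spk, spk_total, t, u, P);
  }
  if (hear_learning) {
    if (!success) {
      if (sphc && P.sphc_target == 1) dec_floor(hear, hear_total, i, u, P.M);
      if (P.pun_hearer_own) dec_floor(hear, hear_total, i, u, P.M);
    }
    bool adds = (P.regime <= 1) ? (success && P.learn_hearer)
              : (P.regime == 2) ? P.learn_hearer : true;
    if (adds) learn_exemplar(hear, hear_total, t, u, P);
  }
}

// --- communicative accuracy -------------------------------------------------

static void behavioral_dist_inplace(std::vector<double>& w, int n, int rule) {
  if (rule == 0) return;
  double mx = w[0];
  for (int j = 1; j < n; ++j) if (w[j] > mx) mx = w[j];
  int cnt = 0;
  for (int j = 0; j < n; ++j) if (w[j] >= mx - WTA_TOL) ++cnt;
  for (int j = 0; j < n; ++j) w[j] = (w[j] >= mx - WTA_TOL) ? 1.0 / cnt : 0.0;
}

// Full-context behavioural P and R (column-major M x S) for one store.
static void behavioral_matrices(const Store& st, const Params& P,
                                std::vector<double>& Pm,
                                std::vector<double>& Rm,
                                std::vector<int>& full_ctx,
                                std::vector<double>& wbuf) {
  int M = P.M, S = P.S;
  for (int m = 0; m < M; ++m) {
    production_weights(st, m, P, wbuf);
    behavioral_dist_inplace(wbuf, S, P.selection);
    for (int s = 0; s < S; ++s) Pm[cell(m, s, M)] = wbuf[s];
  }
  for (int s = 0; s < S; ++s) {
    reception_weights(st, s, full_ctx, P, wbuf);
    behavioral_dist_inplace(wbuf, M, P.selection);
    for (int m = 0; m < M; ++m) Rm[cell(m, s, M)] = wbuf[m];
  }
}

static double population_ca(const std::vector<Store>& stores,
                            const std::vector<int>& members, const Params& P) {
  int n = (int)members.size();
  int M = P.M, S = P.S, sz = M * S;
  std::vector<std::vector<double> > Pms(n), Rms(n);
  std::vector<int> full_ctx(M);
  for (int m = 0; m < M; ++m) full_ctx[m] = m;
  std::vector<double> wbuf(std::max(M, S));
  for (int a = 0; a < n; ++a) {
    Pms[a].resize(sz);
    Rms[a].resize(sz);
    behavioral_matrices(stores[members[a]], P, Pms[a], Rms[a], full_ctx, wbuf);
  }
  double acc = 0.0;
  for (int a = 0; a < n; ++a) {
    for (int b = 0; b < n; ++b) {
      if (a == b) continue;
      long double pv = 0.0L;
      for (int j = 0; j < sz; ++j) pv += Pms[a][j] * Rms[b][j];
      acc += (double)pv / M;  // mirrors sum(P * R) / nm
    }
  }
  return acc / (double)(n * (n - 1));
}

// --- main entry -------------------------------------------------------------

// [[Rcpp::export]]
List run_engine_cpp(List stores_in, List params) {
  Params P;
  P.M = as<int>(params["n_meanings"]);
  P.S = as<int>(params["n_signals"]);
  P.regime = as<int>(params["regime"]);
  P.weighting = as<int>(params["weighting"]);
  P.selection = as<int>(params["selection"]);
  P.learn_speaker = as<bool>(params["learn_speaker"]);
  P.learn_hearer = as<bool>(params["learn_hearer"]);
  P.pun_speaker_own = as<bool>(params["pun_speaker_own"]);
  P.pun_hearer_own = as<bool>(params["pun_hearer_own"]);
  P.pun_sphc = as<bool>(params["pun_sphc"]);
  P.sphc_target = as<int>(params["sphc_target"]);
  P.inh_kind = as<int>(params["inh_kind"]);
  P.inh_strength = as<int>(params["inh_strength"]);
  P.memory_limit = as<int>(params["memory_limit"]);
  P.context_size = as<int>(params["context_size"]);
  P.dist = as<std::vector<double> >(params["dist"]);
  P.dynamic = as<int>(params["dynamic"]);
  P.learner_interactions = as<int>(params["learner_interactions"]);
  P.learner_role = as<int>(params["learner_role"]);
  P.max_interactions = as<int>(params["max_interactions"]);
  P.check_interval = as<int>(params["check_interval"]);
  IntegerMatrix edges = as<IntegerMatrix>(params["edges"]);

  int n = stores_in.size();
  int M = P.M, S = P.S, sz = M * S;
  std::vector<Store> stores(n);
  std::vector<int> totals(n, 0);
  std::vector<int> ids(n), births(n);
  std::vector<bool> learning(n);
  for (int a = 0; a < n; ++a) {
    IntegerMatrix cm = as<IntegerMatrix>(stores_in[a]);
    stores[a].assign(cm.begin(), cm.end());
    int tot = 0;
    for (int j = 0; j < sz; ++j) tot += stores[a][j];
    totals[a] = tot;
    ids[a] = a + 1;
    births[a] = a;
    learning[a] = (P.dynamic == 0);
  }
  std::vector<int> members(n);
  for (int a = 0; a < n; ++a) members[a] = a;

  // gradual-dynamic learner state
  Store learner(sz, 0);
  int learner_total = 0, learner_id = 0, learner_birth = 0, learner_done = 0;
  bool learner_active = false;
  int next_id = n + 1, next_birth = n;

  std::vector<double> wbuf(std::max(M, S));
  std::vector<int> ctx;
  std::vector<int> pool(M);
  std::vector<double> ctxw;

  bool converged = false;
  int conv_iter = NA_INTEGER;
  double ca = NA_REAL;
  std::vector<int> traj_it;
  std::vector<double> traj_ca;

  int nE = edges.nrow();
  int it = 0;
  while (it < P.max_interactions) {
    // 1. pairing
    int spk_idx = -1, hear_idx = -1;      // indices into stores[] (established)
    bool learner_is_speaker = false, learner_in_play = false;
    if (P.dynamic == 0) {
      int k = unif_index0(nE);
      spk_idx = edges(k, 0) - 1;
      hear_idx = edges(k, 1) - 1;
    } else {
      if (!learner_active) {
        std::fill(learner.begin(), learner.end(), 0);
        learner_total = 0;
        learner_id = next_id++;
        learner_birth = next_birth++;
        learner_done = 0;
        learner_active = true;
      }
      int partner = unif_index0(n);
      learner_in_play = true;
      if (P.learner_role == 1) learner_is_speaker = (unif_rand() < 0.5);
      if (learner_is_speaker) hear_idx = partner; else spk_idx = partner;
    }

    Store& spk = (learner_in_play && learner_is_speaker) ? learner
                                                          : stores[spk_idx];
    int& spk_total = (learner_in_play && learner_is_speaker) ? learner_total
                                                             : totals[spk_idx];
    bool spk_learning = (learner_in_play && learner_is_speaker)
                          ? true
                          : (learner_in_play ? false : learning[spk_idx]);
    Store& hear = (learner_in_play && !learner_is_speaker) ? learner
                                                           : stores[hear_idx];
    int& hear_total = (learner_in_play && !learner_is_speaker)
                        ? learner_total : totals[hear_idx];
    bool hear_learning = (learner_in_play && !learner_is_speaker)
                           ? true
                           : (learner_in_play ? false : learning[hear_idx]);

    // 2. context
    if (P.context_size == M) {
      if ((int)ctx.size() != M) {
        ctx.resize(M);
        for (int m = 0; m < M; ++m) ctx[m] = m;
      }
    } else {
      for (int m = 0; m < M; ++m) pool[m] = m;
      for (int j = 0; j < P.context_size; ++j) {
        int r = unif_index0(M - j);
        std::swap(pool[j], pool[j + r]);
      }
      ctx.assign(pool.begin(), pool.begin() + P.context_size);
      std::sort(ctx.begin(), ctx.end());
    }

    // 3. topic
    int csz = (int)ctx.size();
    ctxw.resize(csz);
    for (int j = 0; j < csz; ++j) ctxw[j] = P.dist[ctx[j]];
    double cw_tot = ld_sum(ctxw, csz);
    for (int j = 0; j < csz; ++j) ctxw[j] /= cw_tot;
    int t = ctx[invcdf_normalized0(ctxw, csz)];

    // 4. utterance
    production_weights(spk, t, P, wbuf);
    int u = select0(wbuf, S, P.selection);

    // 5. interpretation
    reception_weights(hear, u, ctx, P, wbuf);
    int i = ctx[select0(wbuf, csz, P.selection)];
    bool success = (t == i);

    // 6. updates
    apply_updates(spk, spk_total, spk_learning, hear, hear_total,
                  hear_learning, t, u, i, success, P);
    ++it;

    // gradual lifecycle: replacement of the oldest established agent
    if (P.dynamic == 1) {
      ++learner_done;
      if (learner_done >= P.learner_interactions) {
        int oldest = 0;
        for (int a = 1; a < n; ++a)
          if (births[a] < births[oldest]) oldest = a;
        stores[oldest] = learner;
        totals[oldest] = learner_total;
        ids[oldest] = learner_id;
        births[oldest] = learner_birth;
        learning[oldest] = false;
        learner_active = false;
        learner_done = 0;
      }
    }

    // convergence check
    if (it % P.check_interval == 0 || it == P.max_interactions) {
      ca = population_ca(stores, members, P);
      traj_it.push_back(it);
      traj_ca.push_back(ca);
      if (ca >= 1.0 - 1e-9) {
        converged = true;
        conv_iter = it;
        break;
      }
    }
  }

  List stores_out(n);
  for (int a = 0; a < n; ++a) {
    IntegerMatrix cm(M, S);
    std::copy(stores[a].begin(), stores[a].end(), cm.begin());
    stores_out[a] = cm;
  }
  IntegerMatrix learner_out(M, S);
  if (learner_active)
    std::copy(learner.begin(), learner.end(), learner_out.begin());

  return List::create(
    _["converged"] = converged,
    _["convergence_iteration"] = conv_iter,
    _["final_ca"] = ca,
    _["traj_iteration"] = wrap(traj_it),
    _["traj_ca"] = wrap(traj_ca),
    _["n_interactions"] = it,
    _["stores"] = stores_out,
    _["ids"] = wrap(ids),
    _["births"] = wrap(births),
    _["learning"] = wrap(learning),
    _["learner_active"] = learner_active,
    _["learner_store"] = learner_out,
    _["learner_id"] = learner_id,
    _["learner_birth"] = learner_birth,
    _["learner_done"] = learner_done,
    _["next_id"] = next_id,
    _["next_birth"] = next_birth);
}
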