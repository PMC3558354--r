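// Lattice agent-based model of vaccine-elicited immune response versus
// continuous carcinogenesis.  One run with one seed is one virtual mouse.
//
// All randomness is drawn from R's RNG (unif_rand), so a run is fully
// determined by the R-side seed; the exported granular entry points
// (init/inject/step) consume the stream in exactly the same order as the
// full-run loop, making the two paths bit-identical.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

enum Cls { C_B = 0, C_TH, C_TC, C_NK, C_DC, C_VC, C_TU, C_AG, C_AB, NCLS };
static const char *CLS_NAMES[NCLS] = {"B",  "Th", "Tc", "NK", "DC",
                                      "VC", "TU", "AG", "AB"};
static const int N_IMMUNE = 5; // B, Th, Tc, NK, DC are homeostatic

struct Pars {
  int L, S;              // lattice side, number of sites
  int rlen, mmin;        // receptor length (bits), specific match threshold
  int allo_relax;        // threshold relaxation for allogeneic vaccine cells
  double cbase;          // affinity base c in (0,1]
  int step_hours, steps_per_day, horizon_steps;
  int tumor_birth;       // newborn tumor cells per step
  double p_dup;          // tumor duplication probability per cell per step
  double threshold;      // palpable-tumor cell count
  double p_aspecific;    // probability of aspecific encounters (uptake, help)
  double nk_kill;        // NK aspecific kill probability on co-location
  double il12_boost, il12_decay, il12_deposit;
  int vaccine_dose, ab_burst, ag_burst;
  int baseline[N_IMMUNE];
  int lifespan[NCLS];    // steps; <=0 means immortal (tumor cells)
  int taa;               // tumor-associated-antigen epitope bit pattern
  double max_expansion;  // clonal carrying capacity, multiple of baseline
};

struct State {
  int step;
  bool stopped;
  std::vector<double> il12;
  std::vector<int> site[NCLS], rec[NCLS], state[NCLS], age[NCLS];
  double born, dup, kil_tc, kil_ab, kil_nk;
};

// ---------- RNG helpers (R stream) ----------

static inline double ru() { return unif_rand(); }

static inline int ri(int n) { // uniform integer in [0, n)
  int k = (int)(ru() * n);
  return (k >= n) ? n - 1 : k;
}

template <typename T> static void shuffle_vec(std::vector<T> &v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = ri(i + 1);
    std::swap(v[i], v[j]);
  }
}

static inline int rand_receptor(int rlen) {
  int r = 0;
  for (int b = 0; b < rlen; ++b)
    if (ru() < 0.5) r |= (1 << b);
  return r;
}

// ---------- model primitives ----------

static inline int hamming(int a, int b) {
  int x = a ^ b, m = 0;
  while (x) { m += x & 1; x >>= 1; }
  return m;
}

// Complementarity (lock-and-key) convention: larger Hamming distance means
// a stronger match; below the threshold the affinity is exactly zero.
static inline double affinity_m(int m, int mmin, int rlen, double c) {
  if (m < mmin) return 0.0;
  return std::pow(c, rlen - m);
}

static inline double aff(int receptor, int epitope, const Pars &p) {
  return affinity_m(hamming(receptor, epitope), p.mmin, p.rlen, p.cbase);
}

static void add_agent(State &st, int cls, int site, int rec, int state) {
  st.site[cls].push_back(site);
  st.rec[cls].push_back(rec);
  st.state[cls].push_back(state);
  st.age[cls].push_back(0);
}

static void compact(State &st, int cls, const std::vector<char> &dead) {
  size_t k = 0, n = st.site[cls].size();
  for (size_t i = 0; i < n; ++i) {
    if (!dead[i]) {
      st.site[cls][k] = st.site[cls][i];
      st.rec[cls][k] = st.rec[cls][i];
      st.state[cls][k] = st.state[cls][i];
      st.age[cls][k] = st.age[cls][i];
      ++k;
    }
  }
  st.site[cls].resize(k);
  st.rec[cls].resize(k);
  st.state[cls].resize(k);
  st.age[cls].resize(k);
}

// ---------- parameter / state marshalling ----------

static Pars parse_pars(const List &prm) {
  Pars p;
  p.L = as<int>(prm["lattice_side"]);
  p.S = p.L * p.L;
  p.rlen = as<int>(prm["receptor_len"]);
  p.mmin = as<int>(prm["min_match"]);
  p.allo_relax = as<int>(prm["allo_relax"]);
  p.cbase = as<double>(prm["affinity_base"]);
  p.step_hours = as<int>(prm["step_hours"]);
  p.steps_per_day = std::max(1, 24 / p.step_hours);
  p.horizon_steps = as<int>(prm["horizon_steps"]);
  p.tumor_birth = as<int>(prm["tumor_birth"]);
  p.p_dup = as<double>(prm["p_dup"]);
  p.threshold = as<double>(prm["palpable_threshold"]);
  p.p_aspecific = as<double>(prm["p_aspecific"]);
  p.nk_kill = as<double>(prm["nk_kill"]);
  p.il12_boost = as<double>(prm["il12_boost"]);
  p.il12_decay = as<double>(prm["il12_decay"]);
  p.il12_deposit = as<double>(prm["il12_deposit"]);
  p.vaccine_dose = as<int>(prm["vaccine_dose"]);
  p.ab_burst = as<int>(prm["ab_burst"]);
  p.ag_burst = as<int>(prm["ag_burst"]);
  IntegerVector base = prm["baseline"];
  for (int i = 0; i < N_IMMUNE; ++i) p.baseline[i] = base[i];
  IntegerVector ls = prm["lifespan"];
  for (int i = 0; i < NCLS; ++i) p.lifespan[i] = ls[i];
  p.taa = as<int>(prm["taa_epitope"]);
  p.max_expansion = as<double>(prm["max_expansion"]);
  return p;
}

// clonal expansion is resource-limited: no division above the cap
static inline bool below_cap(const State &st, const Pars &p, int cls) {
  return (double)st.site[cls].size() <
         p.max_expansion * (double)p.baseline[cls];
}

static List state_to_list(const State &st) {
  List agents(NCLS);
  for (int c = 0; c < NCLS; ++c) {
    agents[c] = List::create(_["site"] = wrap(st.site[c]),
                             _["rec"] = wrap(st.rec[c]),
                             _["state"] = wrap(st.state[c]),
                             _["age"] = wrap(st.age[c]));
  }
  agents.attr("names") = CharacterVector(CLS_NAMES, CLS_NAMES + NCLS);
  NumericVector counters = NumericVector::create(
      _["tumor_born"] = st.born, _["tumor_dup"] = st.dup,
      _["killed_tc"] = st.kil_tc, _["killed_ab"] = st.kil_ab,
      _["killed_nk"] = st.kil_nk);
  return List::create(_["step"] = st.step, _["stopped"] = st.stopped,
                      _["il12"] = wrap(st.il12), _["agents"] = agents,
                      _["counters"] = counters);
}

static State state_from_list(const List &lst) {
  State st;
  st.step = as<int>(lst["step"]);
  st.stopped = as<bool>(lst["stopped"]);
  st.il12 = as<std::vector<double> >(lst["il12"]);
  List agents = lst["agents"];
  for (int c = 0; c < NCLS; ++c) {
    List a = agents[c];
    st.site[c] = as<std::vector<int> >(a["site"]);
    st.rec[c] = as<std::vector<int> >(a["rec"]);
    st.state[c] = as<std::vector<int> >(a["state"]);
    st.age[c] = as<std::vector<int> >(a["age"]);
  }
  NumericVector ctr = lst["counters"];
  st.born = ctr["tumor_born"];
  st.dup = ctr["tumor_dup"];
  st.kil_tc = ctr["killed_tc"];
  st.kil_ab = ctr["killed_ab"];
  st.kil_nk = ctr["killed_nk"];
  return st;
}

// ---------- dynamics ----------

static void init_state_impl(State &st, const Pars &p) {
  st.step = 0;
  st.stopped = false;
  st.il12.assign(p.S, 0.0);
  st.born = st.dup = st.kil_tc = st.kil_ab = st.kil_nk = 0.0;
  for (int c = 0; c < N_IMMUNE; ++c) {
    for (int i = 0; i < p.baseline[c]; ++i)
      add_agent(st, c, ri(p.S), rand_receptor(p.rlen), 0);
  }
}

static void inject_impl(State &st, const Pars &p) {
  for (int i = 0; i < p.vaccine_dose; ++i) {
    int s = ri(p.S);
    add_agent(st, C_VC, s, p.taa, 0);
    st.il12[s] += p.il12_deposit;
  }
}

static inline int move_site(int site, int L, int S) {
  int x = site % L, y = site / L;
  // Moore neighborhood, toroidal; 8 neighbors, self excluded
  static const int dx[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dy[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  int k = ri(8);
  x = (x + dx[k] + L) % L;
  y = (y + dy[k] + L) % L;
  (void)S;
  return x + L * y;
}

// One simulated time step.  Phases run in fixed order; within each
// interaction rule the acting agents are visited in a freshly randomized
// order, and a cell takes part in at most one specific interaction per step.
static void step_impl(State &st, const Pars &p, int schedule_bit) {
  if (st.stopped)
    stop("cannot step a stopped simulation state");

  // (1) vaccination at the first step of an administration day
  if (schedule_bit && (st.step % p.steps_per_day == 0))
    inject_impl(st, p);

  // (2) movement of mobile agents (lymphocytes, NK, DC, molecules)
  static const int mobile[] = {C_B, C_TH, C_TC, C_NK, C_DC, C_AG, C_AB};
  for (int mi = 0; mi < 7; ++mi) {
    int c = mobile[mi];
    for (size_t i = 0; i < st.site[c].size(); ++i)
      st.site[c][i] = move_site(st.site[c][i], p.L, p.S);
  }

  // (3) site-local interactions
  std::vector<std::vector<int> > by_site[NCLS];
  for (int c = 0; c < NCLS; ++c) {
    by_site[c].assign(p.S, std::vector<int>());
    for (size_t i = 0; i < st.site[c].size(); ++i)
      by_site[c][st.site[c][i]].push_back((int)i);
  }
  std::vector<char> used_th(st.site[C_TH].size(), 0);
  std::vector<char> used_tc(st.site[C_TC].size(), 0);
  std::vector<char> used_b(st.site[C_B].size(), 0);
  std::vector<char> ag_gone(st.site[C_AG].size(), 0);
  std::vector<char> ab_gone(st.site[C_AB].size(), 0);
  std::vector<char> tu_dead(st.site[C_TU].size(), 0);
  std::vector<char> vc_dead(st.site[C_VC].size(), 0);

  // pick a random member of by_site[cls][s] passing a predicate
  struct Pick {
    static int from(const std::vector<int> &ids, const std::vector<char> &skip,
                    const std::vector<int> *state, int want_state) {
      std::vector<int> cand;
      for (size_t k = 0; k < ids.size(); ++k) {
        int i = ids[k];
        if (!skip.empty() && skip[i]) continue;
        if (state && (*state)[i] != want_state) continue;
        cand.push_back(i);
      }
      if (cand.empty()) return -1;
      return cand[ri((int)cand.size())];
    }
  };
  std::vector<char> none;

  std::vector<int> order;

  // (3a) aspecific antigen uptake: unloaded DC engulfs a free antigen
  order.resize(st.site[C_DC].size());
  for (size_t i = 0; i < order.size(); ++i) order[i] = (int)i;
  shuffle_vec(order);
  for (size_t k = 0; k < order.size(); ++k) {
    int i = order[k];
    if (st.state[C_DC][i] != 0) continue;
    int s = st.site[C_DC][i];
    int j = Pick::from(by_site[C_AG][s], ag_gone, NULL, 0);
    if (j >= 0 && ru() < p.p_aspecific) {
      ag_gone[j] = 1;
      st.rec[C_DC][i] = st.rec[C_AG][j]; // presented epitope
      st.state[C_DC][i] = 1;             // loaded
    }
  }

  // (3b) presentation by loaded DC: activates one naive Th and primes one
  // naive Tc per step (counted as the DC's single presentation event);
  // specific, enhanced by local IL-12
  order.resize(st.site[C_DC].size());
  for (size_t i = 0; i < order.size(); ++i) order[i] = (int)i;
  shuffle_vec(order);
  for (size_t k = 0; k < order.size(); ++k) {
    int i = order[k];
    if (st.state[C_DC][i] != 1) continue;
    int s = st.site[C_DC][i];
    double boost = 1.0 + p.il12_boost * st.il12[s];
    int epi = st.rec[C_DC][i];
    int j = Pick::from(by_site[C_TH][s], used_th, &st.state[C_TH], 0);
    if (j >= 0) {
      double pr = std::min(1.0, aff(st.rec[C_TH][j], epi, p) * boost);
      if (pr > 0 && ru() < pr) {
        st.state[C_TH][j] = 1;
        st.age[C_TH][j] = 0;
        used_th[j] = 1;
      }
    }
    j = Pick::from(by_site[C_TC][s], used_tc, &st.state[C_TC], 0);
    if (j >= 0) {
      double pr = std::min(1.0, aff(st.rec[C_TC][j], epi, p) * boost);
      if (pr > 0 && ru() < pr) {
        st.state[C_TC][j] = 1;
        st.age[C_TC][j] = 0;
        used_tc[j] = 1;
      }
    }
  }

  // (3c) allogeneic vaccine cells break tolerance: activate naive Th with a
  // relaxed match threshold (stimulating multiple T-cell clones)
  order.resize(st.site[C_VC].size());
  for (size_t i = 0; i < order.size(); ++i) order[i] = (int)i;
  shuffle_vec(order);
  for (size_t k = 0; k < order.size(); ++k) {
    int i = order[k];
    int s = st.site[C_VC][i];
    int j = Pick::from(by_site[C_TH][s], used_th, &st.state[C_TH], 0);
    if (j < 0) continue;
    int m = hamming(st.rec[C_TH][j], st.rec[C_VC][i]);
    double a = affinity_m(m, p.mmin - p.allo_relax, p.rlen, p.cbase);
    double pr = std::min(1.0, a * (1.0 + p.il12_boost * st.il12[s]));
    if (pr > 0 && ru() < pr) {
      st.state[C_TH][j] = 1;
      st.age[C_TH][j] = 0;
      used_th[j] = 1;
    }
  }

  // (3d) T helper help: an activated Th stimulates duplication of one
  // activated B and one activated Tc sharing its site (clonal expansion)
  order.resize(st.site[C_TH].size());
  for (size_t i = 0; i < order.size(); ++i) order[i] = (int)i;
  shuffle_vec(order);
  for (size_t k = 0; k < order.size(); ++k) {
    int i = order[k];
    if (st.state[C_TH][i] != 1) continue;
    int s = st.site[C_TH][i];
    int j = Pick::from(by_site[C_B][s], none, &st.state[C_B], 1);
    if (j >= 0 && below_cap(st, p, C_B) && ru() < p.p_aspecific)
      add_agent(st, C_B, s, st.rec[C_B][j], 1);
    j = Pick::from(by_site[C_TC][s], none, &st.state[C_TC], 1);
    if (j >= 0 && below_cap(st, p, C_TC) && ru() < p.p_aspecific)
      add_agent(st, C_TC, s, st.rec[C_TC][j], 1);
  }
  // clones created by help are excluded from further interactions this step
  used_b.resize(st.site[C_B].size(), 1);
  used_tc.resize(st.site[C_TC].size(), 1);

  // (3e) B-cell antigen recognition: secretes a burst of antibodies carrying
  // the B receptor; specific, IL-12-enhanced; antigen is not consumed
  order.resize(st.site[C_B].size());
  for (size_t i = 0; i < order.size(); ++i) order[i] = (int)i;
  shuffle_vec(order);
  for (size_t k = 0; k < order.size(); ++k) {
    int i = order[k];
    if (used_b[i]) continue;
    int s = st.site[C_B][i];
    int epi = -1;
    int j = Pick::from(by_site[C_AG][s], ag_gone, NULL, 0);
    if (j >= 0) epi = st.rec[C_AG][j];
    else {
      j = Pick::from(by_site[C_VC][s], vc_dead, NULL, 0);
      if (j >= 0) epi = st.rec[C_VC][j];
    }
    if (epi < 0) continue;
    double a = aff(st.rec[C_B][i], epi, p);
    double pr = std::min(1.0, a * (1.0 + p.il12_boost * st.il12[s]));
    if (pr > 0 && ru() < pr) {
      used_b[i] = 1;
      st.state[C_B][i] = 1;
      st.age[C_B][i] = 0;
      for (int q = 0; q < p.ab_burst; ++q)
        add_agent(st, C_AB, s, st.rec[C_B][i], 0);
      // clonal selection: an antigen-binding B cell divides
      if (below_cap(st, p, C_B))
        add_agent(st, C_B, s, st.rec[C_B][i], 1);
    }
  }

  // (3f) tumor killing: cytotoxic T cell first, then antibody (consumed),
  // then aspecific NK attack
  order.resize(st.site[C_TU].size());
  for (size_t i = 0; i < order.size(); ++i) order[i] = (int)i;
  shuffle_vec(order);
  for (size_t k = 0; k < order.size(); ++k) {
    int i = order[k];
    int s = st.site[C_TU][i];
    int j = Pick::from(by_site[C_TC][s], used_tc, &st.state[C_TC], 1);
    if (j >= 0) {
      if (ru() < aff(st.rec[C_TC][j], p.taa, p)) {
        tu_dead[i] = 1;
        used_tc[j] = 1;
        st.kil_tc += 1.0;
        continue;
      }
    }
    j = Pick::from(by_site[C_AB][s], ab_gone, NULL, 0);
    if (j >= 0) {
      if (ru() < aff(st.rec[C_AB][j], p.taa, p)) {
        tu_dead[i] = 1;
        ab_gone[j] = 1;
        st.kil_ab += 1.0;
        continue;
      }
    }
    if (!by_site[C_NK][s].empty() && ru() < p.nk_kill) {
      tu_dead[i] = 1;
      st.kil_nk += 1.0;
    }
  }

  // (3g) immune clearance of vaccine cells releases antigen
  order.resize(st.site[C_VC].size());
  for (size_t i = 0; i < order.size(); ++i) order[i] = (int)i;
  shuffle_vec(order);
  for (size_t k = 0; k < order.size(); ++k) {
    int i = order[k];
    if (vc_dead[i]) continue;
    int s = st.site[C_VC][i];
    bool killed = false;
    int j = Pick::from(by_site[C_TC][s], used_tc, &st.state[C_TC], 1);
    if (j >= 0 && ru() < aff(st.rec[C_TC][j], p.taa, p)) {
      used_tc[j] = 1;
      killed = true;
    } else if (!by_site[C_NK][s].empty() && ru() < p.p_aspecific) {
      killed = true;
    }
    if (killed) {
      vc_dead[i] = 1;
      for (int q = 0; q < p.ag_burst; ++q)
        add_agent(st, C_AG, s, st.rec[C_VC][i], 0);
    }
  }

  // molecules released during the interaction phase are alive by definition
  ag_gone.resize(st.site[C_AG].size(), 0);
  ab_gone.resize(st.site[C_AB].size(), 0);
  compact(st, C_TU, tu_dead);
  compact(st, C_VC, vc_dead);
  compact(st, C_AG, ag_gone);
  compact(st, C_AB, ab_gone);

  // (4) ageing, death, homeostatic replenishment.  A vaccine cell dying of
  // age is processed and releases its antigen load.
  for (int c = 0; c < NCLS; ++c) {
    if (c == C_TU) continue; // tumor cells are immortal
    size_t n = st.site[c].size();
    std::vector<char> dead(n, 0);
    for (size_t i = 0; i < n; ++i) {
      st.age[c][i] += 1;
      if (p.lifespan[c] > 0 && st.age[c][i] > p.lifespan[c]) dead[i] = 1;
    }
    if (c == C_VC) {
      for (size_t i = 0; i < n; ++i) {
        if (dead[i])
          for (int q = 0; q < p.ag_burst; ++q)
            add_agent(st, C_AG, st.site[c][i], st.rec[c][i], 0);
      }
    }
    compact(st, c, dead);
  }
  for (int c = 0; c < N_IMMUNE; ++c) {
    int deficit = p.baseline[c] - (int)st.site[c].size();
    for (int i = 0; i < deficit; ++i)
      add_agent(st, c, ri(p.S), rand_receptor(p.rlen), 0);
  }

  // (5) carcinogenesis: existing tumor cells duplicate in place, then
  // newborn tumor cells are seeded at random sites
  {
    size_t npre = st.site[C_TU].size();
    for (size_t i = 0; i < npre; ++i) {
      if (ru() < p.p_dup) {
        add_agent(st, C_TU, st.site[C_TU][i], 0, 0);
        st.dup += 1.0;
      }
    }
    for (int i = 0; i < p.tumor_birth; ++i) {
      add_agent(st, C_TU, ri(p.S), 0, 0);
      st.born += 1.0;
    }
  }

  // (6) IL-12 field decay
  for (int s = 0; s < p.S; ++s) st.il12[s] *= (1.0 - p.il12_decay);

  // (7) palpable-tumor stopping rule
  if ((double)st.site[C_TU].size() >= p.threshold) st.stopped = true;
  st.step += 1;
}

// ---------- exported entry points ----------

// [[Rcpp::export]]
List cpp_init_state(List params) {
  Pars p = parse_pars(params);
  State st;
  init_state_impl(st, p);
  return state_to_list(st);
}

// [[Rcpp::export]]
List cpp_inject(List state, List params) {
  Pars p = parse_pars(params);
  State st = state_from_list(state);
  inject_impl(st, p);
  return state_to_list(st);
}

// [[Rcpp::export]]
List cpp_step(List state, List params, int schedule_bit) {
  Pars p = parse_pars(params);
  State st = state_from_list(state);
  step_impl(st, p, schedule_bit);
  return state_to_list(st);
}

// Full virtual-mouse run: init + step loop, recording one trajectory row per
// simulated day.  dose_day[d] == 1 means an administration on day d (0-based).
// [[Rcpp::export]]
List cpp_run_mouse(List params, IntegerVector dose_day) {
  Pars p = parse_pars(params);
  State st;
  init_state_impl(st, p);

  int n_days = p.horizon_steps / p.steps_per_day;
  if (dose_day.size() < n_days)
    stop("dose_day shorter than simulated horizon");

  std::vector<double> traj[10];
  double peak = 0.0;
  int survival_step = p.horizon_steps;
  bool survived = true;

  // record state at the start of each day d (d = 0 is the initial state)
  for (int step = 0; step < p.horizon_steps; ++step) {
    if (step % p.steps_per_day == 0) {
      int day = step / p.steps_per_day;
      double il12_tot = 0.0;
      for (int s = 0; s < p.S; ++s) il12_tot += st.il12[s];
      traj[0].push_back(day);
      traj[1].push_back((double)st.site[C_TU].size());
      traj[2].push_back((double)st.site[C_B].size());
      traj[3].push_back((double)st.site[C_TH].size());
      traj[4].push_back((double)st.site[C_TC].size());
      traj[5].push_back((double)st.site[C_NK].size());
      traj[6].push_back((double)st.site[C_DC].size());
      traj[7].push_back((double)st.site[C_AB].size());
      traj[8].push_back((double)st.site[C_VC].size());
      traj[9].push_back(il12_tot);
    }
    int day = step / p.steps_per_day;
    step_impl(st, p, dose_day[day]);
    double ntu = (double)st.site[C_TU].size();
    if (ntu > peak) peak = ntu;
    if (st.stopped) {
      survived = false;
      survival_step = st.step;
      break;
    }
  }
  // final row: state after the last executed step
  {
    double il12_tot = 0.0;
    for (int s = 0; s < p.S; ++s) il12_tot += st.il12[s];
    traj[0].push_back((double)st.step / p.steps_per_day);
    traj[1].push_back((double)st.site[C_TU].size());
    traj[2].push_back((double)st.site[C_B].size());
    traj[3].push_back((double)st.site[C_TH].size());
    traj[4].push_back((double)st.site[C_TC].size());
    traj[5].push_back((double)st.site[C_NK].size());
    traj[6].push_back((double)st.site[C_DC].size());
    traj[7].push_back((double)st.site[C_AB].size());
    traj[8].push_back((double)st.site[C_VC].size());
    traj[9].push_back(il12_tot);
  }

  DataFrame trajectory = DataFrame::create(
      _["day"] = wrap(traj[0]), _["tumor_cells"] = wrap(traj[1]),
      _["B"] = wrap(traj[2]), _["Th"] = wrap(traj[3]),
      _["Tc"] = wrap(traj[4]), _["NK"] = wrap(traj[5]),
      _["DC"] = wrap(traj[6]), _["antibodies"] = wrap(traj[7]),
      _["vaccine_cells"] = wrap(traj[8]), _["il12_total"] = wrap(traj[9]));

  return List::create(_["survived"] = survived,
                      _["survival_step"] = survival_step,
                      _["peak_burden"] = peak, _["trajectory"] = trajectory,
                      _["final_state"] = state_to_list(st));
}
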