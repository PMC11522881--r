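#include <Rcpp.h>
using namespace Rcpp;

// State encoding shared with R/states.R: index = ((h*2 + s)*2 + l)*3 + f,
// h (house) 0 = mobile / 1 = fixed, s (savings) 0/1, l (tenure) 0/1,
// f (family) 0 = single / 1 = couple / 2 = family with dependants.
// Behaviours: 0 = save, 1 = build, 2 = move.

static const int N_STATE = 24;

static inline int sidx(int h, int s, int l, int f) {
  return ((h * 2 + s) * 2 + l) * 3 + f;
}

struct Pars {
  double pss, phb, plm, psl, pfm; // behaviour / shock probabilities
  int bc;                         // build condition: savings required?
  double base, hb, tb, sp;        // family growth: base, house/tenure bonus, savings penalty
};

// Per-step family growth probability, from start-of-step covariates.
static inline double growth_prob(const Pars& p, int h0, int s0, int l0) {
  double g = p.base * (1.0 + p.hb * h0 + p.tb * l0) * (s0 ? p.sp : 1.0);
  if (g < 0.0) g = 0.0;
  if (g > 1.0) g = 1.0;
  return g;
}

// Behaviour resolution: outcomes of enacting `beh` from (h0, s0, l0).
// Writes up to two branches (prob, h, s, l); returns branch count.
static int behaviour_branches(int beh, int h0, int s0, int l0, const Pars& p,
                              double* bp, int* bh, int* bs, int* bl) {
  if (beh == 0) { // save: gain savings with prob pss if none held
    if (s0 == 0) {
      bp[0] = p.pss;       bh[0] = h0; bs[0] = 1;  bl[0] = l0;
      bp[1] = 1.0 - p.pss; bh[1] = h0; bs[1] = s0; bl[1] = l0;
      return 2;
    }
  } else if (beh == 1) { // build: mobile -> fixed; under bc savings are consumed
    bool blocked = (p.bc == 1 && s0 == 0) || h0 == 1;
    if (!blocked) {
      bp[0] = p.phb;       bh[0] = 1;  bs[0] = (p.bc == 1) ? 0 : s0; bl[0] = l0;
      bp[1] = 1.0 - p.phb; bh[1] = h0; bs[1] = s0;                   bl[1] = l0;
      return 2;
    }
  } else { // move: relocation gains tenure, fixed house is abandoned
    bp[0] = p.plm;       bh[0] = 0;  bs[0] = s0; bl[0] = 1;
    bp[1] = 1.0 - p.plm; bh[1] = h0; bs[1] = s0; bl[1] = l0;
    return 2;
  }
  bp[0] = 1.0; bh[0] = h0; bs[0] = s0; bl[0] = l0; // behaviour is a no-op
  return 1;
}

// Family event split: add probability mass p into out[] for end states.
static inline void family_split(double* out, double p, double g, int h, int s, int l, int f0) {
  int fup = f0 < 2 ? f0 + 1 : 2;
  out[sidx(h, s, l, fup)] += p * g;
  out[sidx(h, s, l, f0)] += p * (1.0 - g);
}

// Exact one-step distribution from state (h0, s0, l0, f0) under behaviour beh.
// Event order: behaviour, savings-loss shock, forced-move shock (untenured only),
// family growth (start-of-step covariates).
static void step_distribution(int h0, int s0, int l0, int f0, int beh,
                              const Pars& p, double* out) {
  double bp[2]; int bh[2], bs[2], bl[2];
  int nb = behaviour_branches(beh, h0, s0, l0, p, bp, bh, bs, bl);
  double g = growth_prob(p, h0, s0, l0);

  for (int i = 0; i < nb; ++i) {
    int h1 = bh[i], s1 = bs[i], l1 = bl[i];
    int nl = (s1 == 1) ? 2 : 1;
    for (int j = 0; j < nl; ++j) {
      double p2 = bp[i];
      int s2 = s1;
      if (s1 == 1) { // savings-loss shock
        p2 *= (j == 0) ? (1.0 - p.psl) : p.psl;
        s2 = (j == 0) ? 1 : 0;
      }
      if (l1 == 0) { // forced move possible only without tenure
        family_split(out, p2 * (1.0 - p.pfm), g, h1, s2, l1, f0);
        family_split(out, p2 * p.pfm * p.plm, g, 0, s2, 1, f0);
        family_split(out, p2 * p.pfm * (1.0 - p.plm), g, 0, s2, 0, f0);
      } else {
        family_split(out, p2, g, h1, s2, l1, f0);
      }
    }
  }
}

static Pars make_pars(double pss, double phb, double plm, double psl, double pfm,
                      int bc, double base, double hb, double tb, double sp) {
  Pars p;
  p.pss = pss; p.phb = phb; p.plm = plm; p.psl = psl; p.pfm = pfm;
  p.bc = bc; p.base = base; p.hb = hb; p.tb = tb; p.sp = sp;
  return p;
}

// Full kernel as a 24 x 24 x 3 array (current state, next state, behaviour).
// [[Rcpp::export]]
NumericVector cpp_kernel(double pss, double phb, double plm, double psl, double pfm,
                         int bc, double base, double hb, double tb, double sp) {
  Pars p = make_pars(pss, phb, plm, psl, pfm, bc, base, hb, tb, sp);
  NumericVector out(N_STATE * N_STATE * 3);
  double buf[N_STATE];
  for (int beh = 0; beh < 3; ++beh) {
    for (int h = 0; h < 2; ++h) for (int s = 0; s < 2; ++s)
      for (int l = 0; l < 2; ++l) for (int f = 0; f < 3; ++f) {
        int from = sidx(h, s, l, f);
        std::fill(buf, buf + N_STATE, 0.0);
        step_distribution(h, s, l, f, beh, p, buf);
        for (int to = 0; to < N_STATE; ++to)
          out[from + N_STATE * to + N_STATE * N_STATE * beh] = buf[to];
      }
  }
  out.attr("dim") = IntegerVector::create(N_STATE, N_STATE, 3);
  return out;
}

// Backward induction over the terminal pay-off. Ties within `tol` of the
// maximum are broken save > build > move.
// [[Rcpp::export]]
List cpp_solve(NumericVector kernel, NumericVector payoff, int horizon, double tol) {
  IntegerMatrix policy(N_STATE, horizon);
  NumericMatrix value(N_STATE, horizon + 1);
  for (int sI = 0; sI < N_STATE; ++sI) value(sI, horizon) = payoff[sI];

  for (int t = horizon - 1; t >= 0; --t) {
    for (int sI = 0; sI < N_STATE; ++sI) {
      double ev[3];
      for (int b = 0; b < 3; ++b) {
        double acc = 0.0;
        const double* K = &kernel[sI + N_STATE * N_STATE * b];
        for (int to = 0; to < N_STATE; ++to)
          acc += K[N_STATE * to] * value(to, t + 1);
        ev[b] = acc;
      }
      double best = std::max(ev[0], std::max(ev[1], ev[2]));
      int pick = 0;
      for (int b = 0; b < 3; ++b) {
        if (ev[b] >= best - tol) { pick = b; break; }
      }
      policy(sI, t) = pick;
      value(sI, t) = best;
    }
  }
  return List::create(_["policy"] = policy, _["value"] = value);
}

struct StepLog {
  int beh, success, savings_lost, forced_move, forced_tenure, family_event, state_end;
};

// One event-level step; mirrors step_distribution in law. Uses R's RNG.
static void sim_step(int& h, int& s, int& l, int& f, int beh, const Pars& p, StepLog& log) {
  int h0 = h, s0 = s, l0 = l;
  double g = growth_prob(p, h0, s0, l0);
  log.beh = beh;
  log.success = NA_INTEGER;
  log.savings_lost = NA_INTEGER;
  log.forced_move = NA_INTEGER;
  log.forced_tenure = NA_INTEGER;

  if (beh == 0) {
    if (s0 == 0) {
      log.success = (unif_rand() < p.pss) ? 1 : 0;
      if (log.success == 1) s = 1;
    }
  } else if (beh == 1) {
    bool blocked = (p.bc == 1 && s0 == 0) || h0 == 1;
    if (!blocked) {
      log.success = (unif_rand() < p.phb) ? 1 : 0;
      if (log.success == 1) {
        h = 1;
        if (p.bc == 1) s = 0;
      }
    }
  } else {
    log.success = (unif_rand() < p.plm) ? 1 : 0;
    if (log.success == 1) { h = 0; l = 1; }
  }

  if (s == 1) {
    log.savings_lost = (unif_rand() < p.psl) ? 1 : 0;
    if (log.savings_lost == 1) s = 0;
  }

  if (l == 0) {
    log.forced_move = (unif_rand() < p.pfm) ? 1 : 0;
    if (log.forced_move == 1) {
      h = 0;
      log.forced_tenure = (unif_rand() < p.plm) ? 1 : 0;
      if (log.forced_tenure == 1) l = 1;
    }
  }

  log.family_event = (unif_rand() < g) ? 1 : 0;
  if (log.family_event == 1 && f < 2) f = f + 1;
  log.state_end = sidx(h, s, l, f);
}

// Forward simulation of agents enacting a solved policy.
// init: start state indices (0..23); stay: per-agent stay lengths (steps).
// Returns one row per agent-step with full event logs.
// [[Rcpp::export]]
IntegerMatrix cpp_simulate(IntegerMatrix policy,
                           double pss, double phb, double plm, double psl, double pfm,
                           int bc, double base, double hb, double tb, double sp,
                           IntegerVector init, IntegerVector stay) {
  Pars p = make_pars(pss, phb, plm, psl, pfm, bc, base, hb, tb, sp);
  int n = init.size();
  long total = 0;
  for (int i = 0; i < n; ++i) total += stay[i];
  IntegerMatrix out(total, 10);
  long row = 0;
  for (int a = 0; a < n; ++a) {
    int st = init[a];
    int f = st % 3, l = (st / 3) % 2, s = (st / 6) % 2, h = st / 12;
    for (int t = 0; t < stay[a]; ++t) {
      int beh = policy(sidx(h, s, l, f), t);
      StepLog log;
      int state_start = sidx(h, s, l, f);
      sim_step(h, s, l, f, beh, p, log);
      out(row, 0) = a + 1;
      out(row, 1) = t + 1;
      out(row, 2) = state_start;
      out(row, 3) = log.beh;
      out(row, 4) = log.success;
      out(row, 5) = log.savings_lost;
      out(row, 6) = log.forced_move;
      out(row, 7) = log.forced_tenure;
      out(row, 8) = log.family_event;
      out(row, 9) = log.state_end;
      ++row;
    }
  }
  return out;
}

static inline int draw_init_state(int init_mode) {
  if (init_mode == 1) { // all_mobile: house fixed at mobile, rest uniform
    int r = (int)(unif_rand() * 12);
    if (r > 11) r = 11;
    return r; // indices 0..11 are exactly the h = 0 states
  }
  int r = (int)(unif_rand() * N_STATE);
  if (r > N_STATE - 1) r = N_STATE - 1;
  return r;
}

// Cross-sectional records: one household per entry of `times`, simulated to
// its residence time. Returns n x 6: time, first_house, current_house,
// savings, tenure, family.
// [[Rcpp::export]]
IntegerMatrix cpp_cross_section(IntegerMatrix policy,
                                double pss, double phb, double plm, double psl, double pfm,
                                int bc, double base, double hb, double tb, double sp,
                                IntegerVector times, int init_mode) {
  Pars p = make_pars(pss, phb, plm, psl, pfm, bc, base, hb, tb, sp);
  int n = times.size();
  IntegerMatrix out(n, 6);
  for (int i = 0; i < n; ++i) {
    int st = draw_init_state(init_mode);
    int f = st % 3, l = (st / 3) % 2, s = (st / 6) % 2, h = st / 12;
    int first_h = h;
    for (int t = 0; t < times[i]; ++t) {
      StepLog log;
      sim_step(h, s, l, f, policy(sidx(h, s, l, f), t), p, log);
    }
    out(i, 0) = times[i];
    out(i, 1) = first_h;
    out(i, 2) = h;
    out(i, 3) = s;
    out(i, 4) = l;
    out(i, 5) = f;
  }
  return out;
}

// ABC inner loop: for each prior draw, solve the SDP, simulate one household
// per reference residence time, summarize, and return the distance to the
// reference summary vector (order: 4 transitions, savings none/has, tenure
// none/has, family single/couple/dependants).
// draws: m x 5 (p_s_save, p_l_move, p_h_build, build_condition, scenario 0-based)
// payoffs: 24 x n_scenario terminal pay-off columns.
// [[Rcpp::export]]
NumericVector cpp_abc_distances(NumericVector ref, IntegerVector times, NumericMatrix draws,
                                double psl, double pfm, double base, double hb, double tb,
                                double sp, NumericMatrix payoffs, int horizon, double tol,
                                int init_mode, int proportion) {
  int m = draws.nrow(), n = times.size();
  NumericVector dist(m);
  double ref_n = 0.0;
  for (int k = 0; k < 4; ++k) ref_n += ref[k];

  for (int d = 0; d < m; ++d) {
    Pars p = make_pars(draws(d, 0), draws(d, 2), draws(d, 1), psl, pfm,
                       (int)draws(d, 3), base, hb, tb, sp);
    NumericVector kernel = cpp_kernel(p.pss, p.phb, p.plm, p.psl, p.pfm,
                                      p.bc, p.base, p.hb, p.tb, p.sp);
    int scen = (int)draws(d, 4);
    NumericVector payoff = payoffs(_, scen);
    List sol = cpp_solve(kernel, payoff, horizon, tol);
    IntegerMatrix policy = sol["policy"];

    double stat[11] = {0};
    for (int i = 0; i < n; ++i) {
      int st = draw_init_state(init_mode);
      int f = st % 3, l = (st / 3) % 2, s = (st / 6) % 2, h = st / 12;
      int first_h = h;
      for (int t = 0; t < times[i]; ++t) {
        StepLog log;
        sim_step(h, s, l, f, policy(sidx(h, s, l, f), t), p, log);
      }
      stat[first_h * 2 + h] += 1.0;
      stat[4 + s] += 1.0;
      stat[6 + l] += 1.0;
      stat[8 + f] += 1.0;
    }
    double acc = 0.0;
    for (int k = 0; k < 11; ++k) {
      double sim_v = stat[k], ref_v = ref[k];
      if (proportion == 1) { sim_v /= (double)n; ref_v /= ref_n; }
      acc += std::fabs(sim_v - ref_v);
    }
    dist[d] = acc;
    if (d % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return dist;
}
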