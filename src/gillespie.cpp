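// Event-driven Gillespie simulation of a myosin motor ensemble interacting
// with a rigid actin filament, plus the strain-dependent rate evaluator
// shared with the R side (single source of truth for rate formulas).
//
// Mechanics: linear cross-bridge elasticity; after every event that changes
// the force-bearing set the filament position is re-solved in closed form
// (rigid filament, no viscous drag).  Strain convention: x = c_i + z where
// c_i = site - anchor offset of motor i and z the filament displacement;
// x = 0 at the rigor (AM) free-energy minimum; stretch increases z.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int MECH_DET = 0, MECH_WEAK = 1, MECH_FB = 2;
static const int F_CONST = 1, F_BELL = 2, F_EXP = 3, F_SYM = 4, F_ATTACH = 5,
                 F_EXPFLOOR = 6, F_VEXP = 7, F_REVCONST = 8;

struct Scheme {
  int n_states, n_trans;
  std::vector<int> mech;
  std::vector<double> G, xmin;
  std::vector<int> from, to, form;
  std::vector<double> A, p1, p2, p3;
  std::vector<int> rev;
  double kT, kappa, cap, lcut;
  // per-state transition row indices (rows leaving the state, rows whose
  // backward member enters the state)
  std::vector< std::vector<int> > rows_from, rows_to;
};

static Scheme make_scheme(const NumericMatrix& states,
                          const NumericMatrix& trans,
                          double kT, double kappa, double cap,
                          double lcut = 0.3) {
  Scheme s;
  s.n_states = states.nrow();
  s.n_trans = trans.nrow();
  s.kT = kT; s.kappa = kappa; s.cap = cap; s.lcut = lcut;
  for (int i = 0; i < s.n_states; ++i) {
    s.mech.push_back((int) states(i, 0));
    s.G.push_back(states(i, 1));
    s.xmin.push_back(states(i, 2));
  }
  s.rows_from.resize(s.n_states);
  s.rows_to.resize(s.n_states);
  for (int r = 0; r < s.n_trans; ++r) {
    s.from.push_back((int) trans(r, 0));
    s.to.push_back((int) trans(r, 1));
    s.form.push_back((int) trans(r, 2));
    s.A.push_back(trans(r, 3));
    s.p1.push_back(trans(r, 4));
    s.p2.push_back(trans(r, 5));
    s.rev.push_back((int) trans(r, 6));
    s.p3.push_back(trans.ncol() > 7 ? trans(r, 7) : 1e9);
    s.rows_from[s.from[r]].push_back(r);
    if (s.rev[r]) s.rows_to[s.to[r]].push_back(r);
  }
  return s;
}

static inline double g_of(const Scheme& s, int st, double x) {
  double g = s.G[st];
  if (s.mech[st] == MECH_FB) {
    double d = x - s.xmin[st];
    g += 0.5 * s.kappa * d * d / s.kT;
  }
  return g;
}

// forward and detailed-balance backward rate of transition row r at strain
// x, with the pair-preserving cap (computed in log space to avoid overflow)
static inline void pair_rates(const Scheme& s, int r, double x,
                              double& fwd, double& bwd) {
  double A = s.A[r];
  if (A <= 0.0) { fwd = 0.0; bwd = 0.0; return; }
  double dG = g_of(s, s.to[r], x) - g_of(s, s.from[r], x);
  double lf = std::log(A);
  switch (s.form[r]) {
  case F_BELL: {
    double d = x - s.p1[r];
    lf += -d * d / (2.0 * s.p2[r] * s.p2[r]);
    if (x > s.p3[r]) lf += -(x - s.p3[r]) / s.lcut;  // steric taper
    break; }
  case F_EXP:
    lf += -x / s.p1[r];
    break;
  case F_SYM:
    lf += -0.5 * dG;
    break;
  case F_EXPFLOOR: {
    double xe = x < s.p2[r] ? x : s.p2[r];
    lf += -(xe - s.p2[r]) / s.p1[r];
    break; }
  case F_VEXP:
    lf += std::fabs(x - s.p2[r]) / s.p1[r];
    break;
  case F_REVCONST:
    lf += -dG;
    break;
  default: break; // F_CONST, F_ATTACH
  }
  double lb = lf + dG;
  double lcap = std::log(s.cap);
  if (s.rev[r]) {
    double m = lf > lb ? lf : lb;
    if (m > lcap) { lf -= m - lcap; lb -= m - lcap; }
    fwd = std::exp(lf);
    bwd = std::exp(lb);
  } else {
    fwd = std::exp(lf > lcap ? lcap : lf);
    bwd = 0.0;
  }
}

// [[Rcpp::export]]
NumericMatrix xb_pair_rates_cpp(NumericMatrix states, NumericMatrix trans,
                                double kT, double kappa, double cap,
                                double x, double lambda_cut = 0.3) {
  Scheme s = make_scheme(states, trans, kT, kappa, cap, lambda_cut);
  NumericMatrix out(s.n_trans, 2);
  for (int r = 0; r < s.n_trans; ++r) {
    double f, b;
    pair_rates(s, r, x, f, b);
    out(r, 0) = f; out(r, 1) = b;
  }
  return out;
}

struct Engine {
  Scheme s;
  int n;                       // motors
  std::vector<int> state;
  std::vector<double> cst;     // c_i = site - anchor (NAN if detached)
  std::vector<double> anchor;  // m_i
  std::vector<double> atot;    // per-motor propensity totals
  double z;                    // filament displacement
  double spacing, phase, x_lo, x_hi;
  int mode;                    // 0 free, 1 clamp, 2 ramp(clamped)
  double load;
  std::vector<double> cs_buf;  // reusable candidate-site buffer
  // detached states have x-independent exit rates: cache the constant
  // part and the per-site attach amplitude for an O(1) fast path
  std::vector<double> det_const, det_attach;

  bool attached(int i) const { return state[i] >= 0 && !std::isnan(cst[i]); }

  void cache_detached() {
    det_const.assign(s.n_states, -1.0);
    det_attach.assign(s.n_states, 0.0);
    for (int st = 0; st < s.n_states; ++st) {
      if (s.mech[st] != MECH_DET) continue;
      double tot = 0.0, att = 0.0, f, b;
      for (size_t k = 0; k < s.rows_from[st].size(); ++k) {
        int r = s.rows_from[st][k];
        pair_rates(s, r, 0.0, f, b);
        if (s.form[r] == F_ATTACH) att += f; else tot += f;
      }
      for (size_t k = 0; k < s.rows_to[st].size(); ++k) {
        pair_rates(s, s.rows_to[st][k], 0.0, f, b);
        tot += b;
      }
      det_const[st] = tot;
      det_attach[st] = att;
    }
  }

  // number of candidate sites without materializing them
  int n_cand(int i) const {
    double lo = x_lo - z + anchor[i] - phase;
    double hi = x_hi - z + anchor[i] - phase;
    int j0 = (int) std::ceil(lo / spacing - 1e-12);
    int j1 = (int) std::floor(hi / spacing + 1e-12);
    return j1 >= j0 ? j1 - j0 + 1 : 0;
  }

  // candidate sites for motor i: c values with x = c + z in [x_lo, x_hi]
  void cand_sites(int i, std::vector<double>& out) const {
    out.clear();
    double lo = x_lo - z + anchor[i] - phase;
    double hi = x_hi - z + anchor[i] - phase;
    int j0 = (int) std::ceil(lo / spacing - 1e-12);
    int j1 = (int) std::floor(hi / spacing + 1e-12);
    for (int j = j0; j <= j1; ++j)
      out.push_back(phase + j * spacing - anchor[i]);
  }

  double motor_total(int i) {
    int st = state[i];
    if (s.mech[st] == MECH_DET && det_const[st] >= 0.0)
      return det_const[st] + det_attach[st] * n_cand(i);
    double x = attached(i) ? cst[i] + z : 0.0;
    double tot = 0.0, f, b;
    for (size_t k = 0; k < s.rows_from[st].size(); ++k) {
      int r = s.rows_from[st][k];
      if (s.form[r] == F_ATTACH) {
        pair_rates(s, r, 0.0, f, b);
        tot += f * n_cand(i);
      } else {
        pair_rates(s, r, x, f, b);
        tot += f;
      }
    }
    for (size_t k = 0; k < s.rows_to[st].size(); ++k) {
      pair_rates(s, s.rows_to[st][k], x, f, b);
      tot += b;
    }
    return tot;
  }

  int n_fb() const {
    int m = 0;
    for (int i = 0; i < n; ++i)
      if (attached(i) && s.mech[state[i]] == MECH_FB) ++m;
    return m;
  }

  double tension() const {
    double T = 0.0;
    for (int i = 0; i < n; ++i)
      if (attached(i) && s.mech[state[i]] == MECH_FB)
        T += s.kappa * (cst[i] + z - s.xmin[state[i]]);
    return T;
  }

  // closed-form force balance (free / isotonic modes)
  void solve_z() {
    if (mode != 0) return;
    double sum = 0.0; int m = 0;
    for (int i = 0; i < n; ++i)
      if (attached(i) && s.mech[state[i]] == MECH_FB) {
        sum += s.xmin[state[i]] - cst[i];
        ++m;
      }
    if (m > 0) z = (load / s.kappa + sum) / m;
  }
};

// [[Rcpp::export]]
List xb_simulate_cpp(NumericMatrix states, NumericMatrix trans,
                     double kT, double kappa, double cap, double lambda_cut,
                     NumericVector anchors, IntegerVector init_state,
                     NumericVector init_cst, double z0,
                     double spacing, double phase,
                     double x_lo, double x_hi,
                     int mode, double load,
                     double ramp_speed, double ramp_t0, double ramp_t1,
                     double duration, double record_dt, double update_dt,
                     double max_events, int atp_row, int stop_after_events) {
  Engine e;
  e.s = make_scheme(states, trans, kT, kappa, cap, lambda_cut);
  e.n = anchors.size();
  e.anchor.assign(anchors.begin(), anchors.end());
  e.state.assign(init_state.begin(), init_state.end());
  e.cst.assign(init_cst.begin(), init_cst.end());
  e.z = z0;
  e.spacing = spacing; e.phase = phase; e.x_lo = x_lo; e.x_hi = x_hi;
  e.mode = mode; e.load = load;
  e.solve_z();
  e.cache_detached();
  e.atot.resize(e.n);
  double a0 = 0.0;
  for (int i = 0; i < e.n; ++i) { e.atot[i] = e.motor_total(i); a0 += e.atot[i]; }
  double events_since_resync = 0.0;

  int n_rec = (int) std::floor(duration / record_dt + 1e-9) + 1;
  NumericVector rec_t(n_rec), rec_z(n_rec), rec_F(n_rec), rec_atp(n_rec);
  IntegerMatrix rec_counts(n_rec, e.s.n_states);
  int irec = 0;
  double t = 0.0, atp = 0.0;
  double n_events = 0.0;
  bool absorbed = false, exploded = false;

  RNGScope rng;
  std::vector<double>& cs = e.cs_buf;

  double clamp_base = z0;
  auto clamp_pos = [&](double tt) {
    if (mode != 2) return clamp_base;
    if (tt <= ramp_t0) return clamp_base;
    double te = tt < ramp_t1 ? tt : ramp_t1;
    return clamp_base + ramp_speed * (te - ramp_t0);
  };

  auto record = [&](double tt) {
    rec_t[irec] = tt; rec_z[irec] = e.z; rec_F[irec] = e.tension();
    rec_atp[irec] = atp;
    for (int i = 0; i < e.n; ++i) rec_counts(irec, e.state[i])++;
    ++irec;
  };
  record(0.0);

  double next_rec = record_dt;
  // clamp-position updates only matter while ramping
  double next_upd = (mode == 2) ? ramp_t0 + update_dt : R_PosInf;

  auto refresh_all = [&]() {
    a0 = 0.0;
    for (int i = 0; i < e.n; ++i) { e.atot[i] = e.motor_total(i); a0 += e.atot[i]; }
  };
  auto refresh_one = [&](int i) {
    a0 -= e.atot[i];
    e.atot[i] = e.motor_total(i);
    a0 += e.atot[i];
  };

  while (t < duration) {
    if (events_since_resync > 5e5) {  // guard against float drift
      refresh_all();
      events_since_resync = 0.0;
    }
    double t_ev = (a0 > 0.0) ? t + ::exp_rand() / a0 : R_PosInf;
    double t_tick = next_rec < next_upd ? next_rec : next_upd;

    if (t_ev > t_tick || t_ev > duration) {
      if (!std::isfinite(t_ev) && t_tick > duration) { absorbed = true; }
      double tt = t_tick < duration ? t_tick : duration;
      t = tt;
      if (mode == 2 && tt >= ramp_t0 && next_upd <= tt + 1e-15) {
        double znew = clamp_pos(tt);
        if (znew != e.z) {
          e.z = znew;
          refresh_all();
        }
        next_upd = (tt >= ramp_t1) ? R_PosInf : tt + update_dt;
      }
      while (next_rec <= t + 1e-15 && irec < n_rec) {
        record(next_rec);
        next_rec += record_dt;
      }
      if (absorbed) break;
      continue;
    }

    // an event fires at t_ev
    t = t_ev;
    n_events += 1.0;
    if (n_events > max_events) { exploded = true; break; }

    // select motor
    double u = ::unif_rand() * a0;
    int mi = e.n - 1;
    for (int i = 0; i < e.n; ++i) {
      if (u < e.atot[i]) { mi = i; break; }
      u -= e.atot[i];
    }
    // select transition within motor (recompute its event list)
    int st = e.state[mi];
    double x = e.attached(mi) ? e.cst[mi] + e.z : 0.0;
    int chosen_row = -1, chosen_dir = 0;
    double chosen_c = NA_REAL;
    double f, b;
    bool done = false;
    for (size_t k = 0; k < e.s.rows_from[st].size() && !done; ++k) {
      int r = e.s.rows_from[st][k];
      if (e.s.form[r] == F_ATTACH) {
        e.cand_sites(mi, cs);
        pair_rates(e.s, r, 0.0, f, b);
        for (size_t j = 0; j < cs.size(); ++j) {
          if (u < f) {
            chosen_row = r; chosen_dir = 1; chosen_c = cs[j]; done = true;
            break;
          }
          u -= f;
        }
      } else {
        pair_rates(e.s, r, x, f, b);
        if (u < f) { chosen_row = r; chosen_dir = 1; done = true; }
        else u -= f;
      }
    }
    for (size_t k = 0; k < e.s.rows_to[st].size() && !done; ++k) {
      int r = e.s.rows_to[st][k];
      pair_rates(e.s, r, x, f, b);
      if (u < b) { chosen_row = r; chosen_dir = -1; done = true; }
      else u -= b;
    }
    if (!done) { // numerical slack: re-draw
      refresh_one(mi);
      continue;
    }

    int r = chosen_row;
    int new_state = chosen_dir > 0 ? e.s.to[r] : e.s.from[r];
    if (r == atp_row) atp += chosen_dir;
    int old_mech = e.s.mech[st], new_mech = e.s.mech[new_state];
    double old_xmin = e.s.xmin[st];

    e.state[mi] = new_state;
    if (e.s.form[r] == F_ATTACH && chosen_dir > 0) e.cst[mi] = chosen_c;
    if (new_mech == MECH_DET) e.cst[mi] = NA_REAL;

    bool force_changed =
      (old_mech == MECH_FB || new_mech == MECH_FB) &&
      !(old_mech == new_mech && old_xmin == e.s.xmin[new_state]);
    if (force_changed && e.mode == 0) {
      e.solve_z();
      refresh_all();
    } else {
      refresh_one(mi);
    }
    events_since_resync += 1.0;
    if (stop_after_events > 0 && n_events >= stop_after_events) break;
  }

  // flush remaining records at the frozen configuration
  while (irec < n_rec) {
    double tt = rec_t[irec > 0 ? irec - 1 : 0] + record_dt;
    record(tt > duration ? duration : tt);
  }

  return List::create(
    _["time"] = rec_t, _["position"] = rec_z, _["force"] = rec_F,
    _["atp"] = rec_atp, _["counts"] = rec_counts,
    _["n_events"] = n_events, _["absorbed"] = absorbed,
    _["exploded"] = exploded,
    _["final_state"] = IntegerVector(e.state.begin(), e.state.end()),
    _["final_cst"] = NumericVector(e.cst.begin(), e.cst.end()),
    _["final_z"] = e.z, _["final_t"] = t);
}
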