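#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Reaction channels are passed as an n x 8 matrix, one row per channel:
//   col 0: kind   (0 constant, 1 linear, 2 bimolecular sigv*rsiv,
//                  3 Hill of free sigma, 4 lysozyme-scaled cleavage)
//   col 1-4: rate constants c1..c4 (meaning depends on kind; for the Hill
//            channel c1=v0, c2=v, c3=n, c4=K)
//   col 5-7: stoichiometry over (sigv, rsiv, complex)
// State is carried as doubles so system-size-scaled counts stay exact
// (they remain integers in value for the SSA).

struct Channel {
  int kind;
  double c1, c2, c3, c4;
  double s0, s1, s2;
  double Kn;     // K^n, precomputed for the Hill channel
  int n_int;     // n when it is a small integer, else 0
  int species;   // reactant index for linear channels
};

static std::vector<Channel> unpack(const NumericMatrix& m) {
  std::vector<Channel> ch(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) {
    ch[i].kind = (int) m(i, 0);
    ch[i].c1 = m(i, 1); ch[i].c2 = m(i, 2);
    ch[i].c3 = m(i, 3); ch[i].c4 = m(i, 4);
    ch[i].s0 = m(i, 5); ch[i].s1 = m(i, 6); ch[i].s2 = m(i, 7);
    ch[i].Kn = std::pow(ch[i].c4, ch[i].c3);
    double n = ch[i].c3;
    ch[i].n_int = (n == std::floor(n) && n >= 1 && n <= 4) ? (int) n : 0;
    ch[i].species = (int) ch[i].c2;
  }
  return ch;
}

static inline double ipow(double s, int n) {
  double r = s;
  for (int i = 1; i < n; ++i) r *= s;
  return r;
}

static inline double propensity(const Channel& ch, const double* x, double L) {
  switch (ch.kind) {
  case 0:
    return ch.c1;
  case 1:
    return ch.c1 * x[ch.species];
  case 2:
    return ch.c1 * x[0] * x[1];
  case 3: {
    double s = x[0];
    if (s <= 0.0) return ch.c1;
    double sn = ch.n_int ? ipow(s, ch.n_int) : std::pow(s, ch.c3);
    return ch.c1 + ch.c2 * sn / (sn + ch.Kn);
  }
  case 4:
    return ch.c1 * L * x[2];
  }
  return 0.0;
}

// Gillespie direct method with piecewise-constant lysozyme input.
// The exponential clock is re-drawn at every protocol segment boundary,
// which is exact because propensities are constant between boundaries.
// [[Rcpp::export]]
List ssa_run_cpp(NumericMatrix channels, NumericVector seg_start,
                 NumericVector seg_L, double duration, double sample_interval,
                 NumericVector init, bool record_events) {
  std::vector<Channel> ch = unpack(channels);
  const int nc = (int) ch.size();
  const int nseg = seg_start.size();

  const int nsamp = (int) std::floor(duration / sample_interval + 1e-9) + 1;
  NumericVector grid(nsamp);
  for (int i = 0; i < nsamp; ++i) grid[i] = i * sample_interval;
  NumericMatrix states(nsamp, 3);

  double x[3] = { init[0], init[1], init[2] };
  std::vector<double> a(nc);
  std::vector<double> ev_t;
  std::vector<int> ev_ch;

  int gi = 0;
  for (int k = 0; k < nseg; ++k) {
    double t0 = seg_start[k];
    double t1 = (k + 1 < nseg) ? seg_start[k + 1] : duration;
    if (t1 > duration) t1 = duration;
    if (t0 >= duration) break;
    const double L = seg_L[k];
    double t = t0;

    while (true) {
      double a0 = 0.0;
      for (int j = 0; j < nc; ++j) {
        a[j] = propensity(ch[j], x, L);
        a0 += a[j];
      }
      if (!R_finite(a0) || a0 < 0.0)
        stop("non-finite or negative total propensity in SSA");
      if (a0 <= 0.0) { // fast-forward to segment end: nothing can fire
        t = t1;
        break;
      }
      double tau = exp_rand() / a0;
      if (t + tau >= t1) { // clock re-drawn at the boundary
        t = t1;
        break;
      }
      t += tau;
      // last-event-carried-forward: grid points before this event keep the
      // pre-event state
      while (gi < nsamp && grid[gi] < t) {
        states(gi, 0) = x[0]; states(gi, 1) = x[1]; states(gi, 2) = x[2];
        ++gi;
      }
      double u = unif_rand() * a0;
      int j = 0;
      double acc = a[0];
      while (u > acc && j < nc - 1) acc += a[++j];
      x[0] += ch[j].s0; x[1] += ch[j].s1; x[2] += ch[j].s2;
      if (x[0] < 0.0 || x[1] < 0.0 || x[2] < 0.0)
        stop("internal consistency error: negative copy number after event");
      if (record_events) {
        if (ev_t.size() > 50000000)
          stop("event record exceeds 5e7 events; reduce duration");
        ev_t.push_back(t);
        ev_ch.push_back(j + 1); // 1-based channel index
      }
    }
    // record grid points inside (t_event_last, t1); the boundary point itself
    // is recorded here too since no event fires exactly at t1
    while (gi < nsamp && grid[gi] <= t1 + 1e-12 && grid[gi] < duration - 1e-12) {
      states(gi, 0) = x[0]; states(gi, 1) = x[1]; states(gi, 2) = x[2];
      ++gi;
    }
  }
  while (gi < nsamp) {
    states(gi, 0) = x[0]; states(gi, 1) = x[1]; states(gi, 2) = x[2];
    ++gi;
  }

  List out = List::create(_["times"] = grid, _["states"] = states);
  if (record_events)
    out["events"] = List::create(_["time"] = wrap(ev_t),
                                 _["channel"] = wrap(ev_ch));
  return out;
}

// Chemical Langevin equation, Euler-Maruyama over reaction channels.
// Negative excursions are handled by full truncation: propensities are
// evaluated on the state clamped at zero.
// [[Rcpp::export]]
List cle_run_cpp(NumericMatrix channels, NumericVector seg_start,
                 NumericVector seg_L, double duration, double dt,
                 double sample_interval, NumericVector init) {
  if (dt <= 0.0) stop("dt must be positive");
  std::vector<Channel> ch = unpack(channels);
  const int nc = (int) ch.size();
  const int nseg = seg_start.size();

  const int nsamp = (int) std::floor(duration / sample_interval + 1e-9) + 1;
  NumericVector grid(nsamp);
  for (int i = 0; i < nsamp; ++i) grid[i] = i * sample_interval;
  NumericMatrix states(nsamp, 3);

  double x[3] = { init[0], init[1], init[2] };
  double t = 0.0;
  int gi = 0, k = 0;

  while (true) {
    while (gi < nsamp && grid[gi] <= t + 1e-9) {
      states(gi, 0) = x[0]; states(gi, 1) = x[1]; states(gi, 2) = x[2];
      ++gi;
    }
    if (t >= duration - 1e-9) break;
    while (k + 1 < nseg && t >= seg_start[k + 1] - 1e-9) ++k;
    const double L = seg_L[k];
    double stop_at = duration;
    if (k + 1 < nseg && seg_start[k + 1] < stop_at) stop_at = seg_start[k + 1];
    if (gi < nsamp && grid[gi] < stop_at) stop_at = grid[gi];
    double h = dt;
    if (t + h > stop_at) h = stop_at - t;

    double xc[3] = { x[0] > 0 ? x[0] : 0, x[1] > 0 ? x[1] : 0,
                     x[2] > 0 ? x[2] : 0 };
    for (int j = 0; j < nc; ++j) {
      double aj = propensity(ch[j], xc, L);
      if (aj < 0.0) aj = 0.0;
      double inc = aj * h + std::sqrt(aj * h) * norm_rand();
      x[0] += ch[j].s0 * inc; x[1] += ch[j].s1 * inc; x[2] += ch[j].s2 * inc;
    }
    t += h;
  }
  return List::create(_["times"] = grid, _["states"] = states);
}
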