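// Exact stochastic simulation (Gillespie direct method) of the coupled
// enzyme-expression / catalysis network. The reaction indexing matches
// ssa_propensities() on the R side:
//  0 binding        E -> C            rate k1 * n_s * ne
//  1 unbinding      C -> E            rate km1 * nc
//  2 catalysis      C -> E, P+1       rate kcat * nc
//  3 reverse cat.   E -> C, P-1       rate krev * ne * np
//  4 translation    E+1               rate ktl * m
//  5 transcription  M+1               rate ktx * d
//  6 promoter on    d: 0 -> 1         rate kon * (1-d)
//  7 promoter off   d: 1 -> 0         rate koff * d
//  8 consumption    P-1               rate kc * np
//  9 mRNA decay     M-1               rate kdeg * m
// 10 enzyme dilution   E-1            rate delta * ne
// 11 complex dilution  C-1            rate delta * nc
//
// The loop records a thinned trajectory on a fixed output grid and
// accumulates exact holding-time-weighted stationary histograms after a
// burn-in, so long runs do not require storing every event.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

namespace {

// xoshiro256++ (public-domain algorithm) seeded via splitmix64: fast,
// reproducible across platforms independently of R's RNG state.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]
  inline double runif_oc() {
    return ((next() >> 11) + 1) * (1.0 / 9007199254740992.0);
  }
  // uniform in [0, 1)
  inline double runif_co() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

inline void grow_to(std::vector<double>& h, size_t n) {
  if (h.size() < n + 1) h.resize(n + 1, 0.0);
}

} // namespace

// [[Rcpp::export(name = ".ssa_run")]]
Rcpp::List ssa_run(Rcpp::NumericVector pars, double t_end, double burn_in,
                   Rcpp::IntegerVector init, double record_dt,
                   double seed_dbl, double max_events) {
  const double ns   = pars["n_s"],  k1   = pars["k_1"],  km1 = pars["k_m1"],
               kcat = pars["k_cat"], krev = pars["k_rev"], kc  = pars["k_c"],
               ktx  = pars["k_tx"], ktl  = pars["k_tl"],  kon = pars["k_on"],
               koff = pars["k_off"], kdeg = pars["k_deg"],
               delta = pars["delta"];
  const double k1ns = k1 * ns;
  long d = init[0], m = init[1], ne = init[2], nc = init[3], np = init[4];

  Xoshiro rng(static_cast<uint64_t>(seed_dbl));

  // thinned recording
  const bool record = record_dt > 0;
  std::vector<double> rec_t;
  std::vector<int> rec_d, rec_m, rec_ne, rec_nc, rec_np;
  double next_rec = 0.0;
  auto push_rec = [&](double at) {
    rec_t.push_back(at);
    rec_d.push_back((int)d); rec_m.push_back((int)m);
    rec_ne.push_back((int)ne); rec_nc.push_back((int)nc);
    rec_np.push_back((int)np);
  };

  // exact holding-time histograms after burn_in
  std::vector<double> h_m(16, 0.0), h_ne(64, 0.0), h_nc(64, 0.0),
      h_np(256, 0.0), h_etot(128, 0.0);
  double t = 0.0, events = 0.0;
  double a[12];
  double asum = 0.0;
  // propensities are maintained incrementally; refresh_all() recomputes
  // them (and their sum) from scratch to cancel floating-point drift
  auto refresh_all = [&]() {
    a[0] = k1ns * ne;
    a[1] = km1 * nc;
    a[2] = kcat * nc;
    a[3] = krev * (double)ne * (double)np;
    a[4] = ktl * m;
    a[5] = ktx * d;
    a[6] = kon * (1 - d);
    a[7] = koff * d;
    a[8] = kc * np;
    a[9] = kdeg * m;
    a[10] = delta * ne;
    a[11] = delta * nc;
    asum = 0.0;
    for (int i = 0; i < 12; ++i) asum += a[i];
  };
  refresh_all();

  while (t < t_end) {
    double dt;
    if (asum <= 0.0) {
      dt = t_end - t;  // absorbing state: hold to the end
    } else {
      dt = -std::log(rng.runif_oc()) / asum;
    }
    double t_new = t + dt;
    if (t_new > t_end) { dt = t_end - t; t_new = t_end; }

    // time-weighted occupancy of the state held on [t, t_new)
    if (t_new > burn_in) {
      double w = t_new - std::max(t, burn_in);
      grow_to(h_m, (size_t)m);    h_m[m]  += w;
      grow_to(h_ne, (size_t)ne);  h_ne[ne] += w;
      grow_to(h_nc, (size_t)nc);  h_nc[nc] += w;
      grow_to(h_np, (size_t)np);  h_np[np] += w;
      size_t et = (size_t)(ne + nc);
      grow_to(h_etot, et);        h_etot[et] += w;
    }
    if (record) {
      while (next_rec < t_new && next_rec <= t_end) {
        push_rec(next_rec);
        next_rec += record_dt;
      }
    }
    t = t_new;
    if (t >= t_end || asum <= 0.0) {
      if (asum <= 0.0 && t < t_end) t = t_end;
      break;
    }

    double r = rng.runif_co() * asum;
    int j = 0;
    double acc = a[0];
    while (r >= acc && j < 11) { acc += a[++j]; }
    // apply the state change, then update only affected propensities
    switch (j) {
      case 0: --ne; ++nc; break;
      case 1: ++ne; --nc; break;
      case 2: ++ne; --nc; ++np; break;
      case 3: --ne; ++nc; --np; break;
      case 4: ++ne; break;
      case 5: ++m; break;
      case 6: d = 1; break;
      case 7: d = 0; break;
      case 8: --np; break;
      case 9: --m; break;
      case 10: --ne; break;
      case 11: --nc; break;
    }
    double old;
    switch (j) {
      case 0: case 1: case 2: case 3: case 10: case 11:
        // ne and/or nc and possibly np changed
        old = a[0] + a[1] + a[2] + a[3] + a[8] + a[10] + a[11];
        a[0] = k1ns * ne;
        a[1] = km1 * nc;
        a[2] = kcat * nc;
        a[3] = krev * (double)ne * (double)np;
        a[8] = kc * np;
        a[10] = delta * ne;
        a[11] = delta * nc;
        asum += a[0] + a[1] + a[2] + a[3] + a[8] + a[10] + a[11] - old;
        break;
      case 4:
        old = a[0] + a[3] + a[10];
        a[0] = k1ns * ne;
        a[3] = krev * (double)ne * (double)np;
        a[10] = delta * ne;
        asum += a[0] + a[3] + a[10] - old;
        break;
      case 5: case 9:
        old = a[4] + a[9];
        a[4] = ktl * m;
        a[9] = kdeg * m;
        asum += a[4] + a[9] - old;
        break;
      case 6: case 7:
        old = a[5] + a[6] + a[7];
        a[5] = ktx * d;
        a[6] = kon * (1 - d);
        a[7] = koff * d;
        asum += a[5] + a[6] + a[7] - old;
        break;
      case 8:
        old = a[3] + a[8];
        a[3] = krev * (double)ne * (double)np;
        a[8] = kc * np;
        asum += a[3] + a[8] - old;
        break;
    }
    events += 1.0;
    if (events > max_events)
      Rcpp::stop("event budget exceeded (%.3g events before t = %g of %g); "
                 "shorten t_end, thin the recording, or raise max_events",
                 events, t, t_end);
    if (((uint64_t)events & 0xFFFFF) == 0) {
      refresh_all();  // cancel accumulated floating-point drift in asum
      Rcpp::checkUserInterrupt();
    }
  }
  if (record) push_rec(t_end);

  double tot = 0.0;
  for (double w : h_np) tot += w;
  return Rcpp::List::create(
      Rcpp::Named("times") = rec_t,
      Rcpp::Named("dna_on") = rec_d,
      Rcpp::Named("n_m") = rec_m,
      Rcpp::Named("n_e") = rec_ne,
      Rcpp::Named("n_c") = rec_nc,
      Rcpp::Named("n_p") = rec_np,
      Rcpp::Named("hist_time") = tot,
      Rcpp::Named("hist_m") = h_m,
      Rcpp::Named("hist_ne") = h_ne,
      Rcpp::Named("hist_nc") = h_nc,
      Rcpp::Named("hist_np") = h_np,
      Rcpp::Named("hist_etot") = h_etot,
      Rcpp::Named("events") = events,
      Rcpp::Named("final_state") =
          Rcpp::IntegerVector::create((int)d, (int)m, (int)ne, (int)nc,
                                      (int)np));
}
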