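#include <Rcpp.h>
using namespace Rcpp;

// Five first-order channels of the fate scheme:
//   P -> 2P   (alpha)     P -> D (beta)   D -> P (gamma)
//   P -> dead (d1)        D -> dead (d2)  -- deaths increment cumulative N.
// Absorbing boundary: once P + D == 0 no further events can fire.
// Uses R's RNG (unif_rand / exp_rand) so runs are reproducible from set.seed().

static inline void ssa_step(double alpha, double beta, double gamma,
                            double d1, double d2,
                            long &p, long &d, long &n, double &t,
                            bool &absorbed) {
  double a1 = alpha * p, a2 = beta * p, a3 = gamma * d,
         a4 = d1 * p, a5 = d2 * d;
  double a0 = a1 + a2 + a3 + a4 + a5;
  if (p + d == 0 || a0 <= 0.0) { absorbed = true; return; }
  t += exp_rand() / a0;
  double u = unif_rand() * a0;
  if (u < a1)                { p += 1; }
  else if (u < a1 + a2)      { p -= 1; d += 1; }
  else if (u < a1 + a2 + a3) { d -= 1; p += 1; }
  else if (u < a1 + a2 + a3 + a4) { p -= 1; n += 1; }
  else                       { d -= 1; n += 1; }
}

// Sample one path at the requested (increasing) output times.
// [[Rcpp::export]]
NumericMatrix ssa_fate_path(NumericVector rates, IntegerVector init,
                            NumericVector times) {
  double alpha = rates[0], beta = rates[1], gamma = rates[2],
         d1 = rates[3], d2 = rates[4];
  long p = init[0], d = init[1], n = init[2];
  int nt = times.size();
  NumericMatrix out(nt, 3);
  double t = 0.0;
  int it = 0;
  bool absorbed = false;
  while (it < nt) {
    long p0 = p, d0 = d, n0 = n;
    double t0 = t;
    if (!absorbed) ssa_step(alpha, beta, gamma, d1, d2, p, d, n, t, absorbed);
    double tnext = absorbed ? R_PosInf : t;
    while (it < nt && times[it] <= tnext) {
      out(it, 0) = (double)p0; out(it, 1) = (double)d0; out(it, 2) = (double)n0;
      ++it;
    }
    (void)t0;
  }
  return out;
}

// Full jump path: rows (time, P, D, N) for the initial state and every event
// up to t_max, absorption, or max_events.
// [[Rcpp::export]]
NumericMatrix ssa_fate_events(NumericVector rates, IntegerVector init,
                              double t_max, int max_events) {
  double alpha = rates[0], beta = rates[1], gamma = rates[2],
         d1 = rates[3], d2 = rates[4];
  long p = init[0], d = init[1], n = init[2];
  std::vector<double> rec;
  rec.reserve(1024);
  double t = 0.0;
  bool absorbed = false;
  rec.push_back(t); rec.push_back(p); rec.push_back(d); rec.push_back(n);
  int ev = 0;
  while (!absorbed && ev < max_events) {
    ssa_step(alpha, beta, gamma, d1, d2, p, d, n, t, absorbed);
    if (absorbed || t > t_max) break;
    rec.push_back(t); rec.push_back(p); rec.push_back(d); rec.push_back(n);
    ++ev;
  }
  int nr = rec.size() / 4;
  NumericMatrix out(nr, 4);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = rec[4 * i + j];
  colnames(out) = CharacterVector::create("time", "P", "D", "N");
  return out;
}

// Ensemble of independent paths with per-run rates and initial counts.
// Returns n_runs x (3 * n_times): columns ordered P at each time, then D,
// then N (state-major blocks).
// [[Rcpp::export]]
NumericMatrix ssa_fate_ensemble(NumericMatrix rates, IntegerMatrix init,
                                NumericVector times) {
  int n_runs = rates.nrow(), nt = times.size();
  NumericMatrix out(n_runs, 3 * nt);
  for (int r = 0; r < n_runs; ++r) {
    NumericVector rr = rates(r, _);
    IntegerVector ii = init(r, _);
    NumericMatrix path = ssa_fate_path(rr, ii, times);
    for (int it = 0; it < nt; ++it) {
      out(r, it) = path(it, 0);
      out(r, nt + it) = path(it, 1);
      out(r, 2 * nt + it) = path(it, 2);
    }
  }
  return out;
}
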