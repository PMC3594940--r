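// Direct-method stochastic simulation of the (ion count, channel state)
// Markov chain.  Uses R's RNG so runs are reproducible under set.seed().
//
// Reactions per state (n, m):
//   influx   n -> n+1            rate alpha_bar[m]          (ions/ms)
//   efflux   n -> n-1            rate n * beta
//   channel  m -> m', n -> n+dn  rate k_eff           (quad = FALSE)
//                                rate n*(n-1) * k_eff (quad = TRUE)
// Quadratic (two-ion binding) propensities vanish for n < 2, so the ion
// count never goes negative.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List ssa_run(NumericVector alpha_bar, double beta,
             IntegerVector tr_from, IntegerVector tr_to,
             IntegerVector tr_dn, NumericVector tr_k, LogicalVector tr_quad,
             int n0, int m0, double t_end, double burn_in,
             int n_cap, int n_batches, double max_events, int log_max) {
  const int M = alpha_bar.size();
  const int R = tr_from.size();
  const int n_react = 2 + R;  // influx, efflux, channel transitions

  NumericMatrix hist(n_cap + 1, M);        // time-weighted occupancy
  NumericVector batch_int_n(n_batches);    // integral of n over each batch
  NumericMatrix batch_occ(n_batches, M);   // state dwell time per batch
  NumericVector react_count(n_react);
  std::vector<double> log_t, log_n, log_m, log_r;

  double t = 0.0, total_events = 0.0;
  int n = n0, m = m0;
  bool truncated = false;
  double clamped_time = 0.0;
  const double span = t_end - burn_in;
  const double bw = span / n_batches;

  RNGScope scope;
  std::vector<double> a(n_react);

  while (t < t_end) {
    double a0 = 0.0;
    a[0] = alpha_bar[m];
    a[1] = n * beta;
    a0 = a[0] + a[1];
    for (int r = 0; r < R; ++r) {
      double p = 0.0;
      if (tr_from[r] == m) {
        p = tr_quad[r] ? (double)n * (n - 1) * tr_k[r] : tr_k[r];
        if (p < 0) p = 0;
      }
      a[2 + r] = p;
      a0 += p;
    }

    double dwell = (a0 > 0.0) ? exp_rand() / a0 : (t_end - t) + 1.0;
    double t_next = t + dwell;
    if (t_next > t_end) t_next = t_end;

    // accumulate occupancy of (n, m) over [t, t_next) after burn-in
    double lo = t > burn_in ? t : burn_in;
    if (t_next > lo) {
      int nh = n <= n_cap ? n : n_cap;
      if (n > n_cap) clamped_time += t_next - lo;
      hist(nh, m) += t_next - lo;
      // split across batch windows
      double s = lo;
      while (s < t_next) {
        int b = (int)((s - burn_in) / bw);
        if (b >= n_batches) b = n_batches - 1;
        double b_end = burn_in + (b + 1) * bw;
        double e = t_next < b_end ? t_next : b_end;
        batch_int_n[b] += (double)n * (e - s);
        batch_occ(b, m) += e - s;
        s = e;
      }
    }

    if (t + dwell >= t_end || a0 <= 0.0) break;
    t += dwell;

    // pick reaction
    double u = unif_rand() * a0, acc = 0.0;
    int pick = n_react - 1;
    for (int r = 0; r < n_react; ++r) {
      acc += a[r];
      if (u <= acc) { pick = r; break; }
    }
    if (pick == 0) n += 1;
    else if (pick == 1) n -= 1;
    else {
      int r = pick - 2;
      m = tr_to[r];
      n += tr_dn[r];
    }
    if (n < 0) n = 0;  // unreachable: quadratic propensity is 0 for n < 2

    react_count[pick] += 1.0;
    total_events += 1.0;
    if ((int)log_t.size() < log_max) {
      log_t.push_back(t);
      log_r.push_back(pick + 1);
      log_n.push_back(n);
      log_m.push_back(m);
    }
    if (total_events >= max_events) { truncated = true; break; }
  }

  return List::create(
    _["hist"] = hist,
    _["batch_int_n"] = batch_int_n,
    _["batch_occ"] = batch_occ,
    _["react_count"] = react_count,
    _["events"] = total_events,
    _["t_final"] = t,
    _["n_final"] = n,
    _["m_final"] = m + 1,
    _["clamped_time"] = clamped_time,
    _["truncated"] = truncated,
    _["log"] = DataFrame::create(_["t_ms"] = log_t,
                                 _["reaction_id"] = log_r,
                                 _["n"] = log_n, _["m"] = log_m));
}
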