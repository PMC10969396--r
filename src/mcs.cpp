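#include <Rcpp.h>
using namespace Rcpp;

// Synchronous discrete-time contagion on a fixed contact graph.
//
// Status codes: 0 = susceptible, 1 = infected, 2 = recovered, 3 = dead.
// Per step, from the step-start configuration: each susceptible with m
// infected living neighbours becomes infected with probability
// 1 - (1 - beta_eff)^m; each infected recovers (SIR: -> 2, SIS: -> 0) with
// probability min(1, gamma_eff); each living node then dies with
// probability min(1, d). Newborns accumulate in a passive pool
// P <- P * (1 - d) + round(b * n) that never joins the graph.
//
// Two uniforms are consumed per node per step (transition, death) in fixed
// node order regardless of status, so runs with the same seed are coupled
// draw-for-draw across parameterizations.
//
// adjacency: CSR arrays `neighbors` (0-based ids) and `ptr` (length n + 1).
// Returns a list with `counts` ((steps+1) x 4 matrix: S, I, R, passive) and,
// if record_states, `states` ((steps+1) x n status matrix).
// [[Rcpp::export(name = ".mcs_core")]]
List mcs_core(IntegerVector neighbors, IntegerVector ptr, int n, int steps,
              double beta_eff, double gamma_eff, double b, double d,
              bool sis, IntegerVector init_status, bool record_states) {
  std::vector<int> status(init_status.begin(), init_status.end());
  std::vector<int> status_new(n);
  std::vector<int> m_inf(n);
  double rec_p = std::min(1.0, gamma_eff);
  double die_p = std::min(1.0, d);
  double births = std::floor(b * n + 0.5);
  double passive = 0.0;
  double log1mb = (beta_eff < 1.0) ? std::log1p(-beta_eff) : R_NegInf;

  NumericMatrix counts(steps + 1, 4);
  IntegerMatrix states(record_states ? steps + 1 : 0,
                       record_states ? n : 0);

  auto record = [&](int row) {
    int cs = 0, ci = 0, cr = 0;
    for (int j = 0; j < n; ++j) {
      if (status[j] == 0) ++cs;
      else if (status[j] == 1) ++ci;
      else if (status[j] == 2) ++cr;
    }
    counts(row, 0) = cs; counts(row, 1) = ci;
    counts(row, 2) = cr; counts(row, 3) = passive;
    if (record_states)
      for (int j = 0; j < n; ++j) states(row, j) = status[j];
  };
  record(0);

  for (int t = 1; t <= steps; ++t) {
    std::fill(m_inf.begin(), m_inf.end(), 0);
    for (int j = 0; j < n; ++j) {
      if (status[j] != 1) continue;
      for (int e = ptr[j]; e < ptr[j + 1]; ++e) ++m_inf[neighbors[e]];
    }
    for (int j = 0; j < n; ++j) {
      double u_trans = unif_rand();
      double u_death = unif_rand();
      int st = status[j];
      int ns = st;
      if (st == 0) {
        if (m_inf[j] > 0) {
          // infection prob 1 - (1 - beta_eff)^m, in log space for accuracy
          double p_inf = (beta_eff >= 1.0) ? 1.0
                         : -std::expm1(m_inf[j] * log1mb);
          if (u_trans < p_inf) ns = 1;
        }
      } else if (st == 1) {
        if (u_trans < rec_p) ns = sis ? 0 : 2;
      }
      if (st != 3 && u_death < die_p) ns = 3;
      status_new[j] = ns;
    }
    status.swap(status_new);
    passive = passive * (1.0 - die_p) + births;
    record(t);
  }
  if (record_states)
    return List::create(_["counts"] = counts, _["states"] = states);
  return List::create(_["counts"] = counts);
}
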