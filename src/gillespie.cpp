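#include <Rcpp.h>
using namespace Rcpp;

// Exact event-driven (Gillespie) simulation of the two-state process:
//   rho+ division    at rate g_wt  per rho+ cell
//   rho+ -> rho0     at rate r     per rho+ cell (cell conserved)
//   rho0 division    at rate g_mut per rho0 cell
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List gillespie_two_state_cpp(double g_wt, double g_mut, double r,
                             double w0, double m0, double t_end, double cap) {
  std::vector<double> times;
  std::vector<double> wv;
  std::vector<double> mv;
  double t = 0.0, w = w0, m = m0;
  times.push_back(t); wv.push_back(w); mv.push_back(m);
  bool truncated = false;

  for (;;) {
    double rate_div_wt = w * g_wt;
    double rate_conv   = w * r;
    double rate_div_mut = m * g_mut;
    double total = rate_div_wt + rate_conv + rate_div_mut;
    if (total <= 0.0) break;
    t += R::exp_rand() / total;
    if (t > t_end) break;
    double u = unif_rand() * total;
    if (u < rate_div_wt) {
      w += 1.0;
    } else if (u < rate_div_wt + rate_conv) {
      w -= 1.0;
      m += 1.0;
    } else {
      m += 1.0;
    }
    times.push_back(t); wv.push_back(w); mv.push_back(m);
    if (w + m >= cap) { truncated = true; break; }
  }

  return List::create(_["time_h"] = times, _["p_wt"] = wv, _["p_mut"] = mv,
                      _["truncated"] = truncated);
}
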