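#include <Rcpp.h>
using namespace Rcpp;

// Exact SSA over a finite CTMC given in compressed sparse row form.
// nbr_ptr: length n+1, 0-based offsets; nbr_idx: 0-based neighbour states;
// nbr_rate: transition rates; exit_rate: total exit rate per state.
// Uses R's RNG so runs are reproducible under set.seed().
// [[Rcpp::export]]
List ssa_run_cpp(IntegerVector nbr_ptr, IntegerVector nbr_idx,
                 NumericVector nbr_rate, NumericVector exit_rate,
                 int initial0, double t_max, double max_events) {
  std::vector<double> times;
  std::vector<int> states;
  if (max_events < R_PosInf)
    times.reserve((size_t) std::min(max_events, 5e7));
  int cur = initial0;
  double t = 0.0;
  bool hit_tmax = false;
  long long nev = 0;
  long long nmax = (max_events < R_PosInf) ? (long long) max_events : LLONG_MAX;

  while (nev < nmax) {
    double rate = exit_rate[cur];
    if (rate <= 0.0)
      stop("zero total exit rate in state %d (absorbing state reached)", cur + 1);
    double dt = R::exp_rand() / rate;
    if (t + dt > t_max) { hit_tmax = true; break; }
    t += dt;
    double u = R::unif_rand() * rate;
    double acc = 0.0;
    int nxt = nbr_idx[nbr_ptr[cur + 1] - 1];  // guard against rounding past the end
    for (int k = nbr_ptr[cur]; k < nbr_ptr[cur + 1]; ++k) {
      acc += nbr_rate[k];
      if (u <= acc) { nxt = nbr_idx[k]; break; }
    }
    cur = nxt;
    times.push_back(t);
    states.push_back(cur + 1);  // back to 1-based for R
    ++nev;
    if (nev % 1048576 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["times"] = times, _["states"] = states,
                      _["hit_tmax"] = hit_tmax);
}
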