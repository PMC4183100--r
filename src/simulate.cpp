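// Aggregated stochastic simulation of macroscopic currents: the channel
// population is propagated as multinomial state counts with the discrete
// transition kernel exp(Q dt), which is exact in distribution at the sample
// times.  Uses R's RNG so results are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// one multinomial redistribution step; kern columns are source-state
// transition distributions
void step_counts(const mat& kern, const ivec& counts, ivec& out,
                 std::vector<double>& pbuf, std::vector<int>& nbuf) {
  const int ns = kern.n_rows;
  out.zeros();
  for (int j = 0; j < ns; ++j) {
    int nj = counts(j);
    if (nj <= 0) continue;
    for (int a = 0; a < ns; ++a) pbuf[a] = std::max(kern(a, j), 0.0);
    R::rmultinom(nj, pbuf.data(), ns, nbuf.data());
    for (int a = 0; a < ns; ++a) out(a) += nbuf[a];
  }
}

ivec draw_initial(const vec& p0, int nch, std::vector<double>& pbuf,
                  std::vector<int>& nbuf) {
  const int ns = p0.n_elem;
  for (int a = 0; a < ns; ++a) pbuf[a] = std::max(p0(a), 0.0);
  R::rmultinom(nch, pbuf.data(), ns, nbuf.data());
  ivec c(ns);
  for (int a = 0; a < ns; ++a) c(a) = nbuf[a];
  return c;
}

} // namespace

// Simulate N macroscopic currents through a sequence of epochs.
// kerns: Ns x Ns x (n_epochs) when shared across traces, or
//        Ns x Ns x (n_epochs * N) with per-trace blocks when `per_trace`.
// steps: steps per epoch.  Returns currents at all sample times
// (sum(steps)+1 rows including t = 0) as a matrix (time x trace).
// [[Rcpp::export]]
arma::mat cpp_sim_macroscopic(const arma::cube& kerns,
                              const arma::ivec& steps,
                              const arma::vec& p0,
                              const arma::ivec& nch,
                              const arma::vec& istate,
                              bool per_trace) {
  const int ns = p0.n_elem, ne = steps.n_elem, N = nch.n_elem;
  const int ntot = accu(steps);
  mat out(ntot + 1, N);
  std::vector<double> pbuf(ns);
  std::vector<int> nbuf(ns);
  ivec cur(ns), nxt(ns);
  for (int tr = 0; tr < N; ++tr) {
    cur = draw_initial(p0, nch(tr), pbuf, nbuf);
    int row = 0;
    out(row++, tr) = dot(conv_to<vec>::from(cur), istate);
    for (int ep = 0; ep < ne; ++ep) {
      const mat& K = kerns.slice(per_trace ? ep * N + tr : ep);
      for (int s = 0; s < steps(ep); ++s) {
        step_counts(K, cur, nxt, pbuf, nbuf);
        cur = nxt;
        out(row++, tr) = dot(conv_to<vec>::from(cur), istate);
      }
    }
  }
  return out;
}

// Ensemble state-count trajectory for a single population (oracle helper):
// returns Ns x (steps+1) counts.
// [[Rcpp::export]]
arma::imat cpp_sim_ensemble_counts(const arma::mat& kern, const arma::vec& p0,
                                   int nch, int steps) {
  const int ns = p0.n_elem;
  imat out(ns, steps + 1);
  std::vector<double> pbuf(ns);
  std::vector<int> nbuf(ns);
  ivec cur = draw_initial(p0, nch, pbuf, nbuf), nxt(ns);
  out.col(0) = cur;
  for (int s = 0; s < steps; ++s) {
    step_counts(kern, cur, nxt, pbuf, nbuf);
    cur = nxt;
    out.col(s + 1) = cur;
  }
  return out;
}
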