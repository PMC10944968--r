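// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Euler-Maruyama integration of the conductance-based network.
//
// State layout matches the R side: x = [V, gE, gI], each block of length
// n_pop (= 4 * n_nodes). Innovations enter as currents on designated
// populations (rows of `winput` indexed by `input_idx`, one per node),
// pre-generated in R with the desired spectral shape. Returns the membrane
// potential block at every `keep_every`-th step after `n_burn` steps.
//
// [[Rcpp::export]]
arma::mat integrate_network(const arma::mat& GE, const arma::mat& GI,
                            const arma::vec& C, const arma::vec& gL,
                            double VL, double VE, double VI,
                            double kE, double kI,
                            const arma::vec& u,
                            double slope, double thresh,
                            const arma::vec& x0,
                            const arma::mat& winput,
                            const arma::uvec& input_idx,
                            double dt, int n_burn, int keep_every) {
  const int np = GE.n_rows;
  const int n_steps = winput.n_cols;
  const int n_keep = (n_steps - n_burn) / keep_every;

  arma::vec V = x0.subvec(0, np - 1);
  arma::vec gEv = x0.subvec(np, 2 * np - 1);
  arma::vec gIv = x0.subvec(2 * np, 3 * np - 1);
  arma::mat out(np, n_keep);

  int kept = 0;
  for (int t = 0; t < n_steps; ++t) {
    arma::vec rate = 1.0 / (1.0 + arma::exp(-slope * (V - thresh)));
    arma::vec drive = u;
    for (arma::uword j = 0; j < input_idx.n_elem; ++j)
      drive(input_idx(j)) += winput(j, t);
    arma::vec dV = (gL % (VL - V) + gEv % (VE - V) + gIv % (VI - V) + drive) / C;
    arma::vec dgE = kE * (GE * rate - gEv);
    arma::vec dgI = kI * (GI * rate - gIv);
    V += dt * dV;
    gEv += dt * dgE;
    gIv += dt * dgI;
    if (!V.is_finite())
      Rcpp::stop("numerical blow-up during integration at step %d", t);
    if (t >= n_burn && ((t - n_burn) % keep_every == 0) && kept < n_keep) {
      out.col(kept) = V;
      ++kept;
    }
  }
  return out.head_cols(kept);
}
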