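#include <Rcpp.h>
using namespace Rcpp;

// Advance the 1D peroxide/integrity fields over n_steps explicit-Euler
// steps of length dt_min (minutes). Space: second-order centred
// differences; node 0 is a Dirichlet boundary driven by H_surface (one
// value per step, applied at the end-of-step time); the last node is a
// zero-flux Neumann boundary via the ghost-point construction
// H_{N+1} = H_{N-1}. Consumption is integrated explicitly together with
// diffusion; integrity uses the exact exponential update per step.
//
// D_min is the diffusion coefficient in m^2/min, dx in metres, rates in
// 1/min. Aborts if the field goes negative (stability violation).
// [[Rcpp::export]]
List film_advance(NumericVector H0, NumericVector C0,
                  NumericVector H_surface, double dt_min, double dx,
                  double D_min, double k_cons, double k0, double alpha_H) {
  int n = H0.size();
  int n_steps = H_surface.size();
  if (C0.size() != n) stop("H and C fields must have equal length");
  if (n < 3) stop("need at least 3 spatial nodes");

  NumericVector H = clone(H0);
  NumericVector C = clone(C0);
  std::vector<double> Hnew(n);
  double r = D_min * dt_min / (dx * dx);

  for (int s = 0; s < n_steps; ++s) {
    for (int i = 1; i < n - 1; ++i) {
      Hnew[i] = H[i] + r * (H[i + 1] - 2.0 * H[i] + H[i - 1])
                     - dt_min * k_cons * H[i];
    }
    // ghost point: H[n] = H[n-2]
    Hnew[n - 1] = H[n - 1] + r * (2.0 * H[n - 2] - 2.0 * H[n - 1])
                           - dt_min * k_cons * H[n - 1];
    Hnew[0] = H_surface[s];
    for (int i = 0; i < n; ++i) {
      if (Hnew[i] < 0.0) {
        stop("peroxide field went negative at node %d, step %d: "
             "time step violates the stability condition", i + 1, s + 1);
      }
      H[i] = Hnew[i];
      C[i] *= std::exp(-(k0 + alpha_H * H[i]) * dt_min);
    }
  }
  return List::create(_["H"] = H, _["C"] = C);
}
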