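#include <Rcpp.h>
using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Euler-Maruyama integration of the coupled Wilson-Cowan network.
//
// du_i = [-u_i + f(c1 u_i - c2 v_i + P_i + eps * sum_j w_ij u_j)] dt + sigma dW_i
// dv_i = [-v_i + f(c3 u_i - c4 v_i + Q)] dt
//
// Noise enters the u-equation only. Uses R's RNG (norm_rand) so results are
// reproducible under set.seed(). Trajectories are saved every step including
// the initial condition; columns are time points, rows are nodes.
// [[Rcpp::export]]
List em_integrate_cpp(const NumericMatrix& w, NumericVector u0, NumericVector v0,
                      const NumericVector& Pvec, double Q,
                      double c1, double c2, double c3, double c4,
                      double epsilon, double sigma, double dt, int n_steps) {
  const int n = u0.size();
  NumericMatrix U(n, n_steps + 1), V(n, n_steps + 1);
  std::vector<double> u(u0.begin(), u0.end()), v(v0.begin(), v0.end());
  std::vector<double> coup(n, 0.0), du(n), dv(n);
  const double sqdt = std::sqrt(dt);
  const bool coupled = epsilon != 0.0, noisy = sigma > 0.0;

  for (int i = 0; i < n; ++i) { U(i, 0) = u[i]; V(i, 0) = v[i]; }

  RNGScope scope;
  for (int s = 1; s <= n_steps; ++s) {
    if (coupled) {
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int j = 0; j < n; ++j) acc += w(i, j) * u[j];
        coup[i] = epsilon * acc;
      }
    }
    for (int i = 0; i < n; ++i) {
      du[i] = -u[i] + sigmoid(c1 * u[i] - c2 * v[i] + Pvec[i] + coup[i]);
      dv[i] = -v[i] + sigmoid(c3 * u[i] - c4 * v[i] + Q);
    }
    for (int i = 0; i < n; ++i) {
      u[i] += dt * du[i];
      if (noisy) u[i] += sigma * sqdt * norm_rand();
      v[i] += dt * dv[i];
      if (std::abs(u[i]) > 10.0 || std::abs(v[i]) > 10.0)
        return List::create(_["ok"] = false, _["step"] = s, _["node"] = i + 1);
      U(i, s) = u[i]; V(i, s) = v[i];
    }
  }
  return List::create(_["ok"] = true, _["u"] = U, _["v"] = V);
}
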