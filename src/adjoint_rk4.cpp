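#include <Rcpp.h>
using namespace Rcpp;

// Shared RK4 machinery for linear systems along a stored limit cycle.
// fpx_half / fpy_half hold f'(x(t)), f'(y(t)) sampled on the half-grid
// t = j * h/2, j = 0..2M, so every RK4 stage lands exactly on a sample.

namespace {

struct CycleJac {
  const NumericVector& fpx, & fpy;
  double c1, c2, c3, c4;
  // J = [[-1 + c1 fpx, -c2 fpy], [c3 fpx, -1 - c4 fpy]] at half-grid index j
  inline void J(int j, double& a11, double& a12, double& a21, double& a22) const {
    a11 = -1.0 + c1 * fpx[j];
    a12 = -c2 * fpy[j];
    a21 = c3 * fpx[j];
    a22 = -1.0 - c4 * fpy[j];
  }
};

// one backward RK4 step of Z' = -J^T Z from t = i*h to (i-1)*h
inline void step_back(const CycleJac& cj, double h, int i, double& z1, double& z2) {
  double a11, a12, a21, a22, k1[2], k2[2], k3[2], k4[2];
  auto rhs = [&](int j, double y1, double y2, double* out) {
    cj.J(j, a11, a12, a21, a22);
    out[0] = -(a11 * y1 + a21 * y2);
    out[1] = -(a12 * y1 + a22 * y2);
  };
  rhs(2 * i, z1, z2, k1);
  rhs(2 * i - 1, z1 - 0.5 * h * k1[0], z2 - 0.5 * h * k1[1], k2);
  rhs(2 * i - 1, z1 - 0.5 * h * k2[0], z2 - 0.5 * h * k2[1], k3);
  rhs(2 * i - 2, z1 - h * k3[0], z2 - h * k3[1], k4);
  z1 -= h / 6.0 * (k1[0] + 2.0 * k2[0] + 2.0 * k3[0] + k4[0]);
  z2 -= h / 6.0 * (k1[1] + 2.0 * k2[1] + 2.0 * k3[1] + k4[1]);
}

// one forward RK4 step of V' = J V from t = (i-1)*h to i*h
inline void step_fwd(const CycleJac& cj, double h, int i, double& v1, double& v2) {
  double a11, a12, a21, a22, k1[2], k2[2], k3[2], k4[2];
  auto rhs = [&](int j, double y1, double y2, double* out) {
    cj.J(j, a11, a12, a21, a22);
    out[0] = a11 * y1 + a12 * y2;
    out[1] = a21 * y1 + a22 * y2;
  };
  rhs(2 * i - 2, v1, v2, k1);
  rhs(2 * i - 1, v1 + 0.5 * h * k1[0], v2 + 0.5 * h * k1[1], k2);
  rhs(2 * i - 1, v1 + 0.5 * h * k2[0], v2 + 0.5 * h * k2[1], k3);
  rhs(2 * i, v1 + h * k3[0], v2 + h * k3[1], k4);
  v1 += h / 6.0 * (k1[0] + 2.0 * k2[0] + 2.0 * k3[0] + k4[0]);
  v2 += h / 6.0 * (k1[1] + 2.0 * k2[1] + 2.0 * k3[1] + k4[1]);
}

} // namespace

// Monodromy matrix of the variational equation V' = J(t) V over one period.
// [[Rcpp::export]]
NumericMatrix monodromy_cpp(const NumericVector& fpx_half,
                            const NumericVector& fpy_half,
                            double c1, double c2, double c3, double c4,
                            double h, int M) {
  CycleJac cj{fpx_half, fpy_half, c1, c2, c3, c4};
  double e11 = 1, e21 = 0, e12 = 0, e22 = 1;  // columns of V
  for (int i = 1; i <= M; ++i) {
    step_fwd(cj, h, i, e11, e21);
    step_fwd(cj, h, i, e12, e22);
  }
  NumericMatrix Mon(2, 2);
  Mon(0, 0) = e11; Mon(1, 0) = e21; Mon(0, 1) = e12; Mon(1, 1) = e22;
  return Mon;
}

// Backward RK4 integration of the adjoint equation Z' = -J(t)^T Z from the
// initial direction z0 at t = T, renormalized each period until the
// direction converges; returns the final period's samples on the full grid.
// [[Rcpp::export]]
List adjoint_backward_cpp(const NumericVector& fpx_half,
                          const NumericVector& fpy_half,
                          double c1, double c2, double c3, double c4,
                          double h, int M, int max_periods, double tol,
                          NumericVector z0) {
  CycleJac cj{fpx_half, fpy_half, c1, c2, c3, c4};
  double z1 = z0[0], z2 = z0[1];
  double nrm = std::sqrt(z1 * z1 + z2 * z2);
  z1 /= nrm; z2 /= nrm;
  int n_done = 0;
  bool converged = false;
  for (int k = 0; k < max_periods && !converged; ++k) {
    double p1 = z1, p2 = z2;
    for (int i = M; i >= 1; --i) step_back(cj, h, i, z1, z2);
    nrm = std::sqrt(z1 * z1 + z2 * z2);
    z1 /= nrm; z2 /= nrm;
    n_done = k + 1;
    double dminus = std::sqrt((z1 - p1) * (z1 - p1) + (z2 - p2) * (z2 - p2));
    double dplus = std::sqrt((z1 + p1) * (z1 + p1) + (z2 + p2) * (z2 + p2));
    converged = std::min(dminus, dplus) < tol;
  }
  NumericMatrix Z(M + 1, 2);
  Z(M, 0) = z1; Z(M, 1) = z2;
  for (int i = M; i >= 1; --i) {
    step_back(cj, h, i, z1, z2);
    Z(i - 1, 0) = z1; Z(i - 1, 1) = z2;
  }
  return List::create(_["Z"] = Z, _["n_periods"] = n_done,
                      _["converged"] = converged);
}
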