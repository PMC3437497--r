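/* Compiled right-hand side of the transformed Wilson-Cowan node for deSolve.
   State (x, y); parameters (P, Q, c1, c2, c3, c4) set via the init hook. */
#include <R.h>
#include <math.h>

static double parms[6];
#define P_  parms[0]
#define Q_  parms[1]
#define C1_ parms[2]
#define C2_ parms[3]
#define C3_ parms[4]
#define C4_ parms[5]

void scfc_node_init(void (*odeparms)(int *, double *)) {
  int n = 6;
  odeparms(&n, parms);
}

static double sigmf(double x) { return 1.0 / (1.0 + exp(-x)); }

void scfc_node_deriv(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip) {
  const double fx = sigmf(y[0]), fy = sigmf(y[1]);
  ydot[0] = -y[0] + P_ + C1_ * fx - C2_ * fy;
  ydot[1] = -y[1] + Q_ + C3_ * fx - C4_ * fy;
}
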