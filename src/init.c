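#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* .Call entries generated by Rcpp attributes */
extern SEXP _scfc_adjoint_backward_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                                       SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP _scfc_monodromy_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                                SEXP);
extern SEXP _scfc_em_integrate_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                                   SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);

/* compiled deSolve right-hand side (looked up by name with dllname) */
extern void scfc_node_init(void (*odeparms)(int *, double *));
extern void scfc_node_deriv(int *, double *, double *, double *, double *,
                            int *);

static const R_CallMethodDef CallEntries[] = {
    {"_scfc_adjoint_backward_cpp", (DL_FUNC) &_scfc_adjoint_backward_cpp, 11},
    {"_scfc_monodromy_cpp", (DL_FUNC) &_scfc_monodromy_cpp, 8},
    {"_scfc_em_integrate_cpp", (DL_FUNC) &_scfc_em_integrate_cpp, 13},
    {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
    {"scfc_node_init", (DL_FUNC) &scfc_node_init, 1},
    {"scfc_node_deriv", (DL_FUNC) &scfc_node_deriv, 6},
    {NULL, NULL, 0}
};

void R_init_scfc(DllInfo *dll) {
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
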