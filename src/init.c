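#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP sw_rhs_call(SEXP t, SEXP y, SEXP p);
void sw_init(void (*odeparms)(int *, double *));
void sw_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip);

static const R_CallMethodDef call_entries[] = {
    {"sw_rhs_call", (DL_FUNC) &sw_rhs_call, 3},
    {NULL, NULL, 0}
};

void R_init_snailwave(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    /* deSolve resolves sw_init/sw_derivs by name at run time */
    R_useDynamicSymbols(dll, TRUE);
}
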