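#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_set_parms(SEXP p);
SEXP C_eval_derivs(SEXP p, SEXP y);
void plv_initmod(void (*odeparms)(int *, double *));
void plv_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);

static const R_CallMethodDef call_entries[] = {
    {"C_set_parms",   (DL_FUNC) &C_set_parms,   1},
    {"C_eval_derivs", (DL_FUNC) &C_eval_derivs, 2},
    {NULL, NULL, 0}
};

/* registered so deSolve can look the symbols up by name */
static const R_CMethodDef c_entries[] = {
    {"plv_initmod", (DL_FUNC) &plv_initmod, 1},
    {"plv_derivs",  (DL_FUNC) &plv_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_plasmidLV(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
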