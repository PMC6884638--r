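#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP helixkin_ssa_run(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);

void helixkin_init_full(void (*)(int *, double *));
void helixkin_derivs_full(int *, double *, double *, double *, double *, int *);
void helixkin_init_lumped(void (*)(int *, double *));
void helixkin_derivs_lumped(int *, double *, double *, double *, double *, int *);
void helixkin_init_qssa(void (*)(int *, double *));
void helixkin_derivs_qssa(int *, double *, double *, double *, double *, int *);

static const R_CallMethodDef CallEntries[] = {
    {"helixkin_ssa_run", (DL_FUNC) &helixkin_ssa_run, 9},
    {NULL, NULL, 0}
};

/* deSolve looks these up with getNativeSymbolInfo(); register them so the
 * lookup succeeds with dynamic symbols disabled. */
static const R_CMethodDef CEntries[] = {
    {"helixkin_init_full",     (DL_FUNC) &helixkin_init_full,     1},
    {"helixkin_derivs_full",   (DL_FUNC) &helixkin_derivs_full,   6},
    {"helixkin_init_lumped",   (DL_FUNC) &helixkin_init_lumped,   1},
    {"helixkin_derivs_lumped", (DL_FUNC) &helixkin_derivs_lumped, 6},
    {"helixkin_init_qssa",     (DL_FUNC) &helixkin_init_qssa,     1},
    {"helixkin_derivs_qssa",   (DL_FUNC) &helixkin_derivs_qssa,   6},
    {NULL, NULL, 0}
};

void R_init_helixkin(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
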