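#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* derivs/init entry points consumed by deSolve via getNativeSymbolInfo() */
void multisync_radial_init(void (*odeparms)(int *, double *));
void multisync_radial_derivs(int *, double *, double *, double *, double *, int *);
void multisync_goodwin_init(void (*odeparms)(int *, double *));
void multisync_goodwin_derivs(int *, double *, double *, double *, double *, int *);
void multisync_cdk_init(void (*odeparms)(int *, double *));
void multisync_cdk_derivs(int *, double *, double *, double *, double *, int *);
void multisync_coupled_init(void (*odeparms)(int *, double *));
void multisync_coupled_derivs(int *, double *, double *, double *, double *, int *);
void multisync_goodwin_forced_init(void (*odeparms)(int *, double *));
void multisync_goodwin_forced_derivs(int *, double *, double *, double *, double *, int *);

static const R_CMethodDef CEntries[] = {
    {"multisync_radial_init",          (DL_FUNC) &multisync_radial_init,          1},
    {"multisync_radial_derivs",        (DL_FUNC) &multisync_radial_derivs,        6},
    {"multisync_goodwin_init",         (DL_FUNC) &multisync_goodwin_init,         1},
    {"multisync_goodwin_derivs",       (DL_FUNC) &multisync_goodwin_derivs,       6},
    {"multisync_cdk_init",             (DL_FUNC) &multisync_cdk_init,             1},
    {"multisync_cdk_derivs",           (DL_FUNC) &multisync_cdk_derivs,           6},
    {"multisync_coupled_init",         (DL_FUNC) &multisync_coupled_init,         1},
    {"multisync_coupled_derivs",       (DL_FUNC) &multisync_coupled_derivs,       6},
    {"multisync_goodwin_forced_init",  (DL_FUNC) &multisync_goodwin_forced_init,  1},
    {"multisync_goodwin_forced_derivs",(DL_FUNC) &multisync_goodwin_forced_derivs,6},
    {NULL, NULL, 0}
};

void R_init_multisync(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
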