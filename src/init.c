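#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP _hemonet_residual_kernel(SEXP x, SEXP cn, SEXP mode, SEXP hfreeze);
SEXP _hemonet_flows_kernel(SEXP x, SEXP cn, SEXP mode, SEXP hfreeze);

static const R_CallMethodDef CallEntries[] = {
    {"_hemonet_residual_kernel", (DL_FUNC) &_hemonet_residual_kernel, 4},
    {"_hemonet_flows_kernel", (DL_FUNC) &_hemonet_flows_kernel, 4},
    {NULL, NULL, 0}
};

void R_init_hemonet(DllInfo *dll) {
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
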