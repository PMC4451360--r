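/* Mass-state-zero cumomer balance equations, evaluated as a flat term list.
 *
 * The R side (assemble_system) flattens the network into:
 *   parms[0] = N   number of state variables (simulated pools)
 *   parms[1] = T   number of production terms
 *   parms[2] = K   number of RuBP input models
 *   parms[3 .. 3+N-1]          kout[i] = F_i / p_i  (1/s)
 *   then T blocks of 6:        target, coef, f1type, f1idx, f2type, f2idx
 *   then K blocks of 4:        A, a, B, b   (y(t) = A e^{-a t} + B e^{-b t})
 *
 * Factor types: 0 -> constant 1; 1 -> state[idx]; 2 -> input model idx.
 * Each term contributes coef * f1 * f2 to ydot[target]; the linear drain
 * kout[i] * y[i] is subtracted for every state.  Indices are 0-based.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define INSTMFA_MAXPARMS 4096

static double parms[INSTMFA_MAXPARMS];

void instmfa_initmod(void (*odeparms)(int *, double *))
{
    int n = INSTMFA_MAXPARMS;
    odeparms(&n, parms);
}

static double factor_value(int type, int idx, const double *y,
                           const double *inputs, double t)
{
    if (type == 0) return 1.0;
    if (type == 1) return y[idx];
    if (type == 2) {
        const double *m = inputs + 4 * idx;
        return m[0] * exp(-m[1] * t) + m[2] * exp(-m[3] * t);
    }
    return 0.0;
}

void instmfa_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    int N = (int) parms[0];
    int T = (int) parms[1];
    const double *kout = parms + 3;
    const double *terms = parms + 3 + N;
    const double *inputs = parms + 3 + N + 6 * T;
    int i;

    for (i = 0; i < N; i++)
        ydot[i] = -kout[i] * y[i];

    for (i = 0; i < T; i++) {
        const double *tr = terms + 6 * i;
        int target = (int) tr[0];
        double v = tr[1];
        v *= factor_value((int) tr[2], (int) tr[3], y, inputs, *t);
        v *= factor_value((int) tr[4], (int) tr[5], y, inputs, *t);
        ydot[target] += v;
    }
}

static const R_CMethodDef CEntries[] = {
    {"instmfa_derivs",  (DL_FUNC) &instmfa_derivs,  6},
    {"instmfa_initmod", (DL_FUNC) &instmfa_initmod, 1},
    {NULL, NULL, 0}
};

void R_init_instmfa(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
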