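/* Compiled kernels: mass-action ODE right-hand side (deSolve interface)
 * and the Gillespie direct-method stochastic simulation algorithm.
 *
 * Reaction-network encoding shared by both kernels:
 *   every reaction has at most two reactants and a dense net
 *   stoichiometry column; rate laws are elementary mass action
 *   (ODE: k*y1*y2; SSA propensity: k*n1*n2, k*n*(n-1) when the two
 *   reactants are the same species).
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* ---- deSolve compiled model ------------------------------------------- */
/* parms layout (doubles): [n_spec, n_reac,
 *                          k[n_reac],
 *                          re1[n_reac], re2[n_reac]  (1-based, 0 = none),
 *                          stoich[n_spec * n_reac]   (column major)]      */

#define MA_PARMS_MAX 8192
static double ma_parms[MA_PARMS_MAX];

/* copy the packed network description into the static buffer before the
 * solver is invoked (avoids deSolve's fixed-length initfunc contract) */
SEXP C_set_ma_parms(SEXP parms)
{
    int n = LENGTH(parms);
    if (n > MA_PARMS_MAX) error("reaction network too large");
    for (int i = 0; i < n; i++) ma_parms[i] = REAL(parms)[i];
    return R_NilValue;
}

void massaction_derivs(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    const int ns = (int) ma_parms[0];
    const int nr = (int) ma_parms[1];
    const double *k  = ma_parms + 2;
    const double *r1 = ma_parms + 2 + nr;
    const double *r2 = ma_parms + 2 + 2 * nr;
    const double *S  = ma_parms + 2 + 3 * nr;
    int i, j;

    for (i = 0; i < ns; i++) ydot[i] = 0.0;
    for (j = 0; j < nr; j++) {
        double v = k[j];
        int a = (int) r1[j], b = (int) r2[j];
        if (a > 0) v *= y[a - 1];
        if (b > 0) v *= y[b - 1];
        if (v != 0.0) {
            const double *col = S + (size_t) j * ns;
            for (i = 0; i < ns; i++) ydot[i] += col[i] * v;
        }
    }
}

/* ---- Gillespie direct method ------------------------------------------ */
/* Uses R's RNG stream so results are reproducible via set.seed().
 * Returns a list: counts matrix (length(tgrid) x n_spec) with the state
 * immediately before each grid time, the number of reaction events, and
 * a completion flag (0 when the max_events guard tripped).             */

SEXP C_ssa_run(SEXP init, SEXP k_, SEXP re1_, SEXP re2_, SEXP stoich_,
               SEXP tgrid_, SEXP max_events_)
{
    const int ns = LENGTH(init);
    const int nr = LENGTH(k_);
    const int nt = LENGTH(tgrid_);
    const double *k = REAL(k_);
    const int *re1 = INTEGER(re1_);
    const int *re2 = INTEGER(re2_);
    const double *S = REAL(stoich_);
    const double *tgrid = REAL(tgrid_);
    const double max_events = REAL(max_events_)[0];
    const double t_end = tgrid[nt - 1];

    SEXP counts_ = PROTECT(allocMatrix(REALSXP, nt, ns));
    double *counts = REAL(counts_);
    double *n = (double *) R_alloc(ns, sizeof(double));
    double *a = (double *) R_alloc(nr, sizeof(double));
    int i, j, g = 0;
    double t = 0.0, n_events = 0.0;
    int completed = 1;

    for (i = 0; i < ns; i++) n[i] = REAL(init)[i];

    GetRNGstate();
    for (;;) {
        double a0 = 0.0;
        for (j = 0; j < nr; j++) {
            double aj = k[j];
            if (re1[j] > 0) aj *= n[re1[j] - 1];
            if (re2[j] > 0) {
                if (re2[j] == re1[j])
                    aj = k[j] * n[re1[j] - 1] * (n[re1[j] - 1] - 1.0);
                else
                    aj *= n[re2[j] - 1];
            }
            if (aj < 0.0) aj = 0.0;
            a[j] = aj;
            a0 += aj;
        }
        if (a0 <= 0.0) break;                      /* absorbing state */

        double tau = -log(unif_rand()) / a0;
        double t_next = t + tau;
        while (g < nt && tgrid[g] < t_next) {
            for (i = 0; i < ns; i++) counts[g + (size_t) i * nt] = n[i];
            g++;
        }
        if (t_next > t_end) break;
        t = t_next;

        double u = unif_rand() * a0, cum = 0.0;
        int jr = nr - 1;
        for (j = 0; j < nr; j++) {
            cum += a[j];
            if (u <= cum) { jr = j; break; }
        }
        const double *col = S + (size_t) jr * ns;
        for (i = 0; i < ns; i++) n[i] += col[i];

        n_events += 1.0;
        if (n_events >= max_events) { completed = 0; break; }
    }
    PutRNGstate();

    while (g < nt) {                               /* fill remaining grid */
        for (i = 0; i < ns; i++) counts[g + (size_t) i * nt] = n[i];
        g++;
    }

    SEXP out = PROTECT(allocVector(VECSXP, 3));
    SET_VECTOR_ELT(out, 0, counts_);
    SET_VECTOR_ELT(out, 1, ScalarReal(n_events));
    SET_VECTOR_ELT(out, 2, ScalarInteger(completed));
    SEXP nm = PROTECT(allocVector(STRSXP, 3));
    SET_STRING_ELT(nm, 0, mkChar("counts"));
    SET_STRING_ELT(nm, 1, mkChar("n_events"));
    SET_STRING_ELT(nm, 2, mkChar("completed"));
    setAttrib(out, R_NamesSymbol, nm);
    UNPROTECT(3);
    return out;
}

/* ---- registration ----------------------------------------------------- */

static const R_CallMethodDef CallEntries[] = {
    {"C_ssa_run",       (DL_FUNC) &C_ssa_run,       7},
    {"C_set_ma_parms",  (DL_FUNC) &C_set_ma_parms,  1},
    {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
    {"massaction_derivs", (DL_FUNC) &massaction_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_itkmaxent(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
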