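/* Right-hand sides for the network reaction-diffusion model family,
 * in the form expected by deSolve's compiled-model interface.
 *
 * Parameters are passed as a single numeric vector and fetched through
 * deSolve's get_deSolve_gparms() so that problem size (number of regions,
 * number of stacked subjects) can vary at run time.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

static SEXP gparms;

void tauspread_initmod(void (*odeparms)(int *, double *))
{
    DL_FUNC get_gparms = R_GetCCallable("deSolve", "get_deSolve_gparms");
    gparms = (SEXP) get_gparms();
}

/* Single-subject FKPP-type system on R regions.
 *
 * parms layout: [R, rho, alpha, s0 (R), qinf (R), L (R*R, column-major)]
 * state:        s (length R, SUVR scale)
 * ds_i/dt = -rho * sum_j L_ij (s_j - s0_j)
 *           + alpha * (s_i - s0_i) * (qinf_i - (s_i - s0_i))
 * Diffusion is alpha = 0; logistic is rho = 0; the global variant passes
 * constant s0 / qinf vectors.
 */
void tauspread_fkpp(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double *p = REAL(gparms);
    int R = (int) p[0];
    double rho = p[1], alpha = p[2];
    double *s0 = p + 3, *qinf = p + 3 + R, *L = p + 3 + 2 * R;
    int i, j;

    for (i = 0; i < R; i++) {
        double transport = 0.0, d;
        for (j = 0; j < R; j++)
            transport += L[i + R * j] * (y[j] - s0[j]);
        d = y[i] - s0[i];
        ydot[i] = -rho * transport + alpha * d * (qinf[i] - d);
    }
}

/* N independent subjects stacked into one state vector (subject-major:
 * y[(n-1)*R + i] is region i of subject n).  Each subject has its own
 * (rho, alpha); the Laplacian and regional parameters are shared.
 *
 * parms layout: [N, R, rho (N), alpha (N), s0 (R), qinf (R), L (R*R)]
 */
void tauspread_fkpp_stack(int *neq, double *t, double *y, double *ydot,
                          double *yout, int *ip)
{
    double *p = REAL(gparms);
    int N = (int) p[0];
    int R = (int) p[1];
    double *rho = p + 2, *alpha = p + 2 + N;
    double *s0 = p + 2 + 2 * N, *qinf = s0 + R, *L = qinf + R;
    int n, i, j;

    for (n = 0; n < N; n++) {
        double *yn = y + n * R;
        double *dn = ydot + n * R;
        for (i = 0; i < R; i++) {
            double transport = 0.0, d;
            for (j = 0; j < R; j++)
                transport += L[i + R * j] * (yn[j] - s0[j]);
            d = yn[i] - s0[i];
            dn[i] = -rho[n] * transport + alpha[n] * d * (qinf[i] - d);
        }
    }
}

/* Coupled healthy/toxic protein kinetics (heterodimer model).
 *
 * parms layout: [R, rho, k0, k1, k12, k1t (R), L (R*R)]
 * state: [p (R), ptilde (R)]
 * dp_i/dt  = -rho * sum_j L_ij p_j  + k0 - k1 p_i - k12 p_i pt_i
 * dpt_i/dt = -rho * sum_j L_ij pt_j - k1t_i pt_i + k12 p_i pt_i
 */
void tauspread_heterodimer(int *neq, double *t, double *y, double *ydot,
                           double *yout, int *ip)
{
    double *p = REAL(gparms);
    int R = (int) p[0];
    double rho = p[1], k0 = p[2], k1 = p[3], k12 = p[4];
    double *k1t = p + 5, *L = p + 5 + R;
    double *ph = y, *pt = y + R;
    int i, j;

    for (i = 0; i < R; i++) {
        double th = 0.0, tt = 0.0;
        for (j = 0; j < R; j++) {
            th += L[i + R * j] * ph[j];
            tt += L[i + R * j] * pt[j];
        }
        ydot[i] = -rho * th + k0 - k1 * ph[i] - k12 * ph[i] * pt[i];
        ydot[R + i] = -rho * tt - k1t[i] * pt[i] + k12 * ph[i] * pt[i];
    }
}

static const R_CMethodDef cMethods[] = {
    {"tauspread_initmod",     (DL_FUNC) &tauspread_initmod,     1},
    {"tauspread_fkpp",        (DL_FUNC) &tauspread_fkpp,        6},
    {"tauspread_fkpp_stack",  (DL_FUNC) &tauspread_fkpp_stack,  6},
    {"tauspread_heterodimer", (DL_FUNC) &tauspread_heterodimer, 6},
    {NULL, NULL, 0}
};

void R_init_tauspread(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
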