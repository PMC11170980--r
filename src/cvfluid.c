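/* Fixed-step RK4 integration of the lumped-parameter cardiovascular model
 * under a piecewise-constant fluid-perturbation protocol.
 *
 * State vector (11 components):
 *   0 rU    reference BV change under infusion (l)
 *   1 rV    reference BV change under loss (l)
 *   2 BV    blood volume (l)
 *   3 RBC   red-cell content, pct*l
 *   4 rHVL  reference long-term HR change (bpm)
 *   5 HVT   transient HR change under loss (bpm)
 *   6 HVL   long-term HR change under loss (bpm)
 *   7 eint  integral of the HR controller error (bpm*min)
 *   8 HUT   transient HR drop under infusion (bpm)
 *   9 SV    stroke volume (l)
 *  10 TPR   total peripheral resistance (mmHg*min/l)
 *
 * Parameter order matches parameter_names() on the R side.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_STATE 11
#define N_PAR   25

/* rate^power with the convention 0^p := 0 (perturbation responses vanish
 * at rest, whatever the exponent) */
static double rate_pow(double rate, double p)
{
    if (rate <= 0.0) return 0.0;
    return pow(rate, p);
}

static void rhs(const double *pp, double U, double V, double sv_hr,
                const double *y, double *dy)
{
    double A_U_BV = pp[0],  A_V_BV = pp[1],  alpha_U = pp[2],
           alpha_V = pp[3], K_P_BV = pp[4],  G_U_T = pp[5],
           G_V_T = pp[6],   G_V_L = pp[7],   P_U_T = pp[8],
           P_V_L = pp[9],   K_P_H = pp[10],  K_I_H = pp[11],
           G_BV = pp[12],   G_HR = pp[13],   A_SV = pp[14],
           r_SV = pp[15],   K_P_SV = pp[16], A_BP = pp[17],
           K_P_BP = pp[18], r_BP = pp[19],   H0 = pp[22],
           SV0 = pp[23],    TPR0 = pp[24],   BV0 = pp[21];

    double bv = y[2] > 1e-9 ? y[2] : 1e-9; /* guard transient RK substeps */
    double hct = y[3] / bv;
    double q = K_P_BV * (y[2] - BV0 - (y[0] + y[1]));
    double e = y[4] - y[5] - y[6];

    dy[0] = A_U_BV * y[0] + U / (1.0 + alpha_U);
    dy[1] = A_V_BV * y[1] - V / (1.0 + alpha_V);
    dy[2] = U - V - q;
    dy[3] = -V * hct;
    dy[4] = G_V_L * rate_pow(V, P_V_L);
    dy[5] = G_V_T * V;
    dy[6] = K_P_H * e + K_I_H * y[7];
    dy[7] = e;
    dy[8] = G_U_T * rate_pow(U, P_U_T);

    double Hdot = dy[6] + dy[5] - dy[8];
    dy[9] = A_SV * (y[9] - SV0) + G_BV * dy[2] + K_P_SV * (r_SV - y[9])
            + sv_hr * G_HR * Hdot;

    double H = H0 + y[5] + y[6] - y[8];
    double BP = H * y[9] * y[10];
    dy[10] = A_BP * (y[10] - TPR0) + K_P_BP * (r_BP - BP);
}

static void rk4_step(const double *pp, double U, double V, double sv_hr,
                     double h, double *y)
{
    double k1[N_STATE], k2[N_STATE], k3[N_STATE], k4[N_STATE], tmp[N_STATE];
    int i;
    rhs(pp, U, V, sv_hr, y, k1);
    for (i = 0; i < N_STATE; i++) tmp[i] = y[i] + 0.5 * h * k1[i];
    rhs(pp, U, V, sv_hr, tmp, k2);
    for (i = 0; i < N_STATE; i++) tmp[i] = y[i] + 0.5 * h * k2[i];
    rhs(pp, U, V, sv_hr, tmp, k3);
    for (i = 0; i < N_STATE; i++) tmp[i] = y[i] + h * k3[i];
    rhs(pp, U, V, sv_hr, tmp, k4);
    for (i = 0; i < N_STATE; i++)
        y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

/* C_simulate_rk4(params, sv_hr, btime, bU, bV, duration, out_times, dt)
 *
 * Integrates from t = 0 with the baseline-consistent initial state and
 * returns the states at out_times (sorted, within [0, duration]).  The
 * integrator restarts exactly at protocol breakpoints and at output times,
 * so piecewise-constant inputs are never smoothed across discontinuities.
 */
SEXP C_simulate_rk4(SEXP s_params, SEXP s_svhr, SEXP s_btime, SEXP s_bU,
                    SEXP s_bV, SEXP s_duration, SEXP s_out, SEXP s_dt)
{
    const double *pp = REAL(s_params);
    double sv_hr = asReal(s_svhr);
    const double *btime = REAL(s_btime);
    const double *bU = REAL(s_bU);
    const double *bV = REAL(s_bV);
    int nb = LENGTH(s_btime);
    double duration = asReal(s_duration);
    const double *out = REAL(s_out);
    int nout = LENGTH(s_out);
    double dt = asReal(s_dt);

    SEXP s_states = PROTECT(allocMatrix(REALSXP, nout, N_STATE));
    double *st = REAL(s_states);
    for (int i = 0; i < nout * N_STATE; i++) st[i] = NA_REAL;

    /* baseline-consistent initial state */
    double y[N_STATE] = {0};
    y[2] = pp[21];            /* BV0 */
    y[3] = pp[20] * pp[21];   /* HCT0 * BV0 */
    y[9] = pp[23];            /* SV0 */
    y[10] = pp[24];           /* TPR0 */

    /* event times: output times plus protocol breakpoints */
    int nev = nout + nb;
    double *ev = (double *) R_alloc(nev, sizeof(double));
    for (int i = 0; i < nout; i++) ev[i] = out[i];
    for (int i = 0; i < nb; i++) ev[nout + i] = btime[i];
    R_rsort(ev, nev);

    int ok = 1, iout = 0;
    double t = 0.0, t_fail = NA_REAL;

    /* outputs requested at t = 0 (there may be duplicates) */
    while (iout < nout && out[iout] <= 0.0) {
        for (int j = 0; j < N_STATE; j++) st[iout + j * nout] = y[j];
        iout++;
    }

    for (int ie = 0; ie < nev && ok; ie++) {
        double t1 = ev[ie];
        if (t1 <= t) continue;
        /* rates on [t, t1): protocol interval containing t */
        double U = 0.0, V = 0.0;
        if (t < duration) {
            int k = -1;
            for (int i = 0; i < nb; i++) {
                if (btime[i] <= t + 1e-12) k = i; else break;
            }
            if (k >= 0) { U = bU[k]; V = bV[k]; }
        }
        int nstep = (int) ceil((t1 - t) / dt - 1e-9);
        if (nstep < 1) nstep = 1;
        double h = (t1 - t) / nstep;
        for (int s = 0; s < nstep; s++) {
            rk4_step(pp, U, V, sv_hr, h, y);
            if (!R_FINITE(y[2]) || y[2] <= 0.0) { ok = 0; break; }
        }
        for (int j = 0; j < N_STATE && ok; j++) {
            if (!R_FINITE(y[j])) ok = 0;
        }
        t = t1;
        if (!ok) { t_fail = t; break; }
        while (iout < nout && out[iout] <= t + 1e-12) {
            for (int j = 0; j < N_STATE; j++) st[iout + j * nout] = y[j];
            iout++;
        }
    }

    SEXP res = PROTECT(allocVector(VECSXP, 3));
    SET_VECTOR_ELT(res, 0, s_states);
    SET_VECTOR_ELT(res, 1, ScalarLogical(ok));
    SET_VECTOR_ELT(res, 2, ScalarReal(t_fail));
    SEXP nms = PROTECT(allocVector(STRSXP, 3));
    SET_STRING_ELT(nms, 0, mkChar("states"));
    SET_STRING_ELT(nms, 1, mkChar("success"));
    SET_STRING_ELT(nms, 2, mkChar("t_fail"));
    setAttrib(res, R_NamesSymbol, nms);
    UNPROTECT(3);
    return res;
}

static const R_CallMethodDef callMethods[] = {
    {"C_simulate_rk4", (DL_FUNC) &C_simulate_rk4, 8},
    {NULL, NULL, 0}
};

void R_init_cvfluid(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
}
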