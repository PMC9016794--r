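/* Compiled right-hand sides for the shipped oscillator models, in the
 * deSolve compiled-code calling convention (initfunc + derivs pairs).
 * Parameter vectors are assembled on the R side; layouts must match
 * the .c_parms() builders in R/model_zoo.R exactly.
 */
#include <R.h>
#include <math.h>

/* ------------------------------------------------------------------ */
/* Planar radial-polynomial oscillator (normal form & hysteresis fixture)
 * dr/dt = -k * r * Q(r^2),  dtheta/dt = omega0 + beta * r^2
 * Q given by up to MAXC polynomial coefficients in u = r^2 (ascending).
 * parms: [k, omega0, beta, nc, c0..c7]                                */
#define RAD_NP 12
#define RAD_MAXC 8
static double rad_p[RAD_NP];

void multisync_radial_init(void (*odeparms)(int *, double *))
{
    int n = RAD_NP;
    odeparms(&n, rad_p);
}

void multisync_radial_derivs(int *neq, double *t, double *y, double *ydot,
                             double *yout, int *ip)
{
    double k = rad_p[0], omega0 = rad_p[1], beta = rad_p[2];
    int nc = (int) rad_p[3];
    double u = y[0] * y[0] + y[1] * y[1];
    double q = 0.0, up = 1.0;
    int i;
    for (i = 0; i < nc; i++) {
        q += rad_p[4 + i] * up;
        up *= u;
    }
    {
        double g = -k * q;                 /* radial rate / r           */
        double w = omega0 + beta * u;      /* angular velocity          */
        ydot[0] = g * y[0] - w * y[1];
        ydot[1] = g * y[1] + w * y[0];
    }
}

/* ------------------------------------------------------------------ */
/* Clock-like negative-feedback (Goodwin-type) oscillator: y = (M,P,I)
 * parms: [tau, v1,K1,n, v2,K2, k3, v4,K4, k5, v6,K6, Rport]           */
#define GW_NP 13
static double gw_p[GW_NP];

void multisync_goodwin_init(void (*odeparms)(int *, double *))
{
    int n = GW_NP;
    odeparms(&n, gw_p);
}

static void goodwin_rates(const double *p, double Rport,
                          const double *y, double *ydot)
{
    double tau = p[0];
    double v1 = p[1], K1 = p[2], nh = p[3];
    double v2 = p[4], K2 = p[5];
    double k3 = p[6], v4 = p[7], K4 = p[8];
    double k5 = p[9], v6 = p[10], K6 = p[11];
    double M = y[0], P = y[1], I = y[2];
    double Kn = pow(K1, nh);
    double In = pow(I > 0 ? I : 0.0, nh);
    ydot[0] = (v1 * Kn / (Kn + In) * Rport - v2 * M / (K2 + M)) / tau;
    ydot[1] = (k3 * M - v4 * P / (K4 + P)) / tau;
    ydot[2] = (k5 * P - v6 * I / (K6 + I)) / tau;
}

void multisync_goodwin_derivs(int *neq, double *t, double *y, double *ydot,
                              double *yout, int *ip)
{
    goodwin_rates(gw_p, gw_p[12], y, ydot);
}

/* ------------------------------------------------------------------ */
/* Cell-cycle-like relaxation oscillator: y = (C, A, X, W)
 * parms: [eps, vi, vd, Kd, kdeg, VM1, Kc, K1g, V2, K2g, alpha,
 *         VM3, K3g, V4, K4g, ksw, kdw, vsw, Kw, hw, Sport]            */
#define CDK_NP 21
static double cdk_p[CDK_NP];

void multisync_cdk_init(void (*odeparms)(int *, double *))
{
    int n = CDK_NP;
    odeparms(&n, cdk_p);
}

static void cdk_rates(const double *p, double S,
                      const double *y, double *ydot)
{
    double eps = p[0];
    double vi = p[1], vd = p[2], Kd = p[3], kdeg = p[4];
    double VM1 = p[5], Kc = p[6], K1g = p[7];
    double V2 = p[8], K2g = p[9], alpha = p[10];
    double VM3 = p[11], K3g = p[12], V4 = p[13], K4g = p[14];
    double ksw = p[15], kdw = p[16];
    double vsw = p[17], Kw = p[18], hw = p[19];
    double C = y[0], A = y[1], X = y[2], W = y[3];
    double Sh, Kwh, ind;
    if (vsw > 0.0 && S > 0.0) {
        Sh = pow(S, hw);
        Kwh = pow(Kw, hw);
        ind = vsw * Sh / (Kwh + Sh);
    } else {
        ind = 0.0;
    }
    ydot[0] = (vi - vd * X * C / (Kd + C) - kdeg * C) / eps;
    ydot[1] = (VM1 * (C / (Kc + C)) * (1.0 - A) / (K1g + 1.0 - A)
               - V2 * (1.0 + alpha * W) * A / (K2g + A)) / eps;
    ydot[2] = (VM3 * A * (1.0 - X) / (K3g + 1.0 - X)
               - V4 * X / (K4g + X)) / eps;
    ydot[3] = (ksw + ind - kdw * W) / eps;
}

void multisync_cdk_derivs(int *neq, double *t, double *y, double *ydot,
                          double *yout, int *ip)
{
    cdk_rates(cdk_p, cdk_p[20], y, ydot);
}

/* ------------------------------------------------------------------ */
/* Bidirectionally coupled clock + cell cycle: y = (M,P,I,C,A,X,W)
 * parms: [goodwin 12] + [cdk 17 core: eps..kdw] + [vsw, Kw, hw]
 *        + [K_I, g_r] + [coupled flag]  -> 35                         */
#define CPL_NP 35
static double cpl_p[CPL_NP];

void multisync_coupled_init(void (*odeparms)(int *, double *))
{
    int n = CPL_NP;
    odeparms(&n, cpl_p);
}

void multisync_coupled_derivs(int *neq, double *t, double *y, double *ydot,
                              double *yout, int *ip)
{
    double cdk_full[21];
    double S, Rport;
    int i;
    double K_I = cpl_p[32], g_r = cpl_p[33];
    int coupled = cpl_p[34] > 0.0;

    if (coupled) {
        double A = y[4] > 0.0 ? y[4] : 0.0;
        double Kg = pow(K_I, g_r);
        S = y[1];                              /* clock protein P      */
        Rport = Kg / (Kg + pow(A, g_r));       /* mitotic repression   */
    } else {
        S = 0.0;
        Rport = 1.0;
    }
    goodwin_rates(cpl_p, Rport, y, ydot);
    for (i = 0; i < 17; i++) cdk_full[i] = cpl_p[12 + i];
    cdk_full[17] = coupled ? cpl_p[29] : 0.0;  /* vsw                  */
    cdk_full[18] = cpl_p[30];
    cdk_full[19] = cpl_p[31];
    cdk_full[20] = 0.0;                        /* S passed directly    */
    cdk_rates(cdk_full, S, y + 3, ydot + 3);
}

/* ------------------------------------------------------------------ */
/* Periodically forced clock: mRNA synthesis rate v1 varies in time.
 * parms: [goodwin 12, Rport, kind, Tf, amp, duty, lo, hi] -> 19
 * kind 1 = square (lo/hi levels, duty fraction high),
 * kind 2 = sinusoid v1*(1 + amp*sin(2*pi*t/Tf)), clipped at 0.        */
#define GWF_NP 19
static double gwf_p[GWF_NP];

void multisync_goodwin_forced_init(void (*odeparms)(int *, double *))
{
    int n = GWF_NP;
    odeparms(&n, gwf_p);
}

void multisync_goodwin_forced_derivs(int *neq, double *t, double *y,
                                     double *ydot, double *yout, int *ip)
{
    double p[GW_NP];
    int i;
    int kind = (int) gwf_p[13];
    double Tf = gwf_p[14], amp = gwf_p[15], duty = gwf_p[16];
    double lo = gwf_p[17], hi = gwf_p[18];
    for (i = 0; i < GW_NP; i++) p[i] = gwf_p[i];
    if (kind == 1) {
        double ph = fmod(*t / Tf, 1.0);
        if (ph < 0) ph += 1.0;
        p[1] = (ph < duty) ? hi : lo;
    } else {
        double v = gwf_p[1] * (1.0 + amp * sin(2.0 * M_PI * (*t) / Tf));
        p[1] = v > 0.0 ? v : 0.0;
    }
    goodwin_rates(p, p[12], y, ydot);
}
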