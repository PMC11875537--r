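/* Right-hand sides of the community ODE variants, in the layout packed by
 * R/pack.R.  Used two ways: as a deSolve compiled derivative ("plv_derivs",
 * parameters installed beforehand with C_set_parms) and directly through
 * C_eval_derivs for residuals and the exported rhs operation.
 *
 * Parameter vector layouts (all doubles, 0-based offsets):
 *
 * classic LV          [0]=0 [1]=m [2]=D [3..]=mu[m], G[m*m]
 * general MGE model   [0]=1 [1]=m [2]=D [3]=rho [4]=delta [5]=l
 *                     [6..]=mu[m], lam[m*m], G[m*m], kap[m*m],
 *                           eta[m*m*m], niche_map[m], niche_cap[l]
 * strong selection    [0]=2 [1]=m [2]=D [3..]=mu[m], G[m*m], kap[m],
 *                           eta[m*m]
 * metacommunity       [0]=3 [1]=u [2]=v [3]=omega [4..]= a general block
 *
 * Matrices are column-major as in R.  G[i + m*j] is the competition of
 * species j on species i; lam[i + m*j] the growth effect of the plasmid
 * originating from species j in species i; eta[j + m*k + m*m*i] the
 * transfer rate of plasmid j from donor k to recipient i.
 *
 * State layouts: classic s[m]; general s[m] then p[m*m] column-major with
 * the diagonal p_ii slaved to s_i; selection s[m] then p[m]; metacommunity
 * u*v consecutive general blocks (patch (a,b) at index a + u*b, 0-based).
 */

#include <R.h>
#include <Rinternals.h>
#include <stddef.h>

static double *parms_buf = NULL;
static SEXP parms_keep = NULL;
static double *scr = NULL;
static size_t scr_len = 0;

static void ensure_scr(size_t n)
{
    if (n > scr_len) {
        scr = (scr == NULL) ? R_Calloc(n, double) : R_Realloc(scr, n, double);
        scr_len = n;
    }
}

static size_t scratch_need(const double *pv)
{
    int code = (int) pv[0];
    if (code == 1) {
        int m = (int) pv[1];
        return (size_t) m * m;
    }
    if (code == 3) {
        int m = (int) pv[5]; /* pv[4] is the patch code, pv[5] its m */
        return (size_t) m * m;
    }
    return 1;
}

/* classic Lotka-Volterra: s only */
static void deriv_classic(const double *pv, const double *y, double *dy)
{
    int m = (int) pv[1];
    double D = pv[2];
    const double *mu = pv + 3;
    const double *G = mu + m;

    for (int i = 0; i < m; i++) {
        double tot = y[i];
        for (int j = 0; j < m; j++)
            if (j != i) tot += G[i + m * j] * y[j];
        dy[i] = mu[i] * y[i] * (1.0 - tot) - D * y[i];
    }
}

/* general model: growth-rate effects, optional competition modification
 * (delta), optional niche structure, full transfer tensor */
static void deriv_general(const double *pv, const double *y, double *dy)
{
    int m = (int) pv[1];
    double D = pv[2], rho = pv[3], delta = pv[4];
    int l = (int) pv[5];
    const double *mu = pv + 6;
    const double *lam = mu + m;
    const double *G = lam + (size_t) m * m;
    const double *kap = G + (size_t) m * m;
    const double *eta = kap + (size_t) m * m;
    const double *nmap = eta + (size_t) m * m * m;
    const double *ncap = nmap + m;
    const double *s = y;
    const double *p = y + m;
    double *ds = dy, *dp = dy + m;
    double *r = scr; /* carrier fractions p_ij/s_i clamped to [0,1] */

    /* carrier fractions; below the 1e-8 abundance floor the ratio of two
     * vanishing quantities is numerical noise, so it is taken as 0 */
    for (int j = 0; j < m; j++)
        for (int i = 0; i < m; i++) {
            double ri = 0.0;
            if (s[i] > 1e-8) {
                ri = p[i + m * j] / s[i];
                if (ri < 0.0) ri = 0.0;
                else if (ri > 1.0) ri = 1.0;
            }
            r[i + m * j] = ri;
        }

    for (int i = 0; i < m; i++) {
        double c;
        if (l > 0) {
            int ni = (int) nmap[i];
            double tot = s[i];
            for (int j = 0; j < m; j++) {
                if (j == i || (int) nmap[j] != ni) continue;
                tot += (G[i + m * j] + delta * r[j + m * i]) * s[j];
            }
            c = 1.0 - tot / ncap[ni - 1];
        } else {
            double tot = s[i];
            for (int j = 0; j < m; j++) {
                if (j == i) continue;
                tot += (G[i + m * j] + delta * r[j + m * i]) * s[j];
            }
            c = 1.0 - tot;
        }

        double f = 1.0;
        for (int j = 0; j < m; j++)
            if (j != i) f *= 1.0 + lam[i + m * j] * r[i + m * j];
        ds[i] = mu[i] * f * s[i] * c - D * s[i];

        for (int j = 0; j < m; j++) {
            if (j == i) continue;
            double g = 1.0;
            for (int k = 0; k < m; k++)
                if (k != i && k != j)
                    g *= 1.0 + lam[i + m * k] * r[i + m * k];
            double grow = mu[i] * (1.0 + lam[i + m * j]) * g *
                p[i + m * j] * c;
            double pool = 0.0;
            for (int k = 0; k < m; k++) {
                double w = eta[j + m * k + (size_t) m * m * i];
                if (w == 0.0) continue;
                double donor = p[k + m * j];
                /* unequal carrying capacities, two-species form only */
                if (m == 2 && rho != 1.0 && k != i)
                    donor *= (i == 0) ? rho : 1.0 / rho;
                pool += w * donor;
            }
            dp[i + m * j] = grow + (s[i] - p[i + m * j]) * pool -
                (D + kap[i + m * j]) * p[i + m * j];
        }
    }
    for (int i = 0; i < m; i++) dp[i + m * i] = ds[i];
}

/* strong selection: only carriers grow */
static void deriv_selection(const double *pv, const double *y, double *dy)
{
    int m = (int) pv[1];
    double D = pv[2];
    const double *mu = pv + 3;
    const double *G = mu + m;
    const double *kap = G + (size_t) m * m;
    const double *eta = kap + m; /* eta[j + m*i]: donor j -> recipient i */
    const double *s = y;
    const double *p = y + m;
    double *ds = dy, *dp = dy + m;

    for (int i = 0; i < m; i++) {
        double tot = s[i];
        for (int j = 0; j < m; j++)
            if (j != i) tot += G[i + m * j] * s[j];
        double c = 1.0 - tot;
        ds[i] = mu[i] * p[i] * c - D * s[i];
        double pool = 0.0;
        for (int j = 0; j < m; j++)
            pool += eta[j + m * i] * p[j];
        dp[i] = mu[i] * p[i] * c + (s[i] - p[i]) * pool -
            kap[i] * p[i] - D * p[i];
    }
}

/* grid metacommunity: general patches + nearest-neighbour dispersal */
static void deriv_meta(const double *pv, const double *y, double *dy)
{
    int u = (int) pv[1], v = (int) pv[2];
    double omega = pv[3];
    const double *pp = pv + 4;
    int m = (int) pp[1];
    size_t nb = (size_t) m + (size_t) m * m;
    int P = u * v;

    for (int q = 0; q < P; q++)
        deriv_general(pp, y + q * nb, dy + q * nb);

    if (omega > 0.0) {
        for (int q = 0; q < P; q++) {
            int a = q % u, b = q / u;
            int nbr[4];
            int nn = 0;
            if (a > 0) nbr[nn++] = q - 1;
            if (a < u - 1) nbr[nn++] = q + 1;
            if (b > 0) nbr[nn++] = q - u;
            if (b < v - 1) nbr[nn++] = q + u;
            for (int t = 0; t < nn; t++) {
                const double *yn = y + (size_t) nbr[t] * nb;
                const double *ys = y + (size_t) q * nb;
                double *dq = dy + (size_t) q * nb;
                for (size_t c = 0; c < nb; c++)
                    dq[c] += omega * (yn[c] - ys[c]);
            }
        }
    }
}

static void dispatch(const double *pv, const double *y, double *dy)
{
    switch ((int) pv[0]) {
    case 0: deriv_classic(pv, y, dy); break;
    case 1: deriv_general(pv, y, dy); break;
    case 2: deriv_selection(pv, y, dy); break;
    case 3: deriv_meta(pv, y, dy); break;
    default: error("unknown model variant code %d", (int) pv[0]);
    }
}

/* ---- interfaces ---- */

SEXP C_set_parms(SEXP p)
{
    if (TYPEOF(p) != REALSXP)
        error("parameter vector must be double");
    if (parms_keep != NULL) R_ReleaseObject(parms_keep);
    R_PreserveObject(p);
    parms_keep = p;
    parms_buf = REAL(p);
    ensure_scr(scratch_need(parms_buf));
    return R_NilValue;
}

SEXP C_eval_derivs(SEXP p, SEXP y)
{
    if (TYPEOF(p) != REALSXP || TYPEOF(y) != REALSXP)
        error("arguments must be double vectors");
    ensure_scr(scratch_need(REAL(p)));
    SEXP ans = PROTECT(allocVector(REALSXP, XLENGTH(y)));
    dispatch(REAL(p), REAL(y), REAL(ans));
    UNPROTECT(1);
    return ans;
}

/* deSolve entry points */
void plv_initmod(void (*odeparms)(int *, double *))
{
    /* parameters are installed via C_set_parms before each solve */
    if (parms_buf == NULL)
        error("model parameters have not been installed");
}

void plv_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    dispatch(parms_buf, y, ydot);
}
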