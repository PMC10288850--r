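/* Dynamic time warping with squared-difference local cost, symmetric
 * (diagonal/vertical/horizontal) steps, boundary matching, and an optional
 * Sakoe-Chiba band. Returns the Euclidean (square-rooted) accumulated cost
 * together with the step count of one optimal path so callers can
 * length-normalize.
 *
 * Tie-break when predecessors are equal: diagonal, then vertical (advance
 * the query), then horizontal. Only the reported path length depends on it;
 * the distance does not.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>
#include <float.h>

SEXP c_dtw(SEXP xs, SEXP ys, SEXP windows)
{
    const double *x = REAL(xs), *y = REAL(ys);
    const R_xlen_t n = XLENGTH(xs), m = XLENGTH(ys);
    int window = INTEGER(windows)[0]; /* NA_INTEGER = unconstrained */

    if (n == 0 || m == 0)
        error("dtw: empty sequence");

    if (window != NA_INTEGER) {
        /* widen so the corner (n, m) stays reachable */
        R_xlen_t diff = n > m ? n - m : m - n;
        if (window < diff) window = (int) diff;
    }

    /* two-row DP over accumulated cost D and path step count L */
    double *dprev = (double *) R_alloc(m, sizeof(double));
    double *dcur  = (double *) R_alloc(m, sizeof(double));
    double *lprev = (double *) R_alloc(m, sizeof(double));
    double *lcur  = (double *) R_alloc(m, sizeof(double));

    for (R_xlen_t i = 0; i < n; i++) {
        R_xlen_t jlo = 0, jhi = m - 1;
        if (window != NA_INTEGER) {
            if (i > (R_xlen_t) window) jlo = i - window;
            if (i + window < m - 1)    jhi = i + window;
        }
        for (R_xlen_t j = 0; j < m; j++) dcur[j] = R_PosInf;
        for (R_xlen_t j = jlo; j <= jhi; j++) {
            double d = x[i] - y[j];
            double cost = d * d;
            if (i == 0 && j == 0) {
                dcur[j] = cost;
                lcur[j] = 1.0;
            } else {
                double diag = (i > 0 && j > 0) ? dprev[j - 1] : R_PosInf;
                double vert = (i > 0) ? dprev[j] : R_PosInf;
                double horz = (j > 0) ? dcur[j - 1] : R_PosInf;
                double best = diag;
                double len  = (i > 0 && j > 0) ? lprev[j - 1] : 0.0;
                if (vert < best) { best = vert; len = lprev[j]; }
                if (horz < best) { best = horz; len = lcur[j - 1]; }
                dcur[j] = cost + best;
                lcur[j] = len + 1.0;
            }
        }
        double *tmp;
        tmp = dprev; dprev = dcur; dcur = tmp;
        tmp = lprev; lprev = lcur; lcur = tmp;
    }

    SEXP out = PROTECT(allocVector(REALSXP, 2));
    REAL(out)[0] = sqrt(dprev[m - 1]);
    REAL(out)[1] = lprev[m - 1];
    UNPROTECT(1);
    return out;
}
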