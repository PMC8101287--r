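/* Bivalent-analyte surface binding scheme for deSolve's compiled-model
 * interface.  One stacked system integrates every injection concentration of
 * a cycle series at once: state vector is (AB_1, AB2_1, ..., AB_n, AB2_n).
 *
 * Per concentration C_i:
 *   B_free  = R_max - AB - occ * AB2     (occ = ligand equivalents per AB2)
 *   dAB/dt  = kon1*C_i*B_free - koff1*AB - kon2*AB*B_free + koff2*AB2
 *   dAB2/dt = kon2*AB*B_free - koff2*AB2
 *
 * Parameter vector: kon1, koff1, kon2 (RU^-1 s^-1), koff2, Rmax, occ, n,
 * C_1..C_n (M).  Dissociation segments are run with all C_i = 0.
 */
#include <R.h>

#define MAX_CONC 64
#define NPARFIX  7

static double parms[NPARFIX + MAX_CONC];

void initmod_bivalent(void (*odeparms)(int *, double *))
{
    /* caller supplies the exact length; request the maximum and rely on
     * deSolve having been handed a vector of that full length */
    int n = NPARFIX + MAX_CONC;
    odeparms(&n, parms);
}

void derivs_bivalent(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const double kon1 = parms[0], koff1 = parms[1];
    const double kon2 = parms[2], koff2 = parms[3];
    const double rmax = parms[4], occ = parms[5];
    const int n = (int) parms[6];

    for (int i = 0; i < n; i++) {
        const double C = parms[NPARFIX + i];
        const double ab = y[2 * i], ab2 = y[2 * i + 1];
        double bfree = rmax - ab - occ * ab2;
        if (bfree < 0.0) bfree = 0.0;
        const double form2 = kon2 * ab * bfree - koff2 * ab2;
        ydot[2 * i] = kon1 * C * bfree - koff1 * ab - form2;
        ydot[2 * i + 1] = form2;
    }
}
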