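/* Compiled right-hand sides for the two-stage adsorption model, in the
 * deSolve compiled-derivs convention (initfunc + derivs looked up by name).
 *
 * Full ladder state layout (neq = 1 + (Nmax+1) + nC, nC = max(0, Nmax - s)):
 *   y[0]                      M      free monomer, mol/L
 *   y[1 + i], i = 0..Nmax     P_i    propagating chain with i incorporated units
 *   y[2 + Nmax + (i - s)]     C_i    helix-monomer complex, i = s..Nmax-1
 *
 * Constraint: propagation and binding are switched off at the top rung
 * i = Nmax so that chain count and monomer-unit count are conserved exactly
 * on the truncated ladder; the truncation check in R guarantees the top of
 * the ladder is unoccupied to ~1e-10 * I0.
 *
 * Lumped layout (neq = s + 3): y = [M, P_0..P_{s-1}, H, C] where
 * H = sum_{i>=s} P_i and C = sum_{i>=s} C_i. The aggregation is exact for
 * monomer-consumption observables because all helix chains share one set of
 * rate constants.
 *
 * QSSA layout (neq = s + 2): y = [M, P_0..P_{s-1}, H] with effective
 * second-order helix-stage propagation k2eff = kr*kon/(koff+kr).
 */

#include <R.h>

static double parms_full[6];
#define F_K1   parms_full[0]
#define F_KON  parms_full[1]
#define F_KOFF parms_full[2]
#define F_KR   parms_full[3]
#define F_S    parms_full[4]
#define F_NMAX parms_full[5]

void helixkin_init_full(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, parms_full);
}

void helixkin_derivs_full(int *neq, double *t, double *y, double *ydot,
                          double *yout, int *ip)
{
    const int s = (int) F_S, Nmax = (int) F_NMAX;
    const int nC = (Nmax - s) > 0 ? (Nmax - s) : 0;
    const double k1 = F_K1, kon = F_KON, koff = F_KOFF, kr = F_KR;
    const double M = y[0];
    const double *P = y + 1;        /* P_0..P_Nmax */
    const double *C = y + 2 + Nmax; /* C_s..C_{Nmax-1} */
    double *dP = ydot + 1, *dC = ydot + 2 + Nmax;
    int i;

    /* coil propagation active for i < min(s, Nmax); binding for s <= i < Nmax */
    int coil_top = s < Nmax ? s : Nmax;

    double sumPcoil = 0.0, sumPbind = 0.0, sumC = 0.0;
    for (i = 0; i < coil_top; i++) sumPcoil += P[i];
    for (i = s; i < Nmax; i++) sumPbind += P[i];
    for (i = 0; i < nC; i++) sumC += C[i];

    ydot[0] = -k1 * M * sumPcoil - kon * M * sumPbind + koff * sumC;

    dP[0] = (coil_top > 0) ? -k1 * M * P[0] : 0.0;
    for (i = 1; i < coil_top; i++)
        dP[i] = k1 * M * (P[i - 1] - P[i]);
    if (s <= Nmax) {
        /* entry into the helix stage */
        dP[s] = k1 * M * P[s - 1];
        if (s < Nmax)
            dP[s] += -kon * M * P[s] + koff * C[0];
        for (i = s + 1; i < Nmax; i++)
            dP[i] = kr * C[i - 1 - s] - kon * M * P[i] + koff * C[i - s];
        if (Nmax > s)
            dP[Nmax] = kr * C[Nmax - 1 - s];
    } else {
        /* s > Nmax: pure coil growth, top rung absorbs */
        dP[Nmax] = k1 * M * P[Nmax - 1];
    }
    for (i = 0; i < nC; i++)
        dC[i] = kon * M * P[s + i] - (koff + kr) * C[i];
}

static double parms_lump[5];
#define L_K1   parms_lump[0]
#define L_KON  parms_lump[1]
#define L_KOFF parms_lump[2]
#define L_KR   parms_lump[3]
#define L_S    parms_lump[4]

void helixkin_init_lumped(void (*odeparms)(int *, double *))
{
    int n = 5;
    odeparms(&n, parms_lump);
}

void helixkin_derivs_lumped(int *neq, double *t, double *y, double *ydot,
                            double *yout, int *ip)
{
    const int s = (int) L_S;
    const double k1 = L_K1, kon = L_KON, koff = L_KOFF, kr = L_KR;
    const double M = y[0];
    const double *P = y + 1;  /* P_0..P_{s-1} */
    const double H = y[s + 1], C = y[s + 2];
    double *dP = ydot + 1;
    int i;

    double sumPcoil = 0.0;
    for (i = 0; i < s; i++) sumPcoil += P[i];

    ydot[0] = -k1 * M * sumPcoil - kon * M * H + koff * C;
    dP[0] = -k1 * M * P[0];
    for (i = 1; i < s; i++)
        dP[i] = k1 * M * (P[i - 1] - P[i]);
    ydot[s + 1] = k1 * M * P[s - 1] - kon * M * H + (koff + kr) * C;
    ydot[s + 2] = kon * M * H - (koff + kr) * C;
}

static double parms_qssa[3];
#define Q_K1 parms_qssa[0]
#define Q_K2 parms_qssa[1]
#define Q_S  parms_qssa[2]

void helixkin_init_qssa(void (*odeparms)(int *, double *))
{
    int n = 3;
    odeparms(&n, parms_qssa);
}

void helixkin_derivs_qssa(int *neq, double *t, double *y, double *ydot,
                          double *yout, int *ip)
{
    const int s = (int) Q_S;
    const double k1 = Q_K1, k2 = Q_K2;
    const double M = y[0];
    const double *P = y + 1;
    const double H = y[s + 1];
    double *dP = ydot + 1;
    int i;

    double sumPcoil = 0.0;
    for (i = 0; i < s; i++) sumPcoil += P[i];

    ydot[0] = -k1 * M * sumPcoil - k2 * M * H;
    dP[0] = -k1 * M * P[0];
    for (i = 1; i < s; i++)
        dP[i] = k1 * M * (P[i - 1] - P[i]);
    ydot[s + 1] = k1 * M * P[s - 1];
}
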