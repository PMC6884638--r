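/* Gillespie direct-method simulation of the two-stage adsorption network.
 *
 * Exact integer bookkeeping: every chain is an individual with a degree of
 * polymerization and a binding flag. Because all chains within one class
 * (coil, helix-unbound, helix-bound) share the same rate constant, channel
 * selection is class-first (O(1) propensities), then uniform within the
 * class via swap-remove index sets.
 *
 * Volume convention: V = n_init / (N_A * I0), so the stochastic bimolecular
 * constants are c = k * I0 / n_init and the initial monomer count is
 * round(n_init * M0 / I0). Unimolecular constants are unchanged.
 *
 * Uses R's RNG (unif_rand / exp_rand): trajectories are reproducible from
 * set.seed() on the R side.
 */

#include <R.h>
#include <Rinternals.h>
#include <Rmath.h>

#define SET_COIL  0
#define SET_HELIX 1
#define SET_BOUND 2

typedef struct {
    int *ids[3];
    int size[3];
    int *pos;    /* position of chain id within its set */
    int *setof;  /* which set a chain id belongs to */
} chain_sets;

static void cs_move(chain_sets *cs, int id, int to)
{
    int from = cs->setof[id];
    int p = cs->pos[id];
    int last = cs->size[from] - 1;
    int moved = cs->ids[from][last];
    cs->ids[from][p] = moved;
    cs->pos[moved] = p;
    cs->size[from] = last;
    cs->ids[to][cs->size[to]] = id;
    cs->pos[id] = cs->size[to];
    cs->setof[id] = to;
    cs->size[to]++;
}

static int cs_pick(chain_sets *cs, int set)
{
    int k = (int) (unif_rand() * cs->size[set]);
    if (k >= cs->size[set]) k = cs->size[set] - 1;
    return cs->ids[set][k];
}

SEXP helixkin_ssa_run(SEXP sk1, SEXP skon, SEXP skoff, SEXP skr, SEXP ss,
                      SEXP sM0, SEXP sI0, SEXP sn_init, SEXP scheckpoints)
{
    const double k1 = asReal(sk1), kon = asReal(skon), koff = asReal(skoff),
                 kr = asReal(skr), M0 = asReal(sM0), I0 = asReal(sI0);
    const int s = asInteger(ss), n_init = asInteger(sn_init);
    const double c1 = k1 * I0 / n_init;   /* stochastic coil propagation */
    const double con = kon * I0 / n_init; /* stochastic adsorption */
    const double M0count = round(n_init * (M0 / I0));

    const int ncp = LENGTH(scheckpoints);
    const double *cp = REAL(scheckpoints);

    SEXP conv_ring = PROTECT(allocVector(REALSXP, ncp));
    SEXP conv_free = PROTECT(allocVector(REALSXP, ncp));
    SEXP dp_out = PROTECT(allocVector(INTSXP, n_init));
    double *xr = REAL(conv_ring), *xf = REAL(conv_free);
    int *dp = INTEGER(dp_out);

    chain_sets cs;
    int j;
    for (j = 0; j < 3; j++) {
        cs.ids[j] = (int *) R_alloc(n_init, sizeof(int));
        cs.size[j] = 0;
    }
    cs.pos = (int *) R_alloc(n_init, sizeof(int));
    cs.setof = (int *) R_alloc(n_init, sizeof(int));

    /* all chains start as free initiator (DP 0), i.e. coil (s >= 2) */
    for (j = 0; j < n_init; j++) {
        dp[j] = 0;
        cs.ids[SET_COIL][j] = j;
        cs.pos[j] = j;
        cs.setof[j] = SET_COIL;
    }
    cs.size[SET_COIL] = n_init;

    double M = M0count;
    double t = 0.0, n_events = 0.0;
    int icp = 0;

    GetRNGstate();
    while (icp < ncp) {
        double a1 = c1 * M * cs.size[SET_COIL];
        double a2 = con * M * cs.size[SET_HELIX];
        double a3 = koff * cs.size[SET_BOUND];
        double a4 = kr * cs.size[SET_BOUND];
        double atot = a1 + a2 + a3 + a4;

        if (atot <= 0.0) {
            for (; icp < ncp; icp++) {
                xr[icp] = 1.0 - (M + cs.size[SET_BOUND]) / M0count;
                xf[icp] = 1.0 - M / M0count;
            }
            break;
        }

        t += exp_rand() / atot;
        /* record checkpoints passed before this event fires */
        while (icp < ncp && cp[icp] < t) {
            xr[icp] = 1.0 - (M + cs.size[SET_BOUND]) / M0count;
            xf[icp] = 1.0 - M / M0count;
            icp++;
        }
        if (icp >= ncp) break;

        double u = unif_rand() * atot;
        n_events += 1.0;
        if (u < a1) {                       /* coil propagation */
            int id = cs_pick(&cs, SET_COIL);
            dp[id]++;
            M -= 1.0;
            if (dp[id] >= s) cs_move(&cs, id, SET_HELIX);
        } else if (u < a1 + a2) {           /* adsorption */
            int id = cs_pick(&cs, SET_HELIX);
            cs_move(&cs, id, SET_BOUND);
            M -= 1.0;
        } else if (u < a1 + a2 + a3) {      /* desorption */
            int id = cs_pick(&cs, SET_BOUND);
            cs_move(&cs, id, SET_HELIX);
            M += 1.0;
        } else {                            /* in-complex ring opening */
            int id = cs_pick(&cs, SET_BOUND);
            dp[id]++;
            cs_move(&cs, id, SET_HELIX);
        }
    }
    PutRNGstate();

    SEXP out = PROTECT(allocVector(VECSXP, 6));
    SEXP nms = PROTECT(allocVector(STRSXP, 6));
    SET_VECTOR_ELT(out, 0, conv_ring);
    SET_VECTOR_ELT(out, 1, conv_free);
    SET_VECTOR_ELT(out, 2, dp_out);
    SET_VECTOR_ELT(out, 3, ScalarReal(M));
    SET_VECTOR_ELT(out, 4, ScalarReal((double) cs.size[SET_BOUND]));
    SET_VECTOR_ELT(out, 5, ScalarReal(n_events));
    SET_STRING_ELT(nms, 0, mkChar("conv_ring"));
    SET_STRING_ELT(nms, 1, mkChar("conv_free"));
    SET_STRING_ELT(nms, 2, mkChar("dp"));
    SET_STRING_ELT(nms, 3, mkChar("monomer_count"));
    SET_STRING_ELT(nms, 4, mkChar("bound_count"));
    SET_STRING_ELT(nms, 5, mkChar("n_events"));
    setAttrib(out, R_NamesSymbol, nms);
    UNPROTECT(5);
    return out;
}
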