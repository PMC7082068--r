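/* Generic mass-action ODE right-hand side for deSolve's compiled-model
 * interface. The reaction network is encoded once per integration context
 * from R (ptl_set_network); rate constants arrive through deSolve's parms
 * mechanism (ptl_initparms) so the same tables serve every parameter
 * vector visited by the sampler. Supports propagating n_exp independent
 * replicas of the system in one call (stacked multi-experiment
 * likelihoods); the state layout matches R's column-major
 * matrix(y, n_exp, n_sp): y[e + i * n_exp] is species i in replica e.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define PTL_MAX_RXN 1024
#define PTL_MAX_FACT 4096
#define PTL_MAX_TRIP 8192

static int n_sp, n_exp, n_rxn, n_fact, n_trip;
static int fact_sp[PTL_MAX_FACT];   /* species index per factor (0-based) */
static int fact_ex[PTL_MAX_FACT];   /* exponent per factor */
static int fact_off[PTL_MAX_RXN + 1]; /* factor offsets per reaction */
static int trip_sp[PTL_MAX_TRIP];   /* stoichiometry triplets: species, */
static int trip_rx[PTL_MAX_TRIP];   /* reaction, coefficient */
static double trip_coef[PTL_MAX_TRIP];
static double kpar[PTL_MAX_RXN];

void ptl_set_network(int *dims, int *fsp, int *fex, int *foff,
                     int *tsp, int *trx, double *tcoef)
{
    int j;
    n_sp = dims[0];
    n_exp = dims[1];
    n_rxn = dims[2];
    n_fact = dims[3];
    n_trip = dims[4];
    if (n_rxn > PTL_MAX_RXN || n_fact > PTL_MAX_FACT ||
        n_trip > PTL_MAX_TRIP)
        error("reaction network exceeds compiled table capacity");
    for (j = 0; j < n_fact; j++) {
        fact_sp[j] = fsp[j];
        fact_ex[j] = fex[j];
    }
    for (j = 0; j <= n_rxn; j++)
        fact_off[j] = foff[j];
    for (j = 0; j < n_trip; j++) {
        trip_sp[j] = tsp[j];
        trip_rx[j] = trx[j];
        trip_coef[j] = tcoef[j];
    }
}

void ptl_initparms(void (*odeparms)(int *, double *))
{
    int n = n_rxn;
    odeparms(&n, kpar);
}

void ptl_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    int e, j, f;
    double rates[PTL_MAX_RXN];
    for (j = 0; j < *neq; j++)
        ydot[j] = 0.0;
    for (e = 0; e < n_exp; e++) {
        for (j = 0; j < n_rxn; j++) {
            double r = kpar[j];
            for (f = fact_off[j]; f < fact_off[j + 1]; f++) {
                double x = y[e + fact_sp[f] * n_exp];
                if (x < 0.0) x = 0.0;
                if (fact_ex[f] == 1) {
                    r *= x;
                } else {
                    int p;
                    for (p = 0; p < fact_ex[f]; p++)
                        r *= x;
                }
            }
            rates[j] = r;
        }
        for (j = 0; j < n_trip; j++)
            ydot[e + trip_sp[j] * n_exp] += trip_coef[j] * rates[trip_rx[j]];
    }
}

static const R_CMethodDef c_entries[] = {
    {"ptl_set_network", (DL_FUNC) &ptl_set_network, 7},
    {NULL, NULL, 0}
};

void R_init_ptlasso(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
    R_RegisterCCallable("ptlasso", "ptl_derivs", (DL_FUNC) &ptl_derivs);
}
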