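/* Compiled mass-action right-hand side for deSolve.
 *
 * The parameter block is laid out by the R side as
 *   [n_r, n_s, k[n_r], Sre[n_r x n_s], Snet[n_r x n_s], padding...]
 * row-major by reaction. Sre holds reactant stoichiometries (rate-law
 * exponents), Snet the net stoichiometry. The block is padded to a fixed
 * length because deSolve initialisers copy a compile-time number of
 * doubles.
 */

#include <R.h>
#include <math.h>

#define DOPSR_MAXPAR 4096

static double parms[DOPSR_MAXPAR];

void dopsr_initmod(void (*odeparms)(int *, double *))
{
    int n = DOPSR_MAXPAR;
    odeparms(&n, parms);
}

void dopsr_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    int nr = (int) parms[0];
    int ns = (int) parms[1];
    const double *k = parms + 2;
    const double *sre = parms + 2 + nr;
    const double *snet = parms + 2 + nr + (long) nr * ns;

    for (int s = 0; s < ns; s++)
        ydot[s] = 0.0;

    for (int j = 0; j < nr; j++) {
        double rate = k[j];
        const double *re = sre + (long) j * ns;
        const double *ne = snet + (long) j * ns;
        for (int s = 0; s < ns; s++) {
            double m = re[s];
            if (m != 0.0) {
                /* guard tiny negative excursions from the integrator */
                double x = y[s] > 0.0 ? y[s] : 0.0;
                if (m == 1.0)
                    rate *= x;
                else if (m == 2.0)
                    rate *= x * x;
                else
                    rate *= pow(x, m);
            }
        }
        if (rate != 0.0)
            for (int s = 0; s < ns; s++)
                if (ne[s] != 0.0)
                    ydot[s] += ne[s] * rate;
    }
}
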