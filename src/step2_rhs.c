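/* Plug-flow amidation kinetics for the deSolve compiled-code interface.
 *
 * State vector (mol/L):
 *   y[0] 4-aminophenol, y[1] acetic anhydride, y[2] acetaminophen,
 *   y[3] 4'-acetoxyacetanilide, y[4] water, y[5] acetic acid.
 * Parameters: k2 (amidation), kh (anhydride hydrolysis), kda (double
 * acylation), all L mol^-1 min^-1.  Time variable is residence time in min.
 */
#include <R.h>

static double parms[3];
#define k2  parms[0]
#define kh  parms[1]
#define kda parms[2]

void step2_init(void (*odeparms)(int *, double *))
{
    int n = 3;
    odeparms(&n, parms);
}

void step2_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double r2  = k2  * y[0] * y[1];
    double rh  = kh  * y[1] * y[4];
    double rda = kda * y[2] * y[1];

    ydot[0] = -r2;
    ydot[1] = -r2 - rh - rda;
    ydot[2] =  r2 - rda;
    ydot[3] =  rda;
    ydot[4] = -rh;
    ydot[5] =  r2 + 2.0 * rh + rda;
}
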