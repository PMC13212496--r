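/* Three-compartment CAR-T cytotoxicity model: compiled right-hand side
 * for deSolve.  States are stacked triples (T, CART, TC); several systems
 * sharing one parameter set may be integrated together (neq = 3 * nsys),
 * which lets one solver call cover all E:T ratios of an assay.
 *
 * Parameter vector (via initfunc):
 *   0 kp1   tumor proliferation rate, 1/h
 *   1 CT    tumor carrying capacity, cells
 *   2 kc    saturated cytolytic rate, 1/h
 *   3 Kmr   cytolysis half-saturation ratio (CART/T), unitless
 *   4 n     ratio exponent (cooperativity), unitless
 *   5 kp2   cytolysis-driven effector proliferation rate, 1/h
 *   6 Kmp   proliferation half-saturation, cells/h
 *   7 CE    effector carrying capacity, cells
 *   8 kd    basal effector death rate, 1/h
 *   9 gomp_invert  0: g = ln(CE/N) (standard); 1: g = ln(N/CE)
 *  10 legacy       0: ratio-dependent Hill model; 1: mass-action variant
 */
#include <R.h>
#include <math.h>

static double p[11];

void cartkin_init(void (*odeparms)(int *, double *))
{
    int N = 11;
    odeparms(&N, p);
}

void cartkin_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    const double kp1 = p[0], CT = p[1], kc = p[2], Kmr = p[3], n = p[4];
    const double kp2 = p[5], Kmp = p[6], CE = p[7], kd = p[8];
    const int invert = p[9] > 0.5, legacy = p[10] > 0.5;
    int nsys = *neq / 3, i;

    for (i = 0; i < nsys; i++) {
        /* rates are evaluated on states clipped at zero */
        double T  = y[3 * i]     > 0.0 ? y[3 * i]     : 0.0;
        double CA = y[3 * i + 1] > 0.0 ? y[3 * i + 1] : 0.0;
        double TC = y[3 * i + 2] > 0.0 ? y[3 * i + 2] : 0.0;
        double FC, dCA;

        if (legacy) {
            FC  = kc * CA * T;
            dCA = kp2 * CA * T - kd * CA;
        } else {
            if (T > 0.0 && CA > 0.0) {
                /* Hill fraction written as 1/(1 + (Kmr/r)^n) so large
                 * ratios saturate at 1 without overflow */
                double r = CA / T;
                double q = pow(Kmr / r, n);
                FC = kc * T / (1.0 + q);
            } else if (T > 0.0 && n == 0.0) {
                FC = 0.5 * kc * T;      /* n = 0: flat half-rate */
            } else {
                FC = 0.0;               /* continuity at T = 0 or CART = 0 */
            }
            {
                double f2 = FC * FC;
                double FP = kp2 * f2 / (Kmp * Kmp + f2) * CA;
                double N  = CA + TC;
                double g;
                if (N < 1.0) N = 1.0;   /* cap the Gompertz singularity */
                g = invert ? log(N / CE) : log(CE / N);
                dCA = FP * g - kd * CA;
            }
        }
        ydot[3 * i]     = kp1 * T * (1.0 - T / CT) - FC;
        ydot[3 * i + 1] = dCA;
        ydot[3 * i + 2] = -kd * TC;
    }
}
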