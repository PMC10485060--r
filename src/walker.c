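/* Equations of motion of the powered simple walking model, in the form
 * used by deSolve's compiled-model interface.
 *
 * State y = (theta, phi, theta_dot, phi_dot); parameters p = (beta, k).
 * The 2x2 mass matrix is inverted in closed form; its determinant
 * beta*(1+beta) - beta^2*cos^2(theta+phi) is positive for beta > 0.
 */
#include <R.h>
#include <math.h>

static double parms[2];
#define BETA parms[0]
#define KSPR parms[1]

void walker_initmod(void (*odeparms)(int *, double *))
{
    int n = 2;
    odeparms(&n, parms);
}

void walker_rhs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double th = y[0], ph = y[1], thd = y[2], phd = y[3];
    double c = cos(th + ph), s = sin(th + ph);
    double det = BETA * (1.0 + BETA) - BETA * BETA * c * c;
    /* right-hand side of M qdd = b (Coriolis, gravity and spring terms) */
    double b1 = BETA * s * phd * phd + (1.0 + BETA) * sin(th);
    double b2 = BETA * s * thd * thd - BETA * sin(ph) - KSPR * ph;

    ydot[0] = thd;
    ydot[1] = phd;
    ydot[2] = (BETA * b1 - BETA * c * b2) / det;
    ydot[3] = ((1.0 + BETA) * b2 - BETA * c * b1) / det;
}

/* Collision condition theta - phi = 0 (Eq. of the ground-contact surface). */
void walker_root_coll(int *neq, double *t, double *y, int *ng,
                      double *gout, double *out, int *ip)
{
    gout[0] = y[0] - y[1];
}

/* Mid-step symmetry section theta = 0. */
void walker_root_mid(int *neq, double *t, double *y, int *ng,
                     double *gout, double *out, int *ip)
{
    gout[0] = y[0];
}
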