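/* Compiled right-hand side of the fractional-killing model for deSolve.
 *
 * State vector (8):
 *   y[0] BaxmT   total mitochondrial BAX (monomer + BAXm:BCL dimer)
 *   y[1] BaxmBcl BAXm:BCL dimer
 *   y[2] Bh3Bcl  BH3:BCL dimer
 *   y[3] Bh3T    total BH3
 *   y[4] Caspase8
 *   y[5] cIAP
 *   y[6] p53     activity ratio
 *   y[7] Mdm2    activity ratio
 *
 * The parameter block (36 doubles, order fixed by .fk_par_order in R)
 * includes the two protocol-resolved drug inputs so that one phase of a
 * treatment protocol is a single autonomous system.  The R implementation
 * in R/model_core.R is the reference; the two are asserted equal in the
 * test suite.
 */

#include <R.h>
#include <math.h>

static double p[36];

#define kf1       p[0]
#define kf2       p[1]
#define kb        p[2]
#define kasXC     p[3]
#define kdsXC     p[4]
#define kasHC     p[5]
#define kdsHC     p[6]
#define ksBh3     p[7]
#define ks2       p[8]
#define ks3       p[9]
#define kdBh3     p[10]
#define kaC8      p[11]
#define kiC8      p[12]
#define ki2       p[13]
#define ksIAP     p[14]
#define ksIAP2    p[15]
#define kdIAP     p[16]
#define Jhill     p[17]
#define nhill     p[18]
#define R0_p53    p[19]
#define Rp53_p53  p[20]
#define RMdm2_p53 p[21]
#define R0_Mdm2   p[22]
#define Rp53_Mdm2 p[23]
#define sigma     p[24]
#define sigma2    p[25]
#define sigma_drug p[26]
#define tsp53     p[27]
#define tsMdm2    p[28]
#define R_drug    p[29]
#define BaxT      p[30]
#define BclT      p[31]
#define mode_literal p[32]
#define clamp_f   p[33]
#define drug_ciap p[34]
#define drug_mdm2 p[35]

/* overflow-safe logistic */
static double sig(double x)
{
    if (x >= 0.0)
        return 1.0 / (1.0 + exp(-x));
    double e = exp(x);
    return e / (1.0 + e);
}

void fk_initmod(void (*odeparms)(int *, double *))
{
    int n = 36;
    odeparms(&n, p);
}

void fk_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double BaxmT = y[0], BaxmBcl = y[1], Bh3Bcl = y[2], Bh3T = y[3],
           C8 = y[4], cIAP = y[5], p53 = y[6], Mdm2 = y[7];

    /* conserved free species */
    double Bax  = BaxT - BaxmT;
    double Baxm = BaxmT - BaxmBcl;
    double Bh3  = Bh3T - Bh3Bcl;
    double Bcl  = BclT - BaxmBcl - Bh3Bcl;

    /* apoptosis initiation (mass action) */
    ydot[0] = (kf1 + kf2 * Bh3) * Bax - kb * BaxmT;
    ydot[1] = kasXC * Baxm * Bcl - kdsXC * BaxmBcl - kb * BaxmBcl;
    ydot[2] = kasHC * Bh3 * Bcl - kdsHC * Bh3Bcl;
    ydot[3] = ksBh3 + ks2 * p53 + ks3 * C8 - kdBh3 * Bh3T;
    ydot[4] = kaC8 - (kiC8 + ki2 * cIAP) * C8;

    /* drug-induced CIAP accumulation (Hill) */
    double dn = pow(drug_ciap, nhill);
    double hill = (drug_ciap > 0.0) ? dn / (dn + pow(Jhill, nhill)) : 0.0;
    ydot[5] = ksIAP + ksIAP2 * hill - kdIAP * cIAP;

    /* p53 / Mdm2 generic formula */
    double wp53  = R0_p53 + Rp53_p53 * p53 + RMdm2_p53 * Mdm2;
    double wMdm2 = R0_Mdm2 + Rp53_Mdm2 * p53;
    double fp53  = sig(sigma * wp53);
    double s     = (mode_literal > 0.5) ? 1.0 : -1.0;
    double dterm = sig(s * sigma_drug * R_drug * drug_mdm2);
    double fMdm2 = sig(sigma2 * wMdm2) + dterm;
    if (clamp_f > 0.5) {
        if (fMdm2 > 1.0) fMdm2 = 1.0;
        if (fMdm2 < 0.0) fMdm2 = 0.0;
    }
    ydot[6] = tsp53 * (fp53 - p53);
    ydot[7] = tsMdm2 * (fMdm2 - Mdm2);

    if (ip[0] >= 4) {
        yout[0] = Bax;
        yout[1] = Baxm;
        yout[2] = Bh3;
        yout[3] = Bcl;
    }
}
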