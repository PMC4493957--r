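#include <R.h>

/* Two-branch osmostress benchmark model.
 *
 * States (8):
 *   y[0] P    active (phosphorylated) Pbs2 pool of the Sln1 route, fraction
 *   y[1] C    Sho1.Pbs2 complex, fraction
 *   y[2] CP   phosphorylated Sho1.Pbs2 complex, fraction
 *   y[3] H    unphosphorylated Hog1, percent of total WT Hog1
 *   y[4] HPP  phosphorylated Hog1 (Hog1PP), percent
 *   y[5] M    stress mRNA, ratio units
 *   y[6] PR   stress protein, ratio units
 *   y[7] G    internal glycerol, ratio units
 *
 * Parameter vector: 16 kinetic constants followed by the 3 condition inputs
 * (Sln1 branch flag, Sho1 branch flag, NaCl dose in M).  The osmotic signal
 * is the dose attenuated by accumulated glycerol (adaptation); glycerol is
 * produced through the slow transcriptional route (M -> PR -> G) and, in the
 * true structure only, through a direct Hog1PP-dependent term (K_GFB).  The
 * direct term is cooperative (quadratic in the Hog1PP fraction), so the two
 * glycerol routes scale differently with pathway activation and the
 * simplified structure cannot mimic the true one by rescaling the slow
 * route alone.
 */

static double p[19];

#define A_SLN    p[0]   /* Sln1-route activation, 1/(min*M)            */
#define D_SLN    p[1]   /* Sln1-route deactivation, 1/min              */
#define A_SHO    p[2]   /* Sho1.Pbs2 complex formation, 1/(min*M)      */
#define D_SHO    p[3]   /* complex dissociation, 1/min                 */
#define P_SHO    p[4]   /* complex phosphorylation, 1/min              */
#define Q_SHO    p[5]   /* complex dephosphorylation, 1/min            */
#define K_PH_SLN p[6]   /* Hog1 phosphorylation by P, 1/min            */
#define K_PH_SHO p[7]   /* Hog1 phosphorylation by CP, 1/min           */
#define K_DEPH   p[8]   /* Hog1PP dephosphorylation, 1/min             */
#define K_TX     p[9]   /* mRNA synthesis per Hog1PP fraction, 1/min   */
#define K_MDEG   p[10]  /* mRNA degradation, 1/min                     */
#define K_TL     p[11]  /* protein synthesis, 1/min                    */
#define K_PDEG   p[12]  /* protein degradation, 1/min                  */
#define K_GP     p[13]  /* glycerol production by protein, 1/min       */
#define K_GFB    p[14]  /* glycerol production by Hog1PP (removable)   */
#define K_I      p[15]  /* glycerol level halving the osmotic signal   */
#define SLN1_ON  p[16]
#define SHO1_ON  p[17]
#define DOSE     p[18]

void hog_init(void (*odeparms)(int *, double *))
{
    int n = 19;
    odeparms(&n, p);
}

void hog_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double P = y[0], C = y[1], CP = y[2], H = y[3], HPP = y[4];
    double M = y[5], PR = y[6], G = y[7];

    double rel  = G / K_I;
    double sig  = DOSE / (1.0 + rel * rel);
    double phos = K_PH_SLN * P + K_PH_SHO * CP;

    ydot[0] = SLN1_ON * A_SLN * sig * (1.0 - P) - D_SLN * P;
    ydot[1] = SHO1_ON * A_SHO * sig * (1.0 - C - CP) - (D_SHO + P_SHO) * C;
    ydot[2] = P_SHO * C - Q_SHO * CP;
    ydot[3] = -phos * H + K_DEPH * HPP;   /* H + HPP conserved exactly */
    ydot[4] =  phos * H - K_DEPH * HPP;
    ydot[5] = K_TX * HPP / 100.0 - K_MDEG * M;
    ydot[6] = K_TL * M - K_PDEG * PR;
    {
        double hf = HPP / 100.0;
        ydot[7] = K_GP * PR + K_GFB * hf * hf;
    }
}
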