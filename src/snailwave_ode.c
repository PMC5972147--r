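/* Crosstalk network ODE right-hand side.
 *
 * State vector (13):
 *   0 S   nuclear pSMAD2/3-SMAD4 complex
 *   1 I   inhibitory SMAD
 *   2 sm  SNAIL1 mRNA
 *   3 sp  SNAIL1 protein (nuclear)
 *   4 gm  GLI1 mRNA
 *   5 gb  cytosolic SUFU-bound (inactive) GLI1
 *   6 gf  cytosolic free GLI1
 *   7 gn  nuclear GLI1
 *   8 A   GSK3, unphosphorylated active
 *   9 AA  GSK3, tyrosine-phosphorylated extra-active (ER/Golgi)
 *  10 D   GSK3, serine-phosphorylated inactive
 *  11 Rf  fast receptor/ligand pool (rapid on, clears within hours)
 *  12 Rs  slow receptor pool (charges and discharges over tens of hours)
 *
 * A + AA + D is conserved exactly: dA is defined as -(dAA + dD).
 *
 * The stimulus u and the three inhibitor multipliers (f_smad, f_gli, f_gsk)
 * are piecewise constant; the R wrapper integrates segment by segment and
 * passes them as trailing entries of the parameter vector, so the system
 * seen by the integrator is autonomous.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

#define N_PARMS 54
#define N_STATE 13

static double parms[N_PARMS];

void sw_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

static double hill(double x, double K, double n)
{
    double xn, Kn;
    if (x <= 0.0) return 0.0;
    xn = pow(x, n);
    Kn = pow(K, n);
    return xn / (Kn + xn);
}

static double hillrep(double x, double K, double n)
{
    double xn, Kn;
    if (x <= 0.0) return 1.0;
    xn = pow(x, n);
    Kn = pow(K, n);
    return Kn / (Kn + xn);
}

static void sw_rhs(const double *p, const double *y, double *ydot)
{
    /* parameter unpacking: order must match sw_param_order() in R/params.R */
    double b_smad = p[0], k_smad = p[1], K_r = p[2], n_r = p[3];
    double K_i = p[4], d_smad = p[5];
    double b_ismad = p[6], k_ismad = p[7], K_si = p[8], d_ismad = p[9];
    double b_snm = p[10], a_snm_s = p[11], K_snm_s = p[12];
    double a_snm_g = p[13], K_snm_g = p[14], d_snm = p[15];
    double k_snp = p[16], d_snp = p[17], kg_snp = p[18];
    double b_glm = p[19], a_glm_s = p[20], K_glm_s = p[21];
    double a_glm_g = p[22], K_glm_g = p[23], d_glm = p[24];
    double k_glb = p[25], d_glc = p[26], kg_glc = p[27];
    double r_rel0 = p[28], k_rel = p[29], k_imp = p[30];
    double d_gln = p[31], kg_gln = p[32];
    double k_on = p[33], k_off = p[34];
    double k_s_on = p[35], k_s_off = p[36], w_s = p[37];
    double k_aa_u = p[38], k_aa_r = p[39];
    double k_d_u = p[40], K_ds = p[41], k_d_r = p[42];
    double frac_aa0 = p[43], frac_d0 = p[44];
    double n_h = p[45], m_nuc = p[46], m_cyt = p[47];
    double glm_scale = p[48], ismad_scale = p[49];
    double u = p[50], f_smad = p[51], f_gli = p[52], f_gsk = p[53];

    double S = y[0], I = y[1], sm = y[2], sp = y[3];
    double gm = y[4], gb = y[5], gf = y[6], gn = y[7];
    double A = y[8], AA = y[9], D = y[10];
    double Rf = y[11], Rs = y[12];

    double A0 = 1.0 - frac_aa0 - frac_d0;
    double k_aa_b = k_aa_r * frac_aa0 / A0;
    double k_d_b = k_d_r * frac_d0 / A0;

    double pool = Rf + w_s * Rs;
    double drive = f_smad * (b_smad + k_smad * hill(pool, K_r, n_r));
    double gli_sn = f_gli * hill(gn, K_snm_g, n_h);
    double gli_gm = f_gli * hill(gn, K_glm_g, n_h);
    double rel = (r_rel0 + k_rel * m_cyt * f_gsk * AA) * gb;
    double dc = d_glc * (1.0 + kg_glc * m_cyt * f_gsk * A);
    /* tyrosine phosphorylation (A -> AA) tracks the raw stimulus (fast
     * arm at the ER/Golgi); inhibitory serine phosphorylation (A -> D)
     * is driven downstream of pSMAD, which delays its rise to ~12 h */
    double Jaa = (k_aa_b + k_aa_u * u) * A - k_aa_r * AA;
    double Jd = (k_d_b + k_d_u * hill(S, K_ds, n_h)) * A - k_d_r * D;

    ydot[0] = drive * hillrep(I, K_i, n_h) - d_smad * S;
    ydot[1] = ismad_scale * (b_ismad + k_ismad * hill(S, K_si, n_h))
        - d_ismad * I;
    ydot[2] = b_snm + a_snm_s * hill(S, K_snm_s, n_h) + a_snm_g * gli_sn
        - d_snm * sm;
    ydot[3] = k_snp * sm
        - d_snp * (1.0 + kg_snp * m_nuc * f_gsk * A) * sp;
    /* glm_scale models constitutive GLI1 up-regulation: it scales the
     * ligand-independent transcription term only */
    ydot[4] = glm_scale * b_glm + a_glm_s * hill(S, K_glm_s, n_h)
        + a_glm_g * gli_gm - d_glm * gm;
    ydot[5] = k_glb * gm - rel - dc * gb;
    ydot[6] = rel - k_imp * gf - dc * gf;
    ydot[7] = k_imp * gf
        - d_gln * (1.0 + kg_gln * m_nuc * f_gsk * A) * gn;
    ydot[8] = -(Jaa + Jd);
    ydot[9] = Jaa;
    ydot[10] = Jd;
    ydot[11] = k_on * u * (1.0 - Rf) - k_off * Rf;
    ydot[12] = k_s_on * u * (1.0 - Rs) - k_s_off * Rs;
}

/* deSolve entry point */
void sw_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    sw_rhs(parms, y, ydot);
}

/* direct evaluator for tests, fixed-point polishing and oracles */
SEXP sw_rhs_call(SEXP t, SEXP y, SEXP p)
{
    SEXP out;
    double *op;
    if (LENGTH(y) != N_STATE)
        error("state vector must have length %d", N_STATE);
    if (LENGTH(p) != N_PARMS)
        error("parameter vector must have length %d", N_PARMS);
    out = PROTECT(allocVector(REALSXP, N_STATE));
    op = REAL(out);
    sw_rhs(REAL(p), REAL(y), op);
    UNPROTECT(1);
    return out;
}
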