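/* Compiled right-hand sides for the UPR models (deSolve convention).
 *
 * Each model has an init function receiving its parameter vector and a
 * derivative function. The parameter layouts are fixed and mirrored on the
 * R side (upr_c_layout_*); the rate expressions replicate the generic
 * rate-law interpreter exactly, including the non-negativity guards.
 */

#include <R.h>
#include <math.h>

static double fmax0(double x) { return x > 0 ? x : 0; }

/* total-QSSA Michaelis-Menten product rate */
static double tqssa(double kc, double Km, double St, double Et)
{
    double s = St + Et + Km;
    double disc = s * s - 4.0 * St * Et;
    if (disc < 0) disc = 0;
    return 0.5 * kc * (s - sqrt(disc));
}

/* one competitive-regulation activator term accumulator */
typedef struct { double num, den; } regacc;
static void reg_add(regacc *a, double conc, double kc, double Km)
{
    double w = fmax0(conc) / Km;
    a->num += kc * w;
    a->den += w;
}
static double reg_rate(const regacc *a) { return a->num / a->den; }

/* ------------------------------------------------------------------ */
/* full integrated model: 27 species, 84 parameters (82 + extIREp,
 * variant flag: 0 standard, 1 direct_ufp, 2 ufp_stabilised)           */

#define N_FULL_PAR 84
static double pfull[N_FULL_PAR];

void upr_init_full(void (*odeparms)(int *, double *))
{
    int n = N_FULL_PAR;
    odeparms(&n, pfull);
}

/* parameter indices: order of upr_reference_params() */
enum {
    i_mUFPT, i_kdUFP, i_kdBUFP, i_kfB, i_krbUFP, i_kdBiP,
    i_krbIRE1, i_kfIRE1, i_krIRE1, i_nIRE1, i_vsR, i_kdR,
    i_krbPERK, i_kfPERK, i_krPERK, i_nPERK,
    i_krbATF6, i_kdwATF6, i_ktrATF6, i_kcleave, i_kdATF6g, i_kdATF6p50,
    i_kc0WFS1, i_kcA6WFS1, i_KmA6WFS1, i_kdWFS1,
    i_kc0XBP1, i_kcA6XBP1, i_KmA6XBP1, i_extXBP, i_kdmRNA,
    i_kcspl, i_Kmspl, i_ncat, i_kdmXBP1s, i_ktlXBP1, i_kdXBP1s,
    i_kc0BiP, i_kcXsBiP, i_KmXsBiP, i_kcA6BiP, i_KmA6BiP, i_extBiP,
    i_ktlBiP,
    i_kphos, i_Kmphos, i_kmChop, i_kdephos, i_Kmdephos, i_CReP, i_eIF2aT,
    i_ksATF4, i_kATF4, i_nh, i_kdATF4,
    i_kc0CHOP, i_kcA4CHOP, i_kmAtff, i_kcA6CHOP, i_KmA6CHOP,
    i_kcXsCHOP, i_KmXsCHOP, i_extCHOP, i_ktlCHOP, i_kdCHOP,
    i_kcChopG, i_KmChopG, i_ktlG, i_kdG,
    i_ksBH3, i_kcBH3, i_KmBH3, i_kdBH3, i_BAXT,
    i_kactBAX, i_kautoBAX, i_JBAX, i_krevBAX, i_kbclBAX,
    i_Bcl2T, i_KbclCHOP, i_hbcl,
    i_extIREp, i_vflag
};

/* species indices: canonical assembly order */
enum {
    s_UFP, s_BiP, s_BUFP,
    s_IRE1, s_BIRE1, s_IRE1a,
    s_PERK, s_BPERK, s_PERKa,
    s_ATF6, s_BATF6, s_ATF6g, s_ATF6p50, s_WFS1,
    s_mXBP1, s_mXBP1s, s_XBP1s, s_mBiP,
    s_eIF2a, s_eIF2aP, s_ATF4, s_mCHOP, s_CHOP, s_mGADD34, s_GADD34,
    s_BH3, s_BAXa
};

void upr_deriv_full(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    const double *p = pfull;
    int i;
    int vflag = (int) (p[i_vflag] + 0.5);
    for (i = 0; i < *neq; i++) ydot[i] = 0.0;

    /* core stress */
    double v_influx = p[i_mUFPT];
    double v_bu_on  = p[i_kfB] * y[s_BiP] * y[s_UFP];
    double v_bu_off = p[i_krbUFP] * y[s_BUFP];
    double v_ufp_d  = p[i_kdUFP] * y[s_UFP];
    double v_bufp_d = p[i_kdBUFP] * y[s_BUFP];
    double v_bip_d  = p[i_kdBiP] * y[s_BiP];

    ydot[s_UFP]  += v_influx - v_bu_on + v_bu_off - v_ufp_d;
    ydot[s_BiP]  += -v_bu_on + v_bu_off - v_bip_d;
    ydot[s_BUFP] += v_bu_on - v_bu_off - v_bufp_d;

    /* IRE1alpha receptor (stoichiometry nIRE1) */
    {
        double R = y[s_IRE1], BR = y[s_BIRE1], RA = y[s_IRE1a];
        double nI = p[i_nIRE1];
        double vact = p[i_kfIRE1] * pow(fmax0(R), nI);
        if (vflag == 1) vact *= y[s_UFP];
        double vdeact = p[i_krIRE1] * RA;
        if (vflag == 2) vdeact /= (1.0 + p[i_extIREp] * y[s_UFP]);
        double von  = p[i_kfB] * y[s_BiP] * R;
        double voff = p[i_krbIRE1] * BR;
        double vsyn = p[i_vsR], vdeg = p[i_kdR] * R;
        double vadeg = p[i_kdR] * RA, vbdeg = p[i_kdR] * BR;
        ydot[s_IRE1]  += -von + voff - nI * vact + nI * vdeact + vsyn - vdeg;
        ydot[s_BIRE1] += von - voff - vbdeg;
        ydot[s_IRE1a] += vact - vdeact - vadeg;
        ydot[s_BiP]   += -von + voff + vbdeg;
    }

    /* PERK receptor (stoichiometry nPERK) */
    {
        double R = y[s_PERK], BR = y[s_BPERK], RA = y[s_PERKa];
        double nP = p[i_nPERK];
        double vact = p[i_kfPERK] * pow(fmax0(R), nP);
        if (vflag == 1) vact *= y[s_UFP];
        double vdeact = p[i_krPERK] * RA;
        if (vflag == 2) vdeact /= (1.0 + p[i_extIREp] * y[s_UFP]);
        double von  = p[i_kfB] * y[s_BiP] * R;
        double voff = p[i_krbPERK] * BR;
        double vsyn = p[i_vsR], vdeg = p[i_kdR] * R;
        double vadeg = p[i_kdR] * RA, vbdeg = p[i_kdR] * BR;
        ydot[s_PERK]  += -von + voff - nP * vact + nP * vdeact + vsyn - vdeg;
        ydot[s_BPERK] += von - voff - vbdeg;
        ydot[s_PERKa] += vact - vdeact - vadeg;
        ydot[s_BiP]   += -von + voff + vbdeg;
    }

    /* ATF6 branch */
    {
        double A = y[s_ATF6], BA = y[s_BATF6], G = y[s_ATF6g];
        double P50 = y[s_ATF6p50], W = y[s_WFS1];
        double von  = p[i_kfB] * y[s_BiP] * A;
        double voff = p[i_krbATF6] * BA;
        double vsyn = p[i_vsR], vdeg = p[i_kdR] * A;
        double vwdeg = p[i_kdwATF6] * W * A;
        double vtr = p[i_ktrATF6] * A;
        double vcl = p[i_kcleave] * G;
        double vgd = p[i_kdATF6g] * G;
        double vpd = p[i_kdATF6p50] * P50;
        regacc w = {0.0, 1.0};
        reg_add(&w, 1.0, p[i_kc0WFS1], 1.0);
        reg_add(&w, P50, p[i_kcA6WFS1], p[i_KmA6WFS1]);
        double vws = reg_rate(&w);
        double vwd = p[i_kdWFS1] * W;
        double vbdeg = p[i_kdR] * BA;
        ydot[s_ATF6]    += -von + voff + vsyn - vdeg - vwdeg - vtr;
        ydot[s_BATF6]   += von - voff - vbdeg;
        ydot[s_ATF6g]   += vtr - vcl - vgd;
        ydot[s_ATF6p50] += vcl - vpd;
        ydot[s_WFS1]    += vws - vwd;
        ydot[s_BiP]     += -von + voff + vbdeg;
    }

    /* XBP1 / BiP genetics */
    {
        double P50 = y[s_ATF6p50];
        regacc rx = {0.0, 1.0};
        reg_add(&rx, 1.0, p[i_kc0XBP1], 1.0);
        reg_add(&rx, P50, p[i_kcA6XBP1], p[i_KmA6XBP1]);
        reg_add(&rx, p[i_extXBP], p[i_kcA6XBP1], p[i_KmA6XBP1]);
        double v_mx_s = reg_rate(&rx);
        double v_mx_d = p[i_kdmRNA] * y[s_mXBP1];
        double v_spl = tqssa(p[i_kcspl], p[i_Kmspl], fmax0(y[s_mXBP1]),
                             fmax0(p[i_ncat] * y[s_IRE1a]));
        double v_mxs_d = p[i_kdmXBP1s] * y[s_mXBP1s];
        double v_xs_tl = p[i_ktlXBP1] * y[s_mXBP1s];
        double v_xs_d = p[i_kdXBP1s] * y[s_XBP1s];
        regacc rb = {0.0, 1.0};
        reg_add(&rb, 1.0, p[i_kc0BiP], 1.0);
        reg_add(&rb, y[s_XBP1s], p[i_kcXsBiP], p[i_KmXsBiP]);
        reg_add(&rb, P50, p[i_kcA6BiP], p[i_KmA6BiP]);
        reg_add(&rb, p[i_extBiP], p[i_kcXsBiP], p[i_KmXsBiP]);
        double v_mb_s = reg_rate(&rb);
        double v_mb_d = p[i_kdmRNA] * y[s_mBiP];
        double v_b_tl = p[i_ktlBiP] * y[s_mBiP];
        ydot[s_mXBP1]  += v_mx_s - v_mx_d - v_spl;
        ydot[s_mXBP1s] += v_spl - v_mxs_d;
        ydot[s_XBP1s]  += v_xs_tl - v_xs_d;
        ydot[s_mBiP]   += v_mb_s - v_mb_d;
        ydot[s_BiP]    += v_b_tl;
    }

    /* PERK genetics / translation attenuation */
    {
        double PERKA = p[i_nPERK] * y[s_PERKa];
        double e = fmax0(y[s_eIF2a]), ep = fmax0(y[s_eIF2aP]);
        double vph = p[i_kphos] * PERKA * e / (p[i_Kmphos] + e) /
            (1.0 + fmax0(y[s_CHOP]) / p[i_kmChop]);
        double vdg = p[i_kdephos] * y[s_GADD34] * ep / (p[i_Kmdephos] + ep);
        double vdc = p[i_kdephos] * p[i_CReP] * ep / (p[i_Kmdephos] + ep);
        double r = pow(fmax0(y[s_eIF2a]) / p[i_kATF4], p[i_nh]);
        double v_a4 = p[i_ksATF4] / (1.0 + r);
        double v_a4d = p[i_kdATF4] * y[s_ATF4];
        regacc rc = {0.0, 1.0};
        reg_add(&rc, 1.0, p[i_kc0CHOP], 1.0);
        reg_add(&rc, y[s_ATF4], p[i_kcA4CHOP], p[i_kmAtff]);
        reg_add(&rc, y[s_ATF6p50], p[i_kcA6CHOP], p[i_KmA6CHOP]);
        reg_add(&rc, y[s_XBP1s], p[i_kcXsCHOP], p[i_KmXsCHOP]);
        reg_add(&rc, p[i_extCHOP], p[i_kcA6CHOP], p[i_KmA6CHOP]);
        double v_mc_s = reg_rate(&rc);
        double v_mc_d = p[i_kdmRNA] * y[s_mCHOP];
        double v_c_tl = p[i_ktlCHOP] * y[s_mCHOP];
        double v_c_d = p[i_kdCHOP] * y[s_CHOP];
        regacc rg = {0.0, 1.0};
        reg_add(&rg, y[s_CHOP], p[i_kcChopG], p[i_KmChopG]);
        double v_mg_s = reg_rate(&rg);
        double v_mg_d = p[i_kdmRNA] * y[s_mGADD34];
        double v_g_tl = p[i_ktlG] * y[s_mGADD34];
        double v_g_d = p[i_kdG] * y[s_GADD34];
        ydot[s_eIF2a]   += -vph + vdg + vdc;
        ydot[s_eIF2aP]  += vph - vdg - vdc;
        ydot[s_ATF4]    += v_a4 - v_a4d;
        ydot[s_mCHOP]   += v_mc_s - v_mc_d;
        ydot[s_CHOP]    += v_c_tl - v_c_d;
        ydot[s_mGADD34] += v_mg_s - v_mg_d;
        ydot[s_GADD34]  += v_g_tl - v_g_d;
    }

    /* condensed BAX/BAK/BH3 switch */
    {
        double C = fmax0(y[s_CHOP]);
        double B = y[s_BAXa];
        regacc rb3 = {0.0, 1.0};
        reg_add(&rb3, C, p[i_kcBH3], p[i_KmBH3]);
        double v_b3 = p[i_ksBH3] + reg_rate(&rb3);
        double v_b3d = p[i_kdBH3] * y[s_BH3];
        double v_act = p[i_kactBAX] * fmax0(y[s_BH3]) *
            fmax0(p[i_BAXT] - B);
        double Bp = fmax0(B);
        double v_auto = p[i_kautoBAX] * fmax0(p[i_BAXT] - Bp) *
            Bp * Bp / (p[i_JBAX] * p[i_JBAX] + Bp * Bp);
        double Kh = pow(p[i_KbclCHOP], p[i_hbcl]);
        double bcl2 = p[i_Bcl2T] * Kh / (Kh + pow(C, p[i_hbcl]));
        double v_in = (p[i_krevBAX] + p[i_kbclBAX] * bcl2) * B;
        ydot[s_BH3]  += v_b3 - v_b3d;
        ydot[s_BAXa] += v_act + v_auto - v_in;
    }
}

/* ------------------------------------------------------------------ */
/* standalone PERK branch: 7 species, clamped PERKA                    */

#define N_PERK_PAR 29
static double pperk[N_PERK_PAR];

void upr_init_perk(void (*odeparms)(int *, double *))
{
    int n = N_PERK_PAR;
    odeparms(&n, pperk);
}

enum {
    q_PERKA, q_kphos, q_Kmphos, q_kmChop, q_kdephos, q_Kmdephos, q_CReP,
    q_eIF2aT, q_ksATF4, q_kATF4, q_nh, q_kdATF4,
    q_kc0CHOP, q_kcA4CHOP, q_kmAtff, q_kcA6CHOP, q_KmA6CHOP,
    q_kcXsCHOP, q_KmXsCHOP, q_extCHOP, q_ktlCHOP, q_kdCHOP,
    q_kcChopG, q_KmChopG, q_ktlG, q_kdG, q_kdmRNA, q_ATF6p50, q_XBP1s
};

/* species: eIF2a, eIF2aP, ATF4, mCHOP, CHOP, mGADD34, GADD34 */
void upr_deriv_perk(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    const double *p = pperk;
    double e = fmax0(y[0]), ep = fmax0(y[1]);
    double vph = p[q_kphos] * p[q_PERKA] * e / (p[q_Kmphos] + e) /
        (1.0 + fmax0(y[4]) / p[q_kmChop]);
    double vdg = p[q_kdephos] * y[6] * ep / (p[q_Kmdephos] + ep);
    double vdc = p[q_kdephos] * p[q_CReP] * ep / (p[q_Kmdephos] + ep);
    double r = pow(fmax0(y[0]) / p[q_kATF4], p[q_nh]);
    double v_a4 = p[q_ksATF4] / (1.0 + r);
    regacc rc = {0.0, 1.0};
    reg_add(&rc, 1.0, p[q_kc0CHOP], 1.0);
    reg_add(&rc, y[2], p[q_kcA4CHOP], p[q_kmAtff]);
    reg_add(&rc, p[q_ATF6p50], p[q_kcA6CHOP], p[q_KmA6CHOP]);
    reg_add(&rc, p[q_XBP1s], p[q_kcXsCHOP], p[q_KmXsCHOP]);
    reg_add(&rc, p[q_extCHOP], p[q_kcA6CHOP], p[q_KmA6CHOP]);
    double v_mc_s = reg_rate(&rc);
    regacc rg = {0.0, 1.0};
    reg_add(&rg, y[4], p[q_kcChopG], p[q_KmChopG]);
    double v_mg_s = reg_rate(&rg);

    ydot[0] = -vph + vdg + vdc;
    ydot[1] = vph - vdg - vdc;
    ydot[2] = v_a4 - p[q_kdATF4] * y[2];
    ydot[3] = v_mc_s - p[q_kdmRNA] * y[3];
    ydot[4] = p[q_ktlCHOP] * y[3] - p[q_kdCHOP] * y[4];
    ydot[5] = v_mg_s - p[q_kdmRNA] * y[5];
    ydot[6] = p[q_ktlG] * y[5] - p[q_kdG] * y[6];
}

/* ------------------------------------------------------------------ */
/* standalone apoptosis switch: species BH3, BAXa; clamped CHOP        */

#define N_APOP_PAR 14
static double papop[N_APOP_PAR];

void upr_init_apop(void (*odeparms)(int *, double *))
{
    int n = N_APOP_PAR;
    odeparms(&n, papop);
}

enum {
    a_CHOP, a_ksBH3, a_kcBH3, a_KmBH3, a_kdBH3, a_BAXT,
    a_kactBAX, a_kautoBAX, a_JBAX, a_krevBAX, a_kbclBAX,
    a_Bcl2T, a_KbclCHOP, a_hbcl
};

void upr_deriv_apop(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    const double *p = papop;
    double C = fmax0(p[a_CHOP]);
    double B = y[1];
    regacc rb3 = {0.0, 1.0};
    reg_add(&rb3, C, p[a_kcBH3], p[a_KmBH3]);
    double v_b3 = p[a_ksBH3] + reg_rate(&rb3);
    double v_act = p[a_kactBAX] * fmax0(y[0]) * fmax0(p[a_BAXT] - B);
    double Bp = fmax0(B);
    double v_auto = p[a_kautoBAX] * fmax0(p[a_BAXT] - Bp) *
        Bp * Bp / (p[a_JBAX] * p[a_JBAX] + Bp * Bp);
    double Kh = pow(p[a_KbclCHOP], p[a_hbcl]);
    double bcl2 = p[a_Bcl2T] * Kh / (Kh + pow(C, p[a_hbcl]));
    double v_in = (p[a_krevBAX] + p[a_kbclBAX] * bcl2) * B;
    ydot[0] = v_b3 - p[a_kdBH3] * y[0];
    ydot[1] = v_act + v_auto - v_in;
}
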