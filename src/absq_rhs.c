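/* Compiled right-hand side of the PBPK-QSP system, mirroring the reference
 * R implementation in R/dynamics.R (rhs_reference) exactly.  Used through
 * deSolve's compiled-code interface for speed; state layout and parameter
 * vector layout are built on the R side (absq_context).
 *
 * Parameter vector (doubles, 0-based):
 *   [0]        Qco (total cardiac plasma flow, mL/day)
 *   [1..12]    Q per tissue (LUNGS first; order of TISSUES)
 *   [13..24]   vascular sub-volumes (tumor entries recomputed from state)
 *   [25..36]   interstitial sub-volumes (tumor entries recomputed)
 *   [37], [38] arterial / venous blood volumes
 *   [39..110]  kext[species][tissue]   (6 x 12, species-major)
 *   [111..182] klym[species][tissue]
 *   [183..188] birth per species (into venous blood)
 *   [189..194] death per species
 *   [195..211] kinetics: lg, Clear, Ac_DC, Ac_M1, Ac_dead_DC, Ac_dead_M1,
 *              k_prol_TN, TN0, k_TN, k_rc1, s_Treg, s_M2, v_cell_mL,
 *              N_exp, phi_int, phi_vas, volume guard
 */
#include <R.h>
#include <string.h>

#define NPAR 212
#define NTIS 12
#define NSP  6
#define NST  161
static double p[NPAR];
static double cjac[NST * NST];   /* constant (transport + death) Jacobian,
                                    column-major: cjac[i + NST*j] = df_i/dy_j */

static void build_const_jac(void)
{
    const double Qco  = p[0];
    const double *Q   = p + 1;
    const double Vart = p[37], Vven = p[38];
    const double *kext = p + 39, *klym = p + 111;
    const double *death = p + 189;
    int s, i;
    double qsum = 0.0;
    for (i = 1; i < NTIS; i++) qsum += Q[i];
    memset(cjac, 0, sizeof(cjac));
#define J(i, j) cjac[(i) + NST * (j)]
    for (s = 0; s < NSP; s++) {
        const int b = s * 26;
        const double ds = death[s];
        for (i = 0; i < NTIS; i++) {
            const double ke = kext[s * NTIS + i], kl = klym[s * NTIS + i];
            /* vascular balance */
            if (i == 0) {
                J(b, b + 25) += Qco / Vven;
                J(b, b) += -Qco / p[13] - ke - ds;
            } else {
                J(b + i, b + 24) += Q[i] / Vart;
                J(b + i, b + i) += -ke - ds;
                if (i < 10)           /* tumor 1/Vvas terms are dynamic */
                    J(b + i, b + i) += -Q[i] / p[13 + i];
            }
            /* interstitial balance */
            J(b + 12 + i, b + i) += ke;
            J(b + 12 + i, b + 12 + i) += -kl - ds;
            if (i != 9) J(b + 12 + 9, b + 12 + i) += kl;
            /* venous collection */
            if (i >= 1 && i < 10)
                J(b + 25, b + i) += Q[i] / p[13 + i];
        }
        /* arterial pool */
        J(b + 24, b) += Qco / p[13];
        J(b + 24, b + 24) += -qsum / Vart - ds;
        /* venous pool */
        J(b + 25, b + 12 + 9) += klym[s * NTIS + 9];
        J(b + 25, b + 25) += -Qco / Vven - ds;
    }
#undef J
}

void absq_init(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
    build_const_jac();
}

static inline double pos(double x) { return x > 0.0 ? x : 0.0; }

void absq_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const double Qco  = p[0];
    const double *Q   = p + 1;
    const double Vart = p[37], Vven = p[38];
    const double *kext = p + 39, *klym = p + 111;
    const double *birth = p + 183, *death = p + 189;
    const double lg = p[195], Clear = p[196];
    const double AcDC = p[197], AcM1 = p[198];
    const double AdDC = p[199], AdM1 = p[200];
    const double kprol = p[201], TN0 = p[202];
    const double kTN = p[203], krc1 = p[204];
    const double sTreg = p[205], sM2 = p[206];
    const double vcell = p[207], Nexp = p[208];
    const double phi_int = p[209], phi_vas = p[210], guard = p[211];

    double Vvas[NTIS], Vint[NTIS];
    int s, i, k;
    for (i = 0; i < NTIS; i++) { Vvas[i] = p[13 + i]; Vint[i] = p[25 + i]; }

    const double Tv1 = pos(y[157]), Td1 = pos(y[158]);
    const double Tv2 = pos(y[159]), Td2 = pos(y[160]);
    const double V1 = (Tv1 + Td1) * vcell, V2 = (Tv2 + Td2) * vcell;
    Vint[10] = phi_int * V1 > guard ? phi_int * V1 : guard;
    Vint[11] = phi_int * V2 > guard ? phi_int * V2 : guard;
    Vvas[10] = phi_vas * V1 > guard ? phi_vas * V1 : guard;
    Vvas[11] = phi_vas * V2 > guard ? phi_vas * V2 : guard;

    for (s = 0; s < NSP; s++) {
        const int base = s * 26;
        const double *vas = y + base;        /* 12 vascular slots */
        const double *intr = y + base + 12;  /* 12 interstitial slots */
        const double art = y[base + 24], ven = y[base + 25];
        const double Cart = art / Vart, Cven = ven / Vven;
        const double ds = death[s];
        double lymph_to_ln = 0.0, qc_ven = 0.0, qsum = 0.0;
        for (i = 0; i < NTIS; i++) {
            const double ke = kext[s * NTIS + i], kl = klym[s * NTIS + i];
            const double Cvi = vas[i] / Vvas[i];
            double dvas;
            if (i == 0)
                dvas = Qco * (Cven - Cvi);
            else {
                dvas = Q[i] * (Cart - Cvi);
                qc_ven += Q[i] * Cvi;
                qsum += Q[i];
            }
            dvas -= ke * vas[i];
            ydot[base + i] = dvas - ds * vas[i];
            ydot[base + 12 + i] = ke * vas[i] - kl * intr[i] - ds * intr[i];
            if (i != 9) lymph_to_ln += kl * intr[i];
        }
        ydot[base + 12 + 9] += lymph_to_ln;
        ydot[base + 24] = Qco * (vas[0] / Vvas[0]) - qsum * Cart - ds * art;
        ydot[base + 25] = qc_ven + klym[s * NTIS + 9] * intr[9]
            - Qco * Cven + birth[s] - ds * ven;
    }

    /* tumor interstitial interaction kernel */
    for (k = 0; k < 2; k++) {
        const int tum = 10 + k;               /* tissue index */
        const int iv = 157 + 2 * k, id = iv + 1;
        const double Tv = pos(y[iv]), Td = pos(y[id]);
        const double Vi = Vint[tum];
        const int oDC = 0 * 26 + 12 + tum, oM1 = 1 * 26 + 12 + tum;
        const int oM2 = 2 * 26 + 12 + tum, oTR = 3 * 26 + 12 + tum;
        const int oTE = 4 * 26 + 12 + tum, oAP = 5 * 26 + 12 + tum;
        const double DC = pos(y[oDC]), M1 = pos(y[oM1]), M2 = pos(y[oM2]);
        const double TR = pos(y[oTR]), TE = pos(y[oTE]), AP = pos(y[oAP]);
        const double cDCA = (DC + AP) / Vi, cM1 = M1 / Vi;
        const double cTv = Tv / Vi, cTd = Td / Vi;
        const double cyto = krc1 * (TE / Vi) * Tv /
            (1.0 + sTreg * TR / Vi + sM2 * M2 / Vi);
        const double phagoV = (AcDC * cDCA + AcM1 * cM1) * Tv;
        const double phagoD = (AdDC * cDCA + AdM1 * cM1) * Td;
        const double dcflux = DC * (AcDC * cTv + AdDC * cTd);
        const double m1flux = M1 * (AcM1 * cTv + AdM1 * cTd);
        ydot[iv] = lg * Tv - cyto - phagoV;
        ydot[id] = cyto - Clear * Td - phagoD;
        ydot[oDC] -= dcflux;
        ydot[oM1] -= m1flux;
        ydot[oAP] += dcflux + m1flux;
    }

    /* lymph-node priming */
    {
        const double TN = pos(y[156]);
        const double cAPC = pos(y[5 * 26 + 12 + 9]) / Vint[9];
        const double act = kTN * cAPC * TN;
        ydot[156] = kprol * TN * (1.0 - TN / TN0) - act;
        ydot[4 * 26 + 12 + 9] += Nexp * act;
    }
}

/* Analytic full Jacobian: constant transport part plus the
 * volume-dependent tumor terms and the interaction-kernel block.
 * pd is (*nrowpd) x neq, column-major; column j holds df/dy_j. */
void absq_jac(int *neq, double *t, double *y, int *ml, int *mu,
              double *pd, int *nrowpd, double *yout, int *ip)
{
    const int nr = *nrowpd;
    const double *Q = p + 1;
    const double lg = p[195], Clear = p[196];
    const double AcDC = p[197], AcM1 = p[198];
    const double AdDC = p[199], AdM1 = p[200];
    const double kprol = p[201], TN0 = p[202];
    const double kTN = p[203], krc1 = p[204];
    const double sTreg = p[205], sM2 = p[206];
    const double vcell = p[207], Nexp = p[208];
    const double phi_int = p[209], phi_vas = p[210], guard = p[211];
    int s, k, i, j;

    /* copy the constant part (nr == NST always in practice) */
    if (nr == NST) {
        memcpy(pd, cjac, sizeof(cjac));
    } else {
        for (j = 0; j < NST; j++)
            for (i = 0; i < NST; i++)
                pd[i + nr * j] = cjac[i + NST * j];
    }
#define J(i, j) pd[(i) + nr * (j)]

    for (k = 0; k < 2; k++) {
        const int tum = 10 + k;
        const int iv = 157 + 2 * k, id = iv + 1;
        const double Tv = y[iv] > 0 ? y[iv] : 0;
        const double Td = y[id] > 0 ? y[id] : 0;
        const double V = (Tv + Td) * vcell;
        double Vvas = phi_vas * V, Vint = phi_int * V;
        double cvv = phi_vas * vcell, cvi = phi_int * vcell;
        if (Vvas <= guard) { Vvas = guard; cvv = 0.0; }
        if (Vint <= guard) { Vint = guard; cvi = 0.0; }
        const double u = 1.0 / Vint;

        /* dynamic vascular terms for every trafficking species */
        for (s = 0; s < NSP; s++) {
            const int vs = s * 26 + tum;
            const int vn = s * 26 + 25;
            const double vas = y[vs];
            J(vs, vs) += -Q[tum] / Vvas;
            J(vn, vs) += Q[tum] / Vvas;
            const double dV = Q[tum] * vas * cvv / (Vvas * Vvas);
            J(vs, iv) += dV;  J(vs, id) += dV;
            J(vn, iv) += -dV; J(vn, id) += -dV;
        }

        /* interaction kernel in the tumor interstitium */
        const int oDC = 0 * 26 + 12 + tum, oM1 = 1 * 26 + 12 + tum;
        const int oM2 = 2 * 26 + 12 + tum, oTR = 3 * 26 + 12 + tum;
        const int oTE = 4 * 26 + 12 + tum, oAP = 5 * 26 + 12 + tum;
        const double DC = y[oDC] > 0 ? y[oDC] : 0;
        const double M1 = y[oM1] > 0 ? y[oM1] : 0;
        const double M2 = y[oM2] > 0 ? y[oM2] : 0;
        const double TR = y[oTR] > 0 ? y[oTR] : 0;
        const double TE = y[oTE] > 0 ? y[oTE] : 0;
        const double AP = y[oAP] > 0 ? y[oAP] : 0;

        /* cytolysis: krc1*TE*Tv / D,  D = Vint + sT*TR + sM2*M2 */
        const double D = Vint + sTreg * TR + sM2 * M2;
        const double cyto = krc1 * TE * Tv / D;
        const double dcy_TE = krc1 * Tv / D;
        const double dcy_Tv = krc1 * TE / D - cyto * cvi / D;
        const double dcy_Td = -cyto * cvi / D;
        const double dcy_TR = -cyto * sTreg / D;
        const double dcy_M2 = -cyto * sM2 / D;

        /* phagocytosis of viable cells: P*Tv*u */
        const double P = AcDC * (DC + AP) + AcM1 * M1;
        const double phagoV = P * Tv * u;
        const double dpv_DC = AcDC * Tv * u;
        const double dpv_M1 = AcM1 * Tv * u;
        const double dpv_Tv = P * u - phagoV * u * cvi;
        const double dpv_Td = -phagoV * u * cvi;

        /* phagocytosis of debris: Pd*Td*u */
        const double Pd = AdDC * (DC + AP) + AdM1 * M1;
        const double phagoD = Pd * Td * u;
        const double dpd_DC = AdDC * Td * u;
        const double dpd_M1 = AdM1 * Td * u;
        const double dpd_Td = Pd * u - phagoD * u * cvi;
        const double dpd_Tv = -phagoD * u * cvi;

        /* conversion fluxes */
        const double dcflux = DC * (AcDC * Tv + AdDC * Td) * u;
        const double ddc_DC = (AcDC * Tv + AdDC * Td) * u;
        const double ddc_Tv = DC * AcDC * u - dcflux * u * cvi;
        const double ddc_Td = DC * AdDC * u - dcflux * u * cvi;
        const double m1flux = M1 * (AcM1 * Tv + AdM1 * Td) * u;
        const double dm1_M1 = (AcM1 * Tv + AdM1 * Td) * u;
        const double dm1_Tv = M1 * AcM1 * u - m1flux * u * cvi;
        const double dm1_Td = M1 * AdM1 * u - m1flux * u * cvi;

        /* ydot[iv] = lg*Tv - cyto - phagoV */
        J(iv, iv) += lg - dcy_Tv - dpv_Tv;
        J(iv, id) += -dcy_Td - dpv_Td;
        J(iv, oTE) += -dcy_TE;
        J(iv, oTR) += -dcy_TR;
        J(iv, oM2) += -dcy_M2;
        J(iv, oDC) += -dpv_DC;
        J(iv, oAP) += -dpv_DC;
        J(iv, oM1) += -dpv_M1;

        /* ydot[id] = cyto - Clear*Td - phagoD */
        J(id, iv) += dcy_Tv - dpd_Tv;
        J(id, id) += dcy_Td - Clear - dpd_Td;
        J(id, oTE) += dcy_TE;
        J(id, oTR) += dcy_TR;
        J(id, oM2) += dcy_M2;
        J(id, oDC) += -dpd_DC;
        J(id, oAP) += -dpd_DC;
        J(id, oM1) += -dpd_M1;

        /* phagocyte -> APC conversion */
        J(oDC, oDC) += -ddc_DC;
        J(oDC, iv) += -ddc_Tv;
        J(oDC, id) += -ddc_Td;
        J(oM1, oM1) += -dm1_M1;
        J(oM1, iv) += -dm1_Tv;
        J(oM1, id) += -dm1_Td;
        J(oAP, oDC) += ddc_DC;
        J(oAP, oM1) += dm1_M1;
        J(oAP, iv) += ddc_Tv + dm1_Tv;
        J(oAP, id) += ddc_Td + dm1_Td;
    }

    /* lymph-node priming */
    {
        const double TN = y[156] > 0 ? y[156] : 0;
        const int oAPL = 5 * 26 + 12 + 9, oTEL = 4 * 26 + 12 + 9;
        const double AP = y[oAPL] > 0 ? y[oAPL] : 0;
        const double uL = 1.0 / p[25 + 9];        /* LN interstitial volume */
        J(156, 156) += kprol * (1.0 - 2.0 * TN / TN0) - kTN * AP * uL;
        J(156, oAPL) += -kTN * TN * uL;
        J(oTEL, 156) += Nexp * kTN * AP * uL;
        J(oTEL, oAPL) += Nexp * kTN * TN * uL;
    }
#undef J
}
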