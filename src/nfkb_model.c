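/* ODE right-hand side for the IKK -> NF-kB translocation model and its
 * variants, in the deSolve compiled-code convention.
 *
 * State layout (concentrations; nuclear species in nuclear-volume units):
 *  0 IKKn    neutral IKK
 *  1 IKKa    active IKK
 *  2 IKKi    inactivated IKK (recycles to neutral)
 *  3 NFkBc   free cytoplasmic NF-kB
 *  4 NFkBn   free nuclear NF-kB
 *  5 IkBac   free cytoplasmic IkBa
 *  6 IkBan   free nuclear IkBa
 *  7 CplxC   IkBa:NF-kB complex, cytoplasm
 *  8 CplxN   IkBa:NF-kB complex, nucleus
 *  9 tIkBa   IkBa mRNA
 * 10 A20     A20-type feedback inhibitor of IKK
 * 11 NFkBDNA DNA-bound nuclear NF-kB (chromatin-pioneering variant)
 * 12 tIkBe  13 IkBec  14 IkBen  15 ECplxC  16 ECplxN   (IkBe variant)
 * 17 IkBbc  18 IkBbn  19 BCplxC  20 BCplxN             (IkBb variant)
 *
 * Time is in seconds. The forcing IKKSpots(t) is an analytic sum of four
 * Gaussians whose parameters travel in the parameter vector, so the solver
 * sees a smooth function with no interpolation kinks.
 *
 * NF-kB is neither synthesized nor degraded anywhere below; the
 * volume-weighted total is conserved exactly and this is asserted in tests.
 */

#include <R.h>
#include <math.h>

#define N_PARMS 65
static double parms[N_PARMS];

#define ka        parms[0]
#define ki_ikk    parms[1]
#define ka20      parms[2]
#define kr_ikk    parms[3]
#define kf        parms[4]
#define kb        parms[5]
#define kc        parms[6]
#define kc2       parms[7]
#define kdeg_ikba parms[8]
#define kdeg_cplx parms[9]
#define kimpN     parms[10]
#define kexpN     parms[11]
#define kimpI     parms[12]
#define kexpI     parms[13]
#define kexpC     parms[14]
#define ktr0      parms[15]
#define ktr       parms[16]
#define kdeg_t    parms[17]
#define ktl       parms[18]
#define ksynA20   parms[19]
#define kdegA20   parms[20]
#define vol_ratio parms[21]   /* Vn / Vc */
#define ka1d      parms[22]
#define kdNFKB    parms[23]
#define h2        parms[24]
#define Ps0       parms[25]
#define Ps        parms[26]
#define KDNA      parms[27]
#define h3        parms[28]
#define ka2a      parms[29]
#define kd1d      parms[30]
#define variant   parms[31]   /* 0 d2fc, 1 d2fc2, 2 +IkBe, 3 +IkBb */
#define ktr_e     parms[32]
#define kdeg_te   parms[33]
#define ktl_e     parms[34]
#define kdeg_ikbe parms[35]
#define kdeg_ecplx parms[36]
#define kimpIe    parms[37]
#define kexpIe    parms[38]
#define kexpCe    parms[39]
#define kc_e      parms[40]
#define kc2_e     parms[41]
#define K_delay   parms[42]   /* seconds */
#define n_delay   parms[43]
#define ksyn_b    parms[44]
#define kdeg_ikbb parms[45]
#define kdeg_bcplx parms[46]
#define kimpIb    parms[47]
#define kexpIb    parms[48]
#define kexpCb    parms[49]
#define kc_b      parms[50]
#define kc2_b     parms[51]
#define spots_on  parms[52]
/* 53..56 Gaussian amplitudes, 57..60 centers (s), 61..64 widths (s) */

void nfkb_initmod(void (*odeparms)(int *, double *)) {
  int n = N_PARMS;
  odeparms(&n, parms);
}

static double ikk_spots(double t) {
  double s = 0.0;
  for (int i = 0; i < 4; i++) {
    double z = (t - parms[57 + i]) / parms[61 + i];
    s += parms[53 + i] * exp(-z * z);
  }
  if (s < 0.0) s = 0.0;
  return spots_on * s;
}

static double pospow(double x, double h) {
  if (x <= 0.0) return 0.0;
  return pow(x, h);
}

void nfkb_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip) {
  double IKKn_ = y[0] > 0 ? y[0] : 0, IKKa_ = y[1] > 0 ? y[1] : 0,
         IKKi_ = y[2] > 0 ? y[2] : 0;
  double NFkBc_ = y[3] > 0 ? y[3] : 0, NFkBn_ = y[4] > 0 ? y[4] : 0;
  double IkBac_ = y[5] > 0 ? y[5] : 0, IkBan_ = y[6] > 0 ? y[6] : 0;
  double CplxC_ = y[7] > 0 ? y[7] : 0, CplxN_ = y[8] > 0 ? y[8] : 0;
  double tIkBa_ = y[9] > 0 ? y[9] : 0, A20_ = y[10] > 0 ? y[10] : 0;
  double DNA_ = y[11] > 0 ? y[11] : 0;
  double v = vol_ratio;
  int var = (int)(variant + 0.5);

  double spots = ikk_spots(*t);

  /* IKK cycle: neutral -> active at CI, active -> inactive (A20-enhanced),
   * inactive recycles; total IKK conserved */
  double act = ka * spots * IKKn_;
  double inact = (ki_ikk + ka20 * A20_) * IKKa_;
  double recyc = kr_ikk * IKKi_;
  ydot[0] = -act + recyc;
  ydot[1] = act - inact;
  ydot[2] = inact - recyc;

  /* IkBa:NF-kB association/dissociation, both compartments */
  double assoc_c = kf * NFkBc_ * IkBac_;
  double dissoc_c = kb * CplxC_;
  double assoc_n = kf * NFkBn_ * IkBan_;
  double dissoc_n = kb * CplxN_;

  /* IKK-driven and constitutive IkBa turnover (NF-kB released intact) */
  double degC_ikk = kc * IKKa_ * CplxC_;
  double degC_const = kdeg_cplx * CplxC_;
  double degI_ikk = kc2 * IKKa_ * IkBac_;

  /* DNA binding (chromatin-pioneering variant only): the printed rate law
   * has no mass-action factor in NFkB; the cooperative Hill term DCoop -> 0
   * as free nuclear NF-kB -> 0 provides the vanishing limit, and a smooth
   * saturating guard NFkB/(NFkB + eps) prevents numerical overshoot below
   * zero. */
  double DCoop = 0.0, NPio = Ps0, bind = 0.0, strip = 0.0, basal_rel = 0.0;
  if (var == 1) {
    double r2 = pospow(NFkBn_ / kdNFKB, h2);
    DCoop = r2 / (1.0 + r2);
    double r3 = pospow(DNA_ / KDNA, h3);
    NPio = Ps0 + Ps * r3 / (1.0 + r3);
    double guard = NFkBn_ / (NFkBn_ + 1e-9);
    bind = ka1d * DCoop * NPio * guard;
    strip = ka2a * IkBan_ * DNA_;
    basal_rel = kd1d * DNA_;
  }

  /* free NF-kB */
  ydot[3] = -assoc_c + dissoc_c + degC_ikk + degC_const
            - kimpN * NFkBc_ + kexpN * NFkBn_ * v;
  ydot[4] = kimpN * NFkBc_ / v - kexpN * NFkBn_
            - assoc_n + dissoc_n - bind + basal_rel;

  /* IkBa protein */
  ydot[5] = ktl * tIkBa_ - assoc_c + dissoc_c - degI_ikk
            - kdeg_ikba * IkBac_ - kimpI * IkBac_ + kexpI * IkBan_ * v;
  ydot[6] = kimpI * IkBac_ / v - kexpI * IkBan_ - assoc_n + dissoc_n
            - strip - kdeg_ikba * IkBan_;

  /* complexes */
  ydot[7] = assoc_c - dissoc_c - degC_ikk - degC_const + kexpC * CplxN_ * v;
  ydot[8] = assoc_n - dissoc_n - kexpC * CplxN_ + strip;

  /* IkBa mRNA (NF-kB-inducible negative feedback) and A20 */
  ydot[9] = ktr0 + ktr * NFkBn_ - kdeg_t * tIkBa_;
  ydot[10] = ksynA20 * NFkBn_ - kdegA20 * A20_;

  /* DNA-bound NF-kB */
  ydot[11] = (var == 1) ? (bind - basal_rel - strip) : 0.0;

  for (int i = 12; i < 21; i++) ydot[i] = 0.0;

  if (var == 2) {
    /* IkBe: NF-kB-inducible with a transcriptional onset delay (Hill in
     * time, t in seconds from stimulus onset); only active post-stimulus */
    double tIkBe_ = y[12] > 0 ? y[12] : 0, IkBec_ = y[13] > 0 ? y[13] : 0,
           IkBen_ = y[14] > 0 ? y[14] : 0, ECplxC_ = y[15] > 0 ? y[15] : 0,
           ECplxN_ = y[16] > 0 ? y[16] : 0;
    double delay = 0.0;
    if (spots_on > 0.5 && *t > 0.0) {
      /* 1/(1 + (K/t)^n): overflow-safe for steep gates */
      delay = 1.0 / (1.0 + pospow(K_delay / *t, n_delay));
    }
    double assoc_ec = kf * NFkBc_ * IkBec_;
    double dissoc_ec = kb * ECplxC_;
    double assoc_en = kf * NFkBn_ * IkBen_;
    double dissoc_en = kb * ECplxN_;
    double degEC_ikk = kc_e * IKKa_ * ECplxC_;
    double degEC_const = kdeg_ecplx * ECplxC_;
    double degEI_ikk = kc2_e * IKKa_ * IkBec_;
    ydot[12] = ktr_e * NFkBn_ * delay - kdeg_te * tIkBe_;
    ydot[13] = ktl_e * tIkBe_ - assoc_ec + dissoc_ec - degEI_ikk
               - kdeg_ikbe * IkBec_ - kimpIe * IkBec_ + kexpIe * IkBen_ * v;
    ydot[14] = kimpIe * IkBec_ / v - kexpIe * IkBen_ - assoc_en + dissoc_en
               - kdeg_ikbe * IkBen_;
    ydot[15] = assoc_ec - dissoc_ec - degEC_ikk - degEC_const
               + kexpCe * ECplxN_ * v;
    ydot[16] = assoc_en - dissoc_en - kexpCe * ECplxN_;
    ydot[3] += -assoc_ec + dissoc_ec + degEC_ikk + degEC_const;
    ydot[4] += -assoc_en + dissoc_en;
  } else if (var == 3) {
    /* IkBb: constitutive synthesis, independent of NF-kB activation */
    double IkBbc_ = y[17] > 0 ? y[17] : 0, IkBbn_ = y[18] > 0 ? y[18] : 0,
           BCplxC_ = y[19] > 0 ? y[19] : 0, BCplxN_ = y[20] > 0 ? y[20] : 0;
    double assoc_bc = kf * NFkBc_ * IkBbc_;
    double dissoc_bc = kb * BCplxC_;
    double assoc_bn = kf * NFkBn_ * IkBbn_;
    double dissoc_bn = kb * BCplxN_;
    double degBC_ikk = kc_b * IKKa_ * BCplxC_;
    double degBC_const = kdeg_bcplx * BCplxC_;
    double degBI_ikk = kc2_b * IKKa_ * IkBbc_;
    ydot[17] = ksyn_b - assoc_bc + dissoc_bc - degBI_ikk
               - kdeg_ikbb * IkBbc_ - kimpIb * IkBbc_ + kexpIb * IkBbn_ * v;
    ydot[18] = kimpIb * IkBbc_ / v - kexpIb * IkBbn_ - assoc_bn + dissoc_bn
               - kdeg_ikbb * IkBbn_;
    ydot[19] = assoc_bc - dissoc_bc - degBC_ikk - degBC_const
               + kexpCb * BCplxN_ * v;
    ydot[20] = assoc_bn - dissoc_bn - kexpCb * BCplxN_;
    ydot[3] += -assoc_bc + dissoc_bc + degBC_ikk + degBC_const;
    ydot[4] += -assoc_bn + dissoc_bn;
  }

  if (ip[0] >= 3) {
    yout[0] = spots;
    yout[1] = DCoop;
    yout[2] = NPio;
  }
}
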