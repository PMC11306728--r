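/* PBPK-RO model right-hand side for deSolve (compiled-model convention).
 *
 * State vector (amounts, umol):
 *   y[0] blood, y[1] adipose, y[2] muscle, y[3] skin,
 *   y[4] liver_ec, y[5] liver_ic, y[6] target_ec, y[7] target_ic_free,
 *   y[8] receptor_complex
 *
 * Parameter vector: see pbpk_parms() on the R side; the ordering here and
 * there must stay in lockstep.
 */
#include <R.h>

#define N_PARMS 35

static double parms[N_PARMS];

#define Qa        parms[0]
#define Qh        parms[1]
#define Qm        parms[2]
#define Qs        parms[3]
#define Qt        parms[4]
#define Va        parms[5]
#define Vm        parms[6]
#define Vs        parms[7]
#define Vhe       parms[8]
#define Vhic      parms[9]
#define Vt        parms[10]
#define Vtic      parms[11]
#define Vb        parms[12]
#define Kpa       parms[13]
#define Kpm       parms[14]
#define Kps       parms[15]
#define fub       parms[16]
#define VmaxUp    parms[17]
#define KmUp      parms[18]
#define VmaxMet   parms[19]
#define KmMet     parms[20]
#define PSdif     parms[21]
#define VmaxTu    parms[22]
#define KmTu      parms[23]
#define PSdifT    parms[24]
#define VmaxTm    parms[25]
#define KmTm      parms[26]
#define kon       parms[27]
#define koff      parms[28]
#define XTotalR   parms[29]
#define CLr       parms[30]
#define recEc     parms[31]
#define infRate   parms[32]
#define infT0     parms[33]
#define infT1     parms[34]

void pbpk_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double Cb = y[0] / Vb;

    /* flow-limited tissues */
    double Ca = y[1] / Va, Cm = y[2] / Vm, Cs = y[3] / Vs;
    double dAa = Qa * (Cb - Ca / Kpa);
    double dAm = Qm * (Cb - Cm / Kpm);
    double dAs = Qs * (Cb - Cs / Kps);

    /* liver: extracellular (perfused) / intracellular pair */
    double Ce   = y[4] / Vhe;
    double CuE  = fub * Ce;
    double Cic  = y[5] / Vhic;
    double upt  = VmaxUp * CuE / (KmUp + CuE) + PSdif * CuE;
    double eff  = PSdif * Cic;
    double met  = VmaxMet * Cic / (KmMet + Cic);
    double dAhe = Qh * (Cb - Ce) - upt + eff;
    double dAhi = upt - eff - met;

    /* target: same structure plus receptor binding */
    double Cte   = y[6] / Vt;
    double CuTe  = fub * Cte;
    double Ctic  = y[7] / Vtic;
    double uptT  = VmaxTu * CuTe / (KmTu + CuTe) + PSdifT * CuTe;
    double effT  = PSdifT * Ctic;
    double metT  = VmaxTm * Ctic / (KmTm + Ctic);
    double Rfree = XTotalR - y[8];
    double Cbind = (recEc > 0.5) ? CuTe : Ctic;
    double bind  = kon * Cbind * Rfree - koff * y[8];

    double dAte, dAti;
    if (recEc > 0.5) {
        dAte = Qt * (Cb - Cte) - uptT + effT - bind;
        dAti = uptT - effT - metT;
    } else {
        dAte = Qt * (Cb - Cte) - uptT + effT;
        dAti = uptT - effT - metT - bind;
    }

    double inf = (infRate > 0.0 && *t >= infT0 && *t < infT1) ? infRate : 0.0;

    double dAb = Qa * (Ca / Kpa - Cb) + Qm * (Cm / Kpm - Cb)
               + Qs * (Cs / Kps - Cb) + Qh * (Ce - Cb) + Qt * (Cte - Cb)
               - CLr * Cb + inf;

    ydot[0] = dAb;
    ydot[1] = dAa;
    ydot[2] = dAm;
    ydot[3] = dAs;
    ydot[4] = dAhe;
    ydot[5] = dAhi;
    ydot[6] = dAte;
    ydot[7] = dAti;
    ydot[8] = bind;
}
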