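/* Right-hand side of the CRISPRi circuit ODE system, evaluated by deSolve.
 *
 * State layout for a circuit with E edges (n = 3E + 9 states):
 *   y[0 .. E-1]       sgRNA_e        (free sgRNA per edge)
 *   y[E .. 2E-1]      dCas:sgRNA_e
 *   y[2E .. 3E-1]     dCas:sgRNA_e:DNA_tgt(e)   (ternary complex)
 *   y[3E .. 3E+2]     mRNA_A, mRNA_B, mRNA_C
 *   y[3E+3 .. 3E+5]   PI_A, PI_B, PI_C          (immature protein)
 *   y[3E+6 .. 3E+8]   P_A, P_B, P_C             (mature reporter)
 *
 * Free dCas and free promoter DNA are eliminated algebraically from the
 * conservation relations (dCas_total, DNA_total per node).
 *
 * Parameter vector (see pack_parms() on the R side), 0-based indices:
 *   0 E, 1 ara, 2 growth mode (0 microplate / 1 constant), 3 m_const,
 *   4 kr_dsd, 5 kf_ds, 6 kr_ds, 7 d_rna, 8 dcas_total,
 *   9 n_hill, 10 K_m, 11 k2, 12 literal_hill_dna, 13 literal_pi,
 *   14 p1, 15-17 p2[k], 18-20 p3[k], 21-23 p4[k], 24-26 p5[k],
 *   27 kPI_base, 28 h_t, 29 K_t,
 *   30 + 7*(j) .. : node block j = 0(A),1(B),2(C):
 *       +0 dna_total, +1 leak_b, +2 k_mrna, +3 prom_eff,
 *       +4 k_pi, +5 m_pi, +6 d_pi
 *   51 + 5*e .. : edge block e = 0..E-1:
 *       +0 src (1..3), +1 tgt (1..3), +2 leak_b_sg, +3 k_sg, +4 kf_dsd
 */

#include <R.h>
#include <math.h>

#define NPARMS 81

static double parms[NPARMS];

void grnmap_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

static double hill_frac(double x, double n, double K)
{
    double xn, Kn;
    if (x <= 0.0) return 0.0;
    xn = pow(x, n);
    Kn = pow(K, n);
    return xn / (xn + Kn);
}

/* growth G(t) and dilution m = G'/G */
static void growth_eval(double t, double *G, double *m)
{
    if (parms[2] > 0.5) { /* constant mode */
        *G = 1.0;
        *m = parms[3];
        return;
    }
    {
        double g = parms[14], dg = 0.0;
        int k;
        for (k = 0; k < 3; k++) {
            double p2 = parms[15 + k], p3 = parms[18 + k];
            double p4 = parms[21 + k], p5 = parms[24 + k];
            double ek = exp(-t * p4);
            double den = 1.0 + p3 * ek;
            double term = p2 / pow(den, 1.0 / p5);
            g += term;
            dg += term * (p4 * p3 * ek) / (p5 * den);
        }
        *G = g;
        *m = (g > 0.0) ? dg / g : 0.0;
    }
}

void grnmap_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const int E = (int)(parms[0] + 0.5);
    const double ara = parms[1];
    const double kr_dsd = parms[4], kf_ds = parms[5], kr_ds = parms[6];
    const double d_rna = parms[7], dcas_tot = parms[8];
    const double n_hill = parms[9], K_m = parms[10], k2 = parms[11];
    const int literal_dna = parms[12] > 0.5;
    const int literal_pi = parms[13] > 0.5;
    const double kpi_base = parms[27], h_t = parms[28], K_t = parms[29];

    double G, m;
    double dcas_free, dna_free[3], dna_tot[3];
    double hillA, prod_mrna[3];
    int e, j;

    growth_eval(*t, &G, &m);

    /* conservation: free dCas and free promoter DNA per node */
    dcas_free = dcas_tot;
    for (e = 0; e < E; e++)
        dcas_free -= y[E + e] + y[2 * E + e];
    for (j = 0; j < 3; j++) {
        dna_tot[j] = parms[30 + 7 * j + 0];
        dna_free[j] = dna_tot[j];
    }
    for (e = 0; e < E; e++) {
        int tgt = (int)(parms[51 + 5 * e + 1] + 0.5) - 1;
        dna_free[tgt] -= y[2 * E + e];
    }

    hillA = hill_frac(ara, n_hill, K_m);

    /* sgRNA / complex dynamics per edge */
    for (e = 0; e < E; e++) {
        const double *eb = parms + 51 + 5 * e;
        int src = (int)(eb[0] + 0.5) - 1;
        int tgt = (int)(eb[1] + 0.5) - 1;
        double b_sg = eb[2], k_sg = eb[3], kf_dsd = eb[4];
        double sg = y[e], ds = y[E + e], tern = y[2 * E + e];
        double prod;

        if (src == 0) { /* arabinose-driven source (node A) */
            double dnaA = literal_dna ? dna_tot[0] : dna_free[0];
            prod = k2 * dnaA * (hillA * (1.0 - b_sg) + b_sg);
        } else {        /* constitutive, scaled by the source promoter efficiency */
            double eff = parms[30 + 7 * src + 3];
            prod = k_sg * eff * dna_free[src];
        }

        ydot[e] = prod - d_rna * sg - kf_ds * dcas_free * sg + kr_ds * ds;
        ydot[E + e] = kf_ds * dcas_free * sg + kr_dsd * tern
                      - m * ds - kr_ds * ds - kf_dsd * ds * dna_free[tgt];
        ydot[2 * E + e] = kf_dsd * ds * dna_free[tgt] - kr_dsd * tern - m * tern;
    }

    /* mRNA production per node */
    {
        const double *nb = parms + 30; /* node A */
        double dnaA = literal_dna ? dna_tot[0] : dna_free[0];
        prod_mrna[0] = k2 * dnaA * (hillA * (1.0 - nb[1]) + nb[1]);
    }
    for (j = 1; j < 3; j++) {
        const double *nb = parms + 30 + 7 * j;
        prod_mrna[j] = nb[2] * nb[3] * dna_free[j]; /* k_mrna * eff * DNA_free */
    }

    for (j = 0; j < 3; j++) {
        const double *nb = parms + 30 + 7 * j;
        double k_pi = nb[4], m_pi = nb[5], d_pi = nb[6];
        double mrna = y[3 * E + j], pi = y[3 * E + 3 + j], p = y[3 * E + 6 + j];

        if (j == 0) /* arabinose-dependent translation of node A */
            k_pi *= kpi_base + (1.0 - kpi_base) * hill_frac(ara, h_t, K_t);

        ydot[3 * E + j] = prod_mrna[j] - d_rna * mrna;
        ydot[3 * E + 3 + j] = k_pi * mrna
                              - nb[5] * (literal_pi ? p : pi)
                              - (m + d_pi) * pi;
        ydot[3 * E + 6 + j] = m_pi * pi - (m + d_pi) * p;
    }

    if (ip[0] >= 6) {
        yout[0] = G;
        yout[1] = m;
        yout[2] = dcas_free;
        yout[3] = dna_free[0];
        yout[4] = dna_free[1];
        yout[5] = dna_free[2];
    }
}
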