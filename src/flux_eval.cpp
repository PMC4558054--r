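// Fast inner loops for the kinetic model: flux-vector evaluation and the ODE
// right-hand side. Mirrors the reference R evaluator in R/fluxes.R exactly;
// the two are cross-checked in the test suite. All indices are 0-based and
// prepared once per compiled network in R.
#include <Rcpp.h>
using namespace Rcpp;

static inline double clamp0(double v) { return v > 0.0 ? v : 0.0; }

// effector value: concentration (i2 < 0) or pool ratio; Inf signalled as -1
static inline double eff_value(const double* x, int i1, int i2, bool& inf) {
  inf = false;
  if (i2 < 0) return clamp0(x[i1]);
  double den = x[i2], num = clamp0(x[i1]);
  if (den <= 0.0) {
    if (num > 0.0) { inf = true; return 0.0; }
    return 0.0;
  }
  return num / den;
}

// [[Rcpp::export(name = ".flux_eval_cpp")]]
NumericVector flux_eval_cpp(NumericVector x, NumericVector p,
                            IntegerVector vmax_idx,
                            IntegerVector sub_off, IntegerVector sub_type,
                            IntegerVector sub_i1, IntegerVector sub_i2,
                            IntegerVector sub_k,
                            IntegerVector reg_off, IntegerVector reg_kind,
                            IntegerVector reg_e1, IntegerVector reg_e2,
                            IntegerVector reg_k, IntegerVector reg_alpha,
                            IntegerVector reg_beta) {
  const int nR = vmax_idx.size();
  NumericVector v(nR);
  const double* xp = x.begin();
  const double* pp = p.begin();
  std::vector<double> terms(32);
  for (int j = 0; j < nR; ++j) {
    double rate = pp[vmax_idx[j]];
    if (rate == 0.0) { v[j] = 0.0; continue; }
    int s0 = sub_off[j], s1 = sub_off[j + 1];
    int ns = s1 - s0;
    if ((int)terms.size() < ns) terms.resize(ns);
    for (int s = s0; s < s1; ++s) {
      double term;
      if (sub_type[s] == 1) {
        double sv = clamp0(xp[sub_i1[s]]);
        term = sv / (sv + pp[sub_k[s]]);
      } else {
        double den = xp[sub_i2[s]], num = clamp0(xp[sub_i1[s]]);
        if (den <= 0.0) term = num > 0.0 ? 1.0 : 0.0;
        else { double r = num / den; term = r / (r + pp[sub_k[s]]); }
      }
      terms[s - s0] = term;
    }
    for (int g = reg_off[j]; g < reg_off[j + 1]; ++g) {
      bool inf;
      double val = eff_value(xp, reg_e1[g], reg_e2[g], inf);
      if (reg_kind[g] == 1) {           // non-competitive inhibition factor
        if (inf) { rate = 0.0; break; }
        rate /= (1.0 + val / pp[reg_k[g]]);
      } else {                          // non-essential activation, term 1
        double A = inf ? 1e77 : val;
        double sv = clamp0(xp[sub_i1[s0]]);
        double KS = pp[sub_k[s0]], KA = pp[reg_k[g]];
        double al = pp[reg_alpha[g]], be = pp[reg_beta[g]];
        terms[0] = sv * (1.0 + be * A / (al * KA)) /
          (KS * (1.0 + A / KA) + sv * (1.0 + A / (al * KA)));
      }
    }
    for (int s = 0; s < ns; ++s) rate *= terms[s];
    v[j] = rate;
  }
  return v;
}

// [[Rcpp::export(name = ".rhs_cpp")]]
NumericVector rhs_cpp(NumericVector x, NumericVector p,
                      IntegerVector vmax_idx,
                      IntegerVector sub_off, IntegerVector sub_type,
                      IntegerVector sub_i1, IntegerVector sub_i2,
                      IntegerVector sub_k,
                      IntegerVector reg_off, IntegerVector reg_kind,
                      IntegerVector reg_e1, IntegerVector reg_e2,
                      IntegerVector reg_k, IntegerVector reg_alpha,
                      IntegerVector reg_beta,
                      NumericMatrix stoich, IntegerVector comp_code,
                      int i_cells, int i_growth, bool dilution) {
  NumericVector v = flux_eval_cpp(x, p, vmax_idx, sub_off, sub_type, sub_i1,
                                  sub_i2, sub_k, reg_off, reg_kind, reg_e1,
                                  reg_e2, reg_k, reg_alpha, reg_beta);
  const int nS = stoich.nrow(), nR = stoich.ncol();
  NumericVector d(nS);
  for (int j = 0; j < nR; ++j) {
    double vj = v[j];
    if (vj == 0.0) continue;
    for (int i = 0; i < nS; ++i) {
      double c = stoich(i, j);
      if (c != 0.0) d[i] += c * vj;
    }
  }
  double Xv = clamp0(x[i_cells]);
  double mu = i_growth >= 0 ? v[i_growth] : 0.0;
  // comp_code: 1 extracellular/product (mM), 2 intracellular per-cell,
  //            3 cells, 4 volume
  for (int i = 0; i < nS; ++i) {
    switch (comp_code[i]) {
    case 1: d[i] *= 1000.0 * Xv; break;
    case 2: if (dilution) d[i] -= mu * x[i]; break;
    case 3: d[i] *= x[i]; break;
    default: d[i] = 0.0;
    }
  }
  return d;
}
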