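#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Monoisotopic masses; keep in sync with R/constants.R
static const double MC = 12.000000;
static const double MH = 1.00782503;
static const double MN = 14.00307401;
static const double MO = 15.99491462;
static const double MP = 30.97376163;
static const double MS = 31.97207117;

// Exhaustive CHONSP enumeration within a ppm tolerance of a neutral mass.
// Outer loops run over the heteroatom/oxygen grid; for each (n,s,p,o,c) the
// admissible hydrogen counts are the integers whose residual falls inside the
// tolerance window (the window is < 1 H mass for sub-ppm tolerances, so this
// loses nothing relative to a full H scan). Candidates must satisfy:
//   |error_ppm| < tol_ppm (strict), H/C and O/C ranges (closed),
//   RDBE = c - h/2 + n/2 + p/2 + 1 >= 0, and, if parity is required,
//   h + n + p even (integer RDBE, neutral even-electron molecule).
// [[Rcpp::export]]
DataFrame enumerateCandidatesCpp(double mass, double tol_ppm,
                                 int c_min, int c_max, int h_min, int h_max,
                                 int n_min, int n_max, int o_min, int o_max,
                                 int s_min, int s_max, int p_min, int p_max,
                                 double hc_min, double hc_max,
                                 double oc_min, double oc_max,
                                 bool parity) {
  std::vector<int> vc, vh, vn, vo, vs, vp;
  std::vector<double> vppm;
  const double tol_da = tol_ppm * mass * 1e-6;

  for (int n = n_min; n <= n_max; ++n) {
    for (int s = s_min; s <= s_max; ++s) {
      for (int p = p_min; p <= p_max; ++p) {
        double base_nsp = n * MN + s * MS + p * MP;
        if (base_nsp > mass + tol_da) break;
        for (int o = o_min; o <= o_max; ++o) {
          double base = base_nsp + o * MO;
          if (base + c_min * MC > mass + tol_da) break;
          for (int c = c_min; c <= c_max; ++c) {
            double rem = mass - base - c * MC;
            if (rem < h_min * MH - tol_da) break; // rem shrinks with c
            if (oc_min > 0 && o < oc_min * c) continue;
            if (o > oc_max * c) continue;
            int h_lo = (int)std::ceil((rem - tol_da) / MH);
            int h_hi = (int)std::floor((rem + tol_da) / MH);
            if (h_lo < h_min) h_lo = h_min;
            if (h_hi > h_max) h_hi = h_max;
            for (int h = h_lo; h <= h_hi; ++h) {
              double err = mass - (base + c * MC + h * MH);
              double ppm = err / mass * 1e6;
              if (std::fabs(ppm) >= tol_ppm) continue;
              double hc = (double)h / c;
              if (hc < hc_min || hc > hc_max) continue;
              double rdbe = c - h / 2.0 + n / 2.0 + p / 2.0 + 1.0;
              if (rdbe < -1e-9) continue;
              if (parity && ((h + n + p) % 2 != 0)) continue;
              vc.push_back(c); vh.push_back(h); vn.push_back(n);
              vo.push_back(o); vs.push_back(s); vp.push_back(p);
              vppm.push_back(ppm);
            }
          }
        }
      }
    }
  }
  return DataFrame::create(_["C"] = vc, _["H"] = vh, _["N"] = vn,
                           _["O"] = vo, _["S"] = vs, _["P"] = vp,
                           _["error_ppm"] = vppm);
}

// Greedy consensus clustering of a pooled, ascending m/z vector.
// A new cluster opens when the next peak lies more than tol_ppm from the
// running (unweighted) mean of the current cluster's members.
// Returns 1-based cluster ids.
// [[Rcpp::export]]
IntegerVector alignGreedyCpp(NumericVector mz, double tol_ppm) {
  int n = mz.size();
  IntegerVector id(n);
  if (n == 0) return id;
  int cur = 1;
  double sum = mz[0];
  int cnt = 1;
  id[0] = 1;
  for (int i = 1; i < n; ++i) {
    double mean = sum / cnt;
    if ((mz[i] - mean) / mean * 1e6 > tol_ppm) {
      ++cur; sum = mz[i]; cnt = 1;
    } else {
      sum += mz[i]; ++cnt;
    }
    id[i] = cur;
  }
  return id;
}
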