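#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive enumeration of CHNOPS integer count vectors whose monoisotopic
// mass lies in [lo, hi]. Loops run over P, S, N, O, C with mass-derived
// upper bounds (count <= remaining mass / element mass, optionally capped
// by per-element maxima); the hydrogen count is solved last within the
// residual mass window, so the inner loop visits at most a couple of H
// values for ppm-scale windows. Completeness is guaranteed because every
// element mass is positive and bounds are exact.
//
// masses / maxc are ordered C, H, N, O, P, S.

// [[Rcpp::export]]
IntegerMatrix enumerate_formulas_cpp(double lo, double hi,
                                     NumericVector masses,
                                     IntegerVector maxc) {
  const double mC = masses[0], mH = masses[1], mN = masses[2],
               mO = masses[3], mP = masses[4], mS = masses[5];
  const double eps = 1e-9;
  std::vector<int> out;

  int pMax = std::min((int)std::floor(hi / mP + eps), maxc[4]);
  for (int p = 0; p <= pMax; ++p) {
    double remP = hi - p * mP;
    if (remP < -eps) break;
    int sMax = std::min((int)std::floor(remP / mS + eps), maxc[5]);
    for (int s = 0; s <= sMax; ++s) {
      double remS = remP - s * mS;
      int nMax = std::min((int)std::floor(remS / mN + eps), maxc[2]);
      for (int n = 0; n <= nMax; ++n) {
        double remN = remS - n * mN;
        int oMax = std::min((int)std::floor(remN / mO + eps), maxc[3]);
        for (int o = 0; o <= oMax; ++o) {
          double remO = remN - o * mO;
          int cMax = std::min((int)std::floor(remO / mC + eps), maxc[0]);
          for (int c = 0; c <= cMax; ++c) {
            double base = lo - (hi - remO) - c * mC; // lo - mass(P,S,N,O,C)
            double room = remO - c * mC;            // hi - mass(P,S,N,O,C)
            int hMin = (int)std::ceil(base / mH - eps);
            if (hMin < 0) hMin = 0;
            int hMax = std::min((int)std::floor(room / mH + eps), maxc[1]);
            for (int h = hMin; h <= hMax; ++h) {
              if (c + h + n + o + p + s == 0) continue;
              out.push_back(c); out.push_back(h); out.push_back(n);
              out.push_back(o); out.push_back(p); out.push_back(s);
            }
          }
        }
      }
    }
  }

  const int nrow = out.size() / 6;
  IntegerMatrix res(nrow, 6);
  for (int i = 0; i < nrow; ++i)
    for (int j = 0; j < 6; ++j)
      res(i, j) = out[6 * i + j];
  colnames(res) = CharacterVector::create("C", "H", "N", "O", "P", "S");
  return res;
}
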