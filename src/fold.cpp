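// Minimum-free-energy folding of short RNA windows with optional
// forced-unpaired constraints. Zuker-style dynamic program: stacks from a
// nearest-neighbor table, log-linear hairpin/bulge/internal-loop penalties,
// affine multiloops. Used for target-site accessibility (opening) energies
// on windows of roughly 100-300 nt, hence no sparsification.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e9;
static const int MIN_HAIRPIN = 3;
static const int MAXLOOP = 30;

// codes: A=0 C=1 G=2 U=3
static inline bool pair_ok(int a, int b) {
  return (a == 0 && b == 3) || (a == 3 && b == 0) ||
         (a == 1 && b == 2) || (a == 2 && b == 1) ||
         (a == 2 && b == 3) || (a == 3 && b == 2);
}

static inline bool au_end(int a, int b) {
  // terminal penalty applies to AU and GU closing pairs
  return !((a == 1 && b == 2) || (a == 2 && b == 1));
}

// [[Rcpp::export]]
double fold_mfe_cpp(IntegerVector codes, LogicalVector mask,
                    NumericVector stack4, List par) {
  const int n = codes.size();
  if (n < MIN_HAIRPIN + 2) return 0.0;
  const double hairpin_base = par["hairpin_base"];
  const double hairpin_slope = par["hairpin_slope"];
  const double bulge_base = par["bulge_base"];
  const double bulge_per = par["bulge_per"];
  const double il_base = par["intloop_base"];
  const double il_per = par["intloop_per"];
  const double il_asym = par["intloop_asym"];
  const double ml_init = par["ml_init"];
  const double ml_branch = par["ml_branch"];
  const double ml_unpaired = par["ml_unpaired"];
  const double term_au = par["terminal_au"];

  std::vector<double> V((size_t)n * n, INF), WM((size_t)n * n, INF);
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = codes[i];
  std::vector<bool> um(n);
  for (int i = 0; i < n; ++i) um[i] = mask[i];

#define IDX(i, j) ((size_t)(i) * n + (j))

  for (int len = MIN_HAIRPIN + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      double v = INF;
      if (!um[i] && !um[j] && pair_ok(s[i], s[j])) {
        const double tij = au_end(s[i], s[j]) ? term_au : 0.0;
        // hairpin
        int hsz = j - i - 1;
        v = hairpin_base + hairpin_slope * std::log((double)hsz / 3.0) + tij;
        // stacks / bulges / internal loops
        for (int k = i + 1; k < j - MIN_HAIRPIN; ++k) {
          const int l1 = k - i - 1;
          if (l1 > MAXLOOP) break;
          for (int l = j - 1; l > k + MIN_HAIRPIN; --l) {
            const int l2 = j - l - 1;
            if (l1 + l2 > MAXLOOP) break;
            const double inner = V[IDX(k, l)];
            if (inner >= INF) continue;
            double e;
            if (l1 == 0 && l2 == 0) {
              e = stack4[((s[i] * 4 + s[k]) * 4 + s[j]) * 4 + s[l]];
              if (NumericVector::is_na(e)) continue;
            } else {
              const double tkl = au_end(s[k], s[l]) ? term_au : 0.0;
              if (l1 == 0 || l2 == 0) {
                e = bulge_base + bulge_per * (l1 + l2 - 1) + tij + tkl;
              } else {
                e = il_base + il_per * (l1 + l2 - 2) +
                    il_asym * std::abs(l1 - l2) + tij + tkl;
              }
            }
            if (inner + e < v) v = inner + e;
          }
        }
        // multiloop: >= 2 branches inside
        for (int k = i + 1; k < j - 1; ++k) {
          const double a = WM[IDX(i + 1, k)];
          if (a >= INF) continue;
          const double b = WM[IDX(k + 1, j - 1)];
          if (b >= INF) continue;
          const double e = a + b + ml_init + ml_branch + tij;
          if (e < v) v = e;
        }
      }
      V[IDX(i, j)] = v;
      // WM: at least one branch on [i, j]
      double wm = INF;
      if (v < INF) {
        const double t = au_end(s[i], s[j]) ? term_au : 0.0;
        wm = v + ml_branch + t;
      }
      if (len > 1) {
        const double a = WM[IDX(i + 1, j)];
        if (a + ml_unpaired < wm) wm = a + ml_unpaired;
        const double b = WM[IDX(i, j - 1)];
        if (b + ml_unpaired < wm) wm = b + ml_unpaired;
        for (int k = i; k < j; ++k) {
          const double c1 = WM[IDX(i, k)];
          if (c1 >= INF) continue;
          const double c2 = WM[IDX(k + 1, j)];
          if (c2 >= INF) continue;
          if (c1 + c2 < wm) wm = c1 + c2;
        }
      }
      WM[IDX(i, j)] = wm;
    }
  }

  // exterior loop
  std::vector<double> W(n + 1, 0.0);
  for (int j = 1; j <= n; ++j) {
    double w = W[j - 1];
    for (int i = 1; i <= j - MIN_HAIRPIN - 1; ++i) {
      const double v = V[IDX(i - 1, j - 1)];
      if (v >= INF) continue;
      const double t = au_end(s[i - 1], s[j - 1]) ? term_au : 0.0;
      const double e = W[i - 1] + v + t;
      if (e < w) w = e;
    }
    W[j] = w;
  }
#undef IDX
  return W[n];
}
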