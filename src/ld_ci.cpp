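#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Two-locus statistics from unphased genotypes: haplotype frequencies by
// EM, |D'| and its likelihood-profile confidence interval on a D' grid.

struct PairStats {
  bool informative;   // polymorphic at both loci with data
  double dprime;      // |D'| at the EM estimate
  double ci_low;      // lower bound of the 90% D' interval
  double ci_high;     // upper bound
  int cls;            // 2 strong LD, 1 strong recombination, 0 inconclusive
};

// genotype-pair log likelihood given haplotype freqs f00,f01,f10,f11
static void geno_probs(const double f[4], double P[3][3]) {
  // hap index h = 2*a + b, allele a at locus 1, b at locus 2
  for (int x = 0; x < 3; ++x)
    for (int y = 0; y < 3; ++y) P[x][y] = 0.0;
  for (int h1 = 0; h1 < 4; ++h1)
    for (int h2 = 0; h2 < 4; ++h2) {
      int x = (h1 >> 1) + (h2 >> 1);
      int y = (h1 & 1) + (h2 & 1);
      P[x][y] += f[h1] * f[h2];
    }
}

static PairStats pair_stats(const int *x, const int *y, int n,
                            double strong_low, double strong_high,
                            double recomb_high, double grid_step) {
  PairStats out;
  out.informative = false;
  out.dprime = NA_REAL; out.ci_low = NA_REAL; out.ci_high = NA_REAL;
  out.cls = -1;
  double cnt[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
  int nc = 0;
  for (int i = 0; i < n; ++i) {
    if (x[i] == NA_INTEGER || y[i] == NA_INTEGER) continue;
    cnt[x[i]][y[i]] += 1.0;
    ++nc;
  }
  if (nc < 2) return out;
  double sx = 0, sy = 0;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) { sx += a * cnt[a][b]; sy += b * cnt[a][b]; }
  double pA = sx / (2.0 * nc), pB = sy / (2.0 * nc);
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return out;

  // EM for f11 (frequency of the minor/minor haplotype)
  double f11 = pA * pB;
  for (int it = 0; it < 100; ++it) {
    double f10 = pA - f11, f01 = pB - f11, f00 = 1 - pA - pB + f11;
    if (f10 < 1e-12) f10 = 1e-12;
    if (f01 < 1e-12) f01 = 1e-12;
    if (f00 < 1e-12) f00 = 1e-12;
    double denom = f11 * f00 + f10 * f01;
    double e11 = denom > 0 ? cnt[1][1] * (f11 * f00) / denom : 0.0;
    double nAB = 2 * cnt[2][2] + cnt[2][1] + cnt[1][2] + e11;
    double f11_new = nAB / (2.0 * nc);
    if (f11_new < 0) f11_new = 0;
    double hi = std::min(pA, pB);
    if (f11_new > hi) f11_new = hi;
    if (std::fabs(f11_new - f11) < 1e-12) { f11 = f11_new; break; }
    f11 = f11_new;
  }
  double D = f11 - pA * pB;
  double dmax = D >= 0 ? std::min(pA * (1 - pB), (1 - pA) * pB)
                       : std::min(pA * pB, (1 - pA) * (1 - pB));
  if (dmax <= 0) return out;
  out.dprime = std::fabs(D) / dmax;
  if (out.dprime > 1) out.dprime = 1;
  double sign = D >= 0 ? 1.0 : -1.0;

  // likelihood profile over |D'| in [0, 1]
  int ng = (int) std::lround(1.0 / grid_step) + 1;
  std::vector<double> ll(ng);
  double maxll = -1e300;
  for (int g = 0; g < ng; ++g) {
    double d = g * grid_step;
    double Dg = sign * d * dmax;
    double f[4];
    f[3] = pA * pB + Dg;               // f11
    f[2] = pA * (1 - pB) - Dg;         // f10
    f[1] = (1 - pA) * pB - Dg;         // f01
    f[0] = (1 - pA) * (1 - pB) + Dg;   // f00
    for (int h = 0; h < 4; ++h) if (f[h] < 1e-12) f[h] = 1e-12;
    double P[3][3];
    geno_probs(f, P);
    double s = 0;
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b)
        if (cnt[a][b] > 0) {
          double p = P[a][b] > 1e-300 ? P[a][b] : 1e-300;
          s += cnt[a][b] * std::log(p);
        }
    ll[g] = s;
    if (s > maxll) maxll = s;
  }
  double tot = 0;
  std::vector<double> w(ng);
  for (int g = 0; g < ng; ++g) { w[g] = std::exp(ll[g] - maxll); tot += w[g]; }
  double cum = 0;
  double dl = 1.0, du = 1.0;
  bool got_l = false, got_u = false;
  for (int g = 0; g < ng; ++g) {
    cum += w[g];
    if (!got_l && cum >= 0.05 * tot) { dl = g * grid_step; got_l = true; }
    if (!got_u && cum >= 0.95 * tot) { du = g * grid_step; got_u = true; break; }
  }
  out.informative = true;
  out.ci_low = dl; out.ci_high = du;
  if (dl >= strong_low && du >= strong_high) out.cls = 2;
  else if (du < recomb_high) out.cls = 1;
  else out.cls = 0;
  return out;
}

// [[Rcpp::export]]
List dprime_ci_cpp(IntegerVector x, IntegerVector y,
                   double strong_low = 0.70, double strong_high = 0.98,
                   double recomb_high = 0.90, double grid_step = 0.001) {
  if (x.size() != y.size()) stop("x and y must have equal length");
  PairStats s = pair_stats(x.begin(), y.begin(), x.size(),
                           strong_low, strong_high, recomb_high, grid_step);
  return List::create(_["informative"] = s.informative,
                      _["dprime"] = s.dprime,
                      _["ci_low"] = s.ci_low, _["ci_high"] = s.ci_high,
                      _["class"] = s.cls);
}

// Scan one chromosome (columns of geno ordered by position) for LD blocks.
// [[Rcpp::export]]
List ld_block_scan_cpp(IntegerMatrix geno, NumericVector pos,
                       double strong_low, double strong_high,
                       double recomb_high, double inf_min_frac,
                       double max_span, double grid_step,
                       bool return_pairs = false) {
  int n = geno.nrow(), m = geno.ncol();
  if ((int) pos.size() != m) stop("pos length must match SNP count");
  // per-pair classes, cls[i][j - i - 1] for pairs within max_span
  std::vector<std::vector<int> > cls(m);
  std::vector<int> pi, pj, pc;
  std::vector<double> pdp, plo, phi;
  std::vector<int> xi(n), yj(n);
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m && pos[j] - pos[i] <= max_span; ++j) {
      for (int r = 0; r < n; ++r) { xi[r] = geno(r, i); yj[r] = geno(r, j); }
      PairStats s = pair_stats(&xi[0], &yj[0], n, strong_low, strong_high,
                               recomb_high, grid_step);
      cls[i].push_back(s.cls);
      if (return_pairs) {
        pi.push_back(i + 1); pj.push_back(j + 1); pc.push_back(s.cls);
        pdp.push_back(s.dprime); plo.push_back(s.ci_low);
        phi.push_back(s.ci_high);
      }
    }
  }
  // candidate spans
  std::vector<int> cs, ce;
  std::vector<double> clen;
  for (int i = 0; i < m; ++i) {
    int n_ld = 0, n_inf = 0;
    for (int j = i + 1; j < m && pos[j] - pos[i] <= max_span; ++j) {
      for (int a = i; a < j; ++a) {
        int lag = j - a - 1;
        if (lag >= (int) cls[a].size()) continue;  // beyond a's span limit
        int c = cls[a][lag];
        if (c == 2) { ++n_ld; ++n_inf; }
        else if (c == 1) ++n_inf;
      }
      if (n_inf > 0 && n_ld > 0 &&
          (double) n_ld >= inf_min_frac * (double) n_inf) {
        cs.push_back(i); ce.push_back(j); clen.push_back(pos[j] - pos[i]);
      }
    }
  }
  // greedy longest-first, non-overlapping (by SNP index)
  std::vector<int> ord(cs.size());
  for (size_t k = 0; k < ord.size(); ++k) ord[k] = (int) k;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (clen[a] != clen[b]) return clen[a] > clen[b];
    if (cs[a] != cs[b]) return cs[a] < cs[b];
    return ce[a] < ce[b];
  });
  std::vector<bool> used(m, false);
  std::vector<int> bs, be;
  for (size_t k = 0; k < ord.size(); ++k) {
    int i = cs[ord[k]], j = ce[ord[k]];
    bool free_span = true;
    for (int a = i; a <= j; ++a) if (used[a]) { free_span = false; break; }
    if (!free_span) continue;
    for (int a = i; a <= j; ++a) used[a] = true;
    bs.push_back(i + 1); be.push_back(j + 1);
  }
  List pairs = R_NilValue;
  if (return_pairs) {
    pairs = List::create(_["i"] = pi, _["j"] = pj, _["class"] = pc,
                         _["dprime"] = pdp, _["ci_low"] = plo,
                         _["ci_high"] = phi);
  }
  return List::create(_["block_start"] = bs, _["block_end"] = be,
                      _["pairs"] = pairs);
}
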