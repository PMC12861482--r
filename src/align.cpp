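#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Global affine-gap aligner (Gotoh) used for promoter pairs:
//   match +2, mismatch -3 (N never matches), gap of length L costs open + L*ext
//   with open = 5, ext = 2 (charged as negative).
// Traceback ties resolved as: diagonal > gap-in-A (consume B) > gap-in-B.
// The DP runs inside a diagonal band that is doubled until the score is
// stable (and falls back to the full matrix), so the reported alignment is
// always the full-matrix optimum.

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    case 'N': return 4;
    default: return -1;
  }
}

static std::vector<int> encode_seq(const std::string &s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[i]);
    if (c < 0) stop("non-ACGTN character '%c' at position %d", s[i], (int)(i + 1));
    v[i] = c;
  }
  return v;
}

static const double NEG = -1e18;

// packed traceback byte: bits 0-1 = M predecessor (0 M, 1 Y, 2 X),
// bit 2 = Y extends, bit 3 = X extends
struct GotohResult { double score; int state; };

static GotohResult gotoh_run(const std::vector<int> &sa, const std::vector<int> &sb,
                             double match, double mismatch,
                             double gap_open, double gap_ext,
                             int band, std::vector<unsigned char> *tb) {
  const int n = sa.size(), m = sb.size();
  const double open_cost = gap_open + gap_ext;
  std::vector<double> bufM(2 * (m + 1)), bufX(2 * (m + 1)), bufY(2 * (m + 1));
  double *Mp = bufM.data(), *M = Mp + (m + 1);
  double *Xp = bufX.data(), *X = Xp + (m + 1);
  double *Yp = bufY.data(), *Y = Yp + (m + 1);
  unsigned char *T = tb ? tb->data() : NULL;
  const size_t W = (size_t)m + 1;

  for (int j = 0; j <= m; ++j) { Mp[j] = NEG; Xp[j] = NEG; Yp[j] = NEG; }
  Mp[0] = 0;
  for (int j = 1; j <= std::min(m, band); ++j) {
    Yp[j] = -(gap_open + gap_ext * j);
    if (T) T[j] = (j == 1) ? 0 : 4;  // Y extend flag from j >= 2
  }
  for (int i = 1; i <= n; ++i) {
    const int lo = std::max(1, i - band), hi = std::min(m, i + band);
    const int a = sa[i - 1];
    for (int j = lo - 1; j <= hi; ++j) { M[j] = NEG; X[j] = NEG; Y[j] = NEG; }
    if (hi < m) { M[hi + 1] = NEG; X[hi + 1] = NEG; Y[hi + 1] = NEG; }
    if (lo == 1 && i <= band) {
      X[0] = -(gap_open + gap_ext * i);
      if (T) T[(size_t)i * W] = (i == 1) ? 0 : 8;  // X extend flag
    }
    unsigned char *Ti = T ? T + (size_t)i * W : NULL;
    for (int j = lo; j <= hi; ++j) {
      const double sub = (a == sb[j - 1] && a != 4) ? match : mismatch;
      unsigned char code = 0;
      // M: diagonal; tie order M > Y > X
      double best = Mp[j - 1];
      if (Yp[j - 1] > best) { best = Yp[j - 1]; code = 1; }
      if (Xp[j - 1] > best) { best = Xp[j - 1]; code = 2; }
      M[j] = best + sub;
      // Y: gap in A, from (i, j-1); open (from M) preferred on tie
      const double yo = M[j - 1] - open_cost, ye = Y[j - 1] - gap_ext;
      if (yo >= ye) Y[j] = yo; else { Y[j] = ye; code |= 4; }
      // X: gap in B, from (i-1, j); open preferred on tie
      const double xo = Mp[j] - open_cost, xe = Xp[j] - gap_ext;
      if (xo >= xe) X[j] = xo; else { X[j] = xe; code |= 8; }
      if (Ti) Ti[j] = code;
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }
  GotohResult r;
  r.score = Mp[m]; r.state = 0;
  if (Yp[m] > r.score) { r.score = Yp[m]; r.state = 1; }
  if (Xp[m] > r.score) { r.score = Xp[m]; r.state = 2; }
  return r;
}

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b,
                 double match = 2.0, double mismatch = -3.0,
                 double gap_open = 5.0, double gap_ext = 2.0,
                 int band = -1) {
  std::vector<int> sa = encode_seq(a), sb = encode_seq(b);
  const int n = sa.size(), m = sb.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const int full = std::max(n, m);
  if (full <= 512) band = full;  // short instances: always full matrix
  if (band <= 0) {
    // verified banding: double until the score stops improving
    band = std::max(64, std::abs(n - m) + 32);
    if (band < full) {
      double sc = gotoh_run(sa, sb, match, mismatch, gap_open, gap_ext, band, NULL).score;
      while (band < full) {
        int nb = std::min(2 * band, full);
        double sc2 = gotoh_run(sa, sb, match, mismatch, gap_open, gap_ext, nb, NULL).score;
        if (sc2 == sc && nb > band + std::abs(n - m)) { band = nb; break; }
        sc = sc2; band = nb;
      }
    } else band = full;
  }
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);
  GotohResult r = gotoh_run(sa, sb, match, mismatch, gap_open, gap_ext, band, &tb);

  std::vector<int> posA, posB, matchcol;
  posA.reserve(n + m); posB.reserve(n + m); matchcol.reserve(n + m);
  const size_t W = (size_t)m + 1;
  int i = n, j = m, state = r.state;
  while (i > 0 || j > 0) {
    const unsigned char c = tb[(size_t)i * W + j];
    if (state == 0) {
      const bool is_match = (sa[i - 1] == sb[j - 1]) && sa[i - 1] != 4;
      posA.push_back(i - 1); posB.push_back(j - 1); matchcol.push_back(is_match ? 1 : 0);
      state = c & 3;
      --i; --j;
    } else if (state == 1) {  // Y: gap in A, consumed b[j-1]
      posA.push_back(NA_INTEGER); posB.push_back(j - 1); matchcol.push_back(0);
      state = (c & 4) ? 1 : 0;
      --j;
    } else {                  // X: gap in B, consumed a[i-1]
      posA.push_back(i - 1); posB.push_back(NA_INTEGER); matchcol.push_back(0);
      state = (c & 8) ? 2 : 0;
      --i;
    }
  }
  std::reverse(posA.begin(), posA.end());
  std::reverse(posB.begin(), posB.end());
  std::reverse(matchcol.begin(), matchcol.end());
  return List::create(_["score"] = r.score,
                      _["pos_a"] = IntegerVector(posA.begin(), posA.end()),
                      _["pos_b"] = IntegerVector(posB.begin(), posB.end()),
                      _["match"] = LogicalVector(matchcol.begin(), matchcol.end()));
}

// Banded global alignment score with linear gap cost (match/mismatch/gap per
// base); used for gene-sequence similarity in reciprocal-best-hit search.
// [[Rcpp::export(name = ".banded_score")]]
double banded_score(std::string a, std::string b,
                    double match = 1.0, double mismatch = -1.0, double gap = -2.0,
                    int band = 0) {
  std::vector<int> sa = encode_seq(a), sb = encode_seq(b);
  const int n = sa.size(), m = sb.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if (band <= 0) band = std::max(30, std::abs(n - m) + 15);
  if (band < std::abs(n - m)) band = std::abs(n - m);
  std::vector<double> prev(m + 1, NEG), cur(m + 1, NEG);
  for (int j = 0; j <= std::min(m, band); ++j) prev[j] = gap * j;
  for (int i = 1; i <= n; ++i) {
    int lo = std::max(1, i - band), hi = std::min(m, i + band);
    std::fill(cur.begin(), cur.end(), NEG);
    if (lo == 1 && i <= band) cur[0] = gap * i;
    for (int j = lo; j <= hi; ++j) {
      bool is_match = (sa[i - 1] == sb[j - 1]) && sa[i - 1] != 4;
      double best = prev[j - 1] + (is_match ? match : mismatch);
      if (prev[j] > NEG / 2 && prev[j] + gap > best) best = prev[j] + gap;
      if (cur[j - 1] > NEG / 2 && cur[j - 1] + gap > best) best = cur[j - 1] + gap;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// PWM scan: seq over A/C/G/T/N, log-odds matrix 4 x L (rows A,C,G,T).
// Windows containing N are skipped. Returns 0-based offsets.
// [[Rcpp::export(name = ".pwm_scan")]]
DataFrame pwm_scan(std::string seq, NumericMatrix logodds, double threshold) {
  std::vector<int> s = encode_seq(seq);
  const int n = s.size(), L = logodds.ncol();
  std::vector<int> offs; std::vector<double> scores; std::vector<int> strands;
  if (n >= L) {
    for (int off = 0; off + L <= n; ++off) {
      double fwd = 0, rev = 0; bool ok = true;
      for (int k = 0; k < L; ++k) {
        int c = s[off + k];
        if (c == 4) { ok = false; break; }
        fwd += logodds(c, k);
        rev += logodds(3 - c, L - 1 - k); // complement base, reversed position
      }
      if (!ok) continue;
      if (fwd > threshold) { offs.push_back(off); scores.push_back(fwd); strands.push_back(1); }
      if (rev > threshold) { offs.push_back(off); scores.push_back(rev); strands.push_back(-1); }
    }
  }
  return DataFrame::create(_["offset"] = IntegerVector(offs.begin(), offs.end()),
                           _["strand"] = IntegerVector(strands.begin(), strands.end()),
                           _["log_odds"] = NumericVector(scores.begin(), scores.end()));
}
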