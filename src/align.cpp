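// Affine-gap pairwise DNA alignment: global (Gotoh, optionally free end gaps),
// local (Smith-Waterman, score only), and an exhaustive brute-force enumerator
// used as an independent oracle on short strings.
#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double NEG = -1e18;

// EDNAFULL-like handling of N: ambiguous positions never reward a match.
static inline double subScore(char a, char b, double match, double mismatch) {
  if (a == 'N' || b == 'N') return (a == b) ? -1.0 : -2.0;
  return (a == b) ? match : mismatch;
}

// pick max with state priority M(0) > X(1, gap in b) > Y(2, gap in a)
static inline int pickState(double m, double x, double y, double &best) {
  best = m;
  int s = 0;
  if (x > best + 1e-9) { best = x; s = 1; }
  if (y > best + 1e-9) { best = y; s = 2; }
  return s;
}

//' @noRd
// [[Rcpp::export(name = ".gotohAlign")]]
List gotohAlign(std::string a, std::string b,
                double match, double mismatch,
                double gapOpen, double gapExtend,
                bool endGapsFree) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  // score matrices and traceback (predecessor state) per state
  std::vector<double> M((n + 1) * (m + 1), NEG), X(M), Y(M);
  std::vector<unsigned char> pM(M.size(), 0), pX(M.size(), 0), pY(M.size(), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = endGapsFree ? 0.0 : -(gapOpen + gapExtend * i);
    pX[at(i, 0)] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = endGapsFree ? 0.0 : -(gapOpen + gapExtend * j);
    pY[at(0, j)] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int ij = at(i, j);
      // M: consume a[i-1] vs b[j-1]
      {
        const int p = at(i - 1, j - 1);
        double best;
        int s = pickState(M[p], X[p], Y[p], best);
        M[ij] = best + subScore(a[i - 1], b[j - 1], match, mismatch);
        pM[ij] = (unsigned char)s;
      }
      // X: gap in b (vertical). Terminal column gaps free when endGapsFree.
      {
        const int p = at(i - 1, j);
        const bool freeHere = endGapsFree && (j == m);
        const double go = freeHere ? 0.0 : gapOpen + gapExtend;
        const double ge = freeHere ? 0.0 : gapExtend;
        double best;
        int s = pickState(M[p] - go, X[p] - ge, Y[p] - go, best);
        X[ij] = best;
        pX[ij] = (unsigned char)s;
      }
      // Y: gap in a (horizontal). Terminal row gaps free when endGapsFree.
      {
        const int p = at(i, j - 1);
        const bool freeHere = endGapsFree && (i == n);
        const double go = freeHere ? 0.0 : gapOpen + gapExtend;
        const double ge = freeHere ? 0.0 : gapExtend;
        double best;
        int s = pickState(M[p] - go, X[p] - go, Y[p] - ge, best);
        Y[ij] = best;
        pY[ij] = (unsigned char)s;
      }
    }
  }

  const int end = at(n, m);
  double score;
  int state = pickState(M[end], X[end], Y[end], score);

  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
    const int ij = at(i, j);
    if (state == 0) {
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      state = pM[ij];
      --i; --j;
    } else if (state == 1) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      state = pX[ij];
      --i;
    } else {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      state = pY[ij];
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  int identities = 0;
  for (size_t k = 0; k < ra.size(); ++k)
    if (ra[k] != '-' && ra[k] == rb[k]) ++identities;

  return List::create(_["alignedA"] = ra, _["alignedB"] = rb,
                      _["score"] = score, _["identities"] = identities,
                      _["length"] = (int)ra.size());
}

// Smith-Waterman affine, score only (plus end coordinates in ref/query).
static double swScore(const std::string &q, const std::string &r,
                      double match, double mismatch,
                      double gapOpen, double gapExtend,
                      int *endQ = nullptr, int *endR = nullptr) {
  const int n = (int)q.size(), m = (int)r.size();
  std::vector<double> M0(m + 1, 0.0), M1(m + 1, 0.0);
  std::vector<double> X0(m + 1, NEG), X1(m + 1, NEG);
  std::vector<double> Y0(m + 1, NEG), Y1(m + 1, NEG);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    M1[0] = 0.0; X1[0] = NEG; Y1[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      double diag = std::max(0.0, std::max(M0[j - 1], std::max(X0[j - 1], Y0[j - 1])));
      M1[j] = diag + subScore(q[i - 1], r[j - 1], match, mismatch);
      X1[j] = std::max(M0[j] - gapOpen - gapExtend, X0[j] - gapExtend);
      Y1[j] = std::max(M1[j - 1] - gapOpen - gapExtend, Y1[j - 1] - gapExtend);
      if (M1[j] > best) { best = M1[j]; bi = i; bj = j; }
    }
    std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
  }
  if (endQ) *endQ = bi;
  if (endR) *endR = bj;
  return best;
}

//' @noRd
// [[Rcpp::export(name = ".swAlignScore")]]
List swAlignScore(std::string q, std::string r,
                  double match, double mismatch,
                  double gapOpen, double gapExtend) {
  if (q.empty() || r.empty()) stop("empty sequence");
  int ei = 0, ej = 0;
  double s = swScore(q, r, match, mismatch, gapOpen, gapExtend, &ei, &ej);
  return List::create(_["score"] = s, _["endQuery"] = ei, _["endRef"] = ej);
}

//' @noRd
// [[Rcpp::export(name = ".swScoreMatrix")]]
NumericMatrix swScoreMatrix(CharacterVector queries, CharacterVector refs,
                            double match, double mismatch,
                            double gapOpen, double gapExtend) {
  const int nq = queries.size(), nr = refs.size();
  std::vector<std::string> rs(nr);
  for (int j = 0; j < nr; ++j) rs[j] = as<std::string>(refs[j]);
  NumericMatrix out(nq, nr);
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    for (int j = 0; j < nr; ++j)
      out(i, j) = swScore(q, rs[j], match, mismatch, gapOpen, gapExtend);
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---- exhaustive enumeration oracle (independent of the DP above) ----

// score a complete alignment column walk; terminal gap runs free if endGapsFree
static double scoreAlignment(const std::string &ca, const std::string &cb,
                             double match, double mismatch,
                             double gapOpen, double gapExtend,
                             bool endGapsFree) {
  const size_t L = ca.size();
  double s = 0.0;
  // substitution columns
  for (size_t k = 0; k < L; ++k)
    if (ca[k] != '-' && cb[k] != '-')
      s += subScore(ca[k], cb[k], match, mismatch);
  // gap runs in each row
  for (int row = 0; row < 2; ++row) {
    const std::string &x = (row == 0) ? ca : cb;
    size_t k = 0;
    while (k < L) {
      if (x[k] == '-') {
        size_t start = k;
        while (k < L && x[k] == '-') ++k;
        bool terminal = (start == 0) || (k == L);
        if (!(endGapsFree && terminal))
          s -= gapOpen + gapExtend * (double)(k - start);
      } else ++k;
    }
  }
  return s;
}

static void enumerate(const std::string &a, const std::string &b,
                      size_t i, size_t j, std::string &ca, std::string &cb,
                      double match, double mismatch, double gapOpen,
                      double gapExtend, bool endGapsFree, double &best) {
  if (i == a.size() && j == b.size()) {
    double s = scoreAlignment(ca, cb, match, mismatch, gapOpen, gapExtend,
                              endGapsFree);
    if (s > best) best = s;
    return;
  }
  if (i < a.size() && j < b.size()) {
    ca.push_back(a[i]); cb.push_back(b[j]);
    enumerate(a, b, i + 1, j + 1, ca, cb, match, mismatch, gapOpen, gapExtend,
              endGapsFree, best);
    ca.pop_back(); cb.pop_back();
  }
  if (i < a.size()) {
    ca.push_back(a[i]); cb.push_back('-');
    enumerate(a, b, i + 1, j, ca, cb, match, mismatch, gapOpen, gapExtend,
              endGapsFree, best);
    ca.pop_back(); cb.pop_back();
  }
  if (j < b.size()) {
    ca.push_back('-'); cb.push_back(b[j]);
    enumerate(a, b, i, j + 1, ca, cb, match, mismatch, gapOpen, gapExtend,
              endGapsFree, best);
    ca.pop_back(); cb.pop_back();
  }
}

//' @noRd
// [[Rcpp::export(name = ".bruteAlignScore")]]
double bruteAlignScore(std::string a, std::string b,
                       double match, double mismatch,
                       double gapOpen, double gapExtend,
                       bool endGapsFree) {
  if (a.size() > 10 || b.size() > 10)
    stop("brute-force oracle limited to strings of length <= 10");
  if (a.empty() || b.empty()) stop("empty sequence");
  double best = NEG;
  std::string ca, cb;
  enumerate(a, b, 0, 0, ca, cb, match, mismatch, gapOpen, gapExtend,
            endGapsFree, best);
  return best;
}
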