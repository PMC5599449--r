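#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Affine-gap (Gotoh) Needleman-Wunsch. With free_end_gaps the alignment is
// an "overlap" alignment: terminal gaps cost nothing and are excluded from
// the identity denominator, which approximates blastn identity for
// near-full-length amplicons while staying deterministic.
//
// A gap of length L costs gap_open + L * gap_extend (penalties passed as
// negative numbers). Tie-breaking is fixed: substitution (M) is preferred
// over a gap in b (X, consuming a), which is preferred over a gap in a (Y).

namespace {

const double NEG_INF = -1e18;

inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

inline double subst_score(char a, char b, double match, double mismatch) {
  // N (or any ambiguity code) never scores as a match: conservative for
  // error-bearing reads.
  if (a == b && is_acgt(a)) return match;
  return mismatch;
}

struct AlnResult {
  std::string aligned_a, aligned_b;
  double score;
  int n_columns, n_core_columns, n_matches;
  double identity_percent;
};

AlnResult align_core(const std::string& a, const std::string& b,
                     double match, double mismatch,
                     double gap_open, double gap_extend,
                     bool free_end_gaps) {
  const int n = a.size(), m = b.size();
  const double go = gap_open, ge = gap_extend;

  // state layout: 0 = M (a_i ~ b_j), 1 = X (gap in b), 2 = Y (gap in a)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  std::vector<unsigned char> tbM((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbX((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbY((n + 1) * (m + 1), 0);
  const int W = m + 1;
#define IDX(i, j) ((i) * W + (j))

  M[IDX(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[IDX(i, 0)] = free_end_gaps ? 0.0 : go + i * ge;
    tbX[IDX(i, 0)] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[IDX(0, j)] = free_end_gaps ? 0.0 : go + j * ge;
    tbY[IDX(0, j)] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: diagonal move; tie order M, X, Y
      {
        double s0 = M[IDX(i - 1, j - 1)], s1 = X[IDX(i - 1, j - 1)],
               s2 = Y[IDX(i - 1, j - 1)];
        double best = s0; unsigned char src = 0;
        if (s1 > best) { best = s1; src = 1; }
        if (s2 > best) { best = s2; src = 2; }
        M[IDX(i, j)] = best + subst_score(a[i - 1], b[j - 1], match, mismatch);
        tbM[IDX(i, j)] = src;
      }
      // X: gap in b, consumes a[i]; open from M/Y, extend from X
      {
        double open_m = M[IDX(i - 1, j)] + go + ge;
        double ext_x  = X[IDX(i - 1, j)] + ge;
        double open_y = Y[IDX(i - 1, j)] + go + ge;
        double best = open_m; unsigned char src = 0;
        if (ext_x > best) { best = ext_x; src = 1; }
        if (open_y > best) { best = open_y; src = 2; }
        X[IDX(i, j)] = best;
        tbX[IDX(i, j)] = src;
      }
      // Y: gap in a, consumes b[j]
      {
        double open_m = M[IDX(i, j - 1)] + go + ge;
        double open_x = X[IDX(i, j - 1)] + go + ge;
        double ext_y  = Y[IDX(i, j - 1)] + ge;
        double best = open_m; unsigned char src = 0;
        if (open_x > best) { best = open_x; src = 1; }
        if (ext_y > best) { best = ext_y; src = 2; }
        Y[IDX(i, j)] = best;
        tbY[IDX(i, j)] = src;
      }
    }
  }

  // endpoint: corner first, then last row (descending j), then last column
  // (descending i) -- deterministic, strictly-better replaces
  int ei = n, ej = m;
  auto cell_best = [&](int i, int j, unsigned char& st) {
    double b0 = M[IDX(i, j)], b1 = X[IDX(i, j)], b2 = Y[IDX(i, j)];
    double best = b0; st = 0;
    if (b1 > best) { best = b1; st = 1; }
    if (b2 > best) { best = b2; st = 2; }
    return best;
  };
  unsigned char est;
  double best_score = cell_best(n, m, est);
  if (free_end_gaps) {
    for (int j = m - 1; j >= 0; --j) {
      unsigned char st;
      double s = cell_best(n, j, st);
      if (s > best_score) { best_score = s; ei = n; ej = j; est = st; }
    }
    for (int i = n - 1; i >= 0; --i) {
      unsigned char st;
      double s = cell_best(i, m, st);
      if (s > best_score) { best_score = s; ei = i; ej = m; est = st; }
    }
  }

  // build alignment back to front, then add trailing free gaps
  std::string ra, rb;  // reversed core
  int i = ei, j = ej;
  unsigned char st = est;
  int lead_cols = 0;
  while (i > 0 || j > 0) {
    if (st == 0) {
      if (i == 0 && j == 0) break;
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      unsigned char src = tbM[IDX(i, j)];
      --i; --j; st = src;
    } else if (st == 1) {
      if (j == 0) {  // leading terminal gap in b
        lead_cols = i;
        while (i > 0) { ra.push_back(a[i - 1]); rb.push_back('-'); --i; }
        break;
      }
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      unsigned char src = tbX[IDX(i, j)];
      --i; st = src;
    } else {
      if (i == 0) {  // leading terminal gap in a
        lead_cols = j;
        while (j > 0) { ra.push_back('-'); rb.push_back(b[j - 1]); --j; }
        break;
      }
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      unsigned char src = tbY[IDX(i, j)];
      --j; st = src;
    }
  }
  if (!free_end_gaps) lead_cols = 0;  // gapped boundary columns were scored

  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  int trail_cols = 0;
  if (ei < n) {
    trail_cols = n - ei;
    for (int k = ei; k < n; ++k) { ra.push_back(a[k]); rb.push_back('-'); }
  } else if (ej < m) {
    trail_cols = m - ej;
    for (int k = ej; k < m; ++k) { ra.push_back('-'); rb.push_back(b[k]); }
  }

  AlnResult res;
  res.aligned_a = ra;
  res.aligned_b = rb;
  res.score = best_score;
  res.n_columns = ra.size();
  res.n_core_columns = res.n_columns - lead_cols - trail_cols;
  int matches = 0;
  for (int k = lead_cols; k < res.n_columns - trail_cols; ++k) {
    if (ra[k] == rb[k] && is_acgt(ra[k])) ++matches;
  }
  res.n_matches = matches;
  res.identity_percent =
      res.n_core_columns > 0 ? 100.0 * matches / res.n_core_columns : 0.0;
  return res;
#undef IDX
}

}  // namespace

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b, double match, double mismatch,
                  double gap_open, double gap_extend, bool free_end_gaps) {
  if (a.empty() || b.empty())
    stop("global alignment requires two non-empty sequences");
  AlnResult r =
      align_core(a, b, match, mismatch, gap_open, gap_extend, free_end_gaps);
  return List::create(
      _["aligned_a"] = r.aligned_a, _["aligned_b"] = r.aligned_b,
      _["score"] = r.score, _["identity_percent"] = r.identity_percent,
      _["n_matches"] = r.n_matches, _["n_columns"] = r.n_columns,
      _["n_core_columns"] = r.n_core_columns);
}

// [[Rcpp::export]]
NumericVector nw_identity_many_cpp(std::string query, CharacterVector refs,
                                   double match, double mismatch,
                                   double gap_open, double gap_extend,
                                   bool free_end_gaps) {
  const int k = refs.size();
  NumericVector out(k);
  for (int r = 0; r < k; ++r) {
    std::string ref = as<std::string>(refs[r]);
    if (query.empty() || ref.empty()) {
      out[r] = NA_REAL;
      continue;
    }
    out[r] = align_core(query, ref, match, mismatch, gap_open, gap_extend,
                        free_end_gaps)
                 .identity_percent;
  }
  return out;
}
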