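#include <Rcpp.h>
using namespace Rcpp;

// Three-state global alignment engines (maximisation, penalties subtracted).
// States: 0 = M (match/mismatch), 1 = D (deletion of template residues: gap
// in the target row), 2 = I (insertion into the template: gap in the
// template row).
//
// Gap cost convention: a maximal gap run of length L costs
// opening + ext * (L - 1); the opening of a deletion run over template
// residues s..e is G(mean accessibility over s..e) in the generalized
// engine, and the opening of an insertion run at inter-residue position p
// of the template is open_ins[p] (p = 0..n, flank-average rule).
//
// Tie-breaking (deterministic): at a cell, M is preferred over D over I;
// within a gap state, continuing the run is preferred over opening a new
// one (equivalently, the generalized deletion recursion prefers the
// longest optimal span).

static const double NEG = -1e30;

struct Trace {
  std::vector<int> ai, bi; // 1-based residue indices, 0 = gap
};

// append a column to the (reversed) trace
static inline void push_col(Trace &tr, int ia, int ib) {
  tr.ai.push_back(ia);
  tr.bi.push_back(ib);
}

static List finish(const Trace &tr, double score) {
  int L = tr.ai.size();
  IntegerVector ai(L), bi(L);
  for (int c = 0; c < L; ++c) { // reverse
    ai[c] = tr.ai[L - 1 - c];
    bi[c] = tr.bi[L - 1 - c];
  }
  return List::create(_["score"] = score, _["ai"] = ai, _["bi"] = bi);
}

// pick the best final cell; order encodes the tie preference
static void pick_end(int n, int m, bool free_ends,
                     const std::vector<double> &M, const std::vector<double> &D,
                     const std::vector<double> &I, int si, int sj,
                     double &best, int &bi_, int &bj_, int &bs_) {
  best = NEG * 2; bi_ = n; bj_ = m; bs_ = 0;
  const std::vector<double> *mats[3] = {&M, &D, &I};
  for (int s = 0; s < 3; ++s) {
    double v = (*mats[s])[n * si + m * sj];
    if (v > best) { best = v; bi_ = n; bj_ = m; bs_ = s; }
  }
  if (free_ends) {
    for (int i = n - 1; i >= 0; --i)
      for (int s = 0; s < 3; ++s) {
        double v = (*mats[s])[i * si + m * sj];
        if (v > best) { best = v; bi_ = i; bj_ = m; bs_ = s; }
      }
    for (int j = m - 1; j >= 0; --j)
      for (int s = 0; s < 3; ++s) {
        double v = (*mats[s])[n * si + j * sj];
        if (v > best) { best = v; bi_ = n; bj_ = j; bs_ = s; }
      }
  }
}

// [[Rcpp::export]]
List align_affine_cpp(IntegerVector a, IntegerVector b, NumericMatrix sm,
                      double open, double ext, bool free_ends = false) {
  int n = a.size(), m = b.size();
  int ncol = m + 1;
  std::vector<double> M((n + 1) * ncol, NEG), D((n + 1) * ncol, NEG),
      I((n + 1) * ncol, NEG);
  std::vector<signed char> pM((n + 1) * ncol, -1), pD((n + 1) * ncol, -1),
      pI((n + 1) * ncol, -1);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    D[i * ncol] = free_ends ? 0.0 : -(open + ext * (i - 1));
    pD[i * ncol] = (i == 1) ? 0 : 1; // open from M(0,0), then continue
  }
  for (int j = 1; j <= m; ++j) {
    I[j] = free_ends ? 0.0 : -(open + ext * (j - 1));
    pI[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    int ra = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      int c = i * ncol + j, d = (i - 1) * ncol + (j - 1);
      // M: prefer M > D > I
      double vm = M[d]; signed char sm_ = 0;
      if (D[d] > vm) { vm = D[d]; sm_ = 1; }
      if (I[d] > vm) { vm = I[d]; sm_ = 2; }
      M[c] = vm + sm(ra, b[j - 1] - 1);
      pM[c] = sm_;
      // D: prefer continue > from M > from I
      int u = (i - 1) * ncol + j;
      double vd = D[u] - ext; signed char sd = 1;
      if (M[u] - open > vd) { vd = M[u] - open; sd = 0; }
      if (I[u] - open > vd) { vd = I[u] - open; sd = 2; }
      D[c] = vd; pD[c] = sd;
      // I: prefer continue > from M > from D
      int l = i * ncol + (j - 1);
      double vi = I[l] - ext; signed char si = 2;
      if (M[l] - open > vi) { vi = M[l] - open; si = 0; }
      if (D[l] - open > vi) { vi = D[l] - open; si = 1; }
      I[c] = vi; pI[c] = si;
    }
  }
  double best; int ci, cj, cs;
  pick_end(n, m, free_ends, M, D, I, ncol, 1, best, ci, cj, cs);
  Trace tr;
  for (int i = n; i > ci; --i) push_col(tr, i, 0); // free tail deletion
  for (int j = m; j > cj; --j) push_col(tr, 0, j); // free tail insertion
  int i = ci, j = cj, s = cs;
  while (i > 0 || j > 0) {
    int c = i * ncol + j;
    if (s == 0) {
      push_col(tr, i, j); s = pM[c]; --i; --j;
    } else if (s == 1) {
      push_col(tr, i, 0); s = pD[c]; --i;
      if (i == 0 && j == 0) break;
      if (j == 0 && free_ends && i > 0 && s != 1) { // free leading run
        while (i > 0) { push_col(tr, i, 0); --i; }
        break;
      }
    } else {
      push_col(tr, 0, j); s = pI[c]; --j;
      if (i == 0 && j == 0) break;
      if (i == 0 && free_ends && j > 0 && s != 2) {
        while (j > 0) { push_col(tr, 0, j); --j; }
        break;
      }
    }
  }
  return finish(tr, best);
}

// Generalized engine: deletion-of-template runs are charged from the mean
// accessibility of the deleted span; insertion openings come from the
// precomputed inter-residue vector open_ins (length n + 1).
// [[Rcpp::export]]
List align_acc_cpp(IntegerVector a, IntegerVector b, NumericMatrix sm,
                   NumericVector acc, double alpha, double beta, double ext,
                   NumericVector open_ins, int max_del_span = 0,
                   bool free_ends = false) {
  int n = a.size(), m = b.size();
  if ((int)acc.size() != n) stop("accessibility track length mismatch");
  if ((int)open_ins.size() != n + 1) stop("open_ins must have length n + 1");
  int cap = (max_del_span <= 0 || max_del_span > n) ? n : max_del_span;
  int nrow = n + 1; // column-contiguous layout: cell (i, j) at j * nrow + i
  // prefix sums of accessibility; deletion opening for span s..e (1-based)
  std::vector<double> pre(n + 1, 0.0);
  for (int i = 1; i <= n; ++i) pre[i] = pre[i - 1] + acc[i - 1];
  // pen[e * (n+1) + s] for spans of length <= cap
  std::vector<double> pen((size_t)(n + 1) * (n + 1), 0.0);
  for (int e = 1; e <= n; ++e)
    for (int s = std::max(1, e - cap + 1); s <= e; ++s)
      pen[(size_t)e * (n + 1) + s] =
          beta * std::exp(-alpha * (pre[e] - pre[s - 1]) / (e - s + 1));

  std::vector<double> M((size_t)nrow * (m + 1), NEG), D((size_t)nrow * (m + 1), NEG),
      I((size_t)nrow * (m + 1), NEG);
  std::vector<signed char> pM(M.size(), -1), pI(M.size(), -1),
      pDs(M.size(), -1); // base state of the deletion run (0=M, 2=I)
  std::vector<int> pDk(M.size(), -1); // run start - 1 (template index)
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    if (free_ends) {
      D[i] = 0.0; pDk[i] = 0; pDs[i] = 0;
    } else if (i <= cap) {
      D[i] = -(pen[(size_t)i * (n + 1) + 1] + ext * (i - 1));
      pDk[i] = 0; pDs[i] = 0;
    }
  }
  for (int j = 1; j <= m; ++j) {
    I[(size_t)j * nrow] = free_ends ? 0.0 : -(open_ins[0] + ext * (j - 1));
    pI[(size_t)j * nrow] = (j == 1) ? 0 : 2;
  }
  for (int j = 1; j <= m; ++j) {
    size_t col = (size_t)j * nrow, prev = (size_t)(j - 1) * nrow;
    for (int i = 1; i <= n; ++i) {
      size_t c = col + i, d = prev + (i - 1);
      double vm = M[d]; signed char sm_ = 0;
      if (D[d] > vm) { vm = D[d]; sm_ = 1; }
      if (I[d] > vm) { vm = I[d]; sm_ = 2; }
      M[c] = vm + sm(a[i - 1] - 1, b[j - 1] - 1);
      pM[c] = sm_;
      // I: prefer continue > from M > from D; opening charged at position i
      size_t l = prev + i;
      double vi = I[l] - ext; signed char si = 2;
      if (M[l] - open_ins[i] > vi) { vi = M[l] - open_ins[i]; si = 0; }
      if (D[l] - open_ins[i] > vi) { vi = D[l] - open_ins[i]; si = 1; }
      I[c] = vi; pI[c] = si;
      // D: maximal run over spans k+1..i; prefer longest span (smallest k),
      // base M over I; a run may not follow another deletion run.
      double vd = NEG; int bk = -1; signed char bs = -1;
      const double *pr = &pen[(size_t)i * (n + 1)];
      for (int k = std::max(0, i - cap); k <= i - 1; ++k) {
        double base = M[col + k]; signed char st = 0;
        if (I[col + k] > base) { base = I[col + k]; st = 2; }
        double cand = base - pr[k + 1] - ext * (i - k - 1);
        if (cand > vd) { vd = cand; bk = k; bs = st; }
      }
      D[c] = vd; pDk[c] = bk; pDs[c] = bs;
    }
  }
  double best; int ci, cj, cs;
  pick_end(n, m, free_ends, M, D, I, 1, nrow, best, ci, cj, cs);
  Trace tr;
  for (int i = n; i > ci; --i) push_col(tr, i, 0);
  for (int j = m; j > cj; --j) push_col(tr, 0, j);
  int i = ci, j = cj, s = cs;
  while (i > 0 || j > 0) {
    size_t c = (size_t)j * nrow + i;
    if (s == 0) {
      push_col(tr, i, j); s = pM[c]; --i; --j;
    } else if (s == 1) {
      int k = pDk[c]; signed char bs = pDs[c];
      for (int t = i; t > k; --t) push_col(tr, t, 0);
      i = k; s = bs;
      if (i == 0 && j == 0) break;
    } else {
      push_col(tr, 0, j); s = pI[c]; --j;
      if (i == 0 && j == 0) break;
      if (i == 0 && free_ends && j > 0 && s != 2) {
        while (j > 0) { push_col(tr, 0, j); --j; }
        break;
      }
    }
  }
  return finish(tr, best);
}
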