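#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Sliding-window extremum along each column (van Herk-Gil-Werman, O(n) per
// column independent of window width). Input must already be padded; output
// has nrow(m) - w + 1 rows.
// [[Rcpp::export]]
NumericMatrix cpp_runext_cols(NumericMatrix m, int w, bool maximum) {
  int nr = m.nrow(), nc = m.ncol();
  if (w < 1 || w > nr) stop("window width out of range");
  int outr = nr - w + 1;
  NumericMatrix out(outr, nc);
  std::vector<double> pre(nr), suf(nr);
  for (int j = 0; j < nc; ++j) {
    const double* x = &m(0, j);
    for (int b = 0; b < nr; b += w) {
      int e = std::min(b + w, nr);
      pre[b] = x[b];
      for (int i = b + 1; i < e; ++i)
        pre[i] = maximum ? std::max(pre[i - 1], x[i]) : std::min(pre[i - 1], x[i]);
      suf[e - 1] = x[e - 1];
      for (int i = e - 2; i >= b; --i)
        suf[i] = maximum ? std::max(suf[i + 1], x[i]) : std::min(suf[i + 1], x[i]);
    }
    for (int i = 0; i < outr; ++i) {
      double a = suf[i], b2 = pre[i + w - 1];
      out(i, j) = maximum ? std::max(a, b2) : std::min(a, b2);
    }
  }
  return out;
}

// Sliding-window sum along each column of a padded matrix; output has
// nrow(m) - w + 1 rows. Exact for integer-valued input (sums stay < 2^53).
// [[Rcpp::export]]
NumericMatrix cpp_runsum_cols(NumericMatrix m, int w) {
  int nr = m.nrow(), nc = m.ncol();
  if (w < 1 || w > nr) stop("window width out of range");
  int outr = nr - w + 1;
  NumericMatrix out(outr, nc);
  for (int j = 0; j < nc; ++j) {
    const double* x = &m(0, j);
    double s = 0.0;
    for (int i = 0; i < w; ++i) s += x[i];
    out(0, j) = s;
    for (int i = 1; i < outr; ++i) {
      s += x[i + w - 1] - x[i - 1];
      out(i, j) = s;
    }
  }
  return out;
}

// Valid 1-D convolution along each column; output nrow(m) - len(k) + 1 rows.
// [[Rcpp::export]]
NumericMatrix cpp_conv_cols(NumericMatrix m, NumericVector k) {
  int nr = m.nrow(), nc = m.ncol(), nk = k.size();
  if (nk < 1 || nk > nr) stop("kernel length out of range");
  int outr = nr - nk + 1;
  NumericMatrix out(outr, nc);
  for (int j = 0; j < nc; ++j) {
    const double* x = &m(0, j);
    for (int i = 0; i < outr; ++i) {
      double s = 0.0;
      for (int q = 0; q < nk; ++q) s += x[i + q] * k[q];
      out(i, j) = s;
    }
  }
  return out;
}

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// 8-connected component labelling of a {0,1} matrix (1 = foreground).
// Labels are compact positive integers; caller relabels into raster order.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix obj) {
  int nr = obj.nrow(), nc = obj.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(1024);
  // first pass, column-major scan; provisional labels are 1-based
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!obj(i, j)) continue;
      int best = -1;
      int cand[4][2] = {{i - 1, j}, {i - 1, j - 1}, {i, j - 1}, {i + 1, j - 1}};
      for (int q = 0; q < 4; ++q) {
        int r = cand[q][0], c = cand[q][1];
        if (r < 0 || r >= nr || c < 0) continue;
        int l = lab(r, c);
        if (l > 0) {
          int root = uf_find(parent, l - 1);
          if (best < 0) best = root;
          else if (root != best) parent[root] = uf_find(parent, best);
        }
      }
      if (best < 0) {
        parent.push_back((int)parent.size());
        lab(i, j) = (int)parent.size();
      } else {
        lab(i, j) = uf_find(parent, best) + 1;
      }
    }
  }
  // compress and map to consecutive ids
  std::vector<int> newid(parent.size(), 0);
  int nlab = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0) {
        int root = uf_find(parent, lab(i, j) - 1);
        if (newid[root] == 0) newid[root] = ++nlab;
        lab(i, j) = newid[root];
      }
  return lab;
}
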