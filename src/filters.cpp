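#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Window offsets: size w spans [-((w-1)/2), w/2] around the anchor, so an
// even window places its extra row/column toward larger indices. Windows are
// clipped at the image boundary everywhere below.

static inline void win_bounds(int c, int w, int n, int& lo, int& hi) {
  lo = c - (w - 1) / 2;
  hi = c + w / 2;
  if (lo < 0) lo = 0;
  if (hi > n - 1) hi = n - 1;
}

// [[Rcpp::export(name = ".cpp_find_extrema")]]
List cpp_find_extrema(NumericMatrix x, int window) {
  int H = x.nrow(), W = x.ncol();
  LogicalMatrix mx(H, W), mn(H, W);
  for (int j = 0; j < W; ++j) {
    int jlo, jhi;
    win_bounds(j, window, W, jlo, jhi);
    for (int i = 0; i < H; ++i) {
      int ilo, ihi;
      win_bounds(i, window, H, ilo, ihi);
      double v = x(i, j);
      bool isMax = true, isMin = true;
      for (int jj = jlo; jj <= jhi && (isMax || isMin); ++jj)
        for (int ii = ilo; ii <= ihi; ++ii) {
          if (ii == i && jj == j) continue;
          double u = x(ii, jj);
          if (u >= v) isMax = false;
          if (u <= v) isMin = false;
          if (!isMax && !isMin) break;
        }
      mx(i, j) = isMax;
      mn(i, j) = isMin;
    }
  }
  return List::create(_["maxima"] = mx, _["minima"] = mn);
}

// Separable order-statistics filter: a clipped square window is a product of
// clipped row/column intervals, so max/min commute with the two 1D passes.
static NumericMatrix os_filter(const NumericMatrix& x, int w, bool take_max) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix tmp(H, W), out(H, W);
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      int lo, hi;
      win_bounds(j, w, W, lo, hi);
      double v = x(i, lo);
      for (int jj = lo + 1; jj <= hi; ++jj) {
        double u = x(i, jj);
        if (take_max ? (u > v) : (u < v)) v = u;
      }
      tmp(i, j) = v;
    }
  }
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int lo, hi;
      win_bounds(i, w, H, lo, hi);
      double v = tmp(lo, j);
      for (int ii = lo + 1; ii <= hi; ++ii) {
        double u = tmp(ii, j);
        if (take_max ? (u > v) : (u < v)) v = u;
      }
      out(i, j) = v;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_max_filter")]]
NumericMatrix cpp_max_filter(NumericMatrix x, int w) { return os_filter(x, w, true); }

// [[Rcpp::export(name = ".cpp_min_filter")]]
NumericMatrix cpp_min_filter(NumericMatrix x, int w) { return os_filter(x, w, false); }

// Arithmetic-mean filter; the divisor is the clipped window pixel count so a
// constant image is a fixed point. Summed-area table keeps it O(HW).
// [[Rcpp::export(name = ".cpp_mean_filter")]]
NumericMatrix cpp_mean_filter(NumericMatrix x, int w) {
  int H = x.nrow(), W = x.ncol();
  std::vector<double> sat((H + 1) * (W + 1), 0.0);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      sat[(i + 1) + (j + 1) * (H + 1)] = x(i, j) +
        sat[i + (j + 1) * (H + 1)] + sat[(i + 1) + j * (H + 1)] -
        sat[i + j * (H + 1)];
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    int jlo, jhi;
    win_bounds(j, w, W, jlo, jhi);
    for (int i = 0; i < H; ++i) {
      int ilo, ihi;
      win_bounds(i, w, H, ilo, ihi);
      double s = sat[(ihi + 1) + (jhi + 1) * (H + 1)] -
                 sat[ilo + (jhi + 1) * (H + 1)] -
                 sat[(ihi + 1) + jlo * (H + 1)] +
                 sat[ilo + jlo * (H + 1)];
      out(i, j) = s / ((ihi - ilo + 1) * (jhi - jlo + 1));
    }
  }
  return out;
}

// Nearest-other-point Euclidean distance per point (adjacent-extrema vector).
// [[Rcpp::export(name = ".cpp_adjacent_distances")]]
NumericVector cpp_adjacent_distances(NumericMatrix pts) {
  int n = pts.nrow();
  NumericVector d(n);
  for (int i = 0; i < n; ++i) {
    double best = DBL_MAX;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dr = pts(i, 0) - pts(j, 0), dc = pts(i, 1) - pts(j, 1);
      double dd = dr * dr + dc * dc;
      if (dd < best) best = dd;
    }
    d[i] = std::sqrt(best);
  }
  return d;
}
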