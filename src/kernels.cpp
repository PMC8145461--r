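#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Nearest-neighbour Euclidean distances from each row of `query` to the
// rows of `ref`, by branch-and-bound on one coordinate: ref is sorted along
// its widest axis, each query walks outward from its insertion point and
// stops once the sort-axis gap alone exceeds the best distance found.
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (nr == 0) stop("reference set is empty");
  int ax = 0;
  double best_ext = -1.0;
  for (int c = 0; c < 3; ++c) {
    double lo = R_PosInf, hi = R_NegInf;
    for (int i = 0; i < nr; ++i) {
      const double v = ref(i, c);
      if (v < lo) lo = v;
      if (v > hi) hi = v;
    }
    if (hi - lo > best_ext) { best_ext = hi - lo; ax = c; }
  }
  const int ay = (ax + 1) % 3, az = (ax + 2) % 3;
  std::vector<int> ord(nr);
  for (int i = 0; i < nr; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int i, int j) { return ref(i, ax) < ref(j, ax); });
  std::vector<double> rx(nr), ry(nr), rz(nr);
  for (int k = 0; k < nr; ++k) {
    rx[k] = ref(ord[k], ax);
    ry[k] = ref(ord[k], ay);
    rz[k] = ref(ord[k], az);
  }
  NumericVector out(nq);
  for (int q = 0; q < nq; ++q) {
    const double qx = query(q, ax), qy = query(q, ay), qz = query(q, az);
    int lo = static_cast<int>(
        std::lower_bound(rx.begin(), rx.end(), qx) - rx.begin());
    int hi = lo - 1;
    double best = R_PosInf;
    while (true) {
      const bool can_lo = lo < nr &&
        (rx[lo] - qx) * (rx[lo] - qx) < best;
      const bool can_hi = hi >= 0 &&
        (qx - rx[hi]) * (qx - rx[hi]) < best;
      if (!can_lo && !can_hi) break;
      int k;
      if (can_lo && (!can_hi || rx[lo] - qx <= qx - rx[hi])) k = lo++;
      else k = hi--;
      const double dx = rx[k] - qx, dy = ry[k] - qy, dz = rz[k] - qz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[q] = std::sqrt(best);
  }
  return out;
}

// Weighted mean cross-distance  sum_i sum_j wx_i wy_j |x_i - y_j|.
// [[Rcpp::export]]
double cpp_energy_cross(NumericMatrix X, NumericVector wx,
                        NumericMatrix Y, NumericVector wy) {
  const int n = X.nrow(), m = Y.nrow();
  if (n != wx.size() || m != wy.size()) stop("weight length mismatch");
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2), wi = wx[i];
    double row = 0.0;
    for (int j = 0; j < m; ++j) {
      const double dx = xi - Y(j, 0), dy = yi - Y(j, 1), dz = zi - Y(j, 2);
      row += wy[j] * std::sqrt(dx * dx + dy * dy + dz * dz);
    }
    acc += wi * row;
  }
  return acc;
}
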