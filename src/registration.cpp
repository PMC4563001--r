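// Compiled hot path of the registration: the weighted closest-point metric
// and the multi-resolution brute-force pose search (7 * 7^5 metric
// evaluations per candidate path with the default schedule).
//
// Conventions match the R side exactly: pose parameters ordered
// (alpha, beta, gamma, x, y), angles in degrees, rotation Rz(g)Ry(b)Rx(a)
// about a fixed rotation center, translation (x, y, 0) applied along the
// detector axes. All matrices row-major.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static inline void mat4_mult(const double* A, const double* B, double* C) {
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      double s = 0.0;
      for (int k = 0; k < 4; ++k) s += A[4 * i + k] * B[4 * k + j];
      C[4 * i + j] = s;
    }
}

// Rotation matrix Rz(g) Ry(b) Rx(a), angles in degrees.
static void euler_zyx(double a_deg, double b_deg, double g_deg, double* R) {
  const double d2r = M_PI / 180.0;
  double a = a_deg * d2r, b = b_deg * d2r, g = g_deg * d2r;
  double ca = std::cos(a), sa = std::sin(a);
  double cb = std::cos(b), sb = std::sin(b);
  double cg = std::cos(g), sg = std::sin(g);
  // Rz * Ry * Rx
  R[0] = cg * cb; R[1] = cg * sb * sa - sg * ca; R[2] = cg * sb * ca + sg * sa;
  R[3] = sg * cb; R[4] = sg * sb * sa + cg * ca; R[5] = sg * sb * ca - cg * sa;
  R[6] = -sb;     R[7] = cb * sa;                R[8] = cb * ca;
}

// T_rot = Trans(c) . R . Trans(-c) as a 4x4.
static void rotation_about(const double* R, const double* c, double* T) {
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) T[4 * i + j] = R[3 * i + j];
    T[4 * i + 3] = c[i] - (R[3 * i] * c[0] + R[3 * i + 1] * c[1] +
                           R[3 * i + 2] * c[2]);
  }
  T[12] = T[13] = T[14] = 0.0; T[15] = 1.0;
}

struct MetricWorkspace {
  std::vector<double> px, py, arc;
};

// Closest point on the linearly interpolated projected centerline,
// restricted to the arc interval [lo, hi]. seg_hint: index of a segment at
// or before the one containing lo. Writes the matched arc and segment
// index; returns the squared distance.
static double curve_search(const std::vector<double>& px,
                           const std::vector<double>& py,
                           const std::vector<double>& arc, int np,
                           double cx, double cy, double lo, double hi,
                           int seg_hint, double* best_arc, int* best_seg) {
  double bd = std::numeric_limits<double>::infinity();
  if (np == 1) {
    double dx = px[0] - cx, dy = py[0] - cy;
    *best_arc = 0.0; *best_seg = 0;
    return dx * dx + dy * dy;
  }
  int j = seg_hint;
  while (j > 0 && arc[j] > lo) --j;
  while (j + 1 < np - 1 && arc[j + 1] < lo) ++j;
  for (; j < np - 1 && arc[j] <= hi; ++j) {
    double len = arc[j + 1] - arc[j];
    double ax = px[j], ay = py[j];
    double dx = px[j + 1] - ax, dy = py[j + 1] - ay;
    double t;
    if (len <= 1e-12) {
      t = 0.0;
    } else {
      t = ((cx - ax) * dx + (cy - ay) * dy) / (len * len);
      double tlo = (lo - arc[j]) / len, thi = (hi - arc[j]) / len;
      if (tlo < 0.0) tlo = 0.0;
      if (thi > 1.0) thi = 1.0;
      if (tlo > thi) continue;
      if (t < tlo) t = tlo;
      if (t > thi) t = thi;
    }
    double qx = ax + t * dx - cx, qy = ay + t * dy - cy;
    double d2 = qx * qx + qy * qy;
    if (d2 < bd) {
      bd = d2;
      *best_arc = arc[j] + t * len;
      *best_seg = j;
    }
  }
  return bd;
}

// Weighted closest-point metric for one 3x4 projective chain M (row-major).
// Catheter points are matched to the linearly interpolated projected
// centerline; the window for point i starts at the arc of the previous
// match and extends d_max mm root-ward. Returns +Inf when any path point
// projects at or behind the source. match (optional) receives the 1-based
// index of the path vertex starting the matched segment.
static double eval_metric(const double* M,
                          const double* cx, const double* cy,
                          const double* w, int nc,
                          const double* p3, int np,
                          double dmax,
                          MetricWorkspace& ws,
                          int* match = nullptr) {
  ws.px.resize(np); ws.py.resize(np); ws.arc.resize(np);
  for (int j = 0; j < np; ++j) {
    const double* p = p3 + 3 * j;
    double u = M[0] * p[0] + M[1] * p[1] + M[2] * p[2] + M[3];
    double v = M[4] * p[0] + M[5] * p[1] + M[6] * p[2] + M[7];
    double d = M[8] * p[0] + M[9] * p[1] + M[10] * p[2] + M[11];
    if (d <= 1e-9) return std::numeric_limits<double>::infinity();
    ws.px[j] = u / d;
    ws.py[j] = v / d;
  }
  ws.arc[0] = 0.0;
  for (int j = 1; j < np; ++j) {
    double dx = ws.px[j] - ws.px[j - 1], dy = ws.py[j] - ws.py[j - 1];
    ws.arc[j] = ws.arc[j - 1] + std::sqrt(dx * dx + dy * dy);
  }
  double total = ws.arc[np - 1];
  // tip term: unrestricted minimum over the whole projected centerline
  double anchor_arc = 0.0;
  int anchor_seg = 0;
  double d2 = curve_search(ws.px, ws.py, ws.arc, np, cx[0], cy[0],
                           0.0, total, 0, &anchor_arc, &anchor_seg);
  double m = std::sqrt(d2);
  if (match) match[0] = anchor_seg + 1;
  for (int i = 1; i < nc; ++i) {
    double hi = anchor_arc + dmax;
    if (hi > total) hi = total;
    d2 = curve_search(ws.px, ws.py, ws.arc, np, cx[i], cy[i],
                      anchor_arc, hi, anchor_seg, &anchor_arc, &anchor_seg);
    m += w[i] * std::sqrt(d2);
    if (match) match[i] = anchor_seg + 1;
  }
  return m;
}

static void column_copy(const NumericMatrix& m, std::vector<double>& x,
                        std::vector<double>& y) {
  int n = m.nrow();
  x.resize(n); y.resize(n);
  for (int i = 0; i < n; ++i) { x[i] = m(i, 0); y[i] = m(i, 1); }
}

static std::vector<double> path_rowmajor(const NumericMatrix& path) {
  int np = path.nrow();
  std::vector<double> p3(3 * np);
  for (int j = 0; j < np; ++j) {
    p3[3 * j] = path(j, 0); p3[3 * j + 1] = path(j, 1);
    p3[3 * j + 2] = path(j, 2);
  }
  return p3;
}

static std::vector<double> tip_weights(const NumericVector& carc,
                                       double lambda, double sigma) {
  int nc = carc.size();
  std::vector<double> w(nc, 1.0);
  for (int i = 1; i < nc; ++i) {
    double x = carc[i];
    w[i] = lambda + (1.0 - lambda) * std::exp(-x * x / (2.0 * sigma * sigma));
  }
  return w;
}

// [[Rcpp::export]]
List cpp_metric(NumericMatrix cath, NumericVector cath_arc,
                NumericMatrix path, NumericMatrix m34,
                double lambda, double sigma, double d_max) {
  int nc = cath.nrow(), np = path.nrow();
  if (nc < 1 || np < 1) stop("empty catheter or path");
  std::vector<double> cx, cy;
  column_copy(cath, cx, cy);
  std::vector<double> p3 = path_rowmajor(path);
  std::vector<double> w = tip_weights(cath_arc, lambda, sigma);
  double M[12];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 4; ++j) M[4 * i + j] = m34(i, j);
  MetricWorkspace ws;
  IntegerVector match(nc);
  double value = eval_metric(M, cx.data(), cy.data(), w.data(), nc,
                             p3.data(), np, d_max, ws, INTEGER(match));
  return List::create(_["metric"] = value, _["match"] = match);
}

// Multi-resolution grid search over (alpha, beta, gamma, x, y).
// tproj: 3x4 cone-beam matrix; tdetw: 4x4 detector-from-world. The full
// projective chain for a pose is
//   M = T_proj . T_trans(x, y) . T_det<-w . T_rot(angles, center)
// evaluated as M = C0 + (x tp1 + y tp2) (x) B_row4, with B = T_det<-w T_rot
// and C0 = T_proj B, so the per-(x, y) cost is a rank-one update.
// [[Rcpp::export]]
List cpp_brute_force(NumericMatrix cath, NumericVector cath_arc,
                     NumericMatrix path,
                     NumericMatrix tproj, NumericMatrix tdetw,
                     NumericVector center0, NumericVector half0,
                     int n_iter, double shrink, int d,
                     double lambda, double sigma, double d_max,
                     NumericVector rot_center) {
  int nc = cath.nrow(), np = path.nrow();
  if (nc < 1 || np < 1) stop("empty catheter or path");
  if (d < 2 || d % 2 == 0) stop("steps per dimension must be odd and >= 3");
  std::vector<double> cx, cy;
  column_copy(cath, cx, cy);
  std::vector<double> p3 = path_rowmajor(path);
  std::vector<double> w = tip_weights(cath_arc, lambda, sigma);
  double TP[12];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 4; ++j) TP[4 * i + j] = tproj(i, j);
  double TD[16];
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) TD[4 * i + j] = tdetw(i, j);
  double cc[3] = { rot_center[0], rot_center[1], rot_center[2] };

  std::vector<double> center(center0.begin(), center0.end());
  std::vector<double> s(half0.begin(), half0.end());
  std::vector<double> best_par = center;
  double best_val = std::numeric_limits<double>::infinity();
  NumericVector trace(n_iter);
  long long n_eval = 0;
  MetricWorkspace ws;

  std::vector<double> off(d);
  for (int iter = 0; iter < n_iter; ++iter) {
    std::vector<double> c_it = (iter == 0) ? center : best_par;
    std::vector<std::vector<double>> vals(5, std::vector<double>(d));
    for (int dim = 0; dim < 5; ++dim)
      for (int k = 0; k < d; ++k)
        vals[dim][k] = c_it[dim] - s[dim] + 2.0 * s[dim] * k / (d - 1);
    for (int ia = 0; ia < d; ++ia)
      for (int ib = 0; ib < d; ++ib)
        for (int ig = 0; ig < d; ++ig) {
          double R[9], TR[16], B[16];
          euler_zyx(vals[0][ia], vals[1][ib], vals[2][ig], R);
          rotation_about(R, cc, TR);
          mat4_mult(TD, TR, B);
          double C0[12];
          for (int i = 0; i < 3; ++i)
            for (int j = 0; j < 4; ++j) {
              double acc = 0.0;
              for (int k = 0; k < 4; ++k) acc += TP[4 * i + k] * B[4 * k + j];
              C0[4 * i + j] = acc;
            }
          const double* brow4 = B + 12;  // (0, 0, 0, 1): bottom row of B
          for (int ix = 0; ix < d; ++ix)
            for (int iy = 0; iy < d; ++iy) {
              double x = vals[3][ix], y = vals[4][iy];
              double v0 = x * TP[0] + y * TP[1];
              double v1 = x * TP[4] + y * TP[5];
              double v2 = x * TP[8] + y * TP[9];
              double M[12];
              for (int j = 0; j < 4; ++j) {
                M[j] = C0[j] + v0 * brow4[j];
                M[4 + j] = C0[4 + j] + v1 * brow4[j];
                M[8 + j] = C0[8 + j] + v2 * brow4[j];
              }
              double val = eval_metric(M, cx.data(), cy.data(), w.data(), nc,
                                       p3.data(), np, d_max, ws);
              ++n_eval;
              if (val < best_val) {
                best_val = val;
                best_par[0] = vals[0][ia]; best_par[1] = vals[1][ib];
                best_par[2] = vals[2][ig]; best_par[3] = x; best_par[4] = y;
              }
            }
        }
    trace[iter] = best_val;
    for (int dim = 0; dim < 5; ++dim) s[dim] *= shrink;
  }
  return List::create(_["params"] = NumericVector(best_par.begin(), best_par.end()),
                      _["metric"] = best_val,
                      _["trace"] = trace,
                      _["n_evaluations"] = (double)n_eval);
}
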