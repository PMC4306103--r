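#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Minimizer of  f(x) = l2*(x - u)^2 + l3 * sum_k |x - n_k|
// over the m neighbor values in cand[0..m).  Closed form: the median of the
// neighbors unioned with the m+1 data candidates u + (2k - m)*l3/(2*l2),
// k = 0..m (spacing l3/l2, endpoints u -+ m*l3/(2*l2)).
// cand must have room for 2m+1 doubles.
static inline double prox_median_one(double *cand, int m,
                                     double u, double l2, double l3) {
  const double step = l3 / l2;
  const double lo = u - 0.5 * m * step;
  for (int k = 0; k <= m; ++k) cand[m + k] = lo + k * step;
  // 2m+1 values: median is the (m+1)-th smallest (0-based index m)
  std::nth_element(cand, cand + m, cand + 2 * m + 1);
  return cand[m];
}

// Vectorized proximal median: one instance per row of `nbrs`.
// [[Rcpp::export]]
NumericVector cpp_prox_median(NumericVector u, NumericMatrix nbrs,
                              NumericVector l2, NumericVector l3) {
  const int n = u.size(), m = nbrs.ncol();
  NumericVector out(n);
  std::vector<double> cand(2 * m + 1);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < m; ++k) cand[k] = nbrs(i, k);
    const double a2 = l2[i % l2.size()], a3 = l3[i % l3.size()];
    out[i] = prox_median_one(cand.data(), m, u[i], a2, a3);
  }
  return out;
}

// One Jacobi sweep of the auxiliary-field median update over the whole grid.
// Neighborhood: (2*radius+1)^2 window minus the center, truncated at borders.
// [[Rcpp::export]]
List cpp_median_sweep(NumericMatrix au, NumericMatrix av,
                      NumericMatrix u, NumericMatrix v,
                      double l2, double l3, int radius) {
  const int h = au.nrow(), w = au.ncol();
  NumericMatrix nuM(h, w), nvM(h, w);
  const double *pau = au.begin(), *pav = av.begin();
  const double *pu = u.begin(), *pv = v.begin();
  double *pnu = nuM.begin(), *pnv = nvM.begin();
  const int wsz = 2 * radius + 1;
  std::vector<double> cand(2 * wsz * wsz + 1);
  for (int j = 0; j < w; ++j) {
    const int j0 = std::max(0, j - radius), j1 = std::min(w - 1, j + radius);
    for (int i = 0; i < h; ++i) {
      const int i0 = std::max(0, i - radius), i1 = std::min(h - 1, i + radius);
      const int c = j * h + i;
      int m = 0;
      for (int jj = j0; jj <= j1; ++jj) {
        const int off = jj * h;
        for (int ii = i0; ii <= i1; ++ii)
          if (ii != i || jj != j) cand[m++] = pau[off + ii];
      }
      pnu[c] = prox_median_one(cand.data(), m, pu[c], l2, l3);
      m = 0;
      for (int jj = j0; jj <= j1; ++jj) {
        const int off = jj * h;
        for (int ii = i0; ii <= i1; ++ii)
          if (ii != i || jj != j) cand[m++] = pav[off + ii];
      }
      pnv[c] = prox_median_one(cand.data(), m, pv[c], l2, l3);
    }
  }
  return List::create(_["u_hat"] = nuM, _["v_hat"] = nvM);
}

// Nonlocal L1 term of the coupled objective, as written:
// sum_{(i,j)} sum_{(i',j') in N_{i,j}} |au_{i,j}-au_{i',j'}| + |av_...|
// (each unordered pair counted twice; windows truncated at borders).
// [[Rcpp::export]]
double cpp_nonlocal_l1(NumericMatrix au, NumericMatrix av, int radius) {
  const int h = au.nrow(), w = au.ncol();
  const double *pau = au.begin(), *pav = av.begin();
  double s = 0.0;
  for (int j = 0; j < w; ++j) {
    const int j0 = std::max(0, j - radius), j1 = std::min(w - 1, j + radius);
    for (int i = 0; i < h; ++i) {
      const int i0 = std::max(0, i - radius), i1 = std::min(h - 1, i + radius);
      const double cu = pau[j * h + i], cv = pav[j * h + i];
      for (int jj = j0; jj <= j1; ++jj) {
        const int off = jj * h;
        for (int ii = i0; ii <= i1; ++ii) {
          if (ii == i && jj == j) continue;
          s += std::abs(cu - pau[off + ii]) + std::abs(cv - pav[off + ii]);
        }
      }
    }
  }
  return s;
}

// Gauss-Seidel / SOR sweeps for the linearized flow subproblem.
// Per-pixel 2x2 solve of the normal equations of
//   sum wD*(It + Ix*(U-u0) + Iy*(V-v0))^2
//   + l1 * sum_pairs [wsu*(dU)^2 + wsv*(dV)^2]
//   + l2 * ((U-au)^2 + (V-av)^2)
// Pair weights are stored at the lower-index pixel of each forward pair
// (wsu_h(i,j): pair (i,j)-(i,j+1); wsu_v(i,j): pair (i,j)-(i+1,j)).
// U and V are modified in place.
// [[Rcpp::export]]
void cpp_sor_flow(NumericMatrix Ix, NumericMatrix Iy, NumericMatrix It,
                  NumericMatrix wD,
                  NumericMatrix u0, NumericMatrix v0,
                  NumericMatrix au, NumericMatrix av,
                  NumericMatrix U, NumericMatrix V,
                  NumericMatrix wsu_h, NumericMatrix wsu_v,
                  NumericMatrix wsv_h, NumericMatrix wsv_v,
                  double l1, double l2, int iters, double omega) {
  const int h = U.nrow(), w = U.ncol();
  const double *pIx = Ix.begin(), *pIy = Iy.begin(), *pIt = It.begin();
  const double *pwD = wD.begin(), *pu0 = u0.begin(), *pv0 = v0.begin();
  const double *pau = au.begin(), *pav = av.begin();
  const double *puh = wsu_h.begin(), *puv = wsu_v.begin();
  const double *pvh = wsv_h.begin(), *pvv = wsv_v.begin();
  double *pU = U.begin(), *pV = V.begin();
  for (int it = 0; it < iters; ++it) {
    for (int j = 0; j < w; ++j) {
      const int col = j * h;
      for (int i = 0; i < h; ++i) {
        const int c = col + i;
        double swu = 0.0, swv = 0.0, ssu = 0.0, ssv = 0.0;
        if (j > 0) {
          const int cl = c - h;
          swu += puh[cl]; ssu += puh[cl] * pU[cl];
          swv += pvh[cl]; ssv += pvh[cl] * pV[cl];
        }
        if (j < w - 1) {
          swu += puh[c]; ssu += puh[c] * pU[c + h];
          swv += pvh[c]; ssv += pvh[c] * pV[c + h];
        }
        if (i > 0) {
          const int cu = c - 1;
          swu += puv[cu]; ssu += puv[cu] * pU[cu];
          swv += pvv[cu]; ssv += pvv[cu] * pV[cu];
        }
        if (i < h - 1) {
          swu += puv[c]; ssu += puv[c] * pU[c + 1];
          swv += pvv[c]; ssv += pvv[c] * pV[c + 1];
        }
        const double wd = pwD[c], ix = pIx[c], iy = pIy[c];
        const double rc = wd * (ix * pu0[c] + iy * pv0[c] - pIt[c]);
        const double A11 = wd * ix * ix + l2 + l1 * swu;
        const double A22 = wd * iy * iy + l2 + l1 * swv;
        const double A12 = wd * ix * iy;
        const double b1 = ix * rc + l2 * pau[c] + l1 * ssu;
        const double b2 = iy * rc + l2 * pav[c] + l1 * ssv;
        const double det = A11 * A22 - A12 * A12;
        const double un = (A22 * b1 - A12 * b2) / det;
        const double vn = (A11 * b2 - A12 * b1) / det;
        pU[c] += omega * (un - pU[c]);
        pV[c] += omega * (vn - pV[c]);
      }
    }
  }
}

// Bilinear sampling of img at (xs, ys) (1-based continuous coordinates),
// border-replicated; `outside` is set to 1 where the sample fell off-grid.
// [[Rcpp::export]]
List cpp_bilinear(NumericMatrix img, NumericMatrix xs, NumericMatrix ys) {
  const int h = img.nrow(), w = img.ncol();
  const int n = xs.size();
  NumericMatrix out(xs.nrow(), xs.ncol());
  IntegerMatrix outside(xs.nrow(), xs.ncol());
  const double *pim = img.begin(), *px = xs.begin(), *py = ys.begin();
  double *po = out.begin();
  int *pout = outside.begin();
  for (int c = 0; c < n; ++c) {
    double x = px[c], y = py[c];
    const bool off = (x < 1 || x > w || y < 1 || y > h);
    if (x < 1) x = 1; else if (x > w) x = w;
    if (y < 1) y = 1; else if (y > h) y = h;
    int x0 = (int)x; if (x0 > w - 1) x0 = w - 1;
    int y0 = (int)y; if (y0 > h - 1) y0 = h - 1;
    const double fx = x - x0, fy = y - y0;
    const int c00 = (x0 - 1) * h + (y0 - 1);
    po[c] = (1 - fx) * (1 - fy) * pim[c00] + fx * (1 - fy) * pim[c00 + h] +
            (1 - fx) * fy * pim[c00 + 1] + fx * fy * pim[c00 + h + 1];
    pout[c] = off ? 1 : 0;
  }
  return List::create(_["value"] = out, _["outside"] = outside);
}

// Penalty sums for the energy evaluations: sum of the GNC-blended penalty
// (1-alpha)*x^2 + alpha*(x^2 + eps^2)^a over a vector.
// [[Rcpp::export]]
double cpp_rho_sum(NumericVector x, double alpha, double a, double eps) {
  const int n = x.size();
  const double e2 = eps * eps;
  double s = 0.0;
  if (alpha <= 0) {
    for (int i = 0; i < n; ++i) s += x[i] * x[i];
  } else if (alpha >= 1) {
    for (int i = 0; i < n; ++i) s += std::pow(x[i] * x[i] + e2, a);
  } else {
    for (int i = 0; i < n; ++i) {
      const double q = x[i] * x[i];
      s += (1 - alpha) * q + alpha * std::pow(q + e2, a);
    }
  }
  return s;
}
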