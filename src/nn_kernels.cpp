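#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Dense kernels for the point-set network hot path. Matrix products run
// through R's BLAS; these cover the memory-bound pieces (normalization,
// gathers, pooling) where interpreted elementwise code dominates.

// Batch normalization forward (training mode): per-column standardization
// over all rows + shared affine. Returns pre-activation A (before ReLU),
// the standardized xhat, the standard deviations and the raw batch moments
// (for the running statistics used at evaluation time).
// [[Rcpp::export]]
List cpp_bn_forward(NumericMatrix Z, NumericVector gamma, NumericVector beta,
                    double eps) {
  const int n = Z.nrow(), w = Z.ncol();
  NumericMatrix A(n, w), xhat(n, w);
  NumericVector sg(w), mean(w), var(w);
  for (int j = 0; j < w; ++j) {
    const double *z = &Z(0, j);
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) { s += z[i]; s2 += z[i] * z[i]; }
    const double mu = s / n;
    const double v = s2 / n - mu * mu;
    const double sd = std::sqrt(v + eps);
    mean[j] = mu;
    var[j] = v;
    sg[j] = sd;
    const double g = gamma[j], b = beta[j], inv = 1.0 / sd;
    double *xh = &xhat(0, j);
    double *a = &A(0, j);
    for (int i = 0; i < n; ++i) {
      xh[i] = (z[i] - mu) * inv;
      a[i] = g * xh[i] + b;
    }
  }
  return List::create(_["A"] = A, _["xhat"] = xhat, _["sg"] = sg,
                      _["mean"] = mean, _["var"] = var);
}

// Batch normalization with frozen (running) statistics: evaluation mode.
// [[Rcpp::export]]
NumericMatrix cpp_bn_eval(NumericMatrix Z, NumericVector gamma,
                          NumericVector beta, NumericVector mean,
                          NumericVector var, double eps) {
  const int n = Z.nrow(), w = Z.ncol();
  NumericMatrix A(n, w);
  for (int j = 0; j < w; ++j) {
    const double *z = &Z(0, j);
    double *a = &A(0, j);
    const double inv = gamma[j] / std::sqrt(var[j] + eps);
    const double b = beta[j] - mean[j] * inv;
    for (int i = 0; i < n; ++i) a[i] = z[i] * inv + b;
  }
  return A;
}

// Batch normalization backward. dH must already be masked by the ReLU
// derivative. Returns dZ plus the affine parameter gradients.
// [[Rcpp::export]]
List cpp_bn_backward(NumericMatrix dH, NumericMatrix xhat, NumericVector sg,
                     NumericVector gamma) {
  const int n = dH.nrow(), w = dH.ncol();
  NumericMatrix dZ(n, w);
  NumericVector dgamma(w), dbeta(w);
  for (int j = 0; j < w; ++j) {
    const double *dh = &dH(0, j);
    const double *xh = &xhat(0, j);
    double sdh = 0.0, sdhx = 0.0;
    for (int i = 0; i < n; ++i) {
      sdh += dh[i];
      sdhx += dh[i] * xh[i];
    }
    dgamma[j] = sdhx;
    dbeta[j] = sdh;
    const double g = gamma[j];
    const double m_dxhat = g * sdh / n;
    const double m_dxhat_x = g * sdhx / n;
    const double inv = 1.0 / sg[j];
    double *dz = &dZ(0, j);
    for (int i = 0; i < n; ++i)
      dz[i] = (g * dh[i] - m_dxhat - xh[i] * m_dxhat_x) * inv;
  }
  return List::create(_["dZ"] = dZ, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Row gather: M[idx, ] with 1-based idx.
// [[Rcpp::export]]
NumericMatrix cpp_gather_rows(NumericMatrix M, IntegerVector idx) {
  const int m = idx.size(), w = M.ncol();
  NumericMatrix out(m, w);
  for (int j = 0; j < w; ++j) {
    const double *src = &M(0, j);
    double *dst = &out(0, j);
    for (int i = 0; i < m; ++i) dst[i] = src[idx[i] - 1];
  }
  return out;
}

// Gather + centroid-relative coordinates in one pass:
// out[(i-1)*g + r, ] = P[gi[(i-1)*g + r], ] - C[i, ].
// [[Rcpp::export]]
NumericMatrix cpp_group_rel(NumericMatrix P, IntegerVector gi,
                            NumericMatrix C, int g) {
  const int rows = gi.size(), w = P.ncol();
  NumericMatrix out(rows, w);
  for (int j = 0; j < w; ++j) {
    const double *src = &P(0, j);
    const double *cc = &C(0, j);
    double *dst = &out(0, j);
    for (int i = 0; i < rows; ++i)
      dst[i] = src[gi[i] - 1] - cc[i / g];
  }
  return out;
}

// Scatter-add rows of dX into an n_out-row accumulator by 1-based idx.
// [[Rcpp::export]]
NumericMatrix cpp_scatter_rows(NumericMatrix dX, IntegerVector idx, int n_out) {
  const int m = idx.size(), w = dX.ncol();
  NumericMatrix out(n_out, w);
  for (int j = 0; j < w; ++j) {
    const double *src = &dX(0, j);
    double *dst = &out(0, j);
    for (int i = 0; i < m; ++i) dst[idx[i] - 1] += src[i];
  }
  return out;
}

// Max over g consecutive rows per group; returns maxima and the winning
// replicate (1-based) per cell for gradient routing.
// [[Rcpp::export]]
List cpp_group_maxpool(NumericMatrix H, int g) {
  const int n = H.nrow(), w = H.ncol();
  const int m = n / g;
  NumericMatrix out(m, w);
  IntegerMatrix arg(m, w);
  for (int j = 0; j < w; ++j) {
    const double *h = &H(0, j);
    double *o = &out(0, j);
    int *a = &arg(0, j);
    for (int i = 0; i < m; ++i) {
      const double *blk = h + (size_t)i * g;
      double best = blk[0];
      int bi = 0;
      for (int r = 1; r < g; ++r)
        if (blk[r] > best) { best = blk[r]; bi = r; }
      o[i] = best;
      a[i] = bi + 1;
    }
  }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// Inverse of the pooling: route dOut[i, j] to row (i-1)*g + arg[i, j].
// [[Rcpp::export]]
NumericMatrix cpp_maxpool_backward(NumericMatrix dOut, IntegerMatrix arg,
                                   int g, int n_rows) {
  const int m = dOut.nrow(), w = dOut.ncol();
  NumericMatrix dH(n_rows, w);
  for (int j = 0; j < w; ++j) {
    const double *d = &dOut(0, j);
    const int *a = &arg(0, j);
    double *o = &dH(0, j);
    for (int i = 0; i < m; ++i)
      o[(size_t)i * g + (a[i] - 1)] += d[i];
  }
  return dH;
}

// ReLU derivative mask applied in place semantics: dH * (pre > 0).
// [[Rcpp::export]]
NumericMatrix cpp_relu_mask(NumericMatrix dH, NumericMatrix pre) {
  const int n = dH.nrow(), w = dH.ncol();
  NumericMatrix out(n, w);
  for (int j = 0; j < w; ++j) {
    const double *d = &dH(0, j);
    const double *p = &pre(0, j);
    double *o = &out(0, j);
    for (int i = 0; i < n; ++i) o[i] = p[i] > 0 ? d[i] : 0.0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Local covariance frames: for each query point and its neighbour index list
// (1-based into X), the eigenvectors (ascending eigenvalue order: e3 = normal)
// and the surface-variation curvature lambda_min / trace.
// 3x3 symmetric eigensolver: analytic eigenvalues, null-space eigenvectors.
// ---------------------------------------------------------------------------
namespace {

void eig3_sym(const double a[3][3], double eval[3], double evec[3][3]) {
  // analytic eigenvalues (Smith's trigonometric method)
  const double p1 = a[0][1]*a[0][1] + a[0][2]*a[0][2] + a[1][2]*a[1][2];
  const double q = (a[0][0] + a[1][1] + a[2][2]) / 3.0;
  if (p1 < 1e-30) {
    eval[0] = a[0][0]; eval[1] = a[1][1]; eval[2] = a[2][2];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) evec[i][j] = (i == j) ? 1.0 : 0.0;
    // sort ascending
    for (int i = 0; i < 2; ++i)
      for (int j = i + 1; j < 3; ++j)
        if (eval[j] < eval[i]) {
          std::swap(eval[i], eval[j]);
          for (int k = 0; k < 3; ++k) std::swap(evec[k][i], evec[k][j]);
        }
    return;
  }
  const double p2 = (a[0][0]-q)*(a[0][0]-q) + (a[1][1]-q)*(a[1][1]-q) +
                    (a[2][2]-q)*(a[2][2]-q) + 2.0 * p1;
  const double p = std::sqrt(p2 / 6.0);
  double b[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      b[i][j] = (a[i][j] - (i == j ? q : 0.0)) / p;
  const double detb = b[0][0]*(b[1][1]*b[2][2]-b[1][2]*b[2][1])
                    - b[0][1]*(b[1][0]*b[2][2]-b[1][2]*b[2][0])
                    + b[0][2]*(b[1][0]*b[2][1]-b[1][1]*b[2][0]);
  double r = detb / 2.0;
  if (r < -1.0) r = -1.0;
  if (r > 1.0) r = 1.0;
  const double phi = std::acos(r) / 3.0;
  eval[2] = q + 2.0 * p * std::cos(phi);                    // largest
  eval[0] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0); // smallest
  eval[1] = 3.0 * q - eval[0] - eval[2];
  // eigenvector for each eigenvalue: cross products of rows of (A - l I)
  for (int e = 0; e < 3; ++e) {
    const double l = eval[e];
    double m[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        m[i][j] = a[i][j] - (i == j ? l : 0.0);
    double best[3] = {0, 0, 0};
    double bestn = -1.0;
    for (int r1 = 0; r1 < 3; ++r1) {
      const int r2 = (r1 + 1) % 3;
      const double cx = m[r1][1]*m[r2][2] - m[r1][2]*m[r2][1];
      const double cy = m[r1][2]*m[r2][0] - m[r1][0]*m[r2][2];
      const double cz = m[r1][0]*m[r2][1] - m[r1][1]*m[r2][0];
      const double nn = cx*cx + cy*cy + cz*cz;
      if (nn > bestn) { bestn = nn; best[0] = cx; best[1] = cy; best[2] = cz; }
    }
    double nn = std::sqrt(bestn);
    if (nn < 1e-30) { best[0] = 1; best[1] = 0; best[2] = 0; nn = 1; }
    for (int k = 0; k < 3; ++k) evec[k][e] = best[k] / nn;
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_local_frames(NumericMatrix X, List neighbors) {
  const int n = neighbors.size();
  NumericMatrix e1(n, 3), e2(n, 3), normal(n, 3), center(n, 3);
  NumericVector curvature(n), lambda_min(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector idx = neighbors[i];
    const int m = idx.size();
    double mean[3] = {0, 0, 0};
    for (int k = 0; k < m; ++k)
      for (int j = 0; j < 3; ++j) mean[j] += X(idx[k]-1, j);
    for (int j = 0; j < 3; ++j) { mean[j] /= m; center(i, j) = mean[j]; }
    double a[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
    for (int k = 0; k < m; ++k) {
      double d[3];
      for (int j = 0; j < 3; ++j) d[j] = X(idx[k]-1, j) - mean[j];
      for (int r = 0; r < 3; ++r)
        for (int c = r; c < 3; ++c) a[r][c] += d[r] * d[c];
    }
    a[1][0] = a[0][1]; a[2][0] = a[0][2]; a[2][1] = a[1][2];
    double eval[3], evec[3][3];
    eig3_sym(a, eval, evec);
    for (int j = 0; j < 3; ++j) {
      normal(i, j) = evec[j][0];  // smallest eigenvalue direction
      e2(i, j) = evec[j][1];
      e1(i, j) = evec[j][2];
    }
    const double tot = eval[0] + eval[1] + eval[2];
    curvature[i] = tot > 0 ? eval[0] / tot : 0.0;
    lambda_min[i] = eval[0];
  }
  return List::create(_["normal"] = normal, _["e1"] = e1, _["e2"] = e2,
                      _["center"] = center, _["curvature"] = curvature,
                      _["lambda_min"] = lambda_min);
}
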