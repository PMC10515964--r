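#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shared sampling kernels for volume resampling, transform application and
// the demons registration inner loop. All world coordinates are mm; grids
// are node-centered: world = origin + index0 * spacing.

static inline double sample_nearest(const double *src, const int *d,
                                    double x, double y, double z,
                                    double fill) {
  int i = (int)std::floor(x + 0.5);
  int j = (int)std::floor(y + 0.5);
  int k = (int)std::floor(z + 0.5);
  if (i < 0 || j < 0 || k < 0 || i >= d[0] || j >= d[1] || k >= d[2])
    return fill;
  return src[i + (size_t)d[0] * (j + (size_t)d[1] * k)];
}

static inline double getv(const double *src, const int *d, int i, int j, int k) {
  if (i < 0) i = 0; else if (i >= d[0]) i = d[0] - 1;
  if (j < 0) j = 0; else if (j >= d[1]) j = d[1] - 1;
  if (k < 0) k = 0; else if (k >= d[2]) k = d[2] - 1;
  return src[i + (size_t)d[0] * (j + (size_t)d[1] * k)];
}

static inline double sample_linear(const double *src, const int *d,
                                   double x, double y, double z,
                                   double fill) {
  // fill outside the grid, clamp within half a voxel of the border
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > d[0] - 0.5 || y > d[1] - 0.5 || z > d[2] - 0.5)
    return fill;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double v = 0.0;
  for (int dk = 0; dk <= 1; ++dk) {
    double wz = dk ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    for (int dj = 0; dj <= 1; ++dj) {
      double wy = dj ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      for (int di = 0; di <= 1; ++di) {
        double wx = di ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        v += wx * wy * wz * getv(src, d, i0 + di, j0 + dj, k0 + dk);
      }
    }
  }
  return v;
}

static inline void bspline_w(double t, double *w) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1 - 3 * t + 3 * t2 - t3) / 6.0;
  w[1] = (4 - 6 * t2 + 3 * t3) / 6.0;
  w[2] = (1 + 3 * t + 3 * t2 - 3 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

static inline double sample_bspline(const double *src, const int *d,
                                    double x, double y, double z,
                                    double fill) {
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > d[0] - 0.5 || y > d[1] - 0.5 || z > d[2] - 0.5)
    return fill;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double wx[4], wy[4], wz[4];
  bspline_w(x - i0, wx); bspline_w(y - j0, wy); bspline_w(z - k0, wz);
  double v = 0.0;
  for (int dk = -1; dk <= 2; ++dk)
    for (int dj = -1; dj <= 2; ++dj)
      for (int di = -1; di <= 2; ++di)
        v += wx[di + 1] * wy[dj + 1] * wz[dk + 1] *
             getv(src, d, i0 + di, j0 + dj, k0 + dk);
  return v;
}

// Resample `src` onto an output grid through an affine world map and an
// optional dense displacement field (mm, on the output grid):
//   q(p) = A %*% p + u(p);  out(p) = src(q(p))
// interp: 0 nearest, 1 linear, 3 cubic B-spline (smoothing kernel).
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector src, IntegerVector sdim,
                       NumericVector sspacing, NumericVector sorigin,
                       IntegerVector odim, NumericVector ospacing,
                       NumericVector oorigin, NumericMatrix affine,
                       Nullable<NumericVector> disp, int interp, double fill) {
  int d[3] = {sdim[0], sdim[1], sdim[2]};
  int od[3] = {odim[0], odim[1], odim[2]};
  size_t n = (size_t)od[0] * od[1] * od[2];
  NumericVector out(n);
  const double *s = src.begin();
  const double *u = nullptr;
  if (disp.isNotNull()) u = NumericVector(disp).begin();
  double A[3][4];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 4; ++c) A[r][c] = affine(r, c);
  size_t idx = 0;
  for (int k = 0; k < od[2]; ++k) {
    double pz = oorigin[2] + k * ospacing[2];
    for (int j = 0; j < od[1]; ++j) {
      double py = oorigin[1] + j * ospacing[1];
      for (int i = 0; i < od[0]; ++i, ++idx) {
        double px = oorigin[0] + i * ospacing[0];
        double qx = A[0][0] * px + A[0][1] * py + A[0][2] * pz + A[0][3];
        double qy = A[1][0] * px + A[1][1] * py + A[1][2] * pz + A[1][3];
        double qz = A[2][0] * px + A[2][1] * py + A[2][2] * pz + A[2][3];
        if (u) {
          qx += u[idx];
          qy += u[idx + n];
          qz += u[idx + 2 * n];
        }
        double x = (qx - sorigin[0]) / sspacing[0];
        double y = (qy - sorigin[1]) / sspacing[1];
        double z = (qz - sorigin[2]) / sspacing[2];
        if (interp == 0)      out[idx] = sample_nearest(s, d, x, y, z, fill);
        else if (interp == 1) out[idx] = sample_linear(s, d, x, y, z, fill);
        else if (interp == 2) {
          // clamped linear: extend edge values (used for displacement
          // fields, which must stay well defined at the border)
          double cx = x < 0 ? 0 : (x > d[0] - 1 ? d[0] - 1 : x);
          double cy = y < 0 ? 0 : (y > d[1] - 1 ? d[1] - 1 : y);
          double cz = z < 0 ? 0 : (z > d[2] - 1 ? d[2] - 1 : z);
          out[idx] = sample_linear(s, d, cx, cy, cz, fill);
        }
        else                  out[idx] = sample_bspline(s, d, x, y, z, fill);
      }
    }
  }
  return out;
}

// Central-difference gradient in 1/mm units; one-sided at the borders.
// Returns a vector of length 3n laid out as (gx, gy, gz).
// [[Rcpp::export]]
NumericVector cpp_gradient3d(NumericVector src, IntegerVector sdim,
                             NumericVector spacing) {
  int d[3] = {sdim[0], sdim[1], sdim[2]};
  size_t n = (size_t)d[0] * d[1] * d[2];
  NumericVector out(3 * n);
  const double *s = src.begin();
  size_t idx = 0;
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i, ++idx) {
        int ip = i + 1 < d[0] ? i + 1 : i, im = i > 0 ? i - 1 : i;
        int jp = j + 1 < d[1] ? j + 1 : j, jm = j > 0 ? j - 1 : j;
        int kp = k + 1 < d[2] ? k + 1 : k, km = k > 0 ? k - 1 : k;
        out[idx] = (getv(s, d, ip, j, k) - getv(s, d, im, j, k)) /
                   ((ip - im) * spacing[0]);
        out[idx + n] = (getv(s, d, i, jp, k) - getv(s, d, i, jm, k)) /
                       ((jp - jm) * spacing[1]);
        out[idx + 2 * n] = (getv(s, d, i, j, kp) - getv(s, d, i, j, km)) /
                           ((kp - km) * spacing[2]);
      }
  return out;
}

// Separable Gaussian smoothing, sigma in voxels per axis, reflected borders.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector src, IntegerVector sdim,
                          NumericVector sigma) {
  int d[3] = {sdim[0], sdim[1], sdim[2]};
  size_t n = (size_t)d[0] * d[1] * d[2];
  std::vector<double> buf1(src.begin(), src.end()), buf2(n);
  double *a = buf1.data(), *b = buf2.data();
  size_t stride[3] = {1, (size_t)d[0], (size_t)d[0] * d[1]};
  for (int ax = 0; ax < 3; ++ax) {
    double sg = sigma[ax];
    if (sg <= 0) continue;
    int r = (int)std::ceil(2.5 * sg);
    std::vector<double> w(2 * r + 1);
    double sum = 0;
    for (int t = -r; t <= r; ++t) {
      w[t + r] = std::exp(-0.5 * t * t / (sg * sg));
      sum += w[t + r];
    }
    for (auto &x : w) x /= sum;
    int len = d[ax];
    size_t st = stride[ax];
    // iterate over all lines along axis ax
    size_t nlines = n / len;
    int o1 = (ax == 0) ? 1 : 0, o2 = (ax == 2) ? 1 : 2;
    int l1 = d[o1], l2 = d[o2];
    size_t s1 = stride[o1], s2 = stride[o2];
    (void)nlines;
    for (int c2 = 0; c2 < l2; ++c2)
      for (int c1 = 0; c1 < l1; ++c1) {
        size_t base = c1 * s1 + c2 * s2;
        for (int p = 0; p < len; ++p) {
          double acc = 0;
          for (int t = -r; t <= r; ++t) {
            int q = p + t;
            if (q < 0) q = -q - 1;
            if (q >= len) q = 2 * len - q - 1;
            if (q < 0) q = 0; // tiny axes
            acc += w[t + r] * a[base + (size_t)q * st];
          }
          b[base + (size_t)p * st] = acc;
        }
      }
    std::swap(a, b);
  }
  return NumericVector(a, a + n);
}

// Joint histogram with nearest binning over [amin,amax] x [bmin,bmax].
// [[Rcpp::export]]
NumericMatrix cpp_joint_hist(NumericVector a, NumericVector b, int nbins,
                             double amin, double amax, double bmin,
                             double bmax) {
  NumericMatrix h(nbins, nbins);
  double ra = amax - amin, rb = bmax - bmin;
  if (ra <= 0) ra = 1;
  if (rb <= 0) rb = 1;
  size_t n = a.size();
  for (size_t t = 0; t < n; ++t) {
    double av = a[t], bv = b[t];
    if (!R_finite(av) || !R_finite(bv)) continue;
    int ia = (int)((av - amin) / ra * nbins);
    int ib = (int)((bv - bmin) / rb * nbins);
    if (ia < 0) ia = 0; if (ia >= nbins) ia = nbins - 1;
    if (ib < 0) ib = 0; if (ib >= nbins) ib = nbins - 1;
    h(ia, ib) += 1.0;
  }
  return h;
}

// Block sums: out voxel = sum of its fx x fy x fz block (partial blocks kept).
// [[Rcpp::export]]
NumericVector cpp_block_sum(NumericVector src, IntegerVector sdim,
                            IntegerVector f) {
  int d[3] = {sdim[0], sdim[1], sdim[2]};
  int od[3];
  for (int ax = 0; ax < 3; ++ax) od[ax] = (d[ax] + f[ax] - 1) / f[ax];
  NumericVector out((size_t)od[0] * od[1] * od[2]);
  const double *s = src.begin();
  size_t idx = 0;
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i, ++idx) {
        size_t o = (i / f[0]) +
                   (size_t)od[0] * ((j / f[1]) + (size_t)od[1] * (k / f[2]));
        out[o] += s[idx];
      }
  out.attr("dim") = IntegerVector::create(od[0], od[1], od[2]);
  return out;
}
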