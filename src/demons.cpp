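#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Demons level loop: warp -> force -> fluid smooth -> update -> elastic
// smooth, entirely in compiled code. Channels share the fixed grid; the
// moving channels share one grid. Multimodal handling remaps the warped
// moving intensities through the conditional-mean transfer estimated from
// a joint histogram (recomputed every 10 iterations).

static inline double getv3(const double *s, const int *d, int i, int j,
                           int k) {
  if (i < 0) i = 0; else if (i >= d[0]) i = d[0] - 1;
  if (j < 0) j = 0; else if (j >= d[1]) j = d[1] - 1;
  if (k < 0) k = 0; else if (k >= d[2]) k = d[2] - 1;
  return s[i + (size_t)d[0] * (j + (size_t)d[1] * k)];
}

static inline double lin3(const double *s, const int *d, double x, double y,
                          double z, double fill) {
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
        v += wx * wy * wz * getv3(s, d, i0 + di, j0 + dj, k0 + dk);
      }
    }
  }
  return v;
}

static void gauss3(std::vector<double> &buf, const int *d, double sg) {
  if (sg <= 0) return;
  size_t n = (size_t)d[0] * d[1] * d[2];
  int r = (int)std::ceil(2.5 * sg);
  std::vector<double> w(2 * r + 1);
  double sum = 0;
  for (int t = -r; t <= r; ++t) {
    w[t + r] = std::exp(-0.5 * t * t / (sg * sg));
    sum += w[t + r];
  }
  for (auto &x : w) x /= sum;
  std::vector<double> tmp(n);
  double *a = buf.data(), *b = tmp.data();
  size_t stride[3] = {1, (size_t)d[0], (size_t)d[0] * d[1]};
  for (int ax = 0; ax < 3; ++ax) {
    int len = d[ax];
    size_t st = stride[ax];
    int o1 = (ax == 0) ? 1 : 0, o2 = (ax == 2) ? 1 : 2;
    int l1 = d[o1], l2 = d[o2];
    size_t s1 = stride[o1], s2 = stride[o2];
    for (int c2 = 0; c2 < l2; ++c2)
      for (int c1 = 0; c1 < l1; ++c1) {
        size_t base = c1 * s1 + c2 * s2;
        for (int p = 0; p < len; ++p) {
          double acc = 0;
          for (int t = -r; t <= r; ++t) {
            int q = p + t;
            if (q < 0) q = -q - 1;
            if (q >= len) q = 2 * len - q - 1;
            if (q < 0) q = 0;
            acc += w[t + r] * a[base + (size_t)q * st];
          }
          b[base + (size_t)p * st] = acc;
        }
      }
    std::swap(a, b);
  }
  if (a != buf.data()) std::copy(a, a + n, buf.data());
}

// [[Rcpp::export]]
NumericVector cpp_demons_level(List fixed, List moving, IntegerVector fdim,
                               NumericVector fspacing, NumericVector forigin,
                               IntegerVector mdim, NumericVector mspacing,
                               NumericVector morigin, NumericMatrix affine,
                               NumericVector u0, int iters,
                               double sigma_fluid, double sigma_elastic,
                               double step, double kappa, double maxstep,
                               NumericVector weights, bool multimodal,
                               int nbins) {
  int fd[3] = {fdim[0], fdim[1], fdim[2]};
  int md[3] = {mdim[0], mdim[1], mdim[2]};
  size_t n = (size_t)fd[0] * fd[1] * fd[2];
  int nch = fixed.size();
  double A[3][4];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 4; ++c) A[r][c] = affine(r, c);
  std::vector<std::vector<double>> f(nch), m(nch), grad(nch);
  std::vector<double> gfloor(nch);
  for (int c = 0; c < nch; ++c) {
    NumericVector fv = fixed[c];
    NumericVector mv = moving[c];
    f[c].assign(fv.begin(), fv.end());
    m[c].assign(mv.begin(), mv.end());
    // central-difference gradient of the fixed channel (1/mm)
    grad[c].resize(3 * n);
    size_t idx = 0;
    double gmax = 0;
    for (int k = 0; k < fd[2]; ++k)
      for (int j = 0; j < fd[1]; ++j)
        for (int i = 0; i < fd[0]; ++i, ++idx) {
          int ip = i + 1 < fd[0] ? i + 1 : i, im = i > 0 ? i - 1 : i;
          int jp = j + 1 < fd[1] ? j + 1 : j, jm = j > 0 ? j - 1 : j;
          int kp = k + 1 < fd[2] ? k + 1 : k, km = k > 0 ? k - 1 : k;
          const double *s = f[c].data();
          double gx = (getv3(s, fd, ip, j, k) - getv3(s, fd, im, j, k)) /
            ((ip - im) * fspacing[0]);
          double gy = (getv3(s, fd, i, jp, k) - getv3(s, fd, i, jm, k)) /
            ((jp - jm) * fspacing[1]);
          double gz = (getv3(s, fd, i, j, kp) - getv3(s, fd, i, j, km)) /
            ((kp - km) * fspacing[2]);
          grad[c][idx] = gx;
          grad[c][idx + n] = gy;
          grad[c][idx + 2 * n] = gz;
          double g2 = gx * gx + gy * gy + gz * gz;
          if (g2 > gmax) gmax = g2;
        }
    gfloor[c] = 0.0009 * gmax; // (0.03)^2 relative gradient floor
  }
  std::vector<double> ux(u0.begin(), u0.begin() + n);
  std::vector<double> uy(u0.begin() + n, u0.begin() + 2 * n);
  std::vector<double> uz(u0.begin() + 2 * n, u0.begin() + 3 * n);
  std::vector<double> vx(n), vy(n), vz(n), mw(n);
  std::vector<std::vector<double>> lut(nch);
  for (int it = 0; it < iters; ++it) {
    std::fill(vx.begin(), vx.end(), 0.0);
    std::fill(vy.begin(), vy.end(), 0.0);
    std::fill(vz.begin(), vz.end(), 0.0);
    for (int c = 0; c < nch; ++c) {
      // warp moving channel through A p + u(p)
      size_t idx = 0;
      for (int k = 0; k < fd[2]; ++k) {
        double pz = forigin[2] + k * fspacing[2];
        for (int j = 0; j < fd[1]; ++j) {
          double py = forigin[1] + j * fspacing[1];
          for (int i = 0; i < fd[0]; ++i, ++idx) {
            double px = forigin[0] + i * fspacing[0];
            double qx = A[0][0] * px + A[0][1] * py + A[0][2] * pz + A[0][3]
              + ux[idx];
            double qy = A[1][0] * px + A[1][1] * py + A[1][2] * pz + A[1][3]
              + uy[idx];
            double qz = A[2][0] * px + A[2][1] * py + A[2][2] * pz + A[2][3]
              + uz[idx];
            mw[idx] = lin3(m[c].data(), md,
                           (qx - morigin[0]) / mspacing[0],
                           (qy - morigin[1]) / mspacing[1],
                           (qz - morigin[2]) / mspacing[2], 0.0);
          }
        }
      }
      if (multimodal) {
        if (it % 10 == 0) {
          // conditional mean E[f | bin(mw)] over the unit intensity range
          std::vector<double> hsum(nbins, 0.0), hcnt(nbins, 0.0);
          for (size_t t = 0; t < n; ++t) {
            int b = (int)(mw[t] * nbins);
            if (b < 0) b = 0; if (b >= nbins) b = nbins - 1;
            hsum[b] += f[c][t];
            hcnt[b] += 1.0;
          }
          lut[c].resize(nbins);
          for (int b = 0; b < nbins; ++b)
            lut[c][b] = hcnt[b] > 0 ? hsum[b] / hcnt[b]
                                    : (b + 0.5) / nbins;
        }
        for (size_t t = 0; t < n; ++t) {
          int b = (int)(mw[t] * nbins);
          if (b < 0) b = 0; if (b >= nbins) b = nbins - 1;
          mw[t] = lut[c][b];
        }
      }
      double wc = weights[c];
      for (size_t t = 0; t < n; ++t) {
        double diff = f[c][t] - mw[t];
        double gx = grad[c][t], gy = grad[c][t + n], gz = grad[c][t + 2 * n];
        double g2 = gx * gx + gy * gy + gz * gz;
        double denom = g2 + diff * diff * kappa;
        if (g2 > gfloor[c] && denom > 1e-12) {
          double fac = wc * diff / denom;
          vx[t] += fac * gx;
          vy[t] += fac * gy;
          vz[t] += fac * gz;
        }
      }
    }
    double vmean = 0;
    for (size_t t = 0; t < n; ++t) {
      double vn = std::sqrt(vx[t] * vx[t] + vy[t] * vy[t] + vz[t] * vz[t]);
      if (vn > maxstep) {
        double sc = maxstep / vn;
        vx[t] *= sc; vy[t] *= sc; vz[t] *= sc;
        vn = maxstep;
      }
      vmean += vn;
    }
    vmean /= n;
    gauss3(vx, fd, sigma_fluid);
    gauss3(vy, fd, sigma_fluid);
    gauss3(vz, fd, sigma_fluid);
    for (size_t t = 0; t < n; ++t) {
      ux[t] += step * vx[t];
      uy[t] += step * vy[t];
      uz[t] += step * vz[t];
    }
    gauss3(ux, fd, sigma_elastic);
    gauss3(uy, fd, sigma_elastic);
    gauss3(uz, fd, sigma_elastic);
    double sp = std::min(fspacing[0], std::min(fspacing[1], fspacing[2]));
    if (vmean < 0.01 * sp) break;
  }
  NumericVector out(3 * n);
  std::copy(ux.begin(), ux.end(), out.begin());
  std::copy(uy.begin(), uy.end(), out.begin() + n);
  std::copy(uz.begin(), uz.end(), out.begin() + 2 * n);
  return out;
}
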