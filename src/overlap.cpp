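#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Grant–Pickup first-order Gaussian volume overlap. Each atom carries a
// spherical Gaussian p * exp(-g * r^2) whose exponent g is chosen (R side)
// so an isolated atom's Gaussian volume equals its hard-sphere volume.
// Feature codes: 0 hydrophobe, 1 donor, 2 acceptor.

static inline double pair_overlap(double p2, double gi, double gj, double d2) {
  const double gs = gi + gj;
  return p2 * std::exp(-gi * gj * d2 / gs) * std::pow(M_PI / gs, 1.5);
}

// [[Rcpp::export]]
double gauss_overlap_pairs_cpp(NumericMatrix A, NumericVector gA,
                               NumericMatrix B, NumericVector gB, double amp) {
  const int na = A.nrow(), nb = B.nrow();
  const double p2 = amp * amp;
  double o = 0.0;
  for (int i = 0; i < na; ++i) {
    const double xi = A(i, 0), yi = A(i, 1), zi = A(i, 2), gi = gA[i];
    for (int j = 0; j < nb; ++j) {
      const double dx = xi - B(j, 0), dy = yi - B(j, 1), dz = zi - B(j, 2);
      o += pair_overlap(p2, gi, gB[j], dx * dx + dy * dy + dz * dz);
    }
  }
  return o;
}

// Shape overlap over all pairs + color overlap over same-feature polar pairs
// (color uses its own exponents gcA/gcB).
static void overlap_components(const std::vector<double>& ax, const std::vector<double>& ay,
                               const std::vector<double>& az, const IntegerVector& featA,
                               const NumericVector& gsA, const NumericVector& gcA,
                               const std::vector<double>& bx, const std::vector<double>& by,
                               const std::vector<double>& bz, const IntegerVector& featB,
                               const NumericVector& gsB, const NumericVector& gcB,
                               double amp, double& shape, double& color) {
  const int na = ax.size(), nb = bx.size();
  const double p2 = amp * amp;
  shape = 0.0; color = 0.0;
  for (int i = 0; i < na; ++i) {
    const double xi = ax[i], yi = ay[i], zi = az[i];
    const double gi = gsA[i];
    const int fi = featA[i];
    for (int j = 0; j < nb; ++j) {
      const double dx = xi - bx[j], dy = yi - by[j], dz = zi - bz[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      shape += pair_overlap(p2, gi, gsB[j], d2);
      if (fi > 0 && featB[j] == fi)
        color += pair_overlap(p2, gcA[i], gcB[j], d2);
    }
  }
}

static void rodrigues(const double v[3], double R[9]) {
  const double th = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  if (th < 1e-12) {
    R[0] = 1; R[1] = 0; R[2] = 0;
    R[3] = 0; R[4] = 1; R[5] = 0;
    R[6] = 0; R[7] = 0; R[8] = 1;
    return;
  }
  const double kx = v[0] / th, ky = v[1] / th, kz = v[2] / th;
  const double c = std::cos(th), s = std::sin(th), t = 1.0 - c;
  R[0] = c + kx * kx * t;      R[1] = kx * ky * t - kz * s; R[2] = kx * kz * t + ky * s;
  R[3] = ky * kx * t + kz * s; R[4] = c + ky * ky * t;      R[5] = ky * kz * t - kx * s;
  R[6] = kz * kx * t - ky * s; R[7] = kz * ky * t + kx * s; R[8] = c + kz * kz * t;
}

struct AlignProblem {
  std::vector<double> ax, ay, az;      // fixed set A
  std::vector<double> b0x, b0y, b0z;   // B pre-rotated by R0 about its centroid
  IntegerVector featA, featB;
  NumericVector gsA, gcA, gsB, gcB;
  double amp, w;
  double cax, cay, caz;                // centroid of A (start translation)
  mutable std::vector<double> tbx, tby, tbz;
  int neval = 0;

  // par = (rotation vector delta, translation delta); maximize shape + w*color
  double eval(const double* par) {
    double R[9];
    rodrigues(par, R);
    const int nb = b0x.size();
    for (int j = 0; j < nb; ++j) {
      const double x = b0x[j], y = b0y[j], z = b0z[j];
      tbx[j] = R[0] * x + R[1] * y + R[2] * z + cax + par[3];
      tby[j] = R[3] * x + R[4] * y + R[5] * z + cay + par[4];
      tbz[j] = R[6] * x + R[7] * y + R[8] * z + caz + par[5];
    }
    double shape, color;
    overlap_components(ax, ay, az, featA, gsA, gcA,
                       tbx, tby, tbz, featB, gsB, gcB, amp, shape, color);
    ++neval;
    return shape + w * color;
  }
};

// Derivative-free Nelder-Mead maximization over 6 rigid DOF, starting from
// the pose (R0 about B's centroid, B centroid moved onto A centroid).
// B0 passed here must already be centered and rotated by R0.
// [[Rcpp::export]]
List align_refine_cpp(NumericMatrix A, IntegerVector featA, NumericVector gsA,
                      NumericVector gcA, NumericMatrix B0, IntegerVector featB,
                      NumericVector gsB, NumericVector gcB, double amp,
                      NumericVector centroidA, double w, double rot_step,
                      double trans_step, int maxeval, double ftol) {
  AlignProblem P;
  const int na = A.nrow(), nb = B0.nrow();
  P.ax.resize(na); P.ay.resize(na); P.az.resize(na);
  for (int i = 0; i < na; ++i) { P.ax[i] = A(i, 0); P.ay[i] = A(i, 1); P.az[i] = A(i, 2); }
  P.b0x.resize(nb); P.b0y.resize(nb); P.b0z.resize(nb);
  P.tbx.resize(nb); P.tby.resize(nb); P.tbz.resize(nb);
  for (int j = 0; j < nb; ++j) { P.b0x[j] = B0(j, 0); P.b0y[j] = B0(j, 1); P.b0z[j] = B0(j, 2); }
  P.featA = featA; P.featB = featB;
  P.gsA = gsA; P.gcA = gcA; P.gsB = gsB; P.gcB = gcB;
  P.amp = amp; P.w = w;
  P.cax = centroidA[0]; P.cay = centroidA[1]; P.caz = centroidA[2];

  const int d = 6;
  std::vector<std::vector<double> > x(d + 1, std::vector<double>(d, 0.0));
  std::vector<double> fv(d + 1);
  for (int i = 0; i < d; ++i)
    x[i + 1][i] = (i < 3) ? rot_step : trans_step;
  for (int i = 0; i <= d; ++i) fv[i] = -P.eval(&x[i][0]);  // minimize -f

  const double alpha = 1.0, gamma = 2.0, rho = 0.5, sigma = 0.5;
  std::vector<int> ord(d + 1);
  std::vector<double> xc(d), xr(d), xe(d), xk(d);
  while (P.neval < maxeval) {
    for (int i = 0; i <= d; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) { return fv[a] < fv[b]; });
    if (std::fabs(fv[ord[d]] - fv[ord[0]]) <
        ftol * (std::fabs(fv[ord[0]]) + 1e-12))
      break;
    for (int i = 0; i < d; ++i) {
      xc[i] = 0.0;
      for (int q = 0; q < d; ++q) xc[i] += x[ord[q]][i];
      xc[i] /= d;
    }
    const int hi = ord[d];
    for (int i = 0; i < d; ++i) xr[i] = xc[i] + alpha * (xc[i] - x[hi][i]);
    const double fr = -P.eval(&xr[0]);
    if (fr < fv[ord[0]]) {
      for (int i = 0; i < d; ++i) xe[i] = xc[i] + gamma * (xr[i] - xc[i]);
      const double fe = -P.eval(&xe[0]);
      if (fe < fr) { x[hi] = xe; fv[hi] = fe; }
      else { x[hi] = xr; fv[hi] = fr; }
    } else if (fr < fv[ord[d - 1]]) {
      x[hi] = xr; fv[hi] = fr;
    } else {
      for (int i = 0; i < d; ++i) xk[i] = xc[i] + rho * (x[hi][i] - xc[i]);
      const double fk = -P.eval(&xk[0]);
      if (fk < fv[hi]) { x[hi] = xk; fv[hi] = fk; }
      else {
        const int lo = ord[0];
        for (int q = 0; q <= d; ++q) {
          if (q == lo) continue;
          for (int i = 0; i < d; ++i)
            x[q][i] = x[lo][i] + sigma * (x[q][i] - x[lo][i]);
          fv[q] = -P.eval(&x[q][0]);
        }
      }
    }
  }
  int best = 0;
  for (int i = 1; i <= d; ++i) if (fv[i] < fv[best]) best = i;
  // final components at the best pose
  double R[9];
  rodrigues(&x[best][0], R);
  for (int j = 0; j < nb; ++j) {
    const double xx = P.b0x[j], yy = P.b0y[j], zz = P.b0z[j];
    P.tbx[j] = R[0] * xx + R[1] * yy + R[2] * zz + P.cax + x[best][3];
    P.tby[j] = R[3] * xx + R[4] * yy + R[5] * zz + P.cay + x[best][4];
    P.tbz[j] = R[6] * xx + R[7] * yy + R[8] * zz + P.caz + x[best][5];
  }
  double shape, color;
  overlap_components(P.ax, P.ay, P.az, featA, gsA, gcA,
                     P.tbx, P.tby, P.tbz, featB, gsB, gcB, amp, shape, color);
  return List::create(_["par"] = NumericVector(x[best].begin(), x[best].end()),
                      _["objective"] = -fv[best],
                      _["shape_overlap"] = shape,
                      _["color_overlap"] = color,
                      _["neval"] = P.neval);
}
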