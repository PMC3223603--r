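#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Analytic overlap of two sets of spherical Gaussians rho_i = p * exp(-kappa_i |r - r_i|^2).
// V_AB = sum_{i,j} p^2 * (pi/(k_i + k_j))^{3/2} * exp(-k_i k_j / (k_i + k_j) * d_ij^2),
// restricted to pairs with matching type label (shape overlap passes all-zero types).
// Terms with exponent below skip_log are dropped; at the default -30 the dropped mass
// is < 1e-13 of a single term and well inside every tolerance used downstream.
// [[Rcpp::export]]
double overlap_sum_cpp(NumericMatrix ax, NumericVector ak, IntegerVector atype,
                       NumericMatrix bx, NumericVector bk, IntegerVector btype,
                       double p2, double skip_log) {
  const int na = ax.nrow(), nb = bx.nrow();
  const double pi = M_PI;
  double total = 0.0;
  for (int i = 0; i < na; ++i) {
    const double xi = ax(i, 0), yi = ax(i, 1), zi = ax(i, 2), ki = ak[i];
    const int ti = atype[i];
    for (int j = 0; j < nb; ++j) {
      if (btype[j] != ti) continue;
      const double kj = bk[j], ks = ki + kj;
      const double dx = xi - bx(j, 0), dy = yi - bx(j, 1), dz = zi - bx(j, 2);
      const double arg = -(ki * kj / ks) * (dx * dx + dy * dy + dz * dz);
      if (arg < skip_log) continue;
      total += p2 * std::pow(pi / ks, 1.5) * std::exp(arg);
    }
  }
  return total;
}

// Independent quadrature oracle: evaluates rho_A(r) * rho_B(r) on a regular grid over
// the union bounding box (padded), summing point densities rather than pairwise terms,
// so it shares no code path with overlap_sum_cpp.
// [[Rcpp::export]]
double grid_overlap_cpp(NumericMatrix ax, NumericVector ak,
                        NumericMatrix bx, NumericVector bk,
                        double p, double spacing, double pad) {
  const int na = ax.nrow(), nb = bx.nrow();
  if (na == 0 || nb == 0) return 0.0;
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = R_PosInf;
    hi[d] = R_NegInf;
    for (int i = 0; i < na; ++i) {
      lo[d] = std::min(lo[d], ax(i, d));
      hi[d] = std::max(hi[d], ax(i, d));
    }
    for (int j = 0; j < nb; ++j) {
      lo[d] = std::min(lo[d], bx(j, d));
      hi[d] = std::max(hi[d], bx(j, d));
    }
    lo[d] -= pad;
    hi[d] += pad;
  }
  const int nx = (int)std::ceil((hi[0] - lo[0]) / spacing);
  const int ny = (int)std::ceil((hi[1] - lo[1]) / spacing);
  const int nz = (int)std::ceil((hi[2] - lo[2]) / spacing);
  double total = 0.0;
  for (int ix = 0; ix <= nx; ++ix) {
    const double x = lo[0] + ix * spacing;
    for (int iy = 0; iy <= ny; ++iy) {
      const double y = lo[1] + iy * spacing;
      for (int iz = 0; iz <= nz; ++iz) {
        const double z = lo[2] + iz * spacing;
        double ra = 0.0, rb = 0.0;
        for (int i = 0; i < na; ++i) {
          const double dx = x - ax(i, 0), dy = y - ax(i, 1), dz = z - ax(i, 2);
          ra += p * std::exp(-ak[i] * (dx * dx + dy * dy + dz * dz));
        }
        for (int j = 0; j < nb; ++j) {
          const double dx = x - bx(j, 0), dy = y - bx(j, 1), dz = z - bx(j, 2);
          rb += p * std::exp(-bk[j] * (dx * dx + dy * dy + dz * dz));
        }
        total += ra * rb;
      }
    }
  }
  return total * spacing * spacing * spacing;
}

static void rodrigues(const double* w, double R[3][3]) {
  const double th2 = w[0]*w[0] + w[1]*w[1] + w[2]*w[2];
  const double th = std::sqrt(th2);
  double A, B;
  if (th < 1e-8) { A = 1.0 - th2 / 6.0; B = 0.5 - th2 / 24.0; }
  else { A = std::sin(th) / th; B = (1.0 - std::cos(th)) / th2; }
  const double wx = w[0], wy = w[1], wz = w[2];
  R[0][0] = 1.0 + B * (-wz*wz - wy*wy);
  R[0][1] = -A*wz + B*wx*wy;
  R[0][2] =  A*wy + B*wx*wz;
  R[1][0] =  A*wz + B*wx*wy;
  R[1][1] = 1.0 + B * (-wx*wx - wz*wz);
  R[1][2] = -A*wx + B*wy*wz;
  R[2][0] = -A*wy + B*wx*wz;
  R[2][1] =  A*wx + B*wy*wz;
  R[2][2] = 1.0 + B * (-wx*wx - wy*wy);
}

// Overlap and its analytic gradient with respect to the 6 pose parameters
// par = (w, t): rotation exp([w]) R0 applied to B's coordinates, then
// translation t.  Rotation gradient uses the left-perturbation cross
// product chained through the SO(3) left Jacobian of w.
// [[Rcpp::export]]
List overlap_value_grad_cpp(NumericMatrix ax, NumericVector ak, IntegerVector atype,
                            NumericMatrix bx, NumericVector bk, IntegerVector btype,
                            NumericVector w, NumericMatrix R0, NumericVector t,
                            double p2, double skip_log, bool want_grad) {
  const int na = ax.nrow(), nb = bx.nrow();
  const double pi = M_PI;
  double Rw[3][3], R[3][3];
  rodrigues(REAL(w), Rw);
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c)
      R[r][c] = Rw[r][0]*R0(0,c) + Rw[r][1]*R0(1,c) + Rw[r][2]*R0(2,c);
  double V = 0.0, gt[3] = {0,0,0}, gth[3] = {0,0,0};
  for (int j = 0; j < nb; ++j) {
    const double u0 = R[0][0]*bx(j,0) + R[0][1]*bx(j,1) + R[0][2]*bx(j,2);
    const double u1 = R[1][0]*bx(j,0) + R[1][1]*bx(j,1) + R[1][2]*bx(j,2);
    const double u2 = R[2][0]*bx(j,0) + R[2][1]*bx(j,1) + R[2][2]*bx(j,2);
    const double y0 = u0 + t[0], y1 = u1 + t[1], y2 = u2 + t[2];
    const double kj = bk[j];
    const int tj = btype[j];
    double g0 = 0, g1 = 0, g2 = 0;
    for (int i = 0; i < na; ++i) {
      if (atype[i] != tj) continue;
      const double ki = ak[i], ks = ki + kj, mu = ki * kj / ks;
      const double dx = ax(i,0) - y0, dy = ax(i,1) - y1, dz = ax(i,2) - y2;
      const double arg = -mu * (dx*dx + dy*dy + dz*dz);
      if (arg < skip_log) continue;
      const double term = p2 * std::pow(pi / ks, 1.5) * std::exp(arg);
      V += term;
      if (want_grad) {
        const double c2 = 2.0 * mu * term;
        g0 += c2 * dx; g1 += c2 * dy; g2 += c2 * dz;
      }
    }
    if (want_grad) {
      gt[0] += g0; gt[1] += g1; gt[2] += g2;
      // grad wrt left rotation perturbation: u x g
      gth[0] += u1*g2 - u2*g1;
      gth[1] += u2*g0 - u0*g2;
      gth[2] += u0*g1 - u1*g0;
    }
  }
  if (!want_grad) return List::create(_["value"] = V);
  // chain through the left Jacobian of w
  const double th2 = w[0]*w[0] + w[1]*w[1] + w[2]*w[2];
  const double th = std::sqrt(th2);
  double B, C;
  if (th < 1e-6) { B = 0.5 - th2 / 24.0; C = 1.0/6.0 - th2 / 120.0; }
  else { B = (1.0 - std::cos(th)) / th2; C = (th - std::sin(th)) / (th2 * th); }
  double K[3][3] = {{0, -w[2], w[1]}, {w[2], 0, -w[0]}, {-w[1], w[0], 0}};
  double Jl[3][3];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) {
      double k2 = 0;
      for (int m = 0; m < 3; ++m) k2 += K[r][m] * K[m][c];
      Jl[r][c] = (r == c ? 1.0 : 0.0) + B * K[r][c] + C * k2;
    }
  NumericVector grad(6);
  for (int c = 0; c < 3; ++c)
    grad[c] = Jl[0][c]*gth[0] + Jl[1][c]*gth[1] + Jl[2][c]*gth[2];
  grad[3] = gt[0]; grad[4] = gt[1]; grad[5] = gt[2];
  return List::create(_["value"] = V, _["grad"] = grad);
}
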