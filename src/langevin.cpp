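// Overdamped Langevin rigid-body integrator on a Gaussian-well landscape.
//
// Configuration q = (translation in Angstrom, unit quaternion).  The
// potential is a sum of attractive Gaussian wells in the combined
// translation-orientation metric d^2 = |t - c|^2 + (lambda * theta)^2
// (theta = geodesic rotation angle to the well's orientation, quaternion
// double cover handled via |dot|), plus a quartic confinement wall.
// First-order (Brownian) updates: drift = -grad U * dt / gamma, noise
// variance 2 kB T dt / gamma per degree of freedom.  All randomness comes
// from R's RNG so runs are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void qmul(const double *a, const double *b, double *o) {
  // Hamilton product a (x) b, scalar-first convention
  o[0] = a[0]*b[0] - a[1]*b[1] - a[2]*b[2] - a[3]*b[3];
  o[1] = a[0]*b[1] + a[1]*b[0] + a[2]*b[3] - a[3]*b[2];
  o[2] = a[0]*b[2] - a[1]*b[3] + a[2]*b[0] + a[3]*b[1];
  o[3] = a[0]*b[3] + a[1]*b[2] - a[2]*b[1] + a[3]*b[0];
}

static inline void qnormalize(double *q) {
  double n = std::sqrt(q[0]*q[0] + q[1]*q[1] + q[2]*q[2] + q[3]*q[3]);
  for (int i = 0; i < 4; ++i) q[i] /= n;
}

// geodesic angle (radians, [0, pi]) and the body-frame unit axis taking q
// toward p; returns angle, fills axis (zeroed when angle ~ 0)
static inline double qgeo(const double *q, const double *p, double *axis) {
  // r = conj(q) (x) p, sign-flipped so the scalar part is >= 0
  double cq[4] = { q[0], -q[1], -q[2], -q[3] };
  double r[4];
  qmul(cq, p, r);
  if (r[0] < 0) for (int i = 0; i < 4; ++i) r[i] = -r[i];
  double vn = std::sqrt(r[1]*r[1] + r[2]*r[2] + r[3]*r[3]);
  double ang = 2.0 * std::atan2(vn, r[0]);
  if (vn > 1e-14) {
    axis[0] = r[1]/vn; axis[1] = r[2]/vn; axis[2] = r[3]/vn;
  } else {
    axis[0] = axis[1] = axis[2] = 0.0;
  }
  return ang;
}

struct LandscapeView {
  int k;
  const double *ct;      // k x 3 centers, column-major from R
  const double *cq;      // k x 4 orientations
  const double *depth;
  const double *width;
  double lambda, conf_r, wall_k;
  int nrow_t, nrow_q;
};

// U(q) and its gradient wrt translation (gt, 3) and body-frame rotation
// vector (gr, 3)
static double potential_and_grad(const double *t, const double *q,
                                 const LandscapeView &L,
                                 double *gt, double *gr) {
  double U = 0.0;
  gt[0] = gt[1] = gt[2] = 0.0;
  gr[0] = gr[1] = gr[2] = 0.0;
  for (int i = 0; i < L.k; ++i) {
    double dt3[3], axis[3];
    for (int j = 0; j < 3; ++j) dt3[j] = t[j] - L.ct[i + j * L.nrow_t];
    double p[4];
    for (int j = 0; j < 4; ++j) p[j] = L.cq[i + j * L.nrow_q];
    double th = qgeo(q, p, axis);
    double d2 = dt3[0]*dt3[0] + dt3[1]*dt3[1] + dt3[2]*dt3[2]
              + L.lambda * L.lambda * th * th;
    double w2 = L.width[i] * L.width[i];
    double e = std::exp(-d2 / (2.0 * w2));
    U += -L.depth[i] * e;
    double coeff = (L.depth[i] / w2) * e;   // dU/d(d^2) * 2
    for (int j = 0; j < 3; ++j) gt[j] += coeff * dt3[j];
    // moving along +axis decreases theta, so dU/d(delta) = -coeff*lambda^2*th*axis
    double rc = -coeff * L.lambda * L.lambda * th;
    for (int j = 0; j < 3; ++j) gr[j] += rc * axis[j];
  }
  double r = std::sqrt(t[0]*t[0] + t[1]*t[1] + t[2]*t[2]);
  if (r > L.conf_r) {
    double x = r - L.conf_r;
    U += L.wall_k * x * x * x * x;
    double c = 4.0 * L.wall_k * x * x * x / r;
    for (int j = 0; j < 3; ++j) gt[j] += c * t[j];
  }
  return U;
}

static LandscapeView make_view(NumericMatrix ct, NumericMatrix cq,
                               NumericVector depth, NumericVector width,
                               double lambda, double conf_r, double wall_k) {
  LandscapeView L;
  L.k = ct.nrow();
  L.ct = ct.begin(); L.cq = cq.begin();
  L.depth = depth.begin(); L.width = width.begin();
  L.lambda = lambda; L.conf_r = conf_r; L.wall_k = wall_k;
  L.nrow_t = ct.nrow(); L.nrow_q = cq.nrow();
  return L;
}

// [[Rcpp::export]]
double cpp_potential(NumericVector trans, NumericVector quat,
                     NumericMatrix well_t, NumericMatrix well_q,
                     NumericVector depth, NumericVector width,
                     double lambda, double conf_r, double wall_k) {
  LandscapeView L = make_view(well_t, well_q, depth, width, lambda, conf_r,
                              wall_k);
  double gt[3], gr[3];
  return potential_and_grad(trans.begin(), quat.begin(), L, gt, gr);
}

// [[Rcpp::export]]
List cpp_gradient(NumericVector trans, NumericVector quat,
                  NumericMatrix well_t, NumericMatrix well_q,
                  NumericVector depth, NumericVector width,
                  double lambda, double conf_r, double wall_k) {
  LandscapeView L = make_view(well_t, well_q, depth, width, lambda, conf_r,
                              wall_k);
  double gt[3], gr[3];
  double U = potential_and_grad(trans.begin(), quat.begin(), L, gt, gr);
  return List::create(_["energy"] = U,
                      _["translation"] = NumericVector::create(gt[0], gt[1], gt[2]),
                      _["rotation"] = NumericVector::create(gr[0], gr[1], gr[2]));
}

// [[Rcpp::export]]
List cpp_langevin_run(NumericVector t0, NumericVector q0,
                      NumericMatrix well_t, NumericMatrix well_q,
                      NumericVector depth, NumericVector width,
                      double lambda, double conf_r, double wall_k,
                      double dt, double gamma_t, double gamma_r, double kB,
                      NumericVector temps, int save_every) {
  LandscapeView L = make_view(well_t, well_q, depth, width, lambda, conf_r,
                              wall_k);
  int nsteps = temps.size();
  int nsave = nsteps / save_every + 1;
  NumericMatrix out_t(nsave, 3);
  NumericMatrix out_q(nsave, 4);
  double t[3] = { t0[0], t0[1], t0[2] };
  double q[4] = { q0[0], q0[1], q0[2], q0[3] };
  qnormalize(q);

  int isave = 0;
  auto save = [&](int slot) {
    double s = (q[0] < 0) ? -1.0 : 1.0;   // canonical sign: scalar >= 0
    for (int j = 0; j < 3; ++j) out_t(slot, j) = t[j];
    for (int j = 0; j < 4; ++j) out_q(slot, j) = s * q[j];
  };
  save(isave++);

  double gt[3], gr[3];
  for (int s = 0; s < nsteps; ++s) {
    potential_and_grad(t, q, L, gt, gr);
    double T = temps[s];
    double sig_t = std::sqrt(2.0 * kB * T * dt / gamma_t);
    double sig_r = std::sqrt(2.0 * kB * T * dt / gamma_r);
    for (int j = 0; j < 3; ++j)
      t[j] += -(dt / gamma_t) * gt[j] + sig_t * norm_rand();
    double dv[3];
    for (int j = 0; j < 3; ++j)
      dv[j] = -(dt / gamma_r) * gr[j] + sig_r * norm_rand();
    double ang = std::sqrt(dv[0]*dv[0] + dv[1]*dv[1] + dv[2]*dv[2]);
    if (ang > 1e-14) {
      double h = 0.5 * ang, sh = std::sin(h) / ang;
      double dq[4] = { std::cos(h), sh * dv[0], sh * dv[1], sh * dv[2] };
      double qn[4];
      qmul(q, dq, qn);           // body-frame increment
      for (int j = 0; j < 4; ++j) q[j] = qn[j];
      qnormalize(q);
    }
    if ((s + 1) % save_every == 0) save(isave++);
  }
  return List::create(_["translations"] = out_t, _["quaternions"] = out_q);
}
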