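#include <Rcpp.h>
using namespace Rcpp;

// Periodic wrap to [-pi, pi)
static inline double wrapc(double z) {
  return z - 2.0 * M_PI * std::floor((z + M_PI) / (2.0 * M_PI));
}

// Three-well landscape, treated as periodic on [-pi,pi)^2: the Gaussian
// basin term uses wrapped displacements so every periodic cell carries the
// same three wells.
static inline double u3w(double x, double y, double eps) {
  double bx = wrapc(x + 2.0 * M_PI / 3.0);
  double by = wrapc(y);
  double g = std::exp(-20.0 * bx * bx - 2.0 * by * by);
  return -eps * (std::cos(x) + std::sin(x) + 0.5 * std::cos(y) +
                 2.0 * std::cos(3.0 * x) + 2.0 * g);
}

static inline void grad3w(double x, double y, double eps,
                          double* gx, double* gy) {
  double bx = wrapc(x + 2.0 * M_PI / 3.0);
  double by = wrapc(y);
  double g = std::exp(-20.0 * bx * bx - 2.0 * by * by);
  *gx = -eps * (-std::sin(x) + std::cos(x) - 6.0 * std::sin(3.0 * x) -
                80.0 * bx * g);
  *gy = -eps * (-0.5 * std::sin(y) - 8.0 * by * g);
}

// [[Rcpp::export]]
double potential_cpp(double x, double y, double eps) {
  return u3w(x, y, eps);
}

// [[Rcpp::export]]
NumericMatrix gradient_cpp(NumericVector x, NumericVector y, double eps) {
  int n = x.size();
  NumericMatrix out(n, 2);
  double gx, gy;
  for (int i = 0; i < n; i++) {
    grad3w(x[i], y[i], eps, &gx, &gy);
    out(i, 0) = gx;
    out(i, 1) = gy;
  }
  return out;
}

// Underdamped Langevin integrator (BAOAB splitting).  potential_kind:
// 0 = periodic three-well (records wrapped coordinates),
// 1 = isotropic harmonic with spring constant k_spring (records raw).
// Uses R's RNG so runs are reproducible from set.seed().
// [[Rcpp::export]]
NumericMatrix langevin_cpp(double x0, double y0, double vx0, double vy0,
                           int nequil, int nstep, int stride,
                           double dt, double mass, double gamma, double kT,
                           double eps, double energy_noise,
                           int potential_kind, double k_spring) {
  int nframes = nstep / stride;
  NumericMatrix rec(nframes, 3);
  double x = x0, y = y0, vx = vx0, vy = vy0;
  double c1 = std::exp(-gamma * dt / mass);
  double c2 = (kT > 0.0) ? std::sqrt(kT / mass * (1.0 - c1 * c1)) : 0.0;
  double fx, fy;
  if (potential_kind == 0) {
    grad3w(x, y, eps, &fx, &fy);
  } else {
    fx = k_spring * x;
    fy = k_spring * y;
  }
  fx = -fx;
  fy = -fy;
  int total = nequil + nstep;
  int j = 0;
  for (int i = 1; i <= total; i++) {
    // B: half kick
    vx += 0.5 * dt * fx / mass;
    vy += 0.5 * dt * fy / mass;
    // A: half drift
    x += 0.5 * dt * vx;
    y += 0.5 * dt * vy;
    // O: Ornstein-Uhlenbeck velocity update
    if (c2 > 0.0) {
      vx = c1 * vx + c2 * R::rnorm(0.0, 1.0);
      vy = c1 * vy + c2 * R::rnorm(0.0, 1.0);
    } else {
      vx = c1 * vx;
      vy = c1 * vy;
    }
    // A: half drift
    x += 0.5 * dt * vx;
    y += 0.5 * dt * vy;
    // B: half kick with updated force
    if (potential_kind == 0) {
      grad3w(x, y, eps, &fx, &fy);
      fx = -fx;
      fy = -fy;
    } else {
      fx = -k_spring * x;
      fy = -k_spring * y;
    }
    vx += 0.5 * dt * fx / mass;
    vy += 0.5 * dt * fy / mass;
    if (!std::isfinite(x) || !std::isfinite(y) ||
        std::fabs(x) > 1e6 || std::fabs(y) > 1e6) {
      stop("trajectory diverged at step %d (x=%g, y=%g); reduce the "
           "timestep", i, x, y);
    }
    if (i > nequil && (i - nequil) % stride == 0) {
      double u, rx, ry;
      if (potential_kind == 0) {
        rx = wrapc(x);
        ry = wrapc(y);
        u = u3w(x, y, eps);
      } else {
        rx = x;
        ry = y;
        u = 0.5 * k_spring * (x * x + y * y);
      }
      if (energy_noise > 0.0) u += R::rnorm(0.0, energy_noise);
      rec(j, 0) = rx;
      rec(j, 1) = ry;
      rec(j, 2) = u;
      j++;
      if (j >= nframes) break;
    }
  }
  return rec;
}

// Steepest-descent basin assignment on the periodic three-well landscape.
// Each point is walked downhill (with periodic wrapping) until it comes
// within `capture` of one of the supplied minima; returns 1-based index of
// that minimum, or NA if maxit is exhausted.
// [[Rcpp::export]]
IntegerVector descend_basins_cpp(NumericVector x, NumericVector y, double eps,
                                 NumericVector minx, NumericVector miny,
                                 double step, int maxit, double capture) {
  int n = x.size(), nm = minx.size();
  IntegerVector out(n);
  double gx, gy;
  for (int i = 0; i < n; i++) {
    double px = wrapc(x[i]), py = wrapc(y[i]);
    int hit = NA_INTEGER;
    for (int it = 0; it < maxit; it++) {
      grad3w(px, py, eps, &gx, &gy);
      px = wrapc(px - step * gx);
      py = wrapc(py - step * gy);
      if (it % 5 == 0 || it == maxit - 1) {
        for (int m = 0; m < nm; m++) {
          double dx = wrapc(px - minx[m]);
          double dy = wrapc(py - miny[m]);
          if (dx * dx + dy * dy < capture * capture) {
            hit = m + 1;
            break;
          }
        }
        if (hit != NA_INTEGER) break;
      }
    }
    out[i] = hit;
  }
  return out;
}
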