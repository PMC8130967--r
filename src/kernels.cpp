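#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// squared distance between 3D segments [p0,p1] and [q0,q1] (Eberly's clamped
// quadratic minimisation)
static double seg_seg_dist2(const double *p0, const double *p1,
                            const double *q0, const double *q1) {
  double d1[3], d2[3], r[3];
  for (int k = 0; k < 3; ++k) {
    d1[k] = p1[k] - p0[k];
    d2[k] = q1[k] - q0[k];
    r[k]  = p0[k] - q0[k];
  }
  double a = d1[0]*d1[0] + d1[1]*d1[1] + d1[2]*d1[2];
  double e = d2[0]*d2[0] + d2[1]*d2[1] + d2[2]*d2[2];
  double f = d2[0]*r[0] + d2[1]*r[1] + d2[2]*r[2];
  const double EPS = 1e-14;
  double s = 0.0, t = 0.0;
  if (a <= EPS && e <= EPS) {
    // both degenerate: point-point
  } else if (a <= EPS) {
    t = f / e; t = std::min(1.0, std::max(0.0, t));
  } else {
    double c = d1[0]*r[0] + d1[1]*r[1] + d1[2]*r[2];
    if (e <= EPS) {
      s = -c / a; s = std::min(1.0, std::max(0.0, s));
    } else {
      double b = d1[0]*d2[0] + d1[1]*d2[1] + d1[2]*d2[2];
      double denom = a*e - b*b;
      if (denom > EPS) {
        s = (b*f - c*e) / denom;
        s = std::min(1.0, std::max(0.0, s));
      }
      t = (b*s + f) / e;
      if (t < 0.0)      { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
      else if (t > 1.0) { t = 1.0; s = std::min(1.0, std::max(0.0, (b - c) / a)); }
    }
  }
  double dx = p0[0] + s*d1[0] - (q0[0] + t*d2[0]);
  double dy = p0[1] + s*d1[1] - (q0[1] + t*d2[1]);
  double dz = p0[2] + s*d1[2] - (q0[2] + t*d2[2]);
  return dx*dx + dy*dy + dz*dz;
}

// as above, also reporting the closest-approach parameter s on the first
// segment
static double seg_seg_dist2_param(const double *p0, const double *p1,
                                  const double *q0, const double *q1,
                                  double *s_out) {
  double d1[3], d2[3], r[3];
  for (int k = 0; k < 3; ++k) {
    d1[k] = p1[k] - p0[k];
    d2[k] = q1[k] - q0[k];
    r[k]  = p0[k] - q0[k];
  }
  double a = d1[0]*d1[0] + d1[1]*d1[1] + d1[2]*d1[2];
  double e = d2[0]*d2[0] + d2[1]*d2[1] + d2[2]*d2[2];
  double f = d2[0]*r[0] + d2[1]*r[1] + d2[2]*r[2];
  const double EPS = 1e-14;
  double s = 0.0, t = 0.0;
  if (a <= EPS && e <= EPS) {
  } else if (a <= EPS) {
    t = std::min(1.0, std::max(0.0, f / e));
  } else {
    double c = d1[0]*r[0] + d1[1]*r[1] + d1[2]*r[2];
    if (e <= EPS) {
      s = std::min(1.0, std::max(0.0, -c / a));
    } else {
      double b = d1[0]*d2[0] + d1[1]*d2[1] + d1[2]*d2[2];
      double denom = a*e - b*b;
      if (denom > EPS)
        s = std::min(1.0, std::max(0.0, (b*f - c*e) / denom));
      t = (b*s + f) / e;
      if (t < 0.0)      { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
      else if (t > 1.0) { t = 1.0; s = std::min(1.0, std::max(0.0, (b - c) / a)); }
    }
  }
  *s_out = s;
  double dx = p0[0] + s*d1[0] - (q0[0] + t*d2[0]);
  double dy = p0[1] + s*d1[1] - (q0[1] + t*d2[1]);
  double dz = p0[2] + s*d1[2] - (q0[2] + t*d2[2]);
  return dx*dx + dy*dy + dz*dz;
}

// contact statistics for the network mesh-size metric: for each filament,
// the minimum axis distance to any other filament, and the sorted
// closest-approach positions (um along the filament) of all filaments
// with axis distance <= thr.  Returns per-filament min distances, the
// concatenated consecutive contact spacings, and per-filament contact
// counts.
// [[Rcpp::export]]
List cpp_contact_stats(NumericMatrix P0, NumericMatrix P1, double thr) {
  int n = P0.nrow();
  std::vector<double> a(3*n), b(3*n), len(n);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) { a[3*i+k] = P0(i,k); b[3*i+k] = P1(i,k); }
    double L2 = 0;
    for (int k = 0; k < 3; ++k) {
      double d = b[3*i+k] - a[3*i+k];
      L2 += d*d;
    }
    len[i] = std::sqrt(L2);
  }
  NumericVector mind(n, R_PosInf);
  IntegerVector ncontact(n, 0);
  std::vector< std::vector<double> > tpos(n);
  double thr2 = thr * thr;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double s;
      double d2 = seg_seg_dist2_param(&a[3*i], &b[3*i], &a[3*j], &b[3*j], &s);
      if (d2 < mind[i]) mind[i] = d2;
      if (d2 <= thr2) { tpos[i].push_back(s * len[i]); ++ncontact[i]; }
    }
    mind[i] = std::sqrt(mind[i]);
  }
  std::vector<double> gaps;
  for (int i = 0; i < n; ++i) {
    if (tpos[i].size() < 2) continue;
    std::sort(tpos[i].begin(), tpos[i].end());
    for (size_t k = 1; k < tpos[i].size(); ++k)
      gaps.push_back(tpos[i][k] - tpos[i][k-1]);
  }
  return List::create(_["min_dist"] = mind,
                      _["gaps"] = NumericVector(gaps.begin(), gaps.end()),
                      _["n_contacts"] = ncontact);
}

// per-segment minimum axis-to-axis distance to any other segment
// [[Rcpp::export]]
NumericVector cpp_nn_seg_dist(NumericMatrix P0, NumericMatrix P1) {
  int n = P0.nrow();
  NumericVector out(n, R_PosInf);
  if (n < 2) return out;
  std::vector<double> a(3*n), b(3*n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) { a[3*i+k] = P0(i,k); b[3*i+k] = P1(i,k); }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d2 = seg_seg_dist2(&a[3*i], &b[3*i], &a[3*j], &b[3*j]);
      if (d2 < out[i]) out[i] = d2;
      if (d2 < out[j]) out[j] = d2;
    }
  }
  for (int i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}

// rasterize the z-slice of a union of solid finite cylinders onto an
// nx x nx grid of pixel centers covering [0, box]^2; optional periodic
// images at +-box in x and y.  Returns 1 = inside an obstacle, or, with
// accumulate = true, the number of cylinders covering each pixel (the
// per-obstacle summed-area convention).
// [[Rcpp::export]]
IntegerMatrix cpp_obstacle_mask(NumericMatrix P0, NumericMatrix P1,
                                NumericVector radius, double z,
                                int nx, double box, bool periodic,
                                bool accumulate = false) {
  IntegerMatrix mask(nx, nx);
  double res = box / nx;
  int n = P0.nrow();
  int nshift = periodic ? 3 : 1;
  double shifts[3] = {0.0, -box, box};
  for (int i = 0; i < n; ++i) {
    double r = radius[i];
    double z0 = std::min(P0(i,2), P1(i,2)) - r;
    double z1 = std::max(P0(i,2), P1(i,2)) + r;
    if (z < z0 || z > z1) continue;
    for (int sx = 0; sx < nshift; ++sx) {
      for (int sy = 0; sy < nshift; ++sy) {
        double ax = P0(i,0) + shifts[sx], ay = P0(i,1) + shifts[sy], az = P0(i,2);
        double bx = P1(i,0) + shifts[sx], by = P1(i,1) + shifts[sy], bz = P1(i,2);
        double dx = bx-ax, dy = by-ay, dz = bz-az;
        double L2 = dx*dx + dy*dy + dz*dz;
        if (L2 <= 0) continue;
        // conservative 2D bounding box of the cylinder
        double xlo = std::min(ax,bx) - r, xhi = std::max(ax,bx) + r;
        double ylo = std::min(ay,by) - r, yhi = std::max(ay,by) + r;
        int i0 = std::max(0, (int)std::floor(xlo/res - 0.5));
        int i1 = std::min(nx-1, (int)std::ceil(xhi/res - 0.5));
        int j0 = std::max(0, (int)std::floor(ylo/res - 0.5));
        int j1 = std::min(nx-1, (int)std::ceil(yhi/res - 0.5));
        if (i1 < i0 || j1 < j0) continue;
        for (int ix = i0; ix <= i1; ++ix) {
          double px = (ix + 0.5) * res;
          for (int jy = j0; jy <= j1; ++jy) {
            if (!accumulate && mask(ix, jy)) continue;
            double py = (jy + 0.5) * res;
            double t = ((px-ax)*dx + (py-ay)*dy + (z-az)*dz) / L2;
            if (t < 0.0 || t > 1.0) continue;  // flat-ended cylinder
            double qx = px - (ax + t*dx);
            double qy = py - (ay + t*dy);
            double qz = z  - (az + t*dz);
            if (qx*qx + qy*qy + qz*qz <= r*r) {
              if (accumulate) mask(ix, jy) += 1; else mask(ix, jy) = 1;
            }
          }
        }
      }
    }
  }
  return mask;
}

// Monte Carlo random walk amid a periodically tiled blocked raster.
// blocked: nx x nx integer matrix (1 = blocked), covering [0, box]^2.
// Walkers start uniformly in free space, take Gaussian steps of per-axis
// sd sigma; a step ending in the blocked set is rejected (resampled, up to
// max_try times) or specularly handled by simple bounce-back when
// reflect = true.  Unwrapped positions are recorded at n_rec evenly spaced
// times.  Returns list(x, y) of n_walkers x n_rec matrices of displacements.
// [[Rcpp::export]]
List cpp_mc_walk(IntegerMatrix blocked, double box, int n_walkers,
                 int n_steps, double sigma, int n_rec, int seed,
                 bool reflect) {
  int nx = blocked.nrow();
  double res = box / nx;
  std::mt19937_64 rng((uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL);
  std::normal_distribution<double> gauss(0.0, sigma);
  std::uniform_real_distribution<double> unif(0.0, box);
  NumericMatrix DX(n_walkers, n_rec), DY(n_walkers, n_rec);
  IntegerVector rec_step(n_rec);
  for (int k = 0; k < n_rec; ++k)
    rec_step[k] = (int)std::round((double)(k + 1) * n_steps / n_rec);
  auto is_blocked = [&](double x, double y) {
    int ix = (int)std::floor(x / res); ix %= nx; if (ix < 0) ix += nx;
    int jy = (int)std::floor(y / res); jy %= nx; if (jy < 0) jy += nx;
    return blocked(ix, jy) != 0;
  };
  const int max_try = 50;
  for (int w = 0; w < n_walkers; ++w) {
    double x, y;
    do { x = unif(rng); y = unif(rng); } while (is_blocked(x, y));
    double x0 = x, y0 = y;
    int k = 0;
    for (int s = 1; s <= n_steps; ++s) {
      // a step is admissible when neither its midpoint nor its endpoint
      // lies in the blocked set (the midpoint test prevents tunnelling
      // through blocked walls thinner than the step length)
      if (reflect) {
        double nxp = x + gauss(rng), nyp = y + gauss(rng);
        if (!is_blocked(nxp, nyp) &&
            !is_blocked(0.5 * (x + nxp), 0.5 * (y + nyp))) {
          x = nxp; y = nyp;
        }
        // bounce-back: stay in place when the step hits an obstacle
      } else {
        for (int t = 0; t < max_try; ++t) {
          double nxp = x + gauss(rng), nyp = y + gauss(rng);
          if (!is_blocked(nxp, nyp) &&
              !is_blocked(0.5 * (x + nxp), 0.5 * (y + nyp))) {
            x = nxp; y = nyp; break;
          }
        }
      }
      if (k < n_rec && s == rec_step[k]) {
        DX(w, k) = x - x0; DY(w, k) = y - y0; ++k;
      }
    }
  }
  return List::create(_["dx"] = DX, _["dy"] = DY, _["step"] = rec_step);
}
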