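// Random-walk core for substrates of parallel impermeable cylinders.
//
// Geometry is 2D in the transverse (y,z) plane -- cylinders are invariant
// along x -- plus an independent free 1D walk along x. Extra-axonal walkers
// live in a periodic square box and reflect specularly off cylinder
// surfaces; intra-axonal walkers are confined to their own cylinder.
// Positions are tracked unwrapped so that diffusion-encoding phases can be
// computed from running position integrals reported at caller-supplied
// checkpoint times.
//
// Performance notes: the loop is walker-outer so a walker's state stays in
// registers over the whole trajectory; a single uniform draw per step
// yields both the tabulated transverse direction and the axial sign (the
// axial walk is fixed-step +-sqrt(2 D dt), which has the exact per-step
// variance and is Gaussian over the thousands of steps of any readout).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Circle {
  double y, z, r;
};

// cell list over [0,L)^2 of circle images inflated by `margin`
struct CellGrid {
  int n;
  double L, cell;
  std::vector<std::vector<int>> cells; // indices into images
  std::vector<Circle> images;
  // CSR-flattened per-cell circle copies for cache-friendly scans
  std::vector<int> off;
  std::vector<double> fy, fz, fr;

  void build(const NumericVector& cy, const NumericVector& cz,
             const NumericVector& cr, double L_, double margin) {
    L = L_;
    // small cells keep per-cell candidate lists short; circles are binned
    // into every cell their margin-inflated footprint touches
    cell = std::max(4.0 * margin, L / 256.0);
    n = std::max(1, (int)std::floor(L / cell));
    cell = L / n;
    cells.assign((size_t)n * n, {});
    images.clear();
    for (int i = 0; i < cr.size(); ++i) {
      for (int oy = -1; oy <= 1; ++oy) {
        for (int oz = -1; oz <= 1; ++oz) {
          double y = cy[i] + oy * L, z = cz[i] + oz * L;
          double infl = cr[i] + margin;
          if (y + infl < 0 || y - infl >= L || z + infl < 0 || z - infl >= L)
            continue;
          images.push_back({y, z, cr[i]});
          int idx = (int)images.size() - 1;
          int y0 = std::max(0, (int)std::floor((y - infl) / cell));
          int y1 = std::min(n - 1, (int)std::floor((y + infl) / cell));
          int z0 = std::max(0, (int)std::floor((z - infl) / cell));
          int z1 = std::min(n - 1, (int)std::floor((z + infl) / cell));
          for (int a = y0; a <= y1; ++a)
            for (int b = z0; b <= z1; ++b)
              cells[(size_t)a * n + b].push_back(idx);
        }
      }
    }
    off.assign((size_t)n * n + 1, 0);
    for (size_t c = 0; c < cells.size(); ++c)
      off[c + 1] = off[c] + (int)cells[c].size();
    fy.resize(off.back());
    fz.resize(off.back());
    fr.resize(off.back());
    for (size_t c = 0; c < cells.size(); ++c) {
      int base = off[c];
      for (size_t k = 0; k < cells[c].size(); ++k) {
        const Circle& im = images[cells[c][k]];
        fy[base + k] = im.y;
        fz[base + k] = im.z;
        fr[base + k] = im.r;
      }
    }
  }

  inline size_t cell_index(double y, double z) const {
    int a = (int)std::floor(y / cell);
    int b = (int)std::floor(z / cell);
    a = std::min(std::max(a, 0), n - 1);
    b = std::min(std::max(b, 0), n - 1);
    return (size_t)a * n + b;
  }

  const std::vector<int>& at(double y, double z) const {
    int a = (int)std::floor(y / cell);
    int b = (int)std::floor(z / cell);
    a = std::min(std::max(a, 0), n - 1);
    b = std::min(std::max(b, 0), n - 1);
    return cells[(size_t)a * n + b];
  }
};

// earliest t in (tmin, 1] at which p + t*v crosses circle c (|p-c| = r)
// returns -1 if none
inline double hit_time(double py, double pz, double vy, double vz,
                       const Circle& c, double tmin) {
  double dy = py - c.y, dz = pz - c.z;
  double a = vy * vy + vz * vz;
  if (a <= 0.0) return -1.0;
  double b = 2.0 * (dy * vy + dz * vz);
  double q = dy * dy + dz * dz - c.r * c.r;
  double disc = b * b - 4.0 * a * q;
  if (disc < 0.0) return -1.0;
  double sq = std::sqrt(disc);
  double t1 = (-b - sq) / (2.0 * a);
  double t2 = (-b + sq) / (2.0 * a);
  if (t1 > tmin && t1 <= 1.0) return t1;
  if (t2 > tmin && t2 <= 1.0) return t2;
  return -1.0;
}

inline double wrap(double x, double L) {
  // (std::fmod avoided: it binds to a versioned libm symbol newer than
  // some runtimes provide)
  double w = x - L * std::floor(x / L);
  return (w >= L) ? w - L : w;
}

} // namespace

// [[Rcpp::export(name = ".cpp_random_walk")]]
List cpp_random_walk(NumericVector cy, NumericVector cz, NumericVector cr,
                     double box, IntegerVector membership0,
                     NumericVector y0, NumericVector z0,
                     int n_steps, double dt, double D,
                     NumericVector checkpoints) {
  const int nw = y0.size();
  const int nc = checkpoints.size();
  const double ell = std::sqrt(4.0 * D * dt); // transverse step length
  const double sx = std::sqrt(2.0 * D * dt);  // axial step length
  const double eps = 1e-9;
  const double duration = dt * n_steps;
  const double tol = 1e-7 * duration;

  CellGrid grid;
  grid.build(cy, cz, cr, box, ell + 1e-6);

  // direction table
  const int K = 8192;
  std::vector<double> ct(K), st(K);
  for (int k = 0; k < K; ++k) {
    double th = 2.0 * M_PI * (k + 0.5) / K;
    ct[k] = std::cos(th);
    st[k] = std::sin(th);
  }

  NumericVector outY(nw), outZ(nw), outX(nw);
  NumericMatrix ckY(nw, nc), ckZ(nw, nc), ckX(nw, nc);
  IntegerVector mem_end(nw);

  RNGScope rng;

  for (int w = 0; w < nw; ++w) {
    double py = y0[w], pz = z0[w], px = 0.0;
    double Iy = 0.0, Iz = 0.0, Ix = 0.0;
    int next_ck = 0;
    const int mem = membership0[w];
    const Circle own = (mem >= 0)
      ? Circle{cy[mem], cz[mem], cr[mem]}
      : Circle{0.0, 0.0, 0.0};
    const double safe = (mem >= 0) ? (own.r - ell - eps) : 0.0;
    const double safe2 = safe * safe;

    for (int s = 0; s < n_steps; ++s) {
      double u = unif_rand() * K;
      int k = (int)u;
      if (k >= K) k = K - 1;
      double axs = (u - k < 0.5) ? -sx : sx;
      double vy = ell * ct[k], vz = ell * st[k];
      const double oy = py, oz = pz, ox = px;

      if (mem >= 0) {
        // intra: confined to own cylinder, local (unwrapped) geometry
        double dy0 = py - own.y, dz0 = pz - own.z;
        if (safe > 0.0 && dy0 * dy0 + dz0 * dz0 < safe2) {
          py += vy; // wall out of reach this step
          pz += vz;
        } else {
          double yy = py, zz = pz;
          for (int it = 0; it < 16; ++it) {
            double th = hit_time(yy, zz, vy, vz, own, 0.0);
            if (th < 0.0) {
              yy += vy;
              zz += vz;
              break;
            }
            double hy = yy + th * vy, hz = zz + th * vz;
            double ny = (hy - own.y) / own.r, nz2 = (hz - own.z) / own.r;
            double ry = (1.0 - th) * vy, rz = (1.0 - th) * vz;
            double dot = ry * ny + rz * nz2;
            ry -= 2.0 * dot * ny;
            rz -= 2.0 * dot * nz2;
            yy = hy - eps * ny; // nudge back inside
            zz = hz - eps * nz2;
            vy = ry;
            vz = rz;
            if (it == 15) { vy = 0.0; vz = 0.0; }
          }
          py = yy;
          pz = zz;
        }
      } else {
        // extra: wrapped geometry with ghost images
        double wy = wrap(py, box), wz = wrap(pz, box);
        double offy = py - wy, offz = pz - wz;
        for (int it = 0; it < 16; ++it) {
          size_t ci0 = grid.cell_index(wy, wz);
          int b0 = grid.off[ci0], b1 = grid.off[ci0 + 1];
          double tbest = 2.0;
          int ibest = -1;
          for (int ci = b0; ci < b1; ++ci) {
            double dy = wy - grid.fy[ci], dz = wz - grid.fz[ci];
            double reach = grid.fr[ci] + ell + eps;
            if (dy * dy + dz * dz > reach * reach) continue; // unreachable
            Circle c{grid.fy[ci], grid.fz[ci], grid.fr[ci]};
            double th = hit_time(wy, wz, vy, vz, c, 1e-12);
            if (th >= 0.0 && th < tbest) {
              tbest = th;
              ibest = ci;
            }
          }
          if (ibest < 0) {
            wy += vy;
            wz += vz;
            break;
          }
          const double cyh = grid.fy[ibest], czh = grid.fz[ibest],
                       crh = grid.fr[ibest];
          double hy = wy + tbest * vy, hz = wz + tbest * vz;
          double ny = (hy - cyh) / crh, nz2 = (hz - czh) / crh;
          double ry = (1.0 - tbest) * vy, rz = (1.0 - tbest) * vz;
          double dot = ry * ny + rz * nz2;
          ry -= 2.0 * dot * ny;
          rz -= 2.0 * dot * nz2;
          wy = hy + eps * ny; // nudge outward
          wz = hz + eps * nz2;
          vy = ry;
          vz = rz;
          if (it == 15) { vy = 0.0; vz = 0.0; }
        }
        py = wy + offy;
        pz = wz + offz;
      }
      px += axs;

      // trapezoid integral over the step (linear path approximation);
      // split at any checkpoint inside (t_now, t_end]
      double t_now = s * dt;
      double t_end = (s == n_steps - 1) ? duration : (s + 1) * dt;
      if (next_ck < nc && checkpoints[next_ck] <= t_end + tol) {
        double t0 = t_now;
        double ay = oy, az = oz, ax = ox;
        int ck = next_ck;
        while (ck < nc && checkpoints[ck] <= t_end + tol) {
          double f = (checkpoints[ck] - t_now) / dt;
          if (f < 0.0) f = 0.0;
          if (f > 1.0) f = 1.0;
          double my = oy + f * (py - oy), mz = oz + f * (pz - oz),
                 mx = ox + f * (px - ox);
          double seg = checkpoints[ck] - t0;
          Iy += 0.5 * (ay + my) * seg;
          Iz += 0.5 * (az + mz) * seg;
          Ix += 0.5 * (ax + mx) * seg;
          ckY(w, ck) = Iy;
          ckZ(w, ck) = Iz;
          ckX(w, ck) = Ix;
          ay = my;
          az = mz;
          ax = mx;
          t0 = checkpoints[ck];
          ++ck;
        }
        Iy += 0.5 * (ay + py) * (t_end - t0);
        Iz += 0.5 * (az + pz) * (t_end - t0);
        Ix += 0.5 * (ax + px) * (t_end - t0);
        next_ck = ck;
      } else {
        Iy += 0.5 * (oy + py) * dt;
        Iz += 0.5 * (oz + pz) * dt;
        Ix += 0.5 * (ox + px) * dt;
      }
    }

    outY[w] = py;
    outZ[w] = pz;
    outX[w] = px;

    // membership audit (impermeability: intra stays in its cylinder,
    // extra stays outside all cylinders)
    if (mem >= 0) {
      double dy = py - own.y, dz = pz - own.z;
      mem_end[w] = (dy * dy + dz * dz <= own.r * own.r + 1e-6) ? mem : -2;
    } else {
      double wy = wrap(py, box), wz = wrap(pz, box);
      int inside = -1;
      const std::vector<int>& cand = grid.at(wy, wz);
      for (size_t ci = 0; ci < cand.size(); ++ci) {
        const Circle& c = grid.images[cand[ci]];
        double dy = wy - c.y, dz = wz - c.z;
        if (dy * dy + dz * dz < (c.r - 1e-6) * (c.r - 1e-6)) {
          inside = 1;
          break;
        }
      }
      mem_end[w] = inside > 0 ? -2 : -1;
    }
  }

  return List::create(
    _["y"] = outY, _["z"] = outZ, _["x"] = outX,
    _["int_y"] = ckY, _["int_z"] = ckZ, _["int_x"] = ckX,
    _["membership_end"] = mem_end
  );
}
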