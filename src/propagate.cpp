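#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Deterministic streamline propagation over a voxelwise peak field.
//
// seeds: n x 6 (x, y, z position in mm; initial axial unit vector)
// peak_vecs: total_peaks x 3 unit axial vectors, grouped per voxel
// peak_off: 0-based offset into peak_vecs per grid voxel (length nvox + 1)
// wm: white-matter flag per grid voxel (column-major linear order)
// dim: grid dimensions; vox: voxel size in mm
// step: mm; cos_thresh: cos of the per-step turn limit; max_steps per walk
//
// Walk rule: at each step look up the current voxel's axial vectors
// (nearest-neighbor), take the one closest in angle to the incoming
// direction, sign-aligned with propagation; abort the walk if the angle
// exceeds the turn limit. A walk ends one step after leaving the white
// matter (the exit point is kept as the endpoint). Two walks per seed
// (along +/- the initial vector) are concatenated through the seed.
// [[Rcpp::export]]
List propagate_streamlines(NumericMatrix seeds, NumericMatrix peak_vecs,
                           IntegerVector peak_off, IntegerVector wm,
                           IntegerVector dim, NumericVector vox,
                           double step, double cos_thresh, int max_steps) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double vx = vox[0], vy = vox[1], vz = vox[2];
  const int nseed = seeds.nrow();
  List out(nseed);

  std::vector<double> walk; // reusable buffer (x,y,z triples)

  for (int s = 0; s < nseed; ++s) {
    double sx = seeds(s, 0), sy = seeds(s, 1), sz = seeds(s, 2);
    std::vector<double> fwd, bwd;
    for (int half = 0; half < 2; ++half) {
      double px = sx, py = sy, pz = sz;
      double dx = seeds(s, 3), dy = seeds(s, 4), dz = seeds(s, 5);
      if (half == 1) { dx = -dx; dy = -dy; dz = -dz; }
      std::vector<double> &buf = (half == 0) ? fwd : bwd;
      for (int it = 0; it < max_steps; ++it) {
        int ix = (int)std::floor(px / vx);
        int iy = (int)std::floor(py / vy);
        int iz = (int)std::floor(pz / vz);
        if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz)
          break;                          // left the grid: endpoint recorded
        int lin = ix + iy * nx + iz * nx * ny;
        if (!wm[lin]) break;              // exit voxel is the endpoint
        int o0 = peak_off[lin], o1 = peak_off[lin + 1];
        if (o1 <= o0) break;              // no direction to follow
        double best = -1.0; int bestk = -1; double bestdot = 0.0;
        for (int k = o0; k < o1; ++k) {
          double dot = dx * peak_vecs(k, 0) + dy * peak_vecs(k, 1) +
                       dz * peak_vecs(k, 2);
          double ad = std::fabs(dot);
          if (ad > best) { best = ad; bestk = k; bestdot = dot; }
        }
        if (best < cos_thresh) break;     // turn sharper than the limit
        double sgn = (bestdot >= 0) ? 1.0 : -1.0;
        dx = sgn * peak_vecs(bestk, 0);
        dy = sgn * peak_vecs(bestk, 1);
        dz = sgn * peak_vecs(bestk, 2);
        px += step * dx; py += step * dy; pz += step * dz;
        buf.push_back(px); buf.push_back(py); buf.push_back(pz);
      }
    }
    int nf = fwd.size() / 3, nb = bwd.size() / 3;
    NumericMatrix line(nb + 1 + nf, 3);
    for (int i = 0; i < nb; ++i) {        // backward walk, reversed
      int j = nb - 1 - i;
      line(i, 0) = bwd[3 * j]; line(i, 1) = bwd[3 * j + 1];
      line(i, 2) = bwd[3 * j + 2];
    }
    line(nb, 0) = sx; line(nb, 1) = sy; line(nb, 2) = sz;
    for (int i = 0; i < nf; ++i) {
      line(nb + 1 + i, 0) = fwd[3 * i]; line(nb + 1 + i, 1) = fwd[3 * i + 1];
      line(nb + 1 + i, 2) = fwd[3 * i + 2];
    }
    out[s] = line;
  }
  return out;
}
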