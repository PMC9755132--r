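// Hot loops of the patch-based denoisers: block matching, separable
// orthonormal DCT collaborative filtering (hard-threshold and Wiener
// stages), weighted aggregation, and nonlocal means. Volumes are column-
// major (x fastest), matching R arrays; corners are 0-based here and
// converted at the R boundary.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Vol {
  const double* p;
  int nx, ny, nz;
  Vol(const NumericVector& v, const IntegerVector& dims)
      : p(v.begin()), nx(dims[0]), ny(dims[1]), nz(dims[2]) {}
  inline double at(int x, int y, int z) const {
    return p[x + (std::size_t)nx * (y + (std::size_t)ny * z)];
  }
};

// orthonormal DCT-II matrix, row k = basis vector k
std::vector<double> dct_matrix(int n) {
  std::vector<double> C((std::size_t)n * n);
  for (int k = 0; k < n; ++k) {
    double s = std::sqrt((k == 0 ? 1.0 : 2.0) / n);
    for (int j = 0; j < n; ++j)
      C[(std::size_t)k * n + j] = s * std::cos(M_PI * (2 * j + 1) * k / (2.0 * n));
  }
  return C;
}

// reference-patch corner positions along one axis: stride steps plus the
// final corner n - p so that every voxel is covered
std::vector<int> corner_seq(int n, int p, int s) {
  std::vector<int> out;
  for (int c = 0; c + p <= n; c += s) out.push_back(c);
  if (out.empty() || out.back() != n - p) out.push_back(n - p);
  return out;
}

// SSD with early abort once the running sum exceeds `bound`
inline double patch_ssd(const Vol& v, int ax, int ay, int az,
                        int bx, int by, int bz,
                        int px, int py, int pz, double bound) {
  double d = 0.0;
  for (int iz = 0; iz < pz; ++iz) {
    for (int iy = 0; iy < py; ++iy)
      for (int ix = 0; ix < px; ++ix) {
        double e = v.at(ax + ix, ay + iy, az + iz) -
                   v.at(bx + ix, by + iy, bz + iz);
        d += e * e;
      }
    if (d > bound) return d;
  }
  return d;
}

struct Corner { int x, y, z; double d; };

// best-`maxg` candidates within the search window by mean-squared patch
// distance; the reference is always first and ties are broken by
// lexicographic (x, y, z) corner order (the enumeration order below, kept
// stable by strict-less insertion)
std::vector<Corner> match_group(const Vol& v, int cx, int cy, int cz,
                                int px, int py, int pz,
                                int rx, int ry, int rz, int maxg) {
  std::vector<Corner> best;
  best.reserve(maxg + 1);
  int x0 = std::max(0, cx - rx), x1 = std::min(v.nx - px, cx + rx);
  int y0 = std::max(0, cy - ry), y1 = std::min(v.ny - py, cy + ry);
  int z0 = std::max(0, cz - rz), z1 = std::min(v.nz - pz, cz + rz);
  double worst = R_PosInf;
  for (int x = x0; x <= x1; ++x)
    for (int y = y0; y <= y1; ++y)
      for (int z = z0; z <= z1; ++z) {
        double d = (x == cx && y == cy && z == cz)
                       ? -1.0
                       : patch_ssd(v, cx, cy, cz, x, y, z, px, py, pz, worst);
        if ((int)best.size() == maxg && d >= worst) continue;
        Corner c{x, y, z, d};
        auto it = std::upper_bound(
            best.begin(), best.end(), c,
            [](const Corner& a, const Corner& b) { return a.d < b.d; });
        best.insert(it, c);
        if ((int)best.size() > maxg) best.pop_back();
        if ((int)best.size() == maxg) worst = best.back().d;
      }
  return best;
}

// separable forward (inv = false) or inverse (inv = true) orthonormal DCT
// over a group buffer G[j * pvox + (ix + px*(iy + py*iz))]
void transform_group(std::vector<double>& G, int g, int px, int py, int pz,
                     const std::vector<double>& Cx,
                     const std::vector<double>& Cy,
                     const std::vector<double>& Cz,
                     const std::vector<double>& Cg, bool inv) {
  int pvox = px * py * pz;
  std::vector<double> tmp(std::max(std::max(px, py), std::max(pz, g)));
  // along patch x
  if (px > 1)
    for (int j = 0; j < g; ++j)
      for (int iz = 0; iz < pz; ++iz)
        for (int iy = 0; iy < py; ++iy) {
          double* row = &G[(std::size_t)j * pvox + px * (iy + (std::size_t)py * iz)];
          for (int k = 0; k < px; ++k) {
            double s = 0;
            for (int q = 0; q < px; ++q)
              s += (inv ? Cx[(std::size_t)q * px + k] : Cx[(std::size_t)k * px + q]) * row[q];
            tmp[k] = s;
          }
          std::copy(tmp.begin(), tmp.begin() + px, row);
        }
  // along patch y
  if (py > 1)
    for (int j = 0; j < g; ++j)
      for (int iz = 0; iz < pz; ++iz)
        for (int ix = 0; ix < px; ++ix) {
          double* base = &G[(std::size_t)j * pvox + ix + (std::size_t)px * py * iz];
          for (int k = 0; k < py; ++k) {
            double s = 0;
            for (int q = 0; q < py; ++q)
              s += (inv ? Cy[(std::size_t)q * py + k] : Cy[(std::size_t)k * py + q]) * base[(std::size_t)q * px];
            tmp[k] = s;
          }
          for (int k = 0; k < py; ++k) base[(std::size_t)k * px] = tmp[k];
        }
  // along patch z
  if (pz > 1)
    for (int j = 0; j < g; ++j)
      for (int iy = 0; iy < py; ++iy)
        for (int ix = 0; ix < px; ++ix) {
          double* base = &G[(std::size_t)j * pvox + ix + (std::size_t)px * iy];
          int st = px * py;
          for (int k = 0; k < pz; ++k) {
            double s = 0;
            for (int q = 0; q < pz; ++q)
              s += (inv ? Cz[(std::size_t)q * pz + k] : Cz[(std::size_t)k * pz + q]) * base[(std::size_t)q * st];
            tmp[k] = s;
          }
          for (int k = 0; k < pz; ++k) base[(std::size_t)k * st] = tmp[k];
        }
  // along grouping dimension
  if (g > 1)
    for (int p = 0; p < pvox; ++p) {
      for (int k = 0; k < g; ++k) {
        double s = 0;
        for (int q = 0; q < g; ++q)
          s += (inv ? Cg[(std::size_t)q * g + k] : Cg[(std::size_t)k * g + q]) * G[(std::size_t)q * pvox + p];
        tmp[k] = s;
      }
      for (int k = 0; k < g; ++k) G[(std::size_t)k * pvox + p] = tmp[k];
    }
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_block_match(NumericVector vol, IntegerVector dims,
                              IntegerVector corner, IntegerVector patch,
                              IntegerVector search, int max_group) {
  Vol v(vol, dims);
  std::vector<Corner> grp =
      match_group(v, corner[0], corner[1], corner[2], patch[0], patch[1],
                  patch[2], search[0], search[1], search[2], max_group);
  IntegerMatrix out(grp.size(), 3);
  for (std::size_t i = 0; i < grp.size(); ++i) {
    out(i, 0) = grp[i].x;
    out(i, 1) = grp[i].y;
    out(i, 2) = grp[i].z;
  }
  return out;
}

// Full hard-threshold (or Wiener, when a pilot estimate is supplied)
// block-matching collaborative-filtering pass.
// [[Rcpp::export]]
NumericVector cpp_bm_denoise(NumericVector vol, IntegerVector dims,
                             IntegerVector patch, IntegerVector stride,
                             IntegerVector search, int max_group,
                             double threshold, double sigma,
                             Nullable<NumericVector> pilot_ = R_NilValue) {
  Vol v(vol, dims);
  bool wiener = pilot_.isNotNull();
  NumericVector pilot;
  if (wiener) pilot = pilot_.get();
  Vol vp(wiener ? pilot : vol, dims);  // match (and pilot coeffs) on pilot

  int px = patch[0], py = patch[1], pz = patch[2];
  if (px > dims[0] || py > dims[1] || pz > dims[2])
    stop("patch larger than volume");
  int pvox = px * py * pz;

  std::vector<double> Cx = dct_matrix(px), Cy = dct_matrix(py),
                      Cz = dct_matrix(pz);
  std::vector<std::vector<double>> Cgs(max_group + 1);
  for (int g = 1; g <= max_group; ++g) Cgs[g] = dct_matrix(g);

  std::vector<int> xs = corner_seq(dims[0], px, stride[0]);
  std::vector<int> ys = corner_seq(dims[1], py, stride[1]);
  std::vector<int> zs = corner_seq(dims[2], pz, stride[2]);

  std::size_t nvox = vol.size();
  std::vector<double> num(nvox, 0.0), den(nvox, 0.0);
  std::vector<double> G, P;

  for (int zc : zs)
    for (int yc : ys)
      for (int xc : xs) {
        std::vector<Corner> grp =
            match_group(vp, xc, yc, zc, px, py, pz, search[0], search[1],
                        search[2], max_group);
        int g = (int)grp.size();
        G.assign((std::size_t)g * pvox, 0.0);
        for (int j = 0; j < g; ++j)
          for (int iz = 0; iz < pz; ++iz)
            for (int iy = 0; iy < py; ++iy)
              for (int ix = 0; ix < px; ++ix)
                G[(std::size_t)j * pvox + ix + px * (iy + (std::size_t)py * iz)] =
                    v.at(grp[j].x + ix, grp[j].y + iy, grp[j].z + iz);
        transform_group(G, g, px, py, pz, Cx, Cy, Cz, Cgs[g], false);

        double w;
        if (!wiener) {
          int nret = 0;
          for (std::size_t i = 0; i < G.size(); ++i) {
            if (i == 0) {  // group DC always retained
              if (G[i] != 0.0) ++nret;
              continue;
            }
            if (std::fabs(G[i]) < threshold) G[i] = 0.0;
            else ++nret;
          }
          w = 1.0 / (1.0 + nret);
        } else {
          P.assign((std::size_t)g * pvox, 0.0);
          for (int j = 0; j < g; ++j)
            for (int iz = 0; iz < pz; ++iz)
              for (int iy = 0; iy < py; ++iy)
                for (int ix = 0; ix < px; ++ix)
                  P[(std::size_t)j * pvox + ix + px * (iy + (std::size_t)py * iz)] =
                      vp.at(grp[j].x + ix, grp[j].y + iy, grp[j].z + iz);
          transform_group(P, g, px, py, pz, Cx, Cy, Cz, Cgs[g], false);
          double s2 = sigma * sigma, wsum = 0.0;
          for (std::size_t i = 0; i < G.size(); ++i) {
            double t2 = P[i] * P[i];
            double wi = t2 / (t2 + s2);
            G[i] *= wi;
            wsum += wi * wi;
          }
          w = 1.0 / (1.0 + wsum);
        }

        transform_group(G, g, px, py, pz, Cx, Cy, Cz, Cgs[g], true);
        for (int j = 0; j < g; ++j)
          for (int iz = 0; iz < pz; ++iz)
            for (int iy = 0; iy < py; ++iy)
              for (int ix = 0; ix < px; ++ix) {
                std::size_t o = grp[j].x + ix +
                    (std::size_t)dims[0] * (grp[j].y + iy +
                    (std::size_t)dims[1] * (grp[j].z + iz));
                num[o] += w * G[(std::size_t)j * pvox + ix + px * (iy + (std::size_t)py * iz)];
                den[o] += w;
              }
      }

  NumericVector out(nvox);
  for (std::size_t i = 0; i < nvox; ++i)
    out[i] = den[i] > 0 ? num[i] / den[i] : vol[i];
  out.attr("dim") = dims;
  return out;
}

// All matched groups for a stride sweep; corners returned as 0-based flat
// indices (x + nx*(y + ny*z)), one row per reference patch, -1 padding.
// [[Rcpp::export]]
IntegerMatrix cpp_match_all(NumericVector vol, IntegerVector dims,
                            IntegerVector patch, IntegerVector stride,
                            IntegerVector search, int max_group) {
  Vol v(vol, dims);
  int px = patch[0], py = patch[1], pz = patch[2];
  if (px > dims[0] || py > dims[1] || pz > dims[2])
    stop("patch larger than volume");
  std::vector<int> xs = corner_seq(dims[0], px, stride[0]);
  std::vector<int> ys = corner_seq(dims[1], py, stride[1]);
  std::vector<int> zs = corner_seq(dims[2], pz, stride[2]);
  std::size_t nref = xs.size() * ys.size() * zs.size();
  IntegerMatrix out(nref, max_group);
  std::size_t r = 0;
  for (int zc : zs)
    for (int yc : ys)
      for (int xc : xs) {
        std::vector<Corner> grp =
            match_group(v, xc, yc, zc, px, py, pz, search[0], search[1],
                        search[2], max_group);
        for (int j = 0; j < max_group; ++j)
          out(r, j) = j < (int)grp.size()
                          ? grp[j].x + dims[0] * (grp[j].y + dims[1] * grp[j].z)
                          : -1;
        ++r;
      }
  return out;
}

// Nonlocal means: each voxel is the similarity-weighted mean of window
// centers, with the noise-compensated exponential weight
// exp(-max(d2m - 2 sigma^2, 0) / h^2), d2m the mean squared patch distance.
// [[Rcpp::export]]
NumericVector cpp_nlm(NumericVector vol, IntegerVector dims, int patch_radius,
                      int search_radius, double h, double sigma) {
  Vol v(vol, dims);
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(vol.size());
  double h2 = h * h, s2 = 2.0 * sigma * sigma;
  int pr = patch_radius, sr = search_radius;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double wsum = 0.0, acc = 0.0;
        for (int dz = -sr; dz <= sr; ++dz)
          for (int dy = -sr; dy <= sr; ++dy)
            for (int dx = -sr; dx <= sr; ++dx) {
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
                  zz >= nz)
                continue;
              double d = 0.0;
              int n = 0;
              for (int qz = -pr; qz <= pr; ++qz)
                for (int qy = -pr; qy <= pr; ++qy)
                  for (int qx = -pr; qx <= pr; ++qx) {
                    int ax = x + qx, ay = y + qy, az = z + qz;
                    int bx = xx + qx, by = yy + qy, bz = zz + qz;
                    if (ax < 0 || ay < 0 || az < 0 || ax >= nx || ay >= ny ||
                        az >= nz || bx < 0 || by < 0 || bz < 0 || bx >= nx ||
                        by >= ny || bz >= nz)
                      continue;
                    double e = v.at(ax, ay, az) - v.at(bx, by, bz);
                    d += e * e;
                    ++n;
                  }
              double d2m = n > 0 ? d / n : 0.0;
              double w = std::exp(-std::max(d2m - s2, 0.0) / h2);
              wsum += w;
              acc += w * v.at(xx, yy, zz);
            }
        out[x + (std::size_t)nx * (y + (std::size_t)ny * z)] =
            wsum > 0 ? acc / wsum : v.at(x, y, z);
      }
  out.attr("dim") = dims;
  return out;
}
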