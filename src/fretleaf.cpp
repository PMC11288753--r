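#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Gaussian kernel truncated at 3 sigma, normalised to sum 1.
static std::vector<double> gauss_kernel(double sigma, int &radius) {
  radius = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    s += k[i + radius];
  }
  for (double &v : k) v /= s;
  return k;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Separable 3D Gaussian blur with replicate (nearest) edge padding.
// sigma is given in voxels per axis; an axis with sigma <= 0 is skipped.
// Each pass streams contiguous memory: the x pass convolves within lines,
// the y and z passes accumulate weighted shifted columns/planes.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur3d(NumericVector x, NumericVector sigma_vox) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 3) stop("expected a 3D array");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long plane = (long)nx * ny;
  std::vector<double> a(x.begin(), x.end());
  std::vector<double> b(a.size());

  // x axis: contiguous lines
  if (sigma_vox[0] > 0) {
    int radius; std::vector<double> k = gauss_kernel(sigma_vox[0], radius);
    for (long line = 0; line < (long)ny * nz; ++line) {
      const double *in = &a[line * nx];
      double *out = &b[line * nx];
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        if (i >= radius && i < nx - radius) {
          const double *p = in + i - radius;
          for (int d = 0; d <= 2 * radius; ++d) acc += k[d] * p[d];
        } else {
          for (int d = -radius; d <= radius; ++d)
            acc += k[d + radius] * in[clampi(i + d, 0, nx - 1)];
        }
        out[i] = acc;
      }
    }
    a.swap(b);
  }
  // y axis: per z-plane, weighted sum of shifted columns (contiguous in i)
  if (sigma_vox[1] > 0) {
    int radius; std::vector<double> k = gauss_kernel(sigma_vox[1], radius);
    for (int z = 0; z < nz; ++z) {
      const double *in = &a[(long)z * plane];
      double *out = &b[(long)z * plane];
      for (int j = 0; j < ny; ++j) {
        double *o = out + (long)j * nx;
        for (int i = 0; i < nx; ++i) o[i] = 0.0;
        for (int d = -radius; d <= radius; ++d) {
          const double w = k[d + radius];
          const double *p = in + (long)clampi(j + d, 0, ny - 1) * nx;
          for (int i = 0; i < nx; ++i) o[i] += w * p[i];
        }
      }
    }
    a.swap(b);
  }
  // z axis: weighted sum of shifted planes (contiguous)
  if (sigma_vox[2] > 0) {
    int radius; std::vector<double> k = gauss_kernel(sigma_vox[2], radius);
    for (int z = 0; z < nz; ++z) {
      double *out = &b[(long)z * plane];
      for (long i = 0; i < plane; ++i) out[i] = 0.0;
      for (int d = -radius; d <= radius; ++d) {
        const double w = k[d + radius];
        const double *p = &a[(long)clampi(z + d, 0, nz - 1) * plane];
        for (long i = 0; i < plane; ++i) out[i] += w * p[i];
      }
    }
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// 256-bin intensity histogram over [0, hi] (values clamped into range);
// used by the global Otsu threshold.
// [[Rcpp::export]]
NumericVector cpp_hist256(NumericVector x, double hi) {
  NumericVector counts(256);
  double scale = 256.0 / hi;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    int b = (int)(x[i] * scale);
    if (b < 0) b = 0;
    if (b > 255) b = 255;
    counts[b] += 1.0;
  }
  return counts;
}

// clip to [0, 65535] and round (16-bit quantization)
// [[Rcpp::export]]
NumericVector cpp_quantize16(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = std::round(x[i]);
    if (v < 0) v = 0;
    if (v > 65535) v = 65535;
    out[i] = v;
  }
  out.attr("dim") = x.attr("dim");
  return out;
}

// Connected-component labeling of a 3D binary mask under 6- or 26-
// connectivity. Returns an integer array with labels 1..N in discovery
// order (raster order of the first voxel of each component).
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, int connectivity) {
  IntegerVector dim = mask.attr("dim");
  if (dim.size() != 3) stop("expected a 3D array");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long nvox = (long)nx * ny * nz;

  // neighbour offsets
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manhattan = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manhattan != 1) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  int nnb = (int)dxs.size();

  IntegerVector labels(nvox, 0);
  labels.attr("dim") = dim;
  std::vector<long> queue;
  queue.reserve(1024);
  int current = 0;

  for (long seed = 0; seed < nvox; ++seed) {
    if (!mask[seed] || labels[seed] != 0) continue;
    ++current;
    labels[seed] = current;
    queue.clear();
    queue.push_back(seed);
    size_t head = 0;
    while (head < queue.size()) {
      long v = queue[head++];
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((long)nx * ny));
      for (int i = 0; i < nnb; ++i) {
        int xx = x + dxs[i], yy = y + dys[i], zz = z + dzs[i];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        long w = (long)xx + (long)nx * ((long)yy + (long)ny * zz);
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          queue.push_back(w);
        }
      }
    }
  }
  return labels;
}
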