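#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Column-major flat index helpers for 5-D (x,y,z,c,n) arrays.
static inline R_xlen_t idx5(int x, int y, int z, int c, int n,
                            int dx, int dy, int dz, int dc) {
  return x + (R_xlen_t)dx * (y + (R_xlen_t)dy * (z + (R_xlen_t)dz * (c + (R_xlen_t)dc * n)));
}
static inline R_xlen_t idx3(int x, int y, int z, int dx, int dy) {
  return x + (R_xlen_t)dx * (y + (R_xlen_t)dy * z);
}

// Valid (no padding) 3-D convolution; input (x,y,z,cin,n), weights
// (k,k,k,cin,cout), bias (cout). "Convolution" in the CNN sense, i.e.
// cross-correlation.
// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector input, IntegerVector indim,
                            NumericVector weights, IntegerVector wdim,
                            NumericVector bias) {
  const int dx = indim[0], dy = indim[1], dz = indim[2], cin = indim[3], nb = indim[4];
  const int kx = wdim[0], ky = wdim[1], kz = wdim[2], cout = wdim[4];
  const int ox = dx - kx + 1, oy = dy - ky + 1, oz = dz - kz + 1;
  if (ox < 1 || oy < 1 || oz < 1) stop("kernel larger than input");
  NumericVector out((R_xlen_t)ox * oy * oz * cout * nb);
  const double *in = input.begin(), *W = weights.begin();
  double *o = out.begin();
  // stride-1 inner loops over the output x axis for vectorization
  for (int n = 0; n < nb; ++n)
    for (int co = 0; co < cout; ++co) {
      const double b = bias[co];
      double *obase = o + idx5(0, 0, 0, co, n, ox, oy, oz, cout);
      for (R_xlen_t i = 0; i < (R_xlen_t)ox * oy * oz; ++i) obase[i] = b;
      for (int ci = 0; ci < cin; ++ci)
        for (int zz = 0; zz < kz; ++zz)
          for (int yy = 0; yy < ky; ++yy)
            for (int xx = 0; xx < kx; ++xx) {
              const double w = W[idx5(xx, yy, zz, ci, co, kx, ky, kz, cin)];
              if (w == 0.0) continue;
              for (int z = 0; z < oz; ++z)
                for (int y = 0; y < oy; ++y) {
                  const double *ip = in + idx5(xx, y + yy, z + zz, ci, n, dx, dy, dz, cin);
                  double *op = obase + idx3(0, y, z, ox, oy);
                  for (int x = 0; x < ox; ++x) op[x] += w * ip[x];
                }
            }
    }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, cout, nb);
  return out;
}

// Backward pass of the valid convolution: returns gradients w.r.t. input,
// weights and bias given the gradient at the output.
// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector input, IntegerVector indim,
                   NumericVector weights, IntegerVector wdim,
                   NumericVector gradOut) {
  const int dx = indim[0], dy = indim[1], dz = indim[2], cin = indim[3], nb = indim[4];
  const int kx = wdim[0], ky = wdim[1], kz = wdim[2], cout = wdim[4];
  const int ox = dx - kx + 1, oy = dy - ky + 1, oz = dz - kz + 1;
  NumericVector gIn((R_xlen_t)dx * dy * dz * cin * nb);
  NumericVector gW(weights.size());
  NumericVector gB(cout);
  const double *in = input.begin(), *W = weights.begin(), *go = gradOut.begin();
  double *gi = gIn.begin(), *gw = gW.begin();
  for (int n = 0; n < nb; ++n)
    for (int co = 0; co < cout; ++co) {
      const double *gbase = go + idx5(0, 0, 0, co, n, ox, oy, oz, cout);
      double bacc = 0.0;
      for (R_xlen_t i = 0; i < (R_xlen_t)ox * oy * oz; ++i) bacc += gbase[i];
      gB[co] += bacc;
      for (int ci = 0; ci < cin; ++ci)
        for (int zz = 0; zz < kz; ++zz)
          for (int yy = 0; yy < ky; ++yy)
            for (int xx = 0; xx < kx; ++xx) {
              const R_xlen_t wi = idx5(xx, yy, zz, ci, co, kx, ky, kz, cin);
              const double w = W[wi];
              double wacc = 0.0;
              for (int z = 0; z < oz; ++z)
                for (int y = 0; y < oy; ++y) {
                  const R_xlen_t ib = idx5(xx, y + yy, z + zz, ci, n, dx, dy, dz, cin);
                  const double *ip = in + ib;
                  double *gip = gi + ib;
                  const double *gp = gbase + idx3(0, y, z, ox, oy);
                  for (int x = 0; x < ox; ++x) {
                    const double g = gp[x];
                    wacc += g * ip[x];
                    gip[x] += g * w;
                  }
                }
              gw[wi] += wacc;
            }
    }
  gIn.attr("dim") = IntegerVector::create(dx, dy, dz, cin, nb);
  gW.attr("dim") = wdim;
  return List::create(_["input"] = gIn, _["weights"] = gW, _["bias"] = gB);
}

// Nearest-neighbour (repeat) spatial upsampling of a (x,y,z,c,n) array.
// [[Rcpp::export]]
NumericVector cpp_upsample3(NumericVector input, IntegerVector indim, int f) {
  const int dx = indim[0], dy = indim[1], dz = indim[2], dc = indim[3], nb = indim[4];
  const int ox = dx * f, oy = dy * f, oz = dz * f;
  NumericVector out((R_xlen_t)ox * oy * oz * dc * nb);
  const double *in = input.begin();
  double *o = out.begin();
  for (int n = 0; n < nb; ++n)
    for (int c = 0; c < dc; ++c)
      for (int z = 0; z < oz; ++z)
        for (int y = 0; y < oy; ++y)
          for (int x = 0; x < ox; ++x)
            o[idx5(x, y, z, c, n, ox, oy, oz, dc)] =
              in[idx5(x / f, y / f, z / f, c, n, dx, dy, dz, dc)];
  out.attr("dim") = IntegerVector::create(ox, oy, oz, dc, nb);
  return out;
}

// Gradient of repeat-upsampling: sum-pool the upstream gradient.
// [[Rcpp::export]]
NumericVector cpp_upsample3_bw(NumericVector gradOut, IntegerVector outdim, int f) {
  const int ox = outdim[0], oy = outdim[1], oz = outdim[2], dc = outdim[3], nb = outdim[4];
  const int dx = ox / f, dy = oy / f, dz = oz / f;
  NumericVector gIn((R_xlen_t)dx * dy * dz * dc * nb);
  const double *go = gradOut.begin();
  double *gi = gIn.begin();
  for (int n = 0; n < nb; ++n)
    for (int c = 0; c < dc; ++c)
      for (int z = 0; z < oz; ++z)
        for (int y = 0; y < oy; ++y)
          for (int x = 0; x < ox; ++x)
            gi[idx5(x / f, y / f, z / f, c, n, dx, dy, dz, dc)] +=
              go[idx5(x, y, z, c, n, ox, oy, oz, dc)];
  gIn.attr("dim") = IntegerVector::create(dx, dy, dz, dc, nb);
  return gIn;
}

// Mean-pool a single 3-D volume by integer factor f; partial boxes at the
// far edges average over the voxels they contain.
// [[Rcpp::export]]
NumericVector cpp_downsample_mean(NumericVector vol, IntegerVector dim, int f) {
  const int dx = dim[0], dy = dim[1], dz = dim[2];
  const int ox = (dx + f - 1) / f, oy = (dy + f - 1) / f, oz = (dz + f - 1) / f;
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double *in = vol.begin();
  double *o = out.begin();
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int x = 0; x < ox; ++x) {
        double acc = 0.0; int cnt = 0;
        for (int zz = z * f; zz < std::min((z + 1) * f, dz); ++zz)
          for (int yy = y * f; yy < std::min((y + 1) * f, dy); ++yy)
            for (int xx = x * f; xx < std::min((x + 1) * f, dx); ++xx) {
              acc += in[idx3(xx, yy, zz, dx, dy)]; ++cnt;
            }
        o[idx3(x, y, z, ox, oy)] = acc / cnt;
      }
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  return out;
}

// Separable Gaussian blur with reflective boundary, sigma given per axis in
// voxel units (sigma 0 skips an axis).
static void blur_axis(std::vector<double> &v, int dx, int dy, int dz,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (double &w : k) w /= s;
  const int len = axis == 0 ? dx : (axis == 1 ? dy : dz);
  std::vector<double> line(len);
  for (int a = 0; a < (axis == 0 ? dy : dx); ++a)
    for (int b = 0; b < (axis == 2 ? dy : dz); ++b) {
      for (int i = 0; i < len; ++i) {
        int x = axis == 0 ? i : a, y = axis == 1 ? i : (axis == 0 ? a : b), z = axis == 2 ? i : b;
        if (axis == 1) { x = a; z = b; }
        line[i] = v[idx3(x, y, z, dx, dy)];
      }
      for (int i = 0; i < len; ++i) {
        double acc = 0;
        for (int j = -r; j <= r; ++j) {
          int p = i + j;
          if (p < 0) p = -p - 1;
          if (p >= len) p = 2 * len - p - 1;
          acc += k[j + r] * line[p];
        }
        int x = axis == 0 ? i : a, y = axis == 1 ? i : (axis == 0 ? a : b), z = axis == 2 ? i : b;
        if (axis == 1) { x = a; z = b; }
        v[idx3(x, y, z, dx, dy)] = acc;
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector vol, IntegerVector dim, NumericVector sigma) {
  std::vector<double> v(vol.begin(), vol.end());
  blur_axis(v, dim[0], dim[1], dim[2], 0, sigma[0]);
  blur_axis(v, dim[0], dim[1], dim[2], 1, sigma[1]);
  blur_axis(v, dim[0], dim[1], dim[2], 2, sigma[2]);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

static inline double sample_linear(const double *in, int dx, int dy, int dz,
                                   double cx, double cy, double cz, double bg) {
  if (cx < 0 || cy < 0 || cz < 0 || cx > dx - 1 || cy > dy - 1 || cz > dz - 1)
    return bg;
  int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy), z0 = (int)std::floor(cz);
  if (x0 == dx - 1) x0--; if (y0 == dy - 1) y0--; if (z0 == dz - 1) z0--;
  if (dx == 1) x0 = 0; if (dy == 1) y0 = 0; if (dz == 1) z0 = 0;
  const double fx = cx - x0, fy = cy - y0, fz = cz - z0;
  const int x1 = std::min(x0 + 1, dx - 1), y1 = std::min(y0 + 1, dy - 1), z1 = std::min(z0 + 1, dz - 1);
  double acc = 0;
  acc += in[idx3(x0, y0, z0, dx, dy)] * (1 - fx) * (1 - fy) * (1 - fz);
  acc += in[idx3(x1, y0, z0, dx, dy)] * fx * (1 - fy) * (1 - fz);
  acc += in[idx3(x0, y1, z0, dx, dy)] * (1 - fx) * fy * (1 - fz);
  acc += in[idx3(x1, y1, z0, dx, dy)] * fx * fy * (1 - fz);
  acc += in[idx3(x0, y0, z1, dx, dy)] * (1 - fx) * (1 - fy) * fz;
  acc += in[idx3(x1, y0, z1, dx, dy)] * fx * (1 - fy) * fz;
  acc += in[idx3(x0, y1, z1, dx, dy)] * (1 - fx) * fy * fz;
  acc += in[idx3(x1, y1, z1, dx, dy)] * fx * fy * fz;
  return acc;
}

static inline double sample_nearest(const double *in, int dx, int dy, int dz,
                                    double cx, double cy, double cz, double bg) {
  const int x = (int)std::floor(cx + 0.5), y = (int)std::floor(cy + 0.5), z = (int)std::floor(cz + 0.5);
  if (x < 0 || y < 0 || z < 0 || x >= dx || y >= dy || z >= dz) return bg;
  return in[idx3(x, y, z, dx, dy)];
}

// Resample a volume onto an output grid through an affine map from output
// physical coordinates to input physical coordinates:
//   q = M p + t,  continuous input index = (q - inOrigin) / inSpacing.
// mode 0 = trilinear, 1 = nearest. clampEdge 1 clamps sample positions to
// the input domain (border replication, used for grid resampling so the
// physical field of view is preserved); 0 fills with bg (used for rigid
// transforms, where outside the head is background).
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector vol, IntegerVector dim,
                                  NumericVector inSpacing, NumericVector inOrigin,
                                  NumericMatrix M, NumericVector t,
                                  IntegerVector outDim, NumericVector outSpacing,
                                  NumericVector outOrigin, int mode, double bg,
                                  int clampEdge) {
  const int dx = dim[0], dy = dim[1], dz = dim[2];
  const int ox = outDim[0], oy = outDim[1], oz = outDim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double *in = vol.begin();
  double *o = out.begin();
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int x = 0; x < ox; ++x) {
        const double px = outOrigin[0] + x * outSpacing[0];
        const double py = outOrigin[1] + y * outSpacing[1];
        const double pz = outOrigin[2] + z * outSpacing[2];
        const double qx = M(0, 0) * px + M(0, 1) * py + M(0, 2) * pz + t[0];
        const double qy = M(1, 0) * px + M(1, 1) * py + M(1, 2) * pz + t[1];
        const double qz = M(2, 0) * px + M(2, 1) * py + M(2, 2) * pz + t[2];
        double cx = (qx - inOrigin[0]) / inSpacing[0];
        double cy = (qy - inOrigin[1]) / inSpacing[1];
        double cz = (qz - inOrigin[2]) / inSpacing[2];
        if (clampEdge) {
          cx = std::min(std::max(cx, 0.0), (double)dx - 1);
          cy = std::min(std::max(cy, 0.0), (double)dy - 1);
          cz = std::min(std::max(cz, 0.0), (double)dz - 1);
        }
        o[idx3(x, y, z, ox, oy)] = mode == 0
          ? sample_linear(in, dx, dy, dz, cx, cy, cz, bg)
          : sample_nearest(in, dx, dy, dz, cx, cy, cz, bg);
      }
  out.attr("dim") = outDim;
  return out;
}

// Mean squared intensity difference between fixed values at given physical
// points and the moving volume sampled (trilinear) at the mapped points.
// Points mapping outside the moving volume are skipped; returns the mean and
// the number of points used.
// [[Rcpp::export]]
NumericVector cpp_msd_metric(NumericVector fixedVals, NumericMatrix pts,
                             NumericVector mov, IntegerVector mdim,
                             NumericVector mSpacing, NumericVector mOrigin,
                             NumericMatrix M, NumericVector t) {
  const int dx = mdim[0], dy = mdim[1], dz = mdim[2];
  const double *in = mov.begin();
  double acc = 0; R_xlen_t cnt = 0;
  for (R_xlen_t i = 0; i < fixedVals.size(); ++i) {
    const double px = pts(0, i), py = pts(1, i), pz = pts(2, i);
    const double qx = M(0, 0) * px + M(0, 1) * py + M(0, 2) * pz + t[0];
    const double qy = M(1, 0) * px + M(1, 1) * py + M(1, 2) * pz + t[1];
    const double qz = M(2, 0) * px + M(2, 1) * py + M(2, 2) * pz + t[2];
    const double cx = (qx - mOrigin[0]) / mSpacing[0];
    const double cy = (qy - mOrigin[1]) / mSpacing[1];
    const double cz = (qz - mOrigin[2]) / mSpacing[2];
    if (cx < 0 || cy < 0 || cz < 0 || cx > dx - 1 || cy > dy - 1 || cz > dz - 1)
      continue;
    const double v = sample_linear(in, dx, dy, dz, cx, cy, cz, 0.0);
    const double d = fixedVals[i] - v;
    acc += d * d; ++cnt;
  }
  return NumericVector::create(cnt > 0 ? acc / cnt : R_PosInf, (double)cnt);
}

// Connected-component labelling of a {0,1} volume, 6- or 26-connectivity,
// labels assigned in scan order starting at 1.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim, int connectivity) {
  const int dx = dim[0], dy = dim[1], dz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)dx * dy * dz;
  IntegerVector lab(nvox);
  const int *m = mask.begin();
  int *L = lab.begin();
  std::vector<int> nbr;
  for (int zz = -1; zz <= 1; ++zz)
    for (int yy = -1; yy <= 1; ++yy)
      for (int xx = -1; xx <= 1; ++xx) {
        if (xx == 0 && yy == 0 && zz == 0) continue;
        if (connectivity == 6 && std::abs(xx) + std::abs(yy) + std::abs(zz) != 1) continue;
        nbr.push_back(xx); nbr.push_back(yy); nbr.push_back(zz);
      }
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < nvox; ++s) {
    if (m[s] == 0 || L[s] != 0) continue;
    ++next;
    L[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back(); stack.pop_back();
      const int x = cur % dx, y = (cur / dx) % dy, z = cur / ((R_xlen_t)dx * dy);
      for (size_t k = 0; k < nbr.size(); k += 3) {
        const int nx = x + nbr[k], ny = y + nbr[k + 1], nz = z + nbr[k + 2];
        if (nx < 0 || ny < 0 || nz < 0 || nx >= dx || ny >= dy || nz >= dz) continue;
        const R_xlen_t q = idx3(nx, ny, nz, dx, dy);
        if (m[q] != 0 && L[q] == 0) { L[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
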