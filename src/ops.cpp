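// Low-level volumetric kernels for the segmentation network and digitization.
//
// Feature maps are (Nvox x C) matrices with voxel linear index
// v = i + nx*(j + ny*k), 0-based, x fastest (R column-major order).
// Convolution weights: (27*Cin x Cout), row q = o + 27*c where o indexes the
// 3x3x3 offset (dx,dy,dz in {-1,0,1}, dx fastest). Transposed-conv weights:
// (8*Cin x Cout), row q = o + 8*c with o over (dx,dy,dz in {0,1}).

#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// im2col in single precision: P(v, o + 27*c) = x(v + offset_o, c), zero
// padded, offsets (dx,dy,dz) in {-1,0,1}^3 with dx fastest, matching the
// weight row layout. Network convolutions run their GEMMs in float (the
// customary precision for training); the R interface stays double.
static arma::fmat im2col27(const arma::fmat& x, int nx, int ny, int nz) {
  const int cin = x.n_cols;
  arma::fmat P(x.n_rows, 27 * cin, arma::fill::zeros);
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++o)
        for (int c = 0; c < cin; ++c) {
          const int i0 = std::max(0, -dx), i1 = std::min(nx, nx - dx);
          const int j0 = std::max(0, -dy), j1 = std::min(ny, ny - dy);
          const int k0 = std::max(0, -dz), k1 = std::min(nz, nz - dz);
          const int len = i1 - i0;
          if (len <= 0) continue;
          float* dst = P.colptr(o + 27 * c);
          const float* src = x.colptr(c);
          for (int k = k0; k < k1; ++k)
            for (int j = j0; j < j1; ++j) {
              const int vo = i0 + nx * (j + ny * k);
              const int vi = (i0 + dx) + nx * ((j + dy) + ny * (k + dz));
              std::memcpy(dst + vo, src + vi, len * sizeof(float));
            }
        }
  return P;
}

// [[Rcpp::export]]
arma::mat cpp_conv3d_fw(const arma::mat& x, IntegerVector dims,
                        const arma::mat& W, const arma::rowvec& b) {
  const int cin = x.n_cols;
  if ((int)W.n_rows != 27 * cin) stop("conv3d: weight/channel mismatch");
  arma::fmat P = im2col27(arma::conv_to<arma::fmat>::from(x),
                          dims[0], dims[1], dims[2]);
  arma::fmat out = P * arma::conv_to<arma::fmat>::from(W);
  arma::mat outd = arma::conv_to<arma::mat>::from(out);
  outd.each_row() += b;
  return outd;
}

// Rearranged weights for the input-gradient convolution: the adjoint of a
// zero-padded 3x3x3 convolution is a convolution of dY with the spatially
// flipped kernel and swapped channel roles.
static arma::fmat flip_weights(const arma::fmat& W, int cin, int cout) {
  arma::fmat Wf(27 * cout, cin);
  for (int o = 0; o < 27; ++o) {
    const int of = 26 - o;  // spatial flip of the offset
    for (int ci = 0; ci < cin; ++ci)
      for (int co = 0; co < cout; ++co)
        Wf(o + 27 * co, ci) = W(of + 27 * ci, co);
  }
  return Wf;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(const arma::mat& x, IntegerVector dims,
                   const arma::mat& W, const arma::mat& dY) {
  const int cin = x.n_cols, cout = W.n_cols;
  arma::fmat dYf = arma::conv_to<arma::fmat>::from(dY);
  arma::fmat P = im2col27(arma::conv_to<arma::fmat>::from(x),
                          dims[0], dims[1], dims[2]);
  arma::fmat dWf = P.t() * dYf;
  P.reset();
  arma::fmat Q = im2col27(dYf, dims[0], dims[1], dims[2]);
  arma::fmat Wf = flip_weights(arma::conv_to<arma::fmat>::from(W), cin, cout);
  arma::fmat dXf = Q * Wf;
  arma::rowvec db = arma::sum(dY, 0);
  return List::create(_["dW"] = arma::conv_to<arma::mat>::from(dWf),
                      _["db"] = db,
                      _["dX"] = arma::conv_to<arma::mat>::from(dXf));
}

// [[Rcpp::export]]
List cpp_maxpool_fw(const arma::mat& x, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (nx % 2 || ny % 2 || nz % 2) stop("maxpool: dims must be even");
  const int mx = nx / 2, my = ny / 2, mz = nz / 2;
  const int C = x.n_cols;
  arma::mat out(mx * my * mz, C);
  arma::umat idx(mx * my * mz, C);
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i) {
        const int vo = i + mx * (j + my * k);
        for (int c = 0; c < C; ++c) {
          double best = -1e300; arma::uword bidx = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const int vi = (2 * i + dx) + nx * ((2 * j + dy) + ny * (2 * k + dz));
                const double val = x(vi, c);
                if (val > best) { best = val; bidx = vi; }
              }
          out(vo, c) = best;
          idx(vo, c) = bidx;
        }
      }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool_bw(const arma::umat& idx, const arma::mat& dY, int n_in) {
  arma::mat dX(n_in, dY.n_cols, arma::fill::zeros);
  for (arma::uword c = 0; c < dY.n_cols; ++c)
    for (arma::uword v = 0; v < dY.n_rows; ++v)
      dX(idx(v, c), c) += dY(v, c);
  return dX;
}

static arma::uvec weight_rows_up(int o, int cin) {
  arma::uvec idx(cin);
  for (int c = 0; c < cin; ++c) idx[c] = (arma::uword)(o + 8 * c);
  return idx;
}

// Transposed convolution, kernel 2x2x2, stride 2 (doubles every dimension).
// [[Rcpp::export]]
arma::mat cpp_upconv_fw(const arma::mat& x, IntegerVector dims,
                        const arma::mat& W, const arma::rowvec& b) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int cin = x.n_cols, cout = W.n_cols;
  if ((int)W.n_rows != 8 * cin) stop("upconv: weight/channel mismatch");
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  arma::mat out(ox * oy * oz, cout, arma::fill::zeros);
  int o = 0;
  for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx, ++o) {
        arma::mat yo = x * W.rows(weight_rows_up(o, cin));  // (Nin x Cout)
        for (int k = 0; k < nz; ++k)
          for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i) {
              const int vi = i + nx * (j + ny * k);
              const int vo = (2 * i + dx) + ox * ((2 * j + dy) + oy * (2 * k + dz));
              for (int c = 0; c < cout; ++c) out(vo, c) = yo(vi, c);
            }
      }
  out.each_row() += b;
  return out;
}

// [[Rcpp::export]]
List cpp_upconv_bw(const arma::mat& x, IntegerVector dims,
                   const arma::mat& W, const arma::mat& dY) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int cin = x.n_cols, cout = W.n_cols;
  const int ox = 2 * nx, oy = 2 * ny;
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::mat dX(x.n_rows, x.n_cols, arma::fill::zeros);
  int o = 0;
  for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx, ++o) {
        arma::mat dyo(x.n_rows, cout);
        for (int k = 0; k < nz; ++k)
          for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i) {
              const int vi = i + nx * (j + ny * k);
              const int vo = (2 * i + dx) + ox * ((2 * j + dy) + oy * (2 * k + dz));
              for (int c = 0; c < cout; ++c) dyo(vi, c) = dY(vo, c);
            }
        arma::uvec rows = weight_rows_up(o, cin);
        dW.rows(rows) = x.t() * dyo;
        dX += dyo * W.rows(rows).t();
      }
  arma::rowvec db = arma::sum(dY, 0);
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}

struct LinTap { int i0, i1; double w1; };

static std::vector<LinTap> axis_taps(int n_out, int n_in) {
  // Factor-2 trilinear resampling taps: output voxel centre maps to
  // u = (i + 0.5) * n_in / n_out - 0.5, clamped to the input extent.
  std::vector<LinTap> taps(n_out);
  for (int i = 0; i < n_out; ++i) {
    double u = (i + 0.5) * ((double)n_in / n_out) - 0.5;
    if (u < 0) u = 0;
    if (u > n_in - 1) u = n_in - 1;
    int i0 = (int)std::floor(u);
    int i1 = std::min(i0 + 1, n_in - 1);
    taps[i] = {i0, i1, u - i0};
  }
  return taps;
}

// [[Rcpp::export]]
arma::mat cpp_resample_trilinear(const arma::mat& x, IntegerVector dims_in,
                                 IntegerVector dims_out) {
  const int nx = dims_in[0], ny = dims_in[1], nz = dims_in[2];
  const int ox = dims_out[0], oy = dims_out[1], oz = dims_out[2];
  const int C = x.n_cols;
  auto tx = axis_taps(ox, nx), ty = axis_taps(oy, ny), tz = axis_taps(oz, nz);
  arma::mat out(ox * oy * oz, C, arma::fill::zeros);
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        const int vo = i + ox * (j + oy * k);
        const LinTap &ax = tx[i], &ay = ty[j], &az = tz[k];
        const double wx[2] = {1 - ax.w1, ax.w1};
        const double wy[2] = {1 - ay.w1, ay.w1};
        const double wz[2] = {1 - az.w1, az.w1};
        const int ii[2] = {ax.i0, ax.i1}, jj[2] = {ay.i0, ay.i1}, kk[2] = {az.i0, az.i1};
        for (int a = 0; a < 2; ++a)
          for (int bb = 0; bb < 2; ++bb)
            for (int cc = 0; cc < 2; ++cc) {
              const double w = wx[a] * wy[bb] * wz[cc];
              if (w == 0) continue;
              const int vi = ii[a] + nx * (jj[bb] + ny * kk[cc]);
              for (int c = 0; c < C; ++c) out(vo, c) += w * x(vi, c);
            }
      }
  return out;
}

// Adjoint of cpp_resample_trilinear (for backpropagation through the gate).
// [[Rcpp::export]]
arma::mat cpp_resample_trilinear_adj(const arma::mat& dY, IntegerVector dims_in,
                                     IntegerVector dims_out) {
  const int nx = dims_in[0], ny = dims_in[1], nz = dims_in[2];
  const int ox = dims_out[0], oy = dims_out[1], oz = dims_out[2];
  const int C = dY.n_cols;
  auto tx = axis_taps(ox, nx), ty = axis_taps(oy, ny), tz = axis_taps(oz, nz);
  arma::mat dX(nx * ny * nz, C, arma::fill::zeros);
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        const int vo = i + ox * (j + oy * k);
        const LinTap &ax = tx[i], &ay = ty[j], &az = tz[k];
        const double wx[2] = {1 - ax.w1, ax.w1};
        const double wy[2] = {1 - ay.w1, ay.w1};
        const double wz[2] = {1 - az.w1, az.w1};
        const int ii[2] = {ax.i0, ax.i1}, jj[2] = {ay.i0, ay.i1}, kk[2] = {az.i0, az.i1};
        for (int a = 0; a < 2; ++a)
          for (int bb = 0; bb < 2; ++bb)
            for (int cc = 0; cc < 2; ++cc) {
              const double w = wx[a] * wy[bb] * wz[cc];
              if (w == 0) continue;
              const int vi = ii[a] + nx * (jj[bb] + ny * kk[cc]);
              for (int c = 0; c < C; ++c) dX(vi, c) += w * dY(vo, c);
            }
      }
  return dX;
}

// 26-connected component labeling of a binary volume. Components smaller than
// min_voxels are discarded. Labels assigned in scan order of the first voxel.
// [[Rcpp::export]]
IntegerVector cpp_label26(const LogicalVector& mask, IntegerVector dims,
                          int min_voxels) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<int> lab(n, 0);
  IntegerVector out(n, 0);
  int next_label = 0;
  std::vector<int> stack;
  std::vector<std::vector<int>> members;
  for (int v = 0; v < n; ++v) {
    if (!mask[v] || lab[v]) continue;
    ++next_label;
    members.push_back(std::vector<int>());
    lab[v] = next_label;
    stack.push_back(v);
    while (!stack.empty()) {
      const int u = stack.back(); stack.pop_back();
      members.back().push_back(u);
      const int i = u % nx, j = (u / nx) % ny, k = u / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int ni = i + dx, nj = j + dy, nk = k + dz;
            if (ni < 0 || ni >= nx || nj < 0 || nj >= ny || nk < 0 || nk >= nz)
              continue;
            const int w = ni + nx * (nj + ny * nk);
            if (mask[w] && !lab[w]) { lab[w] = next_label; stack.push_back(w); }
          }
    }
  }
  int keep = 0;
  for (size_t m = 0; m < members.size(); ++m) {
    if ((int)members[m].size() < min_voxels) continue;
    ++keep;
    for (int v : members[m]) out[v] = keep;
  }
  return out;
}
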