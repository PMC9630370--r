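// 3D convolution kernels used by the VB-Net layers.
//
// Tensors are R arrays in column-major order with dim (X, Y, Z, C);
// weights have dim (k, k, k, Cin, Cout). Convolutions are implemented as
// im2col + GEMM so that BLAS does the heavy lifting; the transposed
// convolution in the up blocks reuses the backward-data path.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_len(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Gather sliding-window patches into a (n_out x k^3*Cin) matrix.
// Out-of-grid taps read as zero (zero padding).
static arma::mat im2col3d(const double* x, int X, int Y, int Z, int C,
                          int k, int s, int p) {
  const int Xo = out_len(X, k, s, p);
  const int Yo = out_len(Y, k, s, p);
  const int Zo = out_len(Z, k, s, p);
  const arma::uword n_out = (arma::uword)Xo * Yo * Zo;
  arma::mat M(n_out, (arma::uword)k * k * k * C, arma::fill::zeros);

  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * X * Y * Z;
    for (int dz = 0; dz < k; ++dz) {
      for (int dy = 0; dy < k; ++dy) {
        for (int dx = 0; dx < k; ++dx) {
          const arma::uword col =
              (arma::uword)dx + k * ((arma::uword)dy + k * ((arma::uword)dz + k * (arma::uword)c));
          double* Mcol = M.colptr(col);
          for (int ko = 0; ko < Zo; ++ko) {
            const int zi = ko * s - p + dz;
            if (zi < 0 || zi >= Z) continue;
            for (int jo = 0; jo < Yo; ++jo) {
              const int yi = jo * s - p + dy;
              if (yi < 0 || yi >= Y) continue;
              const size_t in_base = (size_t)zi * X * Y + (size_t)yi * X;
              const size_t out_base = (size_t)ko * Xo * Yo + (size_t)jo * Xo;
              for (int io = 0; io < Xo; ++io) {
                const int xi_ = io * s - p + dx;
                if (xi_ < 0 || xi_ >= X) continue;
                Mcol[out_base + io] = xc[in_base + xi_];
              }
            }
          }
        }
      }
    }
  }
  return M;
}

// Scatter-add a patch matrix back onto the input grid (adjoint of im2col3d).
static void col2im3d(const arma::mat& M, double* x, int X, int Y, int Z, int C,
                     int k, int s, int p) {
  const int Xo = out_len(X, k, s, p);
  const int Yo = out_len(Y, k, s, p);
  const int Zo = out_len(Z, k, s, p);

  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * X * Y * Z;
    for (int dz = 0; dz < k; ++dz) {
      for (int dy = 0; dy < k; ++dy) {
        for (int dx = 0; dx < k; ++dx) {
          const arma::uword col =
              (arma::uword)dx + k * ((arma::uword)dy + k * ((arma::uword)dz + k * (arma::uword)c));
          const double* Mcol = M.colptr(col);
          for (int ko = 0; ko < Zo; ++ko) {
            const int zi = ko * s - p + dz;
            if (zi < 0 || zi >= Z) continue;
            for (int jo = 0; jo < Yo; ++jo) {
              const int yi = jo * s - p + dy;
              if (yi < 0 || yi >= Y) continue;
              const size_t in_base = (size_t)zi * X * Y + (size_t)yi * X;
              const size_t out_base = (size_t)ko * Xo * Yo + (size_t)jo * Xo;
              for (int io = 0; io < Xo; ++io) {
                const int xi_ = io * s - p + dx;
                if (xi_ < 0 || xi_ >= X) continue;
                xc[in_base + xi_] += Mcol[out_base + io];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], Cin = xd[3];
  const int k = wd[0], Cout = wd[4];
  if (wd[3] != Cin) stop("conv3d: input channel mismatch");

  arma::mat M = im2col3d(x.begin(), X, Y, Z, Cin, k, stride, pad);
  arma::mat W(const_cast<double*>(w.begin()), (arma::uword)k * k * k * Cin, Cout, false, true);
  arma::mat Ymat = M * W;
  Ymat.each_row() += arma::rowvec(const_cast<double*>(b.begin()), Cout, false, true);

  const int Xo = out_len(X, k, stride, pad);
  const int Yo = out_len(Y, k, stride, pad);
  const int Zo = out_len(Z, k, stride, pad);
  NumericVector out(Ymat.begin(), Ymat.end());
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Cout);
  return out;
}

// Gradients of a conv3d w.r.t. input, weights and bias, given the upstream
// gradient gy on the output. One im2col pass serves both gw and gx.
// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector gd = gy.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], Cin = xd[3];
  const int k = wd[0], Cout = wd[4];
  const arma::uword n_out = (arma::uword)gd[0] * gd[1] * gd[2];

  arma::mat M = im2col3d(x.begin(), X, Y, Z, Cin, k, stride, pad);
  arma::mat GY(const_cast<double*>(gy.begin()), n_out, Cout, false, true);
  arma::mat W(const_cast<double*>(w.begin()), (arma::uword)k * k * k * Cin, Cout, false, true);

  arma::mat GW = M.t() * GY;
  arma::rowvec GB = arma::sum(GY, 0);
  arma::mat GXcol = GY * W.t();

  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  col2im3d(GXcol, gx.begin(), X, Y, Z, Cin, k, stride, pad);

  NumericVector gw(GW.begin(), GW.end());
  gw.attr("dim") = wd;
  NumericVector gb(GB.begin(), GB.end());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Backward-data alone: used as the forward pass of the transposed
// convolution (the up-sampling layers), where gy plays the role of the
// small input and the result lives on the large grid with dims in_dim.
// [[Rcpp::export]]
NumericVector cpp_conv3d_bw_data(NumericVector gy, NumericVector w,
                                 int stride, int pad, IntegerVector in_dim) {
  IntegerVector wd = w.attr("dim");
  IntegerVector gd = gy.attr("dim");
  const int k = wd[0], Cin = wd[3], Cout = wd[4];
  const arma::uword n_out = (arma::uword)gd[0] * gd[1] * gd[2];
  if (gd[3] != Cout) stop("conv3d: gradient channel mismatch");

  arma::mat GY(const_cast<double*>(gy.begin()), n_out, Cout, false, true);
  arma::mat W(const_cast<double*>(w.begin()), (arma::uword)k * k * k * Cin, Cout, false, true);
  arma::mat GXcol = GY * W.t();

  NumericVector gx((R_xlen_t)in_dim[0] * in_dim[1] * in_dim[2] * Cin);
  gx.attr("dim") = in_dim;
  col2im3d(GXcol, gx.begin(), in_dim[0], in_dim[1], in_dim[2], Cin, k, stride, pad);
  return gx;
}

// Weight/bias gradient with the roles of input and output swapped, as needed
// by the transposed convolution: x_small drove a backward-data pass that
// produced the large map; gy_large is the upstream gradient there.
// [[Rcpp::export]]
List cpp_tconv3d_bw_filter(NumericVector gy_large, NumericVector x_small,
                           NumericVector w, int stride, int pad) {
  IntegerVector ld = gy_large.attr("dim");
  IntegerVector sd = x_small.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int X = ld[0], Y = ld[1], Z = ld[2], Cin = ld[3];
  const int k = wd[0], Cout = wd[4];
  const arma::uword n_out = (arma::uword)sd[0] * sd[1] * sd[2];

  arma::mat M = im2col3d(gy_large.begin(), X, Y, Z, Cin, k, stride, pad);
  arma::mat XS(const_cast<double*>(x_small.begin()), n_out, Cout, false, true);
  arma::mat GW = M.t() * XS;
  NumericVector gw(GW.begin(), GW.end());
  gw.attr("dim") = wd;
  return List::create(_["gw"] = gw);
}

// 26-connected component labelling of a binary mask (BFS flood fill).
// Returns integer labels 1..n_comp in scan-order of the first voxel found.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const R_xlen_t n = (R_xlen_t)X * Y * Z;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (mask[start] == 0 || lab[start] != 0) continue;
    ++next;
    lab[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      const int x0 = (int)(v % X);
      const int y0 = (int)((v / X) % Y);
      const int z0 = (int)(v / ((R_xlen_t)X * Y));
      for (int dz = -1; dz <= 1; ++dz) {
        const int z = z0 + dz;
        if (z < 0 || z >= Z) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int y = y0 + dy;
          if (y < 0 || y >= Y) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            const int x = x0 + dx;
            if (x < 0 || x >= X || (dx == 0 && dy == 0 && dz == 0)) continue;
            const R_xlen_t u = (R_xlen_t)z * X * Y + (R_xlen_t)y * X + x;
            if (mask[u] != 0 && lab[u] == 0) {
              lab[u] = next;
              stack.push_back(u);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
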