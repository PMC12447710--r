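// Fused 3-D convolution forward/backward: im2col is materialised one
// z-slab at a time and fed to BLAS (Armadillo), so memory stays at one
// slab regardless of volume size and nothing but the layer input needs to
// be cached for the backward pass.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col_slab(const double* x, int C, int X, int Y, int Z,
                        int k, int stride, int pad, int ox, int oy,
                        int iz, arma::mat& cols) {
  const int z0 = iz * stride - pad;
  for (int iy = 0; iy < oy; ++iy) {
    for (int ix = 0; ix < ox; ++ix) {
      const int col = ix + ox * iy;
      double* o = cols.colptr(col);
      const int x0 = ix * stride - pad;
      const int y0 = iy * stride - pad;
      int r = 0;
      for (int kz = 0; kz < k; ++kz) {
        const int zz = z0 + kz;
        for (int ky = 0; ky < k; ++ky) {
          const int yy = y0 + ky;
          for (int kx = 0; kx < k; ++kx) {
            const int xx = x0 + kx;
            if (xx >= 0 && xx < X && yy >= 0 && yy < Y && zz >= 0 && zz < Z) {
              const double* src = x + (size_t)C * (xx + (size_t)X * (yy + (size_t)Y * zz));
              for (int c = 0; c < C; ++c) o[r++] = src[c];
            } else {
              for (int c = 0; c < C; ++c) o[r++] = 0.0;
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, IntegerVector dims,
                           NumericMatrix W, NumericVector b, int k,
                           int stride, int pad) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int ox = (X + 2 * pad - k) / stride + 1;
  const int oy = (Y + 2 * pad - k) / stride + 1;
  const int oz = (Z + 2 * pad - k) / stride + 1;
  const int Cout = W.nrow();
  NumericVector y((size_t)Cout * ox * oy * oz);
  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  arma::vec bv(b.begin(), b.size(), false);
  arma::mat cols(C * k * k * k, ox * oy);
  for (int iz = 0; iz < oz; ++iz) {
    im2col_slab(x.begin(), C, X, Y, Z, k, stride, pad, ox, oy, iz, cols);
    arma::mat ys = Wm * cols;
    ys.each_col() += bv;
    std::copy(ys.begin(), ys.end(), y.begin() + (size_t)Cout * ox * oy * iz);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, IntegerVector dims, NumericMatrix W,
                  NumericVector dy, int k, int stride, int pad) {
  const int C = dims[0], X = dims[1], Y = dims[2], Z = dims[3];
  const int ox = (X + 2 * pad - k) / stride + 1;
  const int oy = (Y + 2 * pad - k) / stride + 1;
  const int oz = (Z + 2 * pad - k) / stride + 1;
  const int Cout = W.nrow();
  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  NumericVector dx((size_t)C * X * Y * Z);
  arma::mat dW(Cout, C * k * k * k, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat cols(C * k * k * k, ox * oy);
  for (int iz = 0; iz < oz; ++iz) {
    arma::mat dys(const_cast<double*>(dy.begin()) + (size_t)Cout * ox * oy * iz,
                  Cout, ox * oy, false);
    im2col_slab(x.begin(), C, X, Y, Z, k, stride, pad, ox, oy, iz, cols);
    dW += dys * cols.t();
    db += arma::sum(dys, 1);
    arma::mat dcols = Wm.t() * dys;  // (C*k^3) x (ox*oy)
    // scatter-add (col2im) for this slab
    const int z0 = iz * stride - pad;
    for (int iy = 0; iy < oy; ++iy) {
      for (int ix = 0; ix < ox; ++ix) {
        const double* o = dcols.colptr(ix + ox * iy);
        const int x0 = ix * stride - pad;
        const int y0 = iy * stride - pad;
        int r = 0;
        for (int kz = 0; kz < k; ++kz) {
          const int zz = z0 + kz;
          for (int ky = 0; ky < k; ++ky) {
            const int yy = y0 + ky;
            for (int kx = 0; kx < k; ++kx) {
              const int xx = x0 + kx;
              if (xx >= 0 && xx < X && yy >= 0 && yy < Y && zz >= 0 && zz < Z) {
                double* dst = dx.begin() + (size_t)C * (xx + (size_t)X * (yy + (size_t)Y * zz));
                for (int c = 0; c < C; ++c) dst[c] += o[r++];
              } else {
                r += C;
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = wrap(dW), _["db"] = wrap(db));
}
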