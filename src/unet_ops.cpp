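#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Layout conventions shared with the R side:
//  * an activation tensor is an arma::cube H x W x C (R array dim c(H, W, C));
//  * a conv weight is a (k*k*Cin) x Cout matrix whose row index is
//    r = c*k*k + di*k + dj (0-based), with (di, dj) the kernel offset and c
//    the input channel, matching im2col below;
//  * 'same' zero padding, odd k only (validated in R).

static arma::mat im2col_same(const arma::cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, pad = k / 2;
  arma::mat A(H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    for (int di = 0; di < k; ++di) {
      for (int dj = 0; dj < k; ++dj) {
        const int q = c * k * k + di * k + dj;
        const int oi = di - pad, oj = dj - pad;
        const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
        const int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
        if (i1 <= i0) continue;
        for (int j = j0; j < j1; ++j) {
          std::copy(xc.colptr(j + oj) + (i0 + oi),
                    xc.colptr(j + oj) + (i1 + oi),
                    A.colptr(q) + (static_cast<size_t>(j) * H + i0));
        }
      }
    }
  }
  return A;
}

// [[Rcpp::export(name = ".conv2d_same")]]
arma::cube conv2d_same(const arma::cube& x, const arma::mat& w,
                       const arma::vec& b, const int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  if (static_cast<int>(w.n_rows) != k * k * static_cast<int>(x.n_slices))
    stop("conv2d: weight rows (%d) do not match k*k*Cin (%d)",
         (int)w.n_rows, k * k * (int)x.n_slices);
  arma::mat A = im2col_same(x, k);
  arma::mat out = A * w;
  out.each_row() += b.t();
  return arma::cube(out.memptr(), H, W, Cout);
}

// [[Rcpp::export(name = ".conv2d_same_backward")]]
List conv2d_same_backward(const arma::cube& x, const arma::mat& w,
                          const arma::cube& gout, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, pad = k / 2;
  const int Cout = gout.n_slices;
  const arma::mat G(const_cast<double*>(gout.memptr()),
                    static_cast<size_t>(H) * W, Cout, false);
  arma::mat A = im2col_same(x, k);
  arma::mat gw = A.t() * G;
  arma::vec gb = arma::sum(G, 0).t();
  arma::mat GA = G * w.t();
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& gxc = gx.slice(c);
    for (int di = 0; di < k; ++di) {
      for (int dj = 0; dj < k; ++dj) {
        const int q = c * k * k + di * k + dj;
        const int oi = di - pad, oj = dj - pad;
        const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
        const int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
        if (i1 <= i0) continue;
        for (int j = j0; j < j1; ++j) {
          double* dst = gxc.colptr(j + oj) + (i0 + oi);
          const double* src = GA.colptr(q) + (static_cast<size_t>(j) * H + i0);
          for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns pooled cube and the per-output linear
// index (0-based, within slice) of the winning input pixel, ties to the
// first in column-major order.
// [[Rcpp::export(name = ".maxpool2")]]
List maxpool2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) stop("maxpool2: extent (%d x %d) not even", H, W);
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  IntegerVector idx(static_cast<size_t>(Ho) * Wo * C);
  int* ip = INTEGER(idx);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        const int i = 2 * io, j = 2 * jo;
        double best = xc(i, j);
        int bi = i + j * H;
        if (xc(i + 1, j) > best) { best = xc(i + 1, j); bi = i + 1 + j * H; }
        if (xc(i, j + 1) > best) { best = xc(i, j + 1); bi = i + (j + 1) * H; }
        if (xc(i + 1, j + 1) > best) { best = xc(i + 1, j + 1); bi = i + 1 + (j + 1) * H; }
        y(io, jo, c) = best;
        ip[static_cast<size_t>(c) * Ho * Wo + jo * Ho + io] = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
arma::cube maxpool2_backward(const arma::cube& gy, const IntegerVector& idx,
                             const int H, const int W) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  const int* ip = INTEGER(idx);
  for (int c = 0; c < C; ++c) {
    double* gxs = gx.slice_memptr(c);
    const double* gys = gy.slice_memptr(c);
    const size_t n = static_cast<size_t>(Ho) * Wo;
    const int* is = ip + static_cast<size_t>(c) * n;
    for (size_t t = 0; t < n; ++t) gxs[is[t]] += gys[t];
  }
  return gx;
}

// Nearest-neighbour 2x upsampling: y(i, j, c) = x(i / 2, j / 2, c).
// [[Rcpp::export(name = ".upsample2")]]
arma::cube upsample2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    arma::mat& yc = y.slice(c);
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const double v = xc(i, j);
        yc(2 * i, 2 * j) = v;
        yc(2 * i + 1, 2 * j) = v;
        yc(2 * i, 2 * j + 1) = v;
        yc(2 * i + 1, 2 * j + 1) = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".upsample2_backward")]]
arma::cube upsample2_backward(const arma::cube& gy) {
  const int Ho = gy.n_rows / 2, Wo = gy.n_cols / 2, C = gy.n_slices;
  arma::cube gx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& gc = gy.slice(c);
    arma::mat& xc = gx.slice(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        xc(i, j) = gc(2 * i, 2 * j) + gc(2 * i + 1, 2 * j) +
                   gc(2 * i, 2 * j + 1) + gc(2 * i + 1, 2 * j + 1);
  }
  return gx;
}
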