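// Low-level numeric kernels: im2col-based 2-D convolution (forward and
// backward), nearest-neighbour 2x upsampling, max pooling, and 8-connected
// component labelling. Images and feature maps are arma::cube with layout
// (rows = H, cols = W, slices = channels); weights are a (Cout x k*k*Cin)
// matrix whose column order is ((c*k + ki)*k + kj). Padding may be
// asymmetric (TensorFlow "same" semantics need it for even kernels).
//
// The convolution core is templated on the arithmetic type: the neural
// network layers run in single precision (sgemm is ~2x dgemm on one CPU
// and training does not need more), while callers that require exact
// arithmetic (the SSIM local moments) use the double-precision path.
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// fills every entry (zeros where the window runs off the image), writing
// each output column contiguously
template <typename T>
static void im2col_fill(const cube& x, int k, int s, int pt, int pl,
                        int Ho, int Wo, Mat<T>& cols) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const double* xp = x.memptr();
  const std::size_t HW = (std::size_t)H * W;
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      T* col = cols.colptr(i + (std::size_t)Ho * j);
      const int i0 = i * s - pt, j0 = j * s - pl;
      for (int c = 0; c < C; ++c) {
        const double* xc = xp + HW * c;
        for (int ki = 0; ki < k; ++ki) {
          const int xi = i0 + ki;
          T* dst = col + ((std::size_t)c * k + ki) * k;
          if (xi < 0 || xi >= H) {
            for (int kj = 0; kj < k; ++kj) dst[kj] = T(0);
            continue;
          }
          const double* xrow = xc + xi;
          for (int kj = 0; kj < k; ++kj) {
            const int xj = j0 + kj;
            dst[kj] = (xj < 0 || xj >= W) ? T(0)
                      : (T)xrow[(std::size_t)H * xj];
          }
        }
      }
    }
  }
}

template <typename T>
static cube conv_forward_t(const cube& x, const mat& w, const vec& b,
                           int k, int stride, int pt, int pb, int pl,
                           int pr) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = (H + pt + pb - k) / stride + 1;
  const int Wo = (W + pl + pr - k) / stride + 1;
  const int Cout = w.n_rows;
  Mat<T> cols(w.n_cols, (std::size_t)Ho * Wo);
  im2col_fill<T>(x, k, stride, pt, pl, Ho, Wo, cols);
  Mat<T> wf = conv_to<Mat<T> >::from(w);
  Mat<T> res = wf * cols;          // Cout x (Ho*Wo)
  Col<T> bf = conv_to<Col<T> >::from(b);
  res.each_col() += bf;
  cube out(Ho, Wo, Cout);
  for (int c = 0; c < Cout; ++c) {
    double* op = out.slice_memptr(c);
    const T* rp = res.memptr() + c;
    for (std::size_t q = 0; q < (std::size_t)Ho * Wo; ++q)
      op[q] = (double)rp[q * Cout];
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_forward(const arma::cube& x, const arma::mat& w,
                              const arma::vec& b, int k, int stride,
                              int pt, int pb, int pl, int pr,
                              bool single = false) {
  if ((int)w.n_cols != k * k * (int)x.n_slices)
    Rcpp::stop("weight matrix does not match kernel/channel geometry");
  if (single)
    return conv_forward_t<float>(x, w, b, k, stride, pt, pb, pl, pr);
  return conv_forward_t<double>(x, w, b, k, stride, pt, pb, pl, pr);
}

template <typename T>
static Rcpp::List conv_backward_t(const cube& x, const mat& w,
                                  const cube& dout, int k, int stride,
                                  int pt, int pb, int pl, int pr,
                                  bool want_dx, bool want_dw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = dout.n_rows, Wo = dout.n_cols, Cout = dout.n_slices;
  Mat<T> dm(Cout, (std::size_t)Ho * Wo);
  for (int c = 0; c < Cout; ++c) {
    const double* dp = dout.slice_memptr(c);
    T* mp = dm.memptr() + c;
    for (std::size_t q = 0; q < (std::size_t)Ho * Wo; ++q)
      mp[q * Cout] = (T)dp[q];
  }
  mat dW; vec db;
  if (want_dw) {
    Mat<T> cols(w.n_cols, (std::size_t)Ho * Wo);
    im2col_fill<T>(x, k, stride, pt, pl, Ho, Wo, cols);
    dW = conv_to<mat>::from(dm * cols.t());
    db = conv_to<vec>::from(sum(dm, 1));
  }
  cube dx;
  if (want_dx) {
    Mat<T> wf = conv_to<Mat<T> >::from(w);
    Mat<T> dcols = wf.t() * dm;    // (k*k*C) x (Ho*Wo)
    dx.zeros(H, W, C);
    double* dxp = dx.memptr();
    const std::size_t HW = (std::size_t)H * W;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const T* col = dcols.colptr(i + (std::size_t)Ho * j);
        const int i0 = i * stride - pt, j0 = j * stride - pl;
        for (int c = 0; c < C; ++c) {
          double* dxc = dxp + HW * c;
          for (int ki = 0; ki < k; ++ki) {
            const int xi = i0 + ki;
            if (xi < 0 || xi >= H) continue;
            const T* src = col + ((std::size_t)c * k + ki) * k;
            for (int kj = 0; kj < k; ++kj) {
              const int xj = j0 + kj;
              if (xj < 0 || xj >= W) continue;
              dxc[xi + (std::size_t)H * xj] += (double)src[kj];
            }
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_backward(const arma::cube& x, const arma::mat& w,
                               const arma::cube& dout, int k, int stride,
                               int pt, int pb, int pl, int pr,
                               bool want_dx = true, bool want_dw = true,
                               bool single = false) {
  if (single)
    return conv_backward_t<float>(x, w, dout, k, stride, pt, pb, pl, pr,
                                  want_dx, want_dw);
  return conv_backward_t<double>(x, w, dout, k, stride, pt, pb, pl, pr,
                                 want_dx, want_dw);
}

// [[Rcpp::export]]
arma::cube cpp_upsample2x(const arma::cube& x) {
  cube out(2 * x.n_rows, 2 * x.n_cols, x.n_slices);
  for (uword c = 0; c < x.n_slices; ++c)
    for (uword j = 0; j < x.n_cols; ++j)
      for (uword i = 0; i < x.n_rows; ++i) {
        const double v = x(i, j, c);
        out(2 * i, 2 * j, c) = v;
        out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v;
        out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2x_backward(const arma::cube& d) {
  cube out(d.n_rows / 2, d.n_cols / 2, d.n_slices);
  for (uword c = 0; c < out.n_slices; ++c)
    for (uword j = 0; j < out.n_cols; ++j)
      for (uword i = 0; i < out.n_rows; ++i)
        out(i, j, c) = d(2 * i, 2 * j, c) + d(2 * i + 1, 2 * j, c) +
                       d(2 * i, 2 * j + 1, c) + d(2 * i + 1, 2 * j + 1, c);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool_forward(const arma::cube& x, int k, int stride,
                               int pt, int pb, int pl, int pr) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + pt + pb - k) / stride + 1;
  const int Wo = (W + pl + pr - k) / stride + 1;
  cube out(Ho, Wo, C);
  ucube arg(Ho, Wo, C);            // linear index into x
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf; uword bidx = 0;
        for (int ki = 0; ki < k; ++ki)
          for (int kj = 0; kj < k; ++kj) {
            const int xi = i * stride - pt + ki;
            const int xj = j * stride - pl + kj;
            if (xi < 0 || xi >= H || xj < 0 || xj >= W) continue;
            const double v = x(xi, xj, c);
            if (v > best) {
              best = v;
              bidx = xi + (uword)H * xj + (uword)H * W * c;
            }
          }
        out(i, j, c) = best;
        arg(i, j, c) = bidx;
      }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("arg") = arg);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_backward(const arma::cube& dout,
                                const arma::ucube& arg,
                                int H, int W, int C) {
  cube dx(H, W, C, fill::zeros);
  for (uword c = 0; c < dout.n_slices; ++c)
    for (uword j = 0; j < dout.n_cols; ++j)
      for (uword i = 0; i < dout.n_rows; ++i)
        dx(arg(i, j, c)) += dout(i, j, c);
  return dx;
}

// 8-connected component labelling by breadth-first search; labels are
// assigned in column-major scan order starting at 1 (0 = background).
// [[Rcpp::export]]
Rcpp::IntegerMatrix cpp_label_components(const Rcpp::LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  Rcpp::IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        const std::pair<int, int> p = q.front(); q.pop();
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int ni = p.first + di, nj = p.second + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              q.push(std::make_pair(ni, nj));
            }
          }
      }
    }
  }
  return lab;
}
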