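// Convolution primitives for the stain-translation networks.
//
// Tensor layout matches R arrays: dim = (H, W, C, N), column-major, so the
// (H*W) pixels of one channel are contiguous. Convolution weights are stored
// as a (k*k*C_in) x C_out matrix with row index kh + k*kw + k*k*c; transposed
// convolution weights as (k*k*C_out) x C_in. All arithmetic in double.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int conv_out_size(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// Gather the k x k windows of one (H, W, C) sample into a
// (k*k*C) x (OH*OW) matrix. Out-of-bounds positions are zero.
static void im2col(const double* x, int H, int W, int C,
                   int k, int s, int p, int OH, int OW, arma::mat& cols) {
  cols.zeros(k * k * C, OH * OW);
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      const int j = oh + OH * ow;
      const int h0 = oh * s - p, w0 = ow * s - p;
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)H * W * c;
        for (int kw = 0; kw < k; ++kw) {
          const int w_in = w0 + kw;
          if (w_in < 0 || w_in >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int h_in = h0 + kh;
            if (h_in < 0 || h_in >= H) continue;
            cols(kh + k * kw + k * k * c, j) = xc[h_in + (size_t)H * w_in];
          }
        }
      }
    }
  }
}

// Scatter-add the inverse of im2col: accumulate columns back into (H, W, C).
static void col2im(const arma::mat& cols, int H, int W, int C,
                   int k, int s, int p, int OH, int OW, double* x) {
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      const int j = oh + OH * ow;
      const int h0 = oh * s - p, w0 = ow * s - p;
      for (int c = 0; c < C; ++c) {
        double* xc = x + (size_t)H * W * c;
        for (int kw = 0; kw < k; ++kw) {
          const int w_in = w0 + kw;
          if (w_in < 0 || w_in >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int h_in = h0 + kh;
            if (h_in < 0 || h_in >= H) continue;
            xc[h_in + (size_t)H * w_in] += cols(kh + k * kw + k * k * c, j);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv2d_forward(NumericVector x, NumericMatrix w,
                                NumericVector b, int k, int s, int p) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int OH = conv_out_size(H, k, s, p), OW = conv_out_size(W, k, s, p);
  const int Cout = w.ncol();
  if (w.nrow() != k * k * C) stop("conv2d: weight rows != k*k*C_in");
  NumericVector y((R_xlen_t)OH * OW * Cout * N);
  y.attr("dim") = IntegerVector::create(OH, OW, Cout, N);
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat cols;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, s, p, OH, OW, cols);
    arma::mat out = cols.t() * wm;  // (OH*OW) x Cout
    out.each_row() += arma::rowvec(b.begin(), Cout);
    std::copy(out.begin(), out.end(), y.begin() + (size_t)OH * OW * Cout * n);
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv2d_backward(NumericVector x, NumericMatrix w, NumericVector dy,
                        int k, int s, int p) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int OH = conv_out_size(H, k, s, p), OW = conv_out_size(W, k, s, p);
  const int Cout = w.ncol();
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat dw(w.nrow(), Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat cols;
  for (int n = 0; n < N; ++n) {
    arma::mat dyn(dy.begin() + (size_t)OH * OW * Cout * n, OH * OW, Cout, false);
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, s, p, OH, OW, cols);
    dw += cols * dyn;
    db += arma::sum(dyn, 0).t();
    arma::mat dcols = wm * dyn.t();  // (k*k*C) x (OH*OW)
    col2im(dcols, H, W, C, k, s, p, OH, OW, dx.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["dx"] = dx, _["dw"] = wrap(dw), _["db"] = wrap(db));
}

// Transposed convolution: output size (in-1)*s - 2p + k + op.
// Forward is the scatter (col2im) adjoint of the strided conv gather, over
// the OUTPUT grid: for input pixel (ih, iw), kernel tap (kh, kw) lands at
// (ih*s - p + kh, iw*s - p + kw) in the output.
// [[Rcpp::export]]
NumericVector nn_convt2d_forward(NumericVector x, NumericMatrix w,
                                 NumericVector b, int k, int s, int p, int op) {
  IntegerVector xd = x.attr("dim");
  const int IH = xd[0], IW = xd[1], Cin = xd[2], N = xd[3];
  const int Cout = w.nrow() / (k * k);
  if (w.ncol() != Cin) stop("convt2d: weight cols != C_in");
  const int OH = (IH - 1) * s - 2 * p + k + op;
  const int OW = (IW - 1) * s - 2 * p + k + op;
  NumericVector y((R_xlen_t)OH * OW * Cout * N);
  y.attr("dim") = IntegerVector::create(OH, OW, Cout, N);
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  for (int n = 0; n < N; ++n) {
    arma::mat xn(const_cast<double*>(x.begin()) + (size_t)IH * IW * Cin * n,
                 IH * IW, Cin, false);
    arma::mat cols = wm * xn.t();  // (k*k*Cout) x (IH*IW)
    double* yn = y.begin() + (size_t)OH * OW * Cout * n;
    // scatter: treat cols as windows anchored at the strided output grid
    for (int iw = 0; iw < IW; ++iw) {
      for (int ih = 0; ih < IH; ++ih) {
        const int j = ih + IH * iw;
        const int h0 = ih * s - p, w0 = iw * s - p;
        for (int c = 0; c < Cout; ++c) {
          double* yc = yn + (size_t)OH * OW * c;
          for (int kw = 0; kw < k; ++kw) {
            const int w_out = w0 + kw;
            if (w_out < 0 || w_out >= OW) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int h_out = h0 + kh;
              if (h_out < 0 || h_out >= OH) continue;
              yc[h_out + (size_t)OH * w_out] += cols(kh + k * kw + k * k * c, j);
            }
          }
        }
      }
    }
    for (int c = 0; c < Cout; ++c) {
      double* yc = yn + (size_t)OH * OW * c;
      for (int i = 0; i < OH * OW; ++i) yc[i] += b[c];
    }
  }
  return y;
}

// [[Rcpp::export]]
List nn_convt2d_backward(NumericVector x, NumericMatrix w, NumericVector dy,
                         int k, int s, int p, int op) {
  IntegerVector xd = x.attr("dim");
  const int IH = xd[0], IW = xd[1], Cin = xd[2], N = xd[3];
  const int Cout = w.nrow() / (k * k);
  const int OH = (IH - 1) * s - 2 * p + k + op;
  const int OW = (IW - 1) * s - 2 * p + k + op;
  NumericVector dx((R_xlen_t)IH * IW * Cin * N);
  dx.attr("dim") = IntegerVector::create(IH, IW, Cin, N);
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat dw(w.nrow(), Cin, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat dcols(k * k * Cout, IH * IW);
  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + (size_t)OH * OW * Cout * n;
    // gather the adjoint of the forward scatter
    dcols.zeros();
    for (int iw = 0; iw < IW; ++iw) {
      for (int ih = 0; ih < IH; ++ih) {
        const int j = ih + IH * iw;
        const int h0 = ih * s - p, w0 = iw * s - p;
        for (int c = 0; c < Cout; ++c) {
          const double* dyc = dyn + (size_t)OH * OW * c;
          for (int kw = 0; kw < k; ++kw) {
            const int w_out = w0 + kw;
            if (w_out < 0 || w_out >= OW) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int h_out = h0 + kh;
              if (h_out < 0 || h_out >= OH) continue;
              dcols(kh + k * kw + k * k * c, j) = dyc[h_out + (size_t)OH * w_out];
            }
          }
        }
      }
    }
    arma::mat xn(const_cast<double*>(x.begin()) + (size_t)IH * IW * Cin * n,
                 IH * IW, Cin, false);
    dw += dcols * xn;
    // cols = w * x^T  =>  d(x^T) = w^T * dcols, dx = (w^T * dcols)^T
    arma::mat dxt = (wm.t() * dcols).t();     // (IH*IW) x Cin
    std::copy(dxt.begin(), dxt.end(),
              dx.begin() + (size_t)IH * IW * Cin * n);
    for (int c = 0; c < Cout; ++c) {
      const double* dyc = dyn + (size_t)OH * OW * c;
      for (int i = 0; i < OH * OW; ++i) db[c] += dyc[i];
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = wrap(dw), _["db"] = wrap(db));
}

// 8-connected component labelling of a binary image (flood fill with an
// explicit stack). Returns an integer matrix with labels 1..L, 0 background.
// [[Rcpp::export]]
IntegerMatrix nn_bwlabel8(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      if (!mask(h, w) || lab(h, w)) continue;
      ++next;
      stack.push_back(std::make_pair(h, w));
      lab(h, w) = next;
      while (!stack.empty()) {
        const int ch = stack.back().first, cw = stack.back().second;
        stack.pop_back();
        for (int dw = -1; dw <= 1; ++dw) {
          for (int dh = -1; dh <= 1; ++dh) {
            const int nh = ch + dh, nw = cw + dw;
            if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
            if (mask(nh, nw) && !lab(nh, nw)) {
              lab(nh, nw) = next;
              stack.push_back(std::make_pair(nh, nw));
            }
          }
        }
      }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// Connected-component centroids and sizes for an integer label image
// (labels 1..L, 0 = background), as produced by nn_bwlabel8.
// [[Rcpp::export]]
List nn_label_stats(IntegerMatrix lab, int n_labels) {
  std::vector<double> sx(n_labels, 0.0), sy(n_labels, 0.0);
  std::vector<int> cnt(n_labels, 0);
  const int H = lab.nrow(), W = lab.ncol();
  for (int w_ = 0; w_ < W; ++w_) {
    for (int h = 0; h < H; ++h) {
      const int l = lab(h, w_);
      if (l > 0) {
        cnt[l - 1] += 1;
        sx[l - 1] += w_;  // x = column, 0-based
        sy[l - 1] += h;   // y = row, 0-based
      }
    }
  }
  NumericVector cx(n_labels), cy(n_labels);
  IntegerVector area(n_labels);
  for (int i = 0; i < n_labels; ++i) {
    area[i] = cnt[i];
    cx[i] = cnt[i] ? sx[i] / cnt[i] : NA_REAL;
    cy[i] = cnt[i] ? sy[i] / cnt[i] : NA_REAL;
  }
  return List::create(_["x"] = cx, _["y"] = cy, _["area"] = area);
}
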