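// Low-level kernels for the segmentation network: im2col/col2im convolution,
// transposed convolution, max pooling, and an in-place Adam step.
// Feature maps are arma::cube with dimensions (H, W, C), matching an R array
// of dim c(H, W, C). Kernel weights arrive flattened column-major from R
// arrays of dim c(kh, kw, C_in, C_out) (conv) or c(kh, kw, C_out, C_in)
// (transposed conv), i.e. row index dh + kh*dw + kh*kw*channel.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int kh, int kw,
                        int stride, int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(kh * kw * C, (size_t)Ho * Wo, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const size_t j = (size_t)ho + (size_t)Ho * wo;
      for (int c = 0; c < C; ++c) {
        for (int dw = 0; dw < kw; ++dw) {
          const int iw = wo * stride + dw - pad;
          if (iw < 0 || iw >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            const int ih = ho * stride + dh - pad;
            if (ih < 0 || ih >= H) continue;
            cols(dh + kh * dw + kh * kw * c, j) = x(ih, iw, c);
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add columns back onto an (H_out, W_out, C) grid. Column j walks an
// (H_in, W_in) grid; entry (dh,dw,c) of column (h,w) lands at
// (h*stride+dh-pad, w*stride+dw-pad, c). Shared by conv-backward-data and
// transposed-conv-forward.
static arma::cube col2im_add(const arma::mat& cols, int H_in, int W_in, int C,
                             int kh, int kw, int stride, int pad,
                             int H_out, int W_out) {
  arma::cube out(H_out, W_out, C, arma::fill::zeros);
  for (int w = 0; w < W_in; ++w) {
    for (int h = 0; h < H_in; ++h) {
      const size_t j = (size_t)h + (size_t)H_in * w;
      for (int c = 0; c < C; ++c) {
        for (int dw = 0; dw < kw; ++dw) {
          const int ow = w * stride + dw - pad;
          if (ow < 0 || ow >= W_out) continue;
          for (int dh = 0; dh < kh; ++dh) {
            const int oh = h * stride + dh - pad;
            if (oh < 0 || oh >= H_out) continue;
            out(oh, ow, c) += cols(dh + kh * dw + kh * kw * c, j);
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fw(const arma::cube& x, const arma::mat& w_mat,
                         const arma::vec& bias, int kh, int kw,
                         int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int Cout = w_mat.n_cols;
  arma::mat cols = im2col(x, kh, kw, stride, pad, Ho, Wo);
  arma::mat y = w_mat.t() * cols;             // (Cout x Ho*Wo)
  if (bias.n_elem == (size_t)Cout) y.each_col() += bias;
  arma::cube out(Ho, Wo, Cout);
  for (int c = 0; c < Cout; ++c) {
    out.slice(c) = arma::reshape(y.row(c), Ho, Wo);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(const arma::cube& x, const arma::mat& w_mat,
                   const arma::cube& dout, int kh, int kw,
                   int stride, int pad, bool need_dx, bool need_db) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = dout.n_rows, Wo = dout.n_cols, Cout = dout.n_slices;
  arma::mat dy(Cout, (size_t)Ho * Wo);
  for (int c = 0; c < Cout; ++c)
    dy.row(c) = arma::vectorise(dout.slice(c)).t();
  arma::mat cols = im2col(x, kh, kw, stride, pad, Ho, Wo);
  arma::mat dw = cols * dy.t();               // (kh*kw*Cin x Cout)
  List res = List::create(Named("dw") = dw);
  if (need_db) res["db"] = arma::vec(arma::sum(dy, 1));
  if (need_dx) {
    arma::mat dcols = w_mat * dy;             // (kh*kw*Cin x Ho*Wo)
    res["dx"] = col2im_add(dcols, Ho, Wo, x.n_slices, kh, kw, stride, pad, H, W);
  }
  return res;
}

// Transposed convolution: out has size stride*(H-1)+kh-2*pad per dim.
// w_mat is (kh*kw*Cout x Cin).
// [[Rcpp::export]]
arma::cube cpp_convT_fw(const arma::cube& x, const arma::mat& w_mat,
                        const arma::vec& bias, int kh, int kw,
                        int stride, int pad, int Cout) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Ho = stride * (H - 1) + kh - 2 * pad;
  const int Wo = stride * (W - 1) + kw - 2 * pad;
  arma::mat xm(Cin, (size_t)H * W);
  for (int c = 0; c < Cin; ++c)
    xm.row(c) = arma::vectorise(x.slice(c)).t();
  arma::mat cols = w_mat * xm;                // (kh*kw*Cout x H*W)
  arma::cube out = col2im_add(cols, H, W, Cout, kh, kw, stride, pad, Ho, Wo);
  if (bias.n_elem == (size_t)Cout)
    for (int c = 0; c < Cout; ++c) out.slice(c) += bias(c);
  return out;
}

// [[Rcpp::export]]
List cpp_convT_bw(const arma::cube& x, const arma::mat& w_mat,
                  const arma::cube& dout, int kh, int kw,
                  int stride, int pad, bool need_dx, bool need_db) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = dout.n_slices;
  // columns of dout gathered over the *input* grid
  arma::mat dcols = im2col(dout, kh, kw, stride, pad, H, W); // (kh*kw*Cout x H*W)
  arma::mat xm(Cin, (size_t)H * W);
  for (int c = 0; c < Cin; ++c)
    xm.row(c) = arma::vectorise(x.slice(c)).t();
  arma::mat dw = dcols * xm.t();              // (kh*kw*Cout x Cin)
  List res = List::create(Named("dw") = dw);
  if (need_db) {
    arma::vec db(Cout);
    for (int c = 0; c < Cout; ++c) db(c) = arma::accu(dout.slice(c));
    res["db"] = db;
  }
  if (need_dx) {
    arma::mat dxm = w_mat.t() * dcols;        // (Cin x H*W)
    arma::cube dx(H, W, Cin);
    for (int c = 0; c < Cin; ++c)
      dx.slice(c) = arma::reshape(dxm.row(c), H, W);
    res["dx"] = dx;
  }
  return res;
}

// [[Rcpp::export]]
List cpp_maxpool_fw(const arma::cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::cube out(Ho, Wo, C);
  IntegerVector arg((size_t)Ho * Wo * C);     // 1-based linear index into x
  size_t q = 0;
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -std::numeric_limits<double>::infinity();
        int besti = -1;
        for (int dw = 0; dw < k; ++dw) {
          const int iw = wo * stride + dw - pad;
          if (iw < 0 || iw >= W) continue;
          for (int dh = 0; dh < k; ++dh) {
            const int ih = ho * stride + dh - pad;
            if (ih < 0 || ih >= H) continue;
            const double v = x(ih, iw, c);
            if (v > best) { best = v; besti = ih + H * iw + H * W * c; }
          }
        }
        out(ho, wo, c) = best;
        arg[(size_t)ho + (size_t)Ho * wo + (size_t)Ho * Wo * c] = besti + 1;
        ++q;
      }
    }
  }
  (void)q;
  return List::create(Named("y") = out, Named("argmax") = arg);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bw(const arma::cube& dout, const IntegerVector& argmax,
                          int H, int W, int C) {
  arma::cube dx(H, W, C, arma::fill::zeros);
  const double* d = dout.memptr();
  for (size_t i = 0; i < (size_t)argmax.size(); ++i) {
    dx.memptr()[argmax[i] - 1] += d[i];
  }
  return dx;
}

// In-place Adam update; p, m, v are owned by the optimiser (stored in
// environments, never shared), so mutating their memory is safe.
// [[Rcpp::export]]
void cpp_adam_step(NumericVector p, NumericVector g, NumericVector m,
                   NumericVector v, double lr, double b1, double b2,
                   double eps, int t) {
  const double bc1 = 1.0 - std::pow(b1, t);
  const double bc2 = 1.0 - std::pow(b2, t);
  double* pp = REAL(p); double* gp = REAL(g);
  double* mp = REAL(m); double* vp = REAL(v);
  const R_xlen_t n = p.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = b1 * mp[i] + (1.0 - b1) * gp[i];
    vp[i] = b2 * vp[i] + (1.0 - b2) * gp[i] * gp[i];
    pp[i] -= lr * (mp[i] / bc1) / (std::sqrt(vp[i] / bc2) + eps);
  }
}

// Connected-component labelling (4-connectivity) for binary masks; used when
// no instance map is available. Returns an integer label matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int,int>> stack;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({i, j});
      lab(i, j) = next;
      while (!stack.empty()) {
        auto [r, c] = stack.back();
        stack.pop_back();
        const int dr[4] = {-1, 1, 0, 0};
        const int dc[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          const int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back({rr, cc});
          }
        }
      }
    }
  }
  return lab;
}
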