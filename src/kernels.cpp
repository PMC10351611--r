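// Low-level network kernels: same-padded (dilated) convolution, 2x2 max
// pooling (stride 1 or 2) and x2 bilinear upsampling, each with its exact
// adjoint for backpropagation.  Feature maps are H x W x C arrays;
// convolution weights arrive as a (kh*kw*Cin) x Cout matrix whose row index
// runs with ki fastest, then kj, then input channel -- i.e. the column-major
// flattening of an R array with dim c(kh, kw, Cin, Cout).
//
// To keep the training loop memory-bandwidth friendly, R arrays are viewed
// in place (no copy on entry or exit) and the im2col matrix built by the
// forward pass is returned so the backward pass can reuse it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline uword col_index(uword ki, uword kj, uword c, uword kh, uword kw) {
  return ki + kh * (kj + kw * c);
}

// view an R numeric vector/array as an arma matrix without copying
static mat view_mat(Rcpp::NumericVector& x, uword nr, uword nc) {
  return mat(x.begin(), nr, nc, false, true);
}

static Rcpp::NumericVector make_array(uword H, uword W, uword C) {
  Rcpp::NumericVector out(H * W * C);
  out.attr("dim") = Rcpp::IntegerVector::create(H, W, C);
  return out;
}

static void im2col_same(const double* x, uword H, uword W, uword C,
                        uword kh, uword kw, uword dil, mat& col) {
  const sword ph = static_cast<sword>(dil * (kh - 1) / 2);
  const sword pw = static_cast<sword>(dil * (kw - 1) / 2);
  col.zeros();
  for (uword c = 0; c < C; ++c) {
    const double* xc = x + c * H * W;
    for (uword kj = 0; kj < kw; ++kj) {
      for (uword ki = 0; ki < kh; ++ki) {
        const sword di = static_cast<sword>(ki * dil) - ph;
        const sword dj = static_cast<sword>(kj * dil) - pw;
        double* dst0 = col.colptr(col_index(ki, kj, c, kh, kw));
        for (uword j = 0; j < W; ++j) {
          const sword sj = static_cast<sword>(j) + dj;
          if (sj < 0 || sj >= static_cast<sword>(W)) continue;
          const sword i_lo = std::max<sword>(0, -di);
          const sword i_hi = std::min<sword>(H, static_cast<sword>(H) - di);
          if (i_hi <= i_lo) continue;
          std::memcpy(dst0 + j * H + i_lo, xc + sj * H + i_lo + di,
                      sizeof(double) * (i_hi - i_lo));
        }
      }
    }
  }
}

// adjoint of im2col_same: scatter-add the column matrix back onto an image
static void col2im_same(const mat& dcol, double* dx, uword H, uword W,
                        uword C, uword kh, uword kw, uword dil) {
  const sword ph = static_cast<sword>(dil * (kh - 1) / 2);
  const sword pw = static_cast<sword>(dil * (kw - 1) / 2);
  for (uword c = 0; c < C; ++c) {
    double* dc = dx + c * H * W;
    for (uword kj = 0; kj < kw; ++kj) {
      for (uword ki = 0; ki < kh; ++ki) {
        const sword di = static_cast<sword>(ki * dil) - ph;
        const sword dj = static_cast<sword>(kj * dil) - pw;
        const double* src0 = dcol.colptr(col_index(ki, kj, c, kh, kw));
        for (uword j = 0; j < W; ++j) {
          const sword sj = static_cast<sword>(j) + dj;
          if (sj < 0 || sj >= static_cast<sword>(W)) continue;
          const sword i_lo = std::max<sword>(0, -di);
          const sword i_hi = std::min<sword>(H, static_cast<sword>(H) - di);
          double* d = dc + sj * H + i_lo + di;
          const double* s = src0 + j * H + i_lo;
          for (sword i = i_lo; i < i_hi; ++i) *d++ += *s++;
        }
      }
    }
  }
}

static void get_dims(const Rcpp::NumericVector& x, uword& H, uword& W,
                     uword& C) {
  Rcpp::IntegerVector d = x.attr("dim");
  H = d[0]; W = d[1];
  C = (d.size() > 2) ? d[2] : 1;
}

// [[Rcpp::export(name = "cpp_conv2d_fwd")]]
Rcpp::List cpp_conv2d_fwd(Rcpp::NumericVector x, Rcpp::NumericVector w,
                          Rcpp::NumericVector b, const int kh, const int kw,
                          const int dil) {
  uword H, W, C;
  get_dims(x, H, W, C);
  const uword kk = static_cast<uword>(kh) * kw * C;
  const uword cout = w.size() / kk;
  Rcpp::NumericVector colv(Rcpp::no_init(H * W * kk));
  mat col = view_mat(colv, H * W, kk);
  im2col_same(x.begin(), H, W, C, kh, kw, dil, col);
  Rcpp::NumericVector out = make_array(H, W, cout);
  mat y = view_mat(out, H * W, cout);
  mat wm = view_mat(w, kk, cout);
  y = col * wm;
  vec bv(b.begin(), cout, false, true);
  y.each_row() += bv.t();
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("col") = colv);
}

// [[Rcpp::export(name = "cpp_conv2d_bwd")]]
Rcpp::List cpp_conv2d_bwd(Rcpp::NumericVector colv, Rcpp::NumericVector w,
                          Rcpp::NumericVector dy, const int H, const int W,
                          const int C, const int kh, const int kw,
                          const int dil) {
  const uword kk = static_cast<uword>(kh) * kw * C;
  const uword n = static_cast<uword>(H) * W;
  const uword cout = w.size() / kk;
  mat col = view_mat(colv, n, kk);
  mat dym = view_mat(dy, n, cout);
  mat wm = view_mat(w, kk, cout);
  Rcpp::NumericVector dwv(Rcpp::no_init(kk * cout));
  mat dw = view_mat(dwv, kk, cout);
  dw = col.t() * dym;
  dwv.attr("dim") = Rcpp::IntegerVector::create(kk, cout);
  Rcpp::NumericVector dbv(cout);
  vec db(dbv.begin(), cout, false, true);
  db = sum(dym, 0).t();
  mat dcol = dym * wm.t();
  Rcpp::NumericVector dxv = make_array(H, W, C);
  col2im_same(dcol, dxv.begin(), H, W, C, kh, kw, dil);
  return Rcpp::List::create(Rcpp::Named("dx") = dxv,
                            Rcpp::Named("dw") = dwv,
                            Rcpp::Named("db") = dbv);
}

// 2x2 max pooling.  stride 2 halves the resolution (H, W must be even);
// stride 1 with implicit -Inf padding on the bottom/right edge keeps it.
// [[Rcpp::export(name = "cpp_maxpool2_fwd")]]
Rcpp::List cpp_maxpool2_fwd(Rcpp::NumericVector x, const int stride) {
  uword H, W, C;
  get_dims(x, H, W, C);
  const uword Ho = (stride == 2) ? H / 2 : H;
  const uword Wo = (stride == 2) ? W / 2 : W;
  Rcpp::NumericVector out = make_array(Ho, Wo, C);
  Rcpp::NumericVector idx = make_array(Ho, Wo, C);  // 0-based linear index
  double* po = out.begin();
  double* pi = idx.begin();
  const double* px = x.begin();
  for (uword c = 0; c < C; ++c) {
    const double* xc = px + c * H * W;
    for (uword j = 0; j < Wo; ++j) {
      for (uword i = 0; i < Ho; ++i) {
        const uword i0 = i * stride, j0 = j * stride;
        double best = -datum::inf;
        uword arg = 0;
        for (uword dj = 0; dj < 2; ++dj) {
          for (uword di = 0; di < 2; ++di) {
            const uword ii = i0 + di, jj = j0 + dj;
            if (ii >= H || jj >= W) continue;
            const double v = xc[ii + jj * H];
            if (v > best) { best = v; arg = ii + jj * H; }
          }
        }
        *po++ = best;
        *pi++ = static_cast<double>(arg + c * H * W);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = "cpp_maxpool2_bwd")]]
Rcpp::NumericVector cpp_maxpool2_bwd(Rcpp::NumericVector idx,
                                     Rcpp::NumericVector dy, const int H,
                                     const int W) {
  uword Ho, Wo, C;
  get_dims(dy, Ho, Wo, C);
  Rcpp::NumericVector dxv = make_array(H, W, C);
  double* p = dxv.begin();
  const double* q = dy.begin();
  const double* ix = idx.begin();
  for (uword k = 0; k < static_cast<uword>(dy.size()); ++k)
    p[static_cast<uword>(ix[k])] += q[k];
  return dxv;
}

static inline void bilin_coef(const uword i, const uword n_in, uword& i0,
                              uword& i1, double& w1) {
  // scale factor 2, half-pixel centres (align_corners = false)
  double src = (i + 0.5) / 2.0 - 0.5;
  if (src < 0) src = 0;
  if (src > n_in - 1.0) src = n_in - 1.0;
  i0 = static_cast<uword>(std::floor(src));
  i1 = std::min(i0 + 1, n_in - 1);
  w1 = src - i0;
}

// [[Rcpp::export(name = "cpp_upsample2_fwd")]]
Rcpp::NumericVector cpp_upsample2_fwd(Rcpp::NumericVector x) {
  uword H, W, C;
  get_dims(x, H, W, C);
  Rcpp::NumericVector out = make_array(2 * H, 2 * W, C);
  for (uword c = 0; c < C; ++c) {
    const double* xc = x.begin() + c * H * W;
    double* oc = out.begin() + c * 4 * H * W;
    for (uword j = 0; j < 2 * W; ++j) {
      uword j0, j1; double wj;
      bilin_coef(j, W, j0, j1, wj);
      for (uword i = 0; i < 2 * H; ++i) {
        uword i0, i1; double wi;
        bilin_coef(i, H, i0, i1, wi);
        oc[i + j * 2 * H] =
          (1 - wi) * (1 - wj) * xc[i0 + j0 * H] + wi * (1 - wj) * xc[i1 + j0 * H]
          + (1 - wi) * wj * xc[i0 + j1 * H] + wi * wj * xc[i1 + j1 * H];
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = "cpp_upsample2_bwd")]]
Rcpp::NumericVector cpp_upsample2_bwd(Rcpp::NumericVector dy) {
  uword H2, W2, C;
  get_dims(dy, H2, W2, C);
  const uword H = H2 / 2, W = W2 / 2;
  Rcpp::NumericVector dxv = make_array(H, W, C);
  for (uword c = 0; c < C; ++c) {
    const double* gc = dy.begin() + c * 4 * H * W;
    double* dc = dxv.begin() + c * H * W;
    for (uword j = 0; j < 2 * W; ++j) {
      uword j0, j1; double wj;
      bilin_coef(j, W, j0, j1, wj);
      for (uword i = 0; i < 2 * H; ++i) {
        uword i0, i1; double wi;
        bilin_coef(i, H, i0, i1, wi);
        const double g = gc[i + j * 2 * H];
        dc[i0 + j0 * H] += (1 - wi) * (1 - wj) * g;
        dc[i1 + j0 * H] += wi * (1 - wj) * g;
        dc[i0 + j1 * H] += (1 - wi) * wj * g;
        dc[i1 + j1 * H] += wi * wj * g;
      }
    }
  }
  return dxv;
}

// ---- pointwise / normalisation helpers ----------------------------------

// [[Rcpp::export(name = "cpp_relu_fwd")]]
Rcpp::NumericVector cpp_relu_fwd(Rcpp::NumericVector x) {
  Rcpp::NumericVector out(Rcpp::no_init(x.size()));
  out.attr("dim") = x.attr("dim");
  const double* p = x.begin();
  double* q = out.begin();
  for (R_xlen_t k = 0; k < x.size(); ++k) q[k] = p[k] > 0 ? p[k] : 0;
  return out;
}

// [[Rcpp::export(name = "cpp_relu_bwd")]]
Rcpp::NumericVector cpp_relu_bwd(Rcpp::NumericVector dy,
                                 Rcpp::NumericVector out) {
  Rcpp::NumericVector dx(Rcpp::no_init(dy.size()));
  dx.attr("dim") = dy.attr("dim");
  const double* p = dy.begin();
  const double* o = out.begin();
  double* q = dx.begin();
  for (R_xlen_t k = 0; k < dy.size(); ++k) q[k] = o[k] > 0 ? p[k] : 0;
  return dx;
}

// multiply channel c by scalar v[c]
// [[Rcpp::export(name = "cpp_scale_channels")]]
Rcpp::NumericVector cpp_scale_channels(Rcpp::NumericVector x,
                                       Rcpp::NumericVector v) {
  uword H, W, C;
  get_dims(x, H, W, C);
  Rcpp::NumericVector out(Rcpp::no_init(x.size()));
  out.attr("dim") = x.attr("dim");
  const uword n = H * W;
  for (uword c = 0; c < C; ++c) {
    const double s = v[c];
    const double* p = x.begin() + c * n;
    double* q = out.begin() + c * n;
    for (uword k = 0; k < n; ++k) q[k] = p[k] * s;
  }
  return out;
}

// multiply every channel elementwise by an H x W map
// [[Rcpp::export(name = "cpp_scale_spatial")]]
Rcpp::NumericVector cpp_scale_spatial(Rcpp::NumericVector x,
                                      Rcpp::NumericVector m) {
  uword H, W, C;
  get_dims(x, H, W, C);
  Rcpp::NumericVector out(Rcpp::no_init(x.size()));
  out.attr("dim") = x.attr("dim");
  const uword n = H * W;
  const double* mm = m.begin();
  for (uword c = 0; c < C; ++c) {
    const double* p = x.begin() + c * n;
    double* q = out.begin() + c * n;
    for (uword k = 0; k < n; ++k) q[k] = p[k] * mm[k];
  }
  return out;
}

// per-channel standardisation over pixels with affine parameters
// [[Rcpp::export(name = "cpp_instnorm_fwd")]]
Rcpp::List cpp_instnorm_fwd(Rcpp::NumericVector x, Rcpp::NumericVector gamma,
                            Rcpp::NumericVector beta, const double eps) {
  uword H, W, C;
  get_dims(x, H, W, C);
  const uword n = H * W;
  Rcpp::NumericVector out(Rcpp::no_init(x.size()));
  out.attr("dim") = x.attr("dim");
  Rcpp::NumericVector xhat(Rcpp::no_init(x.size()));
  xhat.attr("dim") = x.attr("dim");
  Rcpp::NumericVector istdv(C);
  for (uword c = 0; c < C; ++c) {
    const double* p = x.begin() + c * n;
    double mu = 0;
    for (uword k = 0; k < n; ++k) mu += p[k];
    mu /= n;
    double var = 0;
    for (uword k = 0; k < n; ++k) { const double d = p[k] - mu; var += d * d; }
    var /= n;
    const double istd = 1.0 / std::sqrt(var + eps);
    istdv[c] = istd;
    const double g = gamma[c], b = beta[c];
    double* xh = xhat.begin() + c * n;
    double* q = out.begin() + c * n;
    for (uword k = 0; k < n; ++k) {
      xh[k] = (p[k] - mu) * istd;
      q[k] = g * xh[k] + b;
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("istd") = istdv);
}

// [[Rcpp::export(name = "cpp_instnorm_bwd")]]
Rcpp::List cpp_instnorm_bwd(Rcpp::NumericVector dy, Rcpp::NumericVector xhat,
                            Rcpp::NumericVector istdv,
                            Rcpp::NumericVector gamma) {
  uword H, W, C;
  get_dims(dy, H, W, C);
  const uword n = H * W;
  Rcpp::NumericVector dx(Rcpp::no_init(dy.size()));
  dx.attr("dim") = dy.attr("dim");
  Rcpp::NumericVector dgamma(C), dbeta(C);
  for (uword c = 0; c < C; ++c) {
    const double* g = dy.begin() + c * n;
    const double* xh = xhat.begin() + c * n;
    double sg = 0, sgx = 0;
    for (uword k = 0; k < n; ++k) { sg += g[k]; sgx += g[k] * xh[k]; }
    dgamma[c] = sgx;
    dbeta[c] = sg;
    const double gam = gamma[c], istd = istdv[c];
    const double mg = sg / n, mgx = sgx / n;
    double* q = dx.begin() + c * n;
    for (uword k = 0; k < n; ++k)
      q[k] = gam * istd * (g[k] - mg - xh[k] * mgx);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
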