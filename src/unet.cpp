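// Compact CPU U-net: same-padded 3x3 conv blocks, 2x2 max-pool encoder,
// nearest-neighbour upsample + 2x2 up-conv decoder with skip concatenation,
// final 1x1 conv to 3 class scores (background / uterus / tumor).
// Convolutions are im2col + GEMM; gradients are exact backprop.
// All tensors are arma::cube(H, W, channels); pixel p of a feature map is
// flattened column-major as p = j*H + i.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

// im2col for same-size convolution with explicit top/left zero padding.
// Kernel element (ki, kj) of channel c maps to row c*kh*kw + ki*kw + kj.
static mat im2col(const cube& x, int kh, int kw, int pt, int pl) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat col(C * kh * kw, H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int ki = 0; ki < kh; ++ki) {
      for (int kj = 0; kj < kw; ++kj) {
        const int r = c * kh * kw + ki * kw + kj;
        for (int j = 0; j < W; ++j) {
          const int jj = j - pl + kj;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int ii = i - pt + ki;
            if (ii < 0 || ii >= H) continue;
            col(r, j * H + i) = xs(ii, jj);
          }
        }
      }
    }
  }
  return col;
}

static cube col2im(const mat& dcol, int kh, int kw, int pt, int pl,
                   int C, int H, int W) {
  cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& xs = dx.slice(c);
    for (int ki = 0; ki < kh; ++ki) {
      for (int kj = 0; kj < kw; ++kj) {
        const int r = c * kh * kw + ki * kw + kj;
        for (int j = 0; j < W; ++j) {
          const int jj = j - pl + kj;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int ii = i - pt + ki;
            if (ii < 0 || ii >= H) continue;
            xs(ii, jj) += dcol(r, j * H + i);
          }
        }
      }
    }
  }
  return dx;
}

// conv given a precomputed column matrix; Wm is (Cout, Cin*kh*kw)
static cube conv_from_col(const mat& col, const mat& Wm, const vec& b,
                          int H, int W) {
  mat out = Wm * col;            // (Cout, H*W)
  out.each_col() += b;
  const int Cout = Wm.n_rows;
  cube y(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    y.slice(c) = arma::reshape(out.row(c).t(), H, W);
  return y;
}

static void relu_(cube& x) {
  x.transform([](double v) { return v > 0.0 ? v : 0.0; });
}

// Backward through one convolution. `act_mask_src` (post-ReLU output) masks
// dout in the caller before entry, so here dout is already d(pre-activation).
static cube conv_backward(const cube& dout, const mat& col, const mat& Wm,
                          int kh, int kw, int pt, int pl, int Cin,
                          mat& dW, vec& db, bool need_dx) {
  const int H = dout.n_rows, W = dout.n_cols, Cout = dout.n_slices;
  mat dout_mat(Cout, H * W);
  for (int c = 0; c < Cout; ++c)
    dout_mat.row(c) = arma::vectorise(dout.slice(c)).t();
  dW = dout_mat * col.t();
  db = arma::sum(dout_mat, 1);
  if (!need_dx) return cube();
  mat dcol = Wm.t() * dout_mat;
  return col2im(dcol, kh, kw, pt, pl, Cin, H, W);
}

static void relu_mask_(cube& d, const cube& act) {
  for (arma::uword k = 0; k < d.n_elem; ++k)
    if (act(k) <= 0.0) d(k) = 0.0;
}

// 2x2 max pool, stride 2; argmax offset di + 2*dj recorded for backward.
// Ties resolve to the first element in scan order (di fastest).
static cube maxpool2(const cube& x, arma::ucube& idx) {
  const int H2 = x.n_rows / 2, W2 = x.n_cols / 2, C = x.n_slices;
  cube y(H2, W2, C);
  idx.set_size(H2, W2, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W2; ++j) {
      for (int i = 0; i < H2; ++i) {
        double best = -arma::datum::inf;
        int besto = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; besto = di + 2 * dj; }
          }
        }
        y(i, j, c) = best;
        idx(i, j, c) = besto;
      }
    }
  }
  return y;
}

static cube maxpool2_backward(const cube& dout, const arma::ucube& idx,
                              int H, int W) {
  const int H2 = dout.n_rows, W2 = dout.n_cols, C = dout.n_slices;
  cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i) {
        const int o = (int)idx(i, j, c);
        dx(2 * i + (o % 2), 2 * j + (o / 2), c) += dout(i, j, c);
      }
  return dx;
}

static cube upsample2(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j)
      for (int i = 0; i < 2 * H; ++i)
        y(i, j, c) = x(i / 2, j / 2, c);
  return y;
}

static cube upsample2_backward(const cube& dout) {
  const int H2 = dout.n_rows / 2, W2 = dout.n_cols / 2, C = dout.n_slices;
  cube dx(H2, W2, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W2; ++j)
      for (int i = 0; i < 2 * H2; ++i)
        dx(i / 2, j / 2, c) += dout(i, j, c);
  return dx;
}

struct UnetWeights {
  std::vector<mat> eW1, eW2, uW, dW1, dW2;
  std::vector<vec> eb1, eb2, ub, db1, db2;
  mat bW1, bW2, fW;
  vec bb1, bb2, fb;
};

// Weight list order (fixed contract with the R side):
// enc lvl 0..d-1: W1 b1 W2 b2 | bottleneck: W1 b1 W2 b2 |
// dec lvl d-1..0: upW upb W1 b1 W2 b2 | final: W b
static UnetWeights parse_weights(const List& weights, int depth) {
  UnetWeights w;
  int k = 0;
  w.eW1.resize(depth); w.eb1.resize(depth);
  w.eW2.resize(depth); w.eb2.resize(depth);
  w.uW.resize(depth);  w.ub.resize(depth);
  w.dW1.resize(depth); w.db1.resize(depth);
  w.dW2.resize(depth); w.db2.resize(depth);
  for (int l = 0; l < depth; ++l) {
    w.eW1[l] = as<mat>(weights[k++]); w.eb1[l] = as<vec>(weights[k++]);
    w.eW2[l] = as<mat>(weights[k++]); w.eb2[l] = as<vec>(weights[k++]);
  }
  w.bW1 = as<mat>(weights[k++]); w.bb1 = as<vec>(weights[k++]);
  w.bW2 = as<mat>(weights[k++]); w.bb2 = as<vec>(weights[k++]);
  for (int l = depth - 1; l >= 0; --l) {
    w.uW[l]  = as<mat>(weights[k++]); w.ub[l]  = as<vec>(weights[k++]);
    w.dW1[l] = as<mat>(weights[k++]); w.db1[l] = as<vec>(weights[k++]);
    w.dW2[l] = as<mat>(weights[k++]); w.db2[l] = as<vec>(weights[k++]);
  }
  w.fW = as<mat>(weights[k++]); w.fb = as<vec>(weights[k++]);
  return w;
}

struct ForwardCache {
  std::vector<mat> colE1, colE2, colU, colD1, colD2;
  std::vector<cube> actE1, skip, actU, actD1, actD2;
  std::vector<arma::ucube> poolIdx;
  mat colB1, colB2, colF;
  cube actB1, actB2, logits;
};

static void unet_forward(const arma::mat& x, const UnetWeights& w, int depth,
                         ForwardCache& fc, bool keep_cache) {
  const int H0 = x.n_rows, W0 = x.n_cols;
  fc.colE1.resize(depth); fc.colE2.resize(depth);
  fc.colU.resize(depth);  fc.colD1.resize(depth); fc.colD2.resize(depth);
  fc.actE1.resize(depth); fc.skip.resize(depth);
  fc.actU.resize(depth);  fc.actD1.resize(depth); fc.actD2.resize(depth);
  fc.poolIdx.resize(depth);

  cube cur(H0, W0, 1);
  cur.slice(0) = x;
  int H = H0, W = W0;
  for (int l = 0; l < depth; ++l) {
    mat c1 = im2col(cur, 3, 3, 1, 1);
    cube a1 = conv_from_col(c1, w.eW1[l], w.eb1[l], H, W); relu_(a1);
    mat c2 = im2col(a1, 3, 3, 1, 1);
    cube a2 = conv_from_col(c2, w.eW2[l], w.eb2[l], H, W); relu_(a2);
    cur = maxpool2(a2, fc.poolIdx[l]);
    if (keep_cache) { fc.colE1[l] = std::move(c1); fc.colE2[l] = std::move(c2);
                      fc.actE1[l] = std::move(a1); }
    fc.skip[l] = std::move(a2);
    H /= 2; W /= 2;
  }
  {
    mat c1 = im2col(cur, 3, 3, 1, 1);
    fc.actB1 = conv_from_col(c1, w.bW1, w.bb1, H, W); relu_(fc.actB1);
    mat c2 = im2col(fc.actB1, 3, 3, 1, 1);
    fc.actB2 = conv_from_col(c2, w.bW2, w.bb2, H, W); relu_(fc.actB2);
    if (keep_cache) { fc.colB1 = std::move(c1); fc.colB2 = std::move(c2); }
  }
  cur = fc.actB2;
  for (int l = depth - 1; l >= 0; --l) {
    H *= 2; W *= 2;
    cube ups = upsample2(cur);
    mat cu = im2col(ups, 2, 2, 0, 0);
    cube au = conv_from_col(cu, w.uW[l], w.ub[l], H, W); relu_(au);
    cube cat = arma::join_slices(fc.skip[l], au);
    mat c1 = im2col(cat, 3, 3, 1, 1);
    cube a1 = conv_from_col(c1, w.dW1[l], w.db1[l], H, W); relu_(a1);
    mat c2 = im2col(a1, 3, 3, 1, 1);
    cube a2 = conv_from_col(c2, w.dW2[l], w.db2[l], H, W); relu_(a2);
    cur = a2;
    if (keep_cache) {
      fc.colU[l] = std::move(cu); fc.colD1[l] = std::move(c1);
      fc.colD2[l] = std::move(c2);
      fc.actU[l] = std::move(au); fc.actD1[l] = std::move(a1);
      fc.actD2[l] = std::move(a2);
    }
  }
  mat cf = im2col(cur, 1, 1, 0, 0);
  fc.logits = conv_from_col(cf, w.fW, w.fb, H, W);
  if (keep_cache) fc.colF = std::move(cf);
}

// [[Rcpp::export]]
arma::cube cpp_unet_logits(const arma::mat& x, List weights, int depth,
                           int base) {
  UnetWeights w = parse_weights(weights, depth);
  ForwardCache fc;
  unet_forward(x, w, depth, fc, false);
  return fc.logits;
}

// class_w: optional per-class loss weights (length 3) or empty for
// unweighted; the loss is the weighted mean pixel cross-entropy.
// [[Rcpp::export]]
List cpp_unet_grad(const arma::mat& x, const arma::imat& y, List weights,
                   int depth, int base, NumericVector class_w) {
  const int H0 = x.n_rows, W0 = x.n_cols;
  if ((int)y.n_rows != H0 || (int)y.n_cols != W0)
    stop("image and mask shapes differ");
  const bool weighted = class_w.size() == 3;
  UnetWeights w = parse_weights(weights, depth);
  ForwardCache fc;
  unet_forward(x, w, depth, fc, true);

  // softmax cross-entropy over the 3 class maps, (weighted) mean over pixels
  double wsum = 0.0;
  for (int j = 0; j < W0; ++j)
    for (int i = 0; i < H0; ++i) {
      const int yy = y(i, j);
      if (yy < 0 || yy > 2) stop("mask labels must lie in {0,1,2}");
      wsum += weighted ? class_w[yy] : 1.0;
    }
  double loss = 0.0;
  cube dlog(H0, W0, 3);
  for (int j = 0; j < W0; ++j) {
    for (int i = 0; i < H0; ++i) {
      const int yy = y(i, j);
      const double pw = weighted ? class_w[yy] : 1.0;
      double m = fc.logits(i, j, 0);
      for (int k = 1; k < 3; ++k) m = std::max(m, fc.logits(i, j, k));
      double s = 0.0;
      for (int k = 0; k < 3; ++k) s += std::exp(fc.logits(i, j, k) - m);
      loss += -pw * (fc.logits(i, j, yy) - m - std::log(s));
      for (int k = 0; k < 3; ++k)
        dlog(i, j, k) = pw *
          (std::exp(fc.logits(i, j, k) - m) / s - (k == yy ? 1.0 : 0.0)) / wsum;
    }
  }
  loss /= wsum;

  UnetWeights g;  // gradients, same shapes
  g.eW1.resize(depth); g.eb1.resize(depth); g.eW2.resize(depth);
  g.eb2.resize(depth); g.uW.resize(depth);  g.ub.resize(depth);
  g.dW1.resize(depth); g.db1.resize(depth); g.dW2.resize(depth);
  g.db2.resize(depth);

  cube dcur = conv_backward(dlog, fc.colF, w.fW, 1, 1, 0, 0, base,
                            g.fW, g.fb, true);
  std::vector<cube> dskip(depth);
  for (int l = 0; l < depth; ++l) {
    const int ch = base << l;
    relu_mask_(dcur, fc.actD2[l]);
    cube d1 = conv_backward(dcur, fc.colD2[l], w.dW2[l], 3, 3, 1, 1, ch,
                            g.dW2[l], g.db2[l], true);
    relu_mask_(d1, fc.actD1[l]);
    cube dcat = conv_backward(d1, fc.colD1[l], w.dW1[l], 3, 3, 1, 1, 2 * ch,
                              g.dW1[l], g.db1[l], true);
    dskip[l] = dcat.slices(0, ch - 1);
    cube dup = dcat.slices(ch, 2 * ch - 1);
    relu_mask_(dup, fc.actU[l]);
    cube dups = conv_backward(dup, fc.colU[l], w.uW[l], 2, 2, 0, 0, 2 * ch,
                              g.uW[l], g.ub[l], true);
    dcur = upsample2_backward(dups);
  }
  // dcur is now d(bottleneck output)
  relu_mask_(dcur, fc.actB2);
  cube dtmp = conv_backward(dcur, fc.colB2, w.bW2, 3, 3, 1, 1, base << depth,
                            g.bW2, g.bb2, true);
  relu_mask_(dtmp, fc.actB1);
  cube dpool = conv_backward(dtmp, fc.colB1, w.bW1, 3, 3, 1, 1,
                             base << (depth - 1), g.bW1, g.bb1, true);
  for (int l = depth - 1; l >= 0; --l) {
    const int ch = base << l;
    cube ds = maxpool2_backward(dpool, fc.poolIdx[l],
                                fc.skip[l].n_rows, fc.skip[l].n_cols);
    ds += dskip[l];
    relu_mask_(ds, fc.skip[l]);
    cube d1 = conv_backward(ds, fc.colE2[l], w.eW2[l], 3, 3, 1, 1, ch,
                            g.eW2[l], g.eb2[l], true);
    relu_mask_(d1, fc.actE1[l]);
    const int cin = (l == 0) ? 1 : (base << (l - 1));
    dpool = conv_backward(d1, fc.colE1[l], w.eW1[l], 3, 3, 1, 1, cin,
                          g.eW1[l], g.eb1[l], l > 0);
  }

  List grads(10 * depth + 6);
  int k = 0;
  for (int l = 0; l < depth; ++l) {
    grads[k++] = g.eW1[l]; grads[k++] = g.eb1[l];
    grads[k++] = g.eW2[l]; grads[k++] = g.eb2[l];
  }
  grads[k++] = g.bW1; grads[k++] = g.bb1;
  grads[k++] = g.bW2; grads[k++] = g.bb2;
  for (int l = depth - 1; l >= 0; --l) {
    grads[k++] = g.uW[l];  grads[k++] = g.ub[l];
    grads[k++] = g.dW1[l]; grads[k++] = g.db1[l];
    grads[k++] = g.dW2[l]; grads[k++] = g.db2[l];
  }
  grads[k++] = g.fW; grads[k++] = g.fb;
  return List::create(_["loss"] = loss, _["grads"] = grads);
}
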