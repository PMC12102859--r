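// Two-stage cascade building block: a small binary CNN
// (conv-pool-conv-pool-conv-fc, sigmoid output) trained with Adam on
// binary cross-entropy. Convolutions use im2col + GEMM; 'same' zero
// padding; max pooling with stride = pool size. All randomness
// (initial weights, shuffling, validation split) is generated on the R
// side, so the C++ path is a deterministic function of its arguments.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::umat;
using arma::uvec;

namespace {

struct Dims {
  int s, k, p, f1, f2, f3;
  int s2, s3, n1, n2, n3;  // spatial sides after pooling; pixel counts
  Dims(int s_, int k_, int p_, int f1_, int f2_, int f3_)
      : s(s_), k(k_), p(p_), f1(f1_), f2(f2_), f3(f3_) {
    s2 = s / p; s3 = s2 / p;
    n1 = s * s; n2 = s2 * s2; n3 = s3 * s3;
  }
};

struct Weights {
  mat W1, W2, W3, W4;
  vec b1, b2, b3;
  double b4;
};

Weights weights_from_list(const List& w) {
  Weights out;
  out.W1 = as<mat>(w["W1"]); out.b1 = as<vec>(w["b1"]);
  out.W2 = as<mat>(w["W2"]); out.b2 = as<vec>(w["b2"]);
  out.W3 = as<mat>(w["W3"]); out.b3 = as<vec>(w["b3"]);
  out.W4 = as<mat>(w["W4"]); out.b4 = as<double>(w["b4"]);
  return out;
}

List weights_to_list(const Weights& w) {
  return List::create(_["W1"] = w.W1, _["b1"] = w.b1,
                      _["W2"] = w.W2, _["b2"] = w.b2,
                      _["W3"] = w.W3, _["b3"] = w.b3,
                      _["W4"] = w.W4, _["b4"] = w.b4);
}

// A (cin x h*w, pixel index = r + h*c) -> cols ((cin*k^2) x h*w), zero pad.
void im2col(const mat& A, int h, int w, int k, mat& cols) {
  const int cin = A.n_rows, half = k / 2;
  cols.zeros();
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      const int out = r + h * c;
      for (int kc = 0; kc < k; ++kc) {
        const int cc = c + kc - half;
        if (cc < 0 || cc >= w) continue;
        for (int kr = 0; kr < k; ++kr) {
          const int rr = r + kr - half;
          if (rr < 0 || rr >= h) continue;
          const int src = rr + h * cc;
          for (int ci = 0; ci < cin; ++ci)
            cols(ci * k * k + kr * k + kc, out) = A(ci, src);
        }
      }
    }
  }
}

// Transpose of im2col: scatter-add dcols back onto dA (cin x h*w).
void col2im(const mat& dcols, int h, int w, int k, mat& dA) {
  const int cin = dA.n_rows, half = k / 2;
  dA.zeros();
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      const int out = r + h * c;
      for (int kc = 0; kc < k; ++kc) {
        const int cc = c + kc - half;
        if (cc < 0 || cc >= w) continue;
        for (int kr = 0; kr < k; ++kr) {
          const int rr = r + kr - half;
          if (rr < 0 || rr >= h) continue;
          const int src = rr + h * cc;
          for (int ci = 0; ci < cin; ++ci)
            dA(ci, src) += dcols(ci * k * k + kr * k + kc, out);
        }
      }
    }
  }
}

// Max pool A (f x h*w) -> out (f x (h/p * w/p)); amax stores source pixel.
void maxpool(const mat& A, int h, int w, int p, mat& out, umat& amax) {
  const int f = A.n_rows, h2 = h / p, w2 = w / p;
  for (int c2 = 0; c2 < w2; ++c2) {
    for (int r2 = 0; r2 < h2; ++r2) {
      const int o = r2 + h2 * c2;
      for (int fi = 0; fi < f; ++fi) {
        double best = -arma::datum::inf; int bestpix = 0;
        for (int dc = 0; dc < p; ++dc) {
          for (int dr = 0; dr < p; ++dr) {
            const int pix = (r2 * p + dr) + h * (c2 * p + dc);
            if (A(fi, pix) > best) { best = A(fi, pix); bestpix = pix; }
          }
        }
        out(fi, o) = best;
        amax(fi, o) = bestpix;
      }
    }
  }
}

struct Workspace {
  mat x;                       // 3 x s^2
  mat cols1, a1, p1, cols2, a2, p2, cols3, a3;
  umat amax1, amax2;
  mat da1, dp1, da2, dp2, da3, dcols2, dcols3;
  Workspace(const Dims& d) {
    x.set_size(3, d.n1);
    cols1.set_size(3 * d.k * d.k, d.n1);
    a1.set_size(d.f1, d.n1);
    p1.set_size(d.f1, d.n2);  amax1.set_size(d.f1, d.n2);
    cols2.set_size(d.f1 * d.k * d.k, d.n2);
    a2.set_size(d.f2, d.n2);
    p2.set_size(d.f2, d.n3);  amax2.set_size(d.f2, d.n3);
    cols3.set_size(d.f2 * d.k * d.k, d.n3);
    a3.set_size(d.f3, d.n3);
    da1.set_size(d.f1, d.n1); dp1.set_size(d.f1, d.n2);
    da2.set_size(d.f2, d.n2); dp2.set_size(d.f2, d.n3);
    da3.set_size(d.f3, d.n3);
    dcols2.set_size(d.f1 * d.k * d.k, d.n2);
    dcols3.set_size(d.f2 * d.k * d.k, d.n3);
  }
};

// X rows are R-flattened s x s x 3 arrays (row + s*col + s^2*channel).
void load_sample(const mat& X, arma::uword i, const Dims& d, mat& x) {
  for (int ch = 0; ch < 3; ++ch)
    for (int pix = 0; pix < d.n1; ++pix)
      x(ch, pix) = X(i, pix + d.n1 * ch);
}

double forward(const Weights& w, const Dims& d, Workspace& ws) {
  im2col(ws.x, d.s, d.s, d.k, ws.cols1);
  ws.a1 = w.W1 * ws.cols1;
  ws.a1.each_col() += w.b1;
  ws.a1.transform([](double v) { return v > 0.0 ? v : 0.0; });
  maxpool(ws.a1, d.s, d.s, d.p, ws.p1, ws.amax1);
  im2col(ws.p1, d.s2, d.s2, d.k, ws.cols2);
  ws.a2 = w.W2 * ws.cols2;
  ws.a2.each_col() += w.b2;
  ws.a2.transform([](double v) { return v > 0.0 ? v : 0.0; });
  maxpool(ws.a2, d.s2, d.s2, d.p, ws.p2, ws.amax2);
  im2col(ws.p2, d.s3, d.s3, d.k, ws.cols3);
  ws.a3 = w.W3 * ws.cols3;
  ws.a3.each_col() += w.b3;
  ws.a3.transform([](double v) { return v > 0.0 ? v : 0.0; });
  double z = arma::dot(w.W4.row(0), arma::vectorise(ws.a3)) + w.b4;
  return 1.0 / (1.0 + std::exp(-z));
}

// Accumulate gradient of weight * BCE(prob, y) into g. dz = wt*(p - y).
void backward(const Weights& w, const Dims& d, Workspace& ws,
              double prob, double y, double wt, Weights& g) {
  const double dz = wt * (prob - y);
  g.W4.row(0) += dz * arma::vectorise(ws.a3).t();
  g.b4 += dz;
  ws.da3 = arma::reshape(w.W4.row(0).t() * dz, d.f3, d.n3);
  ws.da3.elem(arma::find(ws.a3 == 0.0)).zeros();
  g.W3 += ws.da3 * ws.cols3.t();
  g.b3 += arma::sum(ws.da3, 1);
  ws.dcols3 = w.W3.t() * ws.da3;
  col2im(ws.dcols3, d.s3, d.s3, d.k, ws.dp2);
  ws.da2.zeros();
  for (int o = 0; o < d.n3; ++o)
    for (int fi = 0; fi < d.f2; ++fi)
      ws.da2(fi, ws.amax2(fi, o)) += ws.dp2(fi, o);
  ws.da2.elem(arma::find(ws.a2 == 0.0)).zeros();
  g.W2 += ws.da2 * ws.cols2.t();
  g.b2 += arma::sum(ws.da2, 1);
  ws.dcols2 = w.W2.t() * ws.da2;
  col2im(ws.dcols2, d.s2, d.s2, d.k, ws.dp1);
  ws.da1.zeros();
  for (int o = 0; o < d.n2; ++o)
    for (int fi = 0; fi < d.f1; ++fi)
      ws.da1(fi, ws.amax1(fi, o)) += ws.dp1(fi, o);
  ws.da1.elem(arma::find(ws.a1 == 0.0)).zeros();
  g.W1 += ws.da1 * ws.cols1.t();
  g.b1 += arma::sum(ws.da1, 1);
}

double bce(double p, double y) {
  const double eps = 1e-12;
  p = std::min(std::max(p, eps), 1.0 - eps);
  return -(y * std::log(p) + (1.0 - y) * std::log(1.0 - p));
}

struct Adam {
  Weights m, v;
  double lr, b1, b2, eps;
  long t;
  Adam(const Weights& w, double lr_) : lr(lr_), b1(0.9), b2(0.999),
                                       eps(1e-8), t(0) {
    m.W1 = arma::zeros(arma::size(w.W1)); v.W1 = m.W1;
    m.W2 = arma::zeros(arma::size(w.W2)); v.W2 = m.W2;
    m.W3 = arma::zeros(arma::size(w.W3)); v.W3 = m.W3;
    m.W4 = arma::zeros(arma::size(w.W4)); v.W4 = m.W4;
    m.b1 = arma::zeros(arma::size(w.b1)); v.b1 = m.b1;
    m.b2 = arma::zeros(arma::size(w.b2)); v.b2 = m.b2;
    m.b3 = arma::zeros(arma::size(w.b3)); v.b3 = m.b3;
    m.b4 = 0.0; v.b4 = 0.0;
  }
  void upd(mat& w, mat& mm, mat& vv, const mat& g, double c1, double c2) {
    mm = b1 * mm + (1.0 - b1) * g;
    vv = b2 * vv + (1.0 - b2) * (g % g);
    w -= lr * (mm / c1) / (arma::sqrt(vv / c2) + eps);
  }
  void updv(vec& w, vec& mm, vec& vv, const vec& g, double c1, double c2) {
    mm = b1 * mm + (1.0 - b1) * g;
    vv = b2 * vv + (1.0 - b2) * (g % g);
    w -= lr * (mm / c1) / (arma::sqrt(vv / c2) + eps);
  }
  void step(Weights& w, const Weights& g) {
    ++t;
    const double c1 = 1.0 - std::pow(b1, (double)t);
    const double c2 = 1.0 - std::pow(b2, (double)t);
    upd(w.W1, m.W1, v.W1, g.W1, c1, c2);
    upd(w.W2, m.W2, v.W2, g.W2, c1, c2);
    upd(w.W3, m.W3, v.W3, g.W3, c1, c2);
    upd(w.W4, m.W4, v.W4, g.W4, c1, c2);
    updv(w.b1, m.b1, v.b1, g.b1, c1, c2);
    updv(w.b2, m.b2, v.b2, g.b2, c1, c2);
    updv(w.b3, m.b3, v.b3, g.b3, c1, c2);
    m.b4 = b1 * m.b4 + (1.0 - b1) * g.b4;
    v.b4 = b2 * v.b4 + (1.0 - b2) * g.b4 * g.b4;
    w.b4 -= lr * (m.b4 / c1) / (std::sqrt(v.b4 / c2) + eps);
  }
};

Weights zeros_like(const Weights& w) {
  Weights g;
  g.W1 = arma::zeros(arma::size(w.W1)); g.b1 = arma::zeros(arma::size(w.b1));
  g.W2 = arma::zeros(arma::size(w.W2)); g.b2 = arma::zeros(arma::size(w.b2));
  g.W3 = arma::zeros(arma::size(w.W3)); g.b3 = arma::zeros(arma::size(w.b3));
  g.W4 = arma::zeros(arma::size(w.W4)); g.b4 = 0.0;
  return g;
}

}  // namespace

// [[Rcpp::export]]
arma::vec cnn_forward_cpp(const arma::mat& X, const List& weights,
                          int input_size, int kernel_size, int pool_size,
                          const IntegerVector& filters) {
  Dims d(input_size, kernel_size, pool_size,
         filters[0], filters[1], filters[2]);
  Weights w = weights_from_list(weights);
  Workspace ws(d);
  vec out(X.n_rows);
  for (arma::uword i = 0; i < X.n_rows; ++i) {
    load_sample(X, i, d, ws.x);
    out(i) = forward(w, d, ws);
  }
  return out;
}

// perms: n_train x epochs matrix of 0-based indices into X (row order per
// epoch). sample_weights: per-row loss weight (1 = unweighted).
// [[Rcpp::export]]
List cnn_train_cpp(const arma::mat& X, const arma::vec& y,
                   const List& weights0, int input_size, int kernel_size,
                   int pool_size, const IntegerVector& filters,
                   int epochs, int batch_size, double lr,
                   const arma::umat& perms, const arma::uvec& val_idx,
                   const arma::vec& sample_weights) {
  Dims d(input_size, kernel_size, pool_size,
         filters[0], filters[1], filters[2]);
  Weights w = weights_from_list(weights0);
  Workspace ws(d);
  Adam opt(w, lr);
  const arma::uword ntr = perms.n_rows;
  vec loss_hist(epochs), acc_hist(epochs);
  vec vloss_hist(epochs), vacc_hist(epochs);
  vloss_hist.fill(NA_REAL); vacc_hist.fill(NA_REAL);

  for (int e = 0; e < epochs; ++e) {
    double eloss = 0.0, ew = 0.0; arma::uword ecorrect = 0;
    arma::uword i = 0;
    while (i < ntr) {
      const arma::uword bn = std::min<arma::uword>(batch_size, ntr - i);
      Weights g = zeros_like(w);
      for (arma::uword b = 0; b < bn; ++b) {
        const arma::uword idx = perms(i + b, e);
        load_sample(X, idx, d, ws.x);
        const double prob = forward(w, d, ws);
        const double wt = sample_weights(idx);
        backward(w, d, ws, prob, y(idx), wt / (double)bn, g);
        eloss += wt * bce(prob, y(idx));
        ew += wt;
        if ((prob >= 0.5) == (y(idx) >= 0.5)) ++ecorrect;
      }
      opt.step(w, g);
      i += bn;
    }
    loss_hist(e) = eloss / ew;
    acc_hist(e) = (double)ecorrect / (double)ntr;
    if (val_idx.n_elem > 0) {
      double vl = 0.0; arma::uword vc = 0;
      for (arma::uword j = 0; j < val_idx.n_elem; ++j) {
        load_sample(X, val_idx(j), d, ws.x);
        const double prob = forward(w, d, ws);
        vl += bce(prob, y(val_idx(j)));
        if ((prob >= 0.5) == (y(val_idx(j)) >= 0.5)) ++vc;
      }
      vloss_hist(e) = vl / val_idx.n_elem;
      vacc_hist(e) = (double)vc / (double)val_idx.n_elem;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["weights"] = weights_to_list(w),
      _["loss"] = loss_hist, _["accuracy"] = acc_hist,
      _["val_loss"] = vloss_hist, _["val_accuracy"] = vacc_hist);
}

// Loss and full gradient for one sample; used by the finite-difference
// gradient test.
// [[Rcpp::export]]
List cnn_loss_grad_cpp(const arma::rowvec& xrow, double y,
                       const List& weights, int input_size, int kernel_size,
                       int pool_size, const IntegerVector& filters) {
  Dims d(input_size, kernel_size, pool_size,
         filters[0], filters[1], filters[2]);
  Weights w = weights_from_list(weights);
  Workspace ws(d);
  mat X(1, xrow.n_elem);
  X.row(0) = xrow;
  load_sample(X, 0, d, ws.x);
  const double prob = forward(w, d, ws);
  Weights g = zeros_like(w);
  backward(w, d, ws, prob, y, 1.0, g);
  return List::create(_["loss"] = bce(prob, y), _["prob"] = prob,
                      _["grad"] = weights_to_list(g));
}
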