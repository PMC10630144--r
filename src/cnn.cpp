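// Minimal CNN engine for wavefront-coefficient regression.
//
// Layers operate on batches stored as (C*H*W) x B matrices, column = one
// sample, element index (c*H + i)*W + j (row i, col j within channel c).
// Supported layer types: conv (im2col/col2im), bn (batch norm over
// channel), prelu (per-channel), skip_save / skip_add (residual blocks).
// Training runs entirely in C++ (Adam, MSE loss) so that R-level overhead
// does not dominate; all randomness comes from an explicit seed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

namespace {

struct Layer {
  std::string type;
  // conv
  mat W;        // Cout x (Cin*kh*kw)
  vec b;        // Cout
  int cin = 0, cout = 0, kh = 0, kw = 0, stride = 1, pad = 0;
  int hin = 0, win = 0, hout = 0, wout = 0;
  // bn
  vec gamma, beta, run_mean, run_var;
  double momentum = 0.1, eps = 1e-5;
  // prelu
  vec alpha;
  int channels = 0, hw = 0;
  // adam state
  mat mW, vW;
  vec mb, vb, mg, vg, mbe, vbe, ma, va;
};

struct Cache {
  mat x;        // input to layer
  mat cols;     // im2col matrix (conv)
  mat xhat;     // normalized activations (bn)
  vec mean, invstd;
};

// im2col: output (Cin*kh*kw) x (B*oh*ow); output column order: sample-major,
// then row-major over output positions.
mat im2col(const mat& X, int C, int H, int W, int kh, int kw, int stride,
           int pad, int oh, int ow) {
  const int B = X.n_cols;
  mat cols(C * kh * kw, (size_t)B * oh * ow, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const double* xb = X.colptr(b);
    for (int oy = 0; oy < oh; ++oy) {
      for (int ox = 0; ox < ow; ++ox) {
        double* cp = cols.colptr((size_t)b * oh * ow + (size_t)oy * ow + ox);
        int iy0 = oy * stride - pad, ix0 = ox * stride - pad;
        for (int c = 0; c < C; ++c) {
          for (int ky = 0; ky < kh; ++ky) {
            int iy = iy0 + ky;
            for (int kx = 0; kx < kw; ++kx) {
              int ix = ix0 + kx;
              double v = 0.0;
              if (iy >= 0 && iy < H && ix >= 0 && ix < W)
                v = xb[(c * H + iy) * W + ix];
              cp[(c * kh + ky) * kw + kx] = v;
            }
          }
        }
      }
    }
  }
  return cols;
}

mat col2im(const mat& cols, int C, int H, int W, int kh, int kw, int stride,
           int pad, int oh, int ow, int B) {
  mat X(C * H * W, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    double* xb = X.colptr(b);
    for (int oy = 0; oy < oh; ++oy) {
      for (int ox = 0; ox < ow; ++ox) {
        const double* cp =
            cols.colptr((size_t)b * oh * ow + (size_t)oy * ow + ox);
        int iy0 = oy * stride - pad, ix0 = ox * stride - pad;
        for (int c = 0; c < C; ++c) {
          for (int ky = 0; ky < kh; ++ky) {
            int iy = iy0 + ky;
            if (iy < 0 || iy >= H) continue;
            for (int kx = 0; kx < kw; ++kx) {
              int ix = ix0 + kx;
              if (ix < 0 || ix >= W) continue;
              xb[(c * H + iy) * W + ix] += cp[(c * kh + ky) * kw + kx];
            }
          }
        }
      }
    }
  }
  return X;
}

// rearrange conv output (Cout x B*oh*ow) -> (Cout*oh*ow) x B
mat gather_out(const mat& Y, int cout, int oh, int ow, int B) {
  mat out(cout * oh * ow, B);
  for (int b = 0; b < B; ++b) {
    double* op = out.colptr(b);
    for (int p = 0; p < oh * ow; ++p) {
      const double* yp = Y.colptr((size_t)b * oh * ow + p);
      for (int c = 0; c < cout; ++c) op[c * oh * ow + p] = yp[c];
    }
  }
  return out;
}

mat scatter_out(const mat& dOut, int cout, int oh, int ow, int B) {
  mat dY(cout, (size_t)B * oh * ow);
  for (int b = 0; b < B; ++b) {
    const double* op = dOut.colptr(b);
    for (int p = 0; p < oh * ow; ++p) {
      double* yp = dY.colptr((size_t)b * oh * ow + p);
      for (int c = 0; c < cout; ++c) yp[c] = op[c * oh * ow + p];
    }
  }
  return dY;
}

std::vector<Layer> parse_layers(const List& spec) {
  std::vector<Layer> L;
  for (int i = 0; i < spec.size(); ++i) {
    List ls = spec[i];
    Layer l;
    l.type = as<std::string>(ls["type"]);
    if (l.type == "conv") {
      l.W = as<mat>(ls["W"]);
      l.b = as<vec>(ls["b"]);
      l.cin = as<int>(ls["cin"]);
      l.cout = as<int>(ls["cout"]);
      l.kh = as<int>(ls["kh"]);
      l.kw = as<int>(ls["kw"]);
      l.stride = as<int>(ls["stride"]);
      l.pad = as<int>(ls["pad"]);
      l.hin = as<int>(ls["hin"]);
      l.win = as<int>(ls["win"]);
      l.hout = (l.hin + 2 * l.pad - l.kh) / l.stride + 1;
      l.wout = (l.win + 2 * l.pad - l.kw) / l.stride + 1;
    } else if (l.type == "bn") {
      l.gamma = as<vec>(ls["gamma"]);
      l.beta = as<vec>(ls["beta"]);
      l.run_mean = as<vec>(ls["run_mean"]);
      l.run_var = as<vec>(ls["run_var"]);
      l.channels = as<int>(ls["channels"]);
      l.hw = as<int>(ls["hw"]);
    } else if (l.type == "prelu") {
      l.alpha = as<vec>(ls["alpha"]);
      l.channels = as<int>(ls["channels"]);
      l.hw = as<int>(ls["hw"]);
    } else if (l.type == "skip_save" || l.type == "skip_add") {
      // no parameters
    } else {
      stop("unknown layer type: " + l.type);
    }
    L.push_back(l);
  }
  return L;
}

List layers_to_list(const std::vector<Layer>& L) {
  List out(L.size());
  for (size_t i = 0; i < L.size(); ++i) {
    const Layer& l = L[i];
    if (l.type == "conv") {
      out[i] = List::create(_["type"] = l.type, _["W"] = l.W, _["b"] = l.b,
                            _["cin"] = l.cin, _["cout"] = l.cout,
                            _["kh"] = l.kh, _["kw"] = l.kw,
                            _["stride"] = l.stride, _["pad"] = l.pad,
                            _["hin"] = l.hin, _["win"] = l.win);
    } else if (l.type == "bn") {
      out[i] = List::create(_["type"] = l.type, _["gamma"] = l.gamma,
                            _["beta"] = l.beta, _["run_mean"] = l.run_mean,
                            _["run_var"] = l.run_var,
                            _["channels"] = l.channels, _["hw"] = l.hw);
    } else if (l.type == "prelu") {
      out[i] = List::create(_["type"] = l.type, _["alpha"] = l.alpha,
                            _["channels"] = l.channels, _["hw"] = l.hw);
    } else {
      out[i] = List::create(_["type"] = l.type);
    }
  }
  return out;
}

mat forward_pass(std::vector<Layer>& L, const mat& X, bool training,
                 std::vector<Cache>* caches) {
  mat cur = X;
  std::vector<mat> skip_stack;
  for (size_t i = 0; i < L.size(); ++i) {
    Layer& l = L[i];
    Cache cc;
    if (caches) cc.x = cur;
    if (l.type == "conv") {
      int B = cur.n_cols;
      mat cols = im2col(cur, l.cin, l.hin, l.win, l.kh, l.kw, l.stride, l.pad,
                        l.hout, l.wout);
      mat Y = l.W * cols;
      Y.each_col() += l.b;
      cur = gather_out(Y, l.cout, l.hout, l.wout, B);
      if (caches) cc.cols = std::move(cols);
    } else if (l.type == "bn") {
      int B = cur.n_cols, C = l.channels, HW = l.hw;
      vec mu(C), var(C);
      if (training) {
        for (int c = 0; c < C; ++c) {
          mat sub = cur.rows(c * HW, (c + 1) * HW - 1);
          mu[c] = arma::accu(sub) / ((double)B * HW);
          var[c] = arma::accu(arma::square(sub - mu[c])) / ((double)B * HW);
        }
        l.run_mean = (1 - l.momentum) * l.run_mean + l.momentum * mu;
        l.run_var = (1 - l.momentum) * l.run_var + l.momentum * var;
      } else {
        mu = l.run_mean;
        var = l.run_var;
      }
      vec invstd = 1.0 / arma::sqrt(var + l.eps);
      mat xhat = cur;
      for (int c = 0; c < C; ++c) {
        xhat.rows(c * HW, (c + 1) * HW - 1) =
            (cur.rows(c * HW, (c + 1) * HW - 1) - mu[c]) * invstd[c];
        cur.rows(c * HW, (c + 1) * HW - 1) =
            xhat.rows(c * HW, (c + 1) * HW - 1) * l.gamma[c] + l.beta[c];
      }
      if (caches) {
        cc.xhat = std::move(xhat);
        cc.mean = mu;
        cc.invstd = invstd;
      }
    } else if (l.type == "prelu") {
      int C = l.channels, HW = l.hw;
      for (int c = 0; c < C; ++c) {
        mat sub = cur.rows(c * HW, (c + 1) * HW - 1);
        cur.rows(c * HW, (c + 1) * HW - 1) =
            arma::max(sub, arma::zeros<mat>(sub.n_rows, sub.n_cols)) +
            l.alpha[c] *
                arma::min(sub, arma::zeros<mat>(sub.n_rows, sub.n_cols));
      }
    } else if (l.type == "skip_save") {
      skip_stack.push_back(cur);
    } else if (l.type == "skip_add") {
      cur += skip_stack.back();
      skip_stack.pop_back();
    }
    if (caches) caches->push_back(std::move(cc));
  }
  return cur;
}

struct Grads {
  mat dW;
  vec db, dgamma, dbeta, dalpha;
};

mat backward_pass(std::vector<Layer>& L, const std::vector<Cache>& caches,
                  mat dcur, std::vector<Grads>& grads) {
  std::vector<mat> skip_grad_stack;
  for (int i = (int)L.size() - 1; i >= 0; --i) {
    Layer& l = L[i];
    const Cache& cc = caches[i];
    Grads g;
    if (l.type == "conv") {
      int B = dcur.n_cols;
      mat dY = scatter_out(dcur, l.cout, l.hout, l.wout, B);
      g.dW = dY * cc.cols.t();
      g.db = arma::sum(dY, 1);
      mat dcols = l.W.t() * dY;
      dcur = col2im(dcols, l.cin, l.hin, l.win, l.kh, l.kw, l.stride, l.pad,
                    l.hout, l.wout, B);
    } else if (l.type == "bn") {
      int B = dcur.n_cols, C = l.channels, HW = l.hw;
      g.dgamma.set_size(C);
      g.dbeta.set_size(C);
      double n = (double)B * HW;
      for (int c = 0; c < C; ++c) {
        mat dy = dcur.rows(c * HW, (c + 1) * HW - 1);
        mat xh = cc.xhat.rows(c * HW, (c + 1) * HW - 1);
        g.dgamma[c] = arma::accu(dy % xh);
        g.dbeta[c] = arma::accu(dy);
        mat dxhat = dy * l.gamma[c];
        double s1 = arma::accu(dxhat), s2 = arma::accu(dxhat % xh);
        dcur.rows(c * HW, (c + 1) * HW - 1) =
            cc.invstd[c] * (dxhat - s1 / n - xh * (s2 / n));
      }
    } else if (l.type == "prelu") {
      int C = l.channels, HW = l.hw;
      g.dalpha.set_size(C);
      for (int c = 0; c < C; ++c) {
        mat x = cc.x.rows(c * HW, (c + 1) * HW - 1);
        mat dy = dcur.rows(c * HW, (c + 1) * HW - 1);
        arma::umat neg = (x < 0);
        g.dalpha[c] = arma::accu(dy % x % arma::conv_to<mat>::from(neg));
        dcur.rows(c * HW, (c + 1) * HW - 1) =
            dy % (arma::conv_to<mat>::from(x >= 0) +
                  l.alpha[c] * arma::conv_to<mat>::from(neg));
      }
    } else if (l.type == "skip_save") {
      dcur += skip_grad_stack.back();
      skip_grad_stack.pop_back();
    } else if (l.type == "skip_add") {
      skip_grad_stack.push_back(dcur);
    }
    grads[i] = std::move(g);
  }
  return dcur;
}

void adam_step(mat& w, mat& m, mat& v, const mat& g, double lr, double b1,
               double b2, double eps, double bc1, double bc2) {
  if (m.n_elem == 0) {
    m.zeros(w.n_rows, w.n_cols);
    v.zeros(w.n_rows, w.n_cols);
  }
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
}

void adam_step_v(vec& w, vec& m, vec& v, const vec& g, double lr, double b1,
                 double b2, double eps, double bc1, double bc2) {
  if (m.n_elem == 0) {
    m.zeros(w.n_elem);
    v.zeros(w.n_elem);
  }
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
}

}  // namespace

// [[Rcpp::export(name = ".cnn_forward")]]
arma::mat cnn_forward_cpp(List layer_spec, const arma::mat& X,
                          bool training = false) {
  std::vector<Layer> L = parse_layers(layer_spec);
  return forward_pass(L, X, training, nullptr);
}

// [[Rcpp::export(name = ".cnn_train")]]
List cnn_train_cpp(List layer_spec, const arma::mat& X, const arma::mat& Y,
                   const arma::mat& Xval, const arma::mat& Yval, int epochs,
                   int batch_size, double lr, double beta1, double beta2,
                   double adam_eps, int seed, bool verbose) {
  std::vector<Layer> L = parse_layers(layer_spec);
  const int N = X.n_cols;
  std::mt19937 rng((unsigned)seed);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  vec train_loss(epochs, arma::fill::zeros);
  vec val_loss(epochs, arma::fill::value(arma::datum::nan));
  long step = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0;
    long n_seen = 0;
    for (int start = 0; start < N; start += batch_size) {
      int bs = std::min(batch_size, N - start);
      arma::uvec take(bs);
      for (int k = 0; k < bs; ++k) take[k] = idx[start + k];
      mat xb = X.cols(take), yb = Y.cols(take);
      std::vector<Cache> caches;
      caches.reserve(L.size());
      mat out = forward_pass(L, xb, true, &caches);
      mat diff = out - yb;
      double loss = arma::accu(diff % diff) / (diff.n_elem);
      if (!std::isfinite(loss))
        stop("training diverged (non-finite loss) at epoch %d", ep + 1);
      ep_loss += loss * bs;
      n_seen += bs;
      mat dout = 2.0 * diff / (double)diff.n_elem;
      std::vector<Grads> grads(L.size());
      backward_pass(L, caches, dout, grads);
      ++step;
      double bc1 = 1.0 - std::pow(beta1, (double)step);
      double bc2 = 1.0 - std::pow(beta2, (double)step);
      for (size_t i = 0; i < L.size(); ++i) {
        Layer& l = L[i];
        Grads& g = grads[i];
        if (l.type == "conv") {
          adam_step(l.W, l.mW, l.vW, g.dW, lr, beta1, beta2, adam_eps, bc1,
                    bc2);
          adam_step_v(l.b, l.mb, l.vb, g.db, lr, beta1, beta2, adam_eps, bc1,
                      bc2);
        } else if (l.type == "bn") {
          adam_step_v(l.gamma, l.mg, l.vg, g.dgamma, lr, beta1, beta2,
                      adam_eps, bc1, bc2);
          adam_step_v(l.beta, l.mbe, l.vbe, g.dbeta, lr, beta1, beta2,
                      adam_eps, bc1, bc2);
        } else if (l.type == "prelu") {
          adam_step_v(l.alpha, l.ma, l.va, g.dalpha, lr, beta1, beta2,
                      adam_eps, bc1, bc2);
        }
      }
    }
    train_loss[ep] = ep_loss / n_seen;
    if (Xval.n_cols > 0) {
      mat vout = forward_pass(L, Xval, false, nullptr);
      mat vd = vout - Yval;
      val_loss[ep] = arma::accu(vd % vd) / vd.n_elem;
    }
    if (verbose)
      Rcpp::Rcout << "epoch " << ep + 1 << "/" << epochs << " train "
                  << train_loss[ep] << " val " << val_loss[ep] << std::endl;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["layers"] = layers_to_list(L),
                      _["train_loss"] = train_loss, _["val_loss"] = val_loss);
}

// Per-pixel temporal median over a stack (rows x cols x frames).
// [[Rcpp::export(name = ".temporal_median")]]
arma::mat temporal_median_cpp(const arma::cube& stack) {
  const int R = stack.n_rows, C = stack.n_cols, T = stack.n_slices;
  arma::mat out(R, C);
  std::vector<double> buf(T);
  for (int j = 0; j < C; ++j) {
    for (int i = 0; i < R; ++i) {
      for (int t = 0; t < T; ++t) buf[t] = stack(i, j, t);
      std::nth_element(buf.begin(), buf.begin() + T / 2, buf.end());
      double hi = buf[T / 2];
      if (T % 2 == 1) {
        out(i, j) = hi;
      } else {
        double lo = *std::max_element(buf.begin(), buf.begin() + T / 2);
        out(i, j) = 0.5 * (lo + hi);
      }
    }
  }
  return out;
}
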