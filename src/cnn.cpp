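// 1D-CNN forward/backward engine with Adam, used by build_cnn()/train_cnn().
// Sequential topology: conv1d (valid, stride 1) + ReLU, maxpool1d
// (width = stride, no padding), inverted dropout, flatten, dense.
// Single-threaded and seeded, so runs are bit-reproducible.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

enum LayerKind { CONV = 0, POOL = 1, DROP = 2, FLAT = 3, DENSE = 4 };
enum Activation { ACT_NONE = 0, ACT_RELU = 1, ACT_SOFTMAX = 2 };

struct Layer {
  int kind;
  int arg1;      // filters / pool width / units
  int arg2;      // kernel width (conv)
  double rate;   // dropout rate
  int act;
  arma::mat W;
  arma::vec b;
  // Adam state
  arma::mat mW, vW;
  arma::vec mb, vb;
  // per-sample caches
  arma::mat in;        // input activation (len x ch) or flattened column
  arma::mat im2col;
  arma::mat out_pre;   // pre-activation
  arma::umat argmax;
  arma::mat mask;      // dropout mask
  // gradient accumulators
  arma::mat gW;
  arma::vec gb;
};

struct Net {
  int input_len;
  int input_ch;
  std::vector<Layer> layers;
};

static Net build_net(const List& arch, const List& params) {
  Net net;
  net.input_len = as<int>(arch["input_len"]);
  net.input_ch = as<int>(arch["input_channels"]);
  IntegerVector kind = arch["kind"];
  IntegerVector arg1 = arch["arg1"];
  IntegerVector arg2 = arch["arg2"];
  NumericVector rate = arch["rate"];
  IntegerVector act = arch["act"];
  for (int i = 0; i < kind.size(); ++i) {
    Layer L;
    L.kind = kind[i];
    L.arg1 = arg1[i];
    L.arg2 = arg2[i];
    L.rate = rate[i];
    L.act = act[i];
    if (L.kind == CONV || L.kind == DENSE) {
      List p = params[i];
      L.W = as<arma::mat>(p["W"]);
      L.b = as<arma::vec>(p["b"]);
      L.mW = arma::zeros(L.W.n_rows, L.W.n_cols);
      L.vW = arma::zeros(L.W.n_rows, L.W.n_cols);
      L.mb = arma::zeros(L.b.n_elem);
      L.vb = arma::zeros(L.b.n_elem);
    }
    net.layers.push_back(L);
  }
  return net;
}

static arma::mat im2col1d(const arma::mat& A, int k) {
  const int out_len = (int)A.n_rows - k + 1;
  const int ch = (int)A.n_cols;
  arma::mat IC(out_len, k * ch);
  for (int o = 0; o < k; ++o)
    IC.cols(o * ch, (o + 1) * ch - 1) = A.rows(o, o + out_len - 1);
  return IC;
}

// forward one sample; x enters as (len x ch); returns class probabilities
static arma::vec forward(Net& net, const arma::mat& x, bool training,
                         std::mt19937_64& rng, bool cache) {
  arma::mat A = x;          // pre-flatten: len x ch; post-flatten: n x 1
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  for (auto& L : net.layers) {
    if (cache) L.in = A;
    switch (L.kind) {
    case CONV: {
      if ((int)A.n_rows < L.arg2)
        stop("shape collapse: input length %d < kernel %d", (int)A.n_rows, L.arg2);
      arma::mat IC = im2col1d(A, L.arg2);
      arma::mat Z = IC * L.W;
      Z.each_row() += L.b.t();
      if (cache) { L.im2col = IC; L.out_pre = Z; }
      if (L.act == ACT_RELU) Z = arma::clamp(Z, 0.0, arma::datum::inf);
      A = Z;
      break;
    }
    case POOL: {
      const int p = L.arg1;
      const int out_len = (int)A.n_rows / p;
      const int ch = (int)A.n_cols;
      arma::mat Z(out_len, ch);
      arma::umat AM(out_len, ch);
      for (int c = 0; c < ch; ++c) {
        for (int i = 0; i < out_len; ++i) {
          arma::uword rel;
          double m = A.col(c).subvec(i * p, i * p + p - 1).max(rel);
          Z(i, c) = m;
          AM(i, c) = i * p + rel;
        }
      }
      if (cache) L.argmax = AM;
      A = Z;
      break;
    }
    case DROP: {
      if (training && L.rate > 0) {
        arma::mat M(A.n_rows, A.n_cols);
        const double keep = 1.0 - L.rate;
        for (arma::uword j = 0; j < M.n_elem; ++j)
          M(j) = (unif(rng) < keep) ? 1.0 / keep : 0.0;
        if (cache) L.mask = M;
        A %= M;
      } else if (cache) {
        L.mask = arma::ones(A.n_rows, A.n_cols);
      }
      break;
    }
    case FLAT: {
      A = arma::vectorise(A);   // column-major: channel blocks
      break;
    }
    case DENSE: {
      arma::vec a = A.col(0);
      arma::vec z = L.W.t() * a + L.b;
      if (cache) L.out_pre = z;
      if (L.act == ACT_RELU) z = arma::clamp(z, 0.0, arma::datum::inf);
      else if (L.act == ACT_SOFTMAX) {
        z -= z.max();
        z = arma::exp(z);
        z /= arma::accu(z);
      }
      A = z;
      break;
    }
    }
  }
  return A.col(0);
}

// backward one sample given dL/dz of the final (softmax) dense layer;
// accumulates gW/gb on every weight-bearing layer
static void backward(Net& net, const arma::vec& dlogits) {
  arma::mat D = dlogits;   // gradient flowing backwards
  for (int li = (int)net.layers.size() - 1; li >= 0; --li) {
    Layer& L = net.layers[li];
    switch (L.kind) {
    case DENSE: {
      arma::vec d = D.col(0);
      if (L.act == ACT_RELU) d %= arma::conv_to<arma::vec>::from(L.out_pre > 0);
      // softmax: dlogits already includes the softmax jacobian
      arma::vec a = L.in.col(0);
      L.gW += a * d.t();
      L.gb += d;
      D = L.W * d;
      break;
    }
    case FLAT: {
      D.reshape(L.in.n_rows, L.in.n_cols);
      break;
    }
    case DROP: {
      D %= L.mask;
      break;
    }
    case POOL: {
      arma::mat dA = arma::zeros(L.in.n_rows, L.in.n_cols);
      for (arma::uword c = 0; c < D.n_cols; ++c)
        for (arma::uword i = 0; i < D.n_rows; ++i)
          dA(L.argmax(i, c), c) += D(i, c);
      D = dA;
      break;
    }
    case CONV: {
      arma::mat dZ = D;
      if (L.act == ACT_RELU)
        dZ %= arma::conv_to<arma::mat>::from(L.out_pre > 0);
      L.gW += L.im2col.t() * dZ;
      L.gb += arma::sum(dZ, 0).t();
      arma::mat dIC = dZ * L.W.t();
      const int k = L.arg2;
      const int ch = (int)L.in.n_cols;
      const int out_len = (int)dZ.n_rows;
      arma::mat dA = arma::zeros(L.in.n_rows, L.in.n_cols);
      for (int o = 0; o < k; ++o)
        dA.rows(o, o + out_len - 1) += dIC.cols(o * ch, (o + 1) * ch - 1);
      D = dA;
      break;
    }
    }
  }
}

// loss and dL/dlogits for one sample (softmax output p, true class c)
static double sample_loss(const arma::vec& p, int c, double gamma,
                          arma::vec& dlogits) {
  const double eps = 1e-12;
  const double pc = std::max(p(c), eps);
  double loss;
  if (gamma == 0.0) {
    loss = -std::log(pc);
    dlogits = p;
    dlogits(c) -= 1.0;
  } else {
    const double om = 1.0 - pc;
    loss = -std::pow(om, gamma) * std::log(pc);
    // dL/dp_c, then through the softmax jacobian (only j = c contributes)
    const double dLdp = gamma * std::pow(om, gamma - 1.0) * std::log(pc)
                        - std::pow(om, gamma) / pc;
    dlogits = dLdp * pc * (-p);
    dlogits(c) += dLdp * pc;
  }
  return loss;
}

static void adam_step(Layer& L, double lr, double beta1, double beta2,
                      double eps, int t, int batch_n) {
  arma::mat gW = L.gW / batch_n;
  arma::vec gb = L.gb / batch_n;
  L.mW = beta1 * L.mW + (1 - beta1) * gW;
  L.vW = beta2 * L.vW + (1 - beta2) * (gW % gW);
  L.mb = beta1 * L.mb + (1 - beta1) * gb;
  L.vb = beta2 * L.vb + (1 - beta2) * (gb % gb);
  const double corr1 = 1.0 - std::pow(beta1, t);
  const double corr2 = 1.0 - std::pow(beta2, t);
  L.W -= lr * (L.mW / corr1) / (arma::sqrt(L.vW / corr2) + eps);
  L.b -= lr * (L.mb / corr1) / (arma::sqrt(L.vb / corr2) + eps);
}

static void sgd_step(Layer& L, double lr, int batch_n) {
  L.W -= lr * L.gW / batch_n;
  L.b -= lr * L.gb / batch_n;
}

static void eval_set(Net& net, const arma::mat& X, const IntegerVector& y,
                     double gamma, double& loss, double& acc) {
  std::mt19937_64 dummy(0);
  double lsum = 0;
  int correct = 0;
  const int n = (int)X.n_rows;
  for (int i = 0; i < n; ++i) {
    arma::mat x = X.row(i).t();
    arma::vec p = forward(net, x, false, dummy, false);
    arma::vec dl;
    lsum += sample_loss(p, y[i], gamma, dl);
    if ((int)p.index_max() == y[i]) ++correct;
  }
  loss = lsum / n;
  acc = (double)correct / n;
}

static List export_params(const Net& net) {
  List out(net.layers.size());
  for (size_t i = 0; i < net.layers.size(); ++i) {
    const Layer& L = net.layers[i];
    if (L.kind == CONV || L.kind == DENSE)
      out[i] = List::create(Named("W") = L.W, Named("b") = L.b);
    else
      out[i] = R_NilValue;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_cnn_train(const arma::mat& X, const IntegerVector& y,
                   const arma::mat& Xval, const IntegerVector& yval,
                   const List& arch, const List& params,
                   int epochs, int batch_size, double lr,
                   std::string optimizer, double focal_gamma,
                   int seed, bool verbose) {
  Net net = build_net(arch, params);
  std::mt19937_64 rng((uint64_t)seed);
  const int n = (int)X.n_rows;
  const bool has_val = Xval.n_rows > 0;
  const bool adam = optimizer == "adam";

  std::vector<double> h_tl, h_ta, h_vl, h_va;
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  int t_adam = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(perm.begin(), perm.end(), rng);
    double ep_loss = 0;
    int ep_correct = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int stop_i = std::min(start + batch_size, n);
      const int bn = stop_i - start;
      for (auto& L : net.layers) {
        if (L.kind == CONV || L.kind == DENSE) {
          L.gW = arma::zeros(L.W.n_rows, L.W.n_cols);
          L.gb = arma::zeros(L.b.n_elem);
        }
      }
      for (int s = start; s < stop_i; ++s) {
        const int i = perm[s];
        arma::mat x = X.row(i).t();
        arma::vec p = forward(net, x, true, rng, true);
        arma::vec dlogits;
        double l = sample_loss(p, y[i], focal_gamma, dlogits);
        if (!std::isfinite(l))
          stop("non-finite loss at epoch %d; lower the learning rate", ep + 1);
        ep_loss += l;
        if ((int)p.index_max() == y[i]) ++ep_correct;
        backward(net, dlogits);
      }
      ++t_adam;
      for (auto& L : net.layers) {
        if (L.kind == CONV || L.kind == DENSE) {
          if (adam) adam_step(L, lr, 0.9, 0.999, 1e-8, t_adam, bn);
          else sgd_step(L, lr, bn);
        }
      }
    }
    h_tl.push_back(ep_loss / n);
    h_ta.push_back((double)ep_correct / n);
    if (has_val) {
      double vl, va;
      eval_set(net, Xval, yval, focal_gamma, vl, va);
      h_vl.push_back(vl);
      h_va.push_back(va);
      if (verbose)
        Rprintf("epoch %3d  loss %.4f  acc %.3f  val_loss %.4f  val_acc %.3f\n",
                ep + 1, h_tl.back(), h_ta.back(), vl, va);
    } else if (verbose) {
      Rprintf("epoch %3d  loss %.4f  acc %.3f\n", ep + 1, h_tl.back(), h_ta.back());
    }
    Rcpp::checkUserInterrupt();
  }

  List history = List::create(
    Named("train_loss") = h_tl, Named("train_acc") = h_ta,
    Named("val_loss") = h_vl, Named("val_acc") = h_va);
  return List::create(Named("params") = export_params(net),
                      Named("history") = history);
}

// [[Rcpp::export]]
arma::mat cpp_cnn_predict(const arma::mat& X, const List& arch,
                          const List& params) {
  Net net = build_net(arch, params);
  std::mt19937_64 dummy(0);
  const int n = (int)X.n_rows;
  arma::vec p0 = forward(net, arma::mat(X.row(0)).t(), false, dummy, false);
  arma::mat P(n, p0.n_elem);
  P.row(0) = p0.t();
  for (int i = 1; i < n; ++i) {
    arma::mat x = X.row(i).t();
    P.row(i) = forward(net, x, false, dummy, false).t();
  }
  return P;
}
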