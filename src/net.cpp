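// Minimal 1D-CNN training engine: valid convolution via im2col + GEMM,
// batch normalization, max/average pooling (size 2, stride 2, floor),
// inverted dropout, dense layers, softmax + categorical cross-entropy,
// bias-corrected Adam. Templated on element type: float at run time,
// double for finite-difference gradient tests.
//
// Activation layout between layers: matrix of shape (batch * length, channels)
// with rows sample-major (row = n * length + t). After flatten: (batch, units).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <cstring>

using namespace Rcpp;

enum LType { L_CONV = 0, L_BN, L_RELU, L_MAXPOOL, L_AVGPOOL,
             L_DROPOUT, L_FLATTEN, L_DENSE, L_SOFTMAX };

template <typename eT>
struct Layer {
  int type = 0;
  int kernel = 0, in_ch = 0, out_ch = 0, in_len = 0, out_len = 0;
  int in_units = 0, out_units = 0;
  double rate = 0.0;           // dropout rate
  // trainable parameters + Adam moments
  arma::Mat<eT> W, dW, mW, vW;
  arma::Col<eT> b, db, mb, vb;
  arma::Col<eT> gamma, beta, dgamma, dbeta, mg, vg, mB, vB;
  arma::Col<eT> rmean, rvar;   // BN running statistics (not trainable)
  // per-batch caches
  arma::Mat<eT> Xcol, in, out, mask, xhat;
  arma::Mat<unsigned char> umask;   // relu / maxpool selector
  arma::Col<eT> invstd;
};

struct NetBase {
  virtual ~NetBase() {}
  virtual double train_batch(const arma::mat& X, const arma::ivec& y,
                             double lr, double b1, double b2, double eps) = 0;
  virtual arma::mat predict_probs(const arma::mat& X) = 0;
  virtual double loss(const arma::mat& X, const arma::ivec& y,
                      bool training) = 0;
  virtual arma::vec gradient(const arma::mat& X, const arma::ivec& y) = 0;
  virtual arma::vec get_params() = 0;
  virtual void set_params(const arma::vec& p) = 0;
  virtual double n_params() = 0;
};

template <typename eT>
class Net : public NetBase {
public:
  std::vector< Layer<eT> > layers;
  std::mt19937_64 rng;
  long adam_t = 0;
  double bn_momentum = 0.9;
  double bn_eps = 1e-3;
  int input_len = 0;

  Net(List descr, int seed, int input_len_) : rng((unsigned long)seed) {
    input_len = input_len_;
    for (R_xlen_t i = 0; i < descr.size(); ++i) {
      List d = descr[i];
      Layer<eT> L;
      std::string ty = as<std::string>(d["type"]);
      if (ty == "conv") {
        L.type = L_CONV;
        L.kernel = as<int>(d["kernel"]); L.in_ch = as<int>(d["in_ch"]);
        L.out_ch = as<int>(d["out_ch"]); L.in_len = as<int>(d["in_len"]);
        L.out_len = as<int>(d["out_len"]);
        L.W.set_size(L.kernel * L.in_ch, L.out_ch);
        glorot(L.W, L.kernel * L.in_ch, L.kernel * L.out_ch);
        L.b.zeros(L.out_ch);
        init_adam(L);
      } else if (ty == "bn") {
        L.type = L_BN;
        L.out_ch = as<int>(d["channels"]);
        L.gamma.ones(L.out_ch); L.beta.zeros(L.out_ch);
        L.rmean.zeros(L.out_ch); L.rvar.ones(L.out_ch);
        L.dgamma.zeros(L.out_ch); L.dbeta.zeros(L.out_ch);
        L.mg.zeros(L.out_ch); L.vg.zeros(L.out_ch);
        L.mB.zeros(L.out_ch); L.vB.zeros(L.out_ch);
      } else if (ty == "relu") {
        L.type = L_RELU;
      } else if (ty == "maxpool" || ty == "avgpool") {
        L.type = (ty == "maxpool") ? L_MAXPOOL : L_AVGPOOL;
        L.in_len = as<int>(d["in_len"]); L.out_len = as<int>(d["out_len"]);
        L.out_ch = as<int>(d["channels"]);
      } else if (ty == "dropout") {
        L.type = L_DROPOUT;
        L.rate = as<double>(d["rate"]);
      } else if (ty == "flatten") {
        L.type = L_FLATTEN;
        L.in_len = as<int>(d["len"]); L.out_ch = as<int>(d["channels"]);
      } else if (ty == "dense") {
        L.type = L_DENSE;
        L.in_units = as<int>(d["in_units"]);
        L.out_units = as<int>(d["out_units"]);
        L.W.set_size(L.in_units, L.out_units);
        glorot(L.W, L.in_units, L.out_units);
        L.b.zeros(L.out_units);
        init_adam(L);
      } else if (ty == "softmax") {
        L.type = L_SOFTMAX;
      } else {
        stop("unknown layer type: " + ty);
      }
      layers.push_back(std::move(L));
    }
  }

  void glorot(arma::Mat<eT>& W, int fan_in, int fan_out) {
    double limit = std::sqrt(6.0 / (double)(fan_in + fan_out));
    std::uniform_real_distribution<double> U(-limit, limit);
    for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = (eT)U(rng);
  }

  void init_adam(Layer<eT>& L) {
    L.dW.zeros(L.W.n_rows, L.W.n_cols);
    L.mW.zeros(L.W.n_rows, L.W.n_cols);
    L.vW.zeros(L.W.n_rows, L.W.n_cols);
    L.db.zeros(L.b.n_elem); L.mb.zeros(L.b.n_elem); L.vb.zeros(L.b.n_elem);
  }

  // ---- forward -------------------------------------------------------
  arma::Mat<eT> forward(arma::Mat<eT> A, bool training) {
    for (size_t li = 0; li < layers.size(); ++li) {
      Layer<eT>& L = layers[li];
      switch (L.type) {
      case L_CONV: {
        int B = (int)(A.n_rows / L.in_len);
        L.Xcol.set_size((arma::uword)B * L.out_len,
                        (arma::uword)L.kernel * L.in_ch);
        for (int c = 0; c < L.in_ch; ++c) {
          const eT* src = A.colptr(c);
          for (int j = 0; j < L.kernel; ++j) {
            eT* dst = L.Xcol.colptr(c * L.kernel + j);
            for (int n = 0; n < B; ++n) {
              std::memcpy(dst + (size_t)n * L.out_len,
                          src + (size_t)n * L.in_len + j,
                          sizeof(eT) * L.out_len);
            }
          }
        }
        A = L.Xcol * L.W;
        A.each_row() += L.b.t();
        break;
      }
      case L_BN: {
        const double N = (double)A.n_rows;
        if (training) {
          arma::Row<eT> mu = arma::mean(A, 0);
          arma::Row<eT> va = arma::var(A, 1, 0);  // population variance
          L.invstd = arma::conv_to< arma::Col<eT> >::from(
            (eT)1 / arma::sqrt(va.t() + (eT)bn_eps));
          L.xhat = A;
          L.xhat.each_row() -= mu;
          L.xhat.each_row() %= L.invstd.t();
          A = L.xhat;
          A.each_row() %= L.gamma.t();
          A.each_row() += L.beta.t();
          L.rmean = (eT)bn_momentum * L.rmean +
                    (eT)(1 - bn_momentum) * mu.t();
          L.rvar = (eT)bn_momentum * L.rvar + (eT)(1 - bn_momentum) * va.t();
        } else {
          arma::Col<eT> istd = (eT)1 / arma::sqrt(L.rvar + (eT)bn_eps);
          A.each_row() -= L.rmean.t();
          A.each_row() %= (istd % L.gamma).t();
          A.each_row() += L.beta.t();
        }
        (void)N;
        break;
      }
      case L_RELU: {
        L.umask.set_size(A.n_rows, A.n_cols);
        eT* a = A.memptr();
        unsigned char* u = L.umask.memptr();
        const arma::uword ne = A.n_elem;
        for (arma::uword i = 0; i < ne; ++i) {
          const bool pos = a[i] > (eT)0;
          u[i] = pos;
          if (!pos) a[i] = (eT)0;
        }
        break;
      }
      case L_MAXPOOL:
      case L_AVGPOOL: {
        int B = (int)(A.n_rows / L.in_len);
        arma::Mat<eT> O((arma::uword)B * L.out_len, A.n_cols);
        if (L.type == L_MAXPOOL) {
          L.umask.set_size(O.n_rows, O.n_cols);
          for (arma::uword c = 0; c < A.n_cols; ++c) {
            const eT* a = A.colptr(c);
            eT* o = O.colptr(c);
            unsigned char* u = L.umask.colptr(c);
            for (int n = 0; n < B; ++n) {
              const eT* an = a + (size_t)n * L.in_len;
              eT* on = o + (size_t)n * L.out_len;
              unsigned char* un = u + (size_t)n * L.out_len;
              for (int t = 0; t < L.out_len; ++t) {
                const eT v1 = an[2 * t], v2 = an[2 * t + 1];
                const bool first = v1 >= v2;
                un[t] = first;
                on[t] = first ? v1 : v2;
              }
            }
          }
        } else {
          for (arma::uword c = 0; c < A.n_cols; ++c) {
            const eT* a = A.colptr(c);
            eT* o = O.colptr(c);
            for (int n = 0; n < B; ++n) {
              const eT* an = a + (size_t)n * L.in_len;
              eT* on = o + (size_t)n * L.out_len;
              for (int t = 0; t < L.out_len; ++t) {
                on[t] = (eT)0.5 * (an[2 * t] + an[2 * t + 1]);
              }
            }
          }
        }
        A = std::move(O);
        break;
      }
      case L_DROPOUT: {
        if (training && L.rate > 0) {
          const double keep = 1.0 - L.rate;
          std::uniform_real_distribution<double> U(0.0, 1.0);
          L.mask.set_size(A.n_rows, A.n_cols);
          for (arma::uword i = 0; i < L.mask.n_elem; ++i) {
            L.mask(i) = (U(rng) < keep) ? (eT)(1.0 / keep) : (eT)0;
          }
          A %= L.mask;
        } else {
          L.mask.reset();
        }
        break;
      }
      case L_FLATTEN: {
        int B = (int)(A.n_rows / L.in_len);
        arma::Mat<eT> F((arma::uword)B, (arma::uword)L.in_len * L.out_ch);
        for (int c = 0; c < L.out_ch; ++c) {
          arma::Mat<eT> M(A.colptr(c), L.in_len, B, false, true);
          F.cols((arma::uword)c * L.in_len,
                 (arma::uword)(c + 1) * L.in_len - 1) = M.t();
        }
        A = F;
        break;
      }
      case L_DENSE: {
        L.in = A;
        A = A * L.W;
        A.each_row() += L.b.t();
        break;
      }
      case L_SOFTMAX: {
        arma::Col<eT> mx = arma::max(A, 1);
        A.each_col() -= mx;
        A = arma::exp(A);
        arma::Col<eT> s = arma::sum(A, 1);
        A.each_col() /= s;
        L.out = A;
        break;
      }
      }
    }
    return A;
  }

  // ---- backward ------------------------------------------------------
  // G on entry: gradient of the loss w.r.t. the softmax pre-activation
  // (softmax + cross-entropy combined), shape (batch, n_classes).
  void backward(arma::Mat<eT> G) {
    for (int li = (int)layers.size() - 1; li >= 0; --li) {
      Layer<eT>& L = layers[li];
      switch (L.type) {
      case L_SOFTMAX:
        break;  // folded into the initial G
      case L_DENSE: {
        L.dW = L.in.t() * G;
        L.db = arma::sum(G, 0).t();
        G = G * L.W.t();
        break;
      }
      case L_FLATTEN: {
        int B = (int)G.n_rows;
        arma::Mat<eT> A((arma::uword)B * L.in_len, (arma::uword)L.out_ch);
        for (int c = 0; c < L.out_ch; ++c) {
          arma::Mat<eT> M = G.cols((arma::uword)c * L.in_len,
                                   (arma::uword)(c + 1) * L.in_len - 1).t();
          std::memcpy(A.colptr(c), M.memptr(),
                      sizeof(eT) * (size_t)L.in_len * B);
        }
        G = A;
        break;
      }
      case L_DROPOUT: {
        if (L.mask.n_elem > 0) G %= L.mask;
        break;
      }
      case L_MAXPOOL:
      case L_AVGPOOL: {
        int B = (int)(G.n_rows / L.out_len);
        arma::Mat<eT> A((arma::uword)B * L.in_len, G.n_cols,
                        arma::fill::zeros);
        for (arma::uword c = 0; c < G.n_cols; ++c) {
          const eT* g = G.colptr(c);
          eT* a = A.colptr(c);
          if (L.type == L_MAXPOOL) {
            const unsigned char* m = L.umask.colptr(c);
            for (int n = 0; n < B; ++n) {
              for (int t = 0; t < L.out_len; ++t) {
                size_t r = (size_t)n * L.out_len + t;
                size_t s = (size_t)n * L.in_len + 2 * t;
                a[s + !m[r]] = g[r];
              }
            }
          } else {
            for (int n = 0; n < B; ++n) {
              for (int t = 0; t < L.out_len; ++t) {
                size_t r = (size_t)n * L.out_len + t;
                size_t s = (size_t)n * L.in_len + 2 * t;
                a[s] = (eT)0.5 * g[r];
                a[s + 1] = (eT)0.5 * g[r];
              }
            }
          }
        }
        G = std::move(A);
        break;
      }
      case L_RELU: {
        eT* g = G.memptr();
        const unsigned char* u = L.umask.memptr();
        const arma::uword ne = G.n_elem;
        for (arma::uword i = 0; i < ne; ++i) {
          if (!u[i]) g[i] = (eT)0;
        }
        break;
      }
      case L_BN: {
        const eT N = (eT)G.n_rows;
        L.dbeta = arma::sum(G, 0).t();
        L.dgamma = arma::sum(G % L.xhat, 0).t();
        // dX = gamma*invstd/N * (N*G - dbeta - xhat*dgamma), per channel
        arma::Mat<eT> A = N * G;
        A.each_row() -= L.dbeta.t();
        arma::Mat<eT> T2 = L.xhat;
        T2.each_row() %= L.dgamma.t();
        A -= T2;
        A.each_row() %= ((L.gamma % L.invstd) / N).t();
        G = A;
        break;
      }
      case L_CONV: {
        // G: (batch*out_len, out_ch)
        L.dW = L.Xcol.t() * G;
        L.db = arma::sum(G, 0).t();
        arma::Mat<eT> dXcol = G * L.W.t();  // (batch*out_len, kernel*in_ch)
        int B = (int)(G.n_rows / L.out_len);
        arma::Mat<eT> A((arma::uword)B * L.in_len, (arma::uword)L.in_ch,
                        arma::fill::zeros);
        for (int c = 0; c < L.in_ch; ++c) {
          eT* a = A.colptr(c);
          for (int j = 0; j < L.kernel; ++j) {
            const eT* d = dXcol.colptr(c * L.kernel + j);
            for (int n = 0; n < B; ++n) {
              eT* ap = a + (size_t)n * L.in_len + j;
              const eT* dp = d + (size_t)n * L.out_len;
              for (int t = 0; t < L.out_len; ++t) ap[t] += dp[t];
            }
          }
        }
        G = A;
        break;
      }
      }
    }
  }

  // convert an R (batch x input_len) matrix into the internal layout
  arma::Mat<eT> to_activation(const arma::mat& X) {
    int B = (int)X.n_rows;
    arma::Mat<eT> A((arma::uword)B * input_len, 1);
    for (int n = 0; n < B; ++n) {
      for (int t = 0; t < input_len; ++t) {
        A((arma::uword)n * input_len + t, 0) = (eT)X(n, t);
      }
    }
    return A;
  }

  // mean cross-entropy of probability rows P against integer labels
  double ce_loss(const arma::Mat<eT>& P, const arma::ivec& y) {
    double s = 0;
    for (arma::uword n = 0; n < P.n_rows; ++n) {
      double p = (double)P(n, (arma::uword)y[n]);
      s -= std::log(std::max(p, 1e-12));
    }
    return s / (double)P.n_rows;
  }

  double train_batch(const arma::mat& X, const arma::ivec& y, double lr,
                     double b1, double b2, double eps) override {
    arma::Mat<eT> P = forward(to_activation(X), true);
    double loss = ce_loss(P, y);
    arma::Mat<eT> G = P;
    for (arma::uword n = 0; n < G.n_rows; ++n) {
      G(n, (arma::uword)y[n]) -= (eT)1;
    }
    G /= (eT)G.n_rows;
    backward(G);
    adam_step(lr, b1, b2, eps);
    return loss;
  }

  void adam_one(arma::Mat<eT>& W, arma::Mat<eT>& g, arma::Mat<eT>& m,
                arma::Mat<eT>& v, double lr, double b1, double b2,
                double eps, double c1, double c2) {
    m = (eT)b1 * m + (eT)(1 - b1) * g;
    v = (eT)b2 * v + (eT)(1 - b2) * (g % g);
    W -= (eT)lr * (m / (eT)c1) / (arma::sqrt(v / (eT)c2) + (eT)eps);
  }
  void adam_one(arma::Col<eT>& W, arma::Col<eT>& g, arma::Col<eT>& m,
                arma::Col<eT>& v, double lr, double b1, double b2,
                double eps, double c1, double c2) {
    m = (eT)b1 * m + (eT)(1 - b1) * g;
    v = (eT)b2 * v + (eT)(1 - b2) * (g % g);
    W -= (eT)lr * (m / (eT)c1) / (arma::sqrt(v / (eT)c2) + (eT)eps);
  }

  void adam_step(double lr, double b1, double b2, double eps) {
    ++adam_t;
    double c1 = 1 - std::pow(b1, (double)adam_t);
    double c2 = 1 - std::pow(b2, (double)adam_t);
    for (size_t i = 0; i < layers.size(); ++i) {
      Layer<eT>& L = layers[i];
      if (L.type == L_CONV || L.type == L_DENSE) {
        adam_one(L.W, L.dW, L.mW, L.vW, lr, b1, b2, eps, c1, c2);
        adam_one(L.b, L.db, L.mb, L.vb, lr, b1, b2, eps, c1, c2);
      } else if (L.type == L_BN) {
        adam_one(L.gamma, L.dgamma, L.mg, L.vg, lr, b1, b2, eps, c1, c2);
        adam_one(L.beta, L.dbeta, L.mB, L.vB, lr, b1, b2, eps, c1, c2);
      }
    }
  }

  arma::mat predict_probs(const arma::mat& X) override {
    arma::Mat<eT> P = forward(to_activation(X), false);
    return arma::conv_to<arma::mat>::from(P);
  }

  double loss(const arma::mat& X, const arma::ivec& y,
              bool training) override {
    arma::Mat<eT> P = forward(to_activation(X), training);
    return ce_loss(P, y);
  }

  arma::vec gradient(const arma::mat& X, const arma::ivec& y) override {
    arma::Mat<eT> P = forward(to_activation(X), true);
    arma::Mat<eT> G = P;
    for (arma::uword n = 0; n < G.n_rows; ++n) {
      G(n, (arma::uword)y[n]) -= (eT)1;
    }
    G /= (eT)G.n_rows;
    backward(G);
    std::vector<double> out;
    for (size_t i = 0; i < layers.size(); ++i) {
      Layer<eT>& L = layers[i];
      if (L.type == L_CONV || L.type == L_DENSE) {
        for (arma::uword k = 0; k < L.dW.n_elem; ++k)
          out.push_back((double)L.dW(k));
        for (arma::uword k = 0; k < L.db.n_elem; ++k)
          out.push_back((double)L.db(k));
      } else if (L.type == L_BN) {
        for (arma::uword k = 0; k < L.dgamma.n_elem; ++k)
          out.push_back((double)L.dgamma(k));
        for (arma::uword k = 0; k < L.dbeta.n_elem; ++k)
          out.push_back((double)L.dbeta(k));
      }
    }
    return arma::vec(out);
  }

  arma::vec get_params() override {
    std::vector<double> out;
    for (size_t i = 0; i < layers.size(); ++i) {
      Layer<eT>& L = layers[i];
      if (L.type == L_CONV || L.type == L_DENSE) {
        for (arma::uword k = 0; k < L.W.n_elem; ++k)
          out.push_back((double)L.W(k));
        for (arma::uword k = 0; k < L.b.n_elem; ++k)
          out.push_back((double)L.b(k));
      } else if (L.type == L_BN) {
        for (arma::uword k = 0; k < L.gamma.n_elem; ++k)
          out.push_back((double)L.gamma(k));
        for (arma::uword k = 0; k < L.beta.n_elem; ++k)
          out.push_back((double)L.beta(k));
      }
    }
    return arma::vec(out);
  }

  void set_params(const arma::vec& p) override {
    arma::uword off = 0;
    for (size_t i = 0; i < layers.size(); ++i) {
      Layer<eT>& L = layers[i];
      if (L.type == L_CONV || L.type == L_DENSE) {
        for (arma::uword k = 0; k < L.W.n_elem; ++k) L.W(k) = (eT)p(off++);
        for (arma::uword k = 0; k < L.b.n_elem; ++k) L.b(k) = (eT)p(off++);
      } else if (L.type == L_BN) {
        for (arma::uword k = 0; k < L.gamma.n_elem; ++k)
          L.gamma(k) = (eT)p(off++);
        for (arma::uword k = 0; k < L.beta.n_elem; ++k)
          L.beta(k) = (eT)p(off++);
      }
    }
    if (off != p.n_elem) stop("parameter vector length mismatch");
  }

  double n_params() override {
    double n = 0;
    for (size_t i = 0; i < layers.size(); ++i) {
      Layer<eT>& L = layers[i];
      if (L.type == L_CONV || L.type == L_DENSE) {
        n += (double)(L.W.n_elem + L.b.n_elem);
      } else if (L.type == L_BN) {
        n += (double)(L.gamma.n_elem + L.beta.n_elem);
      }
    }
    return n;
  }
};

// ---- R interface ------------------------------------------------------

// [[Rcpp::export]]
SEXP net_create(List layers, int seed, int input_len, bool double_precision) {
  NetBase* net;
  if (double_precision) {
    net = new Net<double>(layers, seed, input_len);
  } else {
    net = new Net<float>(layers, seed, input_len);
  }
  XPtr<NetBase> ptr(net, true);
  return ptr;
}

static NetBase* get_net(SEXP h) {
  XPtr<NetBase> ptr(h);
  if (!ptr) stop("invalid network handle");
  return ptr.get();
}

// [[Rcpp::export]]
double net_train_batch(SEXP h, const arma::mat& X, const arma::ivec& y,
                       double lr, double beta1, double beta2, double eps) {
  return get_net(h)->train_batch(X, y, lr, beta1, beta2, eps);
}

// [[Rcpp::export]]
arma::mat net_predict(SEXP h, const arma::mat& X) {
  return get_net(h)->predict_probs(X);
}

// [[Rcpp::export]]
double net_loss(SEXP h, const arma::mat& X, const arma::ivec& y,
                bool training) {
  return get_net(h)->loss(X, y, training);
}

// [[Rcpp::export]]
arma::vec net_gradient(SEXP h, const arma::mat& X, const arma::ivec& y) {
  return get_net(h)->gradient(X, y);
}

// [[Rcpp::export]]
arma::vec net_get_params(SEXP h) {
  return get_net(h)->get_params();
}

// [[Rcpp::export]]
void net_set_params(SEXP h, const arma::vec& p) {
  get_net(h)->set_params(p);
}

// [[Rcpp::export]]
double net_n_params(SEXP h) {
  return get_net(h)->n_params();
}
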