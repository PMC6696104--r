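// Production network engine: 1-D convolution via im2col + BLAS, max-pool
// 2/2, flatten, inverted dropout, dense layers, softmax cross-entropy and
// Adam, computed in single precision.  All randomness (weight
// initialization, epoch shuffles, dropout masks) is drawn from R's RNG, so
// set.seed() on the R side makes a whole training run reproducible.  A
// slower pure-R reference implementation of the same forward/backward pass
// lives in R/nn.R and is compared against this engine in the test suite.

#include <RcppArmadillo.h>
#ifdef __SSE2__
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {
// Adam's second-moment accumulators decay toward the denormalized float
// range as training converges; denormal arithmetic is pathologically slow
// on x86, so flush denormals to zero for the duration of a call.
struct DenormalGuard {
#ifdef __SSE2__
  unsigned int saved;
  DenormalGuard() : saved(_mm_getcsr()) {
    _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
    _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
  }
  ~DenormalGuard() { _mm_setcsr(saved); }
#endif
};
}  // namespace

namespace {

struct Layer {
  bool is_conv;
  int KS;        // kernel size (conv only)
  int in_dim;    // conv: KS * C_in; dense: input width
  int out_dim;   // conv: kernel count; dense: neuron count
  bool relu;
  bool flatten;  // dense only: input arrives stacked and is flattened here
  arma::fmat W;
  arma::fvec b;
  arma::fmat mW, vW;  // Adam state
  arma::fvec mb, vb;
};

struct Net {
  std::vector<Layer> layers;
  int input_len;
  int n_classes;
  float keep;
};

// Per-layer caches for one batch.
struct Cache {
  arma::fmat Xcol;      // conv: im2col matrix
  arma::fmat Z;         // pre-activation
  arma::Mat<unsigned char> take_a;  // pool: argmax flag (first of pair)
  arma::fmat Ain;       // dense: layer input (after dropout)
  arma::fmat mask;      // dense: dropout mask (empty if none)
  int L = 0, Lo = 0, C = 0;  // conv: lengths/channels at this layer
  int flatL = 0, flatC = 0;  // dense+flatten: stacked dims before flatten
};

Net build_net(const List& arch, int input_len, int n_classes, double keep,
              bool init) {
  Net net;
  net.input_len = input_len;
  net.n_classes = n_classes;
  net.keep = static_cast<float>(keep);
  int n = arch.size();
  net.layers.resize(n);
  for (int i = 0; i < n; ++i) {
    List ly = arch[i];
    Layer& L = net.layers[i];
    std::string type = as<std::string>(ly["type"]);
    L.is_conv = (type == "conv");
    L.KS = L.is_conv ? as<int>(ly["KS"]) : 0;
    L.in_dim = as<int>(ly["in_dim"]);
    L.out_dim = as<int>(ly["out_dim"]);
    std::string act = as<std::string>(ly["act"]);
    L.relu = (act == "relu");
    L.flatten = !L.is_conv && as<bool>(ly["flatten"]);
    if (init) {
      // He-normal, drawn column-major from R's RNG.
      L.W.set_size(L.in_dim, L.out_dim);
      double s = std::sqrt(2.0 / L.in_dim);
      for (arma::uword k = 0; k < L.W.n_elem; ++k)
        L.W[k] = static_cast<float>(norm_rand() * s);
      L.b.zeros(L.out_dim);
      L.mW.zeros(L.in_dim, L.out_dim);
      L.vW.zeros(L.in_dim, L.out_dim);
      L.mb.zeros(L.out_dim);
      L.vb.zeros(L.out_dim);
    }
  }
  return net;
}

void load_weights(Net& net, const List& weights) {
  for (size_t i = 0; i < net.layers.size(); ++i) {
    List w = weights[i];
    net.layers[i].W =
        arma::conv_to<arma::fmat>::from(as<arma::mat>(w["W"]));
    net.layers[i].b =
        arma::conv_to<arma::fvec>::from(as<arma::vec>(w["b"]));
  }
}

// Rows of the stacked representation: sample b occupies rows
// [b*L, (b+1)*L); row b*L + l is position l.
inline void im2col(const arma::fmat& A, arma::fmat& Xcol, int B, int L,
                   int KS, int C) {
  int pad = (KS - 1) / 2;
  Xcol.zeros(static_cast<arma::uword>(B) * L,
             static_cast<arma::uword>(KS) * C);
  for (int k = 0; k < KS; ++k) {
    int off = k - pad;
    int lo = std::max(0, -off);        // first output pos with valid source
    int hi = std::min(L, L - off) - 1; // last output pos
    if (hi < lo) continue;
    for (int b = 0; b < B; ++b) {
      Xcol.submat(b * L + lo, k * C, b * L + hi, (k + 1) * C - 1) =
          A.submat(b * L + lo + off, 0, b * L + hi + off, C - 1);
    }
  }
}

inline void col2im(const arma::fmat& dXcol, arma::fmat& dA, int B, int L,
                   int KS, int C) {
  int pad = (KS - 1) / 2;
  dA.zeros(static_cast<arma::uword>(B) * L, C);
  for (int k = 0; k < KS; ++k) {
    int off = k - pad;
    int lo = std::max(0, -off);
    int hi = std::min(L, L - off) - 1;
    if (hi < lo) continue;
    for (int b = 0; b < B; ++b) {
      dA.submat(b * L + lo + off, 0, b * L + hi + off, C - 1) +=
          dXcol.submat(b * L + lo, k * C, b * L + hi, (k + 1) * C - 1);
    }
  }
}

// Forward pass; fills caches when train = true.  X is B x input_len.
// Returns the B x n_classes probability matrix.
arma::fmat forward(Net& net, const arma::fmat& X, bool train,
                   std::vector<Cache>* caches) {
  int B = X.n_rows;
  int L = net.input_len;
  int C = 1;
  bool stacked = net.layers[0].is_conv;
  arma::fmat A;
  if (stacked) {
    A.set_size(static_cast<arma::uword>(B) * L, 1);
    for (int b = 0; b < B; ++b)
      for (int l = 0; l < L; ++l) A(b * L + l, 0) = X(b, l);
  } else {
    A = X;
  }
  for (size_t i = 0; i < net.layers.size(); ++i) {
    Layer& ly = net.layers[i];
    Cache* ch = caches ? &(*caches)[i] : nullptr;
    if (ly.is_conv) {
      arma::fmat Xcol;
      im2col(A, Xcol, B, L, ly.KS, C);
      arma::fmat Z = Xcol * ly.W;
      Z.each_row() += ly.b.t();
      arma::fmat R = arma::max(Z, arma::fmat(arma::size(Z), arma::fill::zeros));
      int Lo = L / 2;
      arma::fmat P(static_cast<arma::uword>(B) * Lo, ly.out_dim);
      arma::Mat<unsigned char> take(P.n_rows, P.n_cols);
      for (int b = 0; b < B; ++b) {
        for (int l = 0; l < Lo; ++l) {
          int ra = b * L + 2 * l, rp = b * Lo + l;
          for (int c = 0; c < ly.out_dim; ++c) {
            float xa = R(ra, c), xb = R(ra + 1, c);
            bool ta = xa >= xb;  // ties keep the earlier position
            take(rp, c) = ta;
            P(rp, c) = ta ? xa : xb;
          }
        }
      }
      if (ch) {
        ch->Xcol = std::move(Xcol);
        ch->Z = std::move(Z);
        ch->take_a = std::move(take);
        ch->L = L; ch->Lo = Lo; ch->C = C;
      }
      A = std::move(P);
      L = Lo;
      C = ly.out_dim;
    } else {
      if (ly.flatten && stacked) {
        // F(b, c*L + l) = A(b*L + l, c)
        arma::fmat F(B, static_cast<arma::uword>(L) * C);
        for (int b = 0; b < B; ++b)
          for (int c = 0; c < C; ++c)
            for (int l = 0; l < L; ++l)
              F(b, c * L + l) = A(b * L + l, c);
        if (ch) { ch->flatL = L; ch->flatC = C; }
        A = std::move(F);
        stacked = false;
        if (train && net.keep < 1.0f) {
          arma::fmat mask(A.n_rows, A.n_cols);
          float inv = 1.0f / net.keep;
          for (arma::uword k = 0; k < mask.n_elem; ++k)
            mask[k] = (unif_rand() < net.keep) ? inv : 0.0f;
          A %= mask;
          if (ch) ch->mask = std::move(mask);
        }
      }
      if (ch) ch->Ain = A;
      arma::fmat Z = A * ly.W;
      Z.each_row() += ly.b.t();
      if (ly.relu) {
        A = arma::max(Z, arma::fmat(arma::size(Z), arma::fill::zeros));
      } else {
        A = Z;
      }
      if (ch) ch->Z = std::move(Z);
    }
  }
  // row-wise softmax
  for (int b = 0; b < B; ++b) {
    float mx = A.row(b).max();
    double s = 0;
    for (int c = 0; c < net.n_classes; ++c) {
      A(b, c) = std::exp(A(b, c) - mx);
      s += A(b, c);
    }
    A.row(b) /= static_cast<float>(s);
  }
  return A;
}

// One-pass fused Adam update (no temporaries).
inline void adam_update(float* p, float* m, float* v, const float* g,
                        size_t n, float alpha, float beta1, float beta2,
                        float eps) {
  for (size_t k = 0; k < n; ++k) {
    m[k] = beta1 * m[k] + (1.0f - beta1) * g[k];
    v[k] = beta2 * v[k] + (1.0f - beta2) * g[k] * g[k];
    p[k] -= alpha * m[k] / (std::sqrt(v[k]) + eps);
  }
}

// Backward pass + Adam step.  Returns the batch cross-entropy loss and the
// number of correct argmax predictions via out-params.
void backward_update(Net& net, std::vector<Cache>& caches,
                     const arma::fmat& probs, const arma::ivec& y,
                     float lr, int step, double* loss_out,
                     int* correct_out) {
  int B = probs.n_rows;
  const float beta1 = 0.9f, beta2 = 0.999f, eps = 1e-8f;
  float bc1 = 1.0f - std::pow(beta1, static_cast<float>(step));
  float bc2 = 1.0f - std::pow(beta2, static_cast<float>(step));
  // effective step size with bias correction folded in
  float alpha = lr * std::sqrt(bc2) / bc1;
  // folding sqrt(bc2) into eps keeps the update exactly equivalent to the
  // textbook form: m_hat/(sqrt(v_hat)+eps) = sqrt(bc2)/bc1 * m/(sqrt(v)+sqrt(bc2)*eps)
  float eps_eff = eps * std::sqrt(bc2);

  double loss = 0;
  int correct = 0;
  arma::fmat dA = probs;
  for (int b = 0; b < B; ++b) {
    int cls = y[b] - 1;
    loss -= std::log(std::max(1e-12, static_cast<double>(probs(b, cls))));
    if (probs.row(b).index_max() == static_cast<arma::uword>(cls)) ++correct;
    dA(b, cls) -= 1.0f;
  }
  dA /= static_cast<float>(B);
  *loss_out = loss / B;
  *correct_out = correct;

  for (int i = static_cast<int>(net.layers.size()) - 1; i >= 0; --i) {
    Layer& ly = net.layers[i];
    Cache& ch = caches[i];
    if (!ly.is_conv) {
      arma::fmat dZ = dA;
      if (ly.relu) dZ.elem(arma::find(ch.Z <= 0)).zeros();
      arma::fmat dW = ch.Ain.t() * dZ;
      arma::fvec db = arma::sum(dZ, 0).t();
      dA = dZ * ly.W.t();
      adam_update(ly.W.memptr(), ly.mW.memptr(), ly.vW.memptr(),
                  dW.memptr(), dW.n_elem, alpha, beta1, beta2, eps_eff);
      adam_update(ly.b.memptr(), ly.mb.memptr(), ly.vb.memptr(),
                  db.memptr(), db.n_elem, alpha, beta1, beta2, eps_eff);
      if (ch.mask.n_elem > 0) dA %= ch.mask;
      if (ly.flatten && ch.flatL > 0) {
        // invert the flatten: dS(b*L + l, c) = dA(b, c*L + l)
        int L = ch.flatL, C = ch.flatC;
        arma::fmat dS(static_cast<arma::uword>(B) * L, C);
        for (int b = 0; b < B; ++b)
          for (int c = 0; c < C; ++c)
            for (int l = 0; l < L; ++l)
              dS(b * L + l, c) = dA(b, c * L + l);
        dA = std::move(dS);
      }
    } else {
      // un-pool
      arma::fmat dR(static_cast<arma::uword>(B) * ch.L, ly.out_dim,
                    arma::fill::zeros);
      for (int b = 0; b < B; ++b)
        for (int l = 0; l < ch.Lo; ++l) {
          int ra = b * ch.L + 2 * l, rp = b * ch.Lo + l;
          for (int c = 0; c < ly.out_dim; ++c) {
            float g = dA(rp, c);
            if (ch.take_a(rp, c)) dR(ra, c) = g; else dR(ra + 1, c) = g;
          }
        }
      dR.elem(arma::find(ch.Z <= 0)).zeros();  // ReLU backward
      arma::fmat dW = ch.Xcol.t() * dR;
      arma::fvec db = arma::sum(dR, 0).t();
      arma::fmat dXcol = dR * ly.W.t();
      adam_update(ly.W.memptr(), ly.mW.memptr(), ly.vW.memptr(),
                  dW.memptr(), dW.n_elem, alpha, beta1, beta2, eps_eff);
      adam_update(ly.b.memptr(), ly.mb.memptr(), ly.vb.memptr(),
                  db.memptr(), db.n_elem, alpha, beta1, beta2, eps_eff);
      if (i > 0) col2im(dXcol, dA, B, ch.L, ly.KS, ch.C);
    }
  }
}

arma::fmat predict_probs(Net& net, const arma::fmat& X, int chunk) {
  int n = X.n_rows;
  arma::fmat out(n, net.n_classes);
  for (int s = 0; s < n; s += chunk) {
    int e = std::min(n, s + chunk) - 1;
    out.rows(s, e) = forward(net, X.rows(s, e), false, nullptr);
  }
  return out;
}

List export_weights(const Net& net) {
  List out(net.layers.size());
  for (size_t i = 0; i < net.layers.size(); ++i) {
    out[i] = List::create(
        Named("W") = arma::conv_to<arma::mat>::from(net.layers[i].W),
        Named("b") = arma::conv_to<arma::vec>::from(net.layers[i].b));
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
List engine_train(List arch, arma::mat X, IntegerVector y,
                  Nullable<NumericMatrix> Xval_, Nullable<IntegerVector> yval_,
                  int epochs, int batch_size, double lr, double keep,
                  int input_len, int n_classes) {
  RNGScope rng;
  DenormalGuard ftz;
  Net net = build_net(arch, input_len, n_classes, keep, true);
  arma::fmat Xf = arma::conv_to<arma::fmat>::from(X);
  arma::ivec yy(y.size());
  for (int i = 0; i < y.size(); ++i) yy[i] = y[i];
  bool has_val = Xval_.isNotNull();
  arma::fmat Xv;
  arma::ivec yv;
  if (has_val) {
    Xv = arma::conv_to<arma::fmat>::from(as<arma::mat>(Xval_.get()));
    IntegerVector yvi(yval_.get());
    yv.set_size(yvi.size());
    for (int i = 0; i < yvi.size(); ++i) yv[i] = yvi[i];
  }
  int n = Xf.n_rows;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::vector<Cache> caches(net.layers.size());
  NumericVector h_tl(epochs), h_ta(epochs), h_vl(epochs), h_va(epochs);
  int step = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates with R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    double ep_loss = 0;
    int ep_correct = 0;
    for (int s = 0; s < n; s += batch_size) {
      int bsz = std::min(batch_size, n - s);
      arma::fmat Xb(bsz, Xf.n_cols);
      arma::ivec yb(bsz);
      for (int b = 0; b < bsz; ++b) {
        Xb.row(b) = Xf.row(ord[s + b]);
        yb[b] = yy[ord[s + b]];
      }
      arma::fmat probs = forward(net, Xb, true, &caches);
      double loss;
      int correct;
      backward_update(net, caches, probs, yb, static_cast<float>(lr),
                      ++step, &loss, &correct);
      ep_loss += loss * bsz;
      ep_correct += correct;
    }
    h_tl[ep] = ep_loss / n;
    h_ta[ep] = static_cast<double>(ep_correct) / n;
    if (has_val) {
      arma::fmat Pv = predict_probs(net, Xv, 64);
      double vl = 0;
      int vc = 0;
      for (arma::uword b = 0; b < Pv.n_rows; ++b) {
        int cls = yv[b] - 1;
        vl -= std::log(std::max(1e-12, static_cast<double>(Pv(b, cls))));
        if (Pv.row(b).index_max() == static_cast<arma::uword>(cls)) ++vc;
      }
      h_vl[ep] = vl / Pv.n_rows;
      h_va[ep] = static_cast<double>(vc) / Pv.n_rows;
    } else {
      h_vl[ep] = NA_REAL;
      h_va[ep] = NA_REAL;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(
      Named("weights") = export_weights(net),
      Named("train_loss") = h_tl, Named("train_acc") = h_ta,
      Named("val_loss") = h_vl, Named("val_acc") = h_va);
}

// [[Rcpp::export]]
arma::mat engine_predict(List arch, List weights, arma::mat X,
                         int input_len, int n_classes, int chunk = 64) {
  DenormalGuard ftz;
  Net net = build_net(arch, input_len, n_classes, 1.0, false);
  load_weights(net, weights);
  arma::fmat Xf = arma::conv_to<arma::fmat>::from(X);
  return arma::conv_to<arma::mat>::from(predict_probs(net, Xf, chunk));
}
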