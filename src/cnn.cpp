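// Small dense CNN engine for EEG fingerprinting.
//
// Layout conventions (column-major throughout, matching R arrays):
//  - a batch arrives as an eta x T x C x B array: height = eta (window
//    index), width = T (time), C input channels, B samples;
//  - conv layers use odd kernels with "same" zero padding and stride 1,
//    implemented as im2col + GEMM. The patch matrix is kept transposed
//    (pixels x patch) so that both the im2col writes and the pooling reads
//    run down contiguous columns;
//  - max pooling is p x p with stride p, floor semantics;
//  - the flattened output of the last conv/pool block is the fingerprint.
//
// Weights are an R list: Wc1, bc1, ..., Wck, bck, W1, b1, W2, b2 where
// Wc_b is (F_b x Cin*kh*kw), W1 is (hidden x m), W2 is (n_classes x hidden).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct LayerCache {
  arma::mat colT;  // (H*W*B) x K
  arma::mat actT;  // (H*W*B) x F, post-ReLU
  arma::umat amax; // (Hp*Wp*B) x F, argmax row index into actT
  int H, W, Hp, Wp, F, K;
};

// write one sample's patches into rows [row0, row0 + H*W) of colT
void im2col_same(const arma::cube& x, int kh, int kw, arma::mat& colT,
                 arma::uword row0) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ph = kh / 2, pw = kw / 2;
  for (int c = 0; c < C; ++c) {
    const arma::mat& sl = x.slice(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int q = ki + kh * kj + kh * kw * c;
        double* dst = colT.colptr(q) + row0;
        for (int j = 0; j < W; ++j) {
          const int jj = j + kj - pw;
          double* dj = dst + (arma::uword)H * j;
          if (jj < 0 || jj >= W) {
            std::memset(dj, 0, sizeof(double) * H);
            continue;
          }
          const double* src = sl.colptr(jj);
          const int lo = std::max(0, ph - ki);           // i range with
          const int hi = std::min(H, H + ph - ki);       // 0 <= i+ki-ph < H
          for (int i = 0; i < lo; ++i) dj[i] = 0.0;
          for (int i = lo; i < hi; ++i) dj[i] = src[i + ki - ph];
          for (int i = hi; i < H; ++i) dj[i] = 0.0;
        }
      }
    }
  }
}

// accumulate rows [row0, row0 + H*W) of dcolT back into a sample gradient
void col2im_same(const arma::mat& dcolT, int H, int W, int C, int kh, int kw,
                 arma::cube& dx, arma::uword row0) {
  const int ph = kh / 2, pw = kw / 2;
  dx.zeros();
  for (int c = 0; c < C; ++c) {
    arma::mat& sl = dx.slice(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int q = ki + kh * kj + kh * kw * c;
        const double* src0 = dcolT.colptr(q) + row0;
        for (int j = 0; j < W; ++j) {
          const int jj = j + kj - pw;
          if (jj < 0 || jj >= W) continue;
          double* dst = sl.colptr(jj);
          const double* src = src0 + (arma::uword)H * j;
          const int lo = std::max(0, ph - ki);
          const int hi = std::min(H, H + ph - ki);
          for (int i = lo; i < hi; ++i) dst[i + ki - ph] += src[i];
        }
      }
    }
  }
}

// Forward through all conv blocks; fills caches when given. Returns
// flattened features (m x B).
arma::mat conv_forward(const List& weights, const arma::vec& x,
                       const IntegerVector& dims, int n_blocks, int kh,
                       int kw, int pool, std::vector<LayerCache>* caches) {
  const int eta = dims[0], T = dims[1], C0 = dims[2], B = dims[3];
  int H = eta, W = T, Cin = C0;

  std::vector<arma::cube> X(B);
  for (int b = 0; b < B; ++b) {
    X[b] = arma::cube(x.memptr() + (arma::uword)b * eta * T * C0, eta, T, C0);
  }

  for (int blk = 0; blk < n_blocks; ++blk) {
    const arma::mat Wc = as<arma::mat>(weights[2 * blk]);
    const arma::rowvec bc = as<arma::rowvec>(weights[2 * blk + 1]);
    const int F = Wc.n_rows;
    const int K = Cin * kh * kw;
    if ((int)Wc.n_cols != K) stop("conv weight shape mismatch");
    const int HW = H * W;

    arma::mat colT((arma::uword)HW * B, K);
    for (int b = 0; b < B; ++b)
      im2col_same(X[b], kh, kw, colT, (arma::uword)b * HW);

    arma::mat ZT = colT * Wc.t();      // HW*B x F
    ZT.each_row() += bc;
    ZT.transform([](double v) { return v > 0.0 ? v : 0.0; });

    const int Hp = H / pool, Wp = W / pool;
    if (Hp < 1 || Wp < 1) stop("configuration error: pooled plane vanished");
    arma::umat amax((arma::uword)Hp * Wp * B, F);
    std::vector<arma::cube> Xn(B);
    for (int b = 0; b < B; ++b) Xn[b].set_size(Hp, Wp, F);
    for (int f = 0; f < F; ++f) {
      const double* z = ZT.colptr(f);
      arma::uword* am = amax.colptr(f);
      for (int b = 0; b < B; ++b) {
        const arma::uword base = (arma::uword)b * HW;
        const arma::uword obase = (arma::uword)b * Hp * Wp;
        arma::cube& xn = Xn[b];
        for (int jp = 0; jp < Wp; ++jp) {
          for (int ip = 0; ip < Hp; ++ip) {
            double best = -1.0;  // activations are >= 0 post-ReLU
            arma::uword besti = 0;
            for (int dj = 0; dj < pool; ++dj) {
              const arma::uword col = base + (arma::uword)H * (jp * pool + dj);
              for (int di = 0; di < pool; ++di) {
                const arma::uword p = col + ip * pool + di;
                if (z[p] > best) { best = z[p]; besti = p; }
              }
            }
            xn(ip, jp, f) = best;
            am[obase + ip + (arma::uword)Hp * jp] = besti;
          }
        }
      }
    }

    if (caches) {
      LayerCache lc;
      lc.colT = std::move(colT);
      lc.actT = std::move(ZT);
      lc.amax = std::move(amax);
      lc.H = H; lc.W = W; lc.Hp = Hp; lc.Wp = Wp; lc.F = F; lc.K = K;
      caches->push_back(std::move(lc));
    }

    X = std::move(Xn);
    H = Hp; W = Wp; Cin = F;
  }

  const arma::uword m = (arma::uword)H * W * Cin;
  arma::mat feat(m, B);
  for (int b = 0; b < B; ++b) feat.col(b) = arma::vectorise(X[b]);
  return feat;
}

arma::mat softmax_cols(const arma::mat& logits) {
  arma::mat p = logits;
  for (arma::uword c = 0; c < p.n_cols; ++c) {
    arma::vec v = p.col(c);
    v -= v.max();
    v = arma::exp(v);
    p.col(c) = v / arma::accu(v);
  }
  return p;
}

} // namespace

// Forward pass. Returns the class probabilities (n_classes x B), or the
// flattened fingerprint features (m x B) when features_only is true (in
// which case `weights` may omit the dense head).
// [[Rcpp::export]]
arma::mat cpp_cnn_forward(List weights, NumericVector x, IntegerVector dims,
                          int n_blocks, int kh, int kw, int pool,
                          bool features_only) {
  const arma::vec xv(x.begin(), x.size(), false);
  arma::mat feat = conv_forward(weights, xv, dims, n_blocks, kh, kw, pool,
                                nullptr);
  if (features_only) return feat;
  const arma::mat W1 = as<arma::mat>(weights[2 * n_blocks]);
  const arma::vec b1 = as<arma::vec>(weights[2 * n_blocks + 1]);
  const arma::mat W2 = as<arma::mat>(weights[2 * n_blocks + 2]);
  const arma::vec b2 = as<arma::vec>(weights[2 * n_blocks + 3]);
  arma::mat h = W1 * feat;
  h.each_col() += b1;
  h.transform([](double v) { return v > 0.0 ? v : 0.0; });
  arma::mat logits = W2 * h;
  logits.each_col() += b2;
  return softmax_cols(logits);
}

// One training step: forward + backward on a batch, returning the loss,
// the number of correct predictions, and gradients in weight-list order.
// y holds 0-based class labels. Dropout (inverted) is applied to the
// flattened features, driven by dropout_seed for reproducibility.
// [[Rcpp::export]]
List cpp_cnn_train_step(List weights, NumericVector x, IntegerVector dims,
                        IntegerVector y, int n_blocks, int kh, int kw,
                        int pool, double dropout, int dropout_seed) {
  const int B = dims[3];
  const arma::vec xv(x.begin(), x.size(), false);
  std::vector<LayerCache> caches;
  caches.reserve(n_blocks);
  arma::mat feat = conv_forward(weights, xv, dims, n_blocks, kh, kw, pool,
                                &caches);
  const arma::uword m = feat.n_rows;

  arma::mat mask;
  if (dropout > 0.0) {
    std::mt19937_64 rng(static_cast<uint64_t>(dropout_seed));
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    mask.set_size(m, B);
    const double scale = 1.0 / (1.0 - dropout);
    for (arma::uword c = 0; c < (arma::uword)B; ++c)
      for (arma::uword r = 0; r < m; ++r)
        mask(r, c) = unif(rng) < dropout ? 0.0 : scale;
    feat %= mask;
  }

  const arma::mat W1 = as<arma::mat>(weights[2 * n_blocks]);
  const arma::vec b1 = as<arma::vec>(weights[2 * n_blocks + 1]);
  const arma::mat W2 = as<arma::mat>(weights[2 * n_blocks + 2]);
  const arma::vec b2 = as<arma::vec>(weights[2 * n_blocks + 3]);

  arma::mat h = W1 * feat;
  h.each_col() += b1;
  arma::mat hrelu = h;
  hrelu.transform([](double v) { return v > 0.0 ? v : 0.0; });
  arma::mat logits = W2 * hrelu;
  logits.each_col() += b2;
  arma::mat P = softmax_cols(logits);

  double loss = 0.0;
  int correct = 0;
  for (int b = 0; b < B; ++b) {
    const int lab = y[b];
    loss += -std::log(std::max(P(lab, b), 1e-300));
    arma::uword pred;
    P.col(b).max(pred);
    if ((int)pred == lab) ++correct;
  }
  loss /= B;

  // backward
  arma::mat dlogits = P;
  for (int b = 0; b < B; ++b) dlogits(y[b], b) -= 1.0;
  dlogits /= B;

  arma::mat dW2 = dlogits * hrelu.t();
  arma::vec db2 = arma::sum(dlogits, 1);
  arma::mat dh = W2.t() * dlogits;
  dh.elem(arma::find(hrelu <= 0.0)).zeros();
  arma::mat dW1 = dh * feat.t();
  arma::vec db1 = arma::sum(dh, 1);
  arma::mat dfeat = W1.t() * dh;
  if (dropout > 0.0) dfeat %= mask;

  const LayerCache& last = caches.back();
  std::vector<arma::cube> dX(B);
  for (int b = 0; b < B; ++b) {
    dX[b] = arma::cube(last.Hp, last.Wp, last.F);
    std::memcpy(dX[b].memptr(), dfeat.colptr(b), sizeof(double) * m);
  }

  List grads(2 * n_blocks + 4);
  grads[2 * n_blocks] = dW1;
  grads[2 * n_blocks + 1] = db1;
  grads[2 * n_blocks + 2] = dW2;
  grads[2 * n_blocks + 3] = db2;

  for (int blk = n_blocks - 1; blk >= 0; --blk) {
    const LayerCache& lc = caches[blk];
    const arma::mat Wc = as<arma::mat>(weights[2 * blk]);
    const int HW = lc.H * lc.W;

    // pool backward: scatter into dZT at stored argmax rows
    arma::mat dZT((arma::uword)HW * B, lc.F, arma::fill::zeros);
    for (int f = 0; f < lc.F; ++f) {
      double* dz = dZT.colptr(f);
      const arma::uword* am = lc.amax.colptr(f);
      const arma::uword n_out = (arma::uword)lc.Hp * lc.Wp * B;
      for (arma::uword o = 0; o < n_out; ++o) {
        const int b = o / ((arma::uword)lc.Hp * lc.Wp);
        const arma::uword rem = o - (arma::uword)b * lc.Hp * lc.Wp;
        dz[am[o]] += dX[b](rem % lc.Hp, rem / lc.Hp, f);
      }
    }
    // ReLU backward
    dZT.elem(arma::find(lc.actT <= 0.0)).zeros();

    grads[2 * blk] = arma::mat(dZT.t() * lc.colT);          // F x K
    grads[2 * blk + 1] = arma::vec(arma::sum(dZT, 0).t());  // F

    if (blk > 0) {
      arma::mat dcolT = dZT * Wc;        // HW*B x K
      const LayerCache& prev = caches[blk - 1];
      for (int b = 0; b < B; ++b) {
        arma::cube d(lc.H, lc.W, prev.F);
        col2im_same(dcolT, lc.H, lc.W, prev.F, kh, kw, d, (arma::uword)b * HW);
        dX[b] = std::move(d);
      }
    }
  }

  return List::create(_["loss"] = loss, _["correct"] = correct,
                      _["grads"] = grads);
}

// FNV-1a hash of a raw vector, as a 16-hex-digit string; used to fingerprint
// model weights (model_version) without external digest dependencies.
// [[Rcpp::export]]
std::string cpp_fnv1a(RawVector bytes) {
  uint64_t h = 1469598103934665603ULL;
  for (R_xlen_t i = 0; i < bytes.size(); ++i) {
    h ^= static_cast<uint64_t>(bytes[i]);
    h *= 1099511628211ULL;
  }
  char buf[17];
  std::snprintf(buf, sizeof(buf), "%016llx",
                static_cast<unsigned long long>(h));
  return std::string(buf);
}
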