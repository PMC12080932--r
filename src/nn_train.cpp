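// Full-batch Adam trainer for the small dense calcium-surrogate network
// (tanh hidden layers, linear scalar output, weighted MSE). Mirrors the R
// reference implementation in nn.R but runs the epoch loop in C++; all
// randomness (per-epoch denoising jitter on the lag columns) is drawn from
// R's RNG so training stays reproducible under set.seed().
#include <RcppArmadillo.h>
#ifdef __SSE2__
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List nn_train_cpp(List W0, List b0, const arma::mat &X, const arma::vec &y,
                  const arma::vec &sample_w, int epochs, double lr0,
                  IntegerVector noise_cols, double noise_sd,
                  double noise_decay, int batch_size) {
#ifdef __SSE2__
  // flush denormals: late-training gradients underflow and denormal
  // arithmetic stalls the single-core epoch loop by orders of magnitude
  unsigned int ftz = _MM_GET_FLUSH_ZERO_MODE();
  unsigned int daz = _MM_GET_DENORMALS_ZERO_MODE();
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
  const int nl = W0.size();
  std::vector<arma::mat> W(nl), mW(nl), vW(nl);
  std::vector<arma::rowvec> b(nl), mb(nl), vb(nl);
  for (int l = 0; l < nl; ++l) {
    W[l] = as<arma::mat>(W0[l]);
    b[l] = arma::conv_to<arma::rowvec>::from(as<arma::vec>(b0[l]));
    mW[l].zeros(W[l].n_rows, W[l].n_cols);
    vW[l].zeros(W[l].n_rows, W[l].n_cols);
    mb[l].zeros(b[l].n_elem); vb[l].zeros(b[l].n_elem);
  }
  const arma::uword n = X.n_rows;
  arma::vec sw = sample_w / arma::accu(sample_w);
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  arma::vec loss(epochs);
  std::vector<arma::mat> acts(nl + 1), deltas(nl);
  RNGScope scope;
  // fast jitter RNG (xorshift64*), seeded once from R's RNG so training
  // remains reproducible under set.seed(); the denoising jitter needs
  // millions of draws per epoch, far too many for the R RNG API
  uint64_t rs = (uint64_t)(unif_rand() * 4294967296.0) * 2654435761u + 1u;
  auto fast_unif = [&rs]() {
    rs ^= rs >> 12; rs ^= rs << 25; rs ^= rs >> 27;
    return (double)((rs * 2685821657736338717ULL) >> 11) / 9007199254740992.0;
  };
  // approximate standard normal: scaled Irwin-Hall(3); ample for jitter
  auto fast_norm = [&]() {
    return (fast_unif() + fast_unif() + fast_unif() - 1.5) * 2.0;
  };

  const bool use_mb = batch_size > 0 && (arma::uword)batch_size < n;
  arma::uvec idx;
  arma::vec yb, swb;

  for (int ep = 1; ep <= epochs; ++ep) {
    double lr = lr0;
    if (ep > 0.85 * epochs) lr = lr0 * 0.1;
    else if (ep > 0.6 * epochs) lr = lr0 * 0.3;
    double nsd = noise_sd * std::pow(noise_decay, (double)(ep - 1) / epochs);

    if (use_mb) {
      idx.set_size(batch_size);
      for (int i = 0; i < batch_size; ++i)
        idx(i) = (arma::uword)(fast_unif() * n);
      acts[0] = X.rows(idx);
      yb = y(idx);
      swb = sw(idx);
      swb /= arma::accu(swb);
    } else {
      acts[0] = X;
      yb = y;
      swb = sw;
    }
    if (noise_cols.size() > 0 && nsd > 0) {
      const arma::uword nb = acts[0].n_rows;
      for (int jc = 0; jc < noise_cols.size(); ++jc) {
        int j = noise_cols[jc] - 1;          // R 1-based column index
        double *col = acts[0].colptr(j);
        for (arma::uword i = 0; i < nb; ++i)
          col[i] += nsd * fast_norm();
      }
    }
    for (int l = 0; l < nl; ++l) {
      arma::mat Z = acts[l] * W[l];
      Z.each_row() += b[l];
      acts[l + 1] = (l < nl - 1) ? arma::tanh(Z) : Z;
    }
    arma::vec err = acts[nl].col(0) - yb;
    loss(ep - 1) = arma::accu(swb % arma::square(err));
    arma::mat delta = 2.0 * (err % swb);

    double bc1 = 1.0 - std::pow(beta1, ep), bc2 = 1.0 - std::pow(beta2, ep);
    for (int l = nl - 1; l >= 0; --l) {
      arma::mat gW = acts[l].t() * delta;
      arma::rowvec gb = arma::sum(delta, 0);
      if (l > 0)
        delta = (delta * W[l].t()) % (1.0 - arma::square(acts[l]));
      mW[l] = beta1 * mW[l] + (1 - beta1) * gW;
      vW[l] = beta2 * vW[l] + (1 - beta2) * arma::square(gW);
      mb[l] = beta1 * mb[l] + (1 - beta1) * gb;
      vb[l] = beta2 * vb[l] + (1 - beta2) * arma::square(gb);
      W[l] -= lr * (mW[l] / bc1) / (arma::sqrt(vW[l] / bc2) + eps);
      b[l] -= lr * (mb[l] / bc1) / (arma::sqrt(vb[l] / bc2) + eps);
    }
    if (ep % 200 == 0) {
      // geometric decay of stale Adam moments underflows into denormals,
      // which stalls the FP units; flush tiny magnitudes to zero
      for (int l = 0; l < nl; ++l) {
        mW[l].clean(1e-200); vW[l].clean(1e-200);
        mb[l].clean(1e-200); vb[l].clean(1e-200);
      }
    }
  }

#ifdef __SSE2__
  _MM_SET_FLUSH_ZERO_MODE(ftz);
  _MM_SET_DENORMALS_ZERO_MODE(daz);
#endif
  List Wout(nl), bout(nl);
  for (int l = 0; l < nl; ++l) {
    Wout[l] = wrap(W[l]);
    bout[l] = wrap(arma::conv_to<arma::vec>::from(b[l]));
  }
  return List::create(_["W"] = Wout, _["b"] = bout,
                      _["loss"] = wrap(loss));
}
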