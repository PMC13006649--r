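// Minibatch backpropagation with Adam for the baseline-recognition MLP.
// Single-precision arithmetic: the weights are float during optimization
// (halving GEMM cost on CPU) and returned as double. Deterministic given
// the seed: shuffling uses a private mt19937 with an explicit Fisher-Yates.

#include <RcppArmadillo.h>
#include <random>
#ifdef __SSE2__
#include <xmmintrin.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Adam's moment buffers decay geometrically toward zero for units with
// vanishing gradients; once they underflow into denormal range, scalar
// arithmetic slows by orders of magnitude. Training runs with
// flush-to-zero / denormals-are-zero, restored on exit.
struct FlushDenormals {
#ifdef __SSE2__
  unsigned int saved;
  FlushDenormals() : saved(_mm_getcsr()) { _mm_setcsr(saved | 0x8040u); }
  ~FlushDenormals() { _mm_setcsr(saved); }
#endif
};

static void fisher_yates(std::vector<uword>& idx, std::mt19937& rng) {
  for (uword i = idx.size() - 1; i > 0; --i) {
    uword j = rng() % (i + 1);
    std::swap(idx[i], idx[j]);
  }
}

// [[Rcpp::export(name = ".cpp_train_mlp")]]
Rcpp::List cpp_train_mlp(Rcpp::List W0, Rcpp::List b0,
                         const arma::mat& X, const arma::vec& y,
                         const arma::mat& Xv, const arma::vec& yv,
                         int epochs, int batch_size, double lr0,
                         bool cosine, double lr_min_frac,
                         int patience, bool use_val, int seed,
                         double weight_decay, double dropout,
                         double input_jitter, double level_shift,
                         double ema_decay) {
  FlushDenormals ftz;
  const int L = W0.size();
  std::vector<fmat> W(L), mW(L), vW(L), bestW(L);
  std::vector<frowvec> b(L), mb(L), vb(L), bestb(L);
  for (int l = 0; l < L; ++l) {
    W[l] = conv_to<fmat>::from(Rcpp::as<mat>(W0[l]));
    b[l] = conv_to<frowvec>::from(Rcpp::as<rowvec>(b0[l]));
    mW[l].zeros(W[l].n_rows, W[l].n_cols);
    vW[l].zeros(W[l].n_rows, W[l].n_cols);
    mb[l].zeros(b[l].n_elem);
    vb[l].zeros(b[l].n_elem);
    bestW[l] = W[l];
    bestb[l] = b[l];
  }
  const fmat Xf = conv_to<fmat>::from(X);
  const fvec yf = conv_to<fvec>::from(y);
  const fmat Xvf = conv_to<fmat>::from(Xv);
  const fvec yvf = conv_to<fvec>::from(yv);

  const bool use_ema = ema_decay > 0.0;
  std::vector<fmat> emaW(L);
  std::vector<frowvec> emab(L);
  if (use_ema)
    for (int l = 0; l < L; ++l) { emaW[l] = W[l]; emab[l] = b[l]; }

  const uword n = Xf.n_rows;
  const float beta1 = 0.9f, beta2 = 0.999f, eps = 1e-8f;
  long step = 0;
  double best_val = R_PosInf;
  int stale = 0, epochs_run = 0;
  std::vector<double> history, val_history;
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;

  std::vector<fmat> acts(L), zs(L);

  for (int epoch = 1; epoch <= epochs; ++epoch) {
    double lr = lr0;
    if (cosine) {
      double frac = (epochs > 1) ? double(epoch - 1) / double(epochs - 1)
                                 : 0.0;
      double lr_min = lr0 * lr_min_frac;
      lr = lr_min + (lr0 - lr_min) * (1.0 + std::cos(M_PI * frac)) / 2.0;
    }
    const float lrf = static_cast<float>(lr);
    fisher_yates(idx, rng);
    double ep_loss = 0.0;

    for (uword s = 0; s < n; s += batch_size) {
      const uword e = std::min<uword>(s + batch_size, n) - 1;
      const uword B = e - s + 1;
      uvec rows(B);
      for (uword k = 0; k < B; ++k) rows[k] = idx[s + k];
      fmat a = Xf.rows(rows);
      fvec yb = yf.elem(rows);
      if (level_shift > 0.0) {
        // shift a window and its label by the same constant: a baseline
        // estimator is equivariant under vertical translation
        const double inv = 1.0 / 4294967296.0;
        for (uword k = 0; k < B; ++k) {
          const float c =
            float((rng() * inv * 2.0 - 1.0) * level_shift);
          a.row(k) += c;
          yb[k] += c;
        }
      }
      if (input_jitter > 0.0) {
        // fresh Gaussian perturbation of the inputs every step
        // (Box-Muller on the private generator, for reproducibility)
        const float js = static_cast<float>(input_jitter);
        const double inv = 1.0 / 4294967296.0;
        for (uword k = 0; k + 1 < a.n_elem; k += 2) {
          double u1 = (rng() + 0.5) * inv, u2 = (rng() + 0.5) * inv;
          double r = std::sqrt(-2.0 * std::log(u1));
          a[k]     += js * float(r * std::cos(2.0 * M_PI * u2));
          a[k + 1] += js * float(r * std::sin(2.0 * M_PI * u2));
        }
      }

      std::vector<fmat> masks(L - 1);
      const bool use_drop = dropout > 0.0;
      const float keep = 1.0f - static_cast<float>(dropout);
      for (int l = 0; l < L; ++l) {
        acts[l] = std::move(a);
        fmat z = acts[l] * W[l];
        z.each_row() += b[l];
        if (l < L - 1) {
          if (use_drop) zs[l] = z;
          float* p = z.memptr();
          const uword ne = z.n_elem;
          for (uword k = 0; k < ne; ++k) p[k] = p[k] > 0.0f ? p[k] : 0.0f;
          if (use_drop) {
            // inverted dropout on hidden activations
            fmat m(z.n_rows, z.n_cols);
            for (uword k = 0; k < m.n_elem; ++k)
              m[k] = (rng() * (1.0 / 4294967296.0) < dropout)
                       ? 0.0f : 1.0f / keep;
            masks[l] = m;
            z %= m;
          }
        }
        a = std::move(z);
      }
      fmat resid = std::move(a);
      resid.col(0) -= yb;
      const double loss = accu(square(resid)) / double(B);
      if (!std::isfinite(loss))
        Rcpp::stop("training diverged (non-finite loss) at epoch %d", epoch);
      ep_loss += loss * double(B);

      fmat dz = (2.0f / float(B)) * resid;
      ++step;
      const float corr1 = 1.0f - std::pow(beta1, float(step));
      const float corr2 = 1.0f - std::pow(beta2, float(step));
      const float wdf = 1.0f - lrf * static_cast<float>(weight_decay);
      for (int l = L - 1; l >= 0; --l) {
        fmat gW = acts[l].t() * dz;
        frowvec gb = sum(dz, 0);
        if (l > 0) {
          fmat da = dz * W[l].t();
          if (use_drop) {
            da %= masks[l - 1];
            dz = da % conv_to<fmat>::from(zs[l - 1] > 0.0f);
          } else {
            // ReLU derivative read off the (post-activation) output:
            // act > 0 exactly where z > 0
            float* dp = da.memptr();
            const float* ap = acts[l].memptr();
            const uword ne = da.n_elem;
            for (uword k = 0; k < ne; ++k)
              if (ap[k] <= 0.0f) dp[k] = 0.0f;
            dz = std::move(da);
          }
        }
        {  // fused in-place Adam update of the weight matrix
          const uword ne = W[l].n_elem;
          float* w = W[l].memptr();
          float* mw = mW[l].memptr();
          float* vw = vW[l].memptr();
          const float* g = gW.memptr();
          for (uword k = 0; k < ne; ++k) {
            const float gk = g[k];
            mw[k] = beta1 * mw[k] + (1.0f - beta1) * gk;
            vw[k] = beta2 * vw[k] + (1.0f - beta2) * gk * gk;
            if (weight_decay > 0.0) w[k] *= wdf;
            w[k] -= lrf * (mw[k] / corr1) /
                    (std::sqrt(vw[k] / corr2) + eps);
          }
        }
        {
          const uword ne = b[l].n_elem;
          float* w = b[l].memptr();
          float* mw = mb[l].memptr();
          float* vw = vb[l].memptr();
          const float* g = gb.memptr();
          for (uword k = 0; k < ne; ++k) {
            const float gk = g[k];
            mw[k] = beta1 * mw[k] + (1.0f - beta1) * gk;
            vw[k] = beta2 * vw[k] + (1.0f - beta2) * gk * gk;
            w[k] -= lrf * (mw[k] / corr1) /
                    (std::sqrt(vw[k] / corr2) + eps);
          }
        }
      }
      if (use_ema) {
        const float d = static_cast<float>(ema_decay);
        for (int l = 0; l < L; ++l) {
          emaW[l] = d * emaW[l] + (1.0f - d) * W[l];
          emab[l] = d * emab[l] + (1.0f - d) * b[l];
        }
      }
      if (step % 64 == 0) Rcpp::checkUserInterrupt();
    }
    epochs_run = epoch;
    history.push_back(ep_loss / double(n));

    if (use_val) {
      // validate the averaged model when EMA is on (the weights that
      // will be returned), otherwise the raw weights
      const std::vector<fmat>& Wv = use_ema ? emaW : W;
      const std::vector<frowvec>& bv = use_ema ? emab : b;
      fmat a = Xvf;
      for (int l = 0; l < L; ++l) {
        fmat z = a * Wv[l];
        z.each_row() += bv[l];
        a = (l < L - 1)
          ? clamp(z, 0.0f, std::numeric_limits<float>::max())
          : z;
      }
      const double vloss =
        accu(square(a.col(0) - yvf)) / double(yvf.n_elem);
      val_history.push_back(vloss);
      if (vloss < best_val - 1e-12) {
        best_val = vloss;
        for (int l = 0; l < L; ++l) { bestW[l] = Wv[l]; bestb[l] = bv[l]; }
        stale = 0;
      } else if (++stale >= patience) {
        break;
      }
    }
  }

  if (use_val)
    for (int l = 0; l < L; ++l) { W[l] = bestW[l]; b[l] = bestb[l]; }
  else if (use_ema)
    for (int l = 0; l < L; ++l) { W[l] = emaW[l]; b[l] = emab[l]; }

  Rcpp::List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) {
    Wout[l] = Rcpp::wrap(conv_to<mat>::from(W[l]));
    bout[l] = Rcpp::wrap(conv_to<rowvec>::from(b[l]));
  }
  return Rcpp::List::create(
    Rcpp::Named("W") = Wout, Rcpp::Named("b") = bout,
    Rcpp::Named("history") = history,
    Rcpp::Named("val_history") = val_history,
    Rcpp::Named("best_val") = best_val,
    Rcpp::Named("epochs_run") = epochs_run);
}
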