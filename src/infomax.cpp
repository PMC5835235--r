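// Extended Infomax ICA core: natural-gradient updates with online
// kurtosis-sign switching, learning-rate annealing on the gradient angle,
// and a deterministic internal RNG so a given seed reproduces the
// decomposition bit-for-bit. Input is centered, sphered data (K x N).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {
// xorshift32: tiny deterministic PRNG, platform-independent
struct XorShift {
  uint32_t s;
  explicit XorShift(uint32_t seed) : s(seed ? seed : 1u) {}
  uint32_t next() {
    uint32_t x = s;
    x ^= x << 13; x ^= x >> 17; x ^= x << 5;
    return s = x;
  }
  // uniform integer in [0, n)
  uint32_t below(uint32_t n) { return next() % n; }
};

void shuffle_index(uvec& idx, XorShift& rng) {
  for (uword i = idx.n_elem - 1; i > 0; --i) {
    uword j = rng.below((uint32_t)(i + 1));
    std::swap(idx[i], idx[j]);
  }
}
} // namespace

// [[Rcpp::export(name = ".infomax_core")]]
Rcpp::List infomax_core(const arma::mat& X, int seed,
                        double lrate = -1.0, int max_iter = 512,
                        double w_stop = 1e-7, double anneal_deg = 60.0,
                        double anneal_step = 0.98, int kurt_size = 6000,
                        int ext_interval = 1, double signs_bias = 0.02,
                        double ext_momentum = 0.5) {
  const uword K = X.n_rows, N = X.n_cols;
  if (lrate <= 0) lrate = 0.00065 / std::log((double)K);
  uword block = (uword)std::ceil(std::min(5.0 * std::log((double)N),
                                          0.3 * (double)N));
  if (block < 2) block = 2;
  if (block > N) block = N;

  mat W = eye<mat>(K, K);
  vec bias = zeros<vec>(K);
  vec signs = ones<vec>(K);        // +1: supergaussian; -1: subgaussian
  vec old_kurt = zeros<vec>(K);
  mat BI = (double)block * eye<mat>(K, K);
  mat old_W = W, delta = zeros<mat>(K, K), old_delta = zeros<mat>(K, K);
  double change = 0.0, old_change = 0.0, angle_delta = 0.0;
  bool converged = false;
  int iter = 0, blockno = 0;
  const double max_weight = 1e8;

  XorShift rng((uint32_t)seed);
  uvec perm = regspace<uvec>(0, N - 1);
  uword nsub = std::min((uword)kurt_size, N);

  for (iter = 1; iter <= max_iter; ++iter) {
    shuffle_index(perm, rng);
    // one kurtosis subsample per pass (signs are still refreshed every
    // ext_interval blocks against the current weights)
    uvec sub(nsub);
    for (uword i = 0; i < nsub; ++i) sub[i] = rng.below((uint32_t)N);
    mat Xsub = X.cols(sub);
    bool blowup = false;
    for (uword t = 0; t + block <= N; t += block, ++blockno) {
      mat xb = X.cols(perm.subvec(t, t + block - 1));
      mat u = W * xb + repmat(bias, 1, block);
      mat y = tanh(u);
      W += lrate * (BI - diagmat(signs) * (y * u.t()) - u * u.t()) * W;
      bias += lrate * (-2.0) * sum(y, 1);
      if (W.has_nan() || abs(W).max() > max_weight) { blowup = true; break; }
      if (ext_interval > 0 && blockno % ext_interval == 0) {
        mat us = W * Xsub;
        vec m2 = mean(square(us), 1);
        vec m4 = mean(square(square(us)), 1);
        vec kurt = m4 / square(m2) - 3.0;
        if (ext_momentum > 0)
          kurt = ext_momentum * old_kurt + (1.0 - ext_momentum) * kurt;
        old_kurt = kurt;
        for (uword i = 0; i < K; ++i)
          signs[i] = (kurt[i] + signs_bias > 0) ? 1.0 : -1.0;
      }
    }
    if (blowup) {
      // restart with a smaller rate
      W = eye<mat>(K, K); old_W = W; bias.zeros(); signs.fill(1.0);
      old_kurt.zeros(); delta.zeros(); old_delta.zeros();
      change = old_change = 0.0;
      lrate *= 0.8;
      if (lrate < 1e-12) break;
      continue;
    }
    delta = W - old_W;
    change = accu(square(delta));
    if (iter > 2 && old_change > 0 && change > 0) {
      double c = accu(delta % old_delta) / std::sqrt(change * old_change);
      c = std::max(-1.0, std::min(1.0, c));
      angle_delta = std::acos(c) * 180.0 / M_PI;
      if (angle_delta > anneal_deg) {
        lrate *= anneal_step;
        old_delta = delta;
        old_change = change;
      }
    } else {
      old_delta = delta;
      old_change = change;
    }
    old_W = W;
    if (iter > 2 && change < w_stop) { converged = true; break; }
  }
  return Rcpp::List::create(
      Rcpp::Named("W") = W,
      Rcpp::Named("n_iter") = std::min(iter, max_iter),
      Rcpp::Named("converged") = converged,
      Rcpp::Named("signs") = signs,
      Rcpp::Named("final_lrate") = lrate,
      Rcpp::Named("final_change") = change);
}
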