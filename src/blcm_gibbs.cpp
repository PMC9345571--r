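#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the truncated stick-breaking Dirichlet-process mixture
// of product-Bernoulli capture profiles with data augmentation of the
// unobserved (all-zero) individuals.
//
// Observed individuals are grouped by distinct capture history, so one
// sweep costs O(H * C * K) with H <= 2^K - 1 distinct histories rather
// than O(n * C * K).  Uses R's RNG: seeding happens on the R side.
//
// hist: H x K 0/1 matrix of distinct observed histories
// freq: count of individuals per history (sums to n)
// C:    truncation level (maximum number of latent classes)
// a, b: Gamma hyperprior on the DP concentration alpha
// burn, iter, thin: chain control; iter/thin draws are returned

static void alloc_multinom(int n, const std::vector<double>& p,
                           std::vector<int>& out) {
  // sequential conditional-binomial allocation
  int remaining = n;
  double ptot = 0.0;
  for (double v : p) ptot += v;
  const int C = p.size();
  for (int c = 0; c < C; ++c) {
    if (remaining <= 0) { out[c] = 0; continue; }
    if (c == C - 1) { out[c] = remaining; break; }
    double cond = (ptot > 0.0) ? p[c] / ptot : 0.0;
    if (cond > 1.0) cond = 1.0;
    int draw = (int) R::rbinom(remaining, cond);
    out[c] = draw;
    remaining -= draw;
    ptot -= p[c];
  }
}

// [[Rcpp::export]]
List blcm_gibbs(IntegerMatrix hist, IntegerVector freq, int C,
                double a, double b, int burn, int iter, int thin) {
  const int H = hist.nrow(), K = hist.ncol();
  int n = 0;
  for (int h = 0; h < H; ++h) n += freq[h];
  if (n < 1) stop("no observed individuals");
  if (C < 1 || thin < 1 || iter < thin) stop("invalid chain control");

  std::vector<double> lambda(C * K), V(C), pi(C), logpi(C);
  double alpha = 1.0;

  // initial state drawn from the priors
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < K; ++k) lambda[c * K + k] = R::rbeta(1.0, 1.0);
  for (int c = 0; c < C - 1; ++c) V[c] = R::rbeta(1.0, alpha);
  V[C - 1] = 1.0;
  int n0 = n;

  const int n_keep = iter / thin;
  IntegerVector N_draws(n_keep), n0_draws(n_keep), occ_draws(n_keep);
  NumericVector alpha_draws(n_keep), p0_draws(n_keep);
  int underflow = 0, kept = 0;

  std::vector<double> logphi(C), prob(C), log1mlam(C);
  std::vector<double> loglam(C * K), logmis(C * K);
  std::vector<int> occ(C), alloc(C);
  std::vector<long long> capt(C * K);

  for (int it = 0; it < burn + iter; ++it) {
    // stick weights from the current sticks
    double rem = 1.0, lrem = 0.0;
    for (int c = 0; c < C; ++c) {
      pi[c] = V[c] * rem;
      logpi[c] = std::log(V[c]) + lrem;
      rem *= (1.0 - V[c]);
      lrem += std::log1p(-V[c]);
      if (!R_finite(logpi[c])) logpi[c] = R_NegInf;
    }

    // log capture/miss tables and the all-zero-history log probability
    for (int c = 0; c < C; ++c) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        loglam[c * K + k] = std::log(lambda[c * K + k]);
        logmis[c * K + k] = std::log1p(-lambda[c * K + k]);
        s += logmis[c * K + k];
      }
      log1mlam[c] = s;
    }

    // (1) class allocation, grouped by distinct history
    std::fill(occ.begin(), occ.end(), 0);
    std::fill(capt.begin(), capt.end(), 0LL);
    for (int h = 0; h < H; ++h) {
      double mx = R_NegInf;
      for (int c = 0; c < C; ++c) {
        double s = logpi[c] + log1mlam[c];
        for (int k = 0; k < K; ++k)
          if (hist(h, k)) s += loglam[c * K + k] - logmis[c * K + k];
        logphi[c] = s;
        if (s > mx) mx = s;
      }
      if (!R_finite(mx)) stop("degenerate class-allocation conditional");
      for (int c = 0; c < C; ++c) prob[c] = std::exp(logphi[c] - mx);
      alloc_multinom(freq[h], prob, alloc);
      for (int c = 0; c < C; ++c) {
        if (!alloc[c]) continue;
        occ[c] += alloc[c];
        for (int k = 0; k < K; ++k)
          if (hist(h, k)) capt[c * K + k] += alloc[c];
      }
    }
    // augmented all-zero individuals
    if (n0 > 0) {
      double mx = R_NegInf;
      for (int c = 0; c < C; ++c) {
        logphi[c] = logpi[c] + log1mlam[c];
        if (logphi[c] > mx) mx = logphi[c];
      }
      for (int c = 0; c < C; ++c) prob[c] = std::exp(logphi[c] - mx);
      alloc_multinom(n0, prob, alloc);
      for (int c = 0; c < C; ++c) occ[c] += alloc[c];
    }

    // (2) capture probabilities
    for (int c = 0; c < C; ++c)
      for (int k = 0; k < K; ++k) {
        double cap = (double) capt[c * K + k];
        lambda[c * K + k] =
          R::rbeta(1.0 + cap, 1.0 + (double) occ[c] - cap);
      }

    // (3) stick-breaking fractions
    long long tail = 0;
    for (int c = 0; c < C; ++c) tail += occ[c];
    double sumlog1mV = 0.0;
    for (int c = 0; c < C - 1; ++c) {
      tail -= occ[c];
      V[c] = R::rbeta(1.0 + (double) occ[c], alpha + (double) tail);
      if (V[c] >= 1.0) V[c] = 1.0 - 1e-12;  // guard the log below
      sumlog1mV += std::log1p(-V[c]);
    }
    V[C - 1] = 1.0;

    // (4) concentration parameter
    double rate = b - sumlog1mV;
    if (!R_finite(rate) || rate <= 0.0)
      stop("non-finite conditional for alpha");
    alpha = R::rgamma(a + (double) (C - 1), 1.0 / rate);
    if (!R_finite(alpha) || alpha <= 0.0)
      stop("non-finite draw for alpha");

    // (5) unobserved count: negative-binomial conditional driven by the
    // mixture probability of the all-zero history (reciprocal prior on N),
    // using the freshly updated sticks and capture probabilities
    double rem2 = 1.0, p0 = 0.0;
    for (int c = 0; c < C; ++c) {
      double w = V[c] * rem2;
      rem2 *= (1.0 - V[c]);
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += std::log1p(-lambda[c * K + k]);
      p0 += w * std::exp(s);
    }
    if (p0 <= 0.0) {
      ++underflow;
      n0 = 0;
    } else if (p0 >= 1.0) {
      stop("all-zero-history probability reached 1");
    } else {
      n0 = (int) R::rnbinom((double) n, 1.0 - p0);
    }

    if (it >= burn && (it - burn) % thin == thin - 1) {
      int nocc = 0;
      for (int c = 0; c < C; ++c) if (occ[c] > 0) ++nocc;
      N_draws[kept] = n + n0;
      n0_draws[kept] = n0;
      alpha_draws[kept] = alpha;
      p0_draws[kept] = p0;
      occ_draws[kept] = nocc;
      ++kept;
    }
  }

  return List::create(_["N"] = N_draws, _["n0"] = n0_draws,
                      _["alpha"] = alpha_draws, _["p0"] = p0_draws,
                      _["occupied"] = occ_draws,
                      _["underflow"] = underflow);
}
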