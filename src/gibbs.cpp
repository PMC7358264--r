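#include <Rcpp.h>
using namespace Rcpp;

// Conjugate Gibbs samplers for the two CSM models.  All randomness goes
// through R's RNG (norm_rand / R::rgamma / unif_rand) so that set.seed()
// in R fully determines the draws.

static double rinvgamma(double shape, double rate) {
  // shape-a, rate-b parameterization: density ∝ x^(-a-1) exp(-b/x)
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// One Dirichlet draw with the given shape vector, written into out.
static void draw_dirichlet(const NumericVector& shape, double* out) {
  int K = shape.size();
  double total = 0.0;
  for (int k = 0; k < K; ++k) {
    out[k] = R::rgamma(shape[k], 1.0);
    total += out[k];
  }
  if (total <= 0.0) {
    // pathological underflow with tiny shapes: fall back to the mean
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += shape[k];
    for (int k = 0; k < K; ++k) out[k] = shape[k] / s;
  } else {
    for (int k = 0; k < K; ++k) out[k] /= total;
  }
}

// [[Rcpp::export]]
NumericMatrix rdirichlet_cpp(NumericVector shape, int n) {
  int K = shape.size();
  NumericMatrix out(n, K);
  std::vector<double> row(K);
  for (int i = 0; i < n; ++i) {
    draw_dirichlet(shape, row.data());
    for (int k = 0; k < K; ++k) out(i, k) = row[k];
  }
  return out;
}

// Two-block Gibbs for the single-normal model:
//   y_ij ~ N(mu, sigma^2), mu ~ N(mu0, s0sq), sigma^2 ~ InvGamma(a, b)
// [[Rcpp::export]]
List gibbs_single_cpp(NumericVector y, double mu0, double s0sq,
                      double a, double b,
                      int n_burnin, int n_draws, int thin) {
  int n = y.size();
  double ysum = 0.0, ymean;
  for (int i = 0; i < n; ++i) ysum += y[i];
  ymean = ysum / n;
  double ssd = 0.0;
  for (int i = 0; i < n; ++i) ssd += (y[i] - ymean) * (y[i] - ymean);
  double mu = ymean;
  double sigsq = std::max(ssd / std::max(n - 1, 1), 1e-6);

  NumericVector mu_out(n_draws), sig_out(n_draws);
  int total = n_burnin + n_draws * thin;
  for (int it = 0; it < total; ++it) {
    // mu | sigma^2, y  (normal-normal update)
    double prec = 1.0 / s0sq + n / sigsq;
    double m = (mu0 / s0sq + ysum / sigsq) / prec;
    mu = m + norm_rand() / std::sqrt(prec);
    // sigma^2 | mu, y  (inverse-gamma update)
    double ss = 0.0;
    for (int i = 0; i < n; ++i) ss += (y[i] - mu) * (y[i] - mu);
    sigsq = rinvgamma(a + 0.5 * n, b + 0.5 * ss);
    if (it >= n_burnin && (it - n_burnin) % thin == 0) {
      int s = (it - n_burnin) / thin;
      mu_out[s] = mu;
      sig_out[s] = sigsq;
    }
  }
  return List::create(_["mu"] = mu_out, _["sigma_sq"] = sig_out);
}

// Data-augmentation Gibbs for the K-component normal mixture:
//   y_ij ~ sum_k pi_k N(mu_k, sigma_k^2),
//   (pi_1..pi_K) ~ Dirichlet(alpha), mu_k ~ N(mu0, s0sq),
//   sigma_k^2 ~ InvGamma(a, b), latent labels z_ij.
// Empty components revert to their priors (conditionals stay proper).
// K = 1 is permitted and degenerates to the single model.
// [[Rcpp::export]]
List gibbs_fmm_cpp(NumericVector y, NumericVector alpha,
                   double mu0, double s0sq, double a, double b,
                   NumericVector mu_init, NumericVector sigsq_init,
                   int n_burnin, int n_draws, int thin) {
  int n = y.size();
  int K = alpha.size();
  std::vector<double> mu(K), sigsq(K), pi(K);
  double asum = 0.0;
  for (int k = 0; k < K; ++k) asum += alpha[k];
  for (int k = 0; k < K; ++k) {
    mu[k] = mu_init[k];
    sigsq[k] = std::max(sigsq_init[k], 1e-6);
    pi[k] = alpha[k] / asum;
  }

  NumericMatrix pi_out(n_draws, K), mu_out(n_draws, K), sig_out(n_draws, K);
  std::vector<int> z(n), counts(K);
  std::vector<double> sums(K), ss(K), logw(K), w(K), shape(K);
  NumericVector shape_nv(K);

  int total = n_burnin + n_draws * thin;
  for (int it = 0; it < total; ++it) {
    // z | pi, mu, sigma^2 : categorical, computed on the log scale
    std::fill(counts.begin(), counts.end(), 0);
    std::fill(sums.begin(), sums.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double maxlw = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double d = y[i] - mu[k];
        logw[k] = std::log(pi[k]) - 0.5 * std::log(sigsq[k])
                  - 0.5 * d * d / sigsq[k];
        if (logw[k] > maxlw) maxlw = logw[k];
      }
      double wsum = 0.0;
      for (int k = 0; k < K; ++k) {
        w[k] = std::exp(logw[k] - maxlw);
        wsum += w[k];
      }
      double u = unif_rand() * wsum, acc = 0.0;
      int zi = K - 1;
      for (int k = 0; k < K; ++k) {
        acc += w[k];
        if (u <= acc) { zi = k; break; }
      }
      z[i] = zi;
      counts[zi] += 1;
      sums[zi] += y[i];
    }
    // pi | z : Dirichlet(alpha_k + n_k)
    for (int k = 0; k < K; ++k) shape_nv[k] = alpha[k] + counts[k];
    draw_dirichlet(shape_nv, pi.data());
    // mu_k | z, sigma^2 : normal-normal update (prior when empty)
    for (int k = 0; k < K; ++k) {
      double prec = 1.0 / s0sq + counts[k] / sigsq[k];
      double m = (mu0 / s0sq + sums[k] / sigsq[k]) / prec;
      mu[k] = m + norm_rand() / std::sqrt(prec);
    }
    // sigma_k^2 | z, mu : inverse-gamma update
    std::fill(ss.begin(), ss.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double d = y[i] - mu[z[i]];
      ss[z[i]] += d * d;
    }
    for (int k = 0; k < K; ++k)
      sigsq[k] = rinvgamma(a + 0.5 * counts[k], b + 0.5 * ss[k]);

    if (it >= n_burnin && (it - n_burnin) % thin == 0) {
      int s = (it - n_burnin) / thin;
      for (int k = 0; k < K; ++k) {
        pi_out(s, k) = pi[k];
        mu_out(s, k) = mu[k];
        sig_out(s, k) = sigsq[k];
      }
    }
  }
  return List::create(_["pi"] = pi_out, _["mu"] = mu_out,
                      _["sigma_sq"] = sig_out);
}
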