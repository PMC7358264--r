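#' Fit the finite-mixture CSM model
#'
#' Samples the posterior of a K-component normal mixture on the pooled
#' cumulative outcomes via data-augmentation Gibbs: latent labels
#' `z_ij | . ~ Categorical(prob_k proportional to pi_k *
#' N(y_ij; mu_k, sigma_k^2))`, weights `pi | z ~ Dirichlet(alpha_k +
#' n_k)`, then conjugate normal / inverse-gamma updates for each
#' component's mean and variance.  Components that happen to be empty in
#' an iteration simply revert to their priors.
#'
#' No artificial ordering constraint is imposed on the components.
#' Instead, the component holding the largest Dirichlet weight is
#' initialized at the sample median and the remaining components at outer
#' quantiles of the data; with an informative majority prior such as
#' `Dirichlet(1, 8, 1)` this anchors the body label in practice.  A
#' post-hoc relabeling pass (aligning each retained draw to the
#' initialization means by nearest component mean) is available with
#' `relabel = TRUE` for diagnostics.
#'
#' @param data numeric vector of all pooled outcomes (length >= K + 1).
#' @param priors an [fmm_priors()] object.
#' @param cfg an [mcmc_config()] object.
#' @param relabel logical; run the post-hoc relabeling pass.
#' @return A list of class `csm_fmm_fit` with matrices `pi`, `mu`,
#'   `sigma_sq` (draws x K) and `posterior_mean_pi` (column means of
#'   `pi`, the E(pi_k | Y) used for body selection).
#' @seealso [select_body()], [body_predictive_limits()]
#' @export
#' @examples
#' fix <- builtin_fixture("table1")
#' fit <- fit_fmm(fix$history$outcome, cfg = mcmc_config(seed = 1))
#' fit$posterior_mean_pi
fit_fmm <- function(data, priors = fmm_priors(), cfg = mcmc_config(),
                    relabel = FALSE) {
  if (!inherits(priors, "fmm_priors"))
    stop_csm("priors must come from fmm_priors() (K >= 2; for a single",
             " component use fit_single())")
  if (!inherits(cfg, "mcmc_config"))
    stop_csm("cfg must come from mcmc_config()")
  if (!is.numeric(data) || any(!is.finite(data)))
    stop_csm("data must be finite numeric")
  K <- priors$K
  if (length(data) < K + 1L)
    stop_csm("at least K + 1 = ", K + 1, " observations are needed")

  init <- fmm_init(as.numeric(data), K, priors$dirichlet_alpha)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  draws <- gibbs_fmm_cpp(as.numeric(data), priors$dirichlet_alpha,
                         priors$mu0, priors$sigma0_sq, priors$a, priors$b,
                         init$mu, init$sigma_sq,
                         cfg$n_burnin, cfg$n_draws, cfg$thin)
  if (relabel) draws <- relabel_draws(draws, init$mu)
  structure(list(pi = draws$pi, mu = draws$mu, sigma_sq = draws$sigma_sq,
                 posterior_mean_pi = colMeans(draws$pi),
                 init = init, priors = priors, cfg = cfg,
                 n_obs = length(data)),
            class = "csm_fmm_fit")
}

# Initialization: the max-alpha component sits at the sample median, the
# others at quantiles spread over (0.1, 0.9); component variances are the
# sample variance of the nearest-mean stratum, floored at 1e-6.
fmm_init <- function(data, K, alpha) {
  probs <- if (K == 1L) 0.5 else seq(0.1, 0.9, length.out = K)
  body <- which.max(alpha)
  mid <- which.min(abs(probs - 0.5))
  if (body != mid) probs[c(body, mid)] <- probs[c(mid, body)]
  mu <- as.numeric(quantile(data, probs, names = FALSE, type = 7))
  stratum <- apply(abs(outer(data, mu, "-")), 1L, which.min)
  fallback <- max(var(data), 1e-6)
  sigma_sq <- vapply(seq_len(K), function(k) {
    v <- data[stratum == k]
    if (length(v) >= 2L) max(var(v), 1e-6) else fallback
  }, numeric(1))
  list(mu = mu, sigma_sq = sigma_sq, probs = probs)
}

# Greedy per-draw alignment of component labels to the initialization
# means (diagnostic aid; the informative majority prior usually keeps
# labels stable without it).
relabel_draws <- function(draws, ref_mu) {
  K <- length(ref_mu)
  for (s in seq_len(nrow(draws$mu))) {
    perm <- integer(K)
    taken <- rep(FALSE, K)
    for (k in order(ref_mu)) {
      d <- abs(draws$mu[s, ] - ref_mu[k])
      d[taken] <- Inf
      j <- which.min(d)
      perm[k] <- j
      taken[j] <- TRUE
    }
    draws$pi[s, ] <- draws$pi[s, perm]
    draws$mu[s, ] <- draws$mu[s, perm]
    draws$sigma_sq[s, ] <- draws$sigma_sq[s, perm]
  }
  draws
}

#' Select the body component
#'
#' Under the working assumption that normal sites are the majority, the
#' mixture component with the largest posterior-mean weight
#' `E(pi_k | Y(t))` is taken as the outcome distribution of normal sites
#' (the "body distribution").  Ties are broken deterministically by the
#' smallest component index.
#'
#' @param fit a `csm_fmm_fit`.
#' @return list with `kb` (selected component index) and `weight` (its
#'   posterior-mean weight).
#' @export
select_body <- function(fit) {
  w <- fit$posterior_mean_pi
  if (is.null(w)) stop_csm("fit has no posterior_mean_pi")
  kb <- which.max(w)  # which.max returns the first maximum: smallest index
  list(kb = as.integer(kb), weight = w[kb])
}

#' Posterior predictive critical limits under the body component
#'
#' As [single_predictive_limits()], but each predictive site-average draw
#' uses only the selected body component's parameters:
#' `N(mu_kb, sigma_kb^2 / n_current)`.  The resulting percentiles are the
#' gamma critical limits: atypical-site data influences them only through
#' the (down-weighted) body posterior, which is what makes the mixture
#' route robust to contamination.
#'
#' @param fit a `csm_fmm_fit`.
#' @param kb body component index (from [select_body()]).
#' @param n_current number of current-round patients at the site (>= 1).
#' @param alpha detection threshold in (0, 0.5).
#' @param z optional shared standard-normal draws (see
#'   [single_predictive_limits()]).
#' @return named numeric vector `c(lower, upper)`.
#' @export
body_predictive_limits <- function(fit, kb, n_current, alpha = 0.05,
                                   z = NULL) {
  K <- ncol(fit$pi)
  check_scalar_number(kb, "kb", lower = 1, upper = K)
  predictive_limits_from_draws(fit$mu[, kb], fit$sigma_sq[, kb],
                               n_current, alpha, z)
}

#' @export
print.csm_fmm_fit <- function(x, ...) {
  K <- length(x$posterior_mean_pi)
  b <- select_body(x)
  cat("Finite-mixture CSM fit: K =", K, "components,",
      nrow(x$pi), "retained draws on", x$n_obs, "outcomes\n")
  cat("  E(pi | Y) =", paste(sprintf("%.3f", x$posterior_mean_pi),
                             collapse = ", "), "\n")
  cat(sprintf("  body component kb = %d (weight %.3f), mean %.3f, sd %.3f\n",
              b$kb, b$weight, mean(x$mu[, b$kb]),
              mean(sqrt(x$sigma_sq[, b$kb]))))
  invisible(x)
}
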