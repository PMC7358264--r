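#' Priors for the single-distribution CSM model
#'
#' The single model treats all pooled outcomes as draws from one normal
#' distribution N(mu, sigma^2) with conjugate priors
#' `mu ~ N(mu0, sigma0_sq)` and `sigma^2 ~ InvGamma(a, b)`.  The
#' inverse-gamma is parameterized by shape `a` and scale `b`, density
#' proportional to `x^(-a-1) exp(-b/x)`.  Defaults are the conventional
#' noninformative choices (prior mean 0 with variance 1000;
#' InvGamma(0.1, 0.1)); `sigma0_sq` is a variance, not a standard
#' deviation.
#'
#' @param mu0 prior mean of mu.
#' @param sigma0_sq prior variance of mu (> 0).
#' @param a,b inverse-gamma shape and scale for sigma^2 (> 0).
#' @return a `single_priors` list.
#' @export
single_priors <- function(mu0 = 0, sigma0_sq = 1000, a = 0.1, b = 0.1) {
  check_scalar_number(mu0, "mu0")
  check_scalar_number(sigma0_sq, "sigma0_sq", lower = 0, strict_lower = TRUE)
  check_scalar_number(a, "a", lower = 0, strict_lower = TRUE)
  check_scalar_number(b, "b", lower = 0, strict_lower = TRUE)
  structure(list(mu0 = mu0, sigma0_sq = sigma0_sq, a = a, b = b),
            class = "single_priors")
}

#' Priors for the finite-mixture CSM model
#'
#' The mixture model writes every pooled outcome as a draw from
#' `sum_k pi_k N(mu_k, sigma_k^2)` with `(pi_1..pi_K) ~
#' Dirichlet(alpha_1..alpha_K)` and the same shared normal/inverse-gamma
#' hyperpriors on each component's mean and variance as in
#' [single_priors()].  The default `K = 3` with `Dirichlet(1, 8, 1)`
#' encodes the working assumption that normal sites are the majority while
#' allowing shifts on either side: the heavy middle weight anchors the
#' "body" component, the two light outer weights absorb low- and
#' high-shifted contamination.
#'
#' @param K number of mixture components (>= 2; use the single model for
#'   one component).
#' @param dirichlet_alpha length-K vector of positive Dirichlet
#'   concentration parameters.
#' @param mu0,sigma0_sq,a,b shared component hyperpriors, as in
#'   [single_priors()].
#' @return an `fmm_priors` list.
#' @export
fmm_priors <- function(K = 3, dirichlet_alpha = c(1, 8, 1),
                       mu0 = 0, sigma0_sq = 1000, a = 0.1, b = 0.1) {
  check_scalar_number(K, "K", lower = 2)
  K <- as.integer(K)
  if (!is.numeric(dirichlet_alpha) || length(dirichlet_alpha) != K ||
      any(!is.finite(dirichlet_alpha)) || any(dirichlet_alpha <= 0))
    stop_csm("`dirichlet_alpha` must be ", K, " positive finite numbers")
  check_scalar_number(mu0, "mu0")
  check_scalar_number(sigma0_sq, "sigma0_sq", lower = 0, strict_lower = TRUE)
  check_scalar_number(a, "a", lower = 0, strict_lower = TRUE)
  check_scalar_number(b, "b", lower = 0, strict_lower = TRUE)
  structure(list(K = K, dirichlet_alpha = as.numeric(dirichlet_alpha),
                 mu0 = mu0, sigma0_sq = sigma0_sq, a = a, b = b),
            class = "fmm_priors")
}

#' MCMC chain settings
#'
#' Defaults (2000 burn-in, 10000 retained draws, no thinning) make a
#' single fit run in well under a second while keeping the Monte Carlo
#' error of the predictive percentiles negligible at one-decimal
#' reporting.  At least `min_draws` retained draws are required so that
#' tail percentiles are estimable.
#'
#' @param n_burnin discarded warm-up iterations (>= 0).
#' @param n_draws retained posterior draws (after thinning).
#' @param thin thinning interval (>= 1).
#' @param seed optional integer seed; `NULL` continues the current RNG
#'   stream (used when a caller manages seeding, e.g. the simulator).
#' @param min_draws floor on retained draws (default 500).
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(n_burnin = 2000, n_draws = 10000, thin = 1,
                        seed = NULL, min_draws = 500) {
  check_scalar_number(n_burnin, "n_burnin", lower = 0)
  check_scalar_number(n_draws, "n_draws", lower = 1)
  check_scalar_number(thin, "thin", lower = 1)
  if (n_draws < min_draws)
    stop_csm("n_draws = ", n_draws, " is below the floor of ", min_draws,
             " retained draws needed for percentile estimation",
             " (lower `min_draws` explicitly to override)")
  if (!is.null(seed)) check_scalar_number(seed, "seed")
  structure(list(n_burnin = as.integer(n_burnin),
                 n_draws = as.integer(n_draws),
                 thin = as.integer(thin), seed = seed),
            class = "mcmc_config")
}
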