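#' Fit the single-distribution CSM model
#'
#' Pools all cumulative outcomes and samples the posterior of (mu,
#' sigma^2) under a normal likelihood with independent N(mu0, sigma0_sq)
#' and InvGamma(a, b) priors, via a two-block conjugate Gibbs sampler
#' (normal update for mu given sigma^2, inverse-gamma update for sigma^2
#' given mu).  Both full conditionals are standard, so no tuning is
#' needed.
#'
#' @param data numeric vector of all pooled outcomes (>= 2 values).
#' @param priors a [single_priors()] object.
#' @param cfg an [mcmc_config()] object.
#' @return A list of class `csm_single_fit` with `mu` and `sigma_sq`
#'   (retained draws), plus the priors and config used.
#' @seealso [single_predictive_limits()], [fit_fmm()]
#' @export
#' @examples
#' set.seed(1)
#' fit <- fit_single(rnorm(200, 5, 0.5),
#'                   cfg = mcmc_config(500, 2000, seed = 1))
#' mean(fit$mu)
fit_single <- function(data, priors = single_priors(), cfg = mcmc_config()) {
  if (!inherits(priors, "single_priors"))
    stop_csm("priors must come from single_priors()")
  if (!inherits(cfg, "mcmc_config"))
    stop_csm("cfg must come from mcmc_config()")
  if (!is.numeric(data) || any(!is.finite(data)))
    stop_csm("data must be finite numeric")
  if (length(data) < 2L)
    stop_csm("at least 2 observations are needed to fit the single model")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  draws <- gibbs_single_cpp(as.numeric(data), priors$mu0, priors$sigma0_sq,
                            priors$a, priors$b,
                            cfg$n_burnin, cfg$n_draws, cfg$thin)
  structure(list(mu = draws$mu, sigma_sq = draws$sigma_sq,
                 priors = priors, cfg = cfg, n_obs = length(data)),
            class = "csm_single_fit")
}

#' Posterior predictive critical limits under the single model
#'
#' For each retained posterior draw (mu, sigma^2) one predictive draw of a
#' site average of `n_current` patients is generated as
#' `N(mu, sigma^2 / n_current)`; the empirical `100*alpha`-th and
#' `100*(1-alpha)`-th percentiles of those draws are the lower and upper
#' critical limits (lambda).  Percentiles use linear interpolation between
#' order statistics (quantile type 7).
#'
#' @param fit a `csm_single_fit`.
#' @param n_current number of current-round patients at the site (>= 1).
#' @param alpha detection threshold in (0, 0.5); default 0.05.
#' @param z optional vector of standard-normal draws, one per retained
#'   posterior draw, to be shared across sites within a round so that
#'   sites with equal `n_current` get identical limits.  Drawn internally
#'   when `NULL`.
#' @return named numeric vector `c(lower, upper)`.
#' @export
single_predictive_limits <- function(fit, n_current, alpha = 0.05, z = NULL) {
  predictive_limits_from_draws(fit$mu, fit$sigma_sq, n_current, alpha, z)
}

# Shared predictive-percentile kernel for both models.
predictive_limits_from_draws <- function(mu, sigma_sq, n_current, alpha, z) {
  if (length(mu) == 0L) stop_csm("posterior draws are empty")
  check_scalar_number(n_current, "n_current", lower = 1)
  check_scalar_number(alpha, "alpha", lower = 0, upper = 0.5,
                      strict_lower = TRUE)
  if (alpha >= 0.5) stop_csm("`alpha` must be < 0.5")
  if (is.null(z)) z <- rnorm(length(mu))
  if (length(z) != length(mu))
    stop_csm("`z` must have one standard-normal draw per posterior draw")
  pred <- mu + sqrt(sigma_sq / n_current) * z
  q <- quantile(pred, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' @export
print.csm_single_fit <- function(x, ...) {
  cat("Single-distribution CSM fit:", length(x$mu), "retained draws on",
      x$n_obs, "outcomes\n")
  cat(sprintf("  posterior mean mu = %.3f, sigma = %.3f\n",
              mean(x$mu), mean(sqrt(x$sigma_sq))))
  invisible(x)
}
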