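#' Moments of the contaminated site-average distribution
#'
#' When a fraction `r` of patients come from atypical sites whose
#' outcomes are shifted by `delta`, a single-distribution model fitted to
#' the pooled data is pulled toward the contaminated distribution.
#' Matching first and second moments, the average of `n` patient outcomes
#' is modeled as normal with mean `mu + r * delta` and, in the form used
#' for the worked value here, variance
#' `(sigma_sq + r * (1 - r) * delta^2 * sigma_sq) / n`.
#'
#' The exact two-component moment-matching variance of the mixture is
#' `(sigma_sq + r * (1 - r) * delta^2) / n`; the two coincide when
#' `sigma_sq = 1` (the default working case).  Set `exact = TRUE` for the
#' moment-matching form.  `r = 0` is accepted and returns the
#' uncontaminated `(mu, sigma_sq / n)`.
#'
#' @param r ratio of patients from atypical sites, in \[0, 1\].
#' @param delta location shift of atypical-site outcomes.
#' @param mu normal-site mean.
#' @param sigma_sq outcome variance (> 0).
#' @param n number of patients averaged (>= 1).
#' @param exact logical; use the exact mixture moment-matching variance.
#' @return named numeric vector `c(mean, variance)` of the site-average
#'   distribution.
#' @export
#' @examples
#' contaminated_moments(r = 0.2, delta = 1, mu = 0, sigma_sq = 1, n = 5)
#' # mean 0.2, variance 0.232
contaminated_moments <- function(r, delta = 0, mu = 0, sigma_sq = 1, n = 1,
                                 exact = FALSE) {
  check_scalar_number(r, "r", lower = 0, upper = 1)
  check_scalar_number(delta, "delta")
  check_scalar_number(mu, "mu")
  check_scalar_number(sigma_sq, "sigma_sq", lower = 0, strict_lower = TRUE)
  check_scalar_number(n, "n", lower = 1)
  if (r == 0) {
    # normal-only branch: no contamination
    return(c(mean = mu, variance = sigma_sq / n))
  }
  excess <- r * (1 - r) * delta^2 * (if (exact) 1 else sigma_sq)
  c(mean = mu + r * delta, variance = (sigma_sq + excess) / n)
}
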