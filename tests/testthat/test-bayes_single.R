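test_that("single-model posterior recovers simulating truth", {
  set.seed(10)
  y <- rnorm(5000, mean = 3, sd = 2)
  fit <- fit_single(y, cfg = mcmc_config(seed = 11))
  expect_lt(abs(mean(fit$mu) - 3), 0.1)
  expect_lt(abs(mean(sqrt(fit$sigma_sq)) - 2), 0.1)
})

test_that("posterior mean of mu matches the conjugate closed form", {
  # pin sigma^2 at 4 with a near-degenerate inverse-gamma prior, then the
  # normal-normal update gives the posterior mean of mu in closed form
  set.seed(12)
  y <- rnorm(40, 1, 2)
  s2 <- 4
  pr <- single_priors(mu0 = -1, sigma0_sq = 0.5,
                      a = 1e7, b = (1e7 + 1) * s2)
  fit <- fit_single(y, pr, mcmc_config(seed = 13))
  expect_lt(abs(mean(fit$sigma_sq) - s2), 0.01)
  n <- length(y)
  closed_form <- (pr$mu0 / pr$sigma0_sq + n * mean(y) / s2) /
    (1 / pr$sigma0_sq + n / s2)
  expect_lt(abs(mean(fit$mu) - closed_form), 0.02)
})

test_that("a near-zero-variance prior on mu dominates the data", {
  set.seed(14)
  fit <- fit_single(rnorm(50, 5), single_priors(mu0 = -2, sigma0_sq = 1e-10),
                    quick_mcmc(seed = 15))
  expect_lt(max(abs(fit$mu - (-2))), 0.01)
})

test_that("predictive limits reduce to normal quantiles for degenerate draws", {
  fit <- structure(list(mu = rep(0, 20000), sigma_sq = rep(1, 20000)),
                   class = "csm_single_fit")
  set.seed(16)
  lim <- single_predictive_limits(fit, n_current = 1, alpha = 0.05)
  expect_equal(unname(lim), c(-1.645, 1.645), tolerance = 0.03)
  lim4 <- single_predictive_limits(fit, n_current = 4, alpha = 0.05)
  expect_equal(unname(lim4), c(-0.8224, 0.8224), tolerance = 0.03)
  expect_error(single_predictive_limits(fit, n_current = 0), "n_current")
})

test_that("limits widen monotonically as the current count shrinks", {
  set.seed(17)
  fit <- fit_single(rnorm(100), cfg = quick_mcmc(seed = 18))
  z <- rnorm(length(fit$mu))
  widths <- vapply(2:10, function(n) {
    lim <- single_predictive_limits(fit, n, 0.05, z)
    expect_lt(lim[["lower"]], lim[["upper"]])
    lim[["upper"]] - lim[["lower"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # larger alpha gives a narrower interval on the same draws
  lim05 <- single_predictive_limits(fit, 3, 0.05, z)
  lim20 <- single_predictive_limits(fit, 3, 0.20, z)
  expect_gt(lim20[["lower"]], lim05[["lower"]])
  expect_lt(lim20[["upper"]], lim05[["upper"]])
})

test_that("predictive percentiles converge to the scale-mixture quantiles", {
  # frozen tiny posterior sample; the exact predictive CDF is the average
  # of normal CDFs, inverted numerically as an independent oracle
  mus <- c(-0.2, 0.0, 0.1, 0.4, 0.25)
  s2s <- c(0.8, 1.1, 0.9, 1.4, 1.0)
  n_cur <- 3
  cdf <- function(x) mean(stats::pnorm(x, mus, sqrt(s2s / n_cur)))
  oracle_q <- function(p)
    stats::uniroot(function(x) cdf(x) - p, c(-10, 10), tol = 1e-9)$root
  reps <- 40000
  fit <- structure(list(mu = rep(mus, reps), sigma_sq = rep(s2s, reps)),
                   class = "csm_single_fit")
  set.seed(19)
  lim <- single_predictive_limits(fit, n_cur, alpha = 0.05)
  expect_equal(lim[["lower"]], oracle_q(0.05), tolerance = 0.02)
  expect_equal(lim[["upper"]], oracle_q(0.95), tolerance = 0.02)
})

test_that("single fit validates its inputs", {
  expect_error(fit_single(c(1)), "at least 2")
  expect_error(fit_single(c(1, NA, 2)), "finite")
  expect_error(mcmc_config(n_draws = 100), "floor")
  expect_silent(mcmc_config(n_draws = 100, min_draws = 50))
})
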