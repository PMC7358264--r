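test_that("mixture weight draws live on the simplex", {
  fix <- builtin_fixture("table1")
  fit <- fit_fmm(fix$history$outcome, cfg = quick_mcmc(seed = 21))
  expect_true(all(abs(rowSums(fit$pi) - 1) < 1e-10))
  expect_true(all(fit$sigma_sq > 0))
  expect_equal(fit$posterior_mean_pi, colMeans(fit$pi))
})

test_that("the Dirichlet conditional update matches its conjugate closed form", {
  # frozen labels (0, 10, 0) with prior (1, 8, 1): conditional posterior
  # mean of pi is (alpha_k + n_k) / (sum(alpha) + n) = (1, 18, 1) / 20
  alpha <- c(1, 8, 1)
  counts <- c(0, 10, 0)
  closed <- (alpha + counts) / (sum(alpha) + sum(counts))
  expect_equal(closed, c(0.05, 0.9, 0.05))
  set.seed(22)
  draws <- fmmcsm:::rdirichlet_cpp(alpha + counts, 40000)
  expect_true(all(abs(rowSums(draws) - 1) < 1e-10))
  # MC error of each mean is ~sqrt(p(1-p)/(c+1))/sqrt(n) < 0.0005
  expect_equal(colMeans(draws), closed, tolerance = 0.005)
})

test_that("mixture fit recovers uncontaminated simulating truth", {
  set.seed(23)
  y <- rnorm(2000)
  fit <- fit_fmm(y, cfg = mcmc_config(1000, 4000, seed = 24))
  b <- select_body(fit)
  expect_lt(abs(mean(fit$mu[, b$kb])), 0.1)
  expect_gt(b$weight, 0.8)
})

test_that("body selection takes the largest posterior-mean weight", {
  fake <- function(w) structure(list(posterior_mean_pi = w),
                                class = "csm_fmm_fit")
  expect_equal(select_body(fake(c(0.036, 0.926, 0.037)))$kb, 2L)
  expect_equal(select_body(fake(c(0.5, 0.3, 0.2)))$kb, 1L)
  # exact tie: deterministic smallest index
  expect_equal(select_body(fake(c(1, 1, 1) / 3))$kb, 1L)
})

test_that("body predictive limits reduce to normal quantiles when degenerate", {
  m <- 20000
  fit <- structure(list(pi = matrix(1 / 3, m, 3),
                        mu = matrix(5, m, 3),
                        sigma_sq = matrix(0.04, m, 3),
                        posterior_mean_pi = rep(1 / 3, 3)),
                   class = "csm_fmm_fit")
  set.seed(25)
  lim <- body_predictive_limits(fit, kb = 1, n_current = 4, alpha = 0.05)
  expect_equal(unname(lim), c(5 - 1.645 * 0.1, 5 + 1.645 * 0.1),
               tolerance = 0.01)
  expect_error(body_predictive_limits(fit, kb = 4, n_current = 1), "kb")
})

test_that("relabeling preserves the per-draw parameter sets", {
  fix <- builtin_fixture("table1")
  fit <- fit_fmm(fix$history$outcome, cfg = quick_mcmc(seed = 26))
  fit_r <- fit_fmm(fix$history$outcome, cfg = quick_mcmc(seed = 26),
                   relabel = TRUE)
  # rows are permutations of one another: sorted parameter values agree
  expect_equal(t(apply(fit_r$mu, 1, sort)), t(apply(fit$mu, 1, sort)))
  expect_true(all(abs(rowSums(fit_r$pi) - 1) < 1e-10))
})

test_that("mixture fit validates inputs and rejects K < 2", {
  expect_error(fmm_priors(K = 1), "K")
  expect_error(fmm_priors(K = 3, dirichlet_alpha = c(1, 8)), "dirichlet")
  expect_error(fit_fmm(c(1, 2, 3)), "at least K \\+ 1")
})

test_that("sampler agrees with an independent JAGS fit of the same model", {
  library(rjags)
  set.seed(3)
  y <- c(rnorm(26), rnorm(6, 2))
  fit <- fit_fmm(y, cfg = mcmc_config(seed = 1))
  model_str <- "
  model {
    for (i in 1:n) {
      z[i] ~ dcat(pi[])
      y[i] ~ dnorm(mu[z[i]], tau[z[i]])
    }
    pi ~ ddirch(alpha)
    for (k in 1:3) {
      mu[k] ~ dnorm(0, 0.001)
      tau[k] ~ dgamma(0.1, 0.1)
    }
  }"
  jm <- jags.model(textConnection(model_str),
                   data = list(y = y, n = length(y), alpha = c(1, 8, 1)),
                   inits = list(mu = c(-1, 0, 2), tau = rep(1, 3),
                                .RNG.name = "base::Mersenne-Twister",
                                .RNG.seed = 7),
                   n.chains = 1, quiet = TRUE)
  update(jm, 2000)
  s <- as.matrix(coda.samples(jm, c("pi", "mu"), 10000))
  jags_pi <- colMeans(s[, paste0("pi[", 1:3, "]")])
  expect_equal(unname(fit$posterior_mean_pi), unname(jags_pi),
               tolerance = 0.05)
  kb <- select_body(fit)$kb
  jags_body_mu <- mean(s[, paste0("mu[", which.max(jags_pi), "]")])
  expect_lt(abs(mean(fit$mu[, kb]) - jags_body_mu), 0.1)
})
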