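test_that("flagging uses strict inequalities against the limits", {
  expect_true(flag_site(6.1, 4.9, 5.9))
  expect_false(flag_site(5.5, 5.0, 5.7))
  expect_false(flag_site(5.9, 4.9, 5.9))  # boundary does not flag
  expect_false(flag_site(4.9, 4.9, 5.9))
  expect_error(flag_site(1, 2, 2), "lower")
})

test_that("round 1 of the worked example flags exactly site 5", {
  fix <- builtin_fixture("table1")
  set.seed(31)
  dec <- run_round(fix$history, 1, detection_config("fmm"))
  expect_equal(dec$site_id[dec$flagged], 5L)
  expect_equal(nrow(dec), 5L)
  # equal current counts share one predictive stream: identical limits
  expect_equal(dec$lower[dec$site_id == 3], dec$lower[dec$site_id == 4])
  expect_equal(dec$upper[dec$site_id == 3], dec$upper[dec$site_id == 4])
  expect_gt(attr(dec, "body_weight"), 0.85)
})

test_that("round 2 of the worked example flags no site", {
  fix <- builtin_fixture("table1_2")
  set.seed(32)
  dec <- run_round(fix$history, 2, detection_config("fmm"))
  expect_equal(sum(dec$flagged), 0L)
})

test_that("an extreme alpha leaves nothing flagged", {
  fix <- builtin_fixture("table1")
  set.seed(33)
  dec <- run_round(fix$history, 1,
                   detection_config("fmm", alpha = 1e-6,
                                    mcmc = quick_mcmc()))
  expect_false(any(dec$flagged))
})

test_that("flags are monotone in alpha on shared posterior draws", {
  fix <- builtin_fixture("table1")
  fit <- fit_fmm(fix$history$outcome, cfg = quick_mcmc(seed = 34))
  kb <- select_body(fit)$kb
  set.seed(35)
  z <- rnorm(600)
  rd <- partition_rounds(fix$history, 1)
  for (i in 1:5) {
    avg <- site_average(rd$current_by_site[[i]])
    n_i <- rd$current_counts[[i]]
    lim1 <- body_predictive_limits(fit, kb, n_i, 0.02, z)
    lim2 <- body_predictive_limits(fit, kb, n_i, 0.10, z)
    f1 <- flag_site(avg, lim1[["lower"]], lim1[["upper"]])
    f2 <- flag_site(avg, lim2[["lower"]], lim2[["upper"]])
    expect_true(!f1 || f2)  # flagged at small alpha => flagged at larger
  }
})

test_that("full monitoring run reproduces the worked-example flag set", {
  fix <- builtin_fixture("table1_2")
  rep <- run_monitoring(fix$history, detection_config("fmm"), seed = 36)
  flg <- rep$decisions[rep$decisions$flagged, ]
  expect_equal(nrow(flg), 1L)
  expect_equal(flg$site_id, 5L)
  expect_equal(flg$round, 1L)
  expect_equal(nrow(rep$decisions), 10L)  # 5 sites x 2 rounds, all with data
  expect_length(rep$body_weights_by_round, 2L)
  # deterministic given the seed
  rep2 <- run_monitoring(fix$history, detection_config("fmm"), seed = 36)
  expect_identical(rep$decisions, rep2$decisions)
})

test_that("single-method monitoring produces a structurally complete report", {
  fix <- builtin_fixture("table1_2")
  rep <- run_monitoring(fix$history,
                        detection_config("single", mcmc = quick_mcmc()),
                        seed = 37)
  expect_equal(nrow(rep$decisions), 10L)
  expect_null(rep$body_weights_by_round)
  expect_true(all(rep$decisions$lower < rep$decisions$upper))
})

test_that("a single-round history yields one decision per site with data", {
  set.seed(38)
  h <- random_history(M = 6, T = 1)
  rep <- run_monitoring(h, detection_config("single", mcmc = quick_mcmc()),
                        seed = 39)
  with_data <- sum(partition_rounds(h, 1)$current_counts >= 1)
  expect_equal(nrow(rep$decisions), with_data)
})
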