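test_that("enrollment waves are equal and multinomially assigned", {
  cfg <- scenario_config(n_total = 48, n_rounds = 3)
  set.seed(41)
  counts <- simulate_enrollment(cfg)
  expect_equal(dim(counts), c(3L, 10L))
  expect_equal(unname(rowSums(counts)), c(16, 16, 16))
  expect_equal(sum(counts), 48)
  # degenerate probabilities put every patient at site 1
  cfg1 <- scenario_config(n_total = 48, enrollment_probs = c(1, rep(0, 9)))
  expect_equal(unname(simulate_enrollment(cfg1)[, 1]), c(16, 16, 16))
  # reproducibility under a fixed seed
  set.seed(42); a <- simulate_enrollment(cfg)
  set.seed(42); b <- simulate_enrollment(cfg)
  expect_identical(a, b)
  expect_error(scenario_config(n_total = 50, n_rounds = 3), "divisible")
})

test_that("outcome generation follows the site-state distributions", {
  cfg <- scenario_config(n_total = 48, atypical_shifts = c("2" = 2))
  states <- fmmcsm:::initial_site_states(cfg)
  big <- c(1e5, 1e5, rep(0, 8))
  set.seed(43)
  g <- generate_round_outcomes(big, states)
  y1 <- g$records$outcome[g$records$site_id == 1]
  y2 <- g$records$outcome[g$records$site_id == 2]
  expect_lt(abs(mean(y1)), 3 / sqrt(1e5))
  expect_lt(abs(mean(y2) - 2), 3 / sqrt(1e5))
  # corrected atypical sites revert to the normal distribution
  states$corrected[2] <- TRUE
  g2 <- generate_round_outcomes(big, states, round = 2L,
                                next_patient_id = g$next_patient_id)
  expect_lt(abs(mean(g2$records$outcome[g2$records$site_id == 2])),
            3 / sqrt(1e5))
  # patient ids continue across calls
  expect_equal(min(g2$records$patient_id[g2$records$site_id == 1]),
               1e5 + 1)
})

test_that("a replicate conserves records and keeps correction absorbing", {
  cfg <- scenario_config(n_total = 24, n_sites = 6,
                         enrollment_probs = rep(1 / 6, 6),
                         atypical_shifts = c("1" = 3))
  dcfg <- detection_config("fmm", mcmc = quick_mcmc())
  out <- run_replicate(cfg, dcfg, seed = 44)
  expect_equal(nrow(out$history), 24L)
  expect_equal(dim(out$flags), c(6L, 3L))
  expect_equal(out$truth$is_atypical, c(TRUE, rep(FALSE, 5)))
  if (!is.na(out$corrected_round[1])) {
    t0 <- out$corrected_round[1]
    # once corrected, later rounds of site 1 are N(0,1)-generated; its
    # post-correction sample mean should not carry the +3 shift
    post <- out$history$outcome[out$history$site_id == 1 &
                                  out$history$round > t0]
    if (length(post) >= 2) expect_lt(mean(post), 2)
  }
  expect_true(all(is.na(out$corrected_round[2:6])))
})

test_that("with no shifts and tiny alpha a replicate raises no flags", {
  cfg <- scenario_config(n_total = 24, n_sites = 4,
                         enrollment_probs = rep(0.25, 4))
  dcfg <- detection_config("single", alpha = 1e-6, mcmc = quick_mcmc())
  out <- run_replicate(cfg, dcfg, seed = 45)
  expect_false(any(out$flags))
  expect_true(all(!out$truth$is_atypical))
})

test_that("an undetectable atypical site stays shifted throughout", {
  cfg <- scenario_config(n_total = 24, n_sites = 4,
                         enrollment_probs = rep(0.25, 4),
                         atypical_shifts = c("3" = 2))
  dcfg <- detection_config("single", alpha = 1e-6, mcmc = quick_mcmc())
  out <- run_replicate(cfg, dcfg, seed = 46)
  expect_true(is.na(out$corrected_round[3]))
  y3 <- out$history$outcome[out$history$site_id == 3]
  expect_gt(mean(y3), 0.5)  # every round still carries the +2 shift
})
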