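#' Simulation scenario configuration
#'
#' Defines the ground truth of a simulated multicenter trial: a planned
#' total of `n_total` patients enrolled over `n_rounds` equally sized
#' monitoring waves across `n_sites` sites, with site assignment
#' multinomial under `enrollment_probs`.  Outcomes at normal (and
#' corrected) sites are `N(mu_normal, outcome_sd^2)`; an uncorrected
#' atypical site's outcomes are shifted by its entry in
#' `atypical_shifts`.  The defaults — ten sites with equal enrollment
#' probability 1/10, three rounds, unit outcome standard deviation and a
#' small-trial total of 48 patients — are the reference small-trial
#' study conditions.
#'
#' @param n_total planned number of patients at the final analysis; must
#'   be divisible by `n_rounds` (each round enrolls an equal wave).
#' @param n_sites number of sites M.
#' @param enrollment_probs length-M probabilities summing to 1.
#' @param n_rounds number of monitoring rounds T.
#' @param atypical_shifts named numeric vector mapping site id to its
#'   location shift Delta; sites absent from it are normal (Delta = 0).
#' @param mu_normal normal-site outcome mean.
#' @param outcome_sd outcome standard deviation (> 0).
#' @param seed optional master seed used by [evaluate_scenario()].
#' @param n_reps default number of simulation replicates.
#' @return a `csm_scenario` list.
#' @export
#' @examples
#' scenario_config(atypical_shifts = c("10" = 2))
scenario_config <- function(n_total = 48, n_sites = 10,
                            enrollment_probs = rep(1 / n_sites, n_sites),
                            n_rounds = 3, atypical_shifts = numeric(),
                            mu_normal = 0, outcome_sd = 1,
                            seed = NULL, n_reps = 100) {
  check_scalar_number(n_total, "n_total", lower = 1)
  check_scalar_number(n_sites, "n_sites", lower = 2)
  check_scalar_number(n_rounds, "n_rounds", lower = 1)
  check_scalar_number(outcome_sd, "outcome_sd", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(mu_normal, "mu_normal")
  check_scalar_number(n_reps, "n_reps", lower = 1)
  if (n_total %% n_rounds != 0)
    stop_csm("n_total = ", n_total, " must be divisible by n_rounds = ",
             n_rounds, " (each round enrolls an equal wave)")
  if (length(enrollment_probs) != n_sites ||
      any(enrollment_probs < 0) ||
      abs(sum(enrollment_probs) - 1) > 1e-8)
    stop_csm("enrollment_probs must be ", n_sites,
             " nonnegative values summing to 1")
  if (length(atypical_shifts)) {
    ids <- as.integer(names(atypical_shifts))
    if (anyNA(ids) || any(ids < 1) || any(ids > n_sites))
      stop_csm("atypical_shifts names must be site ids in 1..", n_sites)
    if (!is.numeric(atypical_shifts) || any(!is.finite(atypical_shifts)))
      stop_csm("atypical_shifts values must be finite shifts")
  }
  if (!is.null(seed)) check_scalar_number(seed, "seed")
  structure(list(n_total = as.integer(n_total),
                 n_sites = as.integer(n_sites),
                 enrollment_probs = as.numeric(enrollment_probs),
                 n_rounds = as.integer(n_rounds),
                 atypical_shifts = atypical_shifts,
                 mu_normal = mu_normal, outcome_sd = outcome_sd,
                 seed = seed, n_reps = as.integer(n_reps)),
            class = "csm_scenario")
}

# Initial latent state table for a scenario.
initial_site_states <- function(cfg) {
  shift <- rep(0, cfg$n_sites)
  if (length(cfg$atypical_shifts))
    shift[as.integer(names(cfg$atypical_shifts))] <- cfg$atypical_shifts
  tibble::tibble(site_id = seq_len(cfg$n_sites),
                 is_atypical = shift != 0,
                 corrected = FALSE,
                 shift = shift)
}

#' Simulate per-round enrollment counts
#'
#' Each round enrolls exactly `n_total / n_rounds` patients; each patient
#' is assigned to a site by a multinomial draw with
#' `enrollment_probs`.  A site may receive zero patients in a round, in
#' which case detection skips it that round.
#'
#' @param cfg a [scenario_config()].
#' @return integer matrix, `n_rounds` x `n_sites`.
#' @export
simulate_enrollment <- function(cfg) {
  if (!inherits(cfg, "csm_scenario"))
    stop_csm("cfg must come from scenario_config()")
  per_round <- cfg$n_total %/% cfg$n_rounds
  t(rmultinom(cfg$n_rounds, per_round, cfg$enrollment_probs))
}

#' Generate one round of patient outcomes
#'
#' Outcomes are `N(mu_normal, sd^2)` at normal and corrected sites and
#' `N(mu_normal + shift, sd^2)` at uncorrected atypical sites.  When a
#' matrix of pre-drawn standard-normal variates is supplied (`z`), the
#' outcome is `mu + shift + sd * z`, which lets different monitoring
#' methods be compared on a common random-number stream.
#'
#' @param counts integer vector of per-site patient counts for the round.
#' @param states site-state tibble (`site_id`, `is_atypical`,
#'   `corrected`, `shift`).
#' @param mu_normal,sd outcome distribution of normal sites.
#' @param round round index recorded on the generated rows.
#' @param next_patient_id per-site counter of the next free patient id.
#' @param z optional list of per-site standard-normal vectors (lengths
#'   matching `counts`).
#' @return list with `records` (tibble of PatientRecord rows) and the
#'   updated `next_patient_id`.
#' @export
generate_round_outcomes <- function(counts, states, mu_normal = 0, sd = 1,
                                    round = 1L,
                                    next_patient_id = rep(1L, length(counts)),
                                    z = NULL) {
  M <- length(counts)
  recs <- vector("list", M)
  for (i in seq_len(M)) {
    c_i <- counts[i]
    if (c_i == 0L) next
    zi <- if (is.null(z)) rnorm(c_i) else z[[i]]
    shift <- if (states$is_atypical[i] && !states$corrected[i])
      states$shift[i] else 0
    recs[[i]] <- tibble::tibble(
      site_id = i,
      patient_id = seq.int(next_patient_id[i], length.out = c_i),
      round = as.integer(round),
      outcome = mu_normal + shift + sd * zi)
    next_patient_id[i] <- next_patient_id[i] + c_i
  }
  list(records = do.call(rbind, recs[!vapply(recs, is.null, logical(1))]),
       next_patient_id = next_patient_id)
}

#' Run one simulated monitoring replicate
#'
#' Interleaves outcome generation and detection round by round: generate
#' the round-t wave under the current site states, run detection on the
#' cumulative data, then mark flagged uncorrected atypical sites as
#' corrected before the next round (the corrective action: their
#' subsequent outcomes are drawn from the normal-site distribution).
#' Correction is absorbing.  False flags on truly normal sites change
#' nothing (those sites are already normal).
#'
#' All enrollment counts and outcome variates are pre-drawn immediately
#' after seeding, before any MCMC runs, so two methods called with the
#' same `seed` see identical potential outcomes (common random numbers).
#'
#' @param cfg a [scenario_config()].
#' @param detection_cfg a [detection_config()].
#' @param seed optional integer seed for this replicate.
#' @return list with `flags` (`n_sites` x `n_rounds` logical matrix;
#'   sites without data in a round are `FALSE`), `truth` (initial state
#'   tibble), `corrected_round` (first round after which each site was
#'   corrected, `NA` if never), and `history` (the generated
#'   `csm_history`).
#' @export
run_replicate <- function(cfg, detection_cfg = detection_config(),
                          seed = NULL) {
  if (!inherits(cfg, "csm_scenario"))
    stop_csm("cfg must come from scenario_config()")
  if (!is.null(seed)) set.seed(seed)
  detection_cfg$mcmc$seed <- NULL

  counts <- simulate_enrollment(cfg)
  z <- lapply(seq_len(cfg$n_rounds), function(t)
    lapply(seq_len(cfg$n_sites), function(i) rnorm(counts[t, i])))

  states <- initial_site_states(cfg)
  truth <- states
  flags <- matrix(FALSE, cfg$n_sites, cfg$n_rounds,
                  dimnames = list(site = NULL, round = NULL))
  corrected_round <- rep(NA_integer_, cfg$n_sites)
  next_id <- rep(1L, cfg$n_sites)
  records <- NULL

  for (t in seq_len(cfg$n_rounds)) {
    gen <- generate_round_outcomes(counts[t, ], states, cfg$mu_normal,
                                   cfg$outcome_sd, t, next_id, z[[t]])
    next_id <- gen$next_patient_id
    records <- rbind(records, gen$records)
    history <- trial_history(records, n_sites = cfg$n_sites, n_rounds = t)
    dec <- run_round(history, t, detection_cfg)
    flags[dec$site_id, t] <- dec$flagged
    newly <- which(flags[, t] & states$is_atypical & !states$corrected)
    if (length(newly)) {
      states$corrected[newly] <- TRUE
      corrected_round[newly] <- t
    }
  }
  list(flags = flags, truth = truth, corrected_round = corrected_round,
       history = trial_history(records, n_sites = cfg$n_sites,
                               n_rounds = cfg$n_rounds))
}
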