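#' Cumulative (running-OR) flags
#'
#' Converts per-round flags into "flagged at least once by round t":
#' entry (.., t) is the OR of the flags over rounds 1..t.  Accepts a
#' sites x rounds logical matrix or a reps x sites x rounds array.
#'
#' @param flags logical matrix or 3-d array with rounds as the last
#'   dimension.
#' @return object of the same shape with the running OR applied.
#' @export
#' @examples
#' cumulative_flags(matrix(c(FALSE, TRUE, FALSE), 1))  # F T T
cumulative_flags <- function(flags) {
  if (is.matrix(flags)) {
    t(apply(flags, 1L, function(r) cummax(r) > 0))
  } else if (length(dim(flags)) == 3L) {
    aperm(apply(flags, c(1L, 2L), function(r) cummax(r) > 0), c(2L, 3L, 1L))
  } else {
    stop_csm("flags must be a sites x rounds matrix or reps x sites x",
             " rounds array")
  }
}

#' Monte Carlo standard error of an estimated probability
#'
#' Binomial standard error of a simulated probability:
#' `sqrt(p_hat * (1 - p_hat) / n_sim)` for a per-site cumulative
#' detection probability, with an additional division by `n_normal`
#' inside the root for a type-I error averaged over `n_normal` normal
#' sites.
#'
#' @param p_hat estimated probability in \[0, 1\].
#' @param n_sim number of simulation replicates.
#' @param n_normal number of normal sites averaged over, or `NULL` for
#'   the per-site version.
#' @return standard error.
#' @export
#' @examples
#' mc_standard_error(0.728, 1000)  # 0.01407
mc_standard_error <- function(p_hat, n_sim, n_normal = NULL) {
  check_scalar_number(p_hat, "p_hat", lower = 0, upper = 1)
  check_scalar_number(n_sim, "n_sim", lower = 1)
  denom <- n_sim
  if (!is.null(n_normal)) {
    check_scalar_number(n_normal, "n_normal", lower = 1)
    denom <- n_sim * n_normal
  }
  sqrt(p_hat * (1 - p_hat) / denom)
}

#' Evaluate detection methods on a simulated scenario
#'
#' Runs [run_replicate()] `n_reps` times for each supplied detection
#' configuration and computes the two study metrics: the cumulative
#' detection probability of each truly atypical site (fraction of
#' replicates in which it has been flagged at least once by round t) and
#' the cumulative type I error averaged over the truly normal sites,
#' each with its Monte Carlo standard error.  The methods are compared on
#' identical simulated data streams per replicate (common random
#' numbers), which sharpens method contrasts.
#'
#' @param cfg a [scenario_config()]; `cfg$seed` (or `seed`) drives the
#'   per-replicate seed stream.
#' @param detection_cfgs named list of [detection_config()] objects
#'   (names become the `method` labels; unnamed lists fall back to each
#'   config's `method` field).
#' @param n_reps number of replicates (default `cfg$n_reps`).
#' @param seed master seed; overrides `cfg$seed`.
#' @return A list of class `csm_eval`: `site` (tibble: method, site_id,
#'   round, role, prob, se, n_reps), `type1_avg` (tibble: method, round,
#'   avg_type1, se, n_normal, n_reps), and `flags` (per-method
#'   reps x sites x rounds cumulative flag arrays).
#' @export
evaluate_scenario <- function(cfg, detection_cfgs = list(
                                fmm = detection_config("fmm"),
                                single = detection_config("single")),
                              n_reps = cfg$n_reps, seed = cfg$seed) {
  if (!inherits(cfg, "csm_scenario"))
    stop_csm("cfg must come from scenario_config()")
  if (inherits(detection_cfgs, "detection_config"))
    detection_cfgs <- list(detection_cfgs)
  nm <- names(detection_cfgs)
  if (is.null(nm) || any(nm == ""))
    names(detection_cfgs) <- vapply(detection_cfgs, `[[`, "", "method")
  check_scalar_number(n_reps, "n_reps", lower = 1)

  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)

  truth <- initial_site_states(cfg)
  M <- cfg$n_sites
  Tn <- cfg$n_rounds

  cumflags <- lapply(detection_cfgs, function(dcfg) {
    arr <- array(FALSE, c(n_reps, M, Tn))
    for (r in seq_len(n_reps))
      arr[r, , ] <- run_replicate(cfg, dcfg, seed = rep_seeds[r])$flags
    cumulative_flags(arr)
  })

  site_rows <- list()
  avg_rows <- list()
  normal <- which(!truth$is_atypical)
  for (m in names(cumflags)) {
    cf <- cumflags[[m]]
    prob <- apply(cf, c(2L, 3L), mean)  # sites x rounds
    for (t in seq_len(Tn)) {
      p_t <- prob[, t]
      site_rows[[length(site_rows) + 1L]] <- tibble::tibble(
        method = m, site_id = seq_len(M), round = t,
        role = ifelse(truth$is_atypical, "atypical", "normal"),
        prob = p_t,
        se = vapply(p_t, mc_standard_error, numeric(1), n_sim = n_reps),
        n_reps = as.integer(n_reps))
      if (length(normal)) {
        p_avg <- mean(prob[normal, t])
        avg_rows[[length(avg_rows) + 1L]] <- tibble::tibble(
          method = m, round = t, avg_type1 = p_avg,
          se = mc_standard_error(p_avg, n_reps, length(normal)),
          n_normal = length(normal), n_reps = as.integer(n_reps))
      }
    }
  }
  structure(list(site = do.call(rbind, site_rows),
                 type1_avg = do.call(rbind, avg_rows),
                 flags = cumflags, scenario = cfg),
            class = "csm_eval")
}

#' @export
print.csm_eval <- function(x, digits = 3, ...) {
  cat("Scenario evaluation:", max(x$site$n_reps), "replicates,",
      x$scenario$n_total, "patients,", x$scenario$n_rounds, "rounds\n")
  at <- x$site[x$site$role == "atypical", ]
  if (nrow(at)) {
    cat("Cumulative detection probability (atypical sites):\n")
    print(as.data.frame(at[, c("method", "site_id", "round", "prob", "se")]),
          digits = digits, row.names = FALSE)
  }
  cat("Cumulative type I error averaged over normal sites:\n")
  print(as.data.frame(x$type1_avg), digits = digits, row.names = FALSE)
  invisible(x)
}
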