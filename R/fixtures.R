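# Built-in worked example: a five-site trial monitored twice, 38 patients
# in total, with one atypical site (site 5) at round 1 that is corrected
# after detection.  Data and expected report fragments are stored
# digit-for-digit as published in the worked-example tables.

table1_outcomes <- list(
  `1` = c(5.2, 4.8),
  `2` = c(5.5, 5.2, 5.0),
  `3` = c(4.7, 5.5, 5.5, 5.0, 5.8),
  `4` = c(5.1, 5.0, 6.0, 4.8, 5.6),
  `5` = c(6.3, 5.3, 6.5, 6.2))

table2_outcomes <- list(
  `1` = c(5.1, 5.0, 5.3, 5.3, 5.1, 4.6),
  `2` = c(5.4, 5.4, 4.9, 5.5),
  `3` = c(5.4, 5.3, 5.5),
  `4` = c(6.0, 5.8),
  `5` = c(5.3, 5.4, 5.5, 5.6))

records_from_lists <- function(...) {
  rounds <- list(...)
  next_id <- rep(1L, 5L)
  out <- list()
  for (t in seq_along(rounds)) {
    for (i in seq_along(rounds[[t]])) {
      y <- rounds[[t]][[i]]
      if (!length(y)) next
      out[[length(out) + 1L]] <- data.frame(
        site_id = i, patient_id = seq.int(next_id[i], length.out = length(y)),
        round = t, outcome = y)
      next_id[i] <- next_id[i] + length(y)
    }
  }
  do.call(rbind, out)
}

#' Built-in worked-example fixtures
#'
#' Returns the five-site, two-round worked example as a ready-made
#' `csm_history` together with the published report fragments (site
#' averages, critical limits, mixture weights and flags) that the
#' monitoring run is expected to reproduce.  `"table1"` is the 19-patient
#' first round alone; `"table1_2"` is the full 38-patient two-round
#' trial.
#'
#' @param name `"table1"` or `"table1_2"`.
#' @return A list of class `csm_fixture` with `name`, `history` and
#'   `expected` (averages, one-decimal critical limits, posterior-mean
#'   mixture weights with tolerance, flags).
#' @export
#' @examples
#' fix <- builtin_fixture("table1")
#' partition_rounds(fix$history, 1)$current_counts
builtin_fixture <- function(name = c("table1", "table1_2")) {
  name <- match.arg(name)
  expected1 <- list(
    averages = c(5.0, 5.2, 5.3, 5.3, 6.1),
    limits = rbind(lower = c(4.7, 4.9, 5.0, 5.0, 4.9),
                   upper = c(6.1, 6.0, 5.8, 5.8, 5.9)),
    mixture_weights = c(0.036, 0.926, 0.037),
    weight_tolerance = 0.03,
    body_component = 2L,
    flagged_sites = 5L)
  if (name == "table1") {
    history <- trial_history(records_from_lists(table1_outcomes))
    expected <- list(round1 = expected1)
  } else {
    history <- trial_history(records_from_lists(table1_outcomes,
                                                table2_outcomes))
    expected <- list(
      round1 = expected1,
      round2 = list(
        averages = c(5.1, 5.3, 5.4, 5.9, 5.5),
        limits = rbind(lower = c(5.1, 5.0, 4.9, 4.8, 5.0),
                       upper = c(5.7, 5.8, 5.8, 5.9, 5.7)),
        mixture_weights = c(0.024, 0.951, 0.025),
        weight_tolerance = 0.03,
        body_component = 2L,
        flagged_sites = integer()))
  }
  structure(list(name = name, history = history, expected = expected),
            class = "csm_fixture")
}
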