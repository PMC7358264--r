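#' Build a multi-round trial history
#'
#' A trial history holds one row per patient outcome, keyed by site and by
#' the monitoring round in which the outcome was first available.  This is
#' the bookkeeping object every detection and simulation function consumes:
#' `Y_i(t)` (all outcomes observed at site i by round t) and
#' `y_i(t) = Y_i(t) \ Y_i(t-1)` (the outcomes new at round t) are both
#' derived from it by [partition_rounds()].
#'
#' @param records data frame with columns `site_id`, `patient_id`, `round`,
#'   `outcome`.  `site_id`, `patient_id` and `round` are positive integers;
#'   `patient_id` must be unique within a site; `outcome` is a finite
#'   continuous value.
#' @param n_sites number of sites M (>= 2).  Defaults to the largest
#'   `site_id` present.
#' @param n_rounds number of monitoring rounds T (>= 1).  Defaults to the
#'   largest `round` present.
#' @return A tibble of class `csm_history` with attributes `n_sites` and
#'   `n_rounds`.
#' @seealso [partition_rounds()], [read_trial_csv()], [builtin_fixture()]
#' @export
#' @examples
#' h <- trial_history(data.frame(
#'   site_id = c(1, 1, 2), patient_id = c(1, 2, 1),
#'   round = c(1, 1, 1), outcome = c(5.2, 4.8, 5.5)))
#' partition_rounds(h, 1)$current_counts
trial_history <- function(records, n_sites = NULL, n_rounds = NULL) {
  required <- c("site_id", "patient_id", "round", "outcome")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop_csm("records is missing column(s): ",
             paste(missing_cols, collapse = ", "))
  if (nrow(records) == 0L)
    stop_csm("records is empty: a trial history needs at least one outcome")

  rec <- tibble::as_tibble(records[required])
  for (col in c("site_id", "patient_id", "round")) {
    v <- rec[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 1) || any(v != as.integer(v)))
      stop_csm("`", col, "` must contain positive integers")
    rec[[col]] <- as.integer(v)
  }
  if (!is.numeric(rec$outcome) || any(!is.finite(rec$outcome)))
    stop_csm("`outcome` must be finite numeric")
  dup <- duplicated(rec[c("site_id", "patient_id")])
  if (any(dup))
    stop_csm("duplicate (site_id, patient_id) pairs: ",
             paste(utils::head(which(dup), 5L), collapse = ", "))

  if (is.null(n_sites)) n_sites <- max(rec$site_id)
  if (is.null(n_rounds)) n_rounds <- max(rec$round)
  check_scalar_number(n_sites, "n_sites", lower = 2)
  check_scalar_number(n_rounds, "n_rounds", lower = 1)
  if (max(rec$site_id) > n_sites)
    stop_csm("site_id exceeds n_sites = ", n_sites)
  if (max(rec$round) > n_rounds)
    stop_csm("round exceeds n_rounds = ", n_rounds)

  structure(rec,
            n_sites = as.integer(n_sites),
            n_rounds = as.integer(n_rounds),
            class = c("csm_history", class(rec)))
}

#' Number of sites / rounds of a trial history
#' @param history a `csm_history`.
#' @return integer.
#' @export
n_sites <- function(history) attr(history, "n_sites")

#' @rdname n_sites
#' @export
n_rounds <- function(history) attr(history, "n_rounds")

#' Partition a trial history at a monitoring round
#'
#' Splits the history into the cumulative data `Y_i(t)` (everything
#' observed by round t, used to fit the statistical model) and the
#' current-round data `y_i(t)` (the relative complement of `Y_i(t-1)` in
#' `Y_i(t)`, used to compute the observed site averages that are compared
#' with the critical limits).
#'
#' @param history a `csm_history`.
#' @param t round index, `1 <= t <= n_rounds(history)`.
#' @return A list of class `csm_round` with elements `round`,
#'   `cumulative_by_site`, `current_by_site` (lists of numeric vectors,
#'   one per site 1..M), `cumulative_counts` (`N_i(t)`) and
#'   `current_counts` (`n_i(t)`).
#' @export
partition_rounds <- function(history, t) {
  if (!inherits(history, "csm_history"))
    stop_csm("history must be a csm_history (see trial_history())")
  Tmax <- n_rounds(history)
  check_scalar_number(t, "t", lower = 1, upper = Tmax)
  M <- n_sites(history)
  sites <- seq_len(M)
  fac <- factor(history$site_id, levels = sites)

  cum_idx <- history$round <= t
  cur_idx <- history$round == t
  cumulative_by_site <- split(history$outcome[cum_idx], fac[cum_idx])
  current_by_site <- split(history$outcome[cur_idx], fac[cur_idx])

  structure(list(
    round = as.integer(t),
    cumulative_by_site = cumulative_by_site,
    current_by_site = current_by_site,
    cumulative_counts = lengths(cumulative_by_site),
    current_counts = lengths(current_by_site)
  ), class = "csm_round")
}

#' Site average of current-round outcomes
#'
#' The observed site statistic compared against the critical limits: the
#' arithmetic mean of a site's current-round outcomes.
#'
#' @param values non-empty numeric vector of finite outcomes.
#' @return the arithmetic mean.
#' @export
#' @examples
#' site_average(c(4.7, 5.5, 5.5, 5.0, 5.8))  # 5.3
site_average <- function(values) {
  if (length(values) == 0L)
    stop_csm("cannot average an empty set of outcomes (no data this round)")
  if (!is.numeric(values) || any(!is.finite(values)))
    stop_csm("outcomes must be finite numeric")
  mean(values)
}
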