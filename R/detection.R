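#' Detection configuration
#'
#' Bundles the method choice, detection threshold, priors and MCMC
#' settings used by [run_round()] / [run_monitoring()].
#'
#' @param method `"fmm"` (mixture body-distribution limits) or `"single"`
#'   (single-distribution limits).
#' @param alpha per-site two-sided detection threshold in (0, 0.5);
#'   default 0.05 so each tail holds 5 percent of the posterior
#'   predictive distribution.
#' @param priors a [fmm_priors()] or [single_priors()] object matching
#'   `method`; defaults constructed when `NULL`.
#' @param mcmc an [mcmc_config()].
#' @return a `detection_config` list.
#' @export
detection_config <- function(method = c("fmm", "single"), alpha = 0.05,
                             priors = NULL, mcmc = mcmc_config()) {
  method <- match.arg(method)
  check_scalar_number(alpha, "alpha", lower = 0, upper = 0.5,
                      strict_lower = TRUE)
  if (alpha >= 0.5) stop_csm("`alpha` must be < 0.5")
  if (is.null(priors))
    priors <- if (method == "fmm") fmm_priors() else single_priors()
  expected <- if (method == "fmm") "fmm_priors" else "single_priors"
  if (!inherits(priors, expected))
    stop_csm("method = '", method, "' requires priors of class ", expected)
  if (!inherits(mcmc, "mcmc_config"))
    stop_csm("mcmc must come from mcmc_config()")
  structure(list(method = method, alpha = alpha, priors = priors,
                 mcmc = mcmc),
            class = "detection_config")
}

#' Flag decision for one site
#'
#' A site is atypical when its current-round average lies strictly
#' outside the critical limits; boundary equality does not flag.
#'
#' @param average observed current-round site average.
#' @param lower,upper critical limits (lower < upper).
#' @return logical.
#' @export
#' @examples
#' flag_site(6.1, 4.9, 5.9)  # TRUE
#' flag_site(5.9, 4.9, 5.9)  # FALSE: boundary is not a flag
flag_site <- function(average, lower, upper) {
  if (!is.finite(average) || !is.finite(lower) || !is.finite(upper))
    stop_csm("average and limits must be finite")
  if (lower >= upper) stop_csm("lower limit must be below upper limit")
  average < lower || average > upper
}

#' Run one monitoring round
#'
#' Fits the configured model to ALL cumulative outcomes Y(t) pooled
#' across sites, then compares each site's current-round average to
#' critical limits computed with that site's current-round patient count.
#' One stream of standard-normal predictive draws is generated per round
#' and reused across sites (scaled by `1/sqrt(n_current)`), so sites with
#' equal current counts receive exactly equal limits.  Sites with no
#' current-round data are skipped (no average exists to compare).
#'
#' @param history a `csm_history`.
#' @param t round index.
#' @param cfg a [detection_config()].
#' @return A tibble with one row per site that has current-round data:
#'   `site_id`, `round`, `n_current`, `average`, `lower`, `upper`,
#'   `flagged`; attributes `body_weight`/`kb` (fmm) and `fit`.
#' @export
run_round <- function(history, t, cfg = detection_config()) {
  if (!inherits(cfg, "detection_config"))
    stop_csm("cfg must come from detection_config()")
  rd <- partition_rounds(history, t)
  pooled <- unlist(rd$cumulative_by_site, use.names = FALSE)
  if (length(pooled) == 0L)
    stop_csm("round ", t, " has no cumulative data")
  if (sum(rd$current_counts) == 0L)
    stop_csm("round ", t, " has no current-round data")

  if (cfg$method == "fmm") {
    fit <- fit_fmm(pooled, cfg$priors, cfg$mcmc)
    body <- select_body(fit)
  } else {
    fit <- fit_single(pooled, cfg$priors, cfg$mcmc)
    body <- NULL
  }
  z <- rnorm(cfg$mcmc$n_draws)

  sites <- which(rd$current_counts >= 1L)
  decisions <- lapply(sites, function(i) {
    cur <- rd$current_by_site[[i]]
    avg <- site_average(cur)
    lim <- if (cfg$method == "fmm")
      body_predictive_limits(fit, body$kb, length(cur), cfg$alpha, z)
    else
      single_predictive_limits(fit, length(cur), cfg$alpha, z)
    tibble::tibble(site_id = i, round = as.integer(t),
                   n_current = length(cur), average = avg,
                   lower = lim[["lower"]], upper = lim[["upper"]],
                   flagged = flag_site(avg, lim[["lower"]], lim[["upper"]]))
  })
  out <- do.call(rbind, decisions)
  attr(out, "fit") <- fit
  if (!is.null(body)) {
    attr(out, "kb") <- body$kb
    attr(out, "body_weight") <- body$weight
  }
  out
}

#' Run a full multi-round monitoring sequence
#'
#' Applies [run_round()] sequentially for t = 1..T.  The model at each
#' round is refitted to the whole cumulative data Y(t); previously
#' observed data always stays in the likelihood.  Deterministic given
#' `seed`.
#'
#' @param history a `csm_history`.
#' @param cfg a [detection_config()].
#' @param seed optional integer seed for the whole run; overrides any
#'   seed inside `cfg$mcmc`.
#' @return A list of class `csm_report`: `decisions` (tibble over all
#'   site-rounds with data), `body_weights_by_round` (fmm only),
#'   `config`, `seed`.
#' @export
#' @examples
#' fix <- builtin_fixture("table1_2")
#' rep <- run_monitoring(fix$history, seed = 1)
#' subset(rep$decisions, flagged)
run_monitoring <- function(history, cfg = detection_config(), seed = NULL) {
  if (!inherits(cfg, "detection_config"))
    stop_csm("cfg must come from detection_config()")
  if (is.null(seed)) seed <- cfg$mcmc$seed
  if (!is.null(seed)) set.seed(seed)
  # individual fits consume the single seeded stream
  cfg$mcmc$seed <- NULL

  Tmax <- n_rounds(history)
  rounds <- vector("list", Tmax)
  weights <- rep(NA_real_, Tmax)
  for (t in seq_len(Tmax)) {
    rounds[[t]] <- run_round(history, t, cfg)
    if (cfg$method == "fmm")
      weights[t] <- attr(rounds[[t]], "body_weight")
  }
  decisions <- do.call(rbind, lapply(rounds, function(r) {
    attributes(r)[c("fit", "kb", "body_weight")] <- NULL
    r
  }))
  structure(list(decisions = decisions,
                 body_weights_by_round =
                   if (cfg$method == "fmm") weights else NULL,
                 config = cfg, seed = seed),
            class = "csm_report")
}

#' @export
print.csm_report <- function(x, digits = 1, ...) {
  cat("CSM monitoring report (method =", x$config$method,
      ", alpha =", x$config$alpha, ")\n")
  d <- x$decisions
  d$average <- round_half_up(d$average, digits)
  d$lower <- round_half_up(d$lower, digits)
  d$upper <- round_half_up(d$upper, digits)
  print(as.data.frame(d), row.names = FALSE)
  flg <- x$decisions[x$decisions$flagged, , drop = FALSE]
  if (nrow(flg) == 0L) cat("No site flagged as atypical.\n")
  else cat("Atypical: site", paste(flg$site_id, "(round", flg$round, ")",
                                   collapse = ", "), "\n")
  invisible(x)
}
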