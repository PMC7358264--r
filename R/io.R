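#' Read a trial CSV
#'
#' Reads delimited trial data (comma-separated, UTF-8, `.` decimal,
#' mandatory header) with columns `site_id`, `patient_id`, `round`,
#' `outcome`, one patient record per row.  Malformed rows are reported
#' with their file line numbers.  The numbers of sites and rounds are
#' inferred from the data; a site appearing for the first time at a late
#' round is accepted (staggered site opening).
#'
#' @param path path to the CSV file.
#' @param n_sites,n_rounds optional overrides for the inferred M and T.
#' @return a `csm_history`.
#' @seealso [write_trial_csv()]
#' @export
read_trial_csv <- function(path, n_sites = NULL, n_rounds = NULL) {
  if (!file.exists(path)) stop_csm("file not found: ", path)
  raw <- read.csv(path, colClasses = "character", strip.white = TRUE)
  required <- c("site_id", "patient_id", "round", "outcome")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop_csm("missing column(s) in ", path, ": ",
             paste(missing_cols, collapse = ", "))
  parsed <- lapply(raw[required], function(col)
    suppressWarnings(as.numeric(col)))
  bad <- Reduce(`|`, lapply(parsed, function(col) !is.finite(col)))
  if (any(bad))
    stop_csm("non-numeric or missing values in ", path, " at line(s) ",
             paste(utils::head(which(bad) + 1L, 5L), collapse = ", "),
             " (line 1 is the header)")
  trial_history(as.data.frame(parsed), n_sites = n_sites,
                n_rounds = n_rounds)
}

#' Write a trial history as CSV
#'
#' @param history a `csm_history`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(history, path) {
  write.csv(as.data.frame(history)[c("site_id", "patient_id", "round",
                                     "outcome")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a monitoring report or evaluation table
#'
#' Writes a deterministic delimited report.  For a `csm_report` the
#' decision table (site_id, round, n_current, average, lower, upper,
#' flagged) is preceded by `#`-prefixed run-metadata lines (method,
#' alpha, priors, seed); numbers are rounded half-up at `decimals`
#' (default 1, the reporting convention of monitoring tables).  For a
#' `csm_eval` the long-format metric tables are written at `decimals`
#' default 3.  Re-running with the same seed and config yields a
#' byte-identical file.
#'
#' @param report a `csm_report` or `csm_eval`.
#' @param path output path.
#' @param decimals reported decimal places.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, decimals = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  rnd <- function(d, cols, k) {
    for (col in cols) d[[col]] <- round_half_up(d[[col]], k)
    d
  }
  if (inherits(report, "csm_report")) {
    if (is.null(decimals)) decimals <- 1L
    cfg <- report$config
    pr <- cfg$priors
    writeLines(c(
      paste0("# method: ", cfg$method),
      paste0("# alpha: ", cfg$alpha),
      paste0("# priors: ", paste(names(pr), vapply(pr, function(v)
        paste(v, collapse = ","), ""), sep = "=", collapse = "; ")),
      paste0("# mcmc: burnin=", cfg$mcmc$n_burnin, " draws=",
             cfg$mcmc$n_draws, " thin=", cfg$mcmc$thin),
      paste0("# seed: ", if (is.null(report$seed)) "NA" else report$seed)
    ), con)
    d <- as.data.frame(report$decisions)[
      c("site_id", "round", "n_current", "average", "lower", "upper",
        "flagged")]
    write.csv(rnd(d, c("average", "lower", "upper"), decimals), con,
              row.names = FALSE, quote = FALSE)
  } else if (inherits(report, "csm_eval")) {
    if (is.null(decimals)) decimals <- 3L
    writeLines("# table: site", con)
    write.csv(rnd(as.data.frame(report$site), c("prob", "se"), decimals),
              con, row.names = FALSE, quote = FALSE)
    writeLines("# table: type1_avg", con)
    write.csv(rnd(as.data.frame(report$type1_avg), c("avg_type1", "se"),
                  decimals),
              con, row.names = FALSE, quote = FALSE)
  } else {
    stop_csm("report must be a csm_report or csm_eval")
  }
  invisible(path)
}

#' Default run configuration
#'
#' The configuration shipped as package default: the mixture method with
#' K = 3 components, Dirichlet(1, 8, 1) weight prior, normal(0, 1000)
#' mean prior, inverse-gamma(0.1, 0.1) variance prior, alpha = 0.05, and
#' the standard chain settings.
#'
#' @return nested list mirroring the YAML config schema.
#' @seealso [read_run_config()], [as_detection_config()]
#' @export
default_run_config <- function() {
  list(method = "fmm", alpha = 0.05,
       priors = list(
         single = list(mu0 = 0, sigma0_sq = 1000, a = 0.1, b = 0.1),
         fmm = list(K = 3L, dirichlet_alpha = c(1, 8, 1), mu0 = 0,
                    sigma0_sq = 1000, a = 0.1, b = 0.1)),
       mcmc = list(n_burnin = 2000L, n_draws = 10000L, thin = 1L),
       seed = NULL,
       report = list(decimals = 1L))
}

#' Read / write a run configuration (YAML)
#'
#' Missing keys fall back to [default_run_config()]; unknown top-level
#' keys are rejected.  `write_run_config()` followed by
#' `read_run_config()` is an identity.
#'
#' @param path YAML file path.
#' @return for `read_run_config`, the validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_csm("config file not found: ", path)
  user <- yaml::read_yaml(path)
  base <- default_run_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop_csm("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(base, user)
  as_detection_config(cfg)  # validates
  cfg
}

#' @rdname read_run_config
#' @param cfg a config list.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Convert a run configuration to a detection configuration
#'
#' @param cfg config list as returned by [read_run_config()].
#' @return a [detection_config()].
#' @export
as_detection_config <- function(cfg) {
  priors <- if (cfg$method == "fmm")
    do.call(fmm_priors, cfg$priors$fmm)
  else
    do.call(single_priors, cfg$priors$single)
  mcmc <- do.call(mcmc_config, c(cfg$mcmc, list(seed = cfg$seed)))
  detection_config(cfg$method, cfg$alpha, priors, mcmc)
}

#' Read / write a simulation scenario (YAML)
#'
#' Keys mirror [scenario_config()]; `atypical_shifts` is a mapping from
#' site id to shift.
#'
#' @param path YAML file path.
#' @return for `read_scenario`, a `csm_scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop_csm("scenario file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$atypical_shifts))
    raw$atypical_shifts <- unlist(raw$atypical_shifts)
  do.call(scenario_config, raw)
}

#' @rdname read_scenario
#' @param cfg a `csm_scenario`.
#' @export
write_scenario <- function(cfg, path) {
  out <- unclass(cfg)
  out$atypical_shifts <- as.list(cfg$atypical_shifts)
  yaml::write_yaml(out, path)
  invisible(path)
}
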