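#' Round half away from zero
#'
#' Rounding used at the reporting layer so that printed tables match the
#' usual "half-up" convention (e.g. 5.45 -> 5.5 at one decimal), unlike
#' [base::round()]'s round-half-to-even. Internal computation is always
#' carried at full precision; rounding happens only when values are
#' reported.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(5.45, 1)  # 5.5, where round() gives 5.4
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_csm <- function(...) stop(..., call. = FALSE)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_csm("`", name, "` must be a single finite number")
  if (strict_lower && x <= lower)
    stop_csm("`", name, "` must be > ", lower)
  if (!strict_lower && x < lower)
    stop_csm("`", name, "` must be >= ", lower)
  if (x > upper)
    stop_csm("`", name, "` must be <= ", upper)
  invisible(x)
}
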