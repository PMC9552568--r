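#' Round half away from zero
#'
#' Surveillance tables round percentages with the conventional half-up rule
#' (0.05 rounds to 0.1), not the IEEE banker's rounding used by [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Numeric vector rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(c(0.15, 0.25), 1) # 0.2 0.3
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # tiny nudge guards against representation error just below .5
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop with a classed condition so callers/tests can target scdlink errors.
#' @noRd
scdlink_abort <- function(msg, class = "scdlink_error") {
  stop(structure(
    class = c(class, "scdlink_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' @noRd
assert_probability <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    scdlink_abort(sprintf("`%s` must be a probability in [0, 1]", name),
                  class = "scdlink_config_error")
  }
  invisible(x)
}

#' @noRd
year_of <- function(date) as.integer(format(date, "%Y"))

#' @noRd
mid_year <- function(year) as.Date(sprintf("%d-07-01", year))

# Completed age in years at `at` for someone born on `birth_date`.
#' @noRd
age_at <- function(birth_date, at) {
  by <- as.POSIXlt(birth_date)
  ay <- as.POSIXlt(at)
  age <- ay$year - by$year
  earlier <- (ay$mon < by$mon) | (ay$mon == by$mon & ay$mday < by$mday)
  age - as.integer(earlier)
}
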