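#' Round half away from zero
#'
#' Base R's `round()` rounds half to even. Printed tables in health-services
#' reports conventionally round half up, so percentage and count estimates in
#' this package use this helper instead.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(0.5)    # 1
#' round_half_up(11.25, 1)  # 11.3
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# percentage of a count over a denominator, rounded half-up to one decimal
pct1 <- function(num, den) round_half_up(100 * num / den, 1)

stop_bad_arg <- function(name, msg) {
  stop(sprintf("`%s` %s", name, msg), call. = FALSE)
}

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_bad_arg(name, "must be a probability in [0, 1]")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (any(!is.finite(x)) || any(x < min) || any(x != floor(x))) {
    stop_bad_arg(name, sprintf("must be an integer >= %d", min))
  }
  invisible(x)
}

#' @importFrom rlang .data
#' @importFrom stats setNames
NULL
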