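#' Classify state minor consent/confidentiality protection
#'
#' States fall into two groups for the primary analysis: *protective* states
#' have legislation allowing all minors to consent to contraceptive services
#' AND guaranteeing confidentiality of those services; every other state
#' (no explicit law, laws covering only limited categories of minors such as
#' emancipated minors, or laws giving physicians discretion to disclose to
#' parents) is *not protective*. The `"expanded"` variant used in sensitivity
#' analysis additionally counts as protective the states where all minors may
#' consent but physicians retain disclosure discretion.
#'
#' @param laws A data frame with one row per state and logical columns
#'   `state`, `consent_all_minors`, `confidentiality_guaranteed`,
#'   `physician_discretion_disclosure`, `limited_categories_only`.
#' @param variant `"primary"` (default) or `"expanded"`.
#' @return The input tibble with a logical `protective` column appended.
#' @examples
#' laws <- tibble::tibble(
#'   state = c("S01", "S02", "S03"),
#'   consent_all_minors = c(TRUE, TRUE, FALSE),
#'   confidentiality_guaranteed = c(TRUE, FALSE, FALSE),
#'   physician_discretion_disclosure = c(FALSE, TRUE, FALSE),
#'   limited_categories_only = c(FALSE, FALSE, TRUE)
#' )
#' classify_state(laws)$protective              # TRUE FALSE FALSE
#' classify_state(laws, "expanded")$protective  # TRUE TRUE  FALSE
#' @export
classify_state <- function(laws, variant = c("primary", "expanded")) {
  variant <- match.arg(variant)
  needed <- c("consent_all_minors", "confidentiality_guaranteed",
              "physician_discretion_disclosure")
  missing_cols <- setdiff(c("state", needed), names(laws))
  if (length(missing_cols) > 0) {
    stop("state-law table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  flags <- laws[needed]
  if (anyNA(flags)) {
    bad <- laws$state[apply(is.na(flags), 1, any)]
    stop("incomplete law record for state(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  protective <- laws$consent_all_minors & laws$confidentiality_guaranteed
  if (variant == "expanded") {
    protective <- protective |
      (laws$consent_all_minors & laws$physician_discretion_disclosure)
  }
  dplyr::mutate(tibble::as_tibble(laws), protective = protective)
}

#' Look up per-state protective status as a named logical vector
#'
#' @inheritParams classify_state
#' @return Named logical vector keyed by state code.
#' @export
protective_states <- function(laws, variant = c("primary", "expanded")) {
  cls <- classify_state(laws, variant)
  setNames(cls$protective, cls$state)
}
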