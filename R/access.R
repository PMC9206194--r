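#' Four-category access-change label
#'
#' Truth table over per-epoch access: (TRUE, FALSE) -> `lost`,
#' (TRUE, TRUE) -> `maintained`, (FALSE, TRUE) -> `gained`,
#' (FALSE, FALSE) -> `never`.
#'
#' @param access_2018,access_2020 Logical vectors.
#' @return Factor with levels `lost`, `maintained`, `gained`, `never`.
#' @export
change_category <- function(access_2018, access_2020) {
  stopifnot(length(access_2018) == length(access_2020))
  out <- dplyr::case_when(
    access_2018 & !access_2020 ~ "lost",
    access_2018 & access_2020 ~ "maintained",
    !access_2018 & access_2020 ~ "gained",
    TRUE ~ "never"
  )
  factor(out, levels = c("lost", "maintained", "gained", "never"))
}

#' Combine catchment and state-law criteria into per-epoch access
#'
#' A tract has access to confidential care when (criterion 1) at least one
#' program-funded clinic is within the drive-time threshold of its
#' population-weighted centroid, or (criterion 2) it lies in a state whose
#' law protects minor consent and confidentiality. Modes:
#' \describe{
#'   \item{primary}{catchment OR protective state (main analysis).}
#'   \item{catchment_only}{catchment criterion alone, irrespective of state
#'     law (sensitivity analysis 1).}
#'   \item{expanded_law}{catchment OR expanded-protective state, which also
#'     counts consent-with-physician-discretion states (sensitivity
#'     analysis 2).}
#' }
#'
#' @param in_catchment Logical vector: clinic within threshold, per tract.
#' @param state Character vector of tract state codes.
#' @param state_laws State-law table (see [classify_state()]).
#' @param mode `"primary"`, `"catchment_only"` or `"expanded_law"`.
#' @return Logical access vector.
#' @export
tract_access <- function(in_catchment, state, state_laws,
                         mode = c("primary", "catchment_only", "expanded_law")) {
  mode <- match.arg(mode)
  if (mode == "catchment_only") return(in_catchment)
  variant <- if (mode == "expanded_law") "expanded" else "primary"
  prot <- protective_states(state_laws, variant)
  unknown <- setdiff(unique(state), names(prot))
  if (length(unknown) > 0) {
    stop("no law record for state(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  in_catchment | unname(prot[state])
}

#' Estimate the Medicaid-enrolled population aged 15-17
#'
#' The number of Medicaid-enrolled minors multiplied by the proportion of the
#' tract's minors who are aged 15-17, rounded half up to a whole count.
#'
#' @param medicaid_minors Count of Medicaid-enrolled minors (<18) per tract.
#' @param prop_minors_15_17 Proportion of minors aged 15-17, in \[0, 1\].
#' @return Integer-valued estimate per tract.
#' @examples
#' estimate_medicaid_15_17(1000, 0.17)  # 170
#' @export
estimate_medicaid_15_17 <- function(medicaid_minors, prop_minors_15_17) {
  if (any(medicaid_minors < 0, na.rm = TRUE)) {
    stop("Medicaid minor counts must be non-negative", call. = FALSE)
  }
  if (any(prop_minors_15_17 < 0 | prop_minors_15_17 > 1, na.rm = TRUE)) {
    stop("`prop_minors_15_17` must lie in [0, 1]", call. = FALSE)
  }
  round_half_up(medicaid_minors * prop_minors_15_17)
}

#' Classify tract-level access change between the two epochs
#'
#' Runs the full access evaluation for every tract: drive-time catchment
#' membership against each epoch's clinic roster, combination with state law
#' under the requested mode, the four-category change label, and the
#' Medicaid-stratified youth counts.
#'
#' @param tracts Tract table with `tract_id`, `state`, centroid `x`, `y`,
#'   `pop_15_17`, `medicaid_minors`, `prop_minors_15_17`.
#' @param clinics_2018,clinics_2020 Epoch clinic tables with `x`, `y`.
#' @param net A [road_network()] (or `NULL` for the straight-line fallback).
#' @param state_laws State-law table.
#' @param mode Access mode, see [tract_access()].
#' @param threshold_minutes Drive-time threshold, default 30.
#' @param access_minutes_per_unit Off-network access speed.
#' @return Tibble of access records: `tract_id`, `state`, `access_2018`,
#'   `access_2020`, `category`, `pop_15_17`, `medicaid_15_17_est`,
#'   `non_medicaid_15_17_est`.
#' @export
classify_access <- function(tracts, clinics_2018, clinics_2020, net, state_laws,
                            mode = c("primary", "catchment_only", "expanded_law"),
                            threshold_minutes = 30,
                            access_minutes_per_unit = 1) {
  mode <- match.arg(mode)
  centroids <- tracts[, c("x", "y")]
  if (is.null(net)) {
    in18 <- tract_within_drive(NULL, centroids, clinics_2018,
                               threshold_minutes, access_minutes_per_unit)
    in20 <- tract_within_drive(NULL, centroids, clinics_2020,
                               threshold_minutes, access_minutes_per_unit)
  } else {
    mm <- min_travel_time_multi(net, centroids,
                                list(clinics_2018[, c("x", "y")],
                                     clinics_2020[, c("x", "y")]),
                                access_minutes_per_unit)
    in18 <- mm[, 1] <= threshold_minutes
    in20 <- mm[, 2] <= threshold_minutes
  }
  a18 <- tract_access(in18, tracts$state, state_laws, mode)
  a20 <- tract_access(in20, tracts$state, state_laws, mode)
  med <- estimate_medicaid_15_17(tracts$medicaid_minors,
                                 tracts$prop_minors_15_17)
  med <- pmin(med, tracts$pop_15_17)
  tibble::tibble(
    tract_id = tracts$tract_id,
    state = tracts$state,
    in_catchment_2018 = in18,
    in_catchment_2020 = in20,
    access_2018 = a18,
    access_2020 = a20,
    category = change_category(a18, a20),
    pop_15_17 = tracts$pop_15_17,
    medicaid_15_17_est = med,
    non_medicaid_15_17_est = tracts$pop_15_17 - med
  )
}

#' Youth at risk of losing confidential services
#'
#' Summarizes access records: tract counts and percentages per change
#' category (denominator: all evaluated tracts), and for the tracts that lost
#' access, the total population aged 15-17 with its Medicaid /
#' non-Medicaid split (Medicaid-enrolled youth may retain confidential access
#' through Medicaid statutes).
#'
#' @param records Access records from [classify_access()].
#' @return List with `by_category` (tibble: category, n_tracts, pct_tracts,
#'   youth_15_17), `n_tracts`, `youth_at_risk`, `medicaid_at_risk`,
#'   `non_medicaid_at_risk`, `pct_non_medicaid`.
#' @export
youth_at_risk <- function(records) {
  n_total <- nrow(records)
  by_cat <- records |>
    dplyr::group_by(category = .data$category, .drop = FALSE) |>
    dplyr::summarise(
      n_tracts = dplyr::n(),
      youth_15_17 = sum(.data$pop_15_17),
      medicaid_15_17 = sum(.data$medicaid_15_17_est),
      non_medicaid_15_17 = sum(.data$non_medicaid_15_17_est),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct_tracts = pct1(.data$n_tracts, n_total),
                  .after = "n_tracts")
  lost <- by_cat[by_cat$category == "lost", ]
  list(
    by_category = by_cat,
    n_tracts = n_total,
    youth_at_risk = lost$youth_15_17,
    medicaid_at_risk = lost$medicaid_15_17,
    non_medicaid_at_risk = lost$non_medicaid_15_17,
    pct_non_medicaid = if (lost$youth_15_17 > 0) {
      pct1(lost$non_medicaid_15_17, lost$youth_15_17)
    } else NA_real_
  )
}

#' Percentage of youth without access, by state and epoch
#'
#' For each state, the share of its 15- to 17-year-old population living in
#' tracts without access in the given epoch, plus a count of states above a
#' reporting threshold.
#'
#' @param records Access records from [classify_access()].
#' @param epoch `2018` or `2020`.
#' @param over_threshold Percentage threshold for the state count, default 25.
#' @return Tibble (`state`, `youth_15_17`, `youth_without_access`,
#'   `pct_without_access`, `undefined`) with attribute `n_states_over`.
#'   States with no 15-17 population get `NA` and `undefined = TRUE`.
#' @export
state_percent_without_access <- function(records, epoch = c(2018, 2020),
                                         over_threshold = 25) {
  epoch <- as.character(epoch[1])
  col <- switch(epoch, "2018" = "access_2018", "2020" = "access_2020",
                stop("epoch must be 2018 or 2020", call. = FALSE))
  out <- records |>
    dplyr::group_by(state = .data$state) |>
    dplyr::summarise(
      youth_15_17 = sum(.data$pop_15_17),
      youth_without_access = sum(.data$pop_15_17[!.data[[col]]]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      undefined = .data$youth_15_17 == 0,
      pct_without_access = ifelse(.data$undefined, NA_real_,
                                  100 * .data$youth_without_access /
                                    .data$youth_15_17)
    )
  attr(out, "n_states_over") <-
    sum(out$pct_without_access > over_threshold, na.rm = TRUE)
  out
}
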