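#' Normalize a clinic name for matching
#'
#' Case-folds, strips punctuation, and collapses whitespace. Used both for
#' duplicate detection within an epoch and for matching clinics across epochs
#' (source documents may assign different ids to the same service site).
#'
#' @param name Character vector of clinic names.
#' @return Normalized character vector.
#' @export
normalize_clinic_name <- function(name) {
  out <- tolower(name)
  out <- gsub("[^a-z0-9 ]+", " ", out)
  out <- gsub("\\s+", " ", out)
  trimws(out)
}

# identity key: normalized name + coordinates rounded to 4 decimals
clinic_key <- function(name, x, y) {
  paste(normalize_clinic_name(name),
        sprintf("%.4f", round(x, 4)), sprintf("%.4f", round(y, 4)))
}

#' Remove duplicate clinic records from a roster
#'
#' Two records are duplicates when their normalized names and coordinates
#' (rounded to 4 decimals) coincide. The first occurrence is kept;
#' later occurrences are returned separately so duplicate counts can be
#' reported per epoch.
#'
#' @param roster Data frame with at least `id`, `name`, `x`, `y`.
#' @return List with elements `roster` (unique records) and
#'   `duplicates` (the removed records).
#' @export
deduplicate_roster <- function(roster) {
  roster <- tibble::as_tibble(roster)
  if (nrow(roster) == 0) {
    return(list(roster = roster, duplicates = roster))
  }
  key <- clinic_key(roster$name, roster$x, roster$y)
  dup <- duplicated(key)
  list(roster = roster[!dup, , drop = FALSE],
       duplicates = roster[dup, , drop = FALSE])
}

#' Label clinics as having left, joined, or stayed in the program
#'
#' Differences two deduplicated epoch rosters. Clinic identity across epochs
#' is the normalized name + rounded coordinates (ids are not stable across
#' source documents). Clinics present only in the first epoch *left*, only in
#' the second *joined*, in both *stayed*. For clinics in both epochs the
#' second epoch's attributes win; a conflict in state or coordinates raises a
#' reconciliation warning.
#'
#' @param r2018,r2020 Deduplicated rosters (data frames with `id`, `name`,
#'   `x`, `y` and any attribute columns).
#' @return Tibble of all distinct clinics with a `membership` column
#'   (`"left"`, `"joined"`, `"stayed"`).
#' @examples
#' r1 <- tibble::tibble(id = 1:3, name = c("A", "B", "C"), x = 0, y = 1:3)
#' r2 <- tibble::tibble(id = 4:6, name = c("B", "C", "D"), x = 0, y = c(2, 3, 9))
#' table(classify_membership(r1, r2)$membership)
#' @export
classify_membership <- function(r2018, r2020) {
  r2018 <- tibble::as_tibble(r2018)
  r2020 <- tibble::as_tibble(r2020)
  k18 <- clinic_key(r2018$name, r2018$x, r2018$y)
  k20 <- clinic_key(r2020$name, r2020$x, r2020$y)
  if (anyDuplicated(k18) || anyDuplicated(k20)) {
    stop("rosters must be deduplicated before membership classification",
         call. = FALSE)
  }
  stayed20 <- r2020[k20 %in% k18, , drop = FALSE]
  if ("state" %in% names(r2018) && "state" %in% names(r2020)) {
    m <- match(clinic_key(stayed20$name, stayed20$x, stayed20$y), k18)
    conflict <- r2018$state[m] != stayed20$state
    if (any(conflict, na.rm = TRUE)) {
      warning(sum(conflict, na.rm = TRUE),
              " clinic(s) changed attributes across epochs; ",
              "2020 attributes used", call. = FALSE)
    }
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(r2018[!(k18 %in% k20), , drop = FALSE], membership = "left"),
    dplyr::mutate(stayed20, membership = "stayed"),
    dplyr::mutate(r2020[!(k20 %in% k18), , drop = FALSE], membership = "joined")
  )
  out$membership <- factor(out$membership, levels = c("left", "stayed", "joined"))
  out
}

#' Classify clinic affiliation
#'
#' Assigns each clinic exactly one of four categories using, in order of
#' precedence: crisis pregnancy center (registry or name), Planned Parenthood
#' (name), Federally Qualified Health Center (registry lookup or an
#' `fqhc_flag` column), otherwise Other.
#'
#' @param roster Data frame with `id`, `name` (optionally `fqhc_flag`).
#' @param fqhc_registry Character vector of clinic ids with FQHC designation.
#' @param cpc_registry Character vector of clinic ids known to be crisis
#'   pregnancy centers.
#' @return The roster with an `affiliation` factor column
#'   (`CrisisPregnancyCenter`, `PlannedParenthood`, `FQHC`, `Other`).
#' @export
classify_affiliation <- function(roster, fqhc_registry = character(),
                                 cpc_registry = character()) {
  roster <- tibble::as_tibble(roster)
  nm <- normalize_clinic_name(roster$name)
  is_cpc <- roster$id %in% cpc_registry | grepl("crisis pregnancy", nm)
  is_pp <- grepl("planned parenthood", nm)
  is_fqhc <- roster$id %in% fqhc_registry
  if ("fqhc_flag" %in% names(roster)) {
    is_fqhc <- is_fqhc | (!is.na(roster$fqhc_flag) & roster$fqhc_flag)
  }
  aff <- dplyr::case_when(
    is_cpc ~ "CrisisPregnancyCenter",
    is_pp ~ "PlannedParenthood",
    is_fqhc ~ "FQHC",
    TRUE ~ "Other"
  )
  roster$affiliation <- factor(
    aff, levels = c("CrisisPregnancyCenter", "FQHC", "PlannedParenthood", "Other"))
  roster
}

clinic_stratum <- function(clinics, stratifier, state_laws = NULL) {
  switch(stratifier,
    affiliation = as.character(clinics$affiliation),
    urban_rural = ifelse(clinics$rucc <= 3, "Urban", "Rural"),
    region = as.character(clinics$region),
    law_status = {
      if (is.null(state_laws)) {
        stop("`state_laws` is required for the law_status stratifier",
             call. = FALSE)
      }
      prot <- protective_states(state_laws)
      ifelse(prot[clinics$state], "Protective", "Not protective")
    },
    stop("unknown stratifier: ", stratifier, call. = FALSE)
  )
}

#' Tabulate clinic characteristics before and after the rule change
#'
#' Produces a program-composition table: per-stratum counts and column
#' percentages for the 2018 roster (left + stayed) and the 2020 roster
#' (stayed + joined), the net change, and a per-row chi-square p value
#' comparing the stratum's share of the program between epochs.
#'
#' @param clinics Membership-labelled clinics from [classify_membership()],
#'   with the columns the chosen stratifier needs (`affiliation`, `rucc`,
#'   `region`, `state`).
#' @param stratifier One of `"affiliation"`, `"urban_rural"`, `"region"`,
#'   `"law_status"`.
#' @param state_laws State-law table, required for `"law_status"`.
#' @return Tibble with columns `stratum`, `n_2018`, `pct_2018`, `n_2020`,
#'   `pct_2020`, `net_change`, `net_change_pct`, `p_value`. Totals are stored
#'   in attributes `total_2018` and `total_2020`.
#' @export
tabulate_characteristics <- function(clinics,
                                     stratifier = c("affiliation", "urban_rural",
                                                    "region", "law_status"),
                                     state_laws = NULL) {
  stratifier <- match.arg(stratifier)
  stopifnot("membership" %in% names(clinics))
  stratum <- clinic_stratum(clinics, stratifier, state_laws)
  in18 <- clinics$membership %in% c("left", "stayed")
  in20 <- clinics$membership %in% c("stayed", "joined")
  levels <- if (stratifier == "affiliation") {
    c("CrisisPregnancyCenter", "FQHC", "PlannedParenthood", "Other")
  } else {
    sort(unique(stratum))
  }
  n18 <- vapply(levels, function(l) sum(in18 & stratum == l), integer(1),
                USE.NAMES = FALSE)
  n20 <- vapply(levels, function(l) sum(in20 & stratum == l), integer(1),
                USE.NAMES = FALSE)
  t18 <- sum(in18)
  t20 <- sum(in20)
  pval <- vapply(levels, function(l) {
    tab <- rbind(c(sum(in18 & stratum == l), sum(in18 & stratum != l)),
                 c(sum(in20 & stratum == l), sum(in20 & stratum != l)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA_real_)
    chi_square_test(tab)$p_value
  }, numeric(1), USE.NAMES = FALSE)
  out <- tibble::tibble(
    stratum = levels,
    n_2018 = n18,
    pct_2018 = pct1(n18, t18),
    n_2020 = n20,
    pct_2020 = pct1(n20, t20),
    net_change = n20 - n18,
    net_change_pct = ifelse(n18 > 0, pct1(abs(n20 - n18), n18), NA_real_),
    p_value = pval
  )
  attr(out, "total_2018") <- t18
  attr(out, "total_2020") <- t20
  out
}

#' Summarize program composition change between epochs
#'
#' Computes headline roster-differencing quantities: exits, entries, the net
#' clinic loss (exits minus entries), and the percentage of clinics that left.
#' Two exit percentages are reported because the natural denominators differ:
#' the raw 2018 record count (before duplicate exclusion, when supplied) and
#' the deduplicated 2018 roster.
#'
#' @param membership Membership-labelled clinics from [classify_membership()].
#' @param n_records_2018 Optional raw 2018 record count before deduplication.
#' @return List with `n_2018`, `n_2020`, `n_left`, `n_joined`, `net_loss`,
#'   `pct_left` (deduplicated denominator), `pct_left_raw` (raw denominator,
#'   `NA` if not supplied) and `pct_net_loss_raw`.
#' @export
program_change_summary <- function(membership, n_records_2018 = NULL) {
  n_left <- sum(membership$membership == "left")
  n_joined <- sum(membership$membership == "joined")
  n_stayed <- sum(membership$membership == "stayed")
  n18 <- n_left + n_stayed
  n20 <- n_stayed + n_joined
  list(
    n_2018 = n18,
    n_2020 = n20,
    n_left = n_left,
    n_joined = n_joined,
    net_loss = n_left - n_joined,
    pct_left = pct1(n_left, n18),
    pct_left_raw = if (is.null(n_records_2018)) NA_real_ else
      pct1(n_left, n_records_2018),
    pct_net_loss_raw = if (is.null(n_records_2018)) NA_real_ else
      pct1(n_left - n_joined, n_records_2018)
  )
}

#' Pearson chi-square test of independence for a contingency table
#'
#' Pearson's statistic without continuity correction; degrees of freedom
#' `(r - 1)(c - 1)`. Errors if any expected cell is zero (the statistic is
#' undefined there).
#'
#' @param table Numeric matrix of non-negative counts.
#' @return List with `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_test(rbind(c(10, 20), c(20, 10)))$statistic  # 6.6667
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) {
    bad <- which(expected == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("expected count is zero in cell (%d, %d)", bad[1], bad[2]),
         call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic),
       df = unname(res$parameter),
       p_value = unname(res$p.value))
}
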