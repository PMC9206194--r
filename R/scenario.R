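#' Configuration for a synthetic access scenario
#'
#' Defines the joint structure of a synthetic study region: states (with
#' minor-confidentiality law status), census tracts with population sub-units,
#' a road network, two-epoch clinic rosters with affiliation-specific exit
#' probabilities, and an annual clinic-count series with a planted policy
#' breakpoint. Defaults mirror the observed composition of the Title X
#' program around the 2019 rule change (clinic density ~0.06 clinics per
#' tract, 99% Planned Parenthood exit probability, ~40% of states
#' protective); see the methods vignette for the provenance of each default.
#'
#' `planted_or` plants recoverable lost-vs-maintained odds ratios: a single
#' number for the binary rural indicator, and a length-3 vector (Q2, Q3, Q4
#' vs Q1) for each continuous covariate.
#'
#' @param n_states Number of states (>= 1).
#' @param states_protective_fraction Fraction of states with universal minor
#'   consent + confidentiality protection.
#' @param n_tracts_per_state Tracts per state (>= 1).
#' @param region_labels Region names cycled over states.
#' @param clinic_density Expected 2018 clinics per tract.
#' @param exit_prob_by_affiliation Named probabilities that a 2018 clinic of
#'   each affiliation leaves the program.
#' @param entry_rate Expected 2020 entrants as a fraction of the 2018 roster.
#' @param duplicate_rate Fraction of duplicate records injected per epoch.
#' @param planted_or Named list of planted odds ratios (see Details).
#' @param road_speed_minutes_per_unit Travel minutes per network distance
#'   unit.
#' @param threshold_minutes Drive-time access threshold (minutes).
#' @param seed Integer seed; the single RNG stream for all draws.
#' @param affiliation_probs 2018 affiliation mix.
#' @param entrant_affiliation_probs Affiliation mix of 2020 entrants.
#' @param rural_base_prob Baseline probability that a tract is rural.
#' @param missing_rate Per-covariate missingness rate (svi, %Black,
#'   %Hispanic, birth rate).
#' @param state_side Side length of each square state, in network units.
#' @param road_grid_spacing Road grid node spacing, in network units.
#' @param annual_counts List defining the clinic-count series: `start`,
#'   `end`, `breakpoint`, `level_2018`, `pre_slope`, `post_slope`,
#'   `noise_sd`.
#' @return A validated `scenario_config` object.
#' @export
scenario_config <- function(
    n_states = 20,
    states_protective_fraction = 0.4,
    n_tracts_per_state = 60,
    region_labels = c("Northeast", "Midwest", "South", "West"),
    clinic_density = 0.06,
    exit_prob_by_affiliation = c(CrisisPregnancyCenter = 0.0, FQHC = 0.163,
                                 PlannedParenthood = 0.99, Other = 0.30),
    entry_rate = 0.11,
    duplicate_rate = 0.028,
    planted_or = list(
      rural = 1.27,
      svi_percentile = c(0.84, 0.67, 0.51),
      pct_black = c(0.70, 0.44, 0.34),
      pct_hispanic = c(1.07, 0.84, 0.45),
      birth_rate = c(1.16, 1.12, 1.00),
      prop_under18 = c(1.13, 1.08, 0.97)
    ),
    road_speed_minutes_per_unit = 1,
    threshold_minutes = 30,
    seed = 1,
    affiliation_probs = c(CrisisPregnancyCenter = 0.0, FQHC = 0.317,
                          PlannedParenthood = 0.112, Other = 0.571),
    entrant_affiliation_probs = c(CrisisPregnancyCenter = 0.016, FQHC = 0.40,
                                  PlannedParenthood = 0.002, Other = 0.582),
    rural_base_prob = 0.15,
    missing_rate = 0.005,
    state_side = NULL,
    road_grid_spacing = NULL,
    annual_counts = list(start = 2006, end = 2020, breakpoint = 2019,
                         level_2018 = 4466, pre_slope = -68.2,
                         post_slope = -918.8, noise_sd = 25)) {
  check_count(n_states, "n_states")
  check_count(n_tracts_per_state, "n_tracts_per_state")
  check_prob(states_protective_fraction, "states_protective_fraction")
  check_prob(exit_prob_by_affiliation, "exit_prob_by_affiliation")
  check_prob(entry_rate, "entry_rate")
  check_prob(duplicate_rate, "duplicate_rate")
  check_prob(rural_base_prob, "rural_base_prob")
  check_prob(missing_rate, "missing_rate")
  if (clinic_density <= 0) stop_bad_arg("clinic_density", "must be positive")
  if (road_speed_minutes_per_unit <= 0) {
    stop_bad_arg("road_speed_minutes_per_unit", "must be positive")
  }
  if (threshold_minutes <= 0) stop_bad_arg("threshold_minutes", "must be positive")
  if (any(unlist(planted_or) <= 0)) {
    stop_bad_arg("planted_or", "values must be positive odds ratios")
  }
  affs <- c("CrisisPregnancyCenter", "FQHC", "PlannedParenthood", "Other")
  if (!all(affs %in% names(exit_prob_by_affiliation))) {
    stop_bad_arg("exit_prob_by_affiliation",
                 "must name all four affiliations")
  }
  # keep the per-tract land area constant (60 square units per tract, so the
  # default 60-tract state is a 60 x 60 square) and the road-grid resolution
  # proportional to state size, making scenario size scale-invariant
  if (is.null(state_side)) state_side <- sqrt(60 * n_tracts_per_state)
  if (is.null(road_grid_spacing)) road_grid_spacing <- state_side / 12
  structure(as.list(environment()), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> %d states (%.0f%% protective) x %d tracts, seed %d\n",
    x$n_states, 100 * x$states_protective_fraction, x$n_tracts_per_state,
    x$seed))
  invisible(x)
}

# quartile band edges used when planting continuous covariates;
# edges echo the cut points printed for the real tract distributions
covariate_bands <- list(
  svi_percentile = c(0, 0.25, 0.5, 0.75, 1),
  pct_black = c(0, 0.9, 4, 15, 60),
  pct_hispanic = c(0, 2.8, 8, 20.9, 70),
  birth_rate = c(0, 20, 45, 76, 150),
  prop_under18 = c(0.10, 0.195, 0.232, 0.272, 0.40)
)

#' Build a synthetic state-law table with fixed category counts
#'
#' Deterministic constructor for a law table with exact counts per legal
#' category; the first `n_protective` states get universal consent +
#' confidentiality, then no-law, limited-categories, and
#' physician-discretion states in that order.
#'
#' @param n_protective,n_no_law,n_limited,n_discretion Category counts.
#' @param states Optional state codes (default `"S01"`, `"S02"`, ...).
#' @return State-law tibble accepted by [classify_state()].
#' @export
state_law_table <- function(n_protective, n_no_law, n_limited, n_discretion,
                            states = NULL) {
  n <- n_protective + n_no_law + n_limited + n_discretion
  if (is.null(states)) states <- sprintf("S%02d", seq_len(n))
  stopifnot(length(states) == n)
  cat_ <- rep(c("protective", "no_law", "limited", "discretion"),
              c(n_protective, n_no_law, n_limited, n_discretion))
  tibble::tibble(
    state = states,
    consent_all_minors = cat_ %in% c("protective", "discretion"),
    confidentiality_guaranteed = cat_ == "protective",
    physician_discretion_disclosure = cat_ == "discretion",
    limited_categories_only = cat_ == "limited"
  )
}

#' Generate a rectangular-grid road network covering a set of points
#'
#' Nodes are laid on a regular grid spanning the bounding box of the supplied
#' tract centroids and clinic locations; horizontal/vertical neighbour edges
#' carry `spacing * road_speed_minutes_per_unit` travel minutes. The grid is
#' connected, and shortest-path times between grid nodes equal Manhattan
#' distance times the per-unit travel time.
#'
#' @param config A [scenario_config()] (uses `road_grid_spacing` and
#'   `road_speed_minutes_per_unit`).
#' @param tract_centroids,clinic_points Data frames with `x`, `y`.
#' @return A [road_network()].
#' @export
generate_road_network <- function(config, tract_centroids, clinic_points) {
  pts <- rbind(as_point_matrix(tract_centroids), as_point_matrix(clinic_points))
  if (nrow(pts) == 0 ||
      (diff(range(pts[, 1])) == 0 && diff(range(pts[, 2])) == 0)) {
    stop("cannot build a road network over coincident points", call. = FALSE)
  }
  sp <- config$road_grid_spacing
  xs <- seq(floor(min(pts[, 1]) / sp) * sp, ceiling(max(pts[, 1]) / sp) * sp,
            by = sp)
  ys <- seq(floor(min(pts[, 2]) / sp) * sp, ceiling(max(pts[, 2]) / sp) * sp,
            by = sp)
  grid <- expand.grid(col = seq_along(xs), row = seq_along(ys))
  nodes <- tibble::tibble(
    id = sprintf("N%06d", seq_len(nrow(grid))),
    x = xs[grid$col], y = ys[grid$row]
  )
  ncolg <- length(xs)
  idx <- seq_len(nrow(grid))
  right <- idx[grid$col < ncolg]
  up <- idx[grid$row < length(ys)]
  edges <- tibble::tibble(
    u = nodes$id[c(right, up)],
    v = nodes$id[c(right + 1L, up + ncolg)],
    minutes = sp * config$road_speed_minutes_per_unit
  )
  road_network(nodes, edges, coords = "planar")
}

draw_affiliations <- function(n, probs) {
  affs <- c("CrisisPregnancyCenter", "FQHC", "PlannedParenthood", "Other")
  factor(sample(affs, n, replace = TRUE, prob = probs[affs]), levels = affs)
}

clinic_names <- function(affiliation, ids) {
  stub <- c(CrisisPregnancyCenter = "Crisis Pregnancy Center",
            FQHC = "Community Health Center",
            PlannedParenthood = "Planned Parenthood Health Center",
            Other = "Family Planning Clinic")
  paste(stub[as.character(affiliation)], ids)
}

inject_duplicates <- function(roster, rate, prefix) {
  n_dup <- stats::rbinom(1, nrow(roster), rate)
  if (n_dup == 0 || nrow(roster) == 0) return(roster)
  src <- roster[sample(nrow(roster), n_dup, replace = FALSE), , drop = FALSE]
  src$id <- sprintf("%s%05d", prefix, seq_len(n_dup))
  dplyr::bind_rows(roster, src)
}

# draw a quartile label per tract: uniform for non-lost tracts, odds tilted
# by the planted ORs (Q2..Q4 vs Q1) for lost tracts, then a value uniform
# within the band. Exact 2x2 planting by outcome-conditional sampling.
draw_quartile_covariate <- function(lost, or_vec, bands) {
  n <- length(lost)
  p_lost <- c(1, or_vec) / sum(c(1, or_vec))
  q <- integer(n)
  q[!lost] <- sample(1:4, sum(!lost), replace = TRUE)
  q[lost] <- sample(1:4, sum(lost), replace = TRUE, prob = p_lost)
  lo <- bands[q]
  hi <- bands[q + 1]
  lo + stats::runif(n) * (hi - lo)
}

#' Generate a complete synthetic scenario
#'
#' Produces a seed-reproducible bundle: states with law status, tracts with
#' population sub-units and covariates, a grid road network, 2018/2020
#' clinic rosters (with injected exact-copy duplicate records), and an
#' annual clinic-count series with a planted breakpoint. Clinic exits are
#' drawn per affiliation; tract covariates are drawn conditional on the
#' realized lost-vs-maintained access status so that the planted odds ratios
#' hold exactly in expectation and are recoverable downstream.
#'
#' @param config A [scenario_config()].
#' @return A `scenario_bundle` list: `states`, `state_laws`, `tracts`,
#'   `subunits`, `clinics_2018`, `clinics_2020`, `road_network`,
#'   `annual_counts`, `config`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)

  ## -- states on a grid of squares ------------------------------------
  ns <- config$n_states
  ncols <- ceiling(sqrt(ns))
  side <- config$state_side
  states <- tibble::tibble(
    state = sprintf("S%02d", seq_len(ns)),
    region = factor(rep_len(config$region_labels, ns),
                    levels = config$region_labels),
    x0 = ((seq_len(ns) - 1) %% ncols) * side,
    y0 = ((seq_len(ns) - 1) %/% ncols) * side
  )
  n_prot <- round(ns * config$states_protective_fraction)
  prot_idx <- sample(ns, n_prot)
  not_prot <- setdiff(seq_len(ns), prot_idx)
  # non-protective mix: no-law / limited / physician-discretion (4:19:8)
  sub_cat <- sample(c("no_law", "limited", "discretion"), length(not_prot),
                    replace = TRUE, prob = c(4, 19, 8) / 31)
  cat_ <- character(ns)
  cat_[prot_idx] <- "protective"
  cat_[not_prot] <- sub_cat
  state_laws <- tibble::tibble(
    state = states$state,
    consent_all_minors = cat_ %in% c("protective", "discretion"),
    confidentiality_guaranteed = cat_ == "protective",
    physician_discretion_disclosure = cat_ == "discretion",
    limited_categories_only = cat_ == "limited"
  )

  ## -- tracts and population sub-units --------------------------------
  nt <- ns * config$n_tracts_per_state
  tracts <- tibble::tibble(
    tract_id = sprintf("T%06d", seq_len(nt)),
    state = rep(states$state, each = config$n_tracts_per_state),
    region = rep(states$region, each = config$n_tracts_per_state),
    ax = rep(states$x0, each = config$n_tracts_per_state) +
      stats::runif(nt, 0, side),
    ay = rep(states$y0, each = config$n_tracts_per_state) +
      stats::runif(nt, 0, side)
  )
  n_sub <- sample(1:9, nt, replace = TRUE)
  subunits <- tibble::tibble(
    tract_id = rep(tracts$tract_id, n_sub),
    x = rep(tracts$ax, n_sub) + stats::runif(sum(n_sub), -3, 3),
    y = rep(tracts$ay, n_sub) + stats::runif(sum(n_sub), -3, 3),
    weight = stats::rlnorm(sum(n_sub), meanlog = log(500), sdlog = 0.6)
  )
  wsum <- rowsum(subunits$weight, subunits$tract_id)
  tracts$x <- unname(rowsum(subunits$x * subunits$weight,
                            subunits$tract_id)[, 1] / wsum[, 1])
  tracts$y <- unname(rowsum(subunits$y * subunits$weight,
                            subunits$tract_id)[, 1] / wsum[, 1])

  ## -- 2018 clinic roster ----------------------------------------------
  nc <- max(1L, round(config$clinic_density * nt))
  home <- sample(nt, nc, replace = TRUE)
  ids18 <- sprintf("C%05d", seq_len(nc))
  aff18 <- draw_affiliations(nc, config$affiliation_probs)
  clinics18 <- tibble::tibble(
    id = ids18,
    name = clinic_names(aff18, seq_len(nc)),
    x = tracts$ax[home] + stats::runif(nc, -2, 2),
    y = tracts$ay[home] + stats::runif(nc, -2, 2),
    state = tracts$state[home],
    region = tracts$region[home],
    home_tract = tracts$tract_id[home],
    affiliation = aff18,
    fqhc_flag = aff18 == "FQHC"
  )

  ## -- road network (deterministic given points) ----------------------
  net <- generate_road_network(config, tracts[, c("x", "y")],
                               clinics18[, c("x", "y")])

  ## -- exits and entries -> 2020 roster --------------------------------
  exit_p <- config$exit_prob_by_affiliation[as.character(clinics18$affiliation)]
  exited <- stats::runif(nc) < exit_p
  n_entry <- stats::rbinom(1, nc, config$entry_rate)
  entrants <- NULL
  if (n_entry > 0) {
    ehome <- sample(nt, n_entry, replace = TRUE)
    eaff <- draw_affiliations(n_entry, config$entrant_affiliation_probs)
    entrants <- tibble::tibble(
      id = sprintf("E%05d", seq_len(n_entry)),
      name = clinic_names(eaff, nc + seq_len(n_entry)),
      x = tracts$ax[ehome] + stats::runif(n_entry, -2, 2),
      y = tracts$ay[ehome] + stats::runif(n_entry, -2, 2),
      state = tracts$state[ehome],
      region = tracts$region[ehome],
      home_tract = tracts$tract_id[ehome],
      affiliation = eaff,
      fqhc_flag = eaff == "FQHC"
    )
  }
  clinics20 <- dplyr::bind_rows(clinics18[!exited, , drop = FALSE], entrants)

  ## -- realized access change (primary mode) ---------------------------
  spd <- config$road_speed_minutes_per_unit
  mm <- min_travel_time_multi(net, tracts[, c("x", "y")],
                              list(clinics18[, c("x", "y")],
                                   clinics20[, c("x", "y")]),
                              access_minutes_per_unit = spd)
  in18 <- mm[, 1] <= config$threshold_minutes
  in20 <- mm[, 2] <= config$threshold_minutes
  prot <- protective_states(state_laws)
  a18 <- in18 | unname(prot[tracts$state])
  a20 <- in20 | unname(prot[tracts$state])
  lost <- a18 & !a20

  ## -- covariates conditional on loss (planted effects) ----------------
  p0 <- config$rural_base_prob
  odds0 <- p0 / (1 - p0)
  or_rural <- if (is.null(config$planted_or$rural)) 1 else config$planted_or$rural
  p1 <- or_rural * odds0 / (1 + or_rural * odds0)
  rural <- stats::runif(nt) < ifelse(lost, p1, p0)
  tracts$rucc <- ifelse(rural, sample(4:9, nt, replace = TRUE),
                        sample(1:3, nt, replace = TRUE))
  for (cov in names(covariate_bands)) {
    or_vec <- config$planted_or[[cov]]
    if (is.null(or_vec)) or_vec <- c(1, 1, 1)
    tracts[[cov]] <- draw_quartile_covariate(lost, or_vec,
                                             covariate_bands[[cov]])
  }
  # population structure
  tracts$population_total <- pmax(50, round(stats::rlnorm(nt, log(4000), 0.5)))
  tracts$prop_minors_15_17 <- stats::runif(nt, 0.14, 0.20)
  med_frac <- stats::rbeta(nt, 2.5, 5.5)
  under18 <- tracts$population_total * tracts$prop_under18
  tracts$pop_15_17 <- round(under18 * tracts$prop_minors_15_17)
  tracts$medicaid_minors <- round(under18 * med_frac)
  # missingness, injected into the analysis covariates only
  for (cov in c("svi_percentile", "pct_black", "pct_hispanic", "birth_rate")) {
    miss <- stats::runif(nt) < config$missing_rate
    tracts[[cov]][miss] <- NA_real_
  }

  # clinics carry the RUCC of their home tract's county analogue
  clinics18$rucc <- tracts$rucc[match(clinics18$home_tract, tracts$tract_id)]
  clinics20$rucc <- tracts$rucc[match(clinics20$home_tract, tracts$tract_id)]

  ## -- duplicate record injection --------------------------------------
  clinics18 <- inject_duplicates(clinics18, config$duplicate_rate, "D18")
  clinics20 <- inject_duplicates(clinics20, config$duplicate_rate, "D20")

  ## -- annual clinic-count series --------------------------------------
  ac <- config$annual_counts
  years <- seq(ac$start, ac$end)
  last_pre <- ac$breakpoint - 1
  mu <- ifelse(years <= last_pre,
               ac$level_2018 + ac$pre_slope * (years - 2018),
               ac$level_2018 + ac$pre_slope * (last_pre - 2018) +
                 ac$post_slope * (years - last_pre))
  annual_counts <- tibble::tibble(
    year = years,
    count = pmax(0, round(mu + stats::rnorm(length(years), 0, ac$noise_sd)))
  )

  structure(list(
    states = states[, c("state", "region")],
    state_laws = state_laws,
    tracts = tracts,
    subunits = subunits,
    clinics_2018 = clinics18,
    clinics_2020 = clinics20,
    road_network = net,
    annual_counts = annual_counts,
    config = config
  ), class = "scenario_bundle")
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat(sprintf(
    "<scenario_bundle> %d tracts in %d states; %d/%d clinic records (2018/2020)\n",
    nrow(x$tracts), nrow(x$states), nrow(x$clinics_2018), nrow(x$clinics_2020)))
  invisible(x)
}
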