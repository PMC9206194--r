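#' Assemble the tract-characteristics odds-ratio table
#'
#' Builds the lost-vs-maintained univariate odds-ratio table over the
#' standard tract characteristics: population density (urban/rural from
#' RUCC), census region, and quartiles of SVI percentile, proportion Black,
#' proportion Hispanic, birth rate, and proportion aged under 18. Reference
#' levels are urban, the first region level, and the bottom quartile. Tracts
#' missing a covariate are dropped from that covariate's rows only.
#'
#' @param records Access records from [classify_access()].
#' @param tracts Tract table with `tract_id`, `rucc`, `region` and the
#'   continuous covariates.
#' @return Tibble of [univariate_or()] rows for every predictor, with a
#'   `cut_points` attribute listing quartile cut points per binned covariate.
#' @export
tabulate_access_ors <- function(records, tracts) {
  keep <- intersect(c("tract_id", "state", "rucc", "region",
                      names(covariate_bands)), names(tracts))
  df <- dplyr::inner_join(records, tracts[, keep], by = c("tract_id", "state"))
  sub <- exclude_for_or_analysis(df)
  sub$lost <- sub$category == "lost"
  sub$urban_rural <- factor(ifelse(sub$rucc <= 3, "Urban", "Rural"),
                            levels = c("Urban", "Rural"))
  skipped <- character(0)
  try_or <- function(pred, label) {
    tryCatch({
      rows <- univariate_or(sub, "lost", pred)
      rows$predictor <- label
      rows
    }, error = function(e) {
      skipped <<- c(skipped, label)
      NULL
    })
  }
  out <- list(try_or("urban_rural", "urban_rural"))
  if ("region" %in% names(sub)) {
    sub$region <- factor(sub$region)
    out <- c(out, list(try_or("region", "region")))
  }
  cuts <- list()
  for (cov in intersect(names(covariate_bands), names(sub))) {
    qb <- quartile_bin(sub[[cov]])
    sub[[paste0(cov, "_q")]] <- qb$labels
    cuts[[cov]] <- qb$cut_points
    out <- c(out, list(try_or(paste0(cov, "_q"), cov)))
  }
  out <- dplyr::bind_rows(out)
  attr(out, "cut_points") <- cuts
  # predictors with an empty cell cannot carry a finite Wald interval
  attr(out, "skipped") <- skipped
  out
}

#' Write a scenario bundle to plain-text files
#'
#' @param bundle A `scenario_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    tracts = "tracts.csv", subunits = "subunits.csv",
    clinics_2018 = "clinics_2018.csv", clinics_2020 = "clinics_2020.csv",
    state_laws = "state_laws.csv", annual_counts = "annual_counts.csv"
  )
  paths <- setNames(file.path(dir, paths), names(paths))
  for (nm in names(paths)) readr::write_csv(bundle[[nm]], paths[nm])
  node_path <- file.path(dir, "road_nodes.csv")
  edge_path <- file.path(dir, "road_edges.csv")
  readr::write_csv(bundle$road_network$nodes, node_path)
  readr::write_csv(bundle$road_network$edges, edge_path)
  invisible(c(paths, road_nodes = node_path, road_edges = edge_path))
}

#' Read a scenario bundle written by [write_scenario()]
#'
#' @param dir Directory containing the scenario CSV files.
#' @param coords Coordinate system of the road network.
#' @return A `scenario_bundle` (without a `config`).
#' @export
read_scenario <- function(dir, coords = "planar") {
  rd <- function(f) readr::read_csv(file.path(dir, f), show_col_types = FALSE)
  missing <- setdiff(c("tracts.csv", "clinics_2018.csv", "clinics_2020.csv",
                       "state_laws.csv", "road_nodes.csv", "road_edges.csv"),
                     list.files(dir))
  if (length(missing) > 0) {
    stop("missing scenario file(s) in ", dir, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(
    tracts = rd("tracts.csv"),
    subunits = if (file.exists(file.path(dir, "subunits.csv")))
      rd("subunits.csv") else NULL,
    clinics_2018 = rd("clinics_2018.csv"),
    clinics_2020 = rd("clinics_2020.csv"),
    state_laws = rd("state_laws.csv"),
    annual_counts = if (file.exists(file.path(dir, "annual_counts.csv")))
      rd("annual_counts.csv") else NULL,
    road_network = road_network(rd("road_nodes.csv"), rd("road_edges.csv"),
                                coords = coords)
  ), class = "scenario_bundle")
}

#' Write tract access categories as a GeoJSON FeatureCollection
#'
#' Each tract becomes a square polygon centred on its population-weighted
#' centroid carrying the access-change category, for choropleth-style
#' rendering.
#'
#' @param records Access records from [classify_access()].
#' @param tracts Tract table with `tract_id`, `x`, `y`.
#' @param path Output `.geojson` path.
#' @param half_side Half the square's side length, in coordinate units.
#' @return Invisibly, `path`.
#' @export
write_access_geojson <- function(records, tracts, path, half_side = 1.5) {
  df <- dplyr::inner_join(records, tracts[, c("tract_id", "x", "y")],
                          by = "tract_id")
  features <- lapply(seq_len(nrow(df)), function(i) {
    x <- df$x[i]; y <- df$y[i]; h <- half_side
    ring <- list(c(x - h, y - h), c(x + h, y - h), c(x + h, y + h),
                 c(x - h, y + h), c(x - h, y - h))
    list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(ring)),
      properties = list(tract_id = df$tract_id[i],
                        category = as.character(df$category[i]))
    )
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' Run the full access-change pipeline
#'
#' Orchestrates every stage on a synthetic scenario: generation, roster
#' deduplication and membership differencing, composition tables, per-tract
#' access classification, youth-at-risk summary, state-level percentages for
#' both epochs, the odds-ratio table, and the interrupted time series fit.
#' All inputs and outputs are written to `outdir` as plain files, plus a run
#' log echoing the configuration, so each stage can be re-read and checked
#' independently.
#'
#' @param config A [scenario_config()].
#' @param outdir Output directory.
#' @param mode Access mode, see [tract_access()].
#' @return Invisibly, a list with all intermediate results:
#'   `bundle`, `membership`, `summary` (program change),
#'   `composition_tables`, `records`, `youth`, `state_2018`, `state_2020`,
#'   `or_table`, `its`, and `paths`.
#' @export
run_pipeline <- function(config = scenario_config(), outdir,
                         mode = c("primary", "catchment_only", "expanded_law")) {
  mode <- match.arg(mode)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  bundle <- generate_scenario(config)
  write_scenario(bundle, file.path(outdir, "scenario"))

  d18 <- deduplicate_roster(bundle$clinics_2018)
  d20 <- deduplicate_roster(bundle$clinics_2020)
  membership <- classify_membership(d18$roster, d20$roster)
  membership <- classify_affiliation(membership)
  chg <- program_change_summary(membership,
                                n_records_2018 = nrow(bundle$clinics_2018))

  tables <- lapply(
    c(affiliation = "affiliation", urban_rural = "urban_rural",
      region = "region", law_status = "law_status"),
    function(s) tabulate_characteristics(membership, s,
                                         state_laws = bundle$state_laws)
  )

  records <- classify_access(
    bundle$tracts, d18$roster, d20$roster, bundle$road_network,
    bundle$state_laws, mode = mode,
    threshold_minutes = config$threshold_minutes,
    access_minutes_per_unit = config$road_speed_minutes_per_unit
  )
  youth <- youth_at_risk(records)
  st18 <- state_percent_without_access(records, 2018)
  st20 <- state_percent_without_access(records, 2020)
  or_table <- tabulate_access_ors(records, bundle$tracts)
  its <- segmented_regression(bundle$annual_counts,
                              config$annual_counts$breakpoint)

  paths <- list(
    membership = file.path(outdir, "clinic_membership.csv"),
    access = file.path(outdir, "access_records.csv"),
    or_table = file.path(outdir, "tract_odds_ratios.csv"),
    state_summary = file.path(outdir, "state_summary.csv"),
    its = file.path(outdir, "its_fit.csv"),
    geojson = file.path(outdir, "access_map.geojson"),
    log = file.path(outdir, "run_log.txt")
  )
  readr::write_csv(membership, paths$membership)
  readr::write_csv(records, paths$access)
  readr::write_csv(or_table, paths$or_table)
  for (nm in names(tables)) {
    readr::write_csv(tables[[nm]],
                     file.path(outdir, paste0("table1_", nm, ".csv")))
  }
  readr::write_csv(
    dplyr::bind_rows(`2018` = st18, `2020` = st20, .id = "epoch"),
    paths$state_summary)
  readr::write_csv(tibble::tibble(
    segment = c("pre", "post"),
    slope = c(its$pre_slope, its$post_slope),
    ci_low = c(its$pre_ci[1], its$post_ci[1]),
    ci_high = c(its$pre_ci[2], its$post_ci[2]),
    breakpoint_year = its$breakpoint_year
  ), paths$its)
  write_access_geojson(records, bundle$tracts, paths$geojson)
  writeLines(c(
    sprintf("txaccess %s", as.character(utils::packageVersion("txaccess"))),
    sprintf("R %s", R.version.string),
    sprintf("mode: %s", mode),
    sprintf("seed: %d", config$seed),
    sprintf("threshold_minutes: %s", config$threshold_minutes),
    sprintf("tracts: %d  states: %d", nrow(bundle$tracts), nrow(bundle$states)),
    sprintf("clinic records 2018/2020: %d/%d",
            nrow(bundle$clinics_2018), nrow(bundle$clinics_2020))
  ), paths$log)

  invisible(list(
    bundle = bundle, membership = membership, summary = chg,
    composition_tables = tables, records = records, youth = youth,
    state_2018 = st18, state_2020 = st20, or_table = or_table, its = its,
    paths = paths
  ))
}
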