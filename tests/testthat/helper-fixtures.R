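# Shared fixtures and independent oracles, built in code at test time.

# ---- independent shortest-path oracle: exhaustive simple-path search ----
# depth-first enumeration of simple paths with cost pruning; independent of
# the igraph-backed implementation.
brute_force_shortest <- function(nodes, edges, from, to) {
  adj <- lapply(nodes$id, function(i) {
    hit <- edges$u == i | edges$v == i
    data.frame(nb = ifelse(edges$u[hit] == i, edges$v[hit], edges$u[hit]),
               w = edges$minutes[hit])
  })
  names(adj) <- nodes$id
  best <- Inf
  visit <- function(node, cost, seen) {
    if (cost >= best) return(invisible())
    if (node == to) { best <<- cost; return(invisible()) }
    nb <- adj[[node]]
    for (k in seq_len(nrow(nb))) {
      if (!(nb$nb[k] %in% seen)) {
        visit(nb$nb[k], cost + nb$w[k], c(seen, nb$nb[k]))
      }
    }
  }
  visit(from, 0, from)
  best
}

# random connected weighted network: spanning tree + extra edges
random_network <- function(n_nodes, n_extra = n_nodes %/% 2) {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  nodes <- tibble::tibble(id = ids,
                          x = stats::runif(n_nodes, 0, 100),
                          y = stats::runif(n_nodes, 0, 100))
  u <- v <- character(0)
  for (i in 2:n_nodes) {
    u <- c(u, ids[sample(i - 1, 1)])
    v <- c(v, ids[i])
  }
  for (k in seq_len(n_extra)) {
    pair <- sample(n_nodes, 2)
    u <- c(u, ids[pair[1]])
    v <- c(v, ids[pair[2]])
  }
  edges <- tibble::tibble(u = u, v = v,
                          minutes = stats::runif(length(u), 1, 20))
  road_network(nodes, edges)
}

# ---- calibrated clinic rosters mirroring the observed program change ----
# 4466 raw 2018 records = 4343 unique + 123 duplicates; 1743 unique clinics
# leave, 2600 stay; 494 join; 486 Planned Parenthood sites of which 481
# leave; urban/rural 2793/1550 among the 2018 roster.
calibrated_rosters <- function() {
  n18 <- 4343
  pp <- 486
  pp_left <- 481
  n_left <- 1743
  n_join <- 494
  name <- c(sprintf("Planned Parenthood Health Center %04d", seq_len(pp)),
            sprintf("Family Planning Clinic %04d", seq_len(n18 - pp)))
  # leavers: 481 PP + 1262 others (placed right after the PP block)
  left <- c(rep(TRUE, pp_left), rep(FALSE, pp - pp_left),
            rep(TRUE, n_left - pp_left), rep(FALSE, n18 - pp - (n_left - pp_left)))
  rucc <- c(rep(1L, 2793), rep(5L, n18 - 2793))
  r2018 <- tibble::tibble(
    id = sprintf("A%05d", seq_len(n18)),
    name = name,
    x = seq_len(n18) * 0.01,
    y = 10,
    state = "S01",
    rucc = rucc
  )
  dup <- r2018[seq_len(123), ]
  dup$id <- sprintf("DUP%03d", seq_len(123))
  stayed <- r2018[!left, ]
  joined <- tibble::tibble(
    id = sprintf("J%05d", seq_len(n_join)),
    name = sprintf("New Family Planning Clinic %04d", seq_len(n_join)),
    x = 1000 + seq_len(n_join) * 0.01,
    y = 10,
    state = "S01",
    rucc = 1L
  )
  list(r2018_raw = dplyr::bind_rows(r2018, dup),
       r2020 = dplyr::bind_rows(stayed, joined))
}

# ---- calibrated access records mirroring the tract-level headline ----
# 72 760 tracts: 6299 lost / 61 063 maintained / 729 gained / 4669 never.
# Youth 15-17 in lost tracts total 933 649, of whom 290 799 are
# Medicaid-enrolled (so 642 850 are not).
calibrated_access_records <- function() {
  n <- c(lost = 6299, maintained = 61063, gained = 729, never = 4669)
  category <- factor(rep(names(n), n),
                     levels = c("lost", "maintained", "gained", "never"))
  pop <- rep(100L, sum(n))
  pop[category == "lost"] <- rep(148L, n["lost"]) +
    c(rep(1L, 933649 - 6299 * 148), rep(0L, 6299 - (933649 - 6299 * 148)))
  med_minors <- rep(30L, sum(n))
  med_minors[category == "lost"] <- rep(46L, n["lost"]) +
    c(rep(1L, 290799 - 6299 * 46), rep(0L, 6299 - (290799 - 6299 * 46)))
  med <- estimate_medicaid_15_17(med_minors, 1.0)
  tibble::tibble(
    tract_id = sprintf("T%06d", seq_len(sum(n))),
    state = "S01",
    access_2018 = category %in% c("lost", "maintained"),
    access_2020 = category %in% c("maintained", "gained"),
    category = category,
    pop_15_17 = pop,
    medicaid_15_17_est = med,
    non_medicaid_15_17_est = pop - med
  )
}

# ---- printed Table-2 contingency cells -------------------------------
# cases = tracts that lost access, controls = tracts that kept access;
# expected OR/CI given to the precision of the reference table they mirror.
table2_cells <- function() {
  tibble::tribble(
    ~level, ~cases, ~controls, ~ref_cases, ~ref_controls, ~or, ~lo, ~hi,
    "rural", 1028, 8139, 5271, 52924, 1.27, 1.18, 1.36,
    "midwest", 2706, 11740, 1153, 12069, 2.41, 2.24, 2.60,
    "south", 1003, 23241, 1153, 12069, 0.45, 0.41, 0.49,
    "west", 1437, 14013, 1153, 12069, 1.07, 1.0, 1.16,
    "svi_q2", 1700, 14708, 2049, 14824, 0.84, 0.78, 0.90,
    "svi_q3", 1394, 15063, 2049, 14824, 0.67, 0.62, 0.72,
    "svi_q4", 1127, 15978, 2049, 14824, 0.51, 0.47, 0.55,
    "black_q2", 1824, 15033, 2248, 13025, 0.70, 0.66, 0.75,
    "black_q3", 1230, 16046, 2248, 13025, 0.44, 0.41, 0.48,
    "black_q4", 976, 16682, 2248, 13025, 0.34, 0.31, 0.37,
    "hispanic_q2", 1965, 14759, 1778, 14287, 1.07, 1.00, 1.15,
    "hispanic_q3", 1615, 15441, 1778, 14287, 0.84, 0.78, 0.90,
    "hispanic_q4", 920, 16299, 1778, 14287, 0.45, 0.42, 0.49
  )
}

clinic_key_test <- function(df) {
  paste(normalize_clinic_name(df$name), round(df$x, 4), round(df$y, 4))
}

# small config for fast scenario generation in unit tests
small_config <- function(seed = 1, ...) {
  scenario_config(n_states = 6, n_tracts_per_state = 25,
                  clinic_density = 0.12, seed = seed, ...)
}

# round to the precision at which a reference value is printed
round_to_printed <- function(x, printed) {
  digits <- nchar(sub("^[^.]*\\.?", "", format(printed, drop0trailing = TRUE)))
  round_half_up(x, digits)
}
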