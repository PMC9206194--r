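test_that("change category follows the exact truth table", {
  expect_equal(as.character(change_category(TRUE, FALSE)), "lost")
  expect_equal(as.character(change_category(TRUE, TRUE)), "maintained")
  expect_equal(as.character(change_category(FALSE, TRUE)), "gained")
  expect_equal(as.character(change_category(FALSE, FALSE)), "never")
  # vectorized and level-complete
  out <- change_category(c(TRUE, TRUE, FALSE, FALSE), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(levels(out), c("lost", "maintained", "gained", "never"))
  expect_equal(as.character(out), c("lost", "maintained", "gained", "never"))
})

test_that("access modes combine catchment and law as specified", {
  laws <- state_law_table(1, 0, 1, 1,
                          states = c("PROT", "LIM", "DISC"))
  # protective state, no clinic in range
  expect_true(tract_access(FALSE, "PROT", laws, "primary"))
  expect_false(tract_access(FALSE, "PROT", laws, "catchment_only"))
  # discretion state counts only under the expanded-law sensitivity variant
  expect_false(tract_access(FALSE, "DISC", laws, "primary"))
  expect_true(tract_access(FALSE, "DISC", laws, "expanded_law"))
  # clinic in range: access in every mode
  for (m in c("primary", "catchment_only", "expanded_law")) {
    expect_true(tract_access(TRUE, "LIM", laws, m))
  }
  # non-protective state, no clinic: no access in any mode
  for (m in c("primary", "catchment_only", "expanded_law")) {
    expect_false(tract_access(FALSE, "LIM", laws, m))
  }
  expect_error(tract_access(TRUE, "XX", laws, "primary"), "XX")
})

test_that("Medicaid 15-17 estimate is the rounded product", {
  expect_equal(estimate_medicaid_15_17(1000, 0.17), 170)
  expect_equal(estimate_medicaid_15_17(0, 0.5), 0)
  expect_equal(estimate_medicaid_15_17(5, 0.5), 3)  # half rounds up
  expect_error(estimate_medicaid_15_17(-1, 0.5), "non-negative")
  expect_error(estimate_medicaid_15_17(10, 1.5), "0, 1")
})

test_that("youth-at-risk summary matches a naive per-tract loop oracle", {
  b <- generate_scenario(small_config(seed = 13))
  rec <- classify_access(b$tracts, deduplicate_roster(b$clinics_2018)$roster,
                         deduplicate_roster(b$clinics_2020)$roster,
                         b$road_network, b$state_laws)
  y <- youth_at_risk(rec)
  # categories partition the evaluated tracts
  expect_equal(sum(y$by_category$n_tracts), nrow(b$tracts))
  # naive loop oracle
  for (cat in levels(rec$category)) {
    tot <- 0; n <- 0; med <- 0
    for (i in seq_len(nrow(rec))) {
      if (as.character(rec$category[i]) == cat) {
        n <- n + 1
        tot <- tot + rec$pop_15_17[i]
        med <- med + rec$medicaid_15_17_est[i]
      }
    }
    row <- y$by_category[y$by_category$category == cat, ]
    expect_equal(row$n_tracts, n)
    expect_equal(row$youth_15_17, tot)
    expect_equal(row$medicaid_15_17, med)
  }
  expect_equal(y$non_medicaid_at_risk + y$medicaid_at_risk, y$youth_at_risk)
})

test_that("no youth are at risk when no tract lost access", {
  rec <- tibble::tibble(
    tract_id = c("a", "b"), state = "S01",
    access_2018 = c(TRUE, FALSE), access_2020 = c(TRUE, TRUE),
    category = change_category(c(TRUE, FALSE), c(TRUE, TRUE)),
    pop_15_17 = c(10, 20), medicaid_15_17_est = c(1, 2),
    non_medicaid_15_17_est = c(9, 18)
  )
  y <- youth_at_risk(rec)
  expect_equal(y$youth_at_risk, 0)
  expect_true(is.na(y$pct_non_medicaid))
})

test_that("protective-state tracts can only maintain or gain under the primary mode", {
  for (seed in c(2, 14)) {
    b <- generate_scenario(small_config(seed = seed))
    rec <- classify_access(b$tracts, b$clinics_2018, b$clinics_2020,
                           b$road_network, b$state_laws, mode = "primary")
    prot <- protective_states(b$state_laws)
    in_prot <- unname(prot[rec$state])
    expect_true(all(rec$category[in_prot] %in% c("maintained", "gained")))
    # all lost/never tracts lie in non-protective states
    expect_true(all(!in_prot[rec$category %in% c("lost", "never")]))
  }
})

test_that("catchment-only mode finds protective-state tracts that lost their clinics", {
  b <- generate_scenario(small_config(seed = 6))
  prim <- classify_access(b$tracts, b$clinics_2018, b$clinics_2020,
                          b$road_network, b$state_laws, mode = "primary")
  catch <- classify_access(b$tracts, b$clinics_2018, b$clinics_2020,
                           b$road_network, b$state_laws, mode = "catchment_only")
  # tracts lost under primary are lost under catchment_only as well
  expect_true(all(catch$category[prim$category == "lost"] == "lost"))
  # the extra lost tracts all sit in protective states
  extra <- catch$category == "lost" & prim$category != "lost"
  prot <- protective_states(b$state_laws)
  expect_true(all(unname(prot[catch$state[extra]])))
})

test_that("state percentages match a naive summation oracle and flag empty states", {
  b <- generate_scenario(small_config(seed = 23))
  rec <- classify_access(b$tracts, b$clinics_2018, b$clinics_2020,
                         b$road_network, b$state_laws)
  st <- state_percent_without_access(rec, 2020)
  for (s in st$state) {
    sel <- rec$state == s
    expect_equal(st$pct_without_access[st$state == s],
                 100 * sum(rec$pop_15_17[sel & !rec$access_2020]) /
                   sum(rec$pop_15_17[sel]))
  }
  # all tracts with access -> 0% everywhere
  rec0 <- rec
  rec0$access_2020 <- TRUE
  st0 <- state_percent_without_access(rec0, 2020)
  expect_true(all(st0$pct_without_access == 0))
  expect_equal(attr(st0, "n_states_over"), 0)
  # zero-population state flagged as undefined
  rec$pop_15_17[rec$state == rec$state[1]] <- 0
  stz <- state_percent_without_access(rec, 2020)
  expect_true(stz$undefined[stz$state == rec$state[1]])
  expect_true(is.na(stz$pct_without_access[stz$state == rec$state[1]]))
})
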