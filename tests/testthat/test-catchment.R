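two_node_net <- function() {
  road_network(tibble::tibble(id = c("a", "b"), x = c(0, 10), y = 0),
               tibble::tibble(u = "a", v = "b", minutes = 10))
}

chain_net <- function() {
  road_network(
    tibble::tibble(id = c("a", "b", "c"), x = c(0, 10, 25), y = 0),
    tibble::tibble(u = c("a", "b"), v = c("b", "c"), minutes = c(10, 15))
  )
}

test_that("population-weighted centroid is the weighted coordinate mean", {
  expect_equal(
    population_weighted_centroid(data.frame(x = 3, y = 7, weight = 5)),
    c(x = 3, y = 7))
  expect_equal(
    population_weighted_centroid(data.frame(x = c(0, 2), y = 0, weight = 1)),
    c(x = 1, y = 0))
  # invariance to uniform weight rescaling + direct-summation oracle
  set.seed(12)
  for (rep in 1:10) {
    su <- data.frame(x = runif(10), y = runif(10), weight = runif(10, 0, 5))
    cen <- population_weighted_centroid(su)
    expect_equal(unname(cen["x"]), sum(su$x * su$weight) / sum(su$weight),
                 tolerance = 1e-12)
    su2 <- su; su2$weight <- su$weight * 17.3
    expect_equal(population_weighted_centroid(su2), cen, tolerance = 1e-12)
  }
  expect_error(population_weighted_centroid(
    data.frame(x = 1, y = 1, weight = 0)), "positive sum")
})

test_that("travel times honour edge weights, additivity and zero self-distance", {
  net <- two_node_net()
  tt <- shortest_travel_time(net, data.frame(x = 0, y = 0),
                             data.frame(x = c(0, 10), y = 0))
  expect_equal(tt[1, ], c(0, 10))
  chain <- chain_net()
  tt2 <- shortest_travel_time(chain, data.frame(x = 0, y = 0),
                              data.frame(x = 25, y = 0))
  expect_equal(tt2[1, 1], 25)
  # empty target set
  expect_equal(ncol(shortest_travel_time(net, data.frame(x = 0, y = 0),
                                         data.frame(x = numeric(0),
                                                    y = numeric(0)))), 0)
})

test_that("snap penalties add off-network access time", {
  net <- two_node_net()
  # origin 3 units below node a: 3 minutes of access time at 1 min/unit
  tt <- shortest_travel_time(net, data.frame(x = 0, y = -3),
                             data.frame(x = 10, y = 0))
  expect_equal(tt[1, 1], 13)
  tt2 <- shortest_travel_time(net, data.frame(x = 0, y = -3),
                              data.frame(x = 10, y = 0),
                              access_minutes_per_unit = 2)
  expect_equal(tt2[1, 1], 16)
})

test_that("unreachable targets get infinite travel time", {
  net <- road_network(
    tibble::tibble(id = c("a", "b", "c", "d"), x = c(0, 1, 50, 51), y = 0),
    tibble::tibble(u = c("a", "c"), v = c("b", "d"), minutes = 1)
  )
  tt <- shortest_travel_time(net, data.frame(x = 0, y = 0),
                             data.frame(x = 51, y = 0))
  expect_equal(tt[1, 1], Inf)
})

test_that("network times equal the exhaustive path-enumeration oracle", {
  set.seed(2024)
  for (rep in 1:6) {
    n <- sample(12:40, 1)
    net <- random_network(n)
    ids <- net$nodes$id
    pairs <- t(replicate(8, sample(n, 2)))
    g <- igraph::graph_from_data_frame(net$edges[, c("u", "v")],
                                       directed = FALSE, vertices = ids)
    for (k in seq_len(nrow(pairs))) {
      from <- ids[pairs[k, 1]]
      to <- ids[pairs[k, 2]]
      oracle <- brute_force_shortest(net$nodes, net$edges, from, to)
      got <- shortest_travel_time(
        net,
        net$nodes[pairs[k, 1], c("x", "y")],
        net$nodes[pairs[k, 2], c("x", "y")])[1, 1]
      expect_equal(got, oracle, tolerance = 1e-9)
    }
  }
})

test_that("path costs obey the triangle inequality", {
  set.seed(31)
  net <- random_network(20)
  pts <- net$nodes[, c("x", "y")]
  D <- shortest_travel_time(net, pts, pts)
  for (rep in 1:200) {
    ijk <- sample(20, 3)
    expect_lte(D[ijk[1], ijk[3]],
               D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-9)
  }
})

test_that("drive-time membership is inclusive at the threshold", {
  net <- chain_net()
  origin <- data.frame(x = 0, y = 0)
  expect_true(tract_within_drive(net, origin, data.frame(x = 10, y = 0),
                                 threshold_minutes = 30))   # 10 min
  expect_false(tract_within_drive(net, origin, data.frame(x = 25, y = 0),
                                  threshold_minutes = 20))  # 25 min
  # exactly at the threshold counts as within reach
  expect_true(tract_within_drive(net, origin, data.frame(x = 25, y = 0),
                                 threshold_minutes = 25))
  # no clinics: no access, not an error
  expect_false(tract_within_drive(net, origin,
                                  data.frame(x = numeric(0), y = numeric(0))))
})

test_that("access is monotone in clinics and threshold", {
  set.seed(90)
  for (rep in 1:25) {
    net <- random_network(15)
    tractpts <- data.frame(x = runif(6, 0, 100), y = runif(6, 0, 100))
    clin1 <- data.frame(x = runif(3, 0, 100), y = runif(3, 0, 100))
    clin2 <- rbind(clin1, data.frame(x = runif(2, 0, 100), y = runif(2, 0, 100)))
    thr <- runif(1, 10, 60)
    a1 <- tract_within_drive(net, tractpts, clin1, thr)
    a2 <- tract_within_drive(net, tractpts, clin2, thr)
    a3 <- tract_within_drive(net, tractpts, clin1, thr + 15)
    expect_true(all(a2[a1]))  # adding a clinic never removes access
    expect_true(all(a3[a1]))  # raising the threshold never removes access
  }
})

test_that("min_travel_time agrees with the full travel-time matrix", {
  set.seed(55)
  net <- random_network(25)
  origins <- data.frame(x = runif(12, 0, 100), y = runif(12, 0, 100))
  targets <- data.frame(x = runif(7, 0, 100), y = runif(7, 0, 100))
  full <- shortest_travel_time(net, origins, targets)
  expect_equal(min_travel_time(net, origins, targets),
               apply(full, 1, min), tolerance = 1e-10)
})

test_that("straight-line fallback matches a complete graph of straight-line times", {
  set.seed(66)
  pts <- tibble::tibble(id = sprintf("p%d", 1:8),
                        x = runif(8, 0, 50), y = runif(8, 0, 50))
  pairs <- utils::combn(8, 2)
  edges <- tibble::tibble(
    u = pts$id[pairs[1, ]], v = pts$id[pairs[2, ]],
    minutes = sqrt((pts$x[pairs[1, ]] - pts$x[pairs[2, ]])^2 +
                     (pts$y[pairs[1, ]] - pts$y[pairs[2, ]])^2)
  )
  net <- road_network(pts, edges)
  D_net <- shortest_travel_time(net, pts[, c("x", "y")], pts[, c("x", "y")])
  D_line <- straight_line_travel_time(pts[, c("x", "y")], pts[, c("x", "y")])
  expect_equal(D_net, D_line, tolerance = 1e-9)
})

test_that("lon/lat mode uses haversine distances for snapping", {
  net <- road_network(
    tibble::tibble(id = c("a", "b"), x = c(-75.0, -75.1), y = c(40.0, 40.0)),
    tibble::tibble(u = "a", v = "b", minutes = 12),
    coords = "lonlat"
  )
  # origin exactly on node a, clinic on node b: pure network time
  tt <- shortest_travel_time(net, data.frame(x = -75.0, y = 40.0),
                             data.frame(x = -75.1, y = 40.0))
  expect_equal(tt[1, 1], 12)
  # origin offset ~1.11 km south of node a at 1 min/km
  off <- shortest_travel_time(net, data.frame(x = -75.0, y = 39.99),
                              data.frame(x = -75.1, y = 40.0))
  expect_equal(off[1, 1] - 12,
               geosphere::distHaversine(c(-75, 39.99), c(-75, 40)) / 1000,
               tolerance = 1e-6)
})
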