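#' Construct a road network
#'
#' A road network is an undirected weighted graph: nodes with planar or
#' geographic coordinates and edges carrying positive travel times in minutes.
#' It stands in for a commercial drive-time engine: catchment membership is
#' decided by shortest-path travel time over this graph.
#'
#' @param nodes Data frame with columns `id`, `x`, `y`.
#' @param edges Data frame with columns `u`, `v`, `minutes` (positive).
#' @param coords `"planar"` (Euclidean snap distances) or `"lonlat"`
#'   (haversine snap distances; `x` = longitude, `y` = latitude).
#' @return A `road_network` object.
#' @export
road_network <- function(nodes, edges, coords = c("planar", "lonlat")) {
  coords <- match.arg(coords)
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("id", "x", "y") %in% names(nodes)),
            all(c("u", "v", "minutes") %in% names(edges)))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  if (nrow(edges) > 0) {
    if (any(!is.finite(edges$minutes)) || any(edges$minutes <= 0)) {
      stop("edge travel times must be positive minutes", call. = FALSE)
    }
    known <- c(edges$u, edges$v) %in% nodes$id
    if (!all(known)) stop("edge endpoint not present in nodes", call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, coords = coords),
            class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network> %d nodes, %d edges (%s coordinates)\n",
              nrow(x$nodes), nrow(x$edges), x$coords))
  invisible(x)
}

travel_graph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("u", "v")], directed = FALSE,
    vertices = data.frame(name = as.character(net$nodes$id))
  )
  igraph::E(g)$weight <- net$edges$minutes
  g
}

#' Population-weighted centroid of tract sub-units
#'
#' Census tracts are represented by 1-9 population sub-units (block-group
#' analogues): weighted points whose weighted coordinate-wise mean is the
#' tract's population-weighted centroid, the origin used for drive-time
#' evaluation.
#'
#' @param subunits Data frame with columns `x`, `y`, `weight` (weights >= 0,
#'   positive sum).
#' @return Named numeric vector `c(x =, y =)`.
#' @examples
#' population_weighted_centroid(data.frame(x = c(0, 2), y = 0, weight = 1))
#' @export
population_weighted_centroid <- function(subunits) {
  w <- subunits$weight
  if (length(w) == 0 || any(w < 0) || sum(w) <= 0) {
    stop("sub-unit weights must be >= 0 with a positive sum", call. = FALSE)
  }
  c(x = sum(subunits$x * w) / sum(w), y = sum(subunits$y * w) / sum(w))
}

as_point_matrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  if (is.data.frame(p)) p <- as.matrix(p[, c("x", "y")])
  storage.mode(p) <- "double"
  p
}

# straight-line distance in network units (planar) or km (lonlat)
point_distance <- function(a, b, coords) {
  if (coords == "lonlat") {
    geosphere::distHaversine(a, b) / 1000
  } else {
    sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
  }
}

# nearest network node for each point; returns node index + snap distance.
# planar search is chunked matrix algebra so many thousands of points snap
# quickly; lonlat loops over the smaller dimension.
snap_points <- function(net, points) {
  points <- as_point_matrix(points)
  np <- nrow(points)
  nx <- net$nodes$x
  ny <- net$nodes$y
  idx <- integer(np)
  dist <- numeric(np)
  if (net$coords == "lonlat") {
    for (i in seq_len(np)) {
      d <- geosphere::distHaversine(points[i, , drop = FALSE],
                                    cbind(nx, ny)) / 1000
      idx[i] <- which.min(d)
      dist[i] <- d[idx[i]]
    }
  } else {
    nodes_m <- cbind(nx, ny)
    node_norm <- nx^2 + ny^2
    pt_norm <- points[, 1]^2 + points[, 2]^2
    chunk <- max(1L, floor(8e6 / length(nx)))
    for (s in seq(1L, np, by = chunk)) {
      rows <- s:min(np, s + chunk - 1L)
      # squared distances via ||p||^2 + ||n||^2 - 2 p.n (BLAS)
      d2 <- sweep(-2 * tcrossprod(points[rows, , drop = FALSE], nodes_m),
                  2, node_norm, `+`) + pt_norm[rows]
      j <- max.col(-d2, ties.method = "first")
      idx[rows] <- j
      # recompute the winning distance directly: the expanded-square form
      # is only used to find the argmin, not to report the distance
      dist[rows] <- sqrt((points[rows, 1] - nx[j])^2 +
                           (points[rows, 2] - ny[j])^2)
    }
  }
  list(node = idx, dist = dist)
}

#' Shortest travel time between located points over a road network
#'
#' Origins and targets are snapped to their nearest network node by
#' straight-line distance; the off-network leg is converted to minutes at
#' `access_minutes_per_unit`. Travel time is then snap + shortest path + snap.
#' Unreachable pairs get `Inf`.
#'
#' @param net A [road_network()].
#' @param origins,targets Data frames with `x`, `y` columns (or 2-column
#'   matrices). An empty target set returns a 0-column matrix.
#' @param access_minutes_per_unit Minutes per distance unit (planar) or per
#'   kilometre (lonlat) for the off-network access legs. Default 1.
#' @return Numeric matrix of minutes, `nrow(origins)` x `nrow(targets)`.
#' @export
shortest_travel_time <- function(net, origins, targets,
                                 access_minutes_per_unit = 1) {
  origins <- as_point_matrix(origins)
  targets <- as_point_matrix(targets)
  if (nrow(targets) == 0) {
    return(matrix(numeric(0), nrow = nrow(origins), ncol = 0))
  }
  if (nrow(net$nodes) == 0) stop("road network has no nodes", call. = FALSE)
  g <- travel_graph(net)
  so <- snap_points(net, origins)
  st <- snap_points(net, targets)
  uo <- sort(unique(so$node))
  ut <- sort(unique(st$node))
  D <- igraph::distances(g,
                         v = as.character(net$nodes$id)[uo],
                         to = as.character(net$nodes$id)[ut],
                         algorithm = "dijkstra")
  oi <- match(so$node, uo)
  ti <- match(st$node, ut)
  path <- D[oi, ti, drop = FALSE]
  out <- sweep(sweep(path, 1, so$dist * access_minutes_per_unit, `+`),
               2, st$dist * access_minutes_per_unit, `+`)
  dimnames(out) <- NULL
  out
}

#' Minimum travel time from each origin to its nearest target
#'
#' Memory-light reduction of [shortest_travel_time()]: returns, per origin,
#' the travel time to the closest target. Useful with many tracts and clinics.
#'
#' @inheritParams shortest_travel_time
#' @return Numeric vector, `Inf` where no target is reachable, `Inf` for an
#'   empty target set.
#' @export
min_travel_time <- function(net, origins, targets,
                            access_minutes_per_unit = 1) {
  min_travel_time_multi(net, origins, list(targets),
                        access_minutes_per_unit)[, 1]
}

#' Minimum travel times against several target sets at once
#'
#' Computes, per origin, the travel time to the closest member of each target
#' set, sharing the origin snapping and the shortest-path computation across
#' sets. The workhorse for evaluating the same tract centroids against both
#' epoch rosters.
#'
#' @inheritParams shortest_travel_time
#' @param target_sets List of data frames/matrices of target points.
#' @return Numeric matrix, `nrow(origins)` x `length(target_sets)`.
#' @export
min_travel_time_multi <- function(net, origins, target_sets,
                                  access_minutes_per_unit = 1) {
  origins <- as_point_matrix(origins)
  target_sets <- lapply(target_sets, as_point_matrix)
  out <- matrix(Inf, nrow(origins), length(target_sets))
  nonempty <- vapply(target_sets, nrow, integer(1)) > 0
  if (!any(nonempty)) return(out)
  g <- travel_graph(net)
  so <- snap_points(net, origins)
  all_targets <- do.call(rbind, target_sets[nonempty])
  st <- snap_points(net, all_targets)
  uo <- sort(unique(so$node))
  ut <- sort(unique(st$node))
  D <- igraph::distances(g,
                         v = as.character(net$nodes$id)[uo],
                         to = as.character(net$nodes$id)[ut],
                         algorithm = "dijkstra")
  open <- so$dist * access_minutes_per_unit
  ti_all <- match(st$node, ut)
  tpen_all <- st$dist * access_minutes_per_unit
  offset <- 0L
  oi <- match(so$node, uo)
  for (k in which(nonempty)) {
    nk <- nrow(target_sets[[k]])
    sel <- offset + seq_len(nk)
    offset <- offset + nk
    # per unique origin node: min over this set of path + target snap penalty
    Dt <- sweep(D[, ti_all[sel], drop = FALSE], 2, tpen_all[sel], `+`)
    # row minima via max.col (C code); cap Inf so -Dt stays max.col-safe
    j <- max.col(-pmin(Dt, .Machine$double.xmax), ties.method = "first")
    best_by_node <- Dt[cbind(seq_len(nrow(Dt)), j)]
    out[, k] <- unname(best_by_node[oi] + open)
  }
  out
}

#' Straight-line (haversine/Euclidean) travel-time fallback
#'
#' Alternative to network routing: travel time is straight-line distance
#' times a constant speed. Agrees with network mode on a complete graph whose
#' edge weights encode straight-line times.
#'
#' @inheritParams shortest_travel_time
#' @param coords `"planar"` or `"lonlat"`.
#' @param minutes_per_unit Minutes per distance unit (planar) or per km.
#' @return Numeric matrix of minutes.
#' @export
straight_line_travel_time <- function(origins, targets, minutes_per_unit = 1,
                                      coords = c("planar", "lonlat")) {
  coords <- match.arg(coords)
  origins <- as_point_matrix(origins)
  targets <- as_point_matrix(targets)
  out <- matrix(0, nrow(origins), nrow(targets))
  for (j in seq_len(nrow(targets))) {
    out[, j] <- point_distance(origins,
                               targets[rep(j, nrow(origins)), , drop = FALSE],
                               coords) * minutes_per_unit
  }
  out
}

#' Is a tract within the drive-time threshold of any clinic?
#'
#' Decides, for each tract centroid, whether at least one clinic lies within
#' `threshold_minutes` of travel. The threshold is inclusive: a clinic at
#' exactly the threshold counts as within reach. With no clinics the answer
#' is `FALSE` for every tract (an epoch can have an empty roster).
#'
#' @param net A [road_network()], or `NULL` to use the straight-line fallback.
#' @param centroids Data frame of tract centroids with `x`, `y`.
#' @param clinics Data frame of clinic locations with `x`, `y`.
#' @param threshold_minutes Drive-time threshold, default 30 (the Medicaid
#'   maximum reasonable travel standard for medical care).
#' @param access_minutes_per_unit Off-network access speed, see
#'   [shortest_travel_time()].
#' @return Logical vector, one element per tract.
#' @export
tract_within_drive <- function(net, centroids, clinics,
                               threshold_minutes = 30,
                               access_minutes_per_unit = 1) {
  if (threshold_minutes <= 0) stop("threshold must be positive", call. = FALSE)
  centroids <- as_point_matrix(centroids)
  if (is.null(clinics) || nrow(as_point_matrix(clinics)) == 0) {
    return(rep(FALSE, nrow(centroids)))
  }
  if (is.null(net)) {
    tt <- straight_line_travel_time(centroids, clinics,
                                    minutes_per_unit = access_minutes_per_unit)
    best <- apply(tt, 1, min)
  } else {
    best <- min_travel_time(net, centroids, clinics,
                            access_minutes_per_unit = access_minutes_per_unit)
  }
  best <= threshold_minutes
}
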