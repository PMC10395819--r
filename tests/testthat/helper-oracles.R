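# Independent reference implementations used as oracles. Deliberately written
# with their own primitives (hand-coded haversine, point-by-point iteration)
# so they share no code path with the package.

oracle_haversine <- function(lon1, lat1, lon2, lat2) {
  r <- 6371008.8
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dp <- p2 - p1
  dl <- (lon2 - lon1) * pi / 180
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Literal transcription of the anchor-distance stop-detection procedure:
# iterate point by point, absorb while distance to the anchor < delta, on a
# break test the dwell from the anchor to the previously processed point.
oracle_detect_stops <- function(traj, delta_m = 150, tau_min = 18) {
  n <- nrow(traj)
  out <- list()
  emit <- function(members) {
    dwell <- as.numeric(difftime(traj$timestamp[members[length(members)]],
                                 traj$timestamp[members[1]], units = "mins"))
    if (dwell > tau_min) {
      out[[length(out) + 1L]] <<- data.frame(
        centroid_lon = mean(traj$lon[members]),
        centroid_lat = mean(traj$lat[members]),
        t_start = traj$timestamp[members[1]],
        t_end = traj$timestamp[members[length(members)]],
        n_fixes = length(members)
      )
    }
  }
  if (n < 2) return(NULL)
  members <- 1L
  i <- 2L
  while (i <= n) {
    d <- oracle_haversine(traj$lon[members[1]], traj$lat[members[1]],
                          traj$lon[i], traj$lat[i])
    if (d < delta_m) {
      members <- c(members, i)
    } else {
      emit(members)
      members <- i
    }
    i <- i + 1L
  }
  emit(members)
  if (length(out) == 0) NULL else do.call(rbind, out)
}

# Connected components of the strict eps-ball graph via igraph.
oracle_component_labels <- function(lon, lat, eps_m) {
  n <- length(lon)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    adj[i, ] <- oracle_haversine(lon[i], lat[i], lon, lat) < eps_m
  }
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  as.integer(igraph::components(g)$membership)
}

# Canonical form of a partition label vector (first-appearance relabeling).
canon_labels <- function(x) match(x, unique(x))

# Random mixed dwell/transit trajectory: short jitter steps with occasional
# long jumps, ~2-minute spacing.
random_trajectory <- function(n = 50, seed = 1, id = "rnd") {
  set.seed(seed)
  step_deg <- ifelse(runif(n - 1) < 0.7, 20, runif(n - 1, 100, 400)) / 111195
  ang <- runif(n - 1, 0, 2 * pi)
  lon <- cumsum(c(3.0, step_deg * cos(ang)))
  lat <- cumsum(c(51.2, step_deg * sin(ang)))
  ts <- as.POSIXct("2017-03-01", tz = "UTC") +
    cumsum(c(0, sample(90:150, n - 1, replace = TRUE)))
  tibble::tibble(id = id, timestamp = ts, lon = lon, lat = lat)
}

random_stop_table <- function(n = 30, seed = 1, box_m = 3000) {
  set.seed(seed)
  deg <- box_m / 111195
  tibble::tibble(
    id = "rnd",
    centroid_lon = 3.0 + runif(n, 0, deg),
    centroid_lat = 51.2 + runif(n, 0, deg),
    t_start = as.POSIXct("2017-03-01", tz = "UTC") + (seq_len(n) - 1) * 3600,
    t_end = as.POSIXct("2017-03-01", tz = "UTC") + (seq_len(n) - 1) * 3600 + 1800,
    n_fixes = 10L
  )
}

# Visits table builder for aggregation tests; times are offsets in minutes
# from a fixed UTC hour boundary.
visits_at <- function(region_id, start_min, end_min, id = "v") {
  t0 <- as.POSIXct("2017-03-01 00:00:00", tz = "UTC")
  tibble::tibble(
    id = id, region_id = as.integer(region_id),
    t_start = t0 + start_min * 60, t_end = t0 + end_min * 60
  )
}
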