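#' Detect stop-points in a GPS trajectory
#'
#' Segments a time-ordered trajectory into dwell episodes using an
#' anchor-distance / minimum-duration rule. A candidate stop opens at the
#' current point (the anchor) and absorbs every subsequent fix whose haversine
#' distance to the anchor is strictly less than `delta_m`. When a fix at
#' distance \eqn{\ge} `delta_m` breaks the candidate, the dwell time from the
#' anchor to the last absorbed fix is computed: if it exceeds `tau_min`
#' minutes a stop-point is emitted (centroid = arithmetic mean of member
#' coordinates, interval = first/last member timestamps), otherwise the
#' candidate is discarded. Either way the scan restarts at the breaking fix.
#' A trailing candidate at the end of the trajectory is emitted if it passes
#' the dwell test.
#'
#' Distances are measured to the anchor, not to a running centroid, and both
#' thresholds are strict (`< delta_m` to absorb, `> tau_min` to emit).
#'
#' @param fixes Tibble of fixes (`id`, `timestamp`, `lon`, `lat`), time-sorted
#'   within each individual. Multiple individuals are processed independently.
#' @param delta_m Spatial threshold in meters (default 150).
#' @param tau_min Temporal threshold in minutes (default 18).
#' @return Tibble of stop-points ordered by individual and start time:
#'   `id, centroid_lon, centroid_lat, t_start, t_end, n_fixes`. Individuals
#'   with fewer than 2 fixes contribute no stops.
#' @export
detect_stops <- function(fixes, delta_m = 150, tau_min = 18) {
  stopifnot(delta_m > 0, tau_min > 0)
  empty <- tibble::tibble(
    id = character(), centroid_lon = double(), centroid_lat = double(),
    t_start = as.POSIXct(character(), tz = "UTC"),
    t_end = as.POSIXct(character(), tz = "UTC"), n_fixes = integer()
  )
  if (nrow(fixes) == 0) return(empty)
  parts <- split(fixes, fixes$id)
  out <- purrr::map(parts, detect_stops_one, delta_m = delta_m, tau_min = tau_min)
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) empty else out
}

detect_stops_one <- function(traj, delta_m, tau_min) {
  n <- nrow(traj)
  if (n < 2) return(NULL)
  lon <- traj$lon
  lat <- traj$lat
  tm <- traj$timestamp
  stops <- list()
  i <- 1L
  block <- 512L
  while (i <= n) {
    # scan forward from the anchor in chunks; j = first fix at distance >= delta
    j <- i + 1L
    while (j <= n) {
      hi <- min(n, j + block - 1L)
      d <- geodesic_distance_m(lon[i], lat[i], lon[j:hi], lat[j:hi])
      brk <- which(d >= delta_m)
      if (length(brk) > 0) {
        j <- j + brk[1] - 1L
        break
      }
      j <- hi + 1L
    }
    last <- j - 1L
    dwell <- as.numeric(difftime(tm[last], tm[i], units = "mins"))
    if (dwell > tau_min) {
      idx <- i:last
      stops[[length(stops) + 1L]] <- tibble::tibble(
        id = traj$id[i],
        centroid_lon = mean(lon[idx]),
        centroid_lat = mean(lat[idx]),
        t_start = tm[i],
        t_end = tm[last],
        n_fixes = length(idx)
      )
    }
    i <- j
  }
  if (length(stops) == 0) NULL else dplyr::bind_rows(stops)
}

#' Sensitivity sweep of stop counts over threshold grids
#'
#' Recomputes [detect_stops()] for every combination of spatial and temporal
#' thresholds and tabulates the number of detected stops, mirroring the
#' sensitivity analysis used to choose the published thresholds.
#'
#' @param fixes Tibble of fixes.
#' @param deltas Numeric vector of spatial thresholds (meters).
#' @param taus Numeric vector of temporal thresholds (minutes).
#' @return Integer matrix of stop counts, `length(deltas)` rows by
#'   `length(taus)` columns, dimnames set to the threshold values.
#' @export
sensitivity_sweep <- function(fixes, deltas, taus) {
  stopifnot(length(deltas) > 0, length(taus) > 0)
  counts <- matrix(NA_integer_, nrow = length(deltas), ncol = length(taus),
                   dimnames = list(delta_m = deltas, tau_min = taus))
  for (a in seq_along(deltas)) {
    for (b in seq_along(taus)) {
      counts[a, b] <- nrow(detect_stops(fixes, delta_m = deltas[a], tau_min = taus[b]))
    }
  }
  counts
}
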