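#' Cluster stop-points into stay-regions
#'
#' Spatially aggregates stop-points into stay-regions with density-based
#' clustering on the haversine metric. With a self-inclusive neighborhood size
#' of 2, DBSCAN reduces to the connected components of the graph joining
#' stops strictly closer than `eps_m`; components with fewer than `min_stops`
#' members are noise. Noise stops are dropped (and counted) unless
#' `keep_singletons`, in which case each becomes its own single-stop region.
#'
#' An alternative `method = "complete"` groups stops by complete linkage cut
#' at `eps_m` (every pair within a region closer than `eps_m`), available for
#' sensitivity checks; the default chained-neighborhood clustering is the
#' standard DBSCAN behavior.
#'
#' @param stops Tibble of stop-points from [detect_stops()].
#' @param eps_m Neighborhood radius in meters (published values: 400 for
#'   gulls, 200 for humans).
#' @param min_stops Minimum cluster size for a stay-region (default 2).
#' @param keep_singletons If `TRUE`, noise stops are promoted to single-stop
#'   regions instead of being dropped.
#' @param method `"dbscan"` (default) or `"complete"`.
#' @return List with elements:
#'   \describe{
#'     \item{regions}{tibble `region_id, centroid_lon, centroid_lat, n_stops`;
#'       ids dense from 0, ordered by first member stop.}
#'     \item{visits}{tibble `id, region_id, t_start, t_end`, one row per
#'       surviving stop, chronological; intervals are the stop intervals.}
#'     \item{n_noise}{number of stops discarded as noise.}
#'   }
#' @export
cluster_stops <- function(stops, eps_m = 400, min_stops = 2,
                          keep_singletons = FALSE,
                          method = c("dbscan", "complete")) {
  stopifnot(eps_m > 0, min_stops >= 2)
  method <- match.arg(method)
  empty <- list(
    regions = tibble::tibble(region_id = integer(), centroid_lon = double(),
                             centroid_lat = double(), n_stops = integer()),
    visits = tibble::tibble(id = character(), region_id = integer(),
                            t_start = as.POSIXct(character(), tz = "UTC"),
                            t_end = as.POSIXct(character(), tz = "UTC")),
    n_noise = 0L
  )
  n <- nrow(stops)
  if (n == 0) return(empty)
  stops <- dplyr::arrange(stops, .data$t_start)
  comp <- if (method == "dbscan") {
    eps_graph_components(stops$centroid_lon, stops$centroid_lat, eps_m)
  } else {
    complete_linkage_labels(stops$centroid_lon, stops$centroid_lat, eps_m)
  }
  sizes <- tabulate(comp)
  is_noise <- sizes[comp] < min_stops
  n_noise <- sum(is_noise)
  labels <- rep(NA_integer_, n)
  keep <- !is_noise
  if (keep_singletons) {
    # noise stops each get their own region; no stop is dropped
    comp[is_noise] <- max(comp) + seq_len(n_noise)
    keep <- rep(TRUE, n)
    n_noise <- 0L
  }
  if (!any(keep)) return(utils::modifyList(empty, list(n_noise = n_noise)))
  # dense 0-based region ids in order of first member appearance (t_start order)
  kept_comp <- comp[keep]
  labels[keep] <- match(kept_comp, unique(kept_comp)) - 1L
  members <- stops[keep, , drop = FALSE]
  members$region_id <- labels[keep]
  regions <- dplyr::summarise(
    dplyr::group_by(members, .data$region_id),
    centroid_lon = mean(.data$centroid_lon),
    centroid_lat = mean(.data$centroid_lat),
    n_stops = dplyr::n(),
    .groups = "drop"
  )
  visits <- tibble::tibble(
    id = members$id,
    region_id = members$region_id,
    t_start = members$t_start,
    t_end = members$t_end
  )
  list(regions = regions, visits = visits, n_noise = n_noise)
}

# Connected components of the strict eps-ball graph, by breadth-first search.
eps_graph_components <- function(lon, lat, eps_m) {
  n <- length(lon)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      d <- geodesic_distance_m(lon[v], lat[v], lon, lat)
      nb <- which(d < eps_m & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

complete_linkage_labels <- function(lon, lat, eps_m) {
  n <- length(lon)
  if (n == 1) return(1L)
  d <- geosphere::distm(cbind(lon, lat),
                        fun = function(a, b) geosphere::distHaversine(a, b, r = 6371008.8))
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  as.integer(stats::cutree(hc, h = eps_m - 1e-9))
}

#' Count distinct stay-regions visited per month
#'
#' @param visits Tibble of labeled visits (`id, region_id, t_start, t_end`).
#' @param average If `TRUE`, return the mean count across individuals per
#'   month; otherwise one row per individual and month.
#' @return Tibble `id, month, n_regions` (or `month, mean_regions` when
#'   averaged); `month` is the `"YYYY-MM"` UTC month of the visit start.
#' @export
region_count_by_month <- function(visits, average = FALSE) {
  if (nrow(visits) == 0) {
    return(tibble::tibble(id = character(), month = character(), n_regions = integer()))
  }
  per <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(visits, month = format(.data$t_start, "%Y-%m", tz = "UTC")),
      .data$id, .data$month
    ),
    n_regions = dplyr::n_distinct(.data$region_id),
    .groups = "drop"
  )
  if (!average) return(per)
  dplyr::summarise(dplyr::group_by(per, .data$month),
                   mean_regions = mean(.data$n_regions), .groups = "drop")
}
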