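#' Simulate an Exploration and Preferential Return (EPR) visit sequence
#'
#' At each step the walker visits a brand-new location with probability
#' \eqn{\rho S^{-\gamma}} (with \eqn{S} the number of distinct locations seen
#' so far); otherwise it returns to a previously visited location chosen with
#' probability proportional to its past visit count. The current location is
#' excluded from the return choice, so adjacent repeats occur only while a
#' single location exists. The mechanism predicts sublinear growth
#' \eqn{S(t) \sim t^{1/(1+\gamma)}}.
#'
#' @param n_steps Number of steps (visits) to simulate.
#' @param rho Exploration scale in (0, 1] (default 0.6).
#' @param gamma Exploration decay exponent, \eqn{\ge 0} (default 0.6).
#' @param seed Integer seed; the simulation is reproducible and leaves the
#'   global RNG state untouched.
#' @param id Identifier attached to the emitted sequence.
#' @return List with:
#'   \describe{
#'     \item{sequence}{`symbol_sequence` of visited location ids (0-based).}
#'     \item{S_t}{integer vector, distinct-location count after each step.}
#'     \item{visit_counts}{named integer vector of final visit counts.}
#'     \item{mu_theory}{the asymptotic growth exponent `1 / (1 + gamma)`.}
#'   }
#' @export
simulate_epr <- function(n_steps, rho = 0.6, gamma = 0.6, seed = 1L,
                         id = "epr") {
  stopifnot(n_steps >= 1, rho > 0, rho <= 1, gamma >= 0)
  withr::local_seed(seed)
  symbols <- integer(n_steps)
  S_t <- integer(n_steps)
  counts <- integer(n_steps)  # visit counts by location index
  S <- 0L
  cur <- 0L
  for (t in seq_len(n_steps)) {
    p_new <- if (S == 0L) 1 else min(1, rho * S^(-gamma))
    if (stats::runif(1) < p_new) {
      S <- S + 1L
      cur <- S
    } else if (S == 1L) {
      cur <- 1L  # no alternative: stay at the only known location
    } else {
      w <- counts[seq_len(S)]
      w[cur] <- 0
      cur <- sample.int(S, 1L, prob = w)
    }
    counts[cur] <- counts[cur] + 1L
    symbols[t] <- cur - 1L
    S_t[t] <- S
  }
  counts <- counts[seq_len(S)]
  names(counts) <- seq_len(S) - 1L
  # self-transitions can only arise in the degenerate single-location phase
  scheme <- if (length(symbols) > 1 &&
                any(symbols[-1] == symbols[-length(symbols)])) "ntb" else "np"
  list(
    sequence = symbol_sequence(symbols, scheme, id = id,
                               bin_width = if (scheme == "ntb") 3600 else NULL,
                               t0 = if (scheme == "ntb")
                                 as.POSIXct("2017-01-01", tz = "UTC") else NULL),
    S_t = S_t,
    visit_counts = counts,
    mu_theory = 1 / (1 + gamma)
  )
}

#' Build a planted-stay itinerary
#'
#' Convenience generator of an alternating stay/transit episode table whose
#' stay locations are at least `sep_m` apart, for closed-loop testing of stop
#' detection.
#'
#' @param n_stays Number of dwell episodes.
#' @param dwell_range_s Dwell duration range in seconds (uniform draw;
#'   default 30-60 minutes).
#' @param sep_m Minimum separation between consecutive stay locations in
#'   meters (default 2000).
#' @param speed_ms Transit speed in m/s (default 10).
#' @param origin Lon/lat of the first stay (default on the Belgian coast).
#' @param seed Integer seed.
#' @return Episode tibble accepted by [simulate_raw_gps()]: columns `type`
#'   (stay/transit), `lon`, `lat`, `duration_s`, `speed_ms`.
#' @export
make_planted_itinerary <- function(n_stays = 20, dwell_range_s = c(1800, 3600),
                                   sep_m = 2000, speed_ms = 10,
                                   origin = c(2.92, 51.23), seed = 1L) {
  stopifnot(n_stays >= 1, all(dwell_range_s > 0), sep_m > 0, speed_ms > 0)
  withr::local_seed(seed)
  deg_lat <- sep_m / 111195
  lon <- origin[1]
  lat <- origin[2]
  episodes <- list()
  for (k in seq_len(n_stays)) {
    episodes[[length(episodes) + 1L]] <- tibble::tibble(
      type = "stay", lon = lon, lat = lat,
      duration_s = stats::runif(1, dwell_range_s[1], dwell_range_s[2]),
      speed_ms = NA_real_
    )
    if (k < n_stays) {
      # hop at least sep_m away; meander east/north so stays never collide
      ang <- stats::runif(1, -pi / 4, pi / 4)
      step <- deg_lat * stats::runif(1, 1, 1.5)
      lon <- lon + step * cos(ang) / cos(lat * pi / 180)
      lat <- lat + step * sin(ang)
      episodes[[length(episodes) + 1L]] <- tibble::tibble(
        type = "transit", lon = lon, lat = lat,
        duration_s = NA_real_, speed_ms = speed_ms
      )
    }
  }
  dplyr::bind_rows(episodes)
}

#' Build an itinerary whose stays revisit places under the EPR mechanism
#'
#' Draws a visit order from [simulate_epr()], lays the distinct places out on
#' a spatial spiral with at least `sep_m` separation, and converts the visit
#' order into an alternating stay/transit episode table. Because places are
#' revisited (preferential return), the resulting trajectory exercises the
#' whole pipeline: repeated stops at one place cluster into a stay-region
#' with two or more members.
#'
#' @param n_stays Number of dwell episodes.
#' @param rho,gamma EPR parameters (see [simulate_epr()]).
#' @param sep_m Minimum separation between distinct places, meters.
#' @param dwell_range_s Dwell duration range, seconds.
#' @param speed_ms Transit speed, m/s.
#' @param origin Lon/lat of the first place.
#' @param seed Integer seed.
#' @return List with `itinerary` (episode tibble for [simulate_raw_gps()]),
#'   `symbols` (the planted visit order, 0-based place ids; adjacent EPR
#'   repeats are merged, so it can be shorter than `n_stays`) and `places`
#'   (tibble `place_id, lon, lat`).
#' @export
make_epr_itinerary <- function(n_stays = 40, rho = 0.6, gamma = 0.6,
                               sep_m = 2000, dwell_range_s = c(1800, 5400),
                               speed_ms = 10, origin = c(2.92, 51.23),
                               seed = 1L) {
  epr <- simulate_epr(n_stays, rho = rho, gamma = gamma, seed = seed)
  # adjacent repeats (possible only while a single location exists) merge
  # into one longer dwell, so every emitted stay is a distinct episode
  symbols <- rle(epr$sequence$symbols)$values
  n_stays <- length(symbols)
  n_places <- length(unique(symbols))
  withr::local_seed(seed + 1L)
  # golden-angle spiral: consecutive and nearby places stay >= sep_m apart
  kk <- seq_len(n_places)
  radius <- sep_m * sqrt(kk)
  theta <- kk * pi * (3 - sqrt(5))
  deg <- 1 / 111195
  places <- tibble::tibble(
    place_id = kk - 1L,
    lon = origin[1] + radius * cos(theta) * deg / cos(origin[2] * pi / 180),
    lat = origin[2] + radius * sin(theta) * deg
  )
  dwells <- stats::runif(n_stays, dwell_range_s[1], dwell_range_s[2])
  episodes <- list()
  for (k in seq_len(n_stays)) {
    p <- places[places$place_id == symbols[k], ]
    if (k > 1) {
      episodes[[length(episodes) + 1L]] <- tibble::tibble(
        type = "transit", lon = p$lon, lat = p$lat,
        duration_s = NA_real_, speed_ms = speed_ms
      )
    }
    episodes[[length(episodes) + 1L]] <- tibble::tibble(
      type = "stay", lon = p$lon, lat = p$lat,
      duration_s = dwells[k], speed_ms = NA_real_
    )
  }
  list(itinerary = dplyr::bind_rows(episodes), symbols = symbols, places = places)
}

#' Simulate a raw GPS trajectory with planted stays
#'
#' Emits fixes along an itinerary of alternating stay and transit episodes at
#' jittered sampling intervals. Fixes during a stay scatter around the stay
#' location with isotropic Gaussian noise (applied in the local tangent plane
#' and converted back to degrees); fixes in transit are interpolated along
#' the leg. The returned ground truth lists each planted stay's location and
#' time interval for recall/precision scoring of stop detection.
#'
#' @param itinerary Episode tibble (see [make_planted_itinerary()]): `type`
#'   is `"stay"` (uses `lon`, `lat`, `duration_s`) or `"transit"` (travels
#'   from the previous location to `lon`, `lat` at `speed_ms`).
#' @param sampling_interval_s Mean sampling interval in seconds (default 120,
#'   matching typical high-resolution biologging schedules).
#' @param interval_jitter_s Half-width of the uniform jitter on each interval
#'   (default 30).
#' @param noise_sigma_m GPS noise standard deviation in meters, applied to
#'   dwell fixes (default 20).
#' @param t0 POSIXct start time (default 2017-01-01 UTC).
#' @param id Individual identifier.
#' @param seed Integer seed.
#' @return List with `fixes` (tibble `id, timestamp, lon, lat`, strictly
#'   increasing timestamps) and `truth` (tibble `lon, lat, t_start, t_end`,
#'   one row per planted stay).
#' @export
simulate_raw_gps <- function(itinerary, sampling_interval_s = 120,
                             interval_jitter_s = 30, noise_sigma_m = 20,
                             t0 = as.POSIXct("2017-01-01", tz = "UTC"),
                             id = "synthetic-01", seed = 1L) {
  stopifnot(nrow(itinerary) > 0, sampling_interval_s > 0,
            interval_jitter_s >= 0, interval_jitter_s < sampling_interval_s,
            noise_sigma_m >= 0)
  withr::local_seed(seed)
  # lay the episodes out on a continuous clock
  ep <- itinerary
  ep$duration_s <- ifelse(
    ep$type == "stay", ep$duration_s,
    c(NA, geodesic_distance_m(ep$lon[-nrow(ep)], ep$lat[-nrow(ep)],
                              ep$lon[-1], ep$lat[-1]))[seq_len(nrow(ep))] / ep$speed_ms
  )
  if (ep$type[1] == "transit") stop("itinerary must start with a stay", call. = FALSE)
  ep$end_s <- cumsum(ep$duration_s)
  ep$start_s <- ep$end_s - ep$duration_s
  total <- ep$end_s[nrow(ep)]

  times <- c()
  t <- 0
  while (t <= total) {
    times <- c(times, t)
    t <- t + sampling_interval_s +
      stats::runif(1, -interval_jitter_s, interval_jitter_s)
  }
  k <- findInterval(times, ep$start_s)
  lon <- numeric(length(times))
  lat <- numeric(length(times))
  for (i in seq_along(times)) {
    e <- k[i]
    if (ep$type[e] == "stay") {
      noise <- meters_to_degrees(stats::rnorm(1, 0, noise_sigma_m),
                                 stats::rnorm(1, 0, noise_sigma_m), ep$lat[e])
      lon[i] <- ep$lon[e] + noise[1]
      lat[i] <- ep$lat[e] + noise[2]
    } else {
      frac <- (times[i] - ep$start_s[e]) / ep$duration_s[e]
      lon[i] <- ep$lon[e - 1] + frac * (ep$lon[e] - ep$lon[e - 1])
      lat[i] <- ep$lat[e - 1] + frac * (ep$lat[e] - ep$lat[e - 1])
    }
  }
  fixes <- tibble::tibble(id = id, timestamp = t0 + times, lon = lon, lat = lat)
  stays <- ep[ep$type == "stay", , drop = FALSE]
  truth <- tibble::tibble(lon = stays$lon, lat = stays$lat,
                          t_start = t0 + stays$start_s, t_end = t0 + stays$end_s)
  list(fixes = fixes, truth = truth)
}

meters_to_degrees <- function(dx_m, dy_m, lat) {
  m_per_deg <- 6371008.8 * pi / 180
  c(dx_m / (m_per_deg * cos(lat * pi / 180)), dy_m / m_per_deg)
}

#' Score detected stops against planted stays
#'
#' A detected stop matches a planted stay when their locations are within
#' `delta_m` meters and their time intervals overlap. Matching is greedy in
#' time order; each planted stay matches at most one detected stop.
#'
#' @param detected Stop tibble from [detect_stops()].
#' @param truth Planted-stay tibble from [simulate_raw_gps()].
#' @param delta_m Spatial matching tolerance in meters (default 150).
#' @return List with `recall`, `precision`, `n_matched`.
#' @export
score_stop_recovery <- function(detected, truth, delta_m = 150) {
  used <- rep(FALSE, nrow(detected))
  n_matched <- 0L
  for (i in seq_len(nrow(truth))) {
    if (nrow(detected) == 0) break
    d <- geodesic_distance_m(truth$lon[i], truth$lat[i],
                             detected$centroid_lon, detected$centroid_lat)
    overlap <- detected$t_start <= truth$t_end[i] & detected$t_end >= truth$t_start[i]
    cand <- which(!used & d < delta_m & overlap)
    if (length(cand) > 0) {
      used[cand[1]] <- TRUE
      n_matched <- n_matched + 1L
    }
  }
  list(
    recall = if (nrow(truth) == 0) NA_real_ else n_matched / nrow(truth),
    precision = if (nrow(detected) == 0) NA_real_ else sum(used) / nrow(detected),
    n_matched = n_matched
  )
}

#' Simulate a multi-individual, multi-month GPS study population
#'
#' Emulates the structure of a seabird tracking study at desk scale: each
#' individual gets an independent EPR-driven itinerary per calendar month
#' (see [make_epr_itinerary()]) rendered into noisy raw GPS fixes. Individual
#' heterogeneity enters through the exploration scale rho, drawn uniformly
#' per individual from `rho_range`.
#'
#' @param n_individuals Number of individuals (default 5).
#' @param months Character vector of `"YYYY-MM"` months (default Jan-Jun 2017).
#' @param n_stays_month Dwell episodes per individual-month (default 60).
#' @param rho_range Range of per-individual EPR exploration scales.
#' @param gamma EPR decay exponent (default 0.6).
#' @param noise_sigma_m GPS noise, meters (default 20).
#' @param seed Integer seed.
#' @return List with `fixes` (all individuals and months, one tibble) and
#'   `truth` (planted stays with `id` and `month` columns).
#' @export
simulate_study_population <- function(n_individuals = 5,
                                      months = sprintf("2017-%02d", 1:6),
                                      n_stays_month = 60,
                                      rho_range = c(0.3, 0.9), gamma = 0.6,
                                      noise_sigma_m = 20, seed = 1L) {
  withr::local_seed(seed)
  rhos <- stats::runif(n_individuals, rho_range[1], rho_range[2])
  sub_seeds <- sample.int(1e6, n_individuals * length(months))
  fixes <- list()
  truth <- list()
  k <- 0L
  for (i in seq_len(n_individuals)) {
    ind <- sprintf("bird-%02d", i)
    for (m in months) {
      k <- k + 1L
      t0 <- as.POSIXct(paste0(m, "-01"), tz = "UTC")
      it <- make_epr_itinerary(n_stays_month, rho = rhos[i], gamma = gamma,
                               seed = sub_seeds[k])
      sim <- simulate_raw_gps(it$itinerary, noise_sigma_m = noise_sigma_m,
                              t0 = t0, id = ind, seed = sub_seeds[k] + 1L)
      fixes[[k]] <- sim$fixes
      truth[[k]] <- dplyr::mutate(sim$truth, id = ind, month = m)
    }
  }
  list(fixes = dplyr::bind_rows(fixes), truth = dplyr::bind_rows(truth))
}

#' Archetypal stationary and roaming visit sequences
#'
#' Generates the two canonical visitation profiles used to illustrate the
#' Zipf law of mobility: a "stationary" individual concentrating at least
#' 80% of visits on the top location (steep rank curve, large zeta) and a
#' "roamer" spreading visits over many locations (shallow curve, small
#' zeta). Visit counts are fixed by construction; only the visit order is
#' randomized.
#'
#' @param seed Integer seed.
#' @param n_visits Number of visits in each sequence (default 500).
#' @return List of two `symbol_sequence` objects, `stationary` and `roamer`
#'   (NTB-style: self-transitions allowed).
#' @export
make_archetypes <- function(seed = 1L, n_visits = 500) {
  withr::local_seed(seed)
  stationary_p <- c(0.85, 0.09, 0.03, 0.02, 0.01)
  roamer_p <- (1:30)^-0.8
  roamer_p <- roamer_p / sum(roamer_p)
  build <- function(p, id) {
    n <- pmax(1L, round(p * n_visits))
    symbols <- sample(rep.int(seq_along(n) - 1L, n))
    symbol_sequence(symbols, "ntb", id = id, bin_width = 3600,
                    t0 = as.POSIXct("2017-01-01", tz = "UTC"))
  }
  list(stationary = build(stationary_p, "stationary"),
       roamer = build(roamer_p, "roamer"))
}
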