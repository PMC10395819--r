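#' Radius of gyration
#'
#' Root-mean-square haversine distance of a set of points from their
#' (weighted) center of mass:
#' \deqn{r_g = \sqrt{\tfrac{1}{N}\sum_i w_i\, d(r_i, r_0)^2 / \sum_i w_i}}
#' with \eqn{r_0} the weighted mean coordinate. When computed from a symbol
#' sequence, the points are region centroids weighted by symbol occurrence
#' counts (gaps excluded) — see [sequence_rg()].
#'
#' @param lon,lat Point coordinates in degrees.
#' @param weights Optional non-negative weights (default: equal).
#' @return Radius of gyration in meters.
#' @export
radius_of_gyration <- function(lon, lat, weights = NULL) {
  stopifnot(length(lon) > 0, length(lon) == length(lat))
  if (is.null(weights)) weights <- rep(1, length(lon))
  stopifnot(length(weights) == length(lon), all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  lon0 <- sum(w * lon)
  lat0 <- sum(w * lat)
  d <- geodesic_distance_m(lon, lat, lon0, lat0)
  sqrt(sum(w * d^2))
}

#' Radius of gyration of a symbol sequence
#'
#' @param seq A `symbol_sequence`.
#' @param regions Region table (`region_id, centroid_lon, centroid_lat`)
#'   providing the coordinates of each symbol.
#' @return Radius of gyration in meters, weighting each region by its number
#'   of occurrences in the sequence (gaps excluded).
#' @export
sequence_rg <- function(seq, regions) {
  syms <- stats::na.omit(seq$symbols)
  if (length(syms) == 0) stop("sequence has no non-gap symbols", call. = FALSE)
  counts <- table(syms)
  ids <- as.integer(names(counts))
  idx <- match(ids, regions$region_id)
  if (anyNA(idx)) stop("sequence symbols missing from region table", call. = FALSE)
  radius_of_gyration(regions$centroid_lon[idx], regions$centroid_lat[idx],
                     weights = as.numeric(counts))
}

#' Visitation-frequency rank curve
#'
#' Counts symbol occurrences (each non-gap NTB bin, or each NP event, is one
#' visit), normalizes to proportions, and ranks regions by decreasing
#' frequency (ties broken by increasing region id). The decay of `f` with
#' rank is the Zipf law of mobility, \eqn{f_r \sim r^{-\zeta}}.
#'
#' @param seq A `symbol_sequence` with at least one non-gap symbol.
#' @return Tibble `rank, region_id, n, f` with `f` non-increasing and summing
#'   to 1.
#' @export
visitation_frequency <- function(seq) {
  syms <- stats::na.omit(seq$symbols)
  if (length(syms) == 0) stop("sequence has no non-gap symbols", call. = FALSE)
  counts <- table(syms)
  out <- tibble::tibble(
    region_id = as.integer(names(counts)),
    n = as.integer(counts)
  )
  out <- dplyr::arrange(out, -.data$n, .data$region_id)
  out$rank <- seq_len(nrow(out))
  out$f <- out$n / sum(out$n)
  out[, c("rank", "region_id", "n", "f")]
}

#' Distinct locations over time
#'
#' Cumulative count of first-seen regions along the sequence's own time axis:
#' the bin index for NTB (time advances through gaps, `S` stays flat) or the
#' event index for NP. Sublinear growth \eqn{S(t) \sim t^{\mu}} with
#' \eqn{\mu < 1} signals a decreasing tendency to explore new places.
#'
#' @param seq A non-empty `symbol_sequence`.
#' @return Tibble `t, S` with `S` non-decreasing in unit steps.
#' @export
distinct_over_time <- function(seq) {
  x <- seq$symbols
  stopifnot(length(x) > 0)
  first_seen <- !is.na(x) & !duplicated(x, incomparables = NA)
  tibble::tibble(t = seq_along(x), S = cumsum(first_seen))
}

#' Fit a power-law exponent by log-log least squares
#'
#' Ordinary least squares of `log10(y)` on `log10(x)` over the full curve.
#' For decay curves (visitation frequency) the exponent is reported positive
#' as \eqn{\zeta = -} slope; for growth curves (distinct locations) it is the
#' slope \eqn{\mu} itself.
#'
#' @param x,y Positive numeric vectors of equal length, at least 3 points.
#' @param type `"decay"` (rank curves, exponent = -slope) or `"growth"`
#'   (growth curves, exponent = slope).
#' @return Object of class `scaling_fit`: list with `exponent`, `intercept`
#'   (log10 space), `r_squared`, `n_points`, `type`.
#' @export
fit_exponent <- function(x, y, type = c("decay", "growth")) {
  type <- match.arg(type)
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("need at least 3 positive points to fit", call. = FALSE)
  fit <- stats::lm(ly ~ lx, data = data.frame(lx = log10(x), ly = log10(y)))
  slope <- unname(stats::coef(fit)[2])
  ss_tot <- sum((log10(y) - mean(log10(y)))^2)
  r_squared <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(
      exponent = if (type == "decay") -slope else slope,
      intercept = unname(stats::coef(fit)[1]),
      r_squared = r_squared,
      n_points = length(x),
      type = type
    ),
    class = "scaling_fit"
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> %s exponent = %.4f (R2 = %.3f, n = %d)\n",
              x$type, x$exponent, x$r_squared, x$n_points))
  invisible(x)
}

#' Population-averaged curve
#'
#' Pointwise mean of per-individual curves at each rank (rank curves) or time
#' index (growth curves). At positions beyond the end of a shorter curve,
#' only the individuals whose curve extends that far contribute; the
#' population curve has the length of the longest input curve.
#'
#' @param curves List of numeric vectors (e.g. the `f` column of rank curves
#'   or the `S` column of growth curves).
#' @return Tibble `index, value, n_curves`.
#' @export
population_curve <- function(curves) {
  stopifnot(length(curves) > 0)
  lens <- lengths(curves)
  m <- max(lens)
  value <- vapply(seq_len(m), function(i) {
    v <- vapply(curves[lens >= i], `[[`, numeric(1), i)
    mean(v)
  }, numeric(1))
  n_curves <- vapply(seq_len(m), function(i) sum(lens >= i), integer(1))
  tibble::tibble(index = seq_len(m), value = value, n_curves = n_curves)
}
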