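#' Default Movebank-export column mapping
#'
#' Maps the canonical internal column names (`id`, `timestamp`, `lon`, `lat`)
#' to the column headers of a standard Movebank CSV export.
#'
#' @return Named character vector; names are canonical columns, values are the
#'   CSV headers to read them from.
#' @export
movebank_columns <- function() {
  c(
    id        = "individual-local-identifier",
    timestamp = "timestamp",
    lon       = "location-long",
    lat       = "location-lat"
  )
}

#' Read GPS fixes from a CSV file
#'
#' Reads a table of timestamped GPS fixes (one row per fix), validates
#' coordinates and timestamps, sorts fixes chronologically within each
#' individual, and collapses exact-duplicate timestamps per individual to the
#' first occurrence. Rows with unparseable coordinates or timestamps are
#' dropped and counted.
#'
#' @param path Path to a CSV file with a header row.
#' @param column_map Named character vector mapping the canonical columns
#'   `id`, `timestamp`, `lon`, `lat` to headers in the file. Defaults to the
#'   Movebank export dialect ([movebank_columns()]).
#' @param time_format Optional `strptime()` format for the timestamp column.
#'   When `NULL` (default), ISO-8601 variants are parsed automatically.
#'   Timestamps are interpreted as UTC.
#' @return A tibble of fixes with columns `id` (character), `timestamp`
#'   (POSIXct, UTC), `lon`, `lat` (degrees, WGS84), sorted by `id` then
#'   `timestamp`. The number of dropped invalid rows is attached as attribute
#'   `n_dropped` and reported via `message()`.
#' @export
read_fixes <- function(path, column_map = movebank_columns(), time_format = NULL) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols) > 0) {
    stop("columns not found in ", path, ": ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0) {
    warning("no data rows in ", path, call. = FALSE)
    out <- tibble::tibble(id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                          lon = double(), lat = double())
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  fixes <- tibble::tibble(
    id  = raw[[column_map[["id"]]]],
    timestamp = parse_utc(raw[[column_map[["timestamp"]]]], time_format),
    lon = suppressWarnings(as.numeric(raw[[column_map[["lon"]]]])),
    lat = suppressWarnings(as.numeric(raw[[column_map[["lat"]]]]))
  )
  ok <- !is.na(fixes$id) & !is.na(fixes$timestamp) &
    is.finite(fixes$lon) & is.finite(fixes$lat) &
    fixes$lon >= -180 & fixes$lon <= 180 &
    fixes$lat >= -90 & fixes$lat <= 90
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) dropped (invalid coordinates or timestamps)")
  }
  out <- fixes[ok, , drop = FALSE]
  out <- dplyr::arrange(out, .data$id, .data$timestamp)
  out <- dplyr::distinct(out, .data$id, .data$timestamp, .keep_all = TRUE)
  attr(out, "n_dropped") <- n_dropped
  out
}

parse_utc <- function(x, time_format = NULL) {
  if (inherits(x, "POSIXct")) return(lubridate::with_tz(x, "UTC"))
  if (!is.null(time_format)) {
    return(as.POSIXct(strptime(x, format = time_format, tz = "UTC"), tz = "UTC"))
  }
  suppressWarnings(lubridate::parse_date_time(
    x, orders = c("Ymd HMS", "Ymd HM", "YmdHMS"), tz = "UTC", quiet = TRUE
  ))
}

#' Write fixes to the canonical CSV dialect
#'
#' @param fixes Tibble of fixes as returned by [read_fixes()].
#' @param path Output file path. Columns are `id,timestamp,lon,lat`, with
#'   timestamps formatted ISO-8601 UTC.
#' @return `path`, invisibly.
#' @export
write_fixes <- function(fixes, path) {
  out <- tibble::tibble(
    id = fixes$id,
    timestamp = format(fixes$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    lon = fixes$lon,
    lat = fixes$lat
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Haversine geodesic distance in meters
#'
#' Great-circle distance on a sphere with the mean Earth radius 6371.0088 km.
#' All arguments are recycled to a common length.
#'
#' @param lon1,lat1 Coordinates of the first point(s), decimal degrees WGS84.
#' @param lon2,lat2 Coordinates of the second point(s).
#' @return Numeric vector of distances in meters.
#' @export
geodesic_distance_m <- function(lon1, lat1, lon2, lat2) {
  if (any(!is.finite(c(lon1, lat1, lon2, lat2)))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    stop("coordinates out of range", call. = FALSE)
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371008.8)
}

#' Split fixes by UTC calendar month
#'
#' @param fixes Tibble of fixes (any number of individuals).
#' @return Named list of fix tibbles, one per UTC calendar month present
#'   (names `"YYYY-MM"`); every input row appears in exactly one element.
#' @export
split_by_month <- function(fixes) {
  stopifnot(nrow(fixes) > 0)
  key <- format(fixes$timestamp, "%Y-%m", tz = "UTC")
  split(fixes, key)
}

#' @importFrom dplyr .data
NULL
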