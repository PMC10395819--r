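#' Construct a symbolic mobility sequence
#'
#' A symbol sequence is the discrete representation of an individual's
#' movement: a time-ordered vector of stay-region identifiers. Under the
#' Next Time-Bin (NTB) scheme there is one symbol per fixed-width time bin
#' (`NA` marks a bin with no stay-region time, a gap) and consecutive
#' identical symbols (self-transitions) are retained. Under the Next Place
#' (NP) scheme the sequence holds only transitions between regions: no gaps,
#' no adjacent repeats.
#'
#' @param symbols Integer vector of region ids; `NA` encodes a gap (NTB only).
#' @param scheme `"ntb"` or `"np"`.
#' @param id Individual identifier.
#' @param bin_width Bin width in seconds (NTB only).
#' @param t0 POSIXct start of the first bin (NTB only).
#' @return Object of class `symbol_sequence`.
#' @export
symbol_sequence <- function(symbols, scheme = c("ntb", "np"), id = NA_character_,
                            bin_width = NULL, t0 = NULL) {
  scheme <- match.arg(scheme)
  symbols <- as.integer(symbols)
  if (scheme == "np") {
    if (anyNA(symbols)) stop("NP sequences cannot contain gaps", call. = FALSE)
    if (length(symbols) > 1 && any(symbols[-1] == symbols[-length(symbols)])) {
      stop("NP sequences cannot contain adjacent equal symbols", call. = FALSE)
    }
  }
  structure(
    list(symbols = symbols, scheme = scheme, id = id,
         bin_width = bin_width, t0 = t0),
    class = "symbol_sequence"
  )
}

#' @export
print.symbol_sequence <- function(x, ...) {
  cat(sprintf("<symbol_sequence> %s, %s, %d symbols (%d gaps, %d distinct regions)\n",
              x$id, toupper(x$scheme), length(x$symbols), sum(is.na(x$symbols)),
              length(unique(stats::na.omit(x$symbols)))))
  invisible(x)
}

#' @export
length.symbol_sequence <- function(x) length(x$symbols)

#' Next Time-Bin aggregation of visits
#'
#' Converts labeled visits into one symbol per fixed-width time bin. Bins are
#' anchored at the top of the UTC hour containing the first visit's start and
#' cover the span to the last visit's end. Each bin takes the region with the
#' longest overlap duration inside it; ties on duration go to the region with
#' the higher visit count over the whole sequence, residual ties to the
#' smallest region id. Bins with no stay-region time are gaps (`NA`).
#' Self-transitions are preserved.
#'
#' @param visits Time-ordered visits of one individual
#'   (`id, region_id, t_start, t_end`).
#' @param bin_width Bin width in seconds (default 3600, one hour).
#' @return A `symbol_sequence` with scheme `"ntb"`.
#' @export
aggregate_ntb <- function(visits, bin_width = 3600) {
  stopifnot(bin_width > 0)
  if (nrow(visits) == 0) {
    return(symbol_sequence(integer(), "ntb", bin_width = bin_width))
  }
  visits <- dplyr::arrange(visits, .data$t_start)
  t0 <- lubridate::floor_date(min(visits$t_start), "hour")
  span <- as.numeric(difftime(max(visits$t_end), t0, units = "secs"))
  n_bins <- max(1L, as.integer(ceiling(span / bin_width)))
  n_visits_by_region <- table(visits$region_id)

  vs <- as.numeric(difftime(visits$t_start, t0, units = "secs"))
  ve <- as.numeric(difftime(visits$t_end, t0, units = "secs"))
  # overlap of every visit with every bin it touches, in long form
  rows <- purrr::map(seq_len(nrow(visits)), function(k) {
    b_first <- max(1L, 1L + as.integer(floor(vs[k] / bin_width)))
    b_last <- min(n_bins, 1L + as.integer(floor((ve[k] - 1e-9) / bin_width)))
    if (b_last < b_first) return(NULL)
    b <- b_first:b_last
    lo <- pmax(vs[k], (b - 1) * bin_width)
    hi <- pmin(ve[k], b * bin_width)
    tibble::tibble(bin = b, region_id = visits$region_id[k], overlap = hi - lo)
  })
  long <- dplyr::bind_rows(rows)
  long <- dplyr::summarise(dplyr::group_by(long, .data$bin, .data$region_id),
                           overlap = sum(.data$overlap), .groups = "drop")
  long$n_visits <- as.integer(n_visits_by_region[as.character(long$region_id)])
  long <- long[long$overlap > 0, , drop = FALSE]
  long <- dplyr::arrange(long, .data$bin, -.data$overlap, -.data$n_visits,
                         .data$region_id)
  winners <- dplyr::slice_head(dplyr::group_by(long, .data$bin), n = 1)
  symbols <- rep(NA_integer_, n_bins)
  symbols[winners$bin] <- winners$region_id
  symbol_sequence(symbols, "ntb", id = visits$id[1], bin_width = bin_width, t0 = t0)
}

#' Next Place aggregation of visits
#'
#' Keeps the region ids in visit order with consecutive duplicates collapsed,
#' so the sequence contains only transitions between stay-regions.
#'
#' @param visits Time-ordered visits of one individual.
#' @return A `symbol_sequence` with scheme `"np"`.
#' @export
aggregate_np <- function(visits) {
  if (nrow(visits) == 0) return(symbol_sequence(integer(), "np"))
  visits <- dplyr::arrange(visits, .data$t_start)
  x <- visits$region_id
  keep <- c(TRUE, x[-1] != x[-length(x)])
  symbol_sequence(x[keep], "np", id = visits$id[1])
}
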