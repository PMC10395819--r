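#' Compare two groups of metric values
#'
#' Runs the two-sample Kolmogorov-Smirnov test and the two-group
#' Kruskal-Wallis test on the same inputs (the two non-parametric tests
#' suitable for the very small samples typical of individual-month metric
#' values) and flags significance at the 0.05 and 0.1 levels.
#'
#' @param a,b Numeric vectors of per-individual-per-month metric values.
#' @param labels Character vector of length 2 naming the groups.
#' @return One-row tibble: `group_a, group_b, n_a, n_b, testable, ks_stat,
#'   p_ks, p_kw, flag_ks, flag_kw`. Flags are `"sig"` (p < 0.05), `"weak"`
#'   (p < 0.1) or `"ns"`. Groups with fewer than 2 values are flagged
#'   untestable and carry no p-values.
#' @export
compare_groups <- function(a, b, labels = c("a", "b")) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    return(tibble::tibble(
      group_a = labels[1], group_b = labels[2],
      n_a = length(a), n_b = length(b), testable = FALSE,
      ks_stat = NA_real_, p_ks = NA_real_, p_kw = NA_real_,
      flag_ks = NA_character_, flag_kw = NA_character_
    ))
  }
  ks <- suppressWarnings(stats::ks.test(a, b))
  kw <- stats::kruskal.test(list(a, b))
  tibble::tibble(
    group_a = labels[1], group_b = labels[2],
    n_a = length(a), n_b = length(b), testable = TRUE,
    ks_stat = unname(ks$statistic),
    p_ks = ks$p.value, p_kw = kw$p.value,
    flag_ks = significance_flag(ks$p.value),
    flag_kw = significance_flag(kw$p.value)
  )
}

#' Significance flag from a p-value
#'
#' @param p P-value (vectorized).
#' @param alpha Two thresholds: strong and weak significance (defaults 0.05
#'   and 0.1).
#' @return `"sig"` below the first threshold, `"weak"` below the second,
#'   else `"ns"`.
#' @export
significance_flag <- function(p, alpha = c(0.05, 0.1)) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < alpha[1], "sig", ifelse(p < alpha[2], "weak", "ns")))
}

#' Split monthly values into breeding and non-breeding samples
#'
#' @param values Tibble with columns `month` (either `"YYYY-MM"` strings,
#'   month numbers 1-12, or month abbreviations) and `value`.
#' @param breeding Months making up the breeding season; numbers 1-12 or
#'   abbreviations (default April-June).
#' @return List with numeric vectors `breeding` and `nonbreeding`.
#' @export
season_split <- function(values, breeding = c(4, 5, 6)) {
  mnum <- month_number(values$month)
  bnum <- month_number(breeding)
  list(
    breeding = values$value[mnum %in% bnum],
    nonbreeding = values$value[!(mnum %in% bnum)]
  )
}

month_number <- function(m) {
  if (is.numeric(m)) return(as.integer(m))
  m <- as.character(m)
  out <- match(substr(m, 1, 3), month.abb)
  iso <- grepl("^\\d{4}-\\d{2}", m)
  out[iso] <- as.integer(substr(m[iso], 6, 7))
  if (anyNA(out)) stop("unrecognized month: ", paste(m[is.na(out)], collapse = ", "),
                       call. = FALSE)
  out
}

#' Significance grid over metrics and aggregation schemes
#'
#' Builds the full comparison table for one group contrast: each metric
#' (`f_r`, `r_g`, `S(t)`) crossed with each aggregation scheme (NTB, NP) is
#' compared between the two groups with [compare_groups()].
#'
#' @param values Long tibble with columns `metric`, `scheme`, `group`,
#'   `value`; `group` must have exactly two levels.
#' @param labels Optional group label order (defaults to sorted unique
#'   groups).
#' @return Tibble with one row per metric-scheme cell, columns as in
#'   [compare_groups()] plus `metric` and `scheme`.
#' @export
significance_grid <- function(values, labels = NULL) {
  groups <- if (is.null(labels)) sort(unique(values$group)) else labels
  if (length(groups) != 2) stop("exactly two groups required", call. = FALSE)
  cells <- dplyr::distinct(values[, c("metric", "scheme")])
  purrr::pmap_dfr(cells, function(metric, scheme) {
    sub <- values[values$metric == metric & values$scheme == scheme, ]
    res <- compare_groups(sub$value[sub$group == groups[1]],
                          sub$value[sub$group == groups[2]],
                          labels = groups)
    dplyr::bind_cols(tibble::tibble(metric = metric, scheme = scheme), res)
  })
}
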