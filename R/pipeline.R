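#' Pipeline configuration
#'
#' Bundles all tunable parameters of the monthly mobility analysis with the
#' published defaults: stop detection at delta = 150 m and tau = 18 min,
#' stay-region clustering at eps = 400 m (gull profile; use 200 m for urban
#' human data) with minimum cluster size 2, one-hour NTB bins, and an
#' April-June breeding season.
#'
#' @param delta_m Stop-detection spatial threshold, meters.
#' @param tau_min Stop-detection temporal threshold, minutes.
#' @param eps_m Clustering neighborhood radius, meters.
#' @param min_stops Minimum stops per stay-region.
#' @param keep_singletons Promote noise stops to singleton regions.
#' @param bin_width NTB bin width, seconds.
#' @param breeding_months Months of the breeding season (numbers 1-12).
#' @param sex Optional named character vector mapping individual ids to
#'   `"female"` / `"male"` for the sex contrast.
#' @return A `run_config` list.
#' @export
run_config <- function(delta_m = 150, tau_min = 18, eps_m = 400, min_stops = 2,
                       keep_singletons = FALSE, bin_width = 3600,
                       breeding_months = c(4, 5, 6), sex = NULL) {
  stopifnot(delta_m > 0, tau_min > 0, eps_m > 0, min_stops >= 2, bin_width > 0,
            all(breeding_months %in% 1:12))
  structure(
    list(delta_m = delta_m, tau_min = tau_min, eps_m = eps_m,
         min_stops = min_stops, keep_singletons = keep_singletons,
         bin_width = bin_width, breeding_months = breeding_months, sex = sex),
    class = "run_config"
  )
}

#' Run the full monthly mobility analysis
#'
#' For each individual and UTC calendar month: detects stops, clusters them
#' into stay-regions, builds NTB and NP symbol sequences, and computes the
#' radius of gyration, the visitation-frequency rank curve, and the
#' distinct-locations growth curve. Per month and scheme, the rank and growth
#' curves are averaged across individuals and the collective scaling
#' exponents zeta and mu are fitted on the averaged curves (per-individual
#' fits are also emitted as diagnostics). Significance grids compare breeding
#' vs non-breeding months (and the sexes, when a sex map is supplied) on
#' per-individual-month values of the top-rank visitation frequency, the
#' radius of gyration, and the distinct-region count.
#'
#' The pipeline is fully deterministic: identical input and configuration
#' yield identical results.
#'
#' @param fixes Tibble of validated fixes from [read_fixes()].
#' @param config A [run_config()].
#' @return List of class `mobscale_results`:
#'   \describe{
#'     \item{per_individual}{tibble of per-individual-month metrics
#'       (`id, month, scheme, rg_m, f1, f2, S_end, n_regions, zeta, mu`).}
#'     \item{exponents}{tibble `month, scheme, zeta, mu, ...` fitted on the
#'       population-averaged curves (the monthly exponent matrix).}
#'     \item{rank_curves, growth_curves}{long tibbles of the
#'       population-averaged curves per month and scheme.}
#'     \item{top_rank_freq}{mean top-1 and top-2 visitation frequency per
#'       month and scheme.}
#'     \item{region_counts}{mean distinct stay-regions per month.}
#'     \item{significance}{named list of significance grids.}
#'     \item{log}{drop/noise bookkeeping.}
#'   }
#' @export
run_pipeline <- function(fixes, config = run_config()) {
  stopifnot(inherits(config, "run_config"), nrow(fixes) > 0)
  monthly <- split_by_month(fixes)
  per_rows <- list()
  curve_store <- list()
  n_noise_total <- 0L
  for (month in names(monthly)) {
    by_id <- split(monthly[[month]], monthly[[month]]$id)
    for (ind in names(by_id)) {
      stops <- detect_stops(by_id[[ind]], config$delta_m, config$tau_min)
      if (nrow(stops) == 0) next
      cl <- cluster_stops(stops, eps_m = config$eps_m,
                          min_stops = config$min_stops,
                          keep_singletons = config$keep_singletons)
      n_noise_total <- n_noise_total + cl$n_noise
      if (nrow(cl$visits) == 0) next
      seqs <- list(ntb = aggregate_ntb(cl$visits, config$bin_width),
                   np = aggregate_np(cl$visits))
      for (scheme in names(seqs)) {
        s <- seqs[[scheme]]
        if (sum(!is.na(s$symbols)) == 0) next
        fr <- visitation_frequency(s)
        gr <- distinct_over_time(s)
        zeta <- if (nrow(fr) >= 3)
          fit_exponent(fr$rank, fr$f, "decay")$exponent else NA_real_
        mu <- if (max(gr$S) >= 2)
          fit_exponent(gr$t, gr$S, "growth")$exponent else NA_real_
        per_rows[[length(per_rows) + 1L]] <- tibble::tibble(
          id = ind, month = month, scheme = scheme,
          rg_m = sequence_rg(s, cl$regions),
          f1 = fr$f[1], f2 = if (nrow(fr) >= 2) fr$f[2] else NA_real_,
          S_end = max(gr$S), n_regions = nrow(cl$regions),
          zeta = zeta, mu = mu
        )
        curve_store[[paste(month, scheme, ind, sep = "|")]] <-
          list(f = fr$f, S = gr$S)
      }
    }
  }
  if (length(per_rows) == 0) stop("no stops detected anywhere in the input", call. = FALSE)
  per_individual <- dplyr::bind_rows(per_rows)

  cells <- dplyr::distinct(per_individual[, c("month", "scheme")])
  pop <- purrr::pmap(cells, function(month, scheme) {
    keys <- grep(paste0("^", month, "\\|", scheme, "\\|"), names(curve_store),
                 value = TRUE)
    fcurves <- purrr::map(curve_store[keys], "f")
    scurves <- purrr::map(curve_store[keys], "S")
    rank_avg <- population_curve(fcurves)
    growth_avg <- population_curve(scurves)
    zfit <- if (nrow(rank_avg) >= 3)
      fit_exponent(rank_avg$index, rank_avg$value, "decay") else NULL
    mfit <- if (max(growth_avg$value) > min(growth_avg$value))
      fit_exponent(growth_avg$index, growth_avg$value, "growth") else NULL
    list(
      exponents = tibble::tibble(
        month = month, scheme = scheme,
        zeta = if (is.null(zfit)) NA_real_ else zfit$exponent,
        zeta_r2 = if (is.null(zfit)) NA_real_ else zfit$r_squared,
        mu = if (is.null(mfit)) NA_real_ else mfit$exponent,
        mu_r2 = if (is.null(mfit)) NA_real_ else mfit$r_squared,
        n_individuals = length(keys)
      ),
      rank = dplyr::mutate(rank_avg, month = month, scheme = scheme),
      growth = dplyr::mutate(growth_avg, month = month, scheme = scheme)
    )
  })
  exponents <- dplyr::bind_rows(purrr::map(pop, "exponents"))
  rank_curves <- dplyr::bind_rows(purrr::map(pop, "rank"))
  growth_curves <- dplyr::bind_rows(purrr::map(pop, "growth"))

  top_rank_freq <- dplyr::summarise(
    dplyr::group_by(per_individual, .data$month, .data$scheme),
    mean_f1 = mean(.data$f1, na.rm = TRUE),
    mean_f2 = mean(.data$f2, na.rm = TRUE),
    .groups = "drop"
  )
  region_counts <- dplyr::summarise(
    dplyr::group_by(per_individual[per_individual$scheme == "np", ], .data$month),
    mean_regions = mean(.data$n_regions),
    .groups = "drop"
  )

  significance <- list(
    breeding = significance_breeding(per_individual, config$breeding_months)
  )
  if (!is.null(config$sex)) {
    significance$sex <- significance_sex(per_individual, config$sex)
  }

  structure(
    list(per_individual = per_individual, exponents = exponents,
         rank_curves = rank_curves, growth_curves = growth_curves,
         top_rank_freq = top_rank_freq, region_counts = region_counts,
         significance = significance,
         log = list(n_noise_stops = n_noise_total,
                    n_dropped_rows = attr(fixes, "n_dropped") %||% 0L)),
    class = "mobscale_results"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

metric_long <- function(per_individual) {
  tidyr::pivot_longer(
    per_individual[, c("id", "month", "scheme", "f1", "rg_m", "S_end")],
    cols = c("f1", "rg_m", "S_end"),
    names_to = "metric", values_to = "value"
  ) |>
    dplyr::mutate(metric = dplyr::recode(.data$metric, f1 = "f_r",
                                         rg_m = "r_g", S_end = "S(t)"))
}

significance_breeding <- function(per_individual, breeding_months) {
  long <- metric_long(per_individual)
  long$group <- ifelse(month_number(long$month) %in% breeding_months,
                       "breeding", "non-breeding")
  significance_grid(long, labels = c("breeding", "non-breeding"))
}

significance_sex <- function(per_individual, sex) {
  long <- metric_long(per_individual)
  long$group <- unname(sex[long$id])
  long <- long[!is.na(long$group), , drop = FALSE]
  if (length(unique(long$group)) != 2) return(NULL)
  significance_grid(long)
}

#' Compare two analyzed populations
#'
#' Cross-population significance grid (e.g. gulls vs humans): per metric and
#' scheme, the per-individual-month values of the two result bundles are
#' compared with [compare_groups()].
#'
#' @param res_a,res_b `mobscale_results` objects.
#' @param labels Character vector of length 2 naming the populations.
#' @return Significance grid tibble.
#' @export
compare_populations <- function(res_a, res_b, labels = c("a", "b")) {
  la <- metric_long(res_a$per_individual)
  lb <- metric_long(res_b$per_individual)
  la$group <- labels[1]
  lb$group <- labels[2]
  significance_grid(dplyr::bind_rows(la, lb), labels = labels)
}

#' @export
print.mobscale_results <- function(x, ...) {
  cat("<mobscale_results>\n")
  cat(sprintf("  %d individual-month-scheme records, %d months\n",
              nrow(x$per_individual), length(unique(x$per_individual$month))))
  cat("  monthly population exponents:\n")
  print(as.data.frame(x$exponents[, c("month", "scheme", "zeta", "mu")]),
        row.names = FALSE)
  invisible(x)
}

#' Write pipeline results to disk
#'
#' Writes every result table as CSV plus the exponent matrix as JSON, so each
#' stage's output is re-loadable in isolation.
#'
#' @param results A `mobscale_results` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(results$per_individual, file.path(dir, "per_individual.csv"),
                   progress = FALSE)
  readr::write_csv(results$exponents, file.path(dir, "exponents.csv"), progress = FALSE)
  readr::write_csv(results$rank_curves, file.path(dir, "rank_curves.csv"), progress = FALSE)
  readr::write_csv(results$growth_curves, file.path(dir, "growth_curves.csv"),
                   progress = FALSE)
  readr::write_csv(results$top_rank_freq, file.path(dir, "top_rank_freq.csv"),
                   progress = FALSE)
  readr::write_csv(results$region_counts, file.path(dir, "region_counts.csv"),
                   progress = FALSE)
  for (nm in names(results$significance)) {
    if (is.null(results$significance[[nm]])) next
    readr::write_csv(results$significance[[nm]],
                     file.path(dir, paste0("significance_", nm, ".csv")),
                     progress = FALSE)
  }
  jsonlite::write_json(results$exponents, file.path(dir, "exponents.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
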