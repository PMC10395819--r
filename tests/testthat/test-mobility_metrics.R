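test_that("radius of gyration matches hand-computed RMS deviations", {
  expect_equal(radius_of_gyration(rep(3.1, 5), rep(51.2, 5)), 0)

  # two equally weighted points 1000 m apart on a meridian: r_g = 500 m
  dlat <- 1000 / (6371008.8 * pi / 180)
  expect_equal(radius_of_gyration(c(3, 3), c(51, 51 + dlat)), 500,
               tolerance = 1e-6)

  # 3-point toy case at small extent: planar hand computation
  # points (0,0), (600,0), (0,900) m; centroid (200,300);
  # r_g = sqrt((200^2+300^2 + 400^2+300^2 + 200^2+600^2)/3) = sqrt(260000)
  m <- 6371008.8 * pi / 180
  lon <- c(0, 600 / m, 0)   # at lat ~0, lon degrees = meters / m
  lat <- c(0, 0, 900 / m)
  expect_equal(radius_of_gyration(lon, lat), sqrt(260000), tolerance = 1e-3)

  # weights: duplicating a point equals weighting it
  expect_equal(radius_of_gyration(c(3, 3, 3), c(51, 51, 51 + dlat)),
               radius_of_gyration(c(3, 3), c(51, 51 + dlat), weights = c(2, 1)))
})

test_that("sequence r_g weights regions by occupancy, excluding gaps", {
  dlat <- 1000 / (6371008.8 * pi / 180)
  regions <- tibble::tibble(region_id = c(0L, 1L),
                            centroid_lon = c(3, 3),
                            centroid_lat = c(51, 51 + dlat))
  s <- symbol_sequence(c(0, NA, 0, 1, NA, NA), "ntb")
  expect_equal(sequence_rg(s, regions),
               radius_of_gyration(c(3, 3), c(51, 51 + dlat), weights = c(2, 1)))
})

test_that("visitation frequency counts, normalizes, and ranks correctly", {
  f <- visitation_frequency(symbol_sequence(c(1, 1, 1, 2), "ntb"))
  expect_equal(f$f, c(0.75, 0.25))
  expect_equal(f$region_id, c(1L, 2L))
  expect_equal(visitation_frequency(symbol_sequence(7, "np"))$f, 1.0)
  expect_error(visitation_frequency(symbol_sequence(c(NA, NA), "ntb")), "non-gap")

  for (s in 1:30) {
    set.seed(s)
    syms <- sample(0:6, 50, replace = TRUE)
    fr <- visitation_frequency(symbol_sequence(syms, "ntb"))
    expect_equal(sum(fr$f), 1, tolerance = 1e-9)
    expect_true(all(diff(fr$f) <= 0))
    want <- sort(table(syms), decreasing = TRUE)
    expect_equal(fr$n, as.integer(want), ignore_attr = TRUE)
  }
})

test_that("distinct-locations growth is cumulative first-seen counting", {
  expect_equal(distinct_over_time(symbol_sequence(c(1, 2, 3), "np"))$S, 1:3)
  expect_equal(distinct_over_time(symbol_sequence(c(1, 1, 1), "ntb"))$S,
               c(1L, 1L, 1L))
  # gaps advance time but not S
  expect_equal(distinct_over_time(symbol_sequence(c(1, NA, 2), "ntb"))$S,
               c(1L, 1L, 2L))
  for (s in 1:30) {
    set.seed(s)
    syms <- sample(0:9, 60, replace = TRUE)
    g <- distinct_over_time(symbol_sequence(syms, "ntb"))
    expect_true(all(diff(g$S) %in% c(0L, 1L)))
    expect_equal(g$S[60], length(unique(syms)))
    expect_equal(g$S[1], 1L)
  }
})

test_that("fit_exponent recovers planted exponents", {
  x <- 1:20
  expect_equal(fit_exponent(x, x^-2, "decay")$exponent, 2, tolerance = 1e-9)
  cfit <- fit_exponent(x, rep(5, 20), "growth")
  expect_equal(cfit$exponent, 0, tolerance = 1e-12)
  set.seed(31)
  xn <- seq_len(100)
  yn <- 3 * xn^1.5 * 10^rnorm(100, 0, 0.01)
  nfit <- fit_exponent(xn, yn, "growth")
  expect_equal(nfit$exponent, 1.5, tolerance = 0.05 / 1.5)
  expect_gt(nfit$r_squared, 0.99)
  expect_equal(nfit$n_points, 100L)
  expect_error(fit_exponent(1:2, c(1, 2)), "at least 3")
  expect_error(fit_exponent(1:3, c(0, 0, 0)), "at least 3")
})

test_that("population curves average only the individuals that extend that far", {
  one <- list(c(0.5, 0.3, 0.2))
  expect_equal(population_curve(one)$value, one[[1]])
  expect_equal(population_curve(c(one, one))$value, one[[1]])
  # hand-checked two-curve case of unequal length
  pc <- population_curve(list(c(10, 6, 2), c(20, 8)))
  expect_equal(pc$value, c(15, 7, 2))
  expect_equal(pc$n_curves, c(2L, 2L, 1L))
})
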