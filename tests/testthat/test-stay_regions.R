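two_stops <- function(sep_m, t_gap_h = 2) {
  t0 <- as.POSIXct("2017-05-01", tz = "UTC")
  tibble::tibble(
    id = "g1",
    centroid_lon = c(3.0, 3.0),
    centroid_lat = c(51.2, 51.2 + sep_m / 111195),
    t_start = c(t0, t0 + t_gap_h * 3600),
    t_end = c(t0 + 1800, t0 + t_gap_h * 3600 + 1800),
    n_fixes = c(10L, 12L)
  )
}

test_that("nearby stops merge into one region, isolated stops become noise", {
  cl <- cluster_stops(two_stops(100), eps_m = 400)
  expect_equal(nrow(cl$regions), 1L)
  expect_equal(cl$regions$n_stops, 2L)
  expect_equal(nrow(cl$visits), 2L)
  expect_equal(cl$n_noise, 0L)
  # visit intervals untouched by clustering
  expect_equal(cl$visits$t_start, two_stops(100)$t_start)
  expect_equal(cl$visits$t_end, two_stops(100)$t_end)

  far <- cluster_stops(two_stops(1000), eps_m = 400)
  expect_equal(nrow(far$regions), 0L)
  expect_equal(far$n_noise, 2L)

  single <- cluster_stops(two_stops(1000), eps_m = 400, keep_singletons = TRUE)
  expect_equal(nrow(single$regions), 2L)
  expect_equal(single$n_noise, 0L)
  expect_equal(single$regions$region_id, c(0L, 1L))
})

test_that("clustering equals eps-graph connected components on random instances", {
  for (s in 1:100) {
    stops <- random_stop_table(30, seed = s)
    cl <- cluster_stops(stops, eps_m = 400, keep_singletons = TRUE)
    want <- oracle_component_labels(stops$centroid_lon, stops$centroid_lat, 400)
    # keep_singletons retains every stop, so visits align 1:1 with stops
    expect_equal(nrow(cl$visits), 30L)
    got <- cl$visits$region_id
    expect_equal(canon_labels(got), canon_labels(want), info = paste("seed", s))
    # noise count under the default policy = singleton components
    noise <- cluster_stops(stops, eps_m = 400)$n_noise
    expect_equal(noise, sum(tabulate(want) == 1), info = paste("seed", s))
  }
})

test_that("complete-linkage alternative only ever splits DBSCAN clusters", {
  for (s in 1:20) {
    stops <- random_stop_table(25, seed = s, box_m = 2000)
    db <- cluster_stops(stops, eps_m = 500, keep_singletons = TRUE)$visits$region_id
    cp <- cluster_stops(stops, eps_m = 500, keep_singletons = TRUE,
                        method = "complete")$visits$region_id
    # every complete-linkage cluster lies inside one chained cluster
    expect_true(all(tapply(db, cp, function(v) length(unique(v))) == 1))
  }
})

test_that("distinct region counts per month match a set-cardinality oracle", {
  v <- visits_at(c(0, 1, 0, 2), c(0, 60, 120, 180), c(30, 90, 150, 210))
  counts <- region_count_by_month(v)
  expect_equal(counts$n_regions, 3L)

  set.seed(42)
  months <- sample(sprintf("2017-%02d", 1:3), 200, replace = TRUE)
  vv <- tibble::tibble(
    id = sample(c("a", "b"), 200, replace = TRUE),
    region_id = sample(0:9, 200, replace = TRUE),
    t_start = as.POSIXct(paste0(months, "-10"), tz = "UTC") + runif(200, 0, 86400),
    t_end = as.POSIXct(paste0(months, "-10"), tz = "UTC") + 90000
  )
  got <- region_count_by_month(vv)
  for (k in seq_len(nrow(got))) {
    sub <- vv[vv$id == got$id[k] &
                format(vv$t_start, "%Y-%m", tz = "UTC") == got$month[k], ]
    expect_equal(got$n_regions[k], length(unique(sub$region_id)))
  }
  avg <- region_count_by_month(vv, average = TRUE)
  expect_equal(nrow(avg), 3L)
  expect_equal(avg$mean_regions,
               tapply(got$n_regions, got$month, mean, simplify = TRUE),
               ignore_attr = TRUE)
})
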