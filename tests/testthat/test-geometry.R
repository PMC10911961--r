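test_that("great-circle distance handles identity, a known arc, and symmetry", {
  expect_equal(great_circle_km(-1.5, 55, -1.5, 55), 0)
  # pure-latitude displacement: arc length (0.01 * pi/180) * 6371
  expect_equal(great_circle_km(0, 0, 0, 0.01), 0.01 * pi / 180 * 6371,
               tolerance = 1e-10)
  set.seed(1)
  lon <- runif(20, -10, 10); lat <- runif(20, 40, 60)
  lon2 <- runif(20, -10, 10); lat2 <- runif(20, 40, 60)
  expect_equal(great_circle_km(lon, lat, lon2, lat2),
               great_circle_km(lon2, lat2, lon, lat))
})

test_that("great-circle distance satisfies the triangle inequality", {
  set.seed(2)
  for (i in 1:50) {
    p <- cbind(runif(3, -180, 180), runif(3, -85, 85))
    d12 <- great_circle_km(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    d23 <- great_circle_km(p[2, 1], p[2, 2], p[3, 1], p[3, 2])
    d13 <- great_circle_km(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    expect_lte(d13, d12 + d23 + 1e-9)
  }
})

test_that("initial bearing matches cardinal directions and the geodesy oracle", {
  expect_equal(initial_bearing(0, 0, 0, 1), 0)
  expect_equal(initial_bearing(0, 0, 1, 0), pi / 2, tolerance = 1e-12)
  expect_error(initial_bearing(1, 1, 1, 1), "coincident")
  skip_if_not_installed("geosphere")
  set.seed(3)
  for (i in 1:50) {
    p1 <- c(runif(1, -10, 10), runif(1, 40, 60))
    p2 <- p1 + runif(2, -0.5, 0.5)
    if (all(p1 == p2)) next
    ours <- initial_bearing(p1[1], p1[2], p2[1], p2[2])
    ref <- geosphere::bearing(p1, p2, a = 6371000, f = 0) * pi / 180
    expect_equal(wrap_angle(ours - ref), 0, tolerance = 1e-9)
  }
})

test_that("destination point: identity, due-north closed form, geodesy oracle", {
  expect_equal(destination_point(-1.5, 55, 1.2, 0),
               c(lon = -1.5, lat = 55))
  d <- 0.7
  p <- destination_point(-1.5, 55, 0, d)
  expect_equal(p[["lat"]], 55 + d / 6371 * 180 / pi, tolerance = 1e-12)
  expect_equal(p[["lon"]], -1.5)
  skip_if_not_installed("geosphere")
  set.seed(4)
  for (i in 1:20) {
    lon <- runif(1, -10, 10); lat <- runif(1, 40, 60)
    b <- runif(1, 0, 2 * pi); dk <- runif(1, 0, 5)
    ours <- destination_point(lon, lat, b, dk)
    ref <- geosphere::destPoint(c(lon, lat), b * 180 / pi, dk * 1000,
                                r = 6371000)
    expect_equal(unname(ours), as.numeric(ref), tolerance = 1e-6)
  }
})

test_that("bearing/distance/destination invert each other for sub-km offsets", {
  set.seed(5)
  n <- 500
  lon1 <- runif(n, -10, 10); lat1 <- runif(n, 40, 60)
  b <- runif(n, 0, 2 * pi); d <- runif(n, 1e-4, 0.9)
  for (i in seq_len(n)) {
    p2 <- destination_point(lon1[i], lat1[i], b[i], d[i])
    bb <- initial_bearing(lon1[i], lat1[i], p2[1], p2[2])
    dd <- great_circle_km(lon1[i], lat1[i], p2[1], p2[2])
    p3 <- destination_point(lon1[i], lat1[i], bb, dd)
    expect_lt(max(abs(p3 - p2)), 1e-6)
  }
})

test_that("track_to_steps computes steps, signed angles and the colony covariate", {
  tr <- toy_track()
  st <- track_to_steps(tr)
  expect_s3_class(st, "step_series")
  expect_equal(nrow(st), 3)
  expect_true(is.na(st$angle_rad[1]))
  # east, east along the equator: exactly straight at the middle step
  expect_equal(st$angle_rad[2], 0, tolerance = 1e-9)
  # east then north: left (counter-clockwise) turn of +pi/2
  expect_equal(st$angle_rad[3], pi / 2, tolerance = 1e-6)
  expect_equal(st$behaviour, c("foraging", "foraging", "not_foraging"))
  expect_equal(st$dist_colony_km[1], 0)
  expect_equal(attr(st, "cadence_s"), 1)
  expect_error(track_to_steps(geo_track("x", tr$fixes[1:2, ], -1.5, 55)),
               "too short")
})

test_that("exact-zero steps get the epsilon substitute and are counted", {
  fixes <- data.frame(time = 0:3,
                      lon = c(-1.5, -1.499, -1.499, -1.498),
                      lat = rep(55, 4),
                      behaviour = rep(c("active_search", "direct_flight"), 2),
                      stringsAsFactors = FALSE)
  st <- track_to_steps(geo_track("z", fixes, -1.5, 55))
  expect_equal(st$step_km[2], 1e-6)
  expect_equal(attr(st, "n_zero_steps"), 1)
  expect_true(all(st$step_km > 0))
})

test_that("turning angles negate under track reversal", {
  set.seed(6)
  sim <- simulate_tern_track(sim_config(track_length_s = 50), seed = 6)
  tr <- sim$track
  st <- track_to_steps(tr)
  rev_tr <- tr
  rev_tr$fixes <- tr$fixes[rev(seq_len(nrow(tr$fixes))), ]
  rev_tr$fixes$time <- tr$fixes$time
  str <- track_to_steps(rev_tr)
  a <- st$angle_rad[-1]
  b <- rev(str$angle_rad[-1])
  expect_equal(a, -b, tolerance = 1e-4)
})

test_that("ethogram labels collapse to the binary classes", {
  expect_equal(map_ethogram("active_search"), "foraging")
  expect_equal(map_ethogram("transit_search"), "not_foraging")
  expect_equal(map_ethogram("direct_flight"), "not_foraging")
  expect_equal(map_ethogram(c("foraging", "not_foraging")),
               c("foraging", "not_foraging"))
  expect_error(map_ethogram("loafing"), "loafing")
})

test_that("track filters drop short and single-behaviour tracks, idempotently", {
  mk <- function(id, dur, beh) {
    n <- dur + 1
    fixes <- data.frame(time = 0:dur, lon = seq(-1.5, by = 1e-4, length = n),
                        lat = rep(55, n), behaviour = beh,
                        stringsAsFactors = FALSE)
    geo_track(id, fixes, -1.5, 55)
  }
  short <- mk("short", 59, rep(c("active_search", "direct_flight"), 30))
  mono <- mk("mono", 300, rep("active_search", 301))
  good <- mk("good", 300, rep(c("active_search", "direct_flight"), length.out = 301))
  res <- filter_tracks(list(short, mono, good))
  expect_equal(length(res$kept), 1)
  expect_equal(res$kept[[1]]$track_id, "good")
  expect_equal(res$dropped$reason[res$dropped$track_id == "short"], "too_short")
  expect_equal(res$dropped$reason[res$dropped$track_id == "mono"],
               "single_behaviour")
  # exactly 60 s does not exceed 1 min: dropped
  at60 <- mk("at60", 60, rep(c("active_search", "direct_flight"), length.out = 61))
  expect_equal(filter_tracks(list(at60))$dropped$reason, "too_short")
  # idempotence
  res2 <- filter_tracks(res$kept)
  expect_equal(length(res2$kept), 1)
  expect_equal(nrow(res2$dropped), 0)
})

test_that("reconstruction from bearing/distance recovers the animal track", {
  set.seed(7)
  cfg <- sim_config(track_length_s = 120, n_tracks = 1)
  sim <- simulate_tern_track(cfg, seed = 7)
  boat <- simulate_boat_follow(sim$track, cfg, seed = 8)
  rec <- reconstruct_track(boat)
  expect_lt(max(abs(rec$fixes$lon - sim$track$fixes$lon)), 1e-9)
  expect_lt(max(abs(rec$fixes$lat - sim$track$fixes$lat)), 1e-9)
  tr_plain <- sim$track
  expect_error(reconstruct_track(tr_plain), "bearing/distance")
})

test_that("track and step-series CSV round-trips preserve the data", {
  ds <- small_dataset(n_tracks = 2, track_length_s = 100)
  f1 <- tempfile(fileext = ".csv")
  write_tracks(ds$boat_tracks, f1)
  back <- read_tracks(f1, colony_lon = ds$config$colony_lon,
                      colony_lat = ds$config$colony_lat)
  expect_equal(length(back), 2)
  orig <- ds$boat_tracks[[1]]
  got <- back[[orig$track_id]]
  expect_equal(got$fixes$lon, orig$fixes$lon, tolerance = 1e-12)
  expect_equal(got$fixes$behaviour, orig$fixes$behaviour)
  st <- track_to_steps(ds$tern_tracks[[1]])
  f2 <- tempfile(fileext = ".csv")
  write_step_series(st, f2)
  st2 <- read_step_series(f2)
  expect_equal(st2$step_km, st$step_km, tolerance = 1e-12)
  expect_equal(st2$angle_rad, st$angle_rad, tolerance = 1e-12)
})
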