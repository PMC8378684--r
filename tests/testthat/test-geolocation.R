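test_that("geographic median: identity, symmetry and grid-search oracle", {
  expect_equal(geographic_median(-50, -65), list(lat = -50, lon = -65))
  # the centre of a plus-shaped quadruple; on the sphere the exact median
  # sits ~4e-5 deg off the planar centre, so the bound reflects that
  gm <- geographic_median(c(-50.1, -49.9, -50, -50),
                          c(-65, -65, -64.9, -65.1))
  expect_lt(abs(gm$lat - -50), 1e-4)
  expect_lt(abs(gm$lon - -65), 1e-6)
  # brute-force oracle on three arbitrary points
  lat <- c(-50.30, -49.97, -50.18); lon <- c(-64.80, -65.22, -65.05)
  gm <- geographic_median(lat, lon)
  grid <- expand.grid(lat = seq(min(lat), max(lat), by = 0.001),
                      lon = seq(min(lon), max(lon), by = 0.001))
  obj <- rowSums(sapply(1:3, function(i)
    gc_dist_km(grid$lat, grid$lon, lat[i], lon[i])))
  best <- grid[which.min(obj), ]
  expect_lt(abs(gm$lat - best$lat), 0.002)
  expect_lt(abs(gm$lon - best$lon), 0.002)
})

test_that("proposals collapse to the twilight solution and keep their count", {
  tw <- twilight_times(-50, -65, as.Date("2017-06-21"), -3.44)
  pair <- list(date = as.Date("2017-06-21"), sunrise_utc = tw$sunrise_utc,
               sunset_utc = tw$sunset_utc)
  gp1 <- geolocation_params(n_particles = 1, lat_jitter_sd = 0,
                            lon_jitter_sd = 0,
                            solar_angle_range = c(-3.4401, -3.4399))
  cl <- propose_particles(NULL, pair, gp1)
  expect_equal(nrow(cl$particles), 1)
  expect_lt(abs(cl$particles$lat - -50), 0.05)
  expect_lt(abs(cl$particles$lon - -65), 0.05)
  gp <- geolocation_params(n_particles = 123)
  cl <- propose_particles(list(lat = -50, lon = -65), pair, gp)
  expect_equal(nrow(cl$particles), gp$n_particles)
})

test_that("equinox-window latitude proposals stay within the speed band", {
  tw <- twilight_times(-50, -65, as.Date("2017-09-22"), -3.44)
  pair <- list(date = as.Date("2017-09-22"), sunrise_utc = tw$sunrise_utc,
               sunset_utc = tw$sunset_utc)
  gp <- geolocation_params(n_particles = 500, rng_seed = 4)
  set.seed(4)
  cl <- propose_particles(list(lat = -50, lon = -65), pair, gp)
  r <- gp$speed_max * 24 / 111.2
  expect_true(all(abs(cl$particles$lat - -50) <= r + 1e-9))
})

test_that("particle weights combine speed, SST and land factors", {
  gp <- geolocation_params()
  cloud <- list(date = as.Date("2017-06-21"),
                particles = data.frame(
                  lat = c(-50, -50.4, -49.6, -50.2, -47),
                  lon = c(-65, -65, -65, -66, -66),
                  weight = NA_real_))
  prev <- list(lat = -50, lon = -65)
  tag_sst <- grid_sample(test_sst, -50, -65, layer = "2017-06",
                         method = "bilinear")
  w <- weight_particles(cloud, prev, tag_sst, test_sst, test_mask, gp)
  expect_equal(sum(w$particles$weight), 1, tolerance = 1e-9)
  # hand-computed three-factor product for the same cloud
  d_km <- gc_dist_km(prev$lat, prev$lon, cloud$particles$lat,
                     cloud$particles$lon)
  sp <- d_km / 24
  shape <- (gp$speed_mean / gp$speed_sd)^2
  rate <- gp$speed_mean / gp$speed_sd^2
  ws <- dgamma(pmax(sp, 1e-3), shape, rate)
  ws[sp > gp$speed_max] <- 0
  sat <- grid_sample(test_sst, cloud$particles$lat, cloud$particles$lon,
                     layer = "2017-06", method = "bilinear")
  wt <- ws * dnorm(tag_sst - sat, 0, gp$sst_sd) *
    (grid_sample(test_mask, cloud$particles$lat, cloud$particles$lon) < 0.5)
  expect_equal(w$particles$weight, wt / sum(wt), tolerance = 1e-10)
  # symmetric particles get equal weights
  cl2 <- list(date = as.Date("2017-06-21"),
              particles = data.frame(lat = c(-50.2, -49.8),
                                     lon = c(-65, -65), weight = NA_real_))
  w2 <- weight_particles(cl2, prev, NA, test_sst, NULL, gp)
  expect_equal(w2$particles$weight[1], w2$particles$weight[2],
               tolerance = 1e-9)
})

test_that("particles on land get exactly zero weight", {
  gp <- geolocation_params()
  cloud <- list(date = as.Date("2017-06-21"),
                particles = data.frame(lat = c(-50, -50), lon = c(-70, -62),
                                       weight = NA_real_))
  w <- weight_particles(cloud, NULL, NA, NULL, test_mask, gp)
  expect_identical(w$particles$weight[1], 0)   # -50, -70 is inland
  expect_gt(w$particles$weight[2], 0)
  expect_error(
    weight_particles(list(date = as.Date("2017-06-21"),
                          particles = data.frame(lat = -45, lon = -69,
                                                 weight = NA_real_)),
                     NULL, NA, NULL, test_mask, gp),
    "weights zero")
})

test_that("zero-noise path estimation recovers the true track", {
  cfg <- simulation_config(n_females = 1, n_males = 0, rng_seed = 42,
                           twilight_noise_sd = 0, sst_noise_sd = 0)
  tr <- simulate_tracks(cfg)[[1]]
  rec <- simulate_tag_records(tr, test_sst, cfg)
  sub <- rec[rec$date >= as.Date("2017-05-20") &
               rec$date <= as.Date("2017-07-05"), ]
  gp <- geolocation_params(n_particles = 800, n_iterations = 30,
                           solar_angle_range = c(-3.94, -2.94),
                           lat_jitter_sd = 0.15, rng_seed = 7)
  pe <- estimate_path(sub, test_sst, test_mask, gp)
  truth <- tr$positions[match(pe$date, tr$positions$date), ]
  expect_lt(median(abs(pe$lat - truth$lat)), 0.5)
  expect_lt(median(abs(pe$lon - truth$lon)), 0.2)
  # determinism + weight/land invariants
  pe2 <- estimate_path(sub, test_sst, test_mask, gp)
  expect_identical(pe, pe2)
  expect_false(any(is_land(pe$lat, pe$lon)))
})

test_that("latitude accuracy degrades monotonically with twilight noise", {
  errs <- sapply(c(0, 4, 10), function(noise) {
    cfg <- simulation_config(n_females = 1, n_males = 0, rng_seed = 8,
                             twilight_noise_sd = noise, sst_noise_sd = 0.3)
    tr <- simulate_tracks(cfg)[[1]]
    rec <- simulate_tag_records(tr, test_sst, cfg)
    sub <- rec[rec$date >= as.Date("2017-06-01") &
                 rec$date <= as.Date("2017-07-10"), ]
    gp <- geolocation_params(n_particles = 500, n_iterations = 15,
                             rng_seed = 3)
    pe <- estimate_path(sub, test_sst, test_mask, gp)
    truth <- tr$positions[match(pe$date, tr$positions$date), ]
    median(gc_dist_km(pe$lat, pe$lon, truth$lat, pe$lon))
  })
  expect_true(all(diff(errs) >= -10))  # non-increasing accuracy, 10 km slack
})

test_that("equinox-window latitude dispersion exceeds mid-winter dispersion", {
  cfg <- simulation_config(n_females = 1, n_males = 0, rng_seed = 21)
  tr <- simulate_tracks(cfg)[[1]]
  rec <- simulate_tag_records(tr, test_sst, cfg)
  sub <- rec[rec$date >= as.Date("2017-08-15") &
               rec$date <= as.Date("2017-09-24"), ]
  gp <- geolocation_params(n_particles = 500, n_iterations = 20,
                           rng_seed = 5)
  pe <- estimate_path(sub, test_sst, test_mask, gp,
                      keep_iterations = TRUE,
                      start_location = list(lat = tr$positions$lat[
                        match(min(as.Date(sub$date)), tr$positions$date)],
                        lon = tr$positions$lon[
                          match(min(as.Date(sub$date)), tr$positions$date)]))
  its <- attr(pe, "iterations")
  lat_spread <- apply(its$lat, 2, sd)
  eq <- in_equinox_window(pe$date)
  expect_gt(mean(lat_spread[eq]), mean(lat_spread[!eq]))
})

test_that("trip windows are detected from wet/dry states", {
  dates <- seq(as.Date("2017-04-01"), by = "day", length.out = 150)
  wet <- c(rep(0.02, 5), rep(1, 100), rep(0.02, 45))
  rec <- data.frame(id = "X", date = dates, wet_fraction = wet)
  win <- detect_trip_window(rec)
  expect_equal(win$departure_date, dates[6])
  expect_equal(win$arrival_date, dates[106])
  expect_error(detect_trip_window(
    data.frame(id = "X", date = dates, wet_fraction = rep(0, 150))),
    "departure")
  # ground-truth recovery through the simulator
  cfg <- simulation_config(n_females = 1, n_males = 0, rng_seed = 13)
  tr <- simulate_tracks(cfg)[[1]]
  recs <- simulate_tag_records(tr, test_sst, cfg)
  win <- detect_trip_window(recs)
  expect_equal(win$departure_date, tr$departure_date)
  expect_equal(win$arrival_date, tr$arrival_date)
})

test_that("path estimation validates its inputs", {
  cfg <- simulation_config(n_females = 1, n_males = 0, rng_seed = 2)
  tr <- simulate_tracks(cfg)[[1]]
  rec <- simulate_tag_records(tr, test_sst, cfg)
  gp <- geolocation_params(n_particles = 50, n_iterations = 2)
  expect_error(estimate_path(rec[1, ], test_sst, test_mask, gp),
               "at least 2")
})
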