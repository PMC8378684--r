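# Probabilistic light-level geolocation: per-day particle clouds generated
# from twilight times over a range of solar angles, weighted by travelling
# speed, SST agreement and land avoidance, combined over forward iterations
# into a geographic-median most-probable path.

#' Geolocation parameters
#'
#' @param n_particles particles per day per iteration (default 2000).
#' @param n_iterations forward passes (default 200).
#' @param solar_angle_range twilight sun-elevation angles sampled per
#'   particle, degrees `c(low, high)` (default `c(-7, 0)`).
#' @param speed_mean,speed_sd,speed_max travelling speed plausibility:
#'   gamma density fitted to (mean, sd), hard-capped at `speed_max` km/h.
#' @param sst_sd SD (deg C) of the Gaussian kernel comparing tag minimum
#'   SST to satellite SST.
#' @param equinox_window_days half-width of the equinox window in which
#'   day-length latitude is treated as unidentifiable (default 12).
#' @param lat_jitter_sd,lon_jitter_sd per-particle position jitter, degrees.
#' @param rng_seed integer seed.
#' @return list of class `geolocation_params`.
#' @export
geolocation_params <- function(n_particles = 2000, n_iterations = 200,
                               solar_angle_range = c(-7, 0),
                               speed_mean = 2, speed_sd = 1, speed_max = 8,
                               sst_sd = 1.0, equinox_window_days = 12,
                               lat_jitter_sd = 0.3, lon_jitter_sd = 0.3,
                               rng_seed = 1L) {
  stopifnot(n_particles >= 1, n_iterations >= 1,
            solar_angle_range[1] < solar_angle_range[2],
            sst_sd > 0, speed_max > 0)
  structure(list(n_particles = as.integer(n_particles),
                 n_iterations = as.integer(n_iterations),
                 solar_angle_range = solar_angle_range,
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 speed_max = speed_max, sst_sd = sst_sd,
                 equinox_window_days = equinox_window_days,
                 lat_jitter_sd = lat_jitter_sd, lon_jitter_sd = lon_jitter_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "geolocation_params")
}

# Per-day twilight solution: longitude (angle-independent, from solar
# midday + equation of time) and the latitude-vs-solar-angle curve,
# inverted from the predicted day-length surface. Returns degenerate = TRUE
# near the equinox or when no latitude solves the day length.
.day_solution <- function(date, sunrise_utc, sunset_utc, params,
                          lat_range = c(-68, -30)) {
  midday <- (sunrise_utc + sunset_utc) / 2
  lon <- (720 - midday * 60 - equation_of_time(date)) / 4
  lon <- ((lon + 180) %% 360) - 180
  dl <- sunset_utc - sunrise_utc
  degen <- in_equinox_window(date, params$equinox_window_days) ||
    abs(solar_declination(date)) < 1.5
  angles <- seq(params$solar_angle_range[1], params$solar_angle_range[2],
                length.out = 29)
  lat_at <- rep(NA_real_, length(angles))
  if (!degen) {
    latg <- seq(lat_range[1], lat_range[2], by = 0.05)
    for (k in seq_along(angles)) {
      dls <- day_length(latg, date, angles[k])
      ok <- dls > 1e-6 & dls < 24 - 1e-6
      if (sum(ok) < 2) next
      x <- dls[ok]; y <- latg[ok]
      if (x[1] > x[length(x)]) { x <- rev(x); y <- rev(y) }
      if (dl >= min(x) && dl <= max(x))
        lat_at[k] <- stats::approx(x, y, xout = dl, ties = "ordered")$y
    }
    if (all(is.na(lat_at))) degen <- TRUE
  }
  list(date = date, lon = lon, angles = angles, lat_at = lat_at,
       degenerate = degen)
}

#' Propose a particle cloud for one day
#'
#' Each particle samples a solar angle uniformly from the configured range
#' and takes the latitude solving that day's day-length equation at that
#' angle (plus jitter); longitude comes from the solar-midday inversion
#' (plus jitter). Within the equinox window, where day-length latitude is
#' degenerate, latitudes are drawn uniformly from the speed-reachable band
#' around the previous location instead.
#'
#' @param prev_cloud previous day's cloud (list with `particles`
#'   data.frame) or a single location `list(lat =, lon =)`; may be `NULL`
#'   only off-equinox.
#' @param pair list/row with `date`, `sunrise_utc`, `sunset_utc`.
#' @param params [geolocation_params()].
#' @param day_sol optional precomputed `.day_solution` (internal fast path).
#' @param land_mask optional `regular_grid` land mask; when given, a cloud
#'   entirely on land is rejected with an error naming the date.
#' @return unweighted cloud: list with `date` and `particles`
#'   (data.frame `lat`, `lon`, `weight = NA`).
#' @export
propose_particles <- function(prev_cloud, pair, params, day_sol = NULL,
                              land_mask = NULL) {
  if (is.null(day_sol))
    day_sol <- .day_solution(as.Date(pair$date), pair$sunrise_utc,
                             pair$sunset_utc, params)
  n <- params$n_particles
  prev <- .cloud_center(prev_cloud)
  lon <- day_sol$lon + stats::rnorm(n, 0, params$lon_jitter_sd)
  if (day_sol$degenerate) {
    if (is.null(prev))
      stop("no previous location to anchor equinox-window proposals on ",
           day_sol$date)
    r <- params$speed_max * 24 / 111.2
    lat <- prev$lat + stats::runif(n, -r, r)
  } else {
    a <- stats::runif(n, params$solar_angle_range[1],
                      params$solar_angle_range[2])
    ok <- !is.na(day_sol$lat_at)
    lat0 <- stats::approx(day_sol$angles[ok], day_sol$lat_at[ok], xout = a,
                          rule = 2)$y
    lat <- lat0 + stats::rnorm(n, 0, params$lat_jitter_sd)
  }
  # defensive fraction drawn from the speed-reachable box around the
  # previous location, so a noisy twilight solution can never strand the
  # whole cloud beyond the travelling-speed cap
  n_def <- floor(0.15 * n)
  if (!is.null(prev) && n_def > 0) {
    r <- params$speed_max * 24 / 111.2
    k <- seq_len(n_def)
    lat[k] <- prev$lat + stats::runif(n_def, -r, r)
    r_lon <- r / max(cos(.deg2rad(prev$lat)), 0.2)
    lon[k] <- prev$lon + stats::runif(n_def, -r_lon, r_lon)
  }
  lat <- pmin(pmax(lat, -89), 89)
  if (!is.null(land_mask)) {
    for (try in 1:20) {
      on_land <- grid_sample(land_mask, lat, lon, method = "nearest") >= 0.5
      if (!all(on_land)) break
      lat <- lat + stats::rnorm(n, 0, 0.5)
      lon <- lon + stats::rnorm(n, 0, 0.5)
    }
    if (all(on_land))
      stop("all proposed particles on land on ", day_sol$date)
  }
  list(date = day_sol$date,
       particles = data.frame(lat = lat, lon = lon, weight = NA_real_))
}

.cloud_center <- function(x) {
  if (is.null(x)) return(NULL)
  if (!is.null(x$particles)) {
    w <- x$particles$weight
    if (all(is.na(w))) w <- rep(1, nrow(x$particles))
    return(list(lat = sum(x$particles$lat * w) / sum(w),
                lon = sum(x$particles$lon * w) / sum(w)))
  }
  list(lat = x$lat, lon = x$lon)
}

#' Weight a particle cloud
#'
#' Weight proportional to: gamma travelling-speed plausibility of the
#' implied speed from `prev_location` (hard-capped at `speed_max`, omitted
#' when `prev_location` is `NULL`), times a Gaussian kernel on the
#' difference between the tag's minimum SST and satellite SST at the
#' particle (omitted when `tag_min_sst` is `NA`), times a land-avoidance
#' indicator. Weights are renormalized to sum to one.
#'
#' @param cloud unweighted cloud from [propose_particles()].
#' @param prev_location `list(lat =, lon =)` or `NULL`.
#' @param tag_min_sst tag daily minimum SST, deg C (or `NA`).
#' @param sst_field `regular_grid` of SST; layer picked by the cloud date's
#'   month (first layer if absent).
#' @param land_mask `regular_grid`, 1 = land.
#' @param params [geolocation_params()].
#' @param dt_days days elapsed since `prev_location` (default 1).
#' @return the cloud with normalized `weight` and `effective_sample_size`.
#' @export
weight_particles <- function(cloud, prev_location, tag_min_sst, sst_field,
                             land_mask, params, dt_days = 1) {
  p <- cloud$particles
  stopifnot(nrow(p) >= 1)
  w <- rep(1, nrow(p))
  if (!is.null(prev_location)) {
    d_km <- gc_dist_km(prev_location$lat, prev_location$lon, p$lat, p$lon)
    speed <- d_km / (24 * dt_days)
    shape <- (params$speed_mean / params$speed_sd)^2
    rate <- params$speed_mean / params$speed_sd^2
    w_speed <- stats::dgamma(pmax(speed, 1e-3), shape, rate)
    w_speed[speed > params$speed_max] <- 0
    w <- w * w_speed
  }
  if (!is.na(tag_min_sst) && !is.null(sst_field)) {
    m <- .month_label(cloud$date)
    layer <- if (m %in% sst_field$layers) m else sst_field$layers[1]
    sat <- grid_sample(sst_field, p$lat, p$lon, layer = layer,
                       method = "bilinear")
    w <- w * stats::dnorm(tag_min_sst - sat, 0, params$sst_sd)
  }
  if (!is.null(land_mask)) {
    on_land <- grid_sample(land_mask, p$lat, p$lon, method = "nearest") >= 0.5
    w[on_land] <- 0
  }
  s <- sum(w)
  if (s == 0)
    stop("all particle weights zero on ", cloud$date,
         " (environmental data inconsistent with track)")
  p$weight <- w / s
  list(date = cloud$date, particles = p,
       effective_sample_size = 1 / sum((w / s)^2))
}

#' Estimate the most-probable path from tag records
#'
#' Runs `n_iterations` forward passes of sequential importance sampling:
#' within a pass, each day's cloud is proposed from the twilight solution,
#' weighted against the previously selected location, SST and land, and one
#' particle is drawn by weight. The most-probable path is the per-day
#' geographic median of the retained points across iterations; per-day
#' dispersion is the median great-circle distance to that median.
#'
#' @param records a `tag_records` data.frame (one row per day).
#' @param sst_field,land_mask `regular_grid` objects.
#' @param params [geolocation_params()].
#' @param start_location optional known deployment point
#'   `list(lat =, lon =)` anchoring the first day's speed weight.
#' @param keep_iterations keep the per-iteration points (diagnostics).
#' @return data.frame of class `path_estimate`: `id`, `date`, `lat`, `lon`,
#'   `dispersion_km`; iteration paths in `attr(, "iterations")` if kept.
#' @export
estimate_path <- function(records, sst_field, land_mask, params,
                          start_location = NULL, keep_iterations = FALSE) {
  usable <- !records$missing & !is.na(records$sunrise_utc) &
    !is.na(records$sunset_utc)
  rec <- records[usable, , drop = FALSE]
  if (nrow(rec) < 2) stop("need at least 2 usable days of twilight records")
  set.seed(params$rng_seed)
  nd <- nrow(rec)
  sols <- vector("list", nd)
  for (d in seq_len(nd))
    sols[[d]] <- .day_solution(as.Date(rec$date[d]), rec$sunrise_utc[d],
                               rec$sunset_utc[d], params)
  if (sols[[1]]$degenerate && is.null(start_location))
    stop("track starts inside the equinox window; supply start_location")
  pts_lat <- matrix(NA_real_, params$n_iterations, nd)
  pts_lon <- matrix(NA_real_, params$n_iterations, nd)
  dts <- c(1, as.numeric(diff(as.Date(rec$date))))
  for (it in seq_len(params$n_iterations)) {
    prev <- start_location
    for (d in seq_len(nd)) {
      cl <- propose_particles(prev, rec[d, ], params, day_sol = sols[[d]],
                              land_mask = land_mask)
      cl <- weight_particles(cl, prev, rec$min_sst_c[d], sst_field,
                             land_mask, params, dt_days = dts[d])
      j <- sample.int(nrow(cl$particles), 1, prob = cl$particles$weight)
      pts_lat[it, d] <- cl$particles$lat[j]
      pts_lon[it, d] <- cl$particles$lon[j]
      prev <- list(lat = pts_lat[it, d], lon = pts_lon[it, d])
    }
  }
  lat <- lon <- disp <- numeric(nd)
  for (d in seq_len(nd)) {
    med <- geographic_median(pts_lat[, d], pts_lon[, d])
    lat[d] <- med$lat; lon[d] <- med$lon
    disp[d] <- stats::median(gc_dist_km(med$lat, med$lon,
                                        pts_lat[, d], pts_lon[, d]))
  }
  out <- data.frame(id = rec$id, date = as.Date(rec$date), lat = lat,
                    lon = lon, dispersion_km = disp)
  class(out) <- c("path_estimate", "data.frame")
  if (keep_iterations)
    attr(out, "iterations") <- list(lat = pts_lat, lon = pts_lon)
  out
}

#' Detect the dispersal trip window from wet/dry states
#'
#' Departure is the first date whose wet fraction stays at or above
#' `wet_threshold` for `k` consecutive days; arrival is the first later
#' date whose dry fraction (1 - wet) stays at or above `dry_threshold` for
#' `k` consecutive days (runs truncated by the end of the record count).
#'
#' @param records a `tag_records` data.frame.
#' @param wet_threshold,dry_threshold fraction thresholds (default 0.75).
#' @param k sustained-days requirement (default 2).
#' @return list with `departure_date`, `arrival_date`.
#' @export
detect_trip_window <- function(records, wet_threshold = 0.75,
                               dry_threshold = 0.75, k = 2) {
  stopifnot("wet_fraction" %in% names(records))
  o <- order(as.Date(records$date))
  dates <- as.Date(records$date)[o]
  wet <- records$wet_fraction[o]
  n <- length(wet)
  sustained <- function(x, thr) {
    hit <- x >= thr
    for (i in seq_len(n)) {
      j <- min(i + k - 1, n)
      if (all(hit[i:j])) return(i)
    }
    NA_integer_
  }
  dep <- sustained(wet, wet_threshold)
  if (is.na(dep)) stop("no departure found: wet threshold never sustained")
  arr <- NA_integer_
  hit <- (1 - wet) >= dry_threshold
  for (i in seq((dep + 1), n)) {
    j <- min(i + k - 1, n)
    if (all(hit[i:j])) { arr <- i; break }
  }
  if (is.na(arr)) stop("no arrival found: dry threshold never sustained")
  list(departure_date = dates[dep], arrival_date = dates[arr])
}
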