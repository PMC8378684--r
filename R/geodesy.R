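# Great-circle helpers. All spherical math uses radius 6378137 m (the
# default of geosphere's distance functions), so distances are consistent
# across the geolocation and track-metric layers.

.EARTH_RADIUS_M <- 6378137

#' Great-circle (haversine) distance
#'
#' @param lat1,lon1,lat2,lon2 positions in decimal degrees (vectorized).
#' @return distance in kilometres.
#' @export
gc_dist_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = .EARTH_RADIUS_M) / 1000
}

#' Geographic median of a point set
#'
#' The point minimizing the sum of great-circle distances to the inputs,
#' found by Weiszfeld iteration adapted to the sphere (each step re-weights
#' points by inverse great-circle distance and renormalizes the weighted
#' chord mean back onto the sphere). Converges to sub-metre tolerance for
#' the sub-continental point clouds arising in geolocation.
#'
#' @param lat,lon point coordinates, degrees.
#' @param weights optional non-negative weights.
#' @param tol convergence tolerance in metres (default 1).
#' @param max_iter iteration cap.
#' @return list with `lat`, `lon` of the median point.
#' @export
geographic_median <- function(lat, lon, weights = NULL, tol = 1,
                              max_iter = 200) {
  stopifnot(length(lat) >= 1, length(lat) == length(lon))
  if (is.null(weights)) weights <- rep(1, length(lat))
  stopifnot(all(weights >= 0), any(weights > 0))
  if (length(lat) == 1) return(list(lat = lat, lon = lon))

  phi <- .deg2rad(lat); lam <- .deg2rad(lon)
  xyz <- cbind(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
  # start at the weighted chord mean
  cur <- colSums(xyz * weights); cur <- cur / sqrt(sum(cur^2))
  for (it in seq_len(max_iter)) {
    ang <- acos(pmin(1, pmax(-1, as.vector(xyz %*% cur))))
    d <- ang * .EARTH_RADIUS_M
    if (any(d < 1e-6)) return(.xyz_to_latlon(xyz[which.min(d), ]))
    w <- weights / d
    nxt <- colSums(xyz * w); nxt <- nxt / sqrt(sum(nxt^2))
    step <- acos(pmin(1, pmax(-1, sum(nxt * cur)))) * .EARTH_RADIUS_M
    cur <- nxt
    if (step < tol) break
  }
  .xyz_to_latlon(cur)
}

.xyz_to_latlon <- function(v) {
  list(lat = .rad2deg(asin(pmin(1, pmax(-1, v[3])))),
       lon = .rad2deg(atan2(v[2], v[1])))
}
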