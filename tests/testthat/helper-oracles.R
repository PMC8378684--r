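# Independent oracles used across the suite. These deliberately take
# different computational routes than the package implementation.

# Higher-accuracy solar declination (Meeus-style ecliptic-longitude route,
# independent of the NOAA Fourier fit used in the package).
meeus_declination <- function(date) {
  n <- as.numeric(as.Date(date) - as.Date("2000-01-01")) - 0.5
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- (357.528 + 0.9856003 * n) %% 360 * pi / 180
  lambda <- (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) * pi / 180
  eps <- (23.439 - 0.0000004 * n) * pi / 180
  asin(sin(eps) * sin(lambda)) * 180 / pi
}

# Brute-force latitude from day length: scan phi at 0.01 degree steps
# minimizing |predicted - observed| day length.
grid_search_latitude <- function(day_len_h, date, solar_angle,
                                 lat_range = c(-70, 70)) {
  phi <- seq(lat_range[1], lat_range[2], by = 0.01)
  dls <- day_length(phi, date, solar_angle)
  phi[which.min(abs(dls - day_len_h))]
}

# Closed-form lens (two-circle intersection) area, circles radius r,
# centres distance d apart.
lens_area <- function(r, d) {
  2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
}

# Spherical law of cosines distance (km), same radius as the package.
slc_dist_km <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  acos(pmin(1, sin(lat1 * r) * sin(lat2 * r) +
              cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r))) *
    6378137 / 1000
}

# 2x2 likelihood-ratio (G) statistic for a binary outcome by group.
g_statistic <- function(flag, group) {
  tab <- table(factor(group), factor(flag, levels = c(0, 1)))
  n <- sum(tab)
  g <- 0
  for (i in 1:2) for (j in 1:2) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / n
    if (tab[i, j] > 0) g <- g + 2 * tab[i, j] * log(tab[i, j] / e)
  }
  g
}

# shared small environment rasters (cheap to build)
test_sst <- make_sst_field()
test_mask <- make_land_mask()
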