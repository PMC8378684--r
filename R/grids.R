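# Minimal regular lat/lon raster container used for the satellite SST field
# and the land mask. Values are stored as [lat, lon] (or [lat, lon, layer])
# arrays over cell-centre coordinate vectors; serialized as long-format CSV.

#' Create a regular lat/lon grid
#'
#' @param lat,lon strictly increasing vectors of cell-centre coordinates
#'   (degrees), regular spacing.
#' @param values numeric array, `dim = c(length(lat), length(lon))` or
#'   `c(length(lat), length(lon), n_layers)`.
#' @param layers optional layer labels (e.g. months "2017-04").
#' @return an object of class `regular_grid`.
#' @export
regular_grid <- function(lat, lon, values, layers = NULL) {
  stopifnot(length(lat) > 1, length(lon) > 1,
            all(diff(lat) > 0), all(diff(lon) > 0))
  if (length(dim(values)) == 2) values <- array(values, c(dim(values), 1))
  stopifnot(dim(values)[1] == length(lat), dim(values)[2] == length(lon))
  if (is.null(layers)) layers <- as.character(seq_len(dim(values)[3]))
  stopifnot(length(layers) == dim(values)[3])
  structure(list(lat = lat, lon = lon, values = values,
                 layers = as.character(layers)),
            class = "regular_grid")
}

#' @export
print.regular_grid <- function(x, ...) {
  cat(sprintf("regular_grid: %d x %d cells, %d layer(s)\n",
              length(x$lat), length(x$lon), dim(x$values)[3]))
  cat(sprintf("  lat %.2f..%.2f, lon %.2f..%.2f, spacing %.3g deg\n",
              min(x$lat), max(x$lat), min(x$lon), max(x$lon),
              diff(x$lat[1:2])))
  invisible(x)
}

.grid_layer_index <- function(grid, layer) {
  if (is.null(layer)) return(1L)
  if (is.numeric(layer)) return(as.integer(layer))
  i <- match(as.character(layer), grid$layers)
  if (any(is.na(i))) stop("unknown grid layer: ", layer[is.na(i)][1])
  i
}

#' Sample a grid at points
#'
#' Nearest-neighbour or bilinear interpolation of a `regular_grid` at
#' arbitrary positions. Points outside the grid extent are clamped to the
#' border cell.
#'
#' @param grid a `regular_grid`.
#' @param lat,lon numeric vectors of positions (degrees).
#' @param layer layer label or index (recycled scalar).
#' @param method `"nearest"` or `"bilinear"`.
#' @return numeric vector of sampled values.
#' @export
grid_sample <- function(grid, lat, lon, layer = NULL, method = "nearest") {
  k <- .grid_layer_index(grid, layer)
  v <- grid$values[, , k, drop = TRUE]
  if (method == "nearest") {
    i <- pmin(pmax(findInterval(lat, grid$lat + diff(grid$lat[1:2]) / 2) + 1,
                   1), length(grid$lat))
    j <- pmin(pmax(findInterval(lon, grid$lon + diff(grid$lon[1:2]) / 2) + 1,
                   1), length(grid$lon))
    return(v[cbind(i, j)])
  }
  if (method != "bilinear") stop("unknown sampling method: ", method)
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  i0 <- pmin(pmax(findInterval(lat, grid$lat), 1), nlat - 1)
  j0 <- pmin(pmax(findInterval(lon, grid$lon), 1), nlon - 1)
  ty <- (lat - grid$lat[i0]) / (grid$lat[i0 + 1] - grid$lat[i0])
  tx <- (lon - grid$lon[j0]) / (grid$lon[j0 + 1] - grid$lon[j0])
  ty <- pmin(pmax(ty, 0), 1); tx <- pmin(pmax(tx, 0), 1)
  v00 <- v[cbind(i0, j0)];     v01 <- v[cbind(i0, j0 + 1)]
  v10 <- v[cbind(i0 + 1, j0)]; v11 <- v[cbind(i0 + 1, j0 + 1)]
  (1 - ty) * ((1 - tx) * v00 + tx * v01) + ty * ((1 - tx) * v10 + tx * v11)
}

#' Write / read a regular grid as long-format CSV
#'
#' Columns: `lat, lon, layer, value`. Round trips are exact up to float
#' formatting (values written with 15 significant digits).
#'
#' @param grid a `regular_grid`.
#' @param path CSV file path.
#' @export
write_grid_csv <- function(grid, path) {
  df <- expand.grid(lat = grid$lat, lon = grid$lon, layer = grid$layers,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$value <- as.vector(grid$values)
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @param path CSV file path.
#' @export
read_grid_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lat", "lon", "layer", "value")
  if (!all(need %in% names(df)))
    stop("grid CSV must have columns: ", paste(need, collapse = ", "))
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  layers <- unique(df$layer)
  v <- array(NA_real_, c(length(lat), length(lon), length(layers)))
  i <- match(df$lat, lat); j <- match(df$lon, lon); k <- match(df$layer, layers)
  v[cbind(i, j, k)] <- df$value
  regular_grid(lat, lon, v, layers)
}

# --- stylized Patagonian Shelf environment --------------------------------

# Crude east-coast longitude of South America as a function of latitude,
# linearly interpolated between hand-picked anchor points. Used only to
# build the synthetic land mask; deliberately coarse.
.coast_lon <- function(lat) {
  anchors_lat <- c(-60, -56.5, -55.2, -54.6, -52.5, -50, -46, -43, -41, -38)
  anchors_lon <- c(-75, -68.0, -66.3, -65.1, -68.3, -68.8, -67.4, -64.8,
                   -62.8, -57.5)
  stats::approx(anchors_lat, anchors_lon, xout = lat, rule = 2)$y
}

#' Stylized land test for the Patagonian Shelf study region
#'
#' Boolean land indicator backing the synthetic land-mask raster: land lies
#' west of a coarse piecewise-linear east coast between 56.5S and 38S, with
#' the Beagle Channel carved out so the Martillo Island colony sits on water.
#' This is a synthetic, stylized coastline for simulation and testing, not a
#' cartographic product.
#'
#' @param lat,lon positions, degrees.
#' @return logical vector, `TRUE` on land.
#' @export
is_land <- function(lat, lon) {
  land <- lat > -56.5 & lat < -38 & lon < .coast_lon(lat)
  beagle <- lat >= -55.3 & lat <= -54.6 & lon >= -69 & lon <= -65
  land & !beagle
}

#' Synthetic land mask raster
#'
#' 0.25-degree boolean raster (1 = land) covering 60S-38S, 75W-55W,
#' rasterized from [is_land()].
#'
#' @param resolution cell size in degrees (default 0.25).
#' @return a `regular_grid` with values 0 (sea) / 1 (land).
#' @export
make_land_mask <- function(resolution = 0.25) {
  lat <- seq(-60 + resolution / 2, -38 - resolution / 2, by = resolution)
  lon <- seq(-75 + resolution / 2, -55 - resolution / 2, by = resolution)
  v <- outer(lat, lon, function(a, b) as.numeric(is_land(a, b)))
  regular_grid(lat, lon, v, layers = "land")
}

#' Synthetic monthly sea-surface temperature field
#'
#' Regular 0.25-degree SST field over the study region with a poleward
#' temperature decline (~0.55 deg C per degree latitude, realistic for the
#' Patagonian Shelf), a seasonal cycle peaking in late summer, and a weak
#' zonal gradient. Smooth by construction so that bilinear sampling is a
#' faithful stand-in for satellite SST.
#'
#' @param months character vector "YYYY-MM" of layers to generate.
#' @param resolution cell size in degrees.
#' @return a `regular_grid` with one layer per month, deg C.
#' @export
make_sst_field <- function(months = sprintf("2017-%02d", 3:10),
                           resolution = 0.25) {
  lat <- seq(-60 + resolution / 2, -38 - resolution / 2, by = resolution)
  lon <- seq(-75 + resolution / 2, -55 - resolution / 2, by = resolution)
  v <- array(NA_real_, c(length(lat), length(lon), length(months)))
  for (k in seq_along(months)) {
    m <- as.integer(substr(months[k], 6, 7))
    seasonal <- 3.0 * cos(2 * pi * (m - 2) / 12)  # peak Feb, trough Aug
    v[, , k] <- outer(lat, lon, function(a, b)
      10 + seasonal + 0.55 * (a + 48) + 0.05 * (b + 65))
  }
  regular_grid(lat, lon, v, layers = months)
}

.month_label <- function(date) strftime(as.Date(date), "%Y-%m", tz = "UTC")
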