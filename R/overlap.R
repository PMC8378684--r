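# Gridded penguin-density x fishing-effort overlap and interaction scoring.

#' 2-degree analysis grid specification
#'
#' Cells are half-open `[edge, edge + size)` with edges anchored at even
#' integer degrees (so 0.5-degree effort cells nest exactly).
#'
#' @param cell_size cell size in degrees (default 2).
#' @param lat_range,lon_range bounding box `c(min, max)`, degrees, aligned
#'   to multiples of `cell_size`.
#' @return list of class `grid_spec`.
#' @export
grid_spec <- function(cell_size = 2, lat_range = c(-60, -38),
                      lon_range = c(-70, -54)) {
  stopifnot(cell_size > 0, lat_range[1] < lat_range[2],
            lon_range[1] < lon_range[2])
  if (any(c(lat_range, lon_range) %% cell_size != 0))
    stop("grid bounds must align to multiples of the cell size")
  structure(list(cell_size = cell_size, lat_range = lat_range,
                 lon_range = lon_range), class = "grid_spec")
}

.cell_edge <- function(x, size) floor(x / size) * size

#' Count daily locations on the analysis grid
#'
#' Each daily fix increments exactly one half-open cell for its sex and
#' month; fixes outside the bounding box go to an overflow count reported
#' in `attr(, "overflow")`. Totals are conserved.
#'
#' @param positions data.frame with `date`, `lat`, `lon`, `sex`.
#' @param spec a [grid_spec()].
#' @return data.frame of class `density_grid`: `sex`, `month`, `lat_min`,
#'   `lon_min`, `count` (cells with count > 0 only).
#' @export
grid_counts <- function(positions, spec = grid_spec()) {
  stopifnot(all(c("date", "lat", "lon", "sex") %in% names(positions)))
  sz <- spec$cell_size
  lat0 <- .cell_edge(positions$lat, sz)
  lon0 <- .cell_edge(positions$lon, sz)
  inside <- lat0 >= spec$lat_range[1] & lat0 < spec$lat_range[2] &
    lon0 >= spec$lon_range[1] & lon0 < spec$lon_range[2]
  month <- .month_label(positions$date)
  key <- data.frame(sex = positions$sex[inside], month = month[inside],
                    lat_min = lat0[inside], lon_min = lon0[inside])
  agg <- stats::aggregate(list(count = rep(1L, nrow(key))), key, sum)
  attr(agg, "overflow") <- sum(!inside)
  attr(agg, "spec") <- spec
  class(agg) <- c("density_grid", "data.frame")
  agg
}

#' Normalize counts to the per sex-and-month maximum
#'
#' density = count / max(count) within each sex x month layer, so every
#' non-empty layer has maximum density exactly 1; all-zero layers stay
#' zero.
#'
#' @param counts a `density_grid` from [grid_counts()].
#' @return the grid with a `density` column in \[0, 1\].
#' @export
normalize_density <- function(counts) {
  stopifnot(all(counts$count >= 0))
  key <- interaction(counts$sex, counts$month, drop = TRUE)
  mx <- stats::ave(counts$count, key, FUN = max)
  counts$density <- ifelse(mx > 0, counts$count / mx, 0)
  counts
}

#' Re-grid fishing effort to the analysis grid
#'
#' Sums nested fine cells (e.g. sixteen 0.5-degree cells per 2-degree
#' cell) per fishery and month. Fine-cell edges must align with the coarse
#' grid; total hours are conserved exactly.
#'
#' @param effort an `effort_df` (`fishery`, `month`, `lat_min`, `lon_min`,
#'   `hours`) at fine resolution.
#' @param spec a [grid_spec()].
#' @param fine_cell fine cell size in degrees (default 0.5).
#' @return data.frame of class `effort_grid`: `fishery`, `month`,
#'   `lat_min`, `lon_min`, `hours`, `score`.
#' @export
regrid_effort <- function(effort, spec = grid_spec(), fine_cell = 0.5) {
  stopifnot(all(effort$hours >= 0))
  if (spec$cell_size %% fine_cell != 0)
    stop("fine cells do not nest in the coarse grid")
  if (any(effort$lat_min %% fine_cell != 0) ||
      any(effort$lon_min %% fine_cell != 0))
    stop("effort cell edges misaligned with the fine grid")
  coarse <- data.frame(fishery = effort$fishery, month = effort$month,
                       lat_min = .cell_edge(effort$lat_min, spec$cell_size),
                       lon_min = .cell_edge(effort$lon_min, spec$cell_size))
  agg <- stats::aggregate(list(hours = effort$hours), coarse, sum)
  agg$score <- effort_score(agg$hours)
  class(agg) <- c("effort_grid", "data.frame")
  agg
}

#' Bin fishing hours into the 0-5 effort score
#'
#' Score 0 is reserved for exactly zero hours; the published ranges share
#' endpoints, resolved as left-open right-closed bins:
#' 1: (0, 60\], 2: (60, 200\], 3: (200, 800\], 4: (800, 6000\], 5: > 6000.
#'
#' @param hours non-negative fishing hours (vectorized).
#' @return integer scores in \{0, ..., 5\}.
#' @export
effort_score <- function(hours) {
  if (any(hours < 0)) stop("negative fishing hours")
  breaks <- c(0, 60, 200, 800, 6000, Inf)
  sc <- findInterval(hours, breaks, left.open = TRUE)
  as.integer(ifelse(hours == 0, 0L, sc))
}

#' Build the overlap/interaction table
#'
#' One row per penguin-present cell (density > 0) per sex, month and
#' fishery: `overlap_flag = 1` iff the fishery's score there is positive,
#' and `interaction = density * score` (bounded on \[0, 5\]). Cells with no
#' effort record get score 0.
#'
#' @param density a normalized `density_grid` ([normalize_density()]).
#' @param effort an `effort_grid` ([regrid_effort()]) on the same spec.
#' @return data.frame of class `overlap_table`: `sex`, `month`, `lat_min`,
#'   `lon_min`, `fishery`, `density`, `score`, `overlap_flag`,
#'   `interaction`.
#' @export
build_overlap_table <- function(density, effort) {
  stopifnot("density" %in% names(density))
  pres <- density[density$density > 0, , drop = FALSE]
  out <- list()
  for (fy in unique(effort$fishery)) {
    e <- effort[effort$fishery == fy, , drop = FALSE]
    mrg <- merge(pres, e[, c("month", "lat_min", "lon_min", "score")],
                 by = c("month", "lat_min", "lon_min"), all.x = TRUE)
    mrg$score[is.na(mrg$score)] <- 0L
    mrg$fishery <- fy
    out[[fy]] <- mrg
  }
  tab <- do.call(rbind, out)
  tab$overlap_flag <- as.integer(tab$score > 0)
  tab$interaction <- tab$density * tab$score
  rownames(tab) <- NULL
  tab <- tab[, c("sex", "month", "lat_min", "lon_min", "fishery",
                 "density", "score", "overlap_flag", "interaction")]
  class(tab) <- c("overlap_table", "data.frame")
  tab
}

#' Sex difference in fisheries overlap (binomial GLM)
#'
#' Logistic regression of the overlap flag on sex over all penguin-present
#' cell-month rows of one fishery; the reported statistic is the
#' likelihood-ratio chi-square for sex (equivalent to the 2x2
#' G-statistic).
#'
#' @param table an `overlap_table`, already restricted to one fishery.
#' @return list: `statistic` (LR chi-square), `df` (residual df,
#'   rows - 2), `p_value`, per-sex overlap `proportions`, `separation`
#'   flag.
#' @export
sex_overlap_test <- function(table) {
  stopifnot(length(unique(table$fishery)) == 1,
            length(unique(table$sex)) == 2)
  d <- data.frame(y = table$overlap_flag, sex = factor(table$sex))
  fit <- stats::glm(y ~ sex, family = stats::binomial(), data = d)
  null <- stats::glm(y ~ 1, family = stats::binomial(), data = d)
  lr <- as.numeric(null$deviance - fit$deviance)
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  props <- tapply(d$y, d$sex, mean)
  list(statistic = lr, df = nrow(d) - 2L, p_value = p,
       proportions = props,
       separation = any(props %in% c(0, 1)))
}

#' Sex difference in interaction scores (Gaussian GLM)
#'
#' Linear model `interaction ~ sex` over the overlapping rows
#' (score > 0) of one fishery; reports the ANOVA F test.
#'
#' @param table an `overlap_table` for one fishery.
#' @return list: `statistic` (F), `df` (c(1, residual)), `p_value`,
#'   per-sex `means`.
#' @export
sex_interaction_test <- function(table) {
  stopifnot(length(unique(table$fishery)) == 1)
  d <- table[table$score > 0, , drop = FALSE]
  if (length(unique(d$sex)) != 2)
    stop("both sexes must have overlapping rows")
  fit <- stats::lm(interaction ~ factor(sex), data = d)
  a <- stats::anova(fit)
  list(statistic = a$`F value`[1], df = c(a$Df[1], a$Df[2]),
       p_value = a$`Pr(>F)`[1],
       means = tapply(d$interaction, d$sex, mean))
}

#' Last-month subset of a path
#'
#' Positions within the 30 days before (and including) the blood-sampling
#' date, matching the ~30-day isotopic turnover of penguin whole blood.
#'
#' @param path a `path_estimate` (or data.frame with `date`).
#' @param blood_date Date of blood collection.
#' @param window_days window length before `blood_date` (default 30).
#' @return the subset of `path`; empty subsets are an error.
#' @export
last_month_subset <- function(path, blood_date, window_days = 30) {
  bd <- as.Date(blood_date)
  dts <- as.Date(path$date)
  if (bd < min(dts)) stop("blood date precedes the path")
  keep <- dts >= bd - window_days & dts <= bd
  if (!any(keep)) stop("no positions within the last-month window")
  path[keep, , drop = FALSE]
}
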