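# Per-individual track summaries and sex comparisons with unequal group
# variances (the varIdent-style models of the original analysis).

#' Published deployment summary (winter 2017, Martillo Island)
#'
#' The nine successfully recovered geolocator datasets: tag id, sex,
#' departure and arrival dates (DD/MM/YYYY in the source; stored here as
#' Date), published trip duration (days) and latitudinal range (km).
#'
#' @return data.frame with columns `id`, `sex`, `departure_date`,
#'   `arrival_date`, `trip_duration_days`, `latitudinal_range_km`.
#' @export
martillo_deployments <- function() {
  df <- data.frame(
    id = c("3482", "3488", "3494", "3509", "3514",
           "3497", "3499", "3503", "3510"),
    sex = rep(c("female", "male"), c(5, 4)),
    departure = c("16/03/2017", "16/03/2017", "22/03/2017", "03/04/2017",
                  "29/03/2017", "31/03/2017", "29/03/2017", "29/03/2017",
                  "31/03/2017"),
    arrival = c("18/09/2017", "25/09/2017", "02/10/2017", "21/09/2017",
                "21/09/2017", "20/09/2017", "16/09/2017", "23/09/2017",
                "14/09/2017"),
    trip_duration_days = c(187, 194, 195, 172, 177, 174, 172, 179, 168),
    latitudinal_range_km = c(578.3, 1514.9, 1486.5, 1407.9, 1385.4,
                             1327.7, 1588.3, 1672.5, 1303.5))
  df$departure_date <- parse_dmy(df$departure)
  df$arrival_date <- parse_dmy(df$arrival)
  df[, c("id", "sex", "departure_date", "arrival_date",
         "trip_duration_days", "latitudinal_range_km")]
}

#' Parse DD/MM/YYYY dates
#'
#' @param x character vector of dates in day/month/year order.
#' @return Date vector; malformed entries raise an error naming the entry.
#' @export
parse_dmy <- function(x) {
  d <- as.Date(x, format = "%d/%m/%Y")
  if (any(is.na(d) & !is.na(x)))
    stop("malformed DD/MM/YYYY date: ", x[which(is.na(d) & !is.na(x))[1]])
  d
}

#' Latitudinal range of a path
#'
#' Great-circle (haversine, radius 6378137 m) distance between the
#' northernmost and southernmost points of the path (ties broken by the
#' earliest date). The two extreme points may differ in longitude; the
#' distance is between the full coordinates, matching the straight-line
#' `distm` convention.
#'
#' @param path a `path_estimate` (or any data.frame with `date`, `lat`,
#'   `lon`).
#' @return list with `range_km`, `northernmost` and `southernmost` rows.
#' @export
latitudinal_range <- function(path) {
  if (is.null(path) || nrow(path) == 0) stop("empty path")
  stopifnot(nrow(path) >= 2)
  o <- order(as.Date(path$date))
  path <- path[o, , drop = FALSE]
  i_n <- which(path$lat == max(path$lat))[1]
  i_s <- which(path$lat == min(path$lat))[1]
  list(range_km = gc_dist_km(path$lat[i_n], path$lon[i_n],
                             path$lat[i_s], path$lon[i_s]),
       northernmost = path[i_n, c("date", "lat", "lon")],
       southernmost = path[i_s, c("date", "lat", "lon")])
}

#' Trip duration in days (inclusive)
#'
#' `(arrival - departure) + 1`: both the departure and the arrival day
#' count, the convention that reproduces all nine published durations.
#'
#' @param departure_date,arrival_date Dates (or coercible).
#' @return integer days, >= 1.
#' @export
trip_duration <- function(departure_date, arrival_date) {
  d <- as.Date(departure_date); a <- as.Date(arrival_date)
  if (any(a < d)) stop("arrival precedes departure")
  as.integer(a - d) + 1L
}

#' Per-sex mean and sample SD
#'
#' @param values numeric vector.
#' @param sexes grouping vector (same length).
#' @return data.frame with `sex`, `n`, `mean`, `sd` (n-1 denominator; `sd`
#'   is `NA` and flagged when n = 1).
#' @export
summarize_by_sex <- function(values, sexes) {
  stopifnot(length(values) == length(sexes), length(values) >= 1)
  out <- do.call(rbind, lapply(split(values, sexes), function(v) {
    data.frame(n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }))
  out$sex <- rownames(out)
  out$single_value <- out$n == 1
  rownames(out) <- NULL
  out[, c("sex", "n", "mean", "sd", "single_value")]
}

#' Recapture rate as a printed percentage
#'
#' @param n_recaptured,n_deployed counts.
#' @return percentage rounded to the nearest integer.
#' @export
recapture_rate <- function(n_recaptured, n_deployed) {
  stopifnot(n_deployed > 0, n_recaptured >= 0, n_recaptured <= n_deployed)
  round(100 * n_recaptured / n_deployed)
}

#' Two-group comparison with unequal variances
#'
#' Linear model with a separate residual variance per group, i.e. the
#' Welch unequal-variance comparison: `F = t^2` with Satterthwaite
#' denominator degrees of freedom. This is the closed form of the
#' two-group varIdent-style generalized least squares fit.
#'
#' @param values numeric response.
#' @param groups two-level grouping vector.
#' @return list of class `group_comparison`: `statistic` (F), `t`, `df`
#'   (fractional Satterthwaite), `p_value`, `estimate` (difference of
#'   means, group 2 - group 1), per-group `means`, `sds`, `ns`, and
#'   `variance_ratio`.
#' @export
heteroscedastic_group_test <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2) stop("exactly two groups required")
  v <- split(values, g)
  n <- vapply(v, length, integer(1))
  if (any(n < 2)) stop("each group needs n >= 2")
  m <- vapply(v, mean, numeric(1))
  s2 <- vapply(v, stats::var, numeric(1))
  se2 <- s2 / n
  if (sum(se2) == 0) {
    p <- if (m[1] == m[2]) 1 else 0
    out <- list(statistic = 0, t = 0, df = sum(n) - 2, p_value = p,
                estimate = unname(m[2] - m[1]), means = m, sds = sqrt(s2),
                ns = n, variance_ratio = NA_real_)
    class(out) <- "group_comparison"
    return(out)
  }
  tt <- (m[2] - m[1]) / sqrt(sum(se2))
  df <- sum(se2)^2 / sum(se2^2 / (n - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  out <- list(statistic = unname(tt^2), t = unname(tt), df = unname(df),
              p_value = unname(p), estimate = unname(m[2] - m[1]),
              means = m, sds = sqrt(s2), ns = n,
              variance_ratio = unname(max(s2) / max(min(s2), 1e-300)))
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("F = %.4g (t = %.4g), df = %.2f, p = %.4g\n",
              x$statistic, x$t, x$df, x$p_value))
  cat(sprintf("  means: %s\n",
              paste(sprintf("%s %.3g +/- %.3g (n=%d)", names(x$means),
                            x$means, x$sds, x$ns), collapse = ", ")))
  invisible(x)
}

#' Random-intercept model for daily maximum dive depth
#'
#' Gaussian mixed model `depth ~ sex + (1 | individual)` with a separate
#' residual variance per sex (varIdent-style), fitted by maximum
#' likelihood via nlme. Returns the sex fixed effect with its Wald
#' confidence interval; a (near-)singular random-intercept variance is
#' reported, not fatal.
#'
#' @param depths daily maximum depths (m).
#' @param ids individual identifiers.
#' @param sexes per-observation sex labels (2 levels).
#' @param conf_level confidence level (default 0.95).
#' @return list: `estimate` (sex effect, second level minus first), `se`,
#'   `t`, `df`, `p_value`, `ci`, `group_means`, `random_intercept_sd`,
#'   `residual_sds` (per sex), `singular` flag, and the fitted `model`.
#' @export
random_intercept_depth_model <- function(depths, ids, sexes,
                                         conf_level = 0.95) {
  df <- data.frame(depth = depths, id = factor(ids), sex = factor(sexes))
  df <- df[stats::complete.cases(df), ]
  if (nlevels(df$sex) != 2) stop("exactly two sexes required")
  tab <- table(unique(df[, c("id", "sex")])$sex)
  if (any(tab < 2)) stop("need >= 2 individuals per sex")
  fit <- nlme::lme(depth ~ sex, random = ~ 1 | id,
                   weights = nlme::varIdent(form = ~ 1 | sex),
                   data = df, method = "ML",
                   control = nlme::lmeControl(opt = "optim",
                                              returnObject = TRUE))
  tt <- summary(fit)$tTable
  est <- tt[2, "Value"]; se <- tt[2, "Std.Error"]
  dfree <- tt[2, "DF"]
  z <- stats::qt(1 - (1 - conf_level) / 2, dfree)
  ri_sd <- sqrt(as.numeric(nlme::getVarCov(fit)[1, 1]))
  sig <- fit$sigma
  vw <- nlme::varWeights(fit$modelStruct$varStruct)
  res_sds <- tapply(sig / vw, df$sex, function(x) x[1])
  list(estimate = unname(est), se = unname(se), t = unname(tt[2, "t-value"]),
       df = unname(dfree), p_value = unname(tt[2, "p-value"]),
       ci = c(est - z * se, est + z * se),
       group_means = tapply(df$depth, df$sex, mean),
       random_intercept_sd = ri_sd,
       residual_sds = res_sds,
       singular = ri_sd < 1e-4 * stats::sd(df$depth),
       model = fit)
}
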