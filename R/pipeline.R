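# End-to-end orchestration and the CSV/GeoJSON adapters shared by all
# stages. All dates are written ISO-8601; every writer/reader pair round
# trips up to float formatting.

.write_csv <- function(df, path) {
  df2 <- df
  for (nm in names(df2)) {
    if (inherits(df2[[nm]], "Date")) df2[[nm]] <- format(df2[[nm]], "%Y-%m-%d")
    if (is.numeric(df2[[nm]])) df2[[nm]] <- formatC(df2[[nm]], digits = 12,
                                                    format = "g")
  }
  utils::write.csv(df2, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
}

.parse_iso_dates <- function(x, what) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x))
  if (length(bad))
    stop("malformed ISO date in ", what, " at row ", bad[1], ": ", x[bad[1]])
  d
}

#' Tag-record CSV adapters
#'
#' Columns: `id, date, sunrise_utc, sunset_utc, min_sst_c, max_depth_m,
#' wet_fraction, missing`; dates ISO-8601, times decimal UTC hours.
#'
#' @param records a `tag_records` data.frame.
#' @param path CSV path.
#' @export
write_tag_records <- function(records, path) .write_csv(records, path)

#' @rdname write_tag_records
#' @export
read_tag_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("id", "date", "sunrise_utc", "sunset_utc",
                      "min_sst_c", "max_depth_m", "wet_fraction"),
                "tag-record CSV")
  df$date <- .parse_iso_dates(df$date, "tag-record CSV")
  if (is.null(df$missing)) df$missing <- is.na(df$sunrise_utc)
  df$missing <- as.logical(df$missing)
  bad <- which(df$wet_fraction < 0 | df$wet_fraction > 1)
  if (length(bad)) stop("wet_fraction outside [0,1] at row ", bad[1])
  class(df) <- c("tag_records", "data.frame")
  df
}

#' Fishing-effort CSV adapters
#'
#' Columns: `fishery, month, lat_min, lon_min, hours` (month "YYYY-MM").
#' Negative hours are rejected with the offending row.
#'
#' @param effort an `effort_df`.
#' @param path CSV path.
#' @export
write_effort <- function(effort, path) .write_csv(effort, path)

#' @rdname write_effort
#' @export
read_effort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("fishery", "month", "lat_min", "lon_min", "hours"),
                "effort CSV")
  bad <- which(df$hours < 0)
  if (length(bad)) stop("negative hours in effort CSV at row ", bad[1])
  class(df) <- c("effort_df", "data.frame")
  df
}

#' Isotope sample CSV adapters
#'
#' Columns: `id, sex, d13C, d15N, C_N, year` (truth columns passed
#' through when present).
#'
#' @param samples an `isotope_samples` data.frame.
#' @param path CSV path.
#' @export
write_isotopes <- function(samples, path) .write_csv(samples, path)

#' @rdname write_isotopes
#' @export
read_isotopes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("id", "sex", "d13C", "d15N", "C_N", "year"),
                "isotope CSV")
  bad <- which(!is.finite(df$d13C) | !is.finite(df$d15N))
  if (length(bad)) stop("non-finite isotope value at row ", bad[1])
  class(df) <- c("isotope_samples", "data.frame")
  df
}

#' Path-estimate CSV adapters
#'
#' Columns: `id, date, lat, lon, dispersion_km`.
#'
#' @param path_est a `path_estimate`.
#' @param path CSV path.
#' @export
write_path_estimate <- function(path_est, path) .write_csv(path_est, path)

#' @rdname write_path_estimate
#' @export
read_path_estimate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("id", "date", "lat", "lon"), "path CSV")
  df$date <- .parse_iso_dates(df$date, "path CSV")
  class(df) <- c("path_estimate", "data.frame")
  df
}

#' Write overlap table CSV
#'
#' @param table an `overlap_table`.
#' @param path CSV path.
#' @export
write_overlap_table <- function(table, path) .write_csv(table, path)

#' @rdname write_overlap_table
#' @export
read_overlap_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("sex", "month", "lat_min", "lon_min", "fishery",
                      "density", "score", "overlap_flag", "interaction"),
                "overlap CSV")
  class(df) <- c("overlap_table", "data.frame")
  df
}

#' Write analysis-grid cells as GeoJSON polygons
#'
#' One rectangular polygon feature per row of a density or overlap grid,
#' with the row's attributes as feature properties.
#'
#' @param grid_df data.frame with `lat_min`, `lon_min`.
#' @param cell_size cell size, degrees.
#' @param path output `.geojson` path.
#' @export
write_cells_geojson <- function(grid_df, cell_size, path) {
  feats <- lapply(seq_len(nrow(grid_df)), function(i) {
    y0 <- grid_df$lat_min[i]; x0 <- grid_df$lon_min[i]
    ring <- list(c(x0, y0), c(x0 + cell_size, y0),
                 c(x0 + cell_size, y0 + cell_size), c(x0, y0 + cell_size),
                 c(x0, y0))
    props <- as.list(grid_df[i, setdiff(names(grid_df),
                                        c("lat_min", "lon_min"))])
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param stages character subset of
#'   `c("simulate", "geolocate", "metrics", "overlap", "isotopes")`.
#' @param out_dir output directory (created if needed).
#' @param sim_config [simulation_config()] for the simulate stage.
#' @param geo_params [geolocation_params()].
#' @param spec [grid_spec()] for the overlap stage.
#' @param iso_settings [mcmc_settings()] for the isotope stage.
#' @param records_path,effort_path,isotopes_path input CSVs used when the
#'   simulate stage is disabled.
#' @param rng_seed global seed, fanned out to stage-specific substreams.
#' @return list of class `pipeline_config`, validated fail-fast: every
#'   enabled stage must have its inputs (from an earlier stage or a file).
#' @export
pipeline_config <- function(stages = c("simulate", "geolocate", "metrics",
                                       "overlap", "isotopes"),
                            out_dir = tempfile("winterdisp_run_"),
                            sim_config = NULL, geo_params = NULL,
                            spec = grid_spec(),
                            iso_settings = mcmc_settings(3000, 1000, 2),
                            records_path = NULL, effort_path = NULL,
                            isotopes_path = NULL, rng_seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  rng_seed <- as.integer(rng_seed)
  if (is.null(sim_config)) sim_config <- simulation_config(rng_seed = rng_seed)
  if (is.null(geo_params))
    geo_params <- geolocation_params(n_particles = 500, n_iterations = 20,
                                     rng_seed = rng_seed + 11L)
  simulate_on <- "simulate" %in% stages
  need_file <- function(path, stage, what) {
    if (!simulate_on && stage %in% stages) {
      if (is.null(path) || !file.exists(path))
        stop("stage '", stage, "' enabled but ", what,
             " input is missing: ", if (is.null(path)) "<unset>" else path)
    }
  }
  need_file(records_path, "geolocate", "tag-record")
  need_file(effort_path, "overlap", "fishing-effort")
  need_file(isotopes_path, "isotopes", "isotope-sample")
  structure(list(stages = stages, out_dir = out_dir,
                 sim_config = sim_config, geo_params = geo_params,
                 spec = spec, iso_settings = iso_settings,
                 records_path = records_path, effort_path = effort_path,
                 isotopes_path = isotopes_path, rng_seed = rng_seed),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order (simulate ->
#' geolocate -> metrics / overlap / isotopes), writing each stage's
#' outputs as CSV under `config$out_dir` and recording a manifest row
#' (stage, status, outputs, MD5 checksums, substream seed) per stage. A
#' stage failure halts downstream stages and is recorded. Identical
#' config + seed reproduces identical checksums.
#'
#' @param config a [pipeline_config()].
#' @return list: `manifest` (data.frame), `outputs` (named paths) and the
#'   in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(stage = character(), status = character(),
                         outputs = character(), checksum = character(),
                         seed = integer())
  results <- list()
  outputs <- character()
  failed <- FALSE
  add_row <- function(stage, status, files, seed) {
    chk <- if (length(files)) paste(unname(tools::md5sum(files)),
                                    collapse = ";") else ""
    manifest <<- rbind(manifest, data.frame(
      stage = stage, status = status,
      outputs = paste(files, collapse = ";"), checksum = chk, seed = seed))
  }
  run_stage <- function(stage, seed, fn) {
    if (!(stage %in% config$stages) || failed) {
      if (stage %in% config$stages && failed)
        add_row(stage, "skipped_after_failure", character(), seed)
      return(invisible(NULL))
    }
    res <- tryCatch(fn(seed), error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- TRUE
      add_row(stage, paste0("failed: ", conditionMessage(res)),
              character(), seed)
    } else {
      results[[stage]] <<- res$value
      outputs <<- c(outputs, res$files)
      add_row(stage, "ok", res$files, seed)
    }
  }
  env <- list(sst = make_sst_field(), mask = make_land_mask())

  run_stage("simulate", config$rng_seed, function(seed) {
    sc <- config$sim_config
    sc$rng_seed <- seed
    tracks <- simulate_tracks(sc)
    recs <- do.call(rbind, lapply(tracks, simulate_tag_records,
                                  sst_field = env$sst, config = sc))
    effort <- simulate_fishing_effort(sc)
    iso <- simulate_blood_isotopes(sc)
    f1 <- file.path(config$out_dir, "tag_records.csv")
    f2 <- file.path(config$out_dir, "effort.csv")
    f3 <- file.path(config$out_dir, "isotopes.csv")
    f4 <- file.path(config$out_dir, "truth_tracks.csv")
    write_tag_records(recs, f1); write_effort(effort, f2)
    write_isotopes(iso, f3)
    truth <- do.call(rbind, lapply(tracks, function(tr)
      cbind(id = tr$individual_id, sex = tr$sex, tr$positions)))
    .write_csv(truth, f4)
    list(value = list(tracks = tracks, records = recs, effort = effort,
                      isotopes = iso, truth = truth),
         files = c(f1, f2, f3, f4))
  })

  run_stage("geolocate", config$rng_seed + 11L, function(seed) {
    recs <- if (!is.null(results$simulate)) results$simulate$records
            else read_tag_records(config$records_path)
    gp <- config$geo_params
    gp$rng_seed <- seed
    paths <- list()
    for (id in unique(recs$id)) {
      r <- recs[recs$id == id, , drop = FALSE]
      win <- detect_trip_window(r)
      r <- r[as.Date(r$date) >= win$departure_date &
               as.Date(r$date) <= win$arrival_date, , drop = FALSE]
      start <- list(lat = config$sim_config$colony_location[1],
                    lon = config$sim_config$colony_location[2])
      paths[[id]] <- estimate_path(r, env$sst, env$mask, gp,
                                   start_location = start)
    }
    all_paths <- do.call(rbind, paths)
    f <- file.path(config$out_dir, "paths.csv")
    write_path_estimate(all_paths, f)
    list(value = all_paths, files = f)
  })

  run_stage("metrics", config$rng_seed + 23L, function(seed) {
    paths <- results$geolocate
    if (is.null(paths)) stop("metrics requires the geolocate stage")
    recs <- results$simulate$records
    sex_of <- function(id) if (substr(id, 1, 1) == "F") "female" else "male"
    rows <- lapply(unique(paths$id), function(id) {
      p <- paths[paths$id == id, , drop = FALSE]
      lr <- latitudinal_range(p)
      data.frame(id = id, sex = sex_of(id),
                 departure_date = min(as.Date(p$date)),
                 arrival_date = max(as.Date(p$date)),
                 trip_duration_days = trip_duration(min(as.Date(p$date)),
                                                    max(as.Date(p$date))),
                 latitudinal_range_km = lr$range_km)
    })
    summ <- do.call(rbind, rows)
    f <- file.path(config$out_dir, "trip_summary.csv")
    .write_csv(summ, f)
    stats_out <- list(
      range_test = unclass(heteroscedastic_group_test(
        summ$latitudinal_range_km, summ$sex)[c("statistic", "df", "p_value")]),
      duration_test = unclass(heteroscedastic_group_test(
        summ$trip_duration_days, summ$sex)[c("statistic", "df", "p_value")]))
    if (!is.null(recs)) {
      d <- recs[!is.na(recs$max_depth_m), ]
      dm <- random_intercept_depth_model(
        d$max_depth_m, d$id,
        ifelse(substr(d$id, 1, 1) == "F", "female", "male"))
      stats_out$depth_model <- dm[c("estimate", "se", "p_value", "ci",
                                    "singular")]
    }
    f2 <- file.path(config$out_dir, "track_stats.json")
    jsonlite::write_json(stats_out, f2, auto_unbox = TRUE, digits = 10)
    list(value = list(summary = summ, stats = stats_out), files = c(f, f2))
  })

  run_stage("overlap", config$rng_seed + 37L, function(seed) {
    paths <- results$geolocate
    if (is.null(paths)) stop("overlap requires the geolocate stage")
    effort <- if (!is.null(results$simulate)) results$simulate$effort
              else read_effort(config$effort_path)
    pos <- paths
    pos$sex <- ifelse(substr(pos$id, 1, 1) == "F", "female", "male")
    dens <- normalize_density(grid_counts(pos, config$spec))
    eg <- regrid_effort(effort, config$spec)
    tab <- build_overlap_table(dens, eg)
    f <- file.path(config$out_dir, "overlap.csv")
    write_overlap_table(tab, f)
    f2 <- file.path(config$out_dir, "cells.geojson")
    write_cells_geojson(tab, config$spec$cell_size, f2)
    tests <- lapply(split(tab, tab$fishery), function(tt) {
      list(overlap = sex_overlap_test(tt)[c("statistic", "df", "p_value")],
           interaction = tryCatch(
             sex_interaction_test(tt)[c("statistic", "p_value")],
             error = function(e) list(error = conditionMessage(e))))
    })
    f3 <- file.path(config$out_dir, "overlap_tests.json")
    jsonlite::write_json(tests, f3, auto_unbox = TRUE, digits = 10)
    list(value = list(table = tab, tests = tests), files = c(f, f2, f3))
  })

  run_stage("isotopes", config$rng_seed + 53L, function(seed) {
    iso <- if (!is.null(results$simulate)) results$simulate$isotopes
           else read_isotopes(config$isotopes_path)
    bl <- default_baselines()
    fem <- iso[iso$sex == "female", ]; mal <- iso[iso$sex == "male", ]
    fit_f <- sea_from_samples(fem$d13C, fem$d15N, "female")
    fit_m <- sea_from_samples(mal$d13C, mal$d15N, "male")
    ov <- ellipse_overlap(fit_f, fit_m)
    seab_f <- sea_bayesian(fem$d13C, fem$d15N, seed = seed, label = "female")
    seab_m <- sea_bayesian(mal$d13C, mal$d15N, seed = seed + 1L,
                           label = "male")
    tp_f <- tp_two_baseline(fem$d15N, fem$d13C,
                            bl[bl$name == "southern_patagonia", ],
                            bl[bl$name == "bahia_franklin", ],
                            settings = config$iso_settings, seed = seed)
    tp_m <- tp_one_baseline(mal$d15N, bl[bl$name == "northern_patagonia", ],
                            settings = config$iso_settings, seed = seed + 1L)
    report <- list(
      sea_c = c(female = fit_f$sea_c, male = fit_m$sea_c),
      overlap = ov[c("joint_pct", "pct_of_a", "pct_of_b")],
      p_male_niche_smaller = sea_b_smaller(seab_m, seab_f),
      tp_female = tp_f[c("tp_mean", "tp_sd", "tp_ci", "converged")],
      tp_male = tp_m[c("tp_mean", "tp_sd", "tp_ci", "converged")],
      p_tp_male_gt_female = compare_posteriors(tp_m$draws$tp,
                                               tp_f$draws$tp, seed = seed))
    f <- file.path(config$out_dir, "isotope_report.json")
    jsonlite::write_json(report, f, auto_unbox = TRUE, digits = 10)
    f2 <- file.path(config$out_dir, "tp_draws.csv")
    .write_csv(data.frame(sex = rep(c("female", "male"),
                                    c(nrow(tp_f$draws), nrow(tp_m$draws))),
                          tp = c(tp_f$draws$tp, tp_m$draws$tp)), f2)
    list(value = list(report = report, tp_female = tp_f, tp_male = tp_m),
         files = c(f, f2))
  })

  list(manifest = manifest, outputs = outputs, results = results)
}
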