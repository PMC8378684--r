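test_that("daily fixes land in exactly one half-open cell", {
  spec <- grid_spec()
  one <- data.frame(date = as.Date("2017-05-10"), lat = -49, lon = -64,
                    sex = "female")
  g <- grid_counts(one, spec)
  expect_equal(nrow(g), 1)
  expect_equal(g$lat_min, -50)
  expect_equal(g$lon_min, -64)   # on-edge fix belongs to its lower edge
  expect_equal(g$count, 1L)
  edge <- data.frame(date = as.Date("2017-05-10"), lat = -50, lon = -66,
                     sex = "male")
  ge <- grid_counts(edge, spec)
  expect_equal(c(ge$lat_min, ge$lon_min), c(-50, -66))
  # conservation over random fixes
  set.seed(3)
  n <- 500
  pos <- data.frame(date = sample(seq(as.Date("2017-04-01"),
                                      as.Date("2017-09-30"), by = "day"),
                                  n, replace = TRUE),
                    lat = runif(n, -59.9, -38.1), lon = runif(n, -69.9, -54.1),
                    sex = sample(c("female", "male"), n, replace = TRUE))
  g <- grid_counts(pos, spec)
  expect_equal(sum(g$count) + attr(g, "overflow"), n)
})

test_that("density normalization scales each sex-month layer to max 1", {
  counts <- data.frame(sex = "female", month = "2017-05",
                       lat_min = c(-50, -48, -46), lon_min = -64,
                       count = c(4, 2, 0))
  d <- normalize_density(counts)
  expect_equal(d$density, c(1, 0.5, 0))
  # property: every non-empty layer has max exactly 1
  set.seed(8)
  pos <- data.frame(date = sample(seq(as.Date("2017-04-01"),
                                      as.Date("2017-09-30"), by = "day"),
                                  300, replace = TRUE),
                    lat = runif(300, -56, -40), lon = runif(300, -68, -56),
                    sex = sample(c("female", "male"), 300, replace = TRUE))
  d <- normalize_density(grid_counts(pos, grid_spec()))
  mx <- tapply(d$density, interaction(d$sex, d$month, drop = TRUE), max)
  expect_true(all(abs(mx - 1) < 1e-12))
  expect_true(all(d$density >= 0 & d$density <= 1))
})

test_that("effort re-gridding sums nested cells and conserves hours", {
  fine <- expand.grid(lat_min = seq(-50, -48.5, by = 0.5),
                      lon_min = seq(-64, -62.5, by = 0.5))
  fine$fishery <- "trawl"; fine$month <- "2017-05"; fine$hours <- 10
  cg <- regrid_effort(fine, grid_spec())
  expect_equal(nrow(cg), 1)
  expect_equal(cg$hours, 160)
  expect_equal(cg$score, 2L)
  set.seed(5)
  cfg <- simulation_config(rng_seed = 5)
  eff <- simulate_fishing_effort(cfg)
  cg <- regrid_effort(eff, grid_spec())
  expect_equal(sum(cg$hours), sum(eff$hours))
  bad <- fine; bad$lat_min <- bad$lat_min + 0.2
  expect_error(regrid_effort(bad, grid_spec()), "misaligned")
})

test_that("effort scores reproduce the published bins", {
  expect_identical(effort_score(0), 0L)
  expect_identical(effort_score(100), 2L)
  expect_identical(effort_score(7000), 5L)
  expect_identical(effort_score(c(30, 60, 60.001, 200, 201, 800, 801, 6000,
                                  6000.1)),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L))
  expect_error(effort_score(-1), "negative")
})

test_that("overlap table applies the interaction formula and flags", {
  dens <- data.frame(sex = c("female", "female", "male"),
                     month = "2017-05", lat_min = c(-50, -48, -50),
                     lon_min = -64, count = c(2, 1, 3),
                     density = c(0.5, 1, 1))
  eff <- data.frame(fishery = c("trawl", "trawl"), month = "2017-05",
                    lat_min = c(-50, -48), lon_min = -64,
                    hours = c(900, 0), score = c(4L, 0L))
  tab <- build_overlap_table(dens, eff)
  r1 <- tab[tab$sex == "female" & tab$lat_min == -50, ]
  expect_equal(r1$interaction, 2.0)
  expect_equal(r1$overlap_flag, 1L)
  r2 <- tab[tab$sex == "female" & tab$lat_min == -48, ]
  expect_equal(r2$interaction, 0)
  expect_equal(r2$overlap_flag, 0L)
  r3 <- tab[tab$sex == "male", ]
  expect_equal(r3$interaction, 4.0)
  # maximum attainable interaction is 5 (density 1 x score 5)
  eff5 <- eff; eff5$score[1] <- 5L
  tab5 <- build_overlap_table(dens, eff5)
  expect_equal(max(tab5$interaction), 5.0)
  expect_true(all(tab5$interaction >= 0 & tab5$interaction <= 5))
  expect_true(all((tab5$overlap_flag == 1) == (tab5$score > 0)))
})

test_that("fisheries are analysed separately end to end", {
  cfg <- simulation_config(rng_seed = 17)
  eff <- simulate_fishing_effort(cfg)
  set.seed(2)
  pos <- data.frame(date = sample(seq(as.Date("2017-04-01"),
                                      as.Date("2017-09-30"), by = "day"),
                                  400, replace = TRUE),
                    lat = runif(400, -56, -40), lon = runif(400, -68, -58),
                    sex = sample(c("female", "male"), 400, replace = TRUE))
  dens <- normalize_density(grid_counts(pos, grid_spec()))
  tab <- build_overlap_table(dens, regrid_effort(eff, grid_spec()))
  expect_setequal(unique(tab$fishery), c("trawl", "shrimp"))
  per_fishery <- split(tab, tab$fishery)
  expect_equal(nrow(per_fishery$trawl), nrow(dens[dens$density > 0, ]))
  expect_true(all(tab$interaction >= 0 & tab$interaction <= 5))
})

test_that("binomial sex-overlap test matches the 2x2 G-statistic", {
  set.seed(9)
  tab <- data.frame(fishery = "trawl",
                    sex = rep(c("female", "male"), c(60, 45)),
                    overlap_flag = c(rbinom(60, 1, 0.55), rbinom(45, 1, 0.4)))
  res <- sex_overlap_test(tab)
  expect_equal(res$statistic, g_statistic(tab$overlap_flag, tab$sex),
               tolerance = 1e-8)
  expect_equal(res$df, nrow(tab) - 2L)
  # null: identical proportions
  null_tab <- data.frame(fishery = "trawl",
                         sex = rep(c("female", "male"), each = 40),
                         overlap_flag = rep(c(0, 1), 40))
  res0 <- sex_overlap_test(null_tab)
  expect_lt(res0$statistic, 1e-8)
  expect_gt(res0$p_value, 0.999)
  # complete separation
  sep <- data.frame(fishery = "trawl",
                    sex = rep(c("female", "male"), each = 30),
                    overlap_flag = rep(c(1, 0), each = 30))
  ress <- sex_overlap_test(sep)
  expect_lt(ress$p_value, 1e-6)
  expect_true(ress$separation)
})

test_that("Gaussian interaction test equals the pooled-variance F", {
  set.seed(10)
  tab <- data.frame(fishery = "trawl",
                    sex = rep(c("female", "male"), c(25, 30)),
                    score = 1L,
                    interaction = c(rnorm(25, 1.2, 0.5), rnorm(30, 1.5, 0.5)))
  res <- sex_interaction_test(tab)
  # pooled-variance t from first principles
  a <- tab$interaction[tab$sex == "female"]
  b <- tab$interaction[tab$sex == "male"]
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  tt <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(res$statistic, tt^2, tolerance = 1e-10)
  same <- data.frame(fishery = "trawl",
                     sex = rep(c("female", "male"), each = 24),
                     score = 1L,
                     interaction = rep(rep(c(1, 2, 3), 8), 2))
  res0 <- sex_interaction_test(same)
  expect_lt(res0$statistic, 1e-20)
  expect_gt(res0$p_value, 0.999)
})

test_that("last-month subsetting keeps the 31-day inclusive window", {
  path <- data.frame(date = seq(as.Date("2017-04-01"), by = "day",
                                length.out = 180),
                     lat = -50, lon = -64)
  blood <- max(path$date)
  sub <- last_month_subset(path, blood)
  expect_equal(nrow(sub), 31)
  expect_equal(sub$date, path$date[path$date >= blood - 30 &
                                     path$date <= blood])
  expect_error(last_month_subset(path, as.Date("2017-03-01")), "precedes")
})
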