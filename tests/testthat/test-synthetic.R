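test_that("invalid configurations are rejected naming the field", {
  expect_error(sim_config(p_migrant = 1.2), "p_migrant")
  expect_error(sim_config(years = integer(0)), "years")
  expect_error(sim_config(areas = "one"), "exactly two")
  expect_error(sim_config(isotope = list(sd = -1)), "isotope\\$sd")
  expect_error(sim_config(clutch = list(nu = 0)), "clutch\\$nu")
  expect_error(sim_config(detection = list(p_capture = 2)),
               "detection\\$p_capture")
})

test_that("the generator is deterministic given config and seed", {
  cfg <- sim_config(n_individuals = 40, years = 2015:2016, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  for (tab in c("captures", "resightings", "fixes", "feathers", "nests",
                "chicks")) {
    expect_identical(a[[tab]], b[[tab]], label = tab)
  }
  expect_identical(a$truth$bird_years, b$truth$bird_years)
})

test_that("degenerate migrant probability yields an all-resident cohort", {
  co <- generate_cohort(sim_config(n_individuals = 50, years = 2015:2016,
                                   p_migrant = 0, p_switch = 0, seed = 2))
  expect_true(all(co$truth$bird_years$strategy == "resident"))
  expect_true(all(co$fixes$latitude > 36))
  expect_false(any(co$resightings$wintering_ground))
})

test_that("migrant feather enrichment matches the normal-tail oracle", {
  co <- generate_cohort(sim_config(
    n_individuals = 1500, years = 2016,
    p_migrant = 1, isotope = list(p_premoult = 0),
    detection = list(p_feather = 1, p_capture = 0, p_geolocator = 0,
                     p_winter_resight = 0),
    phenology = list(p_nest = 0), seed = 31))
  frac <- mean(co$feathers$d13c > -20)
  oracle <- 1 - pnorm((-20 + 16.5) / 1.2)   # P(N(-16.5, 1.2) > -20)
  expect_equal(frac, oracle, tolerance = 0.01)
  expect_gt(oracle, 0.99)
})

test_that("truth strategy frequency sits inside binomial bounds", {
  cfg <- sim_config(seed = 17)      # 100 individuals x 5 years
  co <- generate_cohort(cfg)
  by <- co$truth$bird_years
  expect_gte(nrow(by), 500)
  # individual-level initial draw is the Bernoulli(p_migrant) one
  first <- by[by$year == min(by$year), ]
  n <- nrow(first)
  phat <- mean(first$strategy == "migrant")
  half <- qnorm(0.995) * sqrt(0.7 * 0.3 / n)
  expect_gte(phat, 0.7 - half)
  expect_lte(phat, 0.7 + half)
})

test_that("winter fix latitudes respect the classification thresholds", {
  co <- generate_cohort(sim_config(n_individuals = 200, years = 2015:2016,
                                   detection = list(p_geolocator = 0.5),
                                   seed = 23))
  fx <- co$fixes
  fx$year <- winter_breeding_year(as.Date(fx$datetime))
  win <- fx[!is.na(fx$year), ]
  truth <- co$truth$bird_years
  m <- dplyr::inner_join(win, truth, by = c("bird_id", "year"))
  res <- m[m$strategy == "resident", ]
  expect_true(all(res$latitude >= 36))
  mig_counts <- dplyr::count(m[m$strategy == "migrant" & m$latitude < 23, ],
                             bird_id, year)
  mig_tracked <- dplyr::distinct(m[m$strategy == "migrant", ],
                                 bird_id, year)
  expect_equal(nrow(mig_counts), nrow(mig_tracked))
  expect_true(all(mig_counts$n >= 2))
})

test_that("every observation row traces back to a truth row", {
  co <- generate_cohort(sim_config(n_individuals = 40, years = 2015:2016,
                                   seed = 4))
  by_key <- paste(co$truth$bird_years$bird_id, co$truth$bird_years$year)
  expect_true(all(paste(co$captures$bird_id, co$captures$year) %in% by_key))
  expect_true(all(co$feathers$bird_id %in% co$truth$individuals$bird_id))
  expect_true(all(co$fixes$bird_id %in% co$truth$individuals$bird_id))
  expect_true(all(co$nests$nest_id %in% co$truth$nests$nest_id))
  expect_true(all(co$chicks$nest_id %in% co$nests$nest_id))
})

test_that("condition series is built from its stated components", {
  base_cfg <- function(...) sim_config(
    n_individuals = 400, years = 2016,
    detection = list(p_capture = 1, capture_occasions = 2), seed = 77, ...)

  # null deficit: pre-incubation strategy means coincide up to noise
  cfg0 <- base_cfg(condition = list(
    migrant_deficit = c(Cadiz = 0, Seville = 0)))
  set.seed(cfg0$seed)
  by <- tidyr::expand_grid(
    tibble::tibble(bird_id = sprintf("B%04d", 1:400),
                   sex = sample(c("M", "F"), 400, replace = TRUE),
                   area = rep(cfg0$areas, each = 200),
                   cond_intercept = rnorm(400, 0, 0.05),
                   p8 = rnorm(400, 50, 1.5)),
    year = 2016L)
  by$strategy <- sample(c("migrant", "resident"), 400, replace = TRUE)
  by$age_class <- "adult"
  out0 <- generate_condition_series(cfg0, by)
  tr <- out0$truth
  pre <- tr[format(tr$date, "%m-%d") < "05-02", ]
  diff0 <- mean(pre$condition_true[pre$strategy == "migrant"]) -
    mean(pre$condition_true[pre$strategy == "resident"])
  pooled_se <- sqrt(var(pre$condition_true) * 4 / nrow(pre))
  expect_lt(abs(diff0), 3 * pooled_se)

  # sex offset shows up as the male/female mean difference
  s <- 0.08
  sex_diff <- mean(tr$condition_true[tr$sex == "F"]) -
    mean(tr$condition_true[tr$sex == "M"])
  expect_lt(abs(sex_diff - s), 0.02)

  # fully degenerate settings collapse to the baseline constant
  cfgc <- sim_config(
    n_individuals = 20, years = 2016,
    detection = list(p_capture = 1, capture_occasions = 2),
    condition = list(amplitude = 0, sex_offset = 0, area_offset = 0,
                     individual_sd = 0, residual_sd = 1e-12,
                     migrant_deficit = c(Cadiz = 0, Seville = 0)),
    seed = 5)
  coc <- generate_cohort(cfgc)
  expect_equal(raw_condition(coc$captures$mass, coc$captures$p8),
               rep(2.9, nrow(coc$captures)), tolerance = 1e-6)
})
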