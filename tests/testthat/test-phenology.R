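test_that("first-egg back-calculation is exactly 32 days", {
  expect_equal(first_egg_from_hatch(as.Date("2016-05-20")),
               as.Date("2016-04-18"))
  expect_equal(first_egg_from_hatch(as.Date("2015-03-04")),
               as.Date("2015-01-31"))  # crosses the February boundary
  # round trip is the identity on arbitrary dates
  set.seed(1)
  d <- as.Date("2014-01-01") + sample.int(2000, 50)
  expect_equal(first_egg_from_hatch(d) + 32L, d)
})

test_that("wing growth fits exactly on noiseless linear data", {
  chicks <- tidyr::expand_grid(nest_id = c("n1", "n2", "n3"),
                               known_age = 14:30) |>
    dplyr::mutate(wing = 5 * known_age - 10)
  suppressWarnings(m <- fit_wing_growth(chicks))
  expect_equal(m$slope, 5, tolerance = 1e-8)
  expect_equal(m$intercept, -10, tolerance = 1e-6)
  expect_gt(m$r2_marginal, 0.999)
})

test_that("wing growth recovers simulated truth at study scale", {
  set.seed(14)
  n_nests <- 32
  re <- rnorm(n_nests, 0, 3)
  chicks <- tibble::tibble(
    nest_id = rep(sprintf("n%02d", 1:n_nests), each = 3),
    known_age = sample(14:30, n_nests * 3, replace = TRUE))
  chicks$wing <- -10 + 5 * chicks$known_age +
    re[as.integer(factor(chicks$nest_id))] + rnorm(nrow(chicks), 0, 4)
  m <- fit_wing_growth(chicks)
  slope_se <- summary(m$fit)$coefficients["known_age", "Std. Error"]
  expect_lt(abs(m$slope - 5), 2 * slope_se)
  expect_gt(m$r2_marginal, 0.7)
  # age estimates from the fitted model are nearly unbiased
  test_chicks <- tibble::tibble(
    nest_id = "new", known_age = sample(14:30, 96, replace = TRUE))
  test_chicks$wing <- -10 + 5 * test_chicks$known_age +
    rnorm(96, 0, 4)
  test_chicks$date <- as.Date("2018-06-01")
  est <- suppressWarnings(estimate_hatch_from_wing(test_chicks, m))
  expect_lt(abs(mean(est$age_est - test_chicks$known_age)), 0.5)
})

test_that("out-of-window ages are excluded and degenerate inputs fail", {
  chicks <- tidyr::expand_grid(nest_id = c("n1", "n2"), known_age = 10:33) |>
    dplyr::mutate(wing = 5 * known_age - 10)
  expect_message(suppressWarnings(m <- fit_wing_growth(chicks)),
                 "outside the 14-30")
  expect_equal(m$n, 2 * 17)

  one_nest <- tibble::tibble(nest_id = "n1", known_age = 14:30,
                             wing = 5 * (14:30) - 10 + rnorm(17, 0, 1))
  expect_warning(m1 <- fit_wing_growth(one_nest), "single nest")
  expect_equal(m1$nest_sd, 0)

  same_age <- tibble::tibble(nest_id = rep(c("n1", "n2"), each = 6),
                             known_age = 20, wing = rnorm(12, 90, 2))
  expect_error(fit_wing_growth(same_age), "unidentifiable")
})

test_that("wing inversion composes with the 32-day rule", {
  m <- structure(list(intercept = -10, slope = 5, age_window = c(14, 30)),
                 class = "wing_growth_model")
  chick <- tibble::tibble(wing = 90, date = as.Date("2016-06-01"))
  est <- estimate_hatch_from_wing(chick, m)
  expect_equal(est$age_est, 20)
  expect_false(est$extrapolated)
  expect_equal(est$hatch_date, as.Date("2016-05-12"))
  expect_equal(est$first_egg_date, as.Date("2016-04-10"))
  # age outside the linear window is flagged
  old <- tibble::tibble(wing = -10 + 5 * 35, date = as.Date("2016-06-01"))
  expect_warning(e2 <- estimate_hatch_from_wing(old, m), "extrapolated")
  expect_true(e2$extrapolated)
  # non-positive slope refused
  m$slope <- -1
  expect_error(estimate_hatch_from_wing(chick, m), "refusing")
})

test_that("nest outcome uses a strict 20-day threshold", {
  chicks <- tibble::tibble(
    nest_id = c("n1", "n1", "n2", "n2", "n3"),
    age_last_seen = c(22, 5, 18, 20, 21))
  oc <- nest_outcome(chicks)
  expect_equal(oc$outcome[oc$nest_id == "n1"], "success")
  expect_equal(oc$n_fledglings[oc$nest_id == "n1"], 1L)
  expect_equal(oc$outcome[oc$nest_id == "n2"], "failure")  # 20 d not counted
  expect_equal(oc$n_fledglings[oc$nest_id == "n2"], 0L)
  expect_equal(oc$outcome[oc$nest_id == "n3"], "success")
})

test_that("brood condition averages mass/P8 over siblings", {
  chicks <- tibble::tibble(nest_id = c("n1", "n1", "n2"),
                           mass = c(132, 120, 146.6),
                           p8 = c(45, 48, 50))
  bc <- brood_condition(chicks)
  expect_equal(bc$chick_condition[bc$nest_id == "n1"],
               (132 / 45 + 120 / 48) / 2, tolerance = 1e-6)
  expect_equal(bc$chick_condition[bc$nest_id == "n2"], 2.932)
  # zero P8 rows are rejected; empty broods drop out
  bad <- tibble::tibble(nest_id = "n3", mass = 100, p8 = 0)
  expect_message(bc2 <- brood_condition(bad), "rejected")
  expect_equal(nrow(bc2), 0L)
})

test_that("phenology reconstruction records one provenance tag per nest", {
  co <- generate_cohort(sim_config(n_individuals = 60, years = 2015:2016,
                                   seed = 8))
  suppressWarnings(suppressMessages(
    nests <- reconstruct_phenology(co$nests, co$chicks)))
  expect_equal(nrow(nests), nrow(co$nests))
  expect_true(all(nests$provenance %in%
                    c("observed", "backcalc", "wing_estimated", "none")))
  expect_true(all(!is.na(nests$first_egg_date) |
                    nests$provenance == "none"))
  pc <- attr(nests, "provenance_counts")
  expect_equal(sum(pc), nrow(nests))
  # observed and back-calculated dates recover the truth exactly
  truth <- co$truth$nests
  cmp <- dplyr::inner_join(nests, truth, by = "nest_id") |>
    dplyr::filter(provenance %in% c("observed", "backcalc"))
  expect_true(all(cmp$first_egg_date == cmp$first_egg_true))
  # wing-estimated dates land close to the truth
  w <- dplyr::inner_join(nests, truth, by = "nest_id") |>
    dplyr::filter(provenance == "wing_estimated")
  if (nrow(w)) {
    expect_lt(mean(abs(as.numeric(w$first_egg_date - w$first_egg_true))), 4)
  }
  # outcome consistency: fledglings never exceed clutch size
  expect_true(all(nests$n_fledglings <= nests$clutch_size))
})
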