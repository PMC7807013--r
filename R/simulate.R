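#' Configuration for the synthetic partially migratory cohort
#'
#' Builds and validates the parameter set for [generate_cohort()]. The
#' defaults describe a two-area breeding population monitored over five
#' seasons: a productivity-rich area that breeds late and a poorer area that
#' breeds earlier, individuals holding a persistent (occasionally switching)
#' migrant or resident strategy, bimodal feather delta-13C with a pre-moult
#' contamination fraction among migrants, a seasonal sinusoid-plus-noise body
#' condition with sex, area and individual effects and an area-specific
#' pre-incubation migrant deficit, and underdispersed clutch sizes declining
#' with first-egg date.
#'
#' Sub-lists are merged over the defaults, so a single entry can be
#' overridden, e.g. `sim_config(isotope = list(p_premoult = 0))`.
#'
#' @param n_individuals number of individuals (each present in every year).
#' @param years breeding calendar years.
#' @param areas two breeding-area labels, richer area first.
#' @param area_probs assignment probabilities per area.
#' @param p_migrant probability an individual starts as a migrant.
#' @param p_switch per-year probability of switching strategy.
#' @param p_first_year probability an individual is a first-year (not adult)
#'   in its first season.
#' @param isotope `resident_mean`, `migrant_mean` (permil), common `sd`, and
#'   `p_premoult`: probability a migrant's sampled feather was grown before
#'   migration (so carries the resident signature).
#' @param detection detection/sampling probabilities: `p_winter_resight`
#'   (residents, per winter), `p_wintering_ground_sighting` (migrants),
#'   `p_geolocator` (per bird-year), `p_feather`, `p_capture` (per occasion),
#'   `capture_occasions`.
#' @param phenology `mean_doy` (named per area, first-egg day-of-year), `sd`
#'   (days), `p_nest` (fraction of adult female bird-years nesting),
#'   `p_obs_first_egg`, `p_obs_hatch`, `p_second_parent`, `p_hatch` (per-egg).
#' @param clutch Conway-Maxwell-Poisson clutch parameters: baseline `lambda`,
#'   dispersion `nu`, and `beta_date`, the slope of log-lambda on the scaled
#'   first-egg date.
#' @param chick wing-growth truth (`wing_intercept` mm, `wing_slope` mm/day,
#'   `nest_sd`, `resid_sd`), `p_fledge`, `p_known_age`, and chick-condition
#'   parameters (`cond_baseline` g/mm, `cond_area_offset`, `cond_sd`).
#' @param condition adult condition-model truth: `baseline` (g/mm), seasonal
#'   `amplitude`, `peak_doy`, `sex_offset` (added for females), `area_offset`
#'   (added in the richer area), `individual_sd`, `residual_sd`,
#'   `migrant_deficit` (named per area, subtracted from migrants before the
#'   cutoff), `deficit_cutoff` (`"MM-DD"`).
#' @param geolocator fix-generation parameters: winter latitude means/SDs per
#'   strategy and `n_fixes` per tracked winter.
#' @param effects strategy effects on breeding parameters (all zero by
#'   default, the null the field data supported): `fed_shift_migrant` (days),
#'   `clutch_loglambda_shift`, `fledge_logit_shift`, `chick_cond_shift`.
#' @param seed RNG seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_individuals = 100, years = 2014:2018,
                       areas = c("Cadiz", "Seville"),
                       area_probs = c(0.5, 0.5),
                       p_migrant = 0.7, p_switch = 0.1, p_first_year = 0.07,
                       isotope = list(), detection = list(),
                       phenology = list(), clutch = list(), chick = list(),
                       condition = list(), geolocator = list(),
                       effects = list(), seed = 1L) {
  cfg <- list(
    n_individuals = n_individuals, years = years, areas = areas,
    area_probs = area_probs, p_migrant = p_migrant, p_switch = p_switch,
    p_first_year = p_first_year,
    isotope = utils::modifyList(list(
      resident_mean = -23.5, migrant_mean = -16.5, sd = 1.2,
      p_premoult = 0.15), isotope),
    detection = utils::modifyList(list(
      p_winter_resight = 0.6, p_wintering_ground_sighting = 0.01,
      p_geolocator = 0.1, p_feather = 0.5, p_capture = 0.5,
      capture_occasions = 4L), detection),
    phenology = utils::modifyList(list(
      mean_doy = stats::setNames(c(118, 107), areas), sd = 10,
      p_nest = 0.7, p_obs_first_egg = 0.5, p_obs_hatch = 0.6,
      p_second_parent = 0.3, p_hatch = 0.92), phenology),
    clutch = utils::modifyList(list(
      lambda = 4.2, nu = 2.5, beta_date = -0.08), clutch),
    chick = utils::modifyList(list(
      wing_intercept = -10, wing_slope = 5, nest_sd = 3, resid_sd = 4,
      p_fledge = 0.75, p_known_age = 0.2,
      cond_baseline = 2.7, cond_area_offset = 0.05, cond_sd = 0.15), chick),
    condition = utils::modifyList(list(
      baseline = 2.9, amplitude = 0.15, peak_doy = 122, sex_offset = 0.08,
      area_offset = 0.05, individual_sd = 0.05, residual_sd = 0.08,
      migrant_deficit = stats::setNames(c(0, 0.10), areas),
      deficit_cutoff = "05-02"), condition),
    geolocator = utils::modifyList(list(
      resident_lat = 37.2, resident_sd = 0.3,
      migrant_lat = 14.5, migrant_sd = 1, n_fixes = 10L,
      breeding_lon = -5.5, winter_lon = -16), geolocator),
    effects = utils::modifyList(list(
      fed_shift_migrant = 0, clutch_loglambda_shift = 0,
      fledge_logit_shift = 0, chick_cond_shift = 0), effects),
    seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid sim_config: `", field, "` ", why, call. = FALSE)
  }
  chk_prob <- function(x, field) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
      fail(field, "must be a probability in [0, 1]")
    }
  }
  if (cfg$n_individuals < 1) fail("n_individuals", "must be >= 1")
  if (!length(cfg$years)) fail("years", "must be non-empty")
  if (length(cfg$areas) != 2L) fail("areas", "must name exactly two areas")
  if (length(cfg$area_probs) != 2L || abs(sum(cfg$area_probs) - 1) > 1e-8) {
    fail("area_probs", "must be two probabilities summing to 1")
  }
  chk_prob(cfg$p_migrant, "p_migrant")
  chk_prob(cfg$p_switch, "p_switch")
  chk_prob(cfg$p_first_year, "p_first_year")
  chk_prob(cfg$isotope$p_premoult, "isotope$p_premoult")
  if (cfg$isotope$sd <= 0) fail("isotope$sd", "must be > 0")
  for (p in c("p_winter_resight", "p_wintering_ground_sighting",
              "p_geolocator", "p_feather", "p_capture")) {
    chk_prob(cfg$detection[[p]], paste0("detection$", p))
  }
  if (cfg$phenology$sd <= 0) fail("phenology$sd", "must be > 0")
  if (!all(cfg$areas %in% names(cfg$phenology$mean_doy))) {
    fail("phenology$mean_doy", "must be named for both areas")
  }
  chk_prob(cfg$phenology$p_nest, "phenology$p_nest")
  if (cfg$clutch$nu <= 0) fail("clutch$nu", "must be > 0")
  if (cfg$clutch$lambda <= 0) fail("clutch$lambda", "must be > 0")
  if (cfg$condition$residual_sd <= 0) fail("condition$residual_sd",
                                           "must be > 0")
  if (cfg$condition$individual_sd < 0) fail("condition$individual_sd",
                                            "must be >= 0")
  if (!all(cfg$areas %in% names(cfg$condition$migrant_deficit))) {
    fail("condition$migrant_deficit", "must be named for both areas")
  }
  invisible(cfg)
}

winter_window_dates <- function(year) {
  c(start = as.Date(sprintf("%d-11-01", year - 1L)),
    end = as.Date(sprintf("%d-01-15", year)))
}

rdate_in_window <- function(n, year) {
  w <- winter_window_dates(year)
  w[["start"]] + sample.int(as.integer(w[["end"]] - w[["start"]]) + 1L, n,
                            replace = TRUE) - 1L
}

#' Generate a synthetic partially migratory cohort
#'
#' Draws a full observation set -- captures, winter resightings, geolocator
#' fixes, feather isotopes, nests and chick measurements -- together with the
#' ground truth that produced it. The generator is deterministic given the
#' config (which includes the seed). Key structural guarantees: residents
#' never receive wintering-ground resightings and none of their fixes fall
#' south of 36 degrees N in the winter window; every tracked migrant winter
#' has at least two fixes south of 23 degrees N; a migrant's feather carries
#' the Sahelian isotope signature with probability `1 - p_premoult`,
#' otherwise the breeding-ground signature (pre-moult contamination).
#'
#' @param config a [sim_config()].
#' @return a `partmig_cohort` list of tibbles: `captures`, `resightings`,
#'   `fixes`, `feathers`, `nests`, `chicks`, and `truth` (itself a list:
#'   `individuals`, `bird_years`, `nests`, `feathers`, `captures`, plus the
#'   config).
#' @export
generate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_individuals
  years <- sort(config$years)
  ny <- length(years)

  individuals <- tibble::tibble(
    bird_id = sprintf("B%04d", seq_len(n)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    area = sample(config$areas, n, replace = TRUE, prob = config$area_probs),
    cond_intercept = stats::rnorm(n, 0, config$condition$individual_sd),
    p8 = stats::rnorm(n, 50, 1.5),
    first_year_flag = stats::runif(n) < config$p_first_year
  )

  # persistent strategy with per-year switching (Markov chain over years)
  strat <- matrix("", n, ny)
  strat[, 1] <- ifelse(stats::runif(n) < config$p_migrant,
                       "migrant", "resident")
  if (ny > 1) for (t in 2:ny) {
    sw <- stats::runif(n) < config$p_switch
    strat[, t] <- ifelse(sw,
                         ifelse(strat[, t - 1] == "migrant",
                                "resident", "migrant"),
                         strat[, t - 1])
  }
  bird_years <- tidyr::expand_grid(bird_id = individuals$bird_id,
                                   year = years) |>
    dplyr::left_join(individuals, by = "bird_id") |>
    dplyr::mutate(
      strategy = strat[cbind(match(.data$bird_id, individuals$bird_id),
                             match(.data$year, years))],
      age_class = dplyr::if_else(
        .data$first_year_flag & .data$year == years[1],
        "first-year", "adult")
    )

  ## --- winter resightings ------------------------------------------------
  det <- config$detection
  res_rows <- bird_years |>
    dplyr::filter(.data$strategy == "resident",
                  stats::runif(dplyr::n()) < det$p_winter_resight) |>
    dplyr::mutate(n_rec = sample(1:3, dplyr::n(), replace = TRUE)) |>
    tidyr::uncount(.data$n_rec)
  wg_rows <- bird_years |>
    dplyr::filter(.data$strategy == "migrant",
                  stats::runif(dplyr::n()) < det$p_wintering_ground_sighting)
  resightings <- dplyr::bind_rows(
    res_rows |>
      dplyr::mutate(wintering_ground = FALSE, obs_area = .data$area),
    wg_rows |>
      dplyr::mutate(wintering_ground = TRUE, obs_area = "wintering_grounds")
  )
  resightings$date <- if (nrow(resightings)) {
    as.Date(unlist(purrr::map(resightings$year, rdate_in_window, n = 1)),
            origin = "1970-01-01")
  } else as.Date(character())
  resightings <- resightings |>
    dplyr::select("bird_id", "date", area = "obs_area", "wintering_ground") |>
    dplyr::arrange(.data$bird_id, .data$date)

  ## --- geolocator fixes --------------------------------------------------
  geo <- config$geolocator
  geo_by <- bird_years[stats::runif(nrow(bird_years)) < det$p_geolocator, ]
  fixes <- purrr::pmap(
    list(geo_by$bird_id, geo_by$year, geo_by$strategy),
    function(id, yr, st) {
      w <- winter_window_dates(yr)
      dts <- sort(w[["start"]] +
                    sample.int(as.integer(w[["end"]] - w[["start"]]) + 1L,
                               geo$n_fixes, replace = TRUE) - 1L)
      if (st == "resident") {
        lat <- stats::rnorm(geo$n_fixes, geo$resident_lat, geo$resident_sd)
        # reflect at 36.05 so no resident window fix crosses 36 N
        lat <- ifelse(lat < 36.05, 72.10 - lat, lat)
        lon <- stats::rnorm(geo$n_fixes, geo$breeding_lon, 0.3)
      } else {
        lat <- pmin(stats::rnorm(geo$n_fixes, geo$migrant_lat,
                                 geo$migrant_sd), 22.5)
        lon <- stats::rnorm(geo$n_fixes, geo$winter_lon, 0.5)
      }
      # transit fixes outside the window, latitude linearly interpolated
      pre <- w[["start"]] - sample(5:20, 2)
      post <- w[["end"]] + sample(5:20, 2)
      t_lat <- if (st == "resident") {
        stats::rnorm(4, geo$resident_lat, geo$resident_sd)
      } else {
        frac <- stats::runif(4, 0.2, 0.8)
        geo$resident_lat + frac * (geo$migrant_lat - geo$resident_lat)
      }
      tibble::tibble(
        bird_id = id,
        datetime = c(pre, dts, post),
        latitude = c(t_lat[1:2], lat, t_lat[3:4]),
        longitude = c(stats::rnorm(2, geo$breeding_lon, 0.3), lon,
                      stats::rnorm(2, geo$breeding_lon, 0.3))
      )
    }) |>
    purrr::list_rbind()
  if (!nrow(fixes)) {
    fixes <- tibble::tibble(bird_id = character(),
                            datetime = as.Date(character()),
                            latitude = numeric(), longitude = numeric())
  }
  fixes <- dplyr::arrange(fixes, .data$bird_id, .data$datetime)

  ## --- feather isotopes --------------------------------------------------
  iso <- config$isotope
  fth <- bird_years[stats::runif(nrow(bird_years)) < det$p_feather, ]
  premoult <- fth$strategy == "migrant" &
    stats::runif(nrow(fth)) < iso$p_premoult
  mu <- ifelse(fth$strategy == "migrant" & !premoult,
               iso$migrant_mean, iso$resident_mean)
  feathers <- tibble::tibble(
    bird_id = fth$bird_id,
    collection_year = fth$year,
    d13c = stats::rnorm(nrow(fth), mu, iso$sd)
  )
  feather_truth <- dplyr::mutate(feathers, strategy = fth$strategy,
                                 premoult = premoult)

  ## --- nests and chicks --------------------------------------------------
  phen <- config$phenology
  eff <- config$effects
  females <- bird_years |>
    dplyr::filter(.data$sex == "F", .data$age_class == "adult",
                  stats::runif(dplyr::n()) < phen$p_nest)
  nests_truth <- females |>
    dplyr::mutate(
      nest_id = sprintf("N%05d", dplyr::row_number()),
      colony = paste0(.data$area, "-col", 1 + (dplyr::row_number() %% 2L)),
      fed_doy = round(stats::rnorm(
        dplyr::n(), phen$mean_doy[.data$area] +
          eff$fed_shift_migrant * (.data$strategy == "migrant"), phen$sd)),
      first_egg_true = as.Date(sprintf("%d-01-01", .data$year)) +
        .data$fed_doy - 1L
    )
  # pair a male from the same area (without replacement within area-year)
  nests_truth$parent2 <- NA_character_
  males <- dplyr::filter(bird_years, .data$sex == "M",
                         .data$age_class == "adult")
  for (grp in split(seq_len(nrow(nests_truth)),
                    paste(nests_truth$area, nests_truth$year))) {
    key <- paste(nests_truth$area[grp[1]], nests_truth$year[grp[1]])
    pool <- males$bird_id[paste(males$area, males$year) == key]
    take <- grp[stats::runif(length(grp)) < phen$p_second_parent]
    take <- take[seq_len(min(length(take), length(pool)))]
    if (length(take)) {
      nests_truth$parent2[take] <- sample(pool, length(take))
    }
  }
  sc_fed <- as.numeric(scale(nests_truth$fed_doy))
  lam <- exp(log(config$clutch$lambda) + config$clutch$beta_date * sc_fed +
               eff$clutch_loglambda_shift *
               (nests_truth$strategy == "migrant"))
  nests_truth$clutch_size <- rcmp(nrow(nests_truth), lam, config$clutch$nu)
  nests_truth$hatch_true <- nests_truth$first_egg_true + 32L
  obs_fed <- stats::runif(nrow(nests_truth)) < phen$p_obs_first_egg
  obs_hatch <- !obs_fed & stats::runif(nrow(nests_truth)) < phen$p_obs_hatch

  nests <- tibble::tibble(
    nest_id = nests_truth$nest_id,
    colony = nests_truth$colony,
    area = nests_truth$area,
    year = nests_truth$year,
    parent1 = nests_truth$bird_id,
    parent2 = nests_truth$parent2,
    first_egg_observed = dplyr::if_else(obs_fed, nests_truth$first_egg_true,
                                        as.Date(NA)),
    first_hatch_observed = dplyr::if_else(obs_hatch, nests_truth$hatch_true,
                                          as.Date(NA)),
    clutch_size = nests_truth$clutch_size
  )

  ck <- config$chick
  chicks <- purrr::pmap(
    list(nests_truth$nest_id, nests_truth$hatch_true,
         nests_truth$clutch_size, nests_truth$area,
         nests_truth$strategy),
    function(nid, hatch, clutch, area, st) {
      n_h <- stats::rbinom(1L, clutch, phen$p_hatch)
      if (n_h == 0L) return(NULL)
      p_fl <- stats::plogis(stats::qlogis(ck$p_fledge) +
                              eff$fledge_logit_shift * (st == "migrant"))
      fledged <- stats::runif(n_h) < p_fl
      age_last <- ifelse(fledged, sample(24:32, n_h, replace = TRUE),
                         sample(3:20, n_h, replace = TRUE))
      nest_re <- stats::rnorm(1, 0, ck$nest_sd)
      measurable <- age_last >= 14
      mage <- ifelse(measurable,
                     vapply(pmin(30, age_last), function(u)
                       sample(14:u, 1L), numeric(1)),
                     NA_real_)
      wing <- ck$wing_intercept + ck$wing_slope * mage + nest_re +
        stats::rnorm(n_h, 0, ck$resid_sd)
      p8c <- stats::rnorm(n_h, 45, 3)
      cond <- stats::rnorm(n_h, ck$cond_baseline +
                             ck$cond_area_offset * (area == config$areas[1]) +
                             eff$chick_cond_shift * (st == "migrant"),
                           ck$cond_sd)
      tibble::tibble(
        nest_id = nid,
        chick_id = paste0(nid, "-c", seq_len(n_h)),
        date = hatch + ifelse(is.na(mage), NA_integer_, as.integer(mage)),
        known_age = ifelse(!is.na(mage) &
                             stats::runif(n_h) < ck$p_known_age,
                           mage, NA_real_),
        wing = ifelse(measurable, wing, NA_real_),
        p8 = ifelse(measurable, p8c, NA_real_),
        mass = ifelse(measurable, cond * p8c, NA_real_),
        age_last_seen = age_last
      )
    }) |>
    purrr::list_rbind()

  ## --- adult captures (condition series) ---------------------------------
  cond_out <- generate_condition_series(config, bird_years)

  truth <- list(
    individuals = individuals,
    bird_years = dplyr::select(bird_years, "bird_id", "year", "sex", "area",
                               "strategy", "age_class"),
    nests = dplyr::select(nests_truth, "nest_id", "bird_id", "year", "area",
                          "strategy", "first_egg_true", "hatch_true",
                          "clutch_size"),
    feathers = feather_truth,
    captures = cond_out$truth,
    config = config
  )

  structure(list(captures = cond_out$captures, resightings = resightings,
                 fixes = fixes, feathers = feathers, nests = nests,
                 chicks = chicks, truth = truth),
            class = "partmig_cohort")
}

#' Generate the adult capture / condition series
#'
#' Draws capture events for each bird-year and the mass/P8 condition value at
#' each: a seasonal cosine of day-of-year plus sex, area and individual
#' effects, an area-specific deficit applied to migrants only before the
#' pre-incubation cutoff, and Gaussian noise. Every generative term is
#' recorded in the returned truth table. Called by [generate_cohort()] but
#' usable standalone (uses the current RNG state).
#'
#' @param config a [sim_config()].
#' @param bird_years tibble with `bird_id`, `year`, `sex`, `area`,
#'   `strategy`, `age_class`, `cond_intercept`, `p8` (as built by
#'   [generate_cohort()] from the individual table).
#' @return list with `captures` (the observable table) and `truth` (captures
#'   plus every generative component).
#' @export
generate_condition_series <- function(config, bird_years) {
  det <- config$detection
  cnd <- config$condition
  cut_md <- cnd$deficit_cutoff

  caps <- bird_years |>
    dplyr::mutate(n_cap = stats::rbinom(dplyr::n(), det$capture_occasions,
                                        det$p_capture)) |>
    dplyr::filter(.data$n_cap > 0L) |>
    tidyr::uncount(.data$n_cap)
  nc <- nrow(caps)
  # capture effort split so the pre-incubation window is represented
  pre <- stats::runif(nc) < 0.4
  doy <- ifelse(pre, round(stats::runif(nc, 35, 120)),
                round(stats::runif(nc, 122, 320)))
  caps$date <- as.Date(sprintf("%d-01-01", caps$year)) + doy - 1L
  caps$doy <- doy

  seasonal <- cnd$amplitude * cos(2 * pi * (doy - cnd$peak_doy) / 365)
  sex_term <- cnd$sex_offset * (caps$sex == "F")
  area_term <- cnd$area_offset * (caps$area == config$areas[1])
  pre_cut <- format(caps$date, "%m-%d") < cut_md
  deficit <- ifelse(caps$strategy == "migrant" & pre_cut,
                    cnd$migrant_deficit[caps$area], 0)
  noise <- stats::rnorm(nc, 0, cnd$residual_sd)
  cond <- cnd$baseline + seasonal + sex_term + area_term +
    caps$cond_intercept - deficit + noise

  truth <- caps |>
    dplyr::mutate(seasonal = seasonal, sex_term = sex_term,
                  area_term = area_term, deficit = deficit, noise = noise,
                  condition_true = cond) |>
    dplyr::select("bird_id", "year", "date", "sex", "area", "strategy",
                  "age_class", "cond_intercept", "seasonal", "sex_term",
                  "area_term", "deficit", "noise", "condition_true")

  captures <- caps |>
    dplyr::mutate(mass = cond * .data$p8,
                  wing = stats::rnorm(nc, 240, 5),
                  colony = paste0(.data$area, "-col1")) |>
    dplyr::select("bird_id", "date", "age_class", "sex", "colony", "area",
                  "mass", "wing", "p8", "year") |>
    dplyr::arrange(.data$bird_id, .data$date)

  list(captures = captures, truth = truth)
}

#' Synthetic seasonal NDVI pixel series
#'
#' Generates a pixel-level NDVI table for [fit_seasonal_smooth()]: per-area
#' seasonal cosine with configurable peak day and amplitude, a pixel random
#' intercept, and Gaussian noise, sampled on a 16-day satellite revisit
#' cadence.
#'
#' @param n_pixels pixels per area.
#' @param areas area labels.
#' @param peak_doy named peak day-of-year per area.
#' @param baseline,amplitude named per-area level and seasonal amplitude.
#' @param pixel_sd,noise_sd random-intercept and residual SDs.
#' @param years calendar years covered.
#' @param seed RNG seed.
#' @return tibble `pixel_id`, `area`, `date`, `ndvi`.
#' @export
simulate_ndvi_series <- function(n_pixels = 50,
                                 areas = c("Cadiz", "Seville"),
                                 peak_doy = c(Cadiz = 120, Seville = 90),
                                 baseline = c(Cadiz = 0.45, Seville = 0.35),
                                 amplitude = c(Cadiz = 0.2, Seville = 0.18),
                                 pixel_sd = 0.03, noise_sd = 0.05,
                                 years = 2014:2017, seed = 1L) {
  set.seed(seed)
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = 16)
  grid <- tidyr::expand_grid(
    area = areas, px = seq_len(n_pixels), date = dates
  ) |>
    dplyr::mutate(pixel_id = paste0(.data$area, "-px", .data$px))
  re <- stats::rnorm(n_pixels * length(areas), 0, pixel_sd)
  names(re) <- unique(grid$pixel_id)
  doy <- day_of_year(grid$date)
  mu <- baseline[grid$area] +
    amplitude[grid$area] * cos(2 * pi * (doy - peak_doy[grid$area]) / 365) +
    re[grid$pixel_id]
  grid |>
    dplyr::mutate(ndvi = pmin(1, pmax(-1, mu + stats::rnorm(
      dplyr::n(), 0, noise_sd)))) |>
    dplyr::select("pixel_id", "area", "date", "ndvi")
}

#' @export
print.partmig_cohort <- function(x, ...) {
  cat("Synthetic partially migratory cohort\n")
  cat("  individuals:", nrow(x$truth$individuals),
      " bird-years:", nrow(x$truth$bird_years), "\n")
  cat("  captures:", nrow(x$captures),
      " resightings:", nrow(x$resightings),
      " fixes:", nrow(x$fixes), "\n")
  cat("  feathers:", nrow(x$feathers),
      " nests:", nrow(x$nests),
      " chick rows:", nrow(x$chicks), "\n")
  invisible(x)
}
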