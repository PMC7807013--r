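# Shared fixtures and independent oracles for the test suite.

# Brute-force CMP log-pmf: direct series summation of exp'd log terms,
# independent of the package's adaptive truncation machinery.
oracle_cmp_logpmf <- function(y, lambda, nu, jmax = 2000) {
  j <- 0:jmax
  z <- sum(exp(j * log(lambda) - nu * lgamma(j + 1)))
  y * log(lambda) - nu * lgamma(y + 1) - log(z)
}

# Exhaustive truth-table evaluation of the three-stream combination rule:
# all informative verdicts agree -> that strategy; none -> unknown;
# contradiction -> unknown + conflict.
oracle_reconcile <- function(verdicts) {
  inf <- verdicts[verdicts %in% c("migrant", "resident")]
  if (length(inf) == 0) return(list(strategy = "unknown", conflict = FALSE))
  if (length(unique(inf)) == 1) {
    return(list(strategy = inf[[1]], conflict = FALSE))
  }
  list(strategy = "unknown", conflict = TRUE)
}

# Condition rows with a known area-specific deficit for migrants before the
# pre-incubation cutoff, built through the package generator. `deficit_z` is
# the deficit in residual-SD units.
sim_preincubation_rows <- function(seed, deficit_z, n_individuals = 90) {
  resid_sd <- 0.08
  cfg <- sim_config(
    n_individuals = n_individuals, years = 2014:2015,
    detection = list(p_capture = 0.7),
    condition = list(
      residual_sd = resid_sd,
      migrant_deficit = c(Cadiz = 0, Seville = deficit_z * resid_sd)),
    seed = seed)
  set.seed(seed)
  n <- cfg$n_individuals
  ind <- tibble::tibble(
    bird_id = sprintf("B%04d", seq_len(n)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    area = sample(cfg$areas, n, replace = TRUE),
    cond_intercept = rnorm(n, 0, cfg$condition$individual_sd),
    p8 = rnorm(n, 50, 1.5))
  by <- tidyr::expand_grid(ind, year = cfg$years)
  by$strategy <- sample(c("migrant", "resident"), nrow(by), replace = TRUE)
  by$age_class <- "adult"
  out <- generate_condition_series(cfg, by)
  rows <- out$captures |>
    dplyr::inner_join(
      dplyr::select(by, "bird_id", "year", "strategy"),
      by = c("bird_id", "year"))
  rows <- pre_incubation_subset(rows)
  rows$cond_z <- as.numeric(scale(raw_condition(rows$mass, rows$p8)))
  rows
}

# Adult capture table with known variance components for condition-smoother
# recovery tests. Returns the captures plus the truth used.
sim_condition_captures <- function(seed, n = 566, n_birds = 150,
                                   amplitude = 0.15, sex_offset = 0.08,
                                   bird_sd = 0.05, resid_sd = 0.08) {
  set.seed(seed)
  b <- rep(sprintf("B%03d", seq_len(n_birds)), length.out = n)
  sexes <- sample(c("M", "F"), n_birds, replace = TRUE)
  re <- rnorm(n_birds, 0, bird_sd)
  names(re) <- names(sexes) <- unique(b)
  doy <- sample(35:320, n, replace = TRUE)
  raw <- 2.9 + amplitude * cos(2 * pi * (doy - 122) / 365) +
    sex_offset * (sexes[b] == "F") + re[b] + rnorm(n, 0, resid_sd)
  list(
    captures = tibble::tibble(
      bird_id = b, date = as.Date("2016-01-01") + doy - 1,
      sex = sexes[b], mass = raw * 50, p8 = 50,
      age_class = "adult", year = 2016L),
    raw = raw, bird_sd = bird_sd, resid_sd = resid_sd,
    sex_offset = sex_offset)
}
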