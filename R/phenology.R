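#' Back-calculate the first-egg date from the first hatch date
#'
#' Laying onset is reconstructed as exactly 32 calendar days before the first
#' hatch date (laying interval plus incubation, treated as fixed).
#'
#' @param first_hatch_date a `Date` vector.
#' @return a `Date` vector, `first_hatch_date - 32`.
#' @examples
#' first_egg_from_hatch(as.Date("2016-05-20"))  # 2016-04-18
#' @export
first_egg_from_hatch <- function(first_hatch_date) {
  stopifnot(inherits(first_hatch_date, "Date"))
  first_hatch_date - 32L
}

#' Calibrate linear wing growth on known-age chicks
#'
#' Wing chord grows linearly with age between 14 and 30 days; outside that
#' window growth is non-linear and measurements are excluded (with a message
#' giving the count). Fits a linear mixed model of wing chord on age with a
#' nest random intercept and reports the fixed intercept and slope, the
#' variance components and the marginal R-squared (variance of the
#' fixed-effect predictions over total marginal variance).
#'
#' @param chicks tibble with `nest_id`, `known_age` (days), `wing` (mm).
#' @param age_window inclusive age window (days) over which growth is linear.
#' @return a `wing_growth_model` with `intercept`, `slope`, `nest_sd`,
#'   `resid_sd`, `r2_marginal`, `n`, `n_excluded` and the underlying fit.
#' @export
fit_wing_growth <- function(chicks, age_window = c(14, 30)) {
  d <- dplyr::filter(chicks, !is.na(.data$known_age), !is.na(.data$wing))
  in_win <- d$known_age >= age_window[1] & d$known_age <= age_window[2]
  if (any(!in_win)) {
    message(sum(!in_win), " measurement(s) outside the ", age_window[1], "-",
            age_window[2], " day window excluded from wing-growth calibration")
  }
  d <- d[in_win, ]
  if (nrow(d) < 10L) stop("need at least 10 in-window measurements",
                          call. = FALSE)
  if (length(unique(d$known_age)) < 2L) {
    stop("all ages identical: slope unidentifiable", call. = FALSE)
  }
  n_nests <- length(unique(d$nest_id))
  if (n_nests < 2L) {
    warning("single nest: random-effect variance reported as 0", call. = FALSE)
    fit <- stats::lm(wing ~ known_age, data = d)
    beta <- stats::coef(fit)
    nest_sd <- 0
    resid_sd <- stats::sigma(fit)
    pred <- stats::fitted(fit)
  } else {
    fit <- lme4::lmer(wing ~ known_age + (1 | nest_id), data = d, REML = TRUE)
    beta <- lme4::fixef(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    nest_sd <- vc$sdcor[vc$grp == "nest_id"]
    resid_sd <- vc$sdcor[vc$grp == "Residual"]
    pred <- drop(stats::model.matrix(fit) %*% beta)
  }
  var_fixed <- stats::var(pred)
  r2 <- var_fixed / (var_fixed + nest_sd^2 + resid_sd^2)
  structure(list(intercept = unname(beta[1]), slope = unname(beta[2]),
                 nest_sd = nest_sd, resid_sd = resid_sd,
                 r2_marginal = r2, n = nrow(d), n_excluded = sum(!in_win),
                 age_window = age_window, fit = fit),
            class = "wing_growth_model")
}

#' @export
print.wing_growth_model <- function(x, ...) {
  cat("Wing-growth calibration (linear, ages ", x$age_window[1], "-",
      x$age_window[2], " d)\n", sep = "")
  cat("  wing = ", format(x$intercept, digits = 4), " + ",
      format(x$slope, digits = 4), " * age  (n = ", x$n, ")\n", sep = "")
  cat("  nest SD =", format(x$nest_sd, digits = 3),
      " residual SD =", format(x$resid_sd, digits = 3),
      " marginal R2 =", format(x$r2_marginal, digits = 3), "\n")
  invisible(x)
}

#' Estimate chick age, hatch date and first-egg date from wing length
#'
#' Inverts the wing-growth calibration at the population level (fixed effects
#' only; a new chick's nest effect is unknown): age = (wing - intercept) /
#' slope, rounded to the nearest whole day for date arithmetic. Hatch date is
#' the measurement date minus the rounded age, and the first-egg date follows
#' by the 32-day back-calculation. Ages falling outside the linear window are
#' flagged `extrapolated` with a warning, since growth is non-linear there.
#'
#' @param chicks tibble with `wing` (mm) and `date` (measurement `Date`).
#' @param model a [fit_wing_growth()] calibration.
#' @return the input with `age_est` (days, unrounded), `extrapolated`,
#'   `hatch_date` and `first_egg_date` columns appended.
#' @export
estimate_hatch_from_wing <- function(chicks, model) {
  stopifnot(inherits(model, "wing_growth_model"))
  if (model$slope <= 0) stop("non-positive growth slope: refusing to invert",
                             call. = FALSE)
  age <- (chicks$wing - model$intercept) / model$slope
  extrap <- age < model$age_window[1] | age > model$age_window[2]
  if (any(extrap)) {
    warning(sum(extrap), " age estimate(s) outside the linear window; ",
            "flagged as extrapolated", call. = FALSE)
  }
  hatch <- chicks$date - round(age)
  dplyr::mutate(chicks, age_est = age, extrapolated = extrap,
                hatch_date = hatch,
                first_egg_date = first_egg_from_hatch(hatch))
}

#' Nest outcome from chick ages
#'
#' A nest is successful if at least one chick reached an age strictly greater
#' than 20 days; the fledgling count is the number of such chicks. Ages are
#' the best available bound (last seen alive).
#'
#' @param chicks tibble with `nest_id` and `age_last_seen` (days).
#' @return tibble per nest: `nest_id`, `n_fledglings`, `outcome`.
#' @export
nest_outcome <- function(chicks) {
  chicks |>
    dplyr::summarise(
      n_fledglings = sum(.data$age_last_seen > 20, na.rm = TRUE),
      .by = "nest_id"
    ) |>
    dplyr::mutate(outcome = dplyr::if_else(.data$n_fledglings >= 1L,
                                           "success", "failure"))
}

#' Mean chick condition per brood
#'
#' Chick condition is mass divided by P8 length, averaged over siblings to
#' give one value per brood. Rows with non-positive P8 are rejected with a
#' message; broods with no valid chick are excluded.
#'
#' @param chicks tibble with `nest_id`, `mass` (g), `p8` (mm).
#' @return tibble per nest: `nest_id`, `chick_condition` (g/mm), `n_chicks`.
#' @export
brood_condition <- function(chicks) {
  bad <- !is.na(chicks$p8) & chicks$p8 <= 0
  if (any(bad)) message(sum(bad), " chick row(s) with non-positive P8 rejected")
  chicks |>
    dplyr::filter(!is.na(.data$mass), !is.na(.data$p8), .data$p8 > 0) |>
    dplyr::summarise(
      chick_condition = mean(.data$mass / .data$p8),
      n_chicks = dplyr::n(),
      .by = "nest_id"
    )
}

#' Reconstruct nest phenology and outcomes
#'
#' Assembles the analysis-ready nest table. The first-egg date is taken, in
#' order of preference: as observed; back-calculated from an observed first
#' hatch date; or estimated from the earliest chick wing measurement via the
#' wing-growth calibration. Each record carries a provenance tag (`observed`,
#' `backcalc`, `wing_estimated`, or `none`), and outcome and mean brood
#' condition are appended from the chick table.
#'
#' @param nests tibble with `nest_id`, `colony`, `area`, `year`, `parent1`,
#'   `parent2`, `first_egg_observed`, `first_hatch_observed` (Dates, NA when
#'   unobserved), `clutch_size`.
#' @param chicks chick-measurement tibble (see [fit_wing_growth()],
#'   [nest_outcome()], [brood_condition()]).
#' @param wing_model optional [fit_wing_growth()] calibration; when `NULL` and
#'   needed, it is fitted from the known-age chicks in `chicks`.
#' @return the nest table with `first_egg_date`, `provenance`,
#'   `n_fledglings`, `outcome`, `chick_condition` columns; provenance counts
#'   are attached as attribute `"provenance_counts"`.
#' @export
reconstruct_phenology <- function(nests, chicks, wing_model = NULL) {
  need_wing <- is.na(nests$first_egg_observed) &
    is.na(nests$first_hatch_observed)
  if (any(need_wing) && is.null(wing_model)) {
    wing_model <- tryCatch(fit_wing_growth(chicks), error = function(e) {
      warning("wing-growth calibration unavailable (",
              conditionMessage(e), "); unobserved nests left undated",
              call. = FALSE)
      NULL
    })
  }

  wing_est <- NULL
  if (any(need_wing) && !is.null(wing_model)) {
    meas <- chicks |>
      dplyr::filter(.data$nest_id %in% nests$nest_id[need_wing],
                    !is.na(.data$wing), !is.na(.data$date))
    if (nrow(meas)) {
      wing_est <- suppressWarnings(
        estimate_hatch_from_wing(meas, wing_model)
      ) |>
        dplyr::summarise(
          first_egg_wing = min(.data$first_egg_date),
          .by = "nest_id"
        )
    }
  }

  out <- nests |>
    dplyr::left_join(wing_est %||%
                       tibble::tibble(nest_id = nests$nest_id[0],
                                      first_egg_wing = as.Date(character())),
                     by = "nest_id") |>
    dplyr::mutate(
      first_egg_date = dplyr::case_when(
        !is.na(.data$first_egg_observed) ~ .data$first_egg_observed,
        !is.na(.data$first_hatch_observed) ~
          first_egg_from_hatch(.data$first_hatch_observed),
        .default = .data$first_egg_wing
      ),
      provenance = dplyr::case_when(
        !is.na(.data$first_egg_observed) ~ "observed",
        !is.na(.data$first_hatch_observed) ~ "backcalc",
        !is.na(.data$first_egg_wing) ~ "wing_estimated",
        .default = "none"
      )
    ) |>
    dplyr::select(-"first_egg_wing") |>
    dplyr::left_join(nest_outcome(chicks), by = "nest_id") |>
    dplyr::left_join(brood_condition(chicks), by = "nest_id") |>
    dplyr::mutate(
      n_fledglings = dplyr::coalesce(.data$n_fledglings, 0L),
      outcome = dplyr::coalesce(.data$outcome, "failure")
    )
  attr(out, "provenance_counts") <- table(out$provenance)
  out
}
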