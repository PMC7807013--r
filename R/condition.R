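#' Raw body-condition index
#'
#' Mass divided by P8 (eighth primary) length, separating dynamic body
#' condition from structural size. Non-positive inputs are rejected.
#'
#' @param mass body mass in g.
#' @param p8 P8 feather length in mm.
#' @return condition in g/mm.
#' @examples
#' raw_condition(146.6, 50)  # 2.932
#' @export
raw_condition <- function(mass, p8) {
  if (any(mass <= 0, na.rm = TRUE) || any(p8 <= 0, na.rm = TRUE)) {
    stop("mass and P8 must be positive", call. = FALSE)
  }
  mass / p8
}

day_of_year <- function(date) as.POSIXlt(date)$yday + 1

#' Relative body condition from a seasonal penalized-spline mixed model
#'
#' Fits z-scored mass/P8 of adult captures against a cyclic penalized
#' regression spline of day-of-year (cyclic, so condition is continuous across
#' the year boundary), a sex term, and a bird-identity random intercept to
#' account for recaptures. The residuals are the relative-condition index:
#' each bird's condition relative to the population mean for its sex at that
#' date. Smoothing parameters are selected by REML, the backend default.
#'
#' Sex enters either as a parametric offset on a shared seasonal smooth
#' (default) or as separate per-sex smooths (`sex_as = "by"`). With a single
#' sex in the data the sex term is dropped with a warning.
#'
#' @param captures adult capture tibble with `bird_id`, `date` (Date), `sex`,
#'   `mass` (g), `p8` (mm). At least 50 captures spanning 6+ months.
#' @param sex_as `"offset"` (shared smooth plus sex offset) or `"by"`
#'   (separate smooth per sex).
#' @param k basis dimension of the cyclic spline.
#' @return a `condition_smooth` object: the mgcv fit, the variance components,
#'   smooth effective degrees of freedom, and `$index` -- the input rows with
#'   `raw_condition`, `condition_z`, `relative_condition` (residual, z scale)
#'   columns.
#' @export
fit_condition_smooth <- function(captures, sex_as = c("offset", "by"),
                                 k = 10) {
  sex_as <- match.arg(sex_as)
  d <- captures |>
    dplyr::filter(!is.na(.data$mass), !is.na(.data$p8), !is.na(.data$date))
  if (nrow(d) < 50L) stop("need at least 50 captures", call. = FALSE)
  doy <- day_of_year(d$date)
  if (diff(range(doy)) < 180) {
    stop("captures must span at least 6 months of the year", call. = FALSE)
  }
  d$raw_condition <- raw_condition(d$mass, d$p8)
  d$condition_z <- as.numeric(scale(d$raw_condition))
  d$doy <- doy
  d$bird <- factor(d$bird_id)
  d$sex <- factor(d$sex)

  two_sexes <- nlevels(d$sex) >= 2L
  if (!two_sexes) {
    warning("single sex present: fitting without a sex term", call. = FALSE)
  }
  f <- if (!two_sexes) {
    condition_z ~ s(doy, bs = "cc", k = k) + s(bird, bs = "re")
  } else if (sex_as == "offset") {
    condition_z ~ sex + s(doy, bs = "cc", k = k) + s(bird, bs = "re")
  } else {
    condition_z ~ sex + s(doy, bs = "cc", by = sex, k = k) + s(bird, bs = "re")
  }
  fit <- mgcv::gam(f, data = d, method = "REML",
                   knots = list(doy = c(0.5, 366.5)))

  vcomp <- local({
    tmp <- NULL
    utils::capture.output(tmp <- mgcv::gam.vcomp(fit, rescale = TRUE))
    tmp
  })
  re_row <- grep("bird", rownames(vcomp))
  bird_sd <- if (length(re_row)) vcomp[re_row[1], "std.dev"] else 0
  resid_sd <- vcomp["scale", "std.dev"]

  idx <- d |>
    dplyr::mutate(relative_condition = stats::residuals(fit)) |>
    dplyr::select(-"bird")

  structure(list(fit = fit, formula = f, sex_as = sex_as,
                 bird_sd = bird_sd, resid_sd = resid_sd,
                 edf = sum(fit$edf), n = nrow(d),
                 index = idx),
            class = "condition_smooth")
}

#' @export
print.condition_smooth <- function(x, ...) {
  cat("Seasonal condition smooth (cyclic penalized spline + bird random",
      "intercept)\n")
  cat("  n =", x$n, "  total edf =", format(x$edf, digits = 4), "\n")
  cat("  bird SD =", format(x$bird_sd, digits = 3),
      "  residual SD =", format(x$resid_sd, digits = 3), "(z scale)\n")
  invisible(x)
}

#' Pre-incubation subset of condition measures
#'
#' Retains captures taken strictly before the cutoff month-day of their
#' capture year (default 02 May, the peak of mean female condition marking
#' the onset of incubation). The short window after spring arrival is where a
#' carryover effect of the preceding winter is most plausible, before
#' breeding effort dominates condition.
#'
#' @param data tibble with a `Date` column named by `date_col`.
#' @param cutoff `"MM-DD"` month-day applied per capture year.
#' @param date_col name of the date column.
#' @return the retained rows; the number excluded is attached as attribute
#'   `"n_excluded"`.
#' @export
pre_incubation_subset <- function(data, cutoff = "05-02", date_col = "date") {
  keep <- format(data[[date_col]], "%m-%d") < cutoff
  out <- data[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Seasonal NDVI smooth by area with pixel random intercepts
#'
#' Models a pixel-level NDVI series against day-of-year with cyclic penalized
#' regression splines interacting with area, and a pixel-identity random
#' intercept. The area interaction is parameterised as a shared smooth plus a
#' difference smooth (ordered-factor `by` smooth), so the difference smooth's
#' approximate test directly asks whether the two areas' seasonal trends
#' differ. Also reports each area's fitted peak date.
#'
#' @param series tibble with `pixel_id`, `area`, `date` (Date), `ndvi`
#'   (in -1..1).
#' @param k basis dimension of the cyclic spline.
#' @return a `seasonal_smooth` object: the mgcv fit, `peaks` (per-area peak
#'   day-of-year of the fitted seasonal trend), `diff_test` (approximate
#'   p-value and edf of the between-area difference smooth, `NA` with one
#'   area), smooth edf table, and the augmented data.
#' @export
fit_seasonal_smooth <- function(series, k = 12) {
  if (any(abs(series$ndvi) > 1, na.rm = TRUE)) {
    stop("NDVI values must lie in [-1, 1]", call. = FALSE)
  }
  d <- series |>
    dplyr::filter(!is.na(.data$ndvi), !is.na(.data$date)) |>
    dplyr::mutate(doy = day_of_year(.data$date),
                  area = factor(.data$area),
                  pixel = factor(.data$pixel_id))
  areas <- levels(d$area)
  one_area <- length(areas) < 2L
  if (one_area) {
    warning("single area: fitting one seasonal smooth", call. = FALSE)
    f <- ndvi ~ s(doy, bs = "cc", k = k) + s(pixel, bs = "re")
  } else {
    px_per_area <- d |>
      dplyr::summarise(npx = dplyr::n_distinct(.data$pixel), .by = "area")
    if (any(px_per_area$npx < 2L)) {
      stop("need at least 2 pixels per area", call. = FALSE)
    }
    d$area_o <- as.ordered(d$area)
    f <- ndvi ~ area + s(doy, bs = "cc", k = k) +
      s(doy, bs = "cc", by = area_o, k = k) + s(pixel, bs = "re")
  }
  fit <- mgcv::gam(f, data = d, method = "REML",
                   knots = list(doy = c(0.5, 366.5)))

  # per-area fitted seasonal trend at the population level (pixel RE zeroed
  # by predicting for the first pixel and excluding its random effect)
  grid <- tidyr::expand_grid(doy = 1:365, area = factor(areas, areas))
  grid$pixel <- d$pixel[1]
  if (!one_area) grid$area_o <- as.ordered(grid$area)
  pred <- stats::predict(fit, newdata = grid, exclude = "s(pixel)")
  grid$trend <- as.numeric(pred)
  peaks <- grid |>
    dplyr::slice_max(.data$trend, n = 1, by = "area", with_ties = FALSE) |>
    dplyr::select("area", peak_doy = "doy", peak_ndvi = "trend")

  st <- summary(fit)$s.table
  diff_row <- grep("area_o", rownames(st))
  diff_test <- if (one_area || !length(diff_row)) {
    list(p_value = NA_real_, edf = NA_real_)
  } else {
    list(p_value = unname(st[diff_row[1], "p-value"]),
         edf = unname(st[diff_row[1], "edf"]))
  }

  structure(list(fit = fit, peaks = peaks, diff_test = diff_test,
                 smooth_edf = st[, "edf"], n = nrow(d),
                 data = d),
            class = "seasonal_smooth")
}

#' @export
print.seasonal_smooth <- function(x, ...) {
  cat("Seasonal smooth by area (cyclic penalized spline + pixel random",
      "intercept)\n  n =", x$n, "\n")
  print(as.data.frame(x$peaks))
  if (!is.na(x$diff_test$p_value)) {
    cat("  between-area difference smooth: edf =",
        format(x$diff_test$edf, digits = 3), ", p =",
        format.pval(x$diff_test$p_value, digits = 3), "\n")
  }
  invisible(x)
}
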