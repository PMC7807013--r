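#' Configuration of the end-to-end analysis
#'
#' Collects every tunable constant of the pipeline, with the field protocol's
#' values as defaults: the classification thresholds ([strategy_rules()]),
#' the pre-incubation cutoff (captures strictly before 02 May), the years
#' excluded from inference (2018, an effort-imbalanced season; the exclusion
#' applies to the fitness models only, never to the condition smoother or the
#' wing-growth calibration), and the seed governing the random choice of one
#' parent per two-parent clutch.
#'
#' @param rules a [strategy_rules()] object.
#' @param pre_incubation_cutoff `"MM-DD"` cutoff for the pre-incubation
#'   condition subset.
#' @param excluded_years calendar years dropped from inference inputs.
#' @param analyses which of the eight analyses to run (default all):
#'   `cond_yearround`, `cond_preincubation`, `first_egg`, `clutch_size`,
#'   `n_fledglings`, `nest_outcome`, `fledging_prob`, `chick_condition`.
#' @param seed seed for the one-parent-per-clutch draw.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(rules = strategy_rules(),
                            pre_incubation_cutoff = "05-02",
                            excluded_years = 2018L,
                            analyses = c("cond_yearround",
                                         "cond_preincubation", "first_egg",
                                         "clutch_size", "n_fledglings",
                                         "nest_outcome", "fledging_prob",
                                         "chick_condition"),
                            seed = 1L) {
  structure(list(rules = rules,
                 pre_incubation_cutoff = pre_incubation_cutoff,
                 excluded_years = excluded_years,
                 analyses = analyses, seed = seed),
            class = "analysis_config")
}

#' Drop excluded years from an inference input
#'
#' @param data tibble with a year column.
#' @param excluded_years years to drop.
#' @param year_col name of the year column.
#' @return the retained rows; dropped count attached as attribute
#'   `"n_excluded"`. Aborts if nothing remains.
#' @export
apply_exclusions <- function(data, excluded_years, year_col = "year") {
  keep <- !(data[[year_col]] %in% excluded_years)
  if (!any(keep)) stop("all rows fall in excluded years; nothing to analyse",
                       call. = FALSE)
  out <- data[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' One parent per clutch for strategy analyses
#'
#' Joins parental strategy calls onto the nest table and resolves clutches
#' with two known-strategy parents by retaining one parent chosen uniformly
#' at random (seeded, reproducible). Clutches with no known-strategy parent
#' are dropped. The number of two-parent clutches and how many of those were
#' mixed-strategy pairs are attached as attributes.
#'
#' @param nests nest tibble with `parent1`, `parent2`, `year`.
#' @param calls strategy-call tibble ([reconcile_strategies()]).
#' @param seed RNG seed for the parent draw.
#' @return nests with `parent_id` and `strategy` columns, one row per clutch
#'   with a known-strategy parent; attributes `"n_pairs"` and `"n_mixed"`.
#' @export
dedupe_clutch_parents <- function(nests, calls, seed = 1L) {
  known <- dplyr::filter(calls, .data$strategy != "unknown")
  d <- nests |>
    dplyr::left_join(dplyr::select(known, "bird_id", "year",
                                   s1 = "strategy"),
                     by = c(parent1 = "bird_id", "year")) |>
    dplyr::left_join(dplyr::select(known, "bird_id", "year",
                                   s2 = "strategy"),
                     by = c(parent2 = "bird_id", "year"))
  both <- !is.na(d$s1) & !is.na(d$s2)
  n_pairs <- sum(both)
  n_mixed <- sum(both & d$s1 != d$s2)
  set.seed(seed)
  pick1 <- stats::runif(nrow(d)) < 0.5
  d <- d |>
    dplyr::mutate(
      use1 = !is.na(.data$s1) & (is.na(.data$s2) | pick1),
      parent_id = dplyr::case_when(.data$use1 ~ .data$parent1,
                                   !is.na(.data$s2) ~ .data$parent2,
                                   .default = NA_character_),
      strategy = dplyr::case_when(.data$use1 ~ .data$s1,
                                  !is.na(.data$s2) ~ .data$s2,
                                  .default = NA_character_)
    ) |>
    dplyr::filter(!is.na(.data$strategy)) |>
    dplyr::select(-"s1", -"s2", -"use1")
  attr(d, "n_pairs") <- n_pairs
  attr(d, "n_mixed") <- n_mixed
  d
}

# age class per bird-year, as observed at capture (bird-years never captured
# are assumed adult)
bird_year_age <- function(captures) {
  captures |>
    dplyr::summarise(
      age_class = if (any(.data$age_class == "first-year"))
        "first-year" else "adult",
      .by = c("bird_id", "year")
    )
}

#' Run the full carryover analysis
#'
#' Executes every stage in order on a set of input tables (for instance a
#' [generate_cohort()] result): three-stream strategy classification and
#' reconciliation; adult filtering; phenology reconstruction (wing-growth
#' calibration uses all years); the seasonal condition smoother (all adult
#' captures, all years) and the pre-incubation subset; year exclusions
#' (inference inputs only); one parent per clutch; and the eight
#' model-selection analyses relating strategy, area and phenology to
#' condition and breeding success. Deterministic given the tables and config.
#'
#' @param tables a `partmig_cohort` or a named list of tibbles `captures`,
#'   `resightings`, `fixes`, `feathers`, `nests`, `chicks`.
#' @param config an [analysis_config()].
#' @return a `partmig_report`: strategy calls and summaries, consistency
#'   table, wing-growth model, condition fit, reconstructed nest table,
#'   per-analysis selection tables (`$selection`), post-hoc contrasts for the
#'   pre-incubation final model when it retains the interaction, and a
#'   row-count funnel log.
#' @export
run_pipeline <- function(tables, config = analysis_config()) {
  rules <- config$rules
  funnel <- list()
  log_stage <- function(stage, n) funnel[[stage]] <<- n

  ## classification ---------------------------------------------------------
  res_v <- classify_by_resighting(tables$resightings, rules)
  geo_v <- classify_by_geolocator(tables$fixes, rules)
  iso_v <- classify_by_isotope(tables$feathers, rules)
  calls <- reconcile_strategies(res_v, geo_v, iso_v)
  log_stage("bird_years_with_evidence", nrow(calls))
  log_stage("bird_years_determined", sum(calls$strategy != "unknown"))

  ages <- bird_year_age(tables$captures)
  calls <- calls |>
    dplyr::left_join(ages, by = c("bird_id", "year")) |>
    dplyr::mutate(age_class = dplyr::coalesce(.data$age_class, "adult"))
  adult_calls <- dplyr::filter(calls, .data$strategy != "unknown",
                               .data$age_class == "adult")
  log_stage("adult_bird_years_determined", nrow(adult_calls))

  sexes <- tables$captures |>
    dplyr::distinct(.data$bird_id, .data$sex)
  call_summary <- adult_calls |>
    dplyr::left_join(sexes, by = "bird_id") |>
    dplyr::count(.data$strategy, .data$sex)
  consistency <- strategy_consistency(calls)

  ## phenology ---------------------------------------------------------------
  wing_model <- tryCatch(
    suppressMessages(fit_wing_growth(tables$chicks)),
    error = function(e) {
      message("wing-growth calibration skipped: ", conditionMessage(e))
      NULL
    })
  nest_tab <- reconstruct_phenology(tables$nests, tables$chicks, wing_model)
  log_stage("nests", nrow(nest_tab))

  ## condition ---------------------------------------------------------------
  adult_caps <- dplyr::filter(tables$captures, .data$age_class == "adult")
  log_stage("captures_total", nrow(tables$captures))
  log_stage("captures_adult", nrow(adult_caps))
  cond_fit <- fit_condition_smooth(adult_caps)
  index <- cond_fit$index |>
    dplyr::inner_join(dplyr::select(adult_calls, "bird_id", "year",
                                    "strategy"),
                      by = c("bird_id", "year"))
  log_stage("condition_rows_with_strategy", nrow(index))

  ## inference inputs --------------------------------------------------------
  cond_inf <- apply_exclusions(index, config$excluded_years)
  log_stage("condition_rows_after_exclusion", nrow(cond_inf))
  cond_inf <- dplyr::mutate(cond_inf,
                            date_z = as.numeric(scale(.data$doy)))
  cond_pre <- pre_incubation_subset(cond_inf,
                                    config$pre_incubation_cutoff)
  log_stage("condition_rows_preincubation", nrow(cond_pre))

  nest_known <- dedupe_clutch_parents(nest_tab, adult_calls,
                                      seed = config$seed)
  nest_inf <- apply_exclusions(nest_known, config$excluded_years)
  log_stage("nests_with_strategy", nrow(nest_known))
  log_stage("nests_after_exclusion", nrow(nest_inf))
  nest_inf <- nest_inf |>
    dplyr::filter(!is.na(.data$first_egg_date)) |>
    dplyr::mutate(
      fed_doy = day_of_year(.data$first_egg_date),
      fed_z = as.numeric(scale(.data$fed_doy)),
      outcome01 = as.integer(.data$outcome == "success"),
      prop_fledged = .data$n_fledglings / .data$clutch_size
    )

  ## model selection ---------------------------------------------------------
  sa <- c("strategy", "area", "strategy:area")
  specs <- list(
    cond_yearround = list(
      spec = model_spec("relative_condition", c(sa, "sex", "date_z"),
                        "gaussian", random = "bird_id"),
      data = cond_inf),
    cond_preincubation = list(
      spec = model_spec("relative_condition", c(sa, "sex", "date_z"),
                        "gaussian", random = "bird_id"),
      data = cond_pre),
    first_egg = list(
      spec = model_spec("fed_z", sa, "gaussian"),
      data = nest_inf),
    clutch_size = list(
      spec = model_spec("clutch_size", c(sa, "fed_z"), "cmp"),
      data = nest_inf),
    n_fledglings = list(
      spec = model_spec("n_fledglings", c(sa, "fed_z"), "poisson"),
      data = nest_inf),
    nest_outcome = list(
      spec = model_spec("outcome01", c(sa, "fed_z"), "binomial"),
      data = nest_inf),
    fledging_prob = list(
      spec = model_spec("prop_fledged", c(sa, "fed_z"), "quasibinomial",
                        weights = "clutch_size"),
      data = dplyr::filter(nest_inf, .data$clutch_size > 0)),
    chick_condition = list(
      spec = model_spec("chick_condition", c(sa, "fed_z"), "gaussian"),
      data = dplyr::filter(nest_inf, !is.na(.data$chick_condition)))
  )
  specs <- specs[intersect(config$analyses, names(specs))]

  selection <- purrr::imap(specs, function(s, nm) {
    tryCatch(rank_subsets(s$spec, s$data),
             error = function(e) {
               message("analysis '", nm, "' failed: ", conditionMessage(e))
               NULL
             })
  })

  posthoc <- NULL
  sel_pre <- selection$cond_preincubation
  if (!is.null(sel_pre) &&
      "strategy:area" %in% attr(sel_pre, "final_terms")) {
    posthoc <- tryCatch(posthoc_contrasts(final_model(sel_pre)),
                        error = function(e) NULL)
  }

  structure(list(
    calls = calls,
    adult_calls = adult_calls,
    call_summary = call_summary,
    consistency = consistency,
    wing_model = wing_model,
    nests = nest_tab,
    condition = cond_fit,
    condition_inference = cond_inf,
    condition_preincubation = cond_pre,
    nest_inference = nest_inf,
    selection = selection,
    posthoc = posthoc,
    funnel = tibble::tibble(stage = names(funnel),
                            n = unlist(funnel, use.names = FALSE)),
    config = config
  ), class = "partmig_report")
}

#' @export
print.partmig_report <- function(x, ...) {
  cat("Partial-migration carryover analysis\n\n")
  cat("Strategy calls (adult, determined):",
      nrow(x$adult_calls), "bird-years (",
      sum(x$adult_calls$strategy == "migrant"), "migrant /",
      sum(x$adult_calls$strategy == "resident"), "resident )\n")
  cat("Conflicting bird-years:", sum(x$calls$conflict), "\n\n")
  cat("Final models:\n")
  for (nm in names(x$selection)) {
    st <- x$selection[[nm]]
    if (is.null(st)) { cat("  ", nm, ": <failed>\n"); next }
    cat(sprintf("  %-20s %s\n", nm, st$model[st$final]))
  }
  cat("\nFunnel:\n")
  print(as.data.frame(x$funnel), row.names = FALSE)
  invisible(x)
}

#' Isotope-cutoff sensitivity of the whole pipeline
#'
#' Re-runs the pipeline with the isotope cutoff shifted by each sensitivity
#' offset and reports, per cutoff and analysis, the selected final model, so
#' concordance across cutoffs can be checked directly (a well-separated
#' isotope distribution should leave every final model unchanged).
#'
#' @param tables input tables (see [run_pipeline()]).
#' @param config an [analysis_config()]; its rules carry the base cutoff and
#'   offsets.
#' @param analyses which analyses to run per cutoff (defaults to the
#'   config's).
#' @return tibble `cutoff`, `analysis`, `final_model`, plus the reports in a
#'   list-column.
#' @export
pipeline_sensitivity <- function(tables, config = analysis_config(),
                                 analyses = NULL) {
  rules <- config$rules
  cutoffs <- sort(c(rules$isotope_cutoff,
                    rules$isotope_cutoff + rules$sensitivity_offsets))
  purrr::map(cutoffs, function(co) {
    cfg <- config
    cfg$rules$isotope_cutoff <- co
    if (!is.null(analyses)) cfg$analyses <- analyses
    rep <- run_pipeline(tables, cfg)
    tibble::tibble(
      cutoff = co,
      analysis = names(rep$selection),
      final_model = vapply(rep$selection, function(st) {
        if (is.null(st)) NA_character_ else st$model[st$final]
      }, character(1)),
      report = list(rep)
    )
  }) |>
    purrr::list_rbind()
}
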