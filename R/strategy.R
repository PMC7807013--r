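#' Classification rules for migratory-strategy assignment
#'
#' Bundles the decision thresholds used by the three evidence streams. The
#' defaults encode the field protocol: a bird-year is labelled by the breeding
#' calendar year and its strategy is determined by the preceding winter window
#' (01 November of the previous year through 15 January, both ends inclusive).
#' A geolocator bird-year is resident when no window fix falls south of the
#' latitude floor (36 degrees N) and migrant when at least `min_southern_fixes`
#' window fixes fall south of the ceiling (23 degrees N). A feather with
#' delta-13C strictly above the cutoff (-20 permil) identifies a migrant;
#' isotopes never identify residents, because breeding-ground and
#' Sahelian-grown feathers overlap only on the depleted side.
#'
#' @param window_start,window_end winter-window boundaries as `"MM-DD"`
#'   strings; the start must fall late in the calendar year and the end early
#'   in the next.
#' @param resident_lat_floor,migrant_lat_ceiling latitude thresholds in
#'   decimal degrees north; the ceiling must lie south of the floor.
#' @param min_southern_fixes minimum number of window fixes south of the
#'   ceiling required for a migrant call (>= 1).
#' @param isotope_cutoff delta-13C cutoff in permil (strict inequality).
#' @param sensitivity_offsets offsets (permil) added to the cutoff by
#'   [sensitivity_analysis()].
#' @return a `strategy_rules` list.
#' @export
strategy_rules <- function(window_start = "11-01", window_end = "01-15",
                           resident_lat_floor = 36.0,
                           migrant_lat_ceiling = 23.0,
                           min_southern_fixes = 2L,
                           isotope_cutoff = -20.0,
                           sensitivity_offsets = c(-0.5, 0.5)) {
  parse_md <- function(x) {
    p <- as.integer(strsplit(x, "-", fixed = TRUE)[[1]])
    if (length(p) != 2L || anyNA(p) || p[1] < 1 || p[1] > 12 ||
        p[2] < 1 || p[2] > 31) {
      stop("window boundary must be 'MM-DD': got ", x, call. = FALSE)
    }
    p
  }
  smd <- parse_md(window_start); emd <- parse_md(window_end)
  if (smd[1] <= emd[1]) {
    stop("winter window must straddle the year boundary", call. = FALSE)
  }
  if (migrant_lat_ceiling >= resident_lat_floor) {
    stop("migrant latitude ceiling must lie south of the resident floor",
         call. = FALSE)
  }
  if (!is.finite(isotope_cutoff)) stop("isotope cutoff must be finite",
                                       call. = FALSE)
  if (min_southern_fixes < 1) stop("min_southern_fixes must be >= 1",
                                   call. = FALSE)
  structure(list(window_start = window_start, window_end = window_end,
                 resident_lat_floor = resident_lat_floor,
                 migrant_lat_ceiling = migrant_lat_ceiling,
                 min_southern_fixes = as.integer(min_southern_fixes),
                 isotope_cutoff = isotope_cutoff,
                 sensitivity_offsets = sensitivity_offsets),
            class = "strategy_rules")
}

#' Map dates to the breeding year whose winter window contains them
#'
#' Dates from `window_start` to 31 December belong to the following breeding
#' year; dates from 01 January to `window_end` belong to the current year.
#' Dates outside the window map to `NA`.
#'
#' @param dates a `Date` vector.
#' @param rules a [strategy_rules()] object.
#' @return integer breeding years (NA outside the window).
#' @export
winter_breeding_year <- function(dates, rules = strategy_rules()) {
  md <- format(dates, "%m-%d")
  yr <- as.integer(format(dates, "%Y"))
  dplyr::case_when(
    md >= rules$window_start ~ yr + 1L,
    md <= rules$window_end ~ yr,
    .default = NA_integer_
  )
}

#' Strategy verdicts from winter resightings
#'
#' An in-area resighting during the winter window yields a resident verdict
#' for the following breeding season; resightings outside the window yield no
#' verdict. Records flagged as wintering-ground sightings (column
#' `wintering_ground`, e.g. a bird seen in the Sahel) yield migrant verdicts
#' instead. In-area winter records can never produce a migrant verdict.
#'
#' @param resightings tibble with `bird_id`, `date` (Date) and optionally a
#'   logical `wintering_ground` column (defaults to all `FALSE`).
#' @param rules a [strategy_rules()] object.
#' @return tibble of per bird-year verdicts (`bird_id`, `year`, `verdict`,
#'   `stream`, `n_records`).
#' @export
classify_by_resighting <- function(resightings, rules = strategy_rules()) {
  if (anyNA(resightings$date)) {
    stop("undated resighting record(s) at row(s): ",
         paste(which(is.na(resightings$date)), collapse = ", "),
         call. = FALSE)
  }
  if (!"wintering_ground" %in% names(resightings)) {
    resightings$wintering_ground <- FALSE
  }
  resightings |>
    dplyr::mutate(year = winter_breeding_year(.data$date, rules)) |>
    dplyr::filter(!is.na(.data$year)) |>
    dplyr::mutate(verdict = dplyr::if_else(.data$wintering_ground,
                                           "migrant", "resident")) |>
    dplyr::summarise(
      verdict = if (dplyr::n_distinct(.data$verdict) == 1L)
        .data$verdict[1] else "unknown",
      n_records = dplyr::n(),
      .by = c("bird_id", "year")
    ) |>
    dplyr::mutate(stream = "resighting", .before = "n_records")
}

#' Strategy verdicts from geolocator position fixes
#'
#' Applies the latitude rules to winter-window fixes, per bird-year: resident
#' when no window fix lies south of the floor; migrant when at least
#' `min_southern_fixes` window fixes lie south of the ceiling; otherwise
#' unknown (intermediate latitudes). Bird-years appear in the output only when
#' they have at least one window fix -- pure absence of data is no evidence of
#' residency.
#'
#' @param fixes tibble with `bird_id`, `datetime` (Date or POSIXct),
#'   `latitude`, `longitude`.
#' @param rules a [strategy_rules()] object.
#' @return tibble of per bird-year verdicts with a `reason` column.
#' @export
classify_by_geolocator <- function(fixes, rules = strategy_rules()) {
  bad <- which(!is.finite(fixes$latitude) | abs(fixes$latitude) > 90)
  if (length(bad)) {
    stop("latitude out of bounds at row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  fixes |>
    dplyr::mutate(year = winter_breeding_year(as.Date(.data$datetime), rules)) |>
    dplyr::filter(!is.na(.data$year)) |>
    dplyr::summarise(
      n_fixes = dplyr::n(),
      n_south_floor = sum(.data$latitude < rules$resident_lat_floor),
      n_south_ceiling = sum(.data$latitude < rules$migrant_lat_ceiling),
      .by = c("bird_id", "year")
    ) |>
    dplyr::mutate(
      verdict = dplyr::case_when(
        .data$n_south_ceiling >= rules$min_southern_fixes ~ "migrant",
        .data$n_south_floor == 0L ~ "resident",
        .default = "unknown"
      ),
      reason = dplyr::case_when(
        .data$verdict == "migrant" ~ "southern fixes",
        .data$verdict == "resident" ~ "no fix south of floor",
        .default = "intermediate latitudes"
      ),
      stream = "geolocator"
    ) |>
    dplyr::select("bird_id", "year", "verdict", "stream", "n_fixes", "reason")
}

#' Strategy verdicts from feather stable isotopes
#'
#' A winter-grown feather with delta-13C strictly above the cutoff is assigned
#' Sahelian moult origin, identifying a migrant for the breeding season of the
#' collection year (the feather was grown in the preceding winter). Values at
#' or below the cutoff are indeterminate, never resident: enriched values are
#' diagnostic of sub-Saharan origin but depleted values can come from either
#' origin (some migrants moult before departure).
#'
#' @param feathers tibble with `bird_id`, `collection_year`, `d13c` (permil,
#'   VPDB). Values outside -40..0 permil raise a warning.
#' @param rules a [strategy_rules()] object (or use `cutoff` directly).
#' @param cutoff overrides `rules$isotope_cutoff` when supplied.
#' @return tibble of per bird-year verdicts (`migrant` or `indeterminate`).
#' @export
classify_by_isotope <- function(feathers, rules = strategy_rules(),
                                cutoff = NULL) {
  cutoff <- cutoff %||% rules$isotope_cutoff
  if (anyNA(feathers$d13c)) {
    stop("missing d13c at row(s): ",
         paste(which(is.na(feathers$d13c)), collapse = ", "), call. = FALSE)
  }
  if (any(feathers$d13c < -40 | feathers$d13c > 0)) {
    warning("d13c outside plausibility bounds (-40..0 permil) at row(s): ",
            paste(which(feathers$d13c < -40 | feathers$d13c > 0),
                  collapse = ", "), call. = FALSE)
  }
  feathers |>
    dplyr::summarise(d13c = max(.data$d13c),
                     .by = c("bird_id", "collection_year")) |>
    dplyr::transmute(
      bird_id = .data$bird_id,
      year = as.integer(.data$collection_year),
      verdict = dplyr::if_else(.data$d13c > cutoff, "migrant", "indeterminate"),
      stream = "isotope",
      d13c = .data$d13c
    )
}

#' Reconcile evidence streams into strategy calls
#'
#' Combines per bird-year verdicts from the resighting, geolocator and isotope
#' streams. All informative (migrant/resident) verdicts agreeing gives that
#' strategy; no informative verdict gives unknown; a resident and a migrant
#' verdict for the same bird-year gives unknown with the conflict flag set and
#' both evidence items retained -- conflicts are surfaced, never resolved by
#' precedence or vote.
#'
#' @param ... verdict tibbles from the `classify_by_*` functions (each with
#'   `bird_id`, `year`, `verdict`, `stream`).
#' @return a strategy-call tibble: `bird_id`, `year`, `strategy` (migrant /
#'   resident / unknown), `n_streams`, `evidence` (stream=verdict, semicolon
#'   separated), `conflict`.
#' @export
reconcile_strategies <- function(...) {
  verdicts <- dplyr::bind_rows(...)
  if (!nrow(verdicts)) {
    return(tibble::tibble(bird_id = character(), year = integer(),
                          strategy = character(), n_streams = integer(),
                          evidence = character(), conflict = logical()))
  }
  verdicts |>
    dplyr::summarise(
      evidence = paste0(.data$stream, "=", .data$verdict, collapse = ";"),
      n_streams = dplyr::n(),
      n_migrant = sum(.data$verdict == "migrant"),
      n_resident = sum(.data$verdict == "resident"),
      .by = c("bird_id", "year")
    ) |>
    dplyr::mutate(
      conflict = .data$n_migrant > 0L & .data$n_resident > 0L,
      strategy = dplyr::case_when(
        .data$conflict ~ "unknown",
        .data$n_migrant > 0L ~ "migrant",
        .data$n_resident > 0L ~ "resident",
        .default = "unknown"
      )
    ) |>
    dplyr::select("bird_id", "year", "strategy", "n_streams", "evidence",
                  "conflict") |>
    dplyr::arrange(.data$bird_id, .data$year)
}

#' Between-year consistency of individual strategies
#'
#' For individuals with at least two determined (non-unknown) bird-years,
#' tabulates whether the strategy was maintained or switched, and in which
#' direction. Individuals with a single determined year are excluded.
#'
#' @param calls a strategy-call tibble from [reconcile_strategies()].
#' @return tibble per multi-year individual (`bird_id`, `n_years`,
#'   `n_switches`, `pattern`); `pattern` is one of `consistent`,
#'   `migrant_to_resident`, `resident_to_migrant`, `mixed` (switches in both
#'   directions).
#' @export
strategy_consistency <- function(calls) {
  calls |>
    dplyr::filter(.data$strategy != "unknown") |>
    dplyr::arrange(.data$bird_id, .data$year) |>
    dplyr::filter(dplyr::n() >= 2L, .by = "bird_id") |>
    dplyr::summarise(
      n_years = dplyr::n(),
      mr = sum(.data$strategy[-dplyr::n()] == "migrant" &
                 .data$strategy[-1] == "resident"),
      rm = sum(.data$strategy[-dplyr::n()] == "resident" &
                 .data$strategy[-1] == "migrant"),
      .by = "bird_id"
    ) |>
    dplyr::mutate(
      n_switches = .data$mr + .data$rm,
      pattern = dplyr::case_when(
        .data$n_switches == 0L ~ "consistent",
        .data$mr > 0L & .data$rm > 0L ~ "mixed",
        .data$mr > 0L ~ "migrant_to_resident",
        .default = "resident_to_migrant"
      )
    ) |>
    dplyr::select("bird_id", "n_years", "n_switches", "pattern")
}

#' Sensitivity of strategy calls to the isotope cutoff
#'
#' Re-runs the isotope classification (and reconciliation with any other
#' streams supplied) at the base cutoff and at each offset, returning the full
#' strategy-call set per cutoff together with migrant counts. Because the
#' migrant rule is a strict threshold on delta-13C, the set of isotope-called
#' migrants can only shrink as the cutoff increases.
#'
#' @param feathers feather isotope tibble (see [classify_by_isotope()]).
#' @param rules a [strategy_rules()] object; its `sensitivity_offsets` define
#'   the perturbations.
#' @param other_verdicts optional list of verdict tibbles from the other
#'   streams, reconciled together with each isotope variant.
#' @return a tibble with one row per cutoff: `cutoff`, `n_migrant_isotope`,
#'   `n_migrant_total`, and the full call set in the `calls` list-column.
#' @export
sensitivity_analysis <- function(feathers, rules = strategy_rules(),
                                 other_verdicts = list()) {
  cutoffs <- sort(c(rules$isotope_cutoff,
                    rules$isotope_cutoff + rules$sensitivity_offsets))
  purrr::map(cutoffs, function(co) {
    iso <- classify_by_isotope(feathers, rules, cutoff = co)
    calls <- do.call(reconcile_strategies, c(list(iso), other_verdicts))
    tibble::tibble(
      cutoff = co,
      n_migrant_isotope = sum(iso$verdict == "migrant"),
      n_migrant_total = sum(calls$strategy == "migrant"),
      calls = list(calls)
    )
  }) |>
    purrr::list_rbind()
}
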