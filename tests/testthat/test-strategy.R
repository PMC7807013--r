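rules <- strategy_rules()

test_that("winter resightings map to the following breeding season", {
  rs <- tibble::tibble(
    bird_id = c("b1", "b1", "b2"),
    date = as.Date(c("2015-12-10", "2015-10-20", "2016-01-10")))
  v <- classify_by_resighting(rs, rules)
  expect_equal(nrow(v), 2L)
  expect_equal(v$year[v$bird_id == "b1"], 2016L)
  expect_equal(v$verdict[v$bird_id == "b1"], "resident")
  expect_equal(v$year[v$bird_id == "b2"], 2016L)
  # window boundaries are inclusive on both ends
  edge <- tibble::tibble(bird_id = c("e1", "e2"),
                         date = as.Date(c("2015-11-01", "2016-01-15")))
  ve <- classify_by_resighting(edge, rules)
  expect_equal(sort(ve$year), c(2016L, 2016L))
})

test_that("wintering-ground sightings yield migrant verdicts", {
  rs <- tibble::tibble(bird_id = "b9", date = as.Date("2016-12-20"),
                       wintering_ground = TRUE)
  v <- classify_by_resighting(rs, rules)
  expect_equal(v$verdict, "migrant")
  expect_equal(v$year, 2017L)
})

test_that("undated resightings are rejected with row references", {
  rs <- tibble::tibble(bird_id = c("b1", "b2"),
                       date = as.Date(c("2015-12-01", NA)))
  expect_error(classify_by_resighting(rs, rules), "row\\(s\\): 2")
})

test_that("geolocator latitude rules classify winter tracks", {
  mk <- function(id, lats) tibble::tibble(
    bird_id = id, datetime = as.Date("2015-12-01") + seq_along(lats),
    latitude = lats, longitude = -5)
  fx <- dplyr::bind_rows(mk("res", c(37.1, 36.8, 37.0)),
                         mk("mig", c(30.0, 14.2, 14.9)),
                         mk("amb", c(37.0, 30.0)))
  v <- classify_by_geolocator(fx, rules)
  expect_equal(v$verdict[v$bird_id == "res"], "resident")
  expect_equal(v$verdict[v$bird_id == "mig"], "migrant")
  expect_equal(v$verdict[v$bird_id == "amb"], "unknown")
  # a single southern fix is not enough for a migrant call
  v1 <- classify_by_geolocator(mk("one", c(14.0, 37.2, 37.1)), rules)
  expect_equal(v1$verdict, "unknown")
  # fixes outside the window yield no verdict rows
  out <- mk("off", c(14.0, 14.1))
  out$datetime <- as.Date(c("2015-06-01", "2015-07-01"))
  expect_equal(nrow(classify_by_geolocator(out, rules)), 0L)
  # out-of-bounds latitude rejected
  bad <- mk("bad", c(95, 37))
  expect_error(classify_by_geolocator(bad, rules), "out of bounds")
})

test_that("isotope rule identifies migrants only, strictly above the cutoff", {
  fe <- tibble::tibble(bird_id = c("a", "b", "c"),
                       collection_year = 2016L,
                       d13c = c(-18.0, -20.0, -24.5))
  v <- classify_by_isotope(fe, rules)
  expect_equal(v$verdict, c("migrant", "indeterminate", "indeterminate"))
  expect_false(any(v$verdict == "resident"))
  # sensitivity-shifted cutoff flips a near-threshold value
  v2 <- classify_by_isotope(tibble::tibble(bird_id = "a",
                                           collection_year = 2016L,
                                           d13c = -19.8),
                            rules, cutoff = -19.5)
  expect_equal(v2$verdict, "indeterminate")
  expect_error(
    classify_by_isotope(tibble::tibble(bird_id = "x",
                                       collection_year = 2016L,
                                       d13c = NA_real_), rules),
    "missing")
  expect_warning(
    classify_by_isotope(tibble::tibble(bird_id = "x",
                                       collection_year = 2016L,
                                       d13c = 3), rules),
    "plausibility")
})

test_that("reconciliation follows the agreement / conflict policy", {
  mk <- function(verdict, stream) tibble::tibble(
    bird_id = "b1", year = 2016L, verdict = verdict, stream = stream)
  # single stream
  c1 <- reconcile_strategies(mk("resident", "resighting"))
  expect_equal(c1$strategy, "resident")
  expect_false(c1$conflict)
  # agreement across streams
  c2 <- reconcile_strategies(mk("migrant", "isotope"),
                             mk("migrant", "geolocator"))
  expect_equal(c2$strategy, "migrant")
  # contradiction -> unknown + conflict, evidence retained
  c3 <- reconcile_strategies(mk("resident", "resighting"),
                             mk("migrant", "isotope"))
  expect_equal(c3$strategy, "unknown")
  expect_true(c3$conflict)
  expect_match(c3$evidence, "resighting=resident")
  expect_match(c3$evidence, "isotope=migrant")
  # indeterminate-only evidence -> unknown, no conflict
  c4 <- reconcile_strategies(mk("indeterminate", "isotope"))
  expect_equal(c4$strategy, "unknown")
  expect_false(c4$conflict)
})

test_that("reconcile matches the exhaustive truth-table oracle", {
  set.seed(42)
  opts <- list(resighting = c("resident", "migrant", NA),
               geolocator = c("resident", "migrant", "unknown", NA),
               isotope = c("migrant", "indeterminate", NA))
  for (rep in 1:50) {
    combo <- lapply(opts, sample, size = 1)
    tabs <- purrr::imap(combo, function(v, s) {
      if (is.na(v)) return(NULL)
      tibble::tibble(bird_id = "b", year = 2016L, verdict = v, stream = s)
    })
    tabs <- purrr::compact(tabs)
    if (!length(tabs)) next
    got <- do.call(reconcile_strategies, tabs)
    want <- oracle_reconcile(unlist(combo[!is.na(unlist(combo))]))
    expect_equal(got$strategy, want$strategy,
                 label = paste(unlist(combo), collapse = "/"))
    expect_equal(got$conflict, want$conflict)
  }
})

test_that("strategy consistency tabulates switches and excludes singletons", {
  calls <- tibble::tibble(
    bird_id = c("c1", "c1", "s1", "s1", "s2", "s2", "solo", "u1", "u1"),
    year = c(2015L, 2016L, 2015L, 2016L, 2015L, 2016L, 2015L, 2015L, 2016L),
    strategy = c("migrant", "migrant", "migrant", "resident",
                 "resident", "migrant", "migrant", "migrant", "unknown"),
    conflict = FALSE)
  cons <- strategy_consistency(calls)
  expect_false("solo" %in% cons$bird_id)   # one determined year
  expect_false("u1" %in% cons$bird_id)     # one determined year after unknowns
  expect_equal(cons$pattern[cons$bird_id == "c1"], "consistent")
  expect_equal(cons$pattern[cons$bird_id == "s1"], "migrant_to_resident")
  expect_equal(cons$pattern[cons$bird_id == "s2"], "resident_to_migrant")
})

test_that("isotope migrant calls are monotone in the cutoff", {
  set.seed(5)
  fe <- tibble::tibble(bird_id = sprintf("b%03d", 1:200),
                       collection_year = 2016L,
                       d13c = runif(200, -26, -14))
  sens <- sensitivity_analysis(fe, rules)
  expect_equal(sens$cutoff, c(-20.5, -20, -19.5))
  expect_true(all(diff(sens$n_migrant_isotope) <= 0))
  # set inclusion, not just counts
  mig_sets <- lapply(sens$calls, function(cc)
    cc$bird_id[cc$strategy == "migrant"])
  expect_true(all(mig_sets[[2]] %in% mig_sets[[1]]))
  expect_true(all(mig_sets[[3]] %in% mig_sets[[2]]))
  # the worked near-threshold sample
  one <- tibble::tibble(bird_id = "b", collection_year = 2016L, d13c = -19.8)
  s1 <- sensitivity_analysis(one, rules)
  expect_equal(s1$n_migrant_isotope, c(1L, 1L, 0L))
})
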