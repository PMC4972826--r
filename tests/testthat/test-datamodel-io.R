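test_that("event logs infer a lexicographic roster and validate records", {
  log <- tiny_event_log(list(c(1, "B", "A", 1), c(2, "A", "C", 2)))
  expect_s3_class(log, "event_log")
  expect_identical(log$roster, c("A", "B", "C"))
  expect_identical(nrow(log$events), 2L)

  expect_error(tiny_event_log(list(c(1, "A", "A", 1))), "winner and loser")
  expect_error(
    event_log(data.frame(day = 1, winner = "A", loser = "Z", vivarium = 1),
              roster = c("A", "B")),
    "not in the roster"
  )
  expect_error(tiny_event_log(list(c(-1, "A", "B", 1))), "positive integer")
})

test_that("reading a malformed event file names the offending line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("day,winner,loser,behavior,vivarium,zone",
               "5,A,A,fighting,1,top"), path)
  expect_error(read_event_log(path), "line 2")

  writeLines(c("day,winner,loser,behavior,vivarium,zone",
               "1,A,B,fighting,1,top",
               "2,B,Q,fighting,1,top"), path)
  expect_error(read_event_log(path, roster = c("A", "B")), "line 3")
})

test_that("a minimal event file parses and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("day,winner,loser,behavior,vivarium,zone",
               "1,A,B,fighting,1,top",
               "2,B,A,chasing,2,shelf"), path)
  log <- read_event_log(path)
  expect_identical(length(log$roster), 2L)
  expect_identical(nrow(log$events), 2L)

  out <- withr::local_tempfile(fileext = ".csv")
  write_event_log(log, out)
  back <- read_event_log(out)
  expect_identical(back$roster, log$roster)
  expect_identical(back$events$winner, log$events$winner)
  expect_identical(back$events$day, log$events$day)
})

test_that("a simulated colony round-trips bit-exactly through CSV", {
  col <- simulate_colony(sim_config(seed = 3))
  expect_identical(nrow(col$events$events), 1230L)
  expect_identical(length(col$events$roster), 30L)

  ev_path <- withr::local_tempfile(fileext = ".csv")
  write_event_log(col$events, ev_path)
  back <- read_event_log(ev_path, roster = col$events$roster)
  expect_identical(back$events$winner, col$events$events$winner)
  expect_identical(back$events$loser, col$events$events$loser)
  expect_identical(as.integer(back$events$vivarium),
                   as.integer(col$events$events$vivarium))
  expect_identical(frequency_matrix(back), frequency_matrix(col$events))

  cs_path <- withr::local_tempfile(fileext = ".csv")
  write_census_log(col$census, cs_path)
  back_cs <- read_census_log(cs_path, roster = col$census$roster)
  expect_identical(back_cs$sightings$id, col$census$sightings$id)
  expect_identical(length(back_cs$periods), length(col$census$periods))
})

test_that("census logs enforce one sighting per individual per period", {
  df <- data.frame(day = c(1, 1, 1), timepoint = "T1", vivarium = c(1, 1, 2),
                   id = c("A", "B", "A"))
  expect_warning(cl <- census_log(df), "duplicate")
  expect_identical(nrow(cl$sightings), 2L)
  expect_error(census_log(data.frame(day = 1, timepoint = "T1", vivarium = 1,
                                     id = "Z"), roster = c("A", "B")),
               "not in roster")
})

test_that("19 days of 3 censuses give 57 periods", {
  col <- simulate_colony(sim_config(seed = 11))
  expect_identical(length(col$census$periods), 57L)
})

test_that("the frequency matrix counts wins and conserves events", {
  log <- tiny_event_log(list(c(1, "A", "B", 1), c(1, "A", "B", 1),
                             c(2, "B", "C", 1)))
  m <- frequency_matrix(log)
  expect_identical(m["A", "B"], 2L)
  expect_identical(m["B", "C"], 1L)
  expect_identical(sum(m), 3L)

  empty <- event_log(data.frame(day = integer(), winner = character(),
                                loser = character(), vivarium = integer()),
                     roster = c("A", "B", "C"))
  expect_identical(sum(frequency_matrix(empty)), 0L)

  col <- simulate_colony(sim_config(seed = 5))
  expect_identical(sum(frequency_matrix(col$events)), 1230L)
})

test_that("binarization follows the Appleby tie rule", {
  f <- named_matrix(0L, 3)
  f["M01", "M02"] <- 3L; f["M02", "M01"] <- 1L   # decided
  f["M02", "M03"] <- 2L; f["M03", "M02"] <- 2L   # tied
  b <- binarize(f)
  expect_identical(b["M01", "M02"], 1L)
  expect_identical(b["M02", "M01"], 0L)
  expect_identical(b["M02", "M03"], 0L)
  expect_identical(b["M03", "M02"], 0L)
  expect_identical(sum(binarize(named_matrix(0L, 4))), 0L)
  # idempotent on already-binary antisymmetric input
  expect_identical(binarize(b), b)
})

test_that("every dyad of a binarized matrix is 0/1 in at most one direction", {
  set.seed(42)
  for (rep in 1:20) {
    f <- named_matrix(rpois(36, 2), 6)
    b <- binarize(f)
    expect_true(all(b + t(b) <= 1))
    expect_true(all(diag(b) == 0))
  }
})

test_that("symmetrization adds the transpose and is symmetric", {
  f <- named_matrix(0L, 3)
  f["M01", "M02"] <- 2L; f["M02", "M01"] <- 1L
  s <- symmetrize(f)
  expect_identical(s["M01", "M02"], 3L)
  expect_identical(s["M02", "M01"], 3L)
  set.seed(7)
  f2 <- named_matrix(rpois(25, 3), 5)
  expect_true(all(symmetrize(f2) == t(symmetrize(f2))))
})

test_that("roster-labelled matrices round-trip through TSV", {
  m <- matrix(c(0, 2, 1, 0), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, path)
  back <- read_matrix_tsv(path)
  expect_identical(dimnames(back), dimnames(m))
  expect_equal(unname(back), unname(m))
})

test_that("dyad classification separates decided, tied, and unknown", {
  f <- named_matrix(0L, 4)
  f["M01", "M02"] <- 3L                      # decided
  f["M02", "M03"] <- 2L; f["M03", "M02"] <- 2L  # tied
  ds <- dyad_summary(f)
  expect_identical(ds$n_decided, 1L)
  expect_identical(ds$n_tied, 1L)
  expect_identical(ds$n_unknown, 4L)
})
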