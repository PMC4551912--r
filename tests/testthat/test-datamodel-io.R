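# Data model validation and lossless CSV round-trips.

test_that("conditions validate units and control-well constraints", {
  expect_equal(canonical_concentration(2.6, "mM"), 2600)
  expect_equal(canonical_concentration(81, "nM"), 0.081)
  expect_equal(canonical_concentration(1, "percent"), 1)
  expect_error(canonical_concentration(1, "mg/mL"), "unknown concentration unit")
  expect_error(condition("AraC", concentration = -1), "concentration")
  expect_error(condition("AraC", is_control = TRUE), "control wells carry no sensor")
  expect_silent(condition(NA, is_control = TRUE))
})

test_that("well and plate constructors enforce their invariants", {
  expect_error(make_well(c(0, 10, 10), rep(0.1, 3), rep(1, 3)),
               "diff")
  expect_error(make_well(c(0, 10), rep(0.1, 2), c(1, 2, 3)),
               "length")
  w1 <- make_well(c(0, 10), c(0.1, 0.2), c(1, 2), well = "A1")
  w2 <- well_time_series(condition("S1"), c(0, 10), c(0.1, 0.2),
                         list(RFP = c(1, 2)), well = "A2")
  expect_error(plate_experiment(list(w1, w2)), "channel set")
  expect_error(plate_experiment(list(w1, w1)), "duplicated well")
})

test_that("a toy plate CSV round-trips through read_plate", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "plate.csv"); l1 <- file.path(dir, "layout.csv")
  exp <- make_flat_plate(c(10, 20), times = c(0, 10, 20))
  write_plate(exp, p1, layout = l1)
  back <- read_plate(p1, l1)
  expect_length(back$wells, 2)
  expect_length(back$wells[[1]]$times, 3)
  expect_equal(plate_data(back), plate_data(exp))
  expect_equal(plate_layout(back), plate_layout(exp))
  # byte identity of write . read . write
  p2 <- file.path(dir, "plate2.csv")
  write_plate(back, p2)
  expect_identical(readLines(p2), readLines(p1))
})

test_that("plate parsing rejects malformed inputs", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "plate.csv"); l1 <- file.path(dir, "layout.csv")
  exp <- make_flat_plate(c(10, 20), times = c(0, 10, 20))
  write_plate(exp, p1, layout = l1)
  # misspelled od600 column
  tab <- readr::read_csv(p1, show_col_types = FALSE)
  names(tab)[names(tab) == "od600"] <- "od"
  p_bad <- file.path(dir, "bad.csv")
  readr::write_csv(tab, p_bad)
  expect_error(read_plate(p_bad, l1), "od600")
  # data well missing from the layout
  tab2 <- readr::read_csv(p1, show_col_types = FALSE)
  tab2$well[1] <- "Z9"
  readr::write_csv(tab2, p_bad)
  expect_error(read_plate(p_bad, l1), "absent from layout")
  # duplicated timepoint within a well
  tab3 <- readr::read_csv(p1, show_col_types = FALSE)
  tab3$time_min[2] <- tab3$time_min[1]
  readr::write_csv(tab3, p_bad)
  expect_error(read_plate(p_bad, l1), "duplicated|time grid")
})

test_that("generator output round-trips byte-identically", {
  dir <- withr::local_tempdir()
  cfg <- library_config(sensors = "MphR", seed = 42, replicates = 2,
                        n_control_wells = 2)
  exp <- simulate_plate(cfg)
  p1 <- file.path(dir, "a.csv"); l1 <- file.path(dir, "lay.csv")
  p2 <- file.path(dir, "b.csv")
  write_plate(exp, p1, layout = l1)
  write_plate(read_plate(p1, l1), p2)
  expect_identical(readLines(p2), readLines(p1))
})

test_that("event tables validate and round-trip without reordering", {
  m <- matrix(c(5, 1, 9, 2, 8, 3, 7, 4, 6), nrow = 3,
              dimnames = list(NULL, c("GFP", "CFP", "mCherry")))
  s <- cytometry_sample("glucarate", m)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "events.csv")
  write_events(list(s), f)
  back <- read_events(f)
  expect_length(back, 1)
  # event (row) order preserved; channel columns come back alphabetical
  expect_equal(back[[1]]$events,
               s$events[, c("CFP", "GFP", "mCherry")])
  expect_equal(back[[1]]$n_events, 3)
  # duplicated (sample, event, channel) row
  tab <- readr::read_csv(f, show_col_types = FALSE)
  readr::write_csv(rbind(tab, tab[1, ]), f)
  expect_error(read_events(f), "duplicated")
  # ragged channels
  readr::write_csv(tab[-1, ], f)
  expect_error(read_events(f), "ragged")
})

test_that("a large synthetic cytometry sample round-trips losslessly", {
  s <- simulate_events(c("glucarate", "acrylate"), n_events = 10000,
                       seed = 7)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "e1.csv"); f2 <- file.path(dir, "e2.csv")
  write_events(list(s), f1)
  write_events(read_events(f1), f2)
  expect_identical(readLines(f2), readLines(f1))
})

test_that("variant tables round-trip", {
  v <- simulate_variants(seed = 3)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "v1.csv"); f2 <- file.path(dir, "v2.csv")
  write_variants(v, f1)
  write_variants(read_variants(f1), f2)
  expect_identical(readLines(f2), readLines(f1))
})

test_that("round-trips are lossless over randomized small experiments", {
  dir <- withr::local_tempdir()
  for (s in 1:5) {
    cfg <- library_config(sensors = sample(c("AraC", "TetR", "TtgR"), 1),
                          seed = s, replicates = sample(1:3, 1),
                          n_control_wells = sample(0:3, 1))
    exp <- simulate_plate(cfg)
    p1 <- file.path(dir, "r1.csv"); l1 <- file.path(dir, "rl.csv")
    p2 <- file.path(dir, "r2.csv")
    write_plate(exp, p1, layout = l1)
    write_plate(read_plate(p1, l1), p2)
    expect_identical(readLines(p2), readLines(p1))
  }
})
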