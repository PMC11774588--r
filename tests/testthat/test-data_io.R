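test_that("interval_days matches calendar arithmetic", {
  # 16 June -> 22 August: 14 (June) + 31 (July) + 22 = 67
  expect_identical(interval_days(as.Date("2013-06-16"),
                                 as.Date("2013-08-22")), 67L)
  # 22 August -> 16 June over a non-leap February: 298
  expect_identical(interval_days(as.Date("2013-08-22"),
                                 as.Date("2014-06-16")), 298L)
  # winter spanning 29 February 2016
  expect_identical(interval_days(as.Date("2015-08-22"),
                                 as.Date("2016-06-16")), 299L)
  expect_identical(interval_days(as.Date("2013-06-16"),
                                 as.Date("2013-06-17")), 1L)
  expect_error(interval_days(as.Date("2013-06-16"), as.Date("2013-06-16")),
               "positive")
})

test_that("nominal season day-counts are constant except leap-year winters", {
  for (y in 2012:2018) {
    occ <- occasion_grid(c(y, y, y + 1L), c("June", "August", "June"))
    ints <- season_intervals(occ)
    expect_equal(ints$n_days[1L], 67L)
    expect_true(ints$n_days[2L] %in% c(298L, 299L))
    # one summer + the following winter spans exactly one calendar year
    expect_equal(sum(ints$n_days),
                 as.integer(as.Date(sprintf("%d-06-16", y + 1L)) -
                              as.Date(sprintf("%d-06-16", y))))
  }
})

test_that("read_captures parses, infers the occasion grid and validates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("fish_id,cave_id,year,month,fork_length_mm",
               "F1,C1,2013,June,100",
               "F1,C1,2013,August,107",
               "F1,C1,2014,June,110"), f)
  res <- read_captures(f)
  expect_equal(nrow(res$captures), 3L)
  expect_equal(nrow(res$occasions), 3L)
  expect_equal(res$occasions$month, c("June", "August", "June"))
  expect_equal(res$captures$occasion, 1:3)

  # duplicate fish x occasion
  writeLines(c("fish_id,cave_id,year,month,fork_length_mm",
               "F1,C1,2013,June,100",
               "F1,C1,2013,June,102"), f)
  expect_error(read_captures(f), "duplicate fish x occasion")

  # out-of-window length names the row
  writeLines(c("fish_id,cave_id,year,month,fork_length_mm",
               "F1,C1,2013,June,100",
               "F2,C1,2013,June,20"), f)
  expect_error(read_captures(f), "plausibility window.*2")

  # unknown month tag
  writeLines(c("fish_id,cave_id,year,month,fork_length_mm",
               "F1,C1,2013,July,100"), f)
  expect_error(read_captures(f), "month tag")

  # a fish cannot move cave
  writeLines(c("fish_id,cave_id,year,month,fork_length_mm",
               "F1,C1,2013,June,100",
               "F1,C2,2013,August,104"), f)
  expect_error(read_captures(f), "more than one cave")
})

test_that("occasion grid enforces June/August alternation", {
  expect_error(occasion_grid(c(2013, 2014), c("June", "June")), "alternate")
  expect_error(occasion_grid(c(2013, 2013), c("June", "June")), "duplicate")
  g <- occasion_grid(c(2013, 2012), c("June", "August"))
  expect_equal(g$year, c(2012, 2013))  # sorted into calendar order
})

test_that("the inferred grid fills occasions with no captures", {
  # records a year apart: the semi-annual design still has the August
  # occasion in between
  L <- matrix(NA_real_, 1L, 2L); L[1L, ] <- c(100, 112)
  caps <- make_captures(L, c(2013, 2014), c("June", "June"))
  res <- validate_captures(caps)
  expect_equal(nrow(res$occasions), 3L)
  expect_equal(res$occasions$month, c("June", "August", "June"))
  expect_equal(res$captures$occasion, c(1L, 3L))
})

test_that("build_panel derives latent support and intervals", {
  years <- c(2013, 2013, 2014, 2014, 2015, 2015)
  months <- rep(c("June", "August"), 3L)
  L <- matrix(NA_real_, 3L, 6L)
  L[1L, c(2L, 5L)] <- c(100, 118)   # seen at occasions 2 and 5 only
  L[2L, 3L] <- 90                   # single capture
  L[3L, c(1L, 6L)] <- c(80, 120)    # anchors the six-occasion grid
  caps <- make_captures(L, years, months)
  panel <- build_panel(validate_captures(caps),
                       full_temp_grid("C01", 2013:2015))
  expect_equal(panel$fish$first_occasion, c(2L, 3L, 1L))
  expect_equal(panel$fish$last_occasion, c(5L, 3L, 6L))
  # fish 1: latent support {2,3,4,5} -> 3 intervals; fish 2: none
  expect_equal(n_growth_intervals(panel), 3L + 0L + 5L)

  # interval count ignores interior observation gaps
  L2 <- L
  L2[1L, 3:4] <- c(104, 110)
  panel2 <- build_panel(validate_captures(make_captures(L2, years, months)),
                        full_temp_grid("C01", 2013:2015))
  expect_equal(n_growth_intervals(panel2), n_growth_intervals(panel))
  expect_equal(n_growth_intervals(panel2),
               sum(panel2$fish$last_occasion - panel2$fish$first_occasion))

  # missing temperature cells are flagged for augmentation, and absent
  # rows (as opposed to missing values) are an error
  tg <- full_temp_grid("C01", 2013:2015)
  tg$mean_temp_C[c(1L, 4L)] <- NA
  p3 <- build_panel(validate_captures(caps), tg)
  expect_equal(p3$n_missing_temp, 2L)
  expect_error(build_panel(validate_captures(caps), tg[tg$year != 2014, ]),
               "season-year")
})

test_that("a 320-cell grid with 86 missing flags 86 cells", {
  tg <- full_temp_grid(sprintf("C%02d", 1:20), 2012:2019)
  expect_equal(nrow(tg), 320L)
  tg$mean_temp_C[seq_len(86L)] <- NA
  caps <- make_captures(matrix(c(100, 107), 1L, 2L), c(2013, 2013),
                        c("June", "August"), cave = "C01")
  panel <- build_panel(validate_captures(caps), tg)
  expect_equal(panel$n_missing_temp, 86L)
})

test_that("write-then-read round trips are field-for-field identical", {
  sim <- small_sim()
  d <- withr::local_tempdir()
  write_captures(sim$captures, file.path(d, "c.csv"))
  write_temperatures(sim$temperatures, file.path(d, "t.csv"))
  write_repeats(sim$repeats, file.path(d, "r.csv"))
  caps2 <- read_captures(file.path(d, "c.csv"))$captures
  expect_equal(caps2$fish_id, sim$captures$fish_id)
  expect_equal(caps2$fork_length_mm, sim$captures$fork_length_mm)
  expect_equal(caps2$year, sim$captures$year)
  expect_equal(caps2$month, sim$captures$month)
  temps2 <- read_temperatures(file.path(d, "t.csv"))
  expect_equal(temps2$mean_temp_C, sim$temperatures$mean_temp_C)
  expect_equal(temps2$cave_id, sim$temperatures$cave_id)
  reps2 <- read_repeats(file.path(d, "r.csv"))
  expect_equal(reps2$fork_length_mm, sim$repeats$fork_length_mm)
})

test_that("actual capture dates override nominal interval lengths", {
  caps <- tibble::tibble(
    fish_id = c("F1", "F1"), cave_id = "C01", year = 2013,
    month = c("June", "August"), fork_length_mm = c(100, 106),
    capture_date = as.Date(c("2013-06-20", "2013-08-20")))
  panel <- build_panel(validate_captures(caps),
                       full_temp_grid("C01", 2013))
  expect_equal(panel$days[1L, 1L], 61)
  # without dates the nominal 67 applies
  caps$capture_date <- as.Date(NA)
  panel2 <- build_panel(validate_captures(caps),
                        full_temp_grid("C01", 2013))
  expect_equal(panel2$days[1L, 1L], 67)
})

test_that("remove_observations masks only interior captures", {
  years <- c(2013, 2013, 2014)
  months <- c("June", "August", "June")
  L <- matrix(c(100, 104, 110), 1L, 3L)
  panel <- build_panel(validate_captures(make_captures(L, years, months)),
                       full_temp_grid("C01", 2013:2014))
  p2 <- remove_observations(panel, data.frame(fish_id = "F001", occasion = 2L))
  expect_true(is.na(p2$obs[1L, 2L]))
  expect_equal(p2$fish$first_occasion, 1L)  # support unchanged
  expect_error(remove_observations(panel,
                                   data.frame(fish_id = "F001", occasion = 1L)),
               "interior")
})
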