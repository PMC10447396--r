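test_that("exclusion cascade is the identity on clean input and idempotent", {
  w <- sim_world(tiny_cfg(seed = 4))
  out <- apply_exclusions(w$records)
  expect_equal(out$report$retained, nrow(w$records))
  expect_true(all(out$report$removed == 0))
  expect_equal(out$report$input,
               out$report$retained + sum(out$report$removed))
  again <- apply_exclusions(out$records)
  expect_true(all(again$report$removed == 0))
  expect_equal(again$records$record_id, out$records$record_id)
})

test_that("exclusion report reproduces injected defect counts", {
  w <- sim_world(tiny_cfg(seed = 5))
  counts <- c(duplicates = 5, out_of_extent = 2, non_summer = 10,
              under_5 = 3, missing = 1)
  noisy <- inject_cascade_noise(w$records, counts, seed = 6)
  out <- apply_exclusions(noisy)
  expect_equal(unname(out$report$removed),
               c(5, 2, 10, 3, 1))
  expect_equal(out$report$retained, nrow(w$records))
  js <- jsonlite::fromJSON(exclusion_report_json(out$report))
  expect_equal(js$removed$non_summer, 10)
})

test_that("rules apply in fixed order: a non-summer 4-year-old counts as non-summer", {
  w <- sim_world(tiny_cfg(seed = 7))
  rec <- w$records[1, ]
  rec$record_id <- "RX99999"
  rec$age <- 4L
  rec$date <- as.Date("2003-05-10")     # both under-5 and non-summer
  both <- rbind(w$records, rec)
  attr(both, "extent") <- attr(w$records, "extent")
  out <- apply_exclusions(both)
  expect_equal(unname(out$report$removed["non_summer"]), 1L)
  expect_equal(unname(out$report$removed["under_age"]), 0L)
})

test_that("empty retained set raises an explicit error", {
  w <- sim_world(tiny_cfg(seed = 8))
  rec <- w$records
  rec$date <- as.Date("2003-05-01")     # everything non-summer
  attr(rec, "extent") <- attr(w$records, "extent")
  expect_error(apply_exclusions(rec), "empty cohort")
})

test_that("daily mean is (Tmin + Tmax) / 2, checked by independent scan", {
  cfg <- tiny_cfg()
  temp <- make_temperature_surface(cfg)
  temp$tmin[1, 1] <- 10; temp$tmax[1, 1] <- 20
  temp$tmin[2, 2] <- temp$tmax[2, 2] <- 7.3
  tm <- compute_daily_mean(temp)
  expect_equal(tm[1, 1], 15)
  expect_equal(tm[2, 2], 7.3)
  # brute-force re-aggregation over every cell-day
  expect_equal(mean(tm), mean((temp$tmin + temp$tmax) / 2))
  temp$tmin[3, 3] <- NA
  expect_true(is.na(compute_daily_mean(temp)[3, 3]))
})

test_that("location fuzz is a uniform draw on the disc", {
  set.seed(11)
  expect_equal(fuzz_location(3, 4, radius = 0), data.frame(x = 3, y = 4))
  set.seed(11)
  f <- fuzz_location(rep(5, 10000), rep(5, 10000), radius = 0.1)
  d2 <- (f$x - 5)^2 + (f$y - 5)^2
  expect_true(all(d2 <= 0.1^2 + 1e-12))
  # mean squared displacement of a uniform disc is radius^2 / 2
  expect_lt(abs(mean(d2) - 0.1^2 / 2), 0.0002)
})

test_that("cell assignment is half-open and matches a brute-force scan", {
  cfg <- tiny_cfg()
  temp <- make_temperature_surface(cfg)
  # centre of the cell in row 4, col 3 (0-based origin at the corner)
  expect_equal(assign_cell(2.5, 3.5, temp), (4 - 1) * 11 + 3)
  # a point on a shared boundary belongs to the lower/left-inclusive cell
  expect_equal(assign_cell(3, 3.5, temp), (4 - 1) * 11 + 4)
  expect_equal(assign_cell(0, 0, temp), 1L)
  expect_error(assign_cell(11, 1, temp), "linkage error")
  set.seed(12)
  x <- runif(500, 0, 11); y <- runif(500, 0, 11)
  got <- assign_cell(x, y, temp)
  brute <- vapply(seq_along(x), function(i) {
    hit <- which(temp$cells$x0 <= x[i] & x[i] < temp$cells$x0 + 1 &
                   temp$cells$y0 <= y[i] & y[i] < temp$cells$y0 + 1)
    temp$cells$cell[hit]
  }, integer(1))
  expect_equal(got, brute)
})

test_that("lag-averaged exposure matches hand-computed windows", {
  cfg <- tiny_cfg(constant_field = 15)
  temp <- make_temperature_surface(cfg)
  rec <- list(date = as.Date("2003-07-10"), cell = 5L)
  expect_equal(lagged_mean_exposure(rec, temp, 0:3), 15)
  expect_equal(lagged_mean_exposure(rec, temp, c(2L)), 15)
  # plant known values on days d-3..d at one cell
  d <- as.Date("2003-07-10")
  idx <- match(d - 3:0, temp$dates)
  temp$tmin[5, idx] <- temp$tmax[5, idx] <- c(10, 12, 14, 16)
  expect_equal(lagged_mean_exposure(rec, temp, 0:3), 13)
  # a June 1 event with lags 0..5 reaches back into late May
  rec2 <- list(date = as.Date("2003-06-01"), cell = 7L)
  tm <- compute_daily_mean(temp)
  manual <- mean(tm[7, match(as.Date("2003-06-01") - 5:0, temp$dates)])
  expect_equal(lagged_mean_exposure(rec2, temp, 0:5), manual)
  # missing required day: error names the date
  expect_error(lagged_mean_exposure(list(date = as.Date("2003-06-01"),
                                         cell = 1L), temp, 0:7),
               "2003-05-2")
})

test_that("linkage attaches covariates, age groups and periods correctly", {
  w <- sim_linked(tiny_cfg(seed = 13), fuzz_radius = 0)
  lk <- w$linked
  # holiday flag agrees with the calendar
  expect_equal(lk$holiday, as.integer(as.Date(lk$date) %in% w$holidays))
  # same-day coarse covariates agree with a direct lookup
  i <- which.max(lk$age)
  di <- match(as.Date(lk$date[i]), w$cov$dates)
  expect_equal(lk$humidity[i], w$cov$humidity[1, di])  # single coarse cell
  # age grouping boundaries as printed: 15 is a child, 16 working age
  expect_equal(as.character(age_group_of(c(5, 15, 16, 64, 65))),
               c("5-15", "5-15", "16-64", "16-64", "65+"))
  # period cut-points on the study analogue
  pb <- list("2002-2007" = 2002:2007, "2008-2013" = 2008:2013,
             "2014-2019" = 2014:2019)
  expect_equal(period_of(c(2007, 2008, 2019), pb),
               c("2002-2007", "2008-2013", "2014-2019"))
})

test_that("exposure lies within the window extremes and linkage is pure", {
  w <- sim_linked(tiny_cfg(seed = 14))
  tm <- compute_daily_mean(w$temp)
  ok <- vapply(seq_len(nrow(w$linked)), function(i) {
    win <- tm[w$linked$cell[i],
              match(as.Date(w$linked$date[i]) - 3:0, w$temp$dates)]
    w$linked$x_lag[i] >= min(win) - 1e-12 &&
      w$linked$x_lag[i] <= max(win) + 1e-12
  }, logical(1))
  expect_true(all(ok))
  again <- link_records(w$clean$records, w$temp, w$cov, w$holidays,
                        fuzz_radius = 0.1, seed = w$cfg$seed)
  expect_identical(as.data.frame(w$linked), as.data.frame(again))
})

test_that("fuzzing never pushes a record off the grid", {
  w <- sim_world(tiny_cfg(seed = 15))
  rec <- w$records
  rec$x[1] <- 10.9999; rec$y[1] <- 0.0001   # hugging the boundary
  cl <- apply_exclusions(rec)
  lk <- link_records(cl$records, w$temp, w$cov, w$holidays, seed = 99)
  expect_true(all(lk$x_fuzz >= 0 & lk$x_fuzz < 11))
  expect_true(all(lk$y_fuzz >= 0 & lk$y_fuzz < 11))
})
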