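test_that("well-formed CSV parses completely; malformed timestamps are counted", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("station_id,city_id,timestamp,value",
               "s1,qingdao,2018-01-12T00:00:00+0800,35.5",
               "s1,qingdao,2018-01-12T01:00:00+0800,40.25",
               "s2,busan,2018-01-12T01:00:00+0900,12"), f)
  rec <- load_station_records(f)
  expect_equal(nrow(rec), 3L)
  expect_equal(attr(rec, "rejects"), 0L)
  # offsets are honoured: 01:00 at +0900 is the same instant as 00:00 at +0800
  expect_equal(rec$time[3], rec$time[1])

  writeLines(c("station_id,city_id,timestamp,value",
               "s1,qingdao,2018-01-12T00:00:00+0800,35.5",
               "s1,qingdao,not-a-time,40",
               "s1,qingdao,2018-01-12T02:00:00+0800,41"), f)
  rec <- load_station_records(f)
  expect_equal(nrow(rec), 2L)
  expect_equal(attr(rec, "rejects"), 1L)
  expect_equal(attr(rec, "reject_rows"), 2L)
})

test_that("missing columns and unreadable files raise informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sid,city_id,timestamp,value", "s1,a,2018-01-01T00:00:00,1"), f)
  expect_error(load_station_records(f), "station_id")
  expect_error(load_station_records(file.path(tempdir(), "no-such-file.csv")),
               "cannot read")
})

test_that("simulated records round-trip losslessly through write/read", {
  sim <- simulate(chain_scenario(n_cities = 2, spacing_km = 100), seed = 11)
  f <- withr::local_tempfile(fileext = ".csv")
  write_station_records(sim$records, f, tz_offset_hours = 8)
  back <- load_station_records(f)
  expect_equal(attr(back, "rejects"), 0L)
  expect_equal(nrow(back), nrow(sim$records))
  expect_equal(back$station_id, sim$records$station_id)
  expect_equal(as.numeric(back$time), as.numeric(sim$records$time))
  expect_identical(back$value, sim$records$value)
})

test_that("qc removes zeros, >1000 outliers and duplicates per the screening rules", {
  t0 <- as.POSIXct("2018-01-01 00:00:00", tz = "UTC")
  rec <- data.frame(
    station_id = c("s1", "s1", "s1", "s1", "s1", "s1", "s2", "s2"),
    city_id = "a",
    time = t0 + c(0, 1, 2, 3, 3, 4, 4, 4) * 3600,
    value = c(1250, 1000, 0, 50, 50, NA, 60, 70),
    stringsAsFactors = FALSE)
  res <- qc_filter(rec)
  r <- res$report
  expect_equal(r[["n_outlier"]], 1L)      # 1250 strictly above the cap
  expect_equal(r[["n_zero"]], 1L)
  expect_equal(r[["n_missing"]], 1L)
  expect_equal(r[["n_duplicate"]], 1L)    # exact (s1, t3, 50) pair collapses
  expect_equal(r[["n_conflict"]], 2L)     # (s2, t4) reports 60 and 70: both dropped
  expect_true(1000 %in% res$records$value)  # boundary value retained
  # count conservation across removal classes
  expect_equal(r[["n_retained"]] +
                 sum(r[c("n_missing", "n_zero", "n_outlier",
                         "n_duplicate", "n_conflict")]),
               r[["n_input"]])
})

test_that("qc is idempotent and errors when nothing survives", {
  sim <- simulate(chain_scenario(n_cities = 3), seed = 3)
  once <- qc_filter(sim$records)
  twice <- qc_filter(once$records)
  expect_identical(twice$records, once$records)
  expect_equal(twice$report[["n_retained"]], once$report[["n_retained"]])
  expect_equal(sum(twice$report[c("n_missing", "n_zero", "n_outlier",
                                  "n_duplicate", "n_conflict")]), 0L)

  bad <- data.frame(station_id = "s1", city_id = "a",
                    time = as.POSIXct("2018-01-01", tz = "UTC"), value = 0)
  expect_error(qc_filter(bad), "empty after QC")
})

test_that("station averaging takes per-hour means over reporting stations", {
  t0 <- as.POSIXct("2018-01-01 00:00:00", tz = "UTC")
  rec <- data.frame(
    station_id = c("s1", "s2", "s1", "s1", "s2"),
    city_id = "a",
    time = t0 + c(0, 0, 1, 3, 3) * 3600,
    value = c(10, 20, 30, 8, 12),
    stringsAsFactors = FALSE)
  s <- average_stations(rec, "a", tz_offset_hours = 8)
  expect_equal(s$values, c(15, 30, NA, 10))  # hour 2: no station reporting
  expect_error(average_stations(rec, "nowhere"), "unknown city_id")
})

test_that("station averaging matches a brute-force per-hour mean oracle", {
  set.seed(41)
  t0 <- as.POSIXct("2018-03-01 00:00:00", tz = "UTC")
  n_h <- 72
  rec <- do.call(rbind, lapply(1:4, function(sid) {
    hrs <- sort(sample(0:(n_h - 1), 50))
    data.frame(station_id = paste0("s", sid), city_id = "a",
               time = t0 + hrs * 3600,
               value = runif(50, 5, 900), stringsAsFactors = FALSE)
  }))
  s <- average_stations(rec, "a")
  hrs_all <- as.numeric(rec$time - t0, units = "hours")
  h_min <- min(hrs_all)
  for (h in unique(hrs_all)) {
    expect_equal(s$values[h - h_min + 1],
                 mean(rec$value[hrs_all == h]), tolerance = 1e-12)
  }
})

test_that("timezone relabelling shifts wall clocks, preserves instants and values", {
  v <- runif(48, 10, 90)
  s9 <- site_series("busan", as.POSIXct("2018-01-11 15:00:00", tz = "UTC"), v, 9L)
  s8 <- align_timezone(s9, 8L)
  expect_equal(s8$values, s9$values)
  expect_equal(as.numeric(s8$start), as.numeric(s9$start))  # instants untouched
  expect_equal(as.numeric(wall_times(s9) - wall_times(s8), units = "hours"),
               rep(1, 48))  # +9 labels sit one hour later than +8 labels
  expect_identical(align_timezone(s9, 9L), s9)               # identity
  expect_identical(align_timezone(align_timezone(s9, 8L), 9L), s9)  # inverse
})

test_that("station averaging commutes with timezone relabelling", {
  sim <- simulate(chain_scenario(n_cities = 2), seed = 5)
  qc <- qc_filter(sim$records)
  a <- align_timezone(average_stations(qc$records, "city1", 8), 9)
  b <- average_stations(qc$records, "city1", 9)
  expect_equal(a$values, b$values)
  expect_equal(as.numeric(a$start), as.numeric(b$start))
})

test_that("monthly windows have exact calendar length and a completeness flag", {
  v <- rep(50, 24 * 400)
  s <- site_series("a", as.POSIXct("2017-12-31 16:00:00", tz = "UTC"), v, 8L)
  jan <- window_series(s, 2018, 1)
  expect_equal(length(jan), 744L)
  expect_true(attr(jan, "usable"))
  expect_equal(attr(jan, "completeness"), 1)
  feb <- window_series(s, 2018, 2)
  expect_equal(length(feb), 672L)
  # wall-clock midnight Jan 1 in CST is 16:00 UTC Dec 31
  expect_equal(format(wall_times(jan)[1], "%Y-%m-%d %H", tz = "UTC"),
               "2018-01-01 00")

  v2 <- v; v2[seq(1, length(v2), by = 2)] <- NA  # 50% missing
  s2 <- site_series("a", s$start, v2, 8L)
  jan2 <- window_series(s2, 2018, 1, completeness_min = 0.75)
  expect_false(attr(jan2, "usable"))
  expect_equal(attr(jan2, "completeness"), 0.5)
})
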