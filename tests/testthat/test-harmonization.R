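test_that("event windows reproduce the 9:10 a.m. worked example", {
  t <- mk_times("2023-04-03 09:10:00")
  w <- expand_event_window(t, 15)
  expect_equal(format(w$start, "%H:%M"), "08:55")
  expect_equal(format(w$end, "%H:%M"), "09:25")
  # duration is exactly 2H for any H
  for (h in c(5, 10, 15, 20, 30)) {
    wh <- expand_event_window(t, h)
    expect_equal(as.numeric(difftime(wh$end, wh$start, units = "mins")), 2 * h)
  }
  # windows cross midnight
  w0 <- expand_event_window(mk_times("2023-04-03 00:05:00"), 10)
  expect_equal(format(w0$start, "%Y-%m-%d %H:%M"), "2023-04-02 23:55")
  expect_equal(format(w0$end, "%H:%M"), "00:15")
  expect_error(expand_event_window(t, 0), "half_time")
})

test_that("window membership is closed-boundary and handles overlap via union", {
  w <- expand_event_window(mk_times(c("2023-04-03 09:10:00", "2023-04-03 09:30:00")), 15)
  ft <- mk_times(c("2023-04-03 09:00:00",  # inside first
                   "2023-04-03 09:25:00",  # exact end of first = inside
                   "2023-04-03 08:55:00",  # exact start = inside
                   "2023-04-03 09:50:00",  # > 09:45 end of second
                   "2023-04-03 08:54:59")) # just before start
  expect_equal(label_samples(ft, w), c(1L, 1L, 1L, 0L, 0L))
})

test_that("labeling equals the brute-force membership oracle on random streams", {
  for (seed in 1:100) {
    st <- random_stream(seed)
    w <- expand_event_window(st$reports$timestamp, sample(c(5, 10, 15, 20, 30), 1))
    expect_identical(label_samples(st$fixes$timestamp, w),
                     brute_labels(st$fixes$timestamp, w))
  }
})

test_that("smoking-labeled sets nest as the half-time grows", {
  for (seed in 1:20) {
    st <- random_stream(seed)
    prev <- NULL
    for (h in c(5, 10, 15, 20, 30)) {
      lab <- label_samples(st$fixes$timestamp,
                           expand_event_window(st$reports$timestamp, h))
      if (!is.null(prev)) expect_true(all(lab[prev == 1L] == 1L))
      prev <- lab
    }
  }
})

test_that("fallback samples copy the nearest fix, earlier fix on ties", {
  w <- expand_event_window(mk_times("2023-04-03 09:10:00"), 15)  # [08:55, 09:25]
  fixes <- data.frame(timestamp = mk_times(c("2023-04-03 08:30:00",
                                             "2023-04-03 10:00:00")),
                      lat = c(1, 2), lon = c(10, 20))
  fb <- attach_fallback_samples(w, fixes)
  expect_equal(nrow(fb), 1)
  expect_equal(fb$lat, 1)  # 08:30 is 25 min before start; 10:00 is 35 min after end
  expect_equal(format(fb$timestamp, "%H:%M"), "09:10")  # window center
  # equidistant: earlier fix wins
  fixes2 <- data.frame(timestamp = mk_times(c("2023-04-03 08:25:00",
                                              "2023-04-03 09:55:00")),
                       lat = c(5, 6), lon = c(50, 60))
  expect_equal(attach_fallback_samples(w, fixes2)$lat, 5)
  # a window with an interior fix adds nothing
  fixes3 <- data.frame(timestamp = mk_times("2023-04-03 09:00:00"), lat = 1, lon = 1)
  expect_equal(nrow(attach_fallback_samples(w, fixes3)), 0)
  expect_warning(attach_fallback_samples(w, fixes3[0, ]), "no GPS fixes")
})

test_that("temporal features follow the documented calendar rules", {
  f <- temporal_featurize(mk_times("2023-04-03 09:10:00"))  # Monday
  expect_equal(f$bin, 36)  # floor(550 / 15)
  expect_equal(as.character(f$day_of_week), "Mon")
  expect_equal(f$is_weekend, 0L)
  expect_equal(as.character(f$season), "spring")
  sat <- temporal_featurize(mk_times("2021-07-03 12:00:00"))
  expect_equal(sat$is_weekend, 1L)
  expect_equal(as.character(sat$season), "summer")
  expect_equal(as.character(temporal_featurize(mk_times("2021-12-04 12:00:00"))$season),
               "winter")
  # half-hour bins
  expect_equal(temporal_featurize(mk_times("2023-04-03 09:10:00"), 30)$bin, 18)
  expect_error(temporal_featurize(as.POSIXct("2023-04-03 09:10:00", tz = ""), tz = ""),
               "timezone")
})

test_that("per-day bin labels match the quarter-hour worked example", {
  w <- expand_event_window(mk_times("2023-04-03 09:10:00"), 15)
  v <- interval_overlap_labels(w, as.Date("2023-04-03"), 15, "America/Chicago")
  expect_length(v, 96)
  expect_equal(which(v == 1L) - 1L, c(35L, 36L, 37L))  # 08:45, 09:00, 09:15 bins
  v30 <- interval_overlap_labels(w, as.Date("2023-04-03"), 30, "America/Chicago")
  expect_length(v30, 48)
  # zero-measure touch does not set a bin: window ending exactly at 09:15
  w2 <- expand_event_window(mk_times("2023-04-03 09:00:00"), 15)  # [08:45, 09:15]
  v2 <- interval_overlap_labels(w2, as.Date("2023-04-03"), 15, "America/Chicago")
  expect_equal(v2[38], 0L)  # bin 37 = 09:15-09:30
  expect_equal(which(v2 == 1L) - 1L, c(35L, 36L))
  # no windows -> all zero
  expect_equal(sum(interval_overlap_labels(w[0, ], as.Date("2023-04-03"), 15,
                                           "America/Chicago")), 0)
})

test_that("bin structure is stable across DST transition days", {
  tz <- "America/Chicago"
  for (day in as.Date(c("2023-03-12", "2023-11-05", "2023-06-01"))) {
    w <- expand_event_window(as.POSIXct(paste(format(as.Date(day, origin = "1970-01-01")),
                                              "12:10:00"), tz = tz), 15)
    v <- interval_overlap_labels(w, as.Date(day, origin = "1970-01-01"), 15, tz)
    expect_length(v, 96)
    expect_equal(sum(v), 3)
  }
})

test_that("pre-quit restriction is strict and validates ordering", {
  st <- random_stream(7)
  q <- st$fixes$timestamp[30]
  res <- restrict_to_prequit(st, q)
  expect_equal(nrow(res$fixes), sum(as.numeric(st$fixes$timestamp) < as.numeric(q)))
  expect_false(any(as.numeric(res$fixes$timestamp) >= as.numeric(q)))
  expect_false(any(as.numeric(res$reports$timestamp) >= as.numeric(q)))
  # identity when everything is pre-quit
  res2 <- restrict_to_prequit(st, max(st$fixes$timestamp) + 1e6)
  expect_equal(nrow(res2$fixes), nrow(st$fixes))
  # a report exactly at the quit time is dropped
  st3 <- mk_stream(mk_times(c("2023-04-03 09:00:00", "2023-04-03 10:00:00")),
                   mk_times("2023-04-03 11:00:00"))
  res3 <- restrict_to_prequit(st3, mk_times("2023-04-03 11:00:00"))
  expect_equal(nrow(res3$reports), 0)
})

test_that("stream parsing validates columns and counts malformed rows", {
  dir <- withr::local_tempdir()
  gps <- file.path(dir, "g.csv"); rep <- file.path(dir, "r.csv")
  writeLines(c("participant_id,timestamp,lat,lon",
               "P01,2023-04-03T09:00:00-0500,40.0,-90.0",
               "P01,not-a-time,40.1,-90.1",
               "P01,2023-04-03T08:00:00-0500,40.2,-90.2"), gps)
  writeLines(c("participant_id,timestamp,place,reason",
               "P01,2023-04-03T09:05:00-0500,home,habit"), rep)
  meta <- data.frame(participant_id = "P01", timezone = "America/Chicago")
  expect_warning(st <- parse_event_stream(gps, rep, meta), "1 row")
  expect_equal(st$n_malformed, 1L)
  expect_equal(nrow(st$fixes), 2)
  expect_true(!is.unsorted(as.numeric(st$fixes$timestamp)))
  # missing column named in the error
  writeLines(c("participant_id,timestamp,lat", "P01,2023-04-03T09:00:00-0500,40.0"), gps)
  expect_error(parse_event_stream(gps, rep, meta), "lon")
  # zero parseable fixes -> empty-stream error
  writeLines("participant_id,timestamp,lat,lon", gps)
  expect_error(suppressWarnings(parse_event_stream(gps, rep, meta)), "no GPS fixes")
})

test_that("sample tables match a row-by-row recomputation oracle", {
  for (seed in 1:50) {
    st <- random_stream(seed, n_fixes = 40, n_reports = 6)
    h <- sample(c(5, 10, 15, 20, 30), 1)
    tab <- build_sample_table(st, h)
    # row conservation
    w <- expand_event_window(st$reports$timestamp, h)
    ft <- as.numeric(st$fixes$timestamp)
    empty_windows <- sum(vapply(seq_len(nrow(w)), function(i) {
      !any(ft >= as.numeric(w$start[i]) & ft <= as.numeric(w$end[i]))
    }, logical(1)))
    expect_equal(nrow(tab), nrow(st$fixes) + empty_windows)
    expect_gte(nrow(tab), nrow(st$fixes))
    # independent per-row label recomputation for the non-fallback rows
    real <- tab[tab$is_fallback == 0, ]
    expect_equal(real$label, brute_labels(real$timestamp, w))
    expect_true(all(tab$label[tab$is_fallback == 1] == 1L))
    # bin recomputation per row
    lt <- as.POSIXlt(tab$timestamp, tz = st$timezone)
    expect_equal(tab$bin, (lt$hour * 60 + lt$min) %/% 15)
  }
})

test_that("a stream without reports yields an all-nonsmoking table", {
  st <- mk_stream(mk_times(c("2023-04-03 09:00:00", "2023-04-03 10:00:00")),
                  mk_times(character(0)))
  tab <- build_sample_table(st, 15)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$label == 0L))
  expect_equal(attr(tab, "n_fallback"), 0)
})
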