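test_that("generator config validates its fields by name", {
  expect_error(generator_config(n_participants = 0), "n_participants")
  expect_error(generator_config(days_mean = -1), "days_mean")
  expect_error(generator_config(rho_redundancy = 1.5), "rho_redundancy")
  expect_error(generator_config(mobility_factor = 0), "mobility_factor")
  expect_error(generator_config(n_anchors_range = c(3, 2)), "n_anchors_range")
})

test_that("zero habit concentration gives an exactly uniform habit profile", {
  cfg <- generator_config(n_participants = 3, beta_time = 0, seed = 5)
  for (i in 1:3) {
    prof <- sample_participant_profile(cfg, i)
    expect_equal(prof$habit_profile, rep(1 / 96, 96), tolerance = 1e-12)
  }
})

test_that("profiles are deterministic and well-formed", {
  cfg <- generator_config(seed = 9)
  p1 <- sample_participant_profile(cfg, 3)
  p2 <- sample_participant_profile(cfg, 3)
  expect_identical(p1, p2)
  expect_length(p1$habit_profile, 96)
  expect_equal(sum(p1$habit_profile), 1, tolerance = 1e-9)
  expect_gte(nrow(p1$anchors), 1)
  expect_gte(p1$study_days, 3)
  # adding participants never perturbs earlier ones
  cfg_small <- generator_config(n_participants = 5, seed = 9)
  expect_identical(sample_participant_profile(cfg_small, 3), p1)
})

test_that("study day draws match the configured truncated normal", {
  cfg <- generator_config(n_participants = 1000, seed = 42)
  days <- vapply(1:1000, function(i) sample_participant_profile(cfg, i)$study_days,
                 numeric(1))
  se <- sd(days) / sqrt(length(days))
  expect_lt(abs(mean(days) - 13.65), 3 * se + 0.02)  # +truncation shift bound
  expect_true(all(days >= 3))
})

test_that("a stationary participant emits fixes only at report times", {
  cfg <- generator_config(n_participants = 1, n_anchors_range = c(1, 1),
                          gps_noise_sd_m = 0, seed = 2)
  prof <- sample_participant_profile(cfg, 1)
  rt <- local_midnight_at(prof) + c(10, 20, 30) * 3600
  mob <- simulate_mobility(prof, cfg, report_times = rt)
  expect_equal(nrow(mob$fixes), 3)
  expect_equal(as.numeric(mob$fixes$timestamp), as.numeric(rt))
  expect_equal(mob$fixes$lat, rep(unname(prof$anchors[1, 1]), 3))
})

test_that("every transition beyond the 100-ft threshold emits a fix", {
  cfg <- generator_config(n_participants = 1, n_anchors_range = c(2, 2),
                          anchor_spread_m = 1000, gps_noise_sd_m = 0,
                          move_rate = 1, rho_redundancy = 0, seed = 3)
  prof <- sample_participant_profile(cfg, 1)
  # force anchors exactly 1 km apart
  prof$anchors[2, ] <- prof$anchors[1, ] + c(1000 / 111320, 0)
  mob <- simulate_mobility(prof, cfg)
  occ <- mob$occupancy
  transitions <- sum(diff(occ$anchor) != 0)
  expect_gt(transitions, 0)
  expect_equal(nrow(mob$fixes), transitions)
})

test_that("zero base rate produces zero events", {
  cfg <- generator_config(n_participants = 1, base_rate = 0, seed = 4)
  prof <- sample_participant_profile(cfg, 1)
  mob <- simulate_mobility(prof, cfg)
  ev <- simulate_smoking_events(prof, mob$occupancy, cfg)
  expect_equal(nrow(ev$reports), 0)
  expect_equal(nrow(ev$truth), 0)
})

test_that("a concentrated habit confines events to the peak neighborhood", {
  # single sharp peak: compare the realized bin distribution against direct
  # numerical integration of the stated intensity over the occupancy steps
  cfg <- generator_config(n_participants = 1, beta_time = 8, beta_loc = 0,
                          rate_heterogeneity_sd = 0, report_jitter_sd_min = 0,
                          base_rate = 3, days_mean = 60, days_sd = 0, seed = 6)
  prof <- sample_participant_profile(cfg, 1)
  # impose a single-peak profile with the config's concentration
  kappa <- 2.5 * cfg$beta_time
  b <- 0:95; center <- 60
  prof$habit_profile <- exp(kappa * cos(2 * pi * (b - center) / 96))
  prof$habit_profile <- prof$habit_profile / sum(prof$habit_profile)
  mob <- simulate_mobility(prof, cfg)
  ev <- simulate_smoking_events(prof, mob$occupancy, cfg)
  expect_gt(nrow(ev$truth), 500)
  bins <- (as.POSIXlt(ev$truth$true_time, tz = prof$timezone)$hour * 60 +
             as.POSIXlt(ev$truth$true_time, tz = prof$timezone)$min) %/% 15
  in_peak <- abs(bins - center) <= 3
  expect_gte(mean(in_peak), 0.9)
  # oracle: expected share from the intensity itself
  hstd <- (prof$habit_profile - mean(prof$habit_profile)) / sd(prof$habit_profile)
  occ <- mob$occupancy
  waking <- occ$hour >= 7 & occ$hour < 23
  w <- exp(cfg$beta_time * hstd[occ$qh_bin[waking] + 1])
  expected_share <- sum(w[abs(occ$qh_bin[waking] - center) <= 3]) / sum(w)
  expect_equal(mean(in_peak), expected_share, tolerance = 0.05)
})

test_that("privacy offset is a pure translation preserving local geometry", {
  st <- random_stream(31)
  f0 <- st$fixes
  f1 <- apply_privacy_offset(f0, offset = c(0, 0))
  expect_equal(f1$lat, f0$lat)
  f2 <- apply_privacy_offset(f0, seed = 99)
  off <- attr(f2, "offset")
  expect_equal(f2$lat - f0$lat, rep(off[1], nrow(f0)))
  expect_equal(f2$lon - f0$lon, rep(off[2], nrow(f0)))
  expect_identical(f2$timestamp, f0$timestamp)
  # pairwise distances preserved to within the cos(lat) projection drift
  i <- seq(1, nrow(f0), by = 7); j <- rev(i)
  d0 <- great_circle_distance(f0$lat[i], f0$lon[i], f0$lat[j], f0$lon[j])
  d2 <- great_circle_distance(f2$lat[i], f2$lon[i], f2$lat[j], f2$lon[j])
  drift <- abs(off[1]) * pi / 180 * tan(mean(f0$lat) * pi / 180) + 1e-9
  expect_lt(max(abs(d2 - d0) / pmax(d0, 1)), 2 * drift + 1e-6)
})

test_that("cohort generation is reproducible and writes the expected files", {
  cfg <- generator_config(n_participants = 2, seed = 7)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  generate_cohort(cfg, out_dir = dir1)
  generate_cohort(cfg, out_dir = dir2)
  expect_setequal(list.files(dir1),
                  c("P01_gps.csv", "P01_reports.csv", "P02_gps.csv",
                    "P02_reports.csv", "metadata.csv", "ground_truth"))
  for (f in setdiff(list.files(dir1, recursive = TRUE), NULL)) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)),
                     info = f)
  }
})

test_that("reports stay inside the observation window", {
  coh <- generate_cohort(generator_config(n_participants = 4, seed = 13))
  for (i in seq_along(coh$streams)) {
    s <- coh$streams[[i]]
    expect_true(all(as.numeric(s$reports$timestamp) >= as.numeric(s$window_start)))
    expect_true(all(as.numeric(s$reports$timestamp) < as.numeric(s$window_end)))
    # ground truth maps one-to-one onto emitted reports
    expect_equal(nrow(coh$ground_truth[[i]]$events), nrow(s$reports))
  }
})

test_that("the redundancy knob controls time-location mutual information", {
  cfg1 <- generator_config(n_participants = 1, rho_redundancy = 1,
                           n_anchors_range = c(3, 3), days_mean = 30,
                           days_sd = 0, seed = 21)
  cfg0 <- generator_config(n_participants = 1, rho_redundancy = 0,
                           n_anchors_range = c(3, 3), days_mean = 30,
                           days_sd = 0, seed = 21)
  p1 <- sample_participant_profile(cfg1, 1)
  occ1 <- simulate_mobility(p1, cfg1)$occupancy
  occ0 <- simulate_mobility(sample_participant_profile(cfg0, 1), cfg0)$occupancy
  mi1 <- occupancy_mutual_information(occ1)
  mi0 <- occupancy_mutual_information(occ0)
  expect_gt(mi1, mi0)
  # rho = 1: anchor is a deterministic function of hour, so the MI equals
  # the entropy of the scheduled-anchor distribution (the maximum)
  w <- occ1$hour >= 7 & occ1$hour < 23
  tab <- table(occ1$anchor[w]) / sum(w)
  expect_equal(mi1, -sum(tab * log(tab)), tolerance = 1e-6)
  # rho = 0: indistinguishable from independence under permutation.
  # Subsample to one step per hour so occupancy autocorrelation does not
  # invalidate the exchangeable permutation null.
  sub <- occ0[seq(1, nrow(occ0), by = 12), ]
  mi_sub <- occupancy_mutual_information(sub)
  w0 <- sub$hour >= 7 & sub$hour < 23
  null_mi <- withr::with_seed(1, replicate(199, {
    perm <- sub
    perm$anchor[w0] <- sample(perm$anchor[w0])
    occupancy_mutual_information(perm)
  }))
  p_perm <- (1 + sum(null_mi >= mi_sub)) / 200
  expect_gt(p_perm, 0.05)
})
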