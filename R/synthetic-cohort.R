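# Synthetic cohort generator.
#
# The generative model is deliberately minimal: each participant owns a small
# set of anchor locations (home, work, ...), a deterministic hour-of-day ->
# anchor routine, a circular time-of-day habit profile over the 96
# quarter-hour bins, and an anchor preference. Occupancy evolves on a 5-min
# step; smoking events are drawn from an inhomogeneous Poisson process whose
# log-intensity is linear in the standardized habit profile and the
# standardized anchor preference. A redundancy knob interpolates between
# occupancy fully determined by hour of day and occupancy independent of it,
# so both a time-dominant/location-redundant cohort and its converse can be
# realized with known ground truth.

#' Draw one participant's generative profile
#'
#' Deterministic given `(config$seed, participant_index)`: the profile of a
#' given participant never changes when the cohort grows.
#'
#' @param config a [generator_config()].
#' @param participant_index 1-based index, `<= config$n_participants`.
#' @return a `participant_profile` list: anchors (matrix of lat/lon),
#'   `habit_profile` (96 nonnegative weights summing to 1),
#'   `anchor_preference`, a 24-hour `schedule` (anchor index per hour),
#'   enrollment window, timezone, group and `study_days`.
#' @export
sample_participant_profile <- function(config, participant_index) {
  stopifnot(inherits(config, "generator_config"))
  if (!is_count(participant_index) || participant_index < 1 ||
      participant_index > config$n_participants) {
    stop_config("participant_index", "must be in 1..n_participants")
  }
  with_seed(substream_seed(config$seed, participant_index, 1L), {
    # observation window: truncated normal, at least 3 days
    repeat {
      study_days <- stats::rnorm(1, config$days_mean, config$days_sd)
      if (study_days >= 3) break
    }

    n_during <- round(config$prop_during * config$n_participants)
    group <- if (participant_index <= n_during) "during" else "post"
    enrollment_date <- if (group == "during") {
      as.Date("2022-06-01") + floor(stats::runif(1, 0, 345))  # .. 2023-05-11
    } else {
      as.Date("2023-05-12") + floor(stats::runif(1, 0, 203))  # .. 2023-11-30
    }
    timezone <- sample(c("America/New_York", "America/Chicago",
                         "America/Denver", "America/Los_Angeles"),
                       1, prob = c(0.50, 0.39, 0.08, 0.03))

    # anchors around a home base; home first
    ks <- seq(config$n_anchors_range[1], config$n_anchors_range[2])
    k <- if (length(ks) == 1L) ks else sample(ks, 1)
    base_lat <- stats::runif(1, 33, 45)
    base_lon <- stats::runif(1, -118, -80)
    m_per_deg_lat <- 111320
    m_per_deg_lon <- 111320 * cos(base_lat * pi / 180)
    anchors <- cbind(
      lat = base_lat + c(0, stats::rnorm(k - 1, 0, config$anchor_spread_m / m_per_deg_lat)),
      lon = base_lon + c(0, stats::rnorm(k - 1, 0, config$anchor_spread_m / m_per_deg_lon))
    )

    pref <- stats::rgamma(k, shape = 2) + 0.3
    pref[1] <- pref[1] * 2  # home bias
    pref <- pref / sum(pref)

    # deterministic hour -> anchor routine; nights at home
    schedule <- rep(1L, 24)
    if (!is.null(config$visit_schedule)) {
      if (ncol(config$visit_schedule) < k) {
        stop_config("visit_schedule", "fewer columns than participant anchors")
      }
      for (h in WAKING_START_H:(WAKING_END_H - 1L)) {
        w <- config$visit_schedule[h + 1L, seq_len(k)]
        schedule[h + 1L] <- if (sum(w) > 0) sample(seq_len(k), 1, prob = w) else 1L
      }
    } else {
      for (h0 in seq(WAKING_START_H, WAKING_END_H - 1L, by = 3L)) {
        a <- sample(seq_len(k), 1, prob = pref)
        schedule[(h0 + 1L):min(h0 + 3L, WAKING_END_H)] <- a
      }
    }

    # circular habit profile: 1-4 wrapped peaks over the 96 quarter-hour bins,
    # concentration scaled by beta_time (0 => exactly uniform)
    n_peaks <- sample(1:4, 1)
    waking_bins <- (WAKING_START_H * 4):(WAKING_END_H * 4 - 1)
    centers <- sample(waking_bins, n_peaks)
    mix <- stats::rgamma(n_peaks, shape = 2)
    mix <- mix / sum(mix)
    kappa <- 2.5 * config$beta_time
    b <- 0:95
    habit <- rowSums(sapply(seq_len(n_peaks), function(j) {
      mix[j] * exp(kappa * cos(2 * pi * (b - centers[j]) / 96))
    }))
    habit <- habit / sum(habit)

    structure(list(
      participant_id = sprintf("P%02d", participant_index),
      participant_index = as.integer(participant_index),
      anchors = anchors,
      habit_profile = habit,
      anchor_preference = pref,
      schedule = schedule,
      enrollment_date = enrollment_date,
      timezone = timezone,
      group = group,
      study_days = study_days
    ), class = "participant_profile")
  })
}

anchor_place_names <- function(k) {
  nm <- c("home", "work", if (k > 2) sprintf("place_%d", 3:k))
  nm[seq_len(k)]
}

#' Simulate movement-triggered GPS recording for one participant
#'
#' Occupancy evolves on a 5-minute step over the observation window: outside
#' waking hours (07:00-23:00) the participant is at home; during waking hours
#' each step relocates with probability `mobility_factor * move_rate`, the new
#' anchor coming from the hour's deterministic schedule with probability
#' `rho_redundancy` and otherwise from the time-independent anchor
#' preference. A GPS fix is emitted whenever true displacement since the last
#' emitted fix exceeds `fix_threshold_ft` (1 ft = 0.3048 m), and at every
#' supplied report time; emitted positions carry Gaussian noise
#' `gps_noise_sd_m`.
#'
#' @param profile a [sample_participant_profile()] result.
#' @param config the [generator_config()].
#' @param seed RNG substream seed; defaults to the participant's mobility
#'   substream.
#' @param report_times optional POSIXct vector of smoking-report times at
#'   which fixes are additionally emitted.
#' @return list with `fixes` (data.frame: timestamp, lat, lon), `occupancy`
#'   (data.frame: time, hour, qh_bin, anchor per 5-min step) and the window
#'   bounds `window_start`, `window_end`.
#' @export
simulate_mobility <- function(profile, config, seed = NULL, report_times = NULL) {
  stopifnot(inherits(profile, "participant_profile"))
  if (nrow(profile$anchors) < 1) stop_config("anchors", "participant has no anchors")
  if (is.null(seed)) {
    seed <- substream_seed(config$seed, profile$participant_index, 2L)
  }
  tz <- profile$timezone
  window_start <- local_midnight(profile$enrollment_date, tz)
  window_end <- window_start + round(profile$study_days * 86400)

  step_s <- OCCUPANCY_STEP_MIN * 60
  times <- seq(window_start, window_end - 1, by = step_s)
  lt <- as.POSIXlt(times, tz = tz)
  hour <- lt$hour
  qh_bin <- (lt$hour * 60 + lt$min) %/% 15L
  waking <- hour >= WAKING_START_H & hour < WAKING_END_H
  k <- nrow(profile$anchors)
  n <- length(times)

  with_seed(seed, {
    # candidate anchor at steps where the position is (re)decided; elsewhere
    # carried forward. Nights force home (anchor 1).
    p_move <- config$mobility_factor * config$move_rate
    sched_anchor <- pmin(profile$schedule[hour + 1L], k)
    # relocation is reconsidered at random and, additionally, whenever the
    # scheduled anchor changes (routine-block boundaries), so that full
    # redundancy (rho = 1) makes occupancy an exact function of the hour
    sched_change <- c(TRUE, sched_anchor[-1L] != sched_anchor[-n])
    redraw <- waking & (stats::runif(n) < p_move | sched_change)
    redraw[1] <- TRUE
    use_sched <- stats::runif(n) < config$rho_redundancy
    drawn <- integer(n)
    idx <- which(redraw)
    if (length(idx)) {
      free_draw <- sample.int(k, length(idx), replace = TRUE,
                              prob = profile$anchor_preference)
      drawn[idx] <- ifelse(use_sched[idx], sched_anchor[idx], free_draw)
    }
    anchor <- integer(n)
    anchor[!waking] <- 1L
    decided <- !waking | redraw
    anchor[redraw & waking] <- drawn[redraw & waking]
    # forward-fill undecided steps from the last decided one
    pos <- cummax(ifelse(decided, seq_len(n), 0L))
    anchor <- anchor[pos]

    occupancy <- data.frame(time = times, hour = hour, qh_bin = qh_bin,
                            anchor = anchor)

    thr_m <- config$fix_threshold_ft * FT_TO_M
    change_pts <- which(c(TRUE, anchor[-1] != anchor[-n]))
    emit_t <- .POSIXct(numeric(0), tz = tz)
    emit_a <- integer(0)
    last_xy <- NULL
    for (i in change_pts) {
      a <- anchor[i]
      xy <- profile$anchors[a, ]
      if (is.null(last_xy)) {
        # no fix before first displacement beyond threshold; remember start
        last_xy <- xy
        next
      }
      d <- great_circle_distance(last_xy[1], last_xy[2], xy[1], xy[2])
      if (d > thr_m) {
        emit_t <- c(emit_t, times[i])
        emit_a <- c(emit_a, a)
        last_xy <- xy
      }
    }

    if (!is.null(report_times) && length(report_times)) {
      ri <- pmin(pmax(findInterval(as.numeric(report_times), as.numeric(times)), 1L), n)
      emit_t <- c(emit_t, report_times)
      emit_a <- c(emit_a, anchor[ri])
    }

    ord <- order(as.numeric(emit_t))
    emit_t <- emit_t[ord]; emit_a <- emit_a[ord]
    lat <- profile$anchors[emit_a, 1]
    lon <- profile$anchors[emit_a, 2]
    if (config$gps_noise_sd_m > 0 && length(emit_t)) {
      m_per_deg_lat <- 111320
      m_per_deg_lon <- 111320 * cos(mean(profile$anchors[, 1]) * pi / 180)
      lat <- lat + stats::rnorm(length(emit_t), 0, config$gps_noise_sd_m / m_per_deg_lat)
      lon <- lon + stats::rnorm(length(emit_t), 0, config$gps_noise_sd_m / m_per_deg_lon)
    }
    fixes <- data.frame(timestamp = .POSIXct(as.numeric(emit_t), tz = tz),
                        lat = as.numeric(lat), lon = as.numeric(lon))
    list(fixes = fixes, occupancy = occupancy,
         window_start = window_start, window_end = window_end)
  })
}

#' Simulate smoking events from habit and location preference
#'
#' Events follow an inhomogeneous Poisson process over waking hours whose
#' intensity is proportional to
#' `base_rate * exp(beta_time * h(t) + beta_loc * g(anchor(t)))`, where `h`
#' is the standardized (z-scored) habit profile at the quarter-hour bin of
#' `t` and `g` the standardized anchor preference of the occupied anchor.
#' The exponential modulation is normalized to unit time-average over the
#' participant's waking steps, so the expected event count equals
#' `base_rate * waking_hours` regardless of the betas; a per-participant
#' log-normal multiplier (mean 1) adds realistic between-person spread.
#' Reported timestamps are the true times plus Gaussian jitter
#' (`report_jitter_sd_min`), clipped to the observation window.
#'
#' @param profile participant profile.
#' @param occupancy the occupancy timeline from [simulate_mobility()].
#' @param config the [generator_config()].
#' @param seed RNG substream seed; default the participant's event substream.
#' @return list with `reports` (data.frame: timestamp, place, reason) sorted
#'   by reported time, and `truth` (data.frame: true_time, reported_time,
#'   anchor) in the same order.
#' @export
simulate_smoking_events <- function(profile, occupancy, config, seed = NULL) {
  stopifnot(inherits(profile, "participant_profile"))
  if (is.null(seed)) {
    seed <- substream_seed(config$seed, profile$participant_index, 3L)
  }
  tz <- profile$timezone
  waking <- occupancy$hour >= WAKING_START_H & occupancy$hour < WAKING_END_H
  occ <- occupancy[waking, , drop = FALSE]

  h <- profile$habit_profile
  hstd <- if (stats::sd(h) > 0) (h - mean(h)) / stats::sd(h) else rep(0, 96)
  g <- profile$anchor_preference
  gstd <- if (length(g) > 1 && stats::sd(g) > 0) (g - mean(g)) / stats::sd(g) else rep(0, length(g))

  with_seed(seed, {
    mult <- if (config$rate_heterogeneity_sd > 0) {
      stats::rlnorm(1, -config$rate_heterogeneity_sd^2 / 2, config$rate_heterogeneity_sd)
    } else 1
    w <- exp(config$beta_time * hstd[occ$qh_bin + 1L] + config$beta_loc * gstd[occ$anchor])
    z <- mean(w)
    mu <- config$base_rate * mult * (OCCUPANCY_STEP_MIN / 60) * w / z
    counts <- stats::rpois(nrow(occ), mu)
    idx <- rep(seq_len(nrow(occ)), counts)
    n_ev <- length(idx)
    if (n_ev == 0) {
      reports <- data.frame(timestamp = .POSIXct(numeric(0), tz = tz),
                            place = character(0), reason = character(0))
      truth <- data.frame(true_time = .POSIXct(numeric(0), tz = tz),
                          reported_time = .POSIXct(numeric(0), tz = tz),
                          anchor = integer(0))
      return(list(reports = reports, truth = truth))
    }
    true_t <- as.numeric(occ$time[idx]) + stats::runif(n_ev, 0, OCCUPANCY_STEP_MIN * 60)
    rep_t <- true_t + stats::rnorm(n_ev, 0, config$report_jitter_sd_min * 60)
    w_start <- as.numeric(occupancy$time[1])
    w_end <- as.numeric(occupancy$time[nrow(occupancy)]) + OCCUPANCY_STEP_MIN * 60
    rep_t <- pmin(pmax(rep_t, w_start), w_end - 1)
    anchors_ev <- occ$anchor[idx]
    ord <- order(rep_t)
    place <- anchor_place_names(nrow(profile$anchors))[anchors_ev]
    reason <- sample(c("habit", "stress", "boredom", "social"), n_ev,
                     replace = TRUE, prob = c(0.45, 0.25, 0.2, 0.1))
    list(
      reports = data.frame(timestamp = .POSIXct(rep_t[ord], tz = tz),
                           place = place[ord], reason = reason[ord]),
      truth = data.frame(true_time = .POSIXct(true_t[ord], tz = tz),
                         reported_time = .POSIXct(rep_t[ord], tz = tz),
                         anchor = anchors_ev[ord])
    )
  })
}

#' Apply a per-participant privacy offset to GPS fixes
#'
#' Adds one constant (delta lat, delta lon) to every fix, emulating the
#' coordinate anonymization used by movement-logging apps: absolute positions
#' are hidden while relative geometry within a participant is preserved (up
#' to the small change of the local metric with latitude). Timestamps are
#' untouched.
#'
#' @param fixes data.frame with `lat`, `lon` columns.
#' @param seed seed for drawing the offset (uniform in +/-0.2 degrees).
#' @param offset optional explicit `c(dlat, dlon)`; overrides `seed`.
#' @return the fixes with shifted coordinates; the offset used is attached as
#'   attribute `"offset"`.
#' @export
apply_privacy_offset <- function(fixes, seed = 1L, offset = NULL) {
  if (nrow(fixes) < 1) stop("privacy offset requires at least one fix", call. = FALSE)
  if (is.null(offset)) {
    offset <- with_seed(seed, stats::runif(2, -0.2, 0.2))
  }
  fixes$lat <- fixes$lat + offset[1]
  fixes$lon <- fixes$lon + offset[2]
  attr(fixes, "offset") <- offset
  fixes
}

#' Generate a synthetic smoking cohort
#'
#' Draws every participant's profile, mobility, smoking events and privacy
#' offset from per-participant substreams of the master seed, and (optionally)
#' writes the cohort to disk as one GPS CSV and one reports CSV per
#' participant plus a cohort metadata CSV and one ground-truth JSON per
#' participant. Identical config and seed give byte-identical files.
#'
#' @param config a [generator_config()].
#' @param out_dir optional directory to write the cohort to.
#' @return an object of class `smoking_cohort`: `streams` (per participant:
#'   `fixes`, `reports`, `metadata`, `occupancy`), `metadata` (cohort
#'   data.frame incl. quit datetimes), `ground_truth` (per participant:
#'   truth table, habit profile, anchors, schedule, anchor preference) and
#'   the `config`.
#' @examples
#' coh <- generate_cohort(generator_config(n_participants = 2, seed = 7))
#' coh
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  streams <- vector("list", config$n_participants)
  truth <- vector("list", config$n_participants)
  meta_rows <- vector("list", config$n_participants)

  for (i in seq_len(config$n_participants)) {
    prof <- sample_participant_profile(config, i)
    mob <- simulate_mobility(prof, config)
    ev <- simulate_smoking_events(prof, mob$occupancy, config)

    # report-time fixes: position of the occupied anchor at the true event
    # time, with GPS noise (separate substream so fix and event counts are
    # independent of one another's draws)
    rep_fix <- with_seed(substream_seed(config$seed, i, 4L), {
      nr <- nrow(ev$truth)
      if (nr == 0) {
        data.frame(timestamp = .POSIXct(numeric(0), tz = prof$timezone),
                   lat = numeric(0), lon = numeric(0))
      } else {
        xy <- prof$anchors[ev$truth$anchor, , drop = FALSE]
        lat <- xy[, 1]; lon <- xy[, 2]
        if (config$gps_noise_sd_m > 0) {
          m_lat <- 111320
          m_lon <- 111320 * cos(mean(prof$anchors[, 1]) * pi / 180)
          lat <- lat + stats::rnorm(nr, 0, config$gps_noise_sd_m / m_lat)
          lon <- lon + stats::rnorm(nr, 0, config$gps_noise_sd_m / m_lon)
        }
        data.frame(timestamp = ev$truth$reported_time, lat = as.numeric(lat),
                   lon = as.numeric(lon))
      }
    })

    fixes <- rbind(mob$fixes, rep_fix)
    fixes <- fixes[order(as.numeric(fixes$timestamp)), , drop = FALSE]
    rownames(fixes) <- NULL
    fixes <- apply_privacy_offset(fixes, seed = substream_seed(config$seed, i, 5L))

    reports <- ev$reports
    meta_rows[[i]] <- data.frame(
      participant_id = prof$participant_id,
      enrollment_date = prof$enrollment_date,
      timezone = prof$timezone,
      group = prof$group,
      quit_datetime = mob$window_end
    )
    streams[[i]] <- list(
      participant_id = prof$participant_id,
      fixes = fixes, reports = reports,
      occupancy = mob$occupancy,
      window_start = mob$window_start, window_end = mob$window_end,
      timezone = prof$timezone
    )
    truth[[i]] <- list(
      participant_id = prof$participant_id,
      events = ev$truth,
      habit_profile = prof$habit_profile,
      anchors = prof$anchors,
      anchor_preference = prof$anchor_preference,
      schedule = prof$schedule,
      study_days = prof$study_days,
      offset = attr(fixes, "offset")
    )
  }

  metadata <- do.call(rbind, meta_rows)
  cohort <- structure(list(streams = streams, metadata = metadata,
                           ground_truth = truth, config = config),
                      class = "smoking_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' Write a cohort to disk as plain-text CSV/JSON
#'
#' @param cohort a `smoking_cohort`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir, call. = FALSE)
  gt_dir <- file.path(out_dir, "ground_truth")
  dir.create(gt_dir, showWarnings = FALSE)
  for (s in cohort$streams) {
    gps <- data.frame(participant_id = s$participant_id,
                      timestamp = format_iso8601(s$fixes$timestamp),
                      lat = sprintf("%.7f", s$fixes$lat),
                      lon = sprintf("%.7f", s$fixes$lon))
    utils::write.csv(gps, file.path(out_dir, paste0(s$participant_id, "_gps.csv")),
                     row.names = FALSE, quote = FALSE)
    rep <- data.frame(participant_id = s$participant_id,
                      timestamp = format_iso8601(s$reports$timestamp),
                      place = s$reports$place, reason = s$reports$reason)
    utils::write.csv(rep, file.path(out_dir, paste0(s$participant_id, "_reports.csv")),
                     row.names = FALSE, quote = FALSE)
  }
  meta <- cohort$metadata
  meta$quit_datetime <- vapply(seq_len(nrow(meta)), function(i) {
    format(cohort$streams[[i]]$window_end, "%Y-%m-%dT%H:%M:%S%z",
           tz = cohort$streams[[i]]$timezone)
  }, character(1))
  utils::write.csv(meta, file.path(out_dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  for (gt in cohort$ground_truth) {
    x <- list(participant_id = gt$participant_id,
              study_days = gt$study_days,
              habit_profile = gt$habit_profile,
              anchors = unname(gt$anchors),
              anchor_preference = gt$anchor_preference,
              schedule = gt$schedule,
              offset = gt$offset,
              events = data.frame(true_time = format_iso8601(gt$events$true_time),
                                  reported_time = format_iso8601(gt$events$reported_time),
                                  anchor = gt$events$anchor))
    jsonlite::write_json(x, file.path(gt_dir, paste0(gt$participant_id, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' @export
print.smoking_cohort <- function(x, ...) {
  n <- length(x$streams)
  fx <- vapply(x$streams, function(s) nrow(s$fixes), numeric(1))
  ev <- vapply(x$streams, function(s) nrow(s$reports), numeric(1))
  cat("Synthetic smoking cohort\n")
  cat(sprintf("  participants: %d (during/post split %d/%d)\n", n,
              sum(x$metadata$group == "during"), sum(x$metadata$group == "post")))
  cat(sprintf("  mean GPS fixes/participant:      %.2f\n", mean(fx)))
  cat(sprintf("  mean smoking events/participant: %.2f\n", mean(ev)))
  invisible(x)
}

#' Mutual information between hour of day and occupied anchor
#'
#' Plug-in estimate (nats) over the waking steps of an occupancy timeline;
#' used to verify the redundancy knob: `rho_redundancy = 1` maximizes it for
#' the participant's schedule, `rho_redundancy = 0` makes it statistically
#' indistinguishable from zero.
#'
#' @param occupancy occupancy data.frame from [simulate_mobility()].
#' @return mutual information in nats.
#' @export
occupancy_mutual_information <- function(occupancy) {
  w <- occupancy$hour >= WAKING_START_H & occupancy$hour < WAKING_END_H
  tab <- table(occupancy$hour[w], occupancy$anchor[w])
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}
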