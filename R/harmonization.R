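# Harmonization: raw event streams -> labeled sample tables.
#
# Boundary conventions (fixed so every edge case is deterministic):
# * event windows [t-H, t+H] are closed intervals; a fix on either boundary
#   is labeled smoking;
# * day bins are half-open [start, end) on local wall-clock minutes, so a day
#   always yields 96 quarter-hour (or 48 half-hour) bins, DST included;
# * a bin overlaps a window only if the intersection has strictly positive
#   duration;
# * the pre-quit filter is strict: data at exactly the quit datetime is
#   dropped.

#' Construct an event stream from in-memory components
#'
#' @param participant_id id string.
#' @param fixes data.frame with `timestamp` (POSIXct), `lat`, `lon`.
#' @param reports data.frame with `timestamp` (POSIXct); optional `place`,
#'   `reason`.
#' @param timezone Olson timezone of the participant.
#' @param metadata optional one-row data.frame of participant metadata.
#' @return an `event_stream` object with time-sorted fixes and reports.
#' @export
event_stream <- function(participant_id, fixes, reports, timezone,
                         metadata = NULL) {
  if (nrow(fixes) == 0) {
    stop(sprintf("empty stream: participant %s has no GPS fixes", participant_id),
         call. = FALSE)
  }
  fixes <- fixes[order(as.numeric(fixes$timestamp)), , drop = FALSE]
  reports <- reports[order(as.numeric(reports$timestamp)), , drop = FALSE]
  rownames(fixes) <- rownames(reports) <- NULL
  structure(list(participant_id = participant_id, fixes = fixes,
                 reports = reports, timezone = timezone, metadata = metadata,
                 n_malformed = 0L),
            class = "event_stream")
}

#' Parse a participant's GPS and report CSV files
#'
#' Timestamps must be ISO-8601 with a UTC offset; they are localized to the
#' participant's timezone. Rows with unparseable timestamps are dropped and
#' counted (`n_malformed`), with a warning. Output is time-sorted (stable for
#' ties).
#'
#' @param gps_path path to the GPS CSV (columns participant_id, timestamp,
#'   lat, lon).
#' @param reports_path path to the reports CSV (columns participant_id,
#'   timestamp, place, reason).
#' @param metadata_row one-row data.frame with at least `participant_id` and
#'   `timezone`.
#' @return an `event_stream`.
#' @export
parse_event_stream <- function(gps_path, reports_path, metadata_row) {
  tz <- metadata_row$timezone
  gps <- utils::read.csv(gps_path, stringsAsFactors = FALSE)
  for (col in c("participant_id", "timestamp", "lat", "lon")) {
    if (!col %in% names(gps)) {
      stop(sprintf("GPS file %s is missing column `%s`", gps_path, col), call. = FALSE)
    }
  }
  rep <- utils::read.csv(reports_path, stringsAsFactors = FALSE)
  for (col in c("participant_id", "timestamp")) {
    if (!col %in% names(rep)) {
      stop(sprintf("reports file %s is missing column `%s`", reports_path, col),
           call. = FALSE)
    }
  }
  gt <- parse_iso8601(gps$timestamp, tz)
  rt <- parse_iso8601(rep$timestamp, tz)
  n_bad <- sum(is.na(gt)) + sum(is.na(rt))
  if (n_bad > 0) {
    warning(sprintf("%d row(s) with unparseable timestamps skipped", n_bad),
            call. = FALSE)
  }
  fixes <- data.frame(timestamp = gt[!is.na(gt)],
                      lat = as.numeric(gps$lat[!is.na(gt)]),
                      lon = as.numeric(gps$lon[!is.na(gt)]))
  reports <- data.frame(timestamp = rt[!is.na(rt)],
                        place = if ("place" %in% names(rep)) rep$place[!is.na(rt)] else NA,
                        reason = if ("reason" %in% names(rep)) rep$reason[!is.na(rt)] else NA)
  out <- event_stream(metadata_row$participant_id, fixes, reports, tz,
                      metadata = metadata_row)
  out$n_malformed <- n_bad
  out
}

#' Restrict a stream to the pre-quit period
#'
#' Keeps fixes and reports strictly before `quit_datetime` (a record at
#' exactly the quit datetime is dropped).
#'
#' @param stream an `event_stream`.
#' @param quit_datetime POSIXct quit datetime.
#' @return the filtered `event_stream`, with the bound recorded in
#'   `prequit_end`.
#' @export
restrict_to_prequit <- function(stream, quit_datetime) {
  stopifnot(inherits(stream, "event_stream"))
  if (!is.null(stream$metadata) && "enrollment_date" %in% names(stream$metadata)) {
    enr <- local_midnight(as.Date(stream$metadata$enrollment_date), stream$timezone)
    if (as.numeric(quit_datetime) < as.numeric(enr)) {
      stop("quit datetime precedes enrollment", call. = FALSE)
    }
  }
  q <- as.numeric(quit_datetime)
  stream$fixes <- stream$fixes[as.numeric(stream$fixes$timestamp) < q, , drop = FALSE]
  stream$reports <- stream$reports[as.numeric(stream$reports$timestamp) < q, , drop = FALSE]
  rownames(stream$fixes) <- rownames(stream$reports) <- NULL
  stream$prequit_end <- quit_datetime
  stream
}

#' Expand reported event times into half-time windows
#'
#' Each reported time `t` becomes the closed interval `[t - H, t + H]` of
#' duration exactly `2H`; windows may cross midnight.
#'
#' @param report_time POSIXct vector of reported event times.
#' @param half_time_min half-time interval H in minutes (> 0); the study grid
#'   is 5, 10, 15, 20, 30 but any positive value is accepted.
#' @return data.frame with `center`, `start`, `end` (POSIXct).
#' @export
expand_event_window <- function(report_time, half_time_min) {
  if (!is_scalar_num(half_time_min) || half_time_min <= 0) {
    stop("half_time_min must be > 0", call. = FALSE)
  }
  data.frame(center = report_time,
             start = report_time - half_time_min * 60,
             end = report_time + half_time_min * 60)
}

# Merge closed intervals given as numeric start/end into a disjoint union.
merge_intervals <- function(start, end) {
  if (length(start) == 0) return(cbind(start = numeric(0), end = numeric(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {            # closed intervals: touching merges
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

#' Label GPS fixes as smoking / non-smoking
#'
#' A fix is labeled 1 iff its timestamp lies in the union of the (closed)
#' event windows; overlapping windows from nearby reports merge implicitly.
#'
#' @param fix_times POSIXct (or numeric seconds) vector of fix timestamps.
#' @param windows data.frame from [expand_event_window()].
#' @return integer vector of 0/1 labels.
#' @export
label_samples <- function(fix_times, windows) {
  t <- as.numeric(fix_times)
  if (nrow(windows) == 0) return(integer(length(t)))
  mi <- merge_intervals(as.numeric(windows$start), as.numeric(windows$end))
  idx <- findInterval(t, mi[, "start"])
  as.integer(idx >= 1 & t <= mi[pmax(idx, 1L), "end"])
}

#' Create fallback samples for event windows containing no fix
#'
#' For every event window with no interior fix, one smoking-labeled sample is
#' added that copies the coordinates of the fix nearest in absolute time to
#' the window (ties broken toward the earlier fix); its timestamp, used for
#' feature derivation, is the window center. If the participant has no fixes
#' at all, nothing is added and a warning is emitted.
#'
#' @param windows data.frame from [expand_event_window()].
#' @param fixes data.frame with `timestamp`, `lat`, `lon`.
#' @return data.frame of fallback rows (`timestamp`, `lat`, `lon`,
#'   `source_fix` index), possibly empty.
#' @export
attach_fallback_samples <- function(windows, fixes) {
  empty <- data.frame(timestamp = .POSIXct(numeric(0)), lat = numeric(0),
                      lon = numeric(0), source_fix = integer(0))
  if (nrow(windows) == 0) return(empty)
  if (nrow(fixes) == 0) {
    warning("participant has no GPS fixes; cannot create fallback samples",
            call. = FALSE)
    return(empty)
  }
  ft <- as.numeric(fixes$timestamp)
  ws <- as.numeric(windows$start); we <- as.numeric(windows$end)
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    inside <- ft >= ws[i] & ft <= we[i]
    if (any(inside)) return(NULL)
    # distance from each fix to the (closed) window
    d <- pmax(ws[i] - ft, ft - we[i], 0)
    j <- which.min(d)  # which.min takes the first (= earlier) on ties
    data.frame(timestamp = windows$center[i], lat = fixes$lat[j],
               lon = fixes$lon[j], source_fix = j)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

season_of_month <- function(m) {
  c("winter", "winter", "spring", "spring", "spring", "summer",
    "summer", "summer", "fall", "fall", "fall", "winter")[m]
}

#' Derive temporal features from timestamps
#'
#' Day of week and weekend flag from the participant-local calendar, season
#' by the meteorological month rule (Mar-May spring, Jun-Aug summer, Sep-Nov
#' fall, Dec-Feb winter), and the wall-clock time-of-day bin
#' `floor((60 * hour + minute) / bin_width)`.
#'
#' @param timestamp POSIXct vector with a (non-empty) timezone.
#' @param bin_width_min 15 for quarter-hour bins (96/day) or 30 for half-hour
#'   bins (48/day); any divisor of 1440 is accepted.
#' @param tz timezone override; defaults to the timestamps' own.
#' @return data.frame: `day_of_week` (factor Mon..Sun), `is_weekend`,
#'   `season` (factor), `bin` (0-based index).
#' @export
temporal_featurize <- function(timestamp, bin_width_min = 15, tz = NULL) {
  if (is.null(tz)) tz <- attr(timestamp, "tzone")
  if (is.null(tz) || !nzchar(tz)) {
    stop("timestamps must be timezone-aware", call. = FALSE)
  }
  if (!is_scalar_num(bin_width_min) || bin_width_min <= 0 ||
      1440 %% bin_width_min != 0) {
    stop("bin_width_min must divide 1440", call. = FALSE)
  }
  lt <- as.POSIXlt(timestamp, tz = tz)
  dow_levels <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  dow <- dow_levels[ifelse(lt$wday == 0, 7L, lt$wday)]
  data.frame(
    day_of_week = factor(dow, levels = dow_levels),
    is_weekend = as.integer(dow %in% c("Sat", "Sun")),
    season = factor(season_of_month(lt$mon + 1L),
                    levels = c("spring", "summer", "fall", "winter")),
    bin = (lt$hour * 60L + lt$min) %/% as.integer(bin_width_min)
  )
}

#' Per-bin smoking overlap labels for one day
#'
#' The literal construction of daily time-bin labels: bin b of the given day
#' is 1 iff its half-open wall-clock interval overlaps the union of the
#' (closed) event windows with strictly positive duration. This is the
#' coding used by the time-location association analysis; as a *predictor*
#' it would leak the outcome, so the modeling features use the one-hot
#' time-of-day coding from [temporal_featurize()] instead.
#'
#' @param windows data.frame from [expand_event_window()].
#' @param day a `Date` in participant-local time.
#' @param bin_width_min bin width in minutes (15 or 30).
#' @param tz participant timezone.
#' @return integer 0/1 vector of length `1440 / bin_width_min`.
#' @export
interval_overlap_labels <- function(windows, day, bin_width_min = 15,
                                    tz = "UTC") {
  n_bins <- 1440L %/% as.integer(bin_width_min)
  out <- integer(n_bins)
  if (nrow(windows) == 0) return(out)
  midnight <- local_midnight(as.Date(day), tz)
  # window bounds in wall-clock minutes relative to this day's midnight
  wall_min_rel <- function(t) {
    d_off <- as.numeric(local_date(t, tz) - as.Date(day))
    wall_minutes(t, tz) + 1440 * d_off
  }
  ws <- wall_min_rel(windows$start)
  we <- wall_min_rel(windows$end)
  mi <- merge_intervals(ws, we)
  bs <- (seq_len(n_bins) - 1L) * bin_width_min
  be <- bs + bin_width_min
  for (r in seq_len(nrow(mi))) {
    # positive-measure overlap of [s,e] with half-open [bs,be)
    out[mi[r, "start"] < be & mi[r, "end"] > bs] <- 1L
  }
  out
}

#' Build the labeled sample table for one participant
#'
#' Composition of the harmonization steps: expand reports into half-time
#' windows, label each GPS fix smoking/non-smoking by window membership, add
#' fallback samples for windows containing no fix, and attach temporal
#' features. Row count = fix count + number of windows without a fix.
#'
#' @param stream a (pre-quit) `event_stream`.
#' @param half_time_min half-time interval in minutes.
#' @param bin_width_min time-of-day bin width (default 15).
#' @return a `sample_table`: data.frame with columns `participant_id`,
#'   `timestamp`, `lat`, `lon`, `label`, `is_fallback`, `day_of_week`,
#'   `is_weekend`, `season`, `bin`; half-time and provenance in attributes.
#' @examples
#' coh <- generate_cohort(generator_config(n_participants = 1, seed = 3))
#' s <- coh$streams[[1]]
#' st <- build_sample_table(
#'   event_stream(s$participant_id, s$fixes, s$reports, s$timezone),
#'   half_time_min = 15)
#' table(st$label)
#' @export
build_sample_table <- function(stream, half_time_min, bin_width_min = 15) {
  stopifnot(inherits(stream, "event_stream"))
  windows <- expand_event_window(stream$reports$timestamp, half_time_min)
  labels <- label_samples(stream$fixes$timestamp, windows)
  fb <- attach_fallback_samples(windows, stream$fixes)

  base <- data.frame(timestamp = stream$fixes$timestamp,
                     lat = stream$fixes$lat, lon = stream$fixes$lon,
                     label = labels, is_fallback = 0L)
  if (nrow(fb) > 0) {
    base <- rbind(base, data.frame(timestamp = fb$timestamp, lat = fb$lat,
                                   lon = fb$lon, label = 1L, is_fallback = 1L))
  }
  feats <- temporal_featurize(base$timestamp, bin_width_min, tz = stream$timezone)
  out <- cbind(participant_id = stream$participant_id, base, feats)
  rownames(out) <- NULL
  structure(out,
            class = c("sample_table", "data.frame"),
            half_time_min = half_time_min,
            bin_width_min = bin_width_min,
            timezone = stream$timezone,
            n_fixes = nrow(stream$fixes),
            n_reports = nrow(stream$reports),
            n_fallback = nrow(fb))
}
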