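#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set controlling a simulated smoking
#' cohort: how many participants, how long they are observed, how many
#' habitual places ("anchors") they move between, how strongly smoking is
#' concentrated at habitual times of day and preferred places, and how
#' redundant place occupancy is with time of day.
#'
#' The shipped defaults are calibrated so that a default cohort reproduces
#' the pre-quit data characteristics of the motivating field study: about
#' 487 movement-triggered GPS fixes, 47 reported smoking events, 13.65
#' observation days, and 2.8 DBSCAN stay clusters per participant.
#'
#' @param n_participants number of participants (default 38).
#' @param days_mean,days_sd mean and SD of the per-participant observation
#'   window in days, drawn from a normal truncated below at 3 days.
#' @param n_anchors_range inclusive integer range for the number of anchor
#'   locations per participant.
#' @param anchor_spread_m SD (meters) of anchor placement around the
#'   participant's home location.
#' @param visit_schedule optional 24 x K matrix of hour-of-day anchor
#'   preference weights used to draw each participant's deterministic
#'   hour-to-anchor schedule; `NULL` draws a blocked routine automatically.
#' @param base_rate expected smoking events per waking hour (waking hours
#'   are 07:00-23:00). The default reproduces ~46.95 events over 13.65 days.
#' @param beta_time habit concentration (>= 0): scales both the sharpness of
#'   the time-of-day habit profile and the log-linear effect of the
#'   standardized profile on event intensity. 0 means no temporal habit.
#' @param beta_loc location-preference strength (>= 0) on event intensity.
#' @param rho_redundancy in [0, 1]: probability that a relocation follows the
#'   participant's deterministic hour-to-anchor schedule rather than a
#'   time-independent draw from the anchor preferences. 1 makes occupied
#'   anchor a deterministic function of hour of day; 0 makes it independent.
#' @param report_jitter_sd_min SD (minutes) of Gaussian jitter between true
#'   and reported event times. Default 3, below the smallest half-time
#'   interval (5 min) so labeling stays mostly correct.
#' @param fix_threshold_ft displacement (feet) triggering a GPS fix
#'   (1 ft = 0.3048 m exactly). Default 100.
#' @param gps_noise_sd_m SD (meters) of isotropic GPS positional noise.
#' @param mobility_factor in (0, 1]: proportionally damps relocation
#'   frequency (models reduced mobility, e.g. during a public-health
#'   emergency).
#' @param move_rate baseline per-5-minute probability that a waking
#'   participant reconsiders their location. Calibrated together with
#'   `base_rate` to the target fix count.
#' @param rate_heterogeneity_sd SD of the per-participant log-normal event
#'   rate multiplier (mean fixed at 1), giving realistic between-person
#'   spread in event counts.
#' @param prop_during proportion of participants enrolled on or before
#'   2023-05-11 (the public-health-emergency expiry used for the
#'   sensitivity split). Default 29/38.
#' @param seed master seed; per-participant substreams are derived by a
#'   counter scheme so earlier participants are unaffected by cohort growth.
#' @return an object of class `generator_config` (a validated list).
#' @examples
#' cfg <- generator_config(n_participants = 2, seed = 1)
#' cfg$days_mean
#' @export
generator_config <- function(n_participants = 38,
                             days_mean = 13.65,
                             days_sd = 3.43,
                             n_anchors_range = c(1L, 5L),
                             anchor_spread_m = 400,
                             visit_schedule = NULL,
                             base_rate = 46.95 / (13.65 * 16),
                             beta_time = 2,
                             beta_loc = 1,
                             rho_redundancy = 0.5,
                             report_jitter_sd_min = 3,
                             fix_threshold_ft = 100,
                             gps_noise_sd_m = 10,
                             mobility_factor = 1,
                             move_rate = 0.47,
                             rate_heterogeneity_sd = 0.5,
                             prop_during = 29 / 38,
                             seed = 1L) {
  if (!is_count(n_participants) || n_participants < 1) {
    stop_config("n_participants", "must be an integer >= 1")
  }
  if (!is_scalar_num(days_mean) || days_mean <= 0) stop_config("days_mean", "must be > 0")
  if (!is_scalar_num(days_sd) || days_sd < 0) stop_config("days_sd", "must be >= 0")
  if (length(n_anchors_range) != 2L || !is_count(n_anchors_range[1]) ||
      !is_count(n_anchors_range[2]) || n_anchors_range[1] < 1 ||
      n_anchors_range[1] > n_anchors_range[2]) {
    stop_config("n_anchors_range", "must be an increasing pair of integers >= 1")
  }
  if (!is_scalar_num(anchor_spread_m) || anchor_spread_m < 0) {
    stop_config("anchor_spread_m", "must be >= 0")
  }
  if (!is.null(visit_schedule)) {
    if (!is.matrix(visit_schedule) || nrow(visit_schedule) != 24L ||
        any(visit_schedule < 0)) {
      stop_config("visit_schedule", "must be a 24 x K nonnegative matrix or NULL")
    }
  }
  for (fld in c("base_rate", "beta_time", "beta_loc", "report_jitter_sd_min",
                "fix_threshold_ft", "gps_noise_sd_m", "rate_heterogeneity_sd")) {
    v <- get(fld)
    if (!is_scalar_num(v) || v < 0) stop_config(fld, "must be >= 0")
  }
  if (!is_scalar_num(rho_redundancy) || rho_redundancy < 0 || rho_redundancy > 1) {
    stop_config("rho_redundancy", "must lie in [0, 1]")
  }
  if (!is_scalar_num(mobility_factor) || mobility_factor <= 0 || mobility_factor > 1) {
    stop_config("mobility_factor", "must lie in (0, 1]")
  }
  if (!is_scalar_num(move_rate) || move_rate < 0 || move_rate > 1) {
    stop_config("move_rate", "must lie in [0, 1]")
  }
  if (!is_scalar_num(prop_during) || prop_during < 0 || prop_during > 1) {
    stop_config("prop_during", "must lie in [0, 1]")
  }
  if (!is_count(abs(seed))) stop_config("seed", "must be an integer")

  structure(list(
    n_participants = as.integer(n_participants),
    days_mean = days_mean, days_sd = days_sd,
    n_anchors_range = as.integer(n_anchors_range),
    anchor_spread_m = anchor_spread_m,
    visit_schedule = visit_schedule,
    base_rate = base_rate, beta_time = beta_time, beta_loc = beta_loc,
    rho_redundancy = rho_redundancy,
    report_jitter_sd_min = report_jitter_sd_min,
    fix_threshold_ft = fix_threshold_ft,
    gps_noise_sd_m = gps_noise_sd_m,
    mobility_factor = mobility_factor,
    move_rate = move_rate,
    rate_heterogeneity_sd = rate_heterogeneity_sd,
    prop_during = prop_during,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# Constants of the generative model (not tunable): waking hours and the
# occupancy step. Smoking while asleep is not modeled, which keeps habit
# profiles identifiable.
WAKING_START_H <- 7L
WAKING_END_H <- 23L
OCCUPANCY_STEP_MIN <- 5L
FT_TO_M <- 0.3048
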