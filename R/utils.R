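# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

#' @useDynLib geosmoke, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Per-participant RNG substreams: a documented counter scheme so that adding
# participants to a cohort never perturbs the streams of earlier ones.
# substream(seed, index, stage) = (seed * 48271 + index * 9973 + stage) mod (2^31 - 1)
substream_seed <- function(seed, index, stage = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  m <- 2147483647
  as.integer((abs(seed) %% m * 48271 + index * 9973 + stage) %% m)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion", .rng_sample_kind = "Rejection")
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field `%s`: %s", field, msg), call. = FALSE)
}

# Wall-clock minutes since local midnight (0 .. <1440). Bins and habit profiles
# are defined on the local wall clock, so DST transitions never change the bin
# count of a day: skipped or repeated wall times map by clock reading.
wall_minutes <- function(t, tz = NULL) {
  if (is.null(tz)) tz <- attr(t, "tzone")
  lt <- as.POSIXlt(t, tz = tz)
  lt$hour * 60 + lt$min + lt$sec / 60
}

local_date <- function(t, tz = NULL) {
  if (is.null(tz)) tz <- attr(t, "tzone")
  as.Date(format(t, "%Y-%m-%d", tz = tz))
}

local_midnight <- function(day, tz) {
  as.POSIXct(paste0(format(day), " 00:00:00"), tz = tz)
}

# ISO-8601 with numeric UTC offset, second resolution.
format_iso8601 <- function(t) {
  format(t, "%Y-%m-%dT%H:%M:%S%z")
}

parse_iso8601 <- function(x, tz) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S%z", tz = tz)
  # fall back to a space-separated or offset-free form
  miss <- is.na(out) & !is.na(x)
  if (any(miss)) {
    out[miss] <- as.POSIXct(x[miss], format = "%Y-%m-%d %H:%M:%S", tz = tz)
  }
  out
}
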