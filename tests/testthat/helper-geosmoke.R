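# Shared fixtures and independent oracles, all built in code.

mk_times <- function(strings, tz = "America/Chicago") {
  as.POSIXct(strings, tz = tz)
}

mk_stream <- function(fix_times, report_times, tz = "America/Chicago",
                      lat = NULL, lon = NULL, id = "T01") {
  n <- length(fix_times)
  if (is.null(lat)) lat <- rep(40, n)
  if (is.null(lon)) lon <- rep(-90, n)
  event_stream(id,
               data.frame(timestamp = fix_times, lat = lat, lon = lon),
               data.frame(timestamp = report_times,
                          place = rep("home", length(report_times)),
                          reason = rep("habit", length(report_times))),
               tz)
}

# random multi-day stream with fixes and reports at arbitrary times
random_stream <- function(seed, n_fixes = 60, n_reports = 8,
                          tz = "America/Chicago") {
  withr::with_seed(seed, {
    day0 <- as.POSIXct("2023-04-03 00:00:00", tz = tz)
    ft <- day0 + sort(stats::runif(n_fixes, 0, 3 * 86400))
    rt <- day0 + stats::runif(n_reports, 0, 3 * 86400)
    mk_stream(ft, rt, tz,
              lat = 40 + stats::runif(n_fixes, 0, 0.01),
              lon = -90 + stats::runif(n_fixes, 0, 0.01))
  })
}

cohort_streams_first <- function(coh) geosmoke:::cohort_streams(coh)[[1]]

local_midnight_at <- function(prof) {
  as.POSIXct(paste(format(prof$enrollment_date), "00:00:00"), tz = prof$timezone)
}

# brute-force membership oracle: per fix, test every window directly
brute_labels <- function(fix_times, windows) {
  t <- as.numeric(fix_times)
  s <- as.numeric(windows$start); e <- as.numeric(windows$end)
  vapply(t, function(ti) as.integer(any(s <= ti & ti <= e)), integer(1))
}

# well-separated Gaussian blobs in degree space
make_blobs <- function(k, n_per = 30, sep_deg = 0.05, spread_deg = 1e-4,
                       seed = 1) {
  withr::with_seed(seed, {
    centers <- cbind(lat = 40 + sep_deg * seq_len(k),
                     lon = -90 + sep_deg * ((seq_len(k) %% 2) * 2 - 1) * seq_len(k))
    idx <- rep(seq_len(k), each = n_per)
    list(lat = centers[idx, 1] + stats::rnorm(k * n_per, 0, spread_deg),
         lon = centers[idx, 2] + stats::rnorm(k * n_per, 0, spread_deg),
         truth = idx)
  })
}

# independent DBSCAN oracle: density reachability via boolean transitive
# closure on the distance matrix
dbscan_oracle <- function(lat, lon, eps_m, min_samples) {
  n <- length(lat)
  d <- outer(seq_len(n), seq_len(n), function(i, j)
    great_circle_distance(lat[i], lon[i], lat[j], lon[j]))
  within <- d <= eps_m
  core <- colSums(within) >= min_samples
  reach <- within & outer(core, core, "&")  # core-core edges
  repeat {
    nxt <- (reach %*% reach > 0) | reach
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  # components of core points from closure rows
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in which(core)) {
    if (!is.na(comp[i])) next
    members <- which(reach[i, ] | seq_len(n) == i)
    members <- intersect(members, which(core))
    comp[members] <- cid
    cid <- cid + 1L
  }
  list(core = core, core_component = comp, within = within)
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (abs(maxi - expected) < 1e-12) {
    # degenerate (e.g. both partitions trivial): 1 iff the partitions agree
    return(as.numeric(sum_ij == sum_a && sum_a == sum_b))
  }
  (sum_ij - expected) / (maxi - expected)
}

# null distribution of the signed-rank statistic by generating-function
# convolution over doubled midranks (independent of mask enumeration)
signed_rank_null_p <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  w_obs2 <- round(2 * sum(r[d > 0]))
  r2 <- round(2 * r)
  dist <- c(1)  # prob weights over 2W = 0..sum(r2), unnormalized counts
  for (x in r2) {
    nxt <- c(dist, numeric(x)) + c(numeric(x), dist)
    dist <- nxt
  }
  total <- sum(dist)
  w_vals <- seq_along(dist) - 1L
  p <- 2 * min(sum(dist[w_vals <= w_obs2]) / total,
               sum(dist[w_vals >= w_obs2]) / total)
  min(p, 1)
}

# macro-F1 oracle via the 2TP/(2TP+FP+FN) identity
macro_f1_oracle <- function(y, p) {
  per_class <- vapply(c(0, 1), function(cls) {
    tp <- sum(y == cls & p == cls)
    fp <- sum(y != cls & p == cls)
    fn <- sum(y == cls & p != cls)
    den <- 2 * tp + fp + fn
    if (den == 0) 0 else 2 * tp / den
  }, numeric(1))
  mean(per_class)
}

# tiny synthetic design for model-level tests: y determined by one column
separable_data <- function(n = 120, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)[sample(n)]
    x <- cbind(signal = y + stats::rnorm(n, 0, 0.01),
               noise1 = stats::rnorm(n), noise2 = stats::rnorm(n))
    list(x = x, y = y)
  })
}
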