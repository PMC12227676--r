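# Statistical layer: paired Wilcoxon signed-rank tests over the ablation
# grid, Welch t-tests for subgroup characteristics, the enrollment-era
# sensitivity split, and the mixed-effects time-location association
# analysis with support values.

#' Wilcoxon signed-rank test for paired differences
#'
#' Zeros are discarded (standard zero-handling); absolute differences are
#' ranked with midranks for ties and W is the sum of ranks of the positive
#' differences. For 15 or fewer retained pairs the two-sided p-value is
#' exact, by full enumeration of the 2^n sign assignments (valid under ties
#' because the midrank multiset is fixed); beyond that a normal
#' approximation with tie correction is used.
#'
#' @param differences numeric vector of paired differences (or pass `x` and
#'   `y` via `...` as two equal-length vectors to difference).
#' @param exact_max largest n for the exact branch (default 15).
#' @return list: `W`, `p_value`, `n` (retained pairs), `method`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))  # W = 21, p = 0.03125
#' @export
wilcoxon_signed_rank <- function(differences, exact_max = 15L) {
  d <- differences[!is.na(differences)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero: test degenerate", call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact null: W = sum of a uniformly random subset of the midranks
    w_all <- vapply(0:(2^n - 1), function(mask) {
      sum(r[bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) > 0])
    }, numeric(1))
    p <- 2 * min(mean(w_all <= W + 1e-9), mean(w_all >= W - 1e-9))
    p <- min(p, 1)
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(W = W, p_value = p, n = n, method = method)
}

#' Significance flags at the study's alpha conventions
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param adjust `"none"` (default, matching the star conventions of the
#'   analysis) or `"BH"` for Benjamini-Hochberg adjustment before flagging.
#' @return data.frame: `p_value`, `sig_05`, `sig_005`, `stars`.
#' @export
summarize_alpha <- function(p_values, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(all(is.na(p_values) | (p_values >= 0 & p_values <= 1)))
  p <- if (adjust == "BH") stats::p.adjust(p_values, "BH") else p_values
  data.frame(p_value = p_values,
             sig_05 = !is.na(p) & p < 0.05,
             sig_005 = !is.na(p) & p < 0.005,
             stars = ifelse(is.na(p), "", ifelse(p < 0.005, "**",
                            ifelse(p < 0.05, "*", ""))))
}

#' Paired ablation comparisons over a modeling grid
#'
#' For every (spatial method, family, half-time) configuration, tests the
#' per-participant all-features scores against the location-excluded and
#' time-excluded scores with the Wilcoxon signed-rank test, flagging
#' significance at 0.05 and 0.005. Configurations with fewer than 6 complete
#' pairs are flagged underpowered; identical score vectors are degenerate
#' and reported with `p = NA`.
#'
#' @param ablation_result an [ablation_grid()] result.
#' @return data.frame of class `ablation_comparison`: one row per
#'   configuration and excluded feature set, with mean scores, W, p, flags.
#' @export
compare_ablations <- function(ablation_result) {
  res <- ablation_result$results
  if (is.null(res)) stop("empty ablation result", call. = FALSE)
  cfgs <- unique(res[, c("spatial_method", "family", "half_time_min")])
  out <- list()
  for (i in seq_len(nrow(cfgs))) {
    sel <- res$spatial_method == cfgs$spatial_method[i] &
      res$family == cfgs$family[i] &
      res$half_time_min == cfgs$half_time_min[i]
    sub <- res[sel, ]
    all_s <- sub[sub$ablation == "ALL", c("participant_id", "mean_score")]
    for (abl in c("NO_LOCATION", "NO_TIME")) {
      abl_s <- sub[sub$ablation == abl, c("participant_id", "mean_score")]
      m <- merge(all_s, abl_s, by = "participant_id", suffixes = c("_all", "_abl"))
      d <- m$mean_score_all - m$mean_score_abl
      n_pairs <- nrow(m)
      if (n_pairs == 0) next
      p <- NA_real_; W <- NA_real_; note <- ""
      if (all(d == 0)) {
        note <- "degenerate: identical score vectors"
      } else {
        wt <- wilcoxon_signed_rank(d)
        p <- wt$p_value; W <- wt$W
      }
      if (n_pairs < 6) note <- paste(note, "underpowered (n < 6)")
      out[[length(out) + 1L]] <- data.frame(
        spatial_method = cfgs$spatial_method[i], family = cfgs$family[i],
        half_time_min = cfgs$half_time_min[i], excluded = abl,
        n_pairs = n_pairs,
        mean_all = mean(m$mean_score_all), mean_ablated = mean(m$mean_score_abl),
        mean_drop = mean(d), W = W, p_value = p, note = trimws(note))
    }
  }
  out <- do.call(rbind, out)
  out <- cbind(out, summarize_alpha(out$p_value)[, c("sig_05", "sig_005", "stars")])
  class(out) <- c("ablation_comparison", "data.frame")
  out
}

#' Welch (or pooled) two-sample t-test
#'
#' Two-sided test for a difference in means between independent groups;
#' unequal variances (Welch) by default, with a pooled-variance option for
#' literal replication of classic Student output. Constant identical groups
#' return t = 0, p = 1.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param pooled use the pooled-variance Student test instead of Welch.
#' @return list: `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_t_test <- function(group_a, group_b, pooled = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0 &&
      mean(group_a) == mean(group_b)) {
    return(list(t = 0, df = NA_real_, p_value = 1,
                mean_a = mean(group_a), mean_b = mean(group_b)))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = pooled)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Split participants by enrollment era
#'
#' The during-emergency group enrolled on or before 2023-05-11 (the federal
#' Public Health Emergency expiry); the post-emergency group after it.
#' Participants without an enrollment date are excluded with a warning.
#'
#' @param metadata cohort metadata with `participant_id`, `enrollment_date`.
#' @param boundary boundary date (default `"2023-05-11"`, inclusive for the
#'   during group).
#' @return list: `during`, `post` (character vectors of participant ids).
#' @export
covid_subgroup_split <- function(metadata, boundary = as.Date("2023-05-11")) {
  d <- as.Date(metadata$enrollment_date)
  if (anyNA(d)) {
    warning(sprintf("%d participant(s) without enrollment date excluded", sum(is.na(d))),
            call. = FALSE)
  }
  list(during = metadata$participant_id[!is.na(d) & d <= boundary],
       post = metadata$participant_id[!is.na(d) & d > boundary])
}

#' Fit a time-location association model
#'
#' Regresses a location-cluster outcome on a single binary temporal feature.
#' In pooled mode a linear mixed model with a participant random intercept
#' is fitted by maximum likelihood (the fixed effect is the population-level
#' association); in per-participant mode an ordinary least-squares model is
#' fitted for each participant. Outcome codings: `"modal_cluster_binary"`
#' (sample lies in the participant's most frequent smoking cluster) or
#' `"cluster_numeric"` (raw integer label; a literal-replication mode that
#' is scale-dependent by construction).
#'
#' @param data data.frame with columns `participant_id`, `cluster`
#'   (integer labels), `label` (smoking 0/1), `feature` (binary temporal
#'   feature value per sample).
#' @param outcome_coding `"modal_cluster_binary"` or `"cluster_numeric"`.
#' @param stratum `"smoking"`, `"non_smoking"` or `"all"` sample stratum.
#' @param pooled mixed model over participants (default) vs per-participant
#'   OLS.
#' @return for pooled mode a one-row data.frame (estimate, se, p, n); for
#'   per-participant mode one row per participant. `NULL` (with a message
#'   attribute) when the outcome or feature has zero variance.
#' @export
fit_time_location_association <- function(data,
                                          outcome_coding = c("modal_cluster_binary", "cluster_numeric"),
                                          stratum = c("smoking", "non_smoking", "all"),
                                          pooled = TRUE) {
  outcome_coding <- match.arg(outcome_coding)
  stratum <- match.arg(stratum)
  keep <- switch(stratum, smoking = data$label == 1,
                 non_smoking = data$label == 0, all = rep(TRUE, nrow(data)))
  d <- data[keep, , drop = FALSE]
  if (nrow(d) == 0) return(NULL)

  if (outcome_coding == "modal_cluster_binary") {
    # modal smoking cluster per participant, computed on smoking samples
    sm <- data[data$label == 1, ]
    modal <- tapply(sm$cluster, sm$participant_id,
                    function(v) as.integer(names(which.max(table(v)))))
    d$outcome <- as.numeric(d$cluster == modal[as.character(d$participant_id)])
    d <- d[!is.na(d$outcome), , drop = FALSE]
  } else {
    d$outcome <- as.numeric(d$cluster)
  }
  if (nrow(d) == 0) return(NULL)
  if (stats::sd(d$outcome) == 0 || stats::sd(d$feature) == 0) {
    return(structure(list(skipped = TRUE, reason = "zero-variance outcome or feature"),
                     class = "association_skip"))
  }

  if (pooled) {
    n_part <- length(unique(d$participant_id))
    if (n_part >= 2) {
      # Satterthwaite p-values where the fit admits them; in degenerate
      # (e.g. zero-residual) fits fall back to the Wald normal approximation
      co <- tryCatch({
        fit <- suppressMessages(suppressWarnings(
          lmerTest::lmer(outcome ~ feature + (1 | participant_id), data = d,
                         REML = FALSE)))
        cs <- stats::coef(summary(fit))
        c(est = cs["feature", "Estimate"], se = cs["feature", "Std. Error"],
          p = cs["feature", "Pr(>|t|)"])
      }, error = function(e) {
        # zero-residual fits break the mixed-model machinery; the
        # fixed-effects (within-participant) OLS limit is exact there
        fit <- stats::lm(outcome ~ feature + factor(participant_id), data = d)
        cs <- suppressWarnings(stats::coef(summary(fit)))
        est <- cs["feature", "Estimate"]
        p <- cs["feature", "Pr(>|t|)"]
        if (!is.finite(p)) p <- if (abs(est) > 0) 0 else 1
        c(est = est, se = cs["feature", "Std. Error"], p = p)
      })
      return(data.frame(mode = "pooled_lmm", coding = outcome_coding,
                        stratum = stratum, estimate = unname(co["est"]),
                        se = unname(co["se"]), p_value = unname(co["p"]),
                        n = nrow(d), n_participants = n_part))
    }
    # single participant: the random intercept is unidentified; OLS limit
    fit <- stats::lm(outcome ~ feature, data = d)
    co <- stats::coef(summary(fit))
    return(data.frame(mode = "pooled_lmm", coding = outcome_coding,
                      stratum = stratum, estimate = co["feature", "Estimate"],
                      se = co["feature", "Std. Error"],
                      p_value = co["feature", "Pr(>|t|)"],
                      n = nrow(d), n_participants = 1L))
  }

  rows <- lapply(split(d, d$participant_id), function(dp) {
    if (stats::sd(dp$outcome) == 0 || stats::sd(dp$feature) == 0) return(NULL)
    fit <- stats::lm(outcome ~ feature, data = dp)
    co <- stats::coef(summary(fit))
    if (!"feature" %in% rownames(co)) return(NULL)
    data.frame(mode = "per_participant_ols", coding = outcome_coding,
               stratum = stratum, participant_id = dp$participant_id[1],
               estimate = co["feature", "Estimate"],
               se = co["feature", "Std. Error"],
               p_value = co["feature", "Pr(>|t|)"], n = nrow(dp))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Support value of a temporal-feature / location-cluster association
#'
#' The association-rule sense of support: the percentage of stratum samples
#' in which the temporal feature is active AND the sample lies in the given
#' cluster (per participant, clusters are participant-specific).
#'
#' @param feature_active logical/0-1 vector per sample.
#' @param in_cluster logical/0-1 vector per sample.
#' @return percent in `[0, 100]`; `NA` for an empty stratum.
#' @export
association_support <- function(feature_active, in_cluster) {
  n <- length(feature_active)
  if (n == 0) return(NA_real_)
  100 * sum(feature_active == 1 & in_cluster == 1) / n
}

#' Time-location association analysis over a cohort sample table
#'
#' Iterates the association model over every time-of-day bin at the given
#' bin width (the N x M per-feature design): for each bin, the binary
#' feature "sample falls in this bin" is tested against the location-cluster
#' outcome, within the smoking and non-smoking strata. Support values are
#' computed for significant associations, with the modal-cluster outcome
#' defining the cluster of interest.
#'
#' @param data data.frame with `participant_id`, `bin`, `cluster`, `label`.
#' @param bin_width_min bin width the `bin` column was derived at.
#' @param outcome_coding passed to [fit_time_location_association()].
#' @param pooled passed through.
#' @param alpha significance level for the support summary (default 0.05).
#' @param min_active minimum number of stratum samples with the feature
#'   active for a bin to be modeled (bins nobody is ever sampled in carry no
#'   information and are skipped).
#' @return list: `associations` (one row per bin and stratum) and `support`
#'   summary (min/max support among significant associations per stratum).
#' @export
association_analysis <- function(data, bin_width_min = 15,
                                 outcome_coding = "modal_cluster_binary",
                                 pooled = TRUE, alpha = 0.05,
                                 min_active = 10L) {
  n_bins <- 1440L %/% as.integer(bin_width_min)
  sm <- data[data$label == 1, ]
  modal <- tapply(sm$cluster, sm$participant_id,
                  function(v) as.integer(names(which.max(table(v)))))
  in_modal <- as.numeric(data$cluster == modal[as.character(data$participant_id)])
  rows <- list()
  for (b in sort(unique(data$bin))) {
    data$feature <- as.numeric(data$bin == b)
    for (st in c("smoking", "non_smoking")) {
      stratum_sel <- if (st == "smoking") data$label == 1 else data$label == 0
      if (sum(data$feature[stratum_sel]) < min_active) next
      fit <- fit_time_location_association(data, outcome_coding, st, pooled)
      if (is.null(fit) || !is.data.frame(fit) || nrow(fit) == 0) next
      if (!pooled) {
        fit <- data.frame(mode = fit$mode[1], coding = fit$coding[1],
                          stratum = st, estimate = mean(fit$estimate),
                          se = NA_real_, p_value = min(fit$p_value),
                          n = sum(fit$n), n_participants = nrow(fit))
      }
      keep <- switch(st, smoking = data$label == 1, non_smoking = data$label == 0)
      supp <- association_support(data$feature[keep],
                                  in_modal[keep] & !is.na(in_modal[keep]))
      rows[[length(rows) + 1L]] <- cbind(bin = b, fit, support = supp)
    }
  }
  assoc <- if (length(rows)) do.call(rbind, rows) else NULL
  support <- NULL
  if (!is.null(assoc)) {
    sig <- assoc[!is.na(assoc$p_value) & assoc$p_value < alpha, ]
    if (nrow(sig)) {
      support <- do.call(rbind, lapply(split(sig, sig$stratum), function(g) {
        data.frame(stratum = g$stratum[1], bin_width_min = bin_width_min,
                   n_significant = nrow(g),
                   support_min = min(g$support), support_max = max(g$support))
      }))
      rownames(support) <- NULL
    }
  }
  list(associations = assoc, support = support)
}
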