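# Per-participant ablation modeling grid:
# {spatial method} x {LR, RF, MLP} x {half-time} x {ALL, NO_LOCATION, NO_TIME},
# stratified 5-fold CV, scored by Macro-F1.

ABLATIONS <- c("ALL", "NO_LOCATION", "NO_TIME")

#' Model family specification
#'
#' Hyperparameters are fixed, conventional defaults; all are overridable.
#' The MLP architecture is two hidden layers of 300 and 150 ReLU units
#' trained with Adam.
#'
#' @param family `"lr"` (L2 logistic regression), `"rf"` (random forest) or
#'   `"mlp"` (multilayer perceptron).
#' @param C inverse L2 penalty strength for LR.
#' @param max_iter maximum IRLS/coordinate iterations for LR.
#' @param n_trees,max_depth random-forest size (depth `NULL` = unlimited).
#' @param mtry random-forest candidate features per split; `NULL` uses
#'   `floor(p / 3)`, which suits the sparse one-hot design matrices here far
#'   better than the classification default `sqrt(p)`.
#' @param hidden,learning_rate,max_epochs,batch_size MLP settings.
#' @param seed model seed (restarts, bagging, initialization).
#' @return a `model_spec` list.
#' @export
model_spec <- function(family = c("lr", "rf", "mlp"),
                       C = 1.0, max_iter = 1000L,
                       n_trees = 100L, max_depth = NULL, mtry = NULL,
                       hidden = c(300L, 150L), learning_rate = 1e-3,
                       max_epochs = 200L, batch_size = 32L,
                       seed = 1L) {
  family <- match.arg(family)
  stopifnot(length(hidden) == 2, all(hidden >= 1))
  structure(list(family = family, C = C, max_iter = as.integer(max_iter),
                 n_trees = as.integer(n_trees), max_depth = max_depth,
                 mtry = mtry,
                 hidden = as.integer(hidden), learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Assemble the design matrix for one ablation
#'
#' Temporal block: one-hot time-of-day bins (96 at quarter-hour width),
#' 7 day-of-week columns, a weekend flag and 4 season columns. Spatial
#' block: the encoded location representation. `ALL` = temporal + spatial,
#' `NO_LOCATION` = temporal only (independent of the representation),
#' `NO_TIME` = spatial only. Column order is fixed: temporal then spatial.
#'
#' @param sample_table a `sample_table`.
#' @param representation a [spatial_representation()] aligned to its rows
#'   (may be `NULL` for `NO_LOCATION`).
#' @param ablation one of `"ALL"`, `"NO_LOCATION"`, `"NO_TIME"`.
#' @return list: `x` (numeric matrix), `y` (integer labels).
#' @export
assemble_design_matrix <- function(sample_table, representation,
                                   ablation = c("ALL", "NO_LOCATION", "NO_TIME")) {
  ablation <- match.arg(ablation)
  n <- nrow(sample_table)
  blocks <- list()
  if (ablation != "NO_TIME") {
    n_bins <- 1440L %/% attr(sample_table, "bin_width_min")
    bin_m <- matrix(0, n, n_bins, dimnames = list(NULL, paste0("qh_", seq_len(n_bins) - 1L)))
    bin_m[cbind(seq_len(n), sample_table$bin + 1L)] <- 1
    dow_m <- matrix(0, n, 7, dimnames = list(NULL, paste0("dow_", levels(sample_table$day_of_week))))
    dow_m[cbind(seq_len(n), as.integer(sample_table$day_of_week))] <- 1
    sea_m <- matrix(0, n, 4, dimnames = list(NULL, paste0("season_", levels(sample_table$season))))
    sea_m[cbind(seq_len(n), as.integer(sample_table$season))] <- 1
    blocks$temporal <- cbind(bin_m, dow_m, weekend = sample_table$is_weekend, sea_m)
  }
  if (ablation != "NO_LOCATION") {
    if (is.null(representation)) {
      stop("a spatial representation is required unless ablation = NO_LOCATION",
           call. = FALSE)
    }
    blocks$spatial <- encode_location_feature(representation)
  }
  x <- do.call(cbind, blocks)
  if (is.null(x) || ncol(x) == 0) stop("ablation yields zero columns", call. = FALSE)
  list(x = x, y = as.integer(sample_table$label))
}

#' Macro-averaged F1 score for binary labels
#'
#' F1 is computed for class 0 and class 1 separately and averaged without
#' weighting. Any undefined precision, recall or F1 (zero denominator) is
#' taken as 0, so a class absent from both truth and prediction contributes
#' an F1 of 0.
#'
#' @param y_true,y_pred equal-length 0/1 vectors.
#' @return score in `[0, 1]`.
#' @examples
#' macro_f1(c(1, 1, 0, 0), c(1, 0, 0, 0))  # 11/15
#' @export
macro_f1 <- function(y_true, y_pred) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must be nonempty and of equal length", call. = FALSE)
  }
  f1_class <- function(cls) {
    tp <- sum(y_true == cls & y_pred == cls)
    fp <- sum(y_true != cls & y_pred == cls)
    fn <- sum(y_true == cls & y_pred != cls)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  (f1_class(0) + f1_class(1)) / 2
}

#' Stratified k-fold assignment
#'
#' Indices of each class are shuffled under the seed and dealt cyclically
#' into folds, so fold class proportions match the data as closely as
#' possible and the assignment is reproducible.
#'
#' @param y 0/1 label vector.
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return integer fold id (1..k) per observation.
#' @export
stratified_folds <- function(y, k = 5L, seed = 1L) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Train on (xtr, ytr), predict 0/1 labels for xte, for one model family.
fit_predict <- function(xtr, ytr, xte, spec) {
  # fold-level standardization of numeric (non-indicator) columns, using
  # training-fold statistics only
  num_cols <- which(colnames(xtr) == "dfi")
  for (j in num_cols) {
    mu <- mean(xtr[, j]); s <- stats::sd(xtr[, j])
    if (is.na(s) || s == 0) { xtr[, j] <- 0; xte[, j] <- 0 }
    else { xtr[, j] <- (xtr[, j] - mu) / s; xte[, j] <- (xte[, j] - mu) / s }
  }
  switch(spec$family,
    lr = {
      xtr2 <- xtr; xte2 <- xte
      if (ncol(xtr2) < 2) {  # glmnet needs >= 2 columns
        xtr2 <- cbind(xtr2, .pad = 0); xte2 <- cbind(xte2, .pad = 0)
      }
      fit <- glmnet::glmnet(xtr2, factor(ytr, levels = 0:1), family = "binomial",
                            alpha = 0, lambda = 1 / (spec$C * nrow(xtr2)),
                            standardize = FALSE, maxit = spec$max_iter)
      p <- as.numeric(stats::predict(fit, xte2, type = "response"))
      as.integer(p > 0.5)
    },
    rf = {
      mtry <- if (is.null(spec$mtry)) max(1L, ncol(xtr) %/% 3L) else
        min(spec$mtry, ncol(xtr))
      fit <- ranger::ranger(x = xtr, y = factor(ytr, levels = 0:1),
                            num.trees = spec$n_trees, mtry = mtry,
                            max.depth = if (is.null(spec$max_depth)) 0 else spec$max_depth,
                            seed = spec$seed, num.threads = 1L)
      as.integer(as.character(stats::predict(fit, data = xte,
                                             num.threads = 1L)$predictions))
    },
    mlp = {
      p <- .mlp_train_predict(xtr, as.numeric(ytr), xte,
                              spec$hidden[1], spec$hidden[2],
                              spec$learning_rate, spec$max_epochs,
                              spec$batch_size, spec$seed)
      as.integer(p > 0.5)
    }
  )
}

#' Cross-validate one participant's design matrix
#'
#' Stratified 5-fold cross-validation with a fresh model per fold; the
#' participant's score is the mean of the fold Macro-F1 values. Pass a
#' precomputed `folds` vector to share the identical fold partition across
#' ablations and spatial methods (the paired design). Participants with
#' fewer than 10 samples, a single class, or fewer minority samples than
#' folds are skipped with a reason.
#'
#' @param x design matrix.
#' @param y 0/1 labels.
#' @param spec a [model_spec()].
#' @param seed fold seed (ignored when `folds` given).
#' @param folds optional fold assignment from [stratified_folds()].
#' @param k number of folds.
#' @return a `cv_result` (fold scores + mean), or a `cv_skip` with a reason.
#' @export
crossvalidate_participant <- function(x, y, spec, seed = 1L, folds = NULL, k = 5L) {
  skip <- function(reason) structure(list(reason = reason), class = "cv_skip")
  if (length(y) < 10) return(skip("fewer than 10 samples"))
  if (length(unique(y)) < 2) return(skip("single-class labels"))
  if (min(table(y)) < k) return(skip("minority class smaller than fold count"))
  if (is.null(folds)) folds <- stratified_folds(y, k, seed)
  scores <- vapply(seq_len(k), function(f) {
    te <- folds == f
    pred <- fit_predict(x[!te, , drop = FALSE], y[!te], x[te, , drop = FALSE], spec)
    macro_f1(y[te], pred)
  }, numeric(1))
  structure(list(fold_scores = scores, mean_score = mean(scores), k = k),
            class = "cv_result")
}

#' Run the feature-ablation modeling grid over a cohort
#'
#' The central analysis: for every participant, half-time interval, spatial
#' method and model family, fits the all-features, location-excluded and
#' time-excluded models under an identical stratified 5-fold partition and
#' records per-fold and mean Macro-F1. Location-excluded cells do not depend
#' on the spatial method (the design matrix drops the representation and
#' folds are shared), so they are computed once per (family, half-time) and
#' replicated across methods — the repeated location-excluded column of the
#' resulting grid is structural.
#'
#' @param cohort a `smoking_cohort`, or a list of `event_stream`s.
#' @param half_times half-time intervals (minutes) to evaluate.
#' @param spatial_methods subset of `c("dbscan", "kmeans", "dfi")`.
#' @param families subset of `c("lr", "rf", "mlp")`.
#' @param model_specs optional named list of [model_spec()] overrides per
#'   family.
#' @param spatial_cfg optional named list of [spatial_config()] overrides
#'   per method.
#' @param bin_width_min time-of-day bin width for temporal features.
#' @param seed seed controlling fold assignment and model seeds.
#' @param pooled if `TRUE`, all participants are concatenated and modeled as
#'   one pooled dataset instead of individually.
#' @return an `ablation_result` with `$results` (per-participant rows),
#'   `$aggregate` (mean/SD per configuration) and `$skips`.
#' @export
ablation_grid <- function(cohort,
                          half_times = c(5, 10, 15, 20, 30),
                          spatial_methods = c("dbscan", "kmeans", "dfi"),
                          families = c("lr", "rf", "mlp"),
                          model_specs = NULL,
                          spatial_cfg = NULL,
                          bin_width_min = 15,
                          seed = 1L,
                          pooled = FALSE) {
  streams <- cohort_streams(cohort)
  spatial_methods <- match.arg(spatial_methods, several.ok = TRUE)
  families <- match.arg(families, several.ok = TRUE)

  tables <- list()
  for (s in streams) {
    for (ht in half_times) {
      tables[[s$participant_id]][[as.character(ht)]] <-
        build_sample_table(s, ht, bin_width_min)
    }
  }
  if (pooled) {
    pooled_tables <- list()
    for (ht in as.character(half_times)) {
      parts <- lapply(tables, `[[`, ht)
      tab <- do.call(rbind, lapply(parts, as.data.frame))
      attributes(tab)[c("half_time_min", "bin_width_min")] <-
        attributes(parts[[1]])[c("half_time_min", "bin_width_min")]
      class(tab) <- c("sample_table", "data.frame")
      pooled_tables[["POOLED"]][[ht]] <- tab
    }
    tables <- pooled_tables
  }

  rows <- list()
  skips <- list()
  for (pid in names(tables)) {
    for (ht in as.character(half_times)) {
      tab <- tables[[pid]][[ht]]
      y <- as.integer(tab$label)
      fold_seed <- substream_seed(seed, match(pid, names(tables)),
                                  100L + as.integer(as.numeric(ht)))
      folds <- stratified_folds(y, 5L, fold_seed)

      reps <- lapply(spatial_methods, function(m) {
        cfg <- if (!is.null(spatial_cfg[[m]])) spatial_cfg[[m]] else
          spatial_config(m, seed = seed)
        spatial_representation(tab, cfg)
      })
      names(reps) <- spatial_methods

      for (fam in families) {
        spec <- if (!is.null(model_specs[[fam]])) model_specs[[fam]] else
          model_spec(fam, seed = seed)
        # location-excluded: representation-independent, computed once
        dm <- assemble_design_matrix(tab, NULL, "NO_LOCATION")
        cv_noloc <- crossvalidate_participant(dm$x, dm$y, spec, folds = folds)
        for (m in spatial_methods) {
          for (abl in ABLATIONS) {
            cv <- if (abl == "NO_LOCATION") cv_noloc else {
              dm2 <- assemble_design_matrix(tab, reps[[m]], abl)
              crossvalidate_participant(dm2$x, dm2$y, spec, folds = folds)
            }
            if (inherits(cv, "cv_skip")) {
              skips[[length(skips) + 1L]] <- data.frame(
                participant_id = pid, half_time_min = as.numeric(ht),
                spatial_method = m, family = fam, ablation = abl,
                reason = cv$reason)
              next
            }
            rows[[length(rows) + 1L]] <- data.frame(
              participant_id = pid, spatial_method = m, family = fam,
              half_time_min = as.numeric(ht), ablation = abl,
              t(stats::setNames(cv$fold_scores, paste0("fold", 1:5))),
              mean_score = cv$mean_score)
          }
        }
      }
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  skips <- if (length(skips)) do.call(rbind, skips) else NULL

  agg <- NULL
  if (!is.null(results)) {
    agg <- stats::aggregate(mean_score ~ spatial_method + family +
                              half_time_min + ablation,
                            data = results,
                            FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                                n = length(v)))
    agg <- cbind(agg[, 1:4],
                 mean = agg$mean_score[, "mean"],
                 sd = agg$mean_score[, "sd"],
                 n = agg$mean_score[, "n"])
    agg$mean_pct <- 100 * agg$mean
    agg$sd_pct <- 100 * agg$sd
  }
  structure(list(results = results, aggregate = agg, skips = skips,
                 half_times = half_times, spatial_methods = spatial_methods,
                 families = families, seed = seed, pooled = pooled),
            class = "ablation_result")
}

# Coerce a cohort-like object to a list of pre-quit event streams.
cohort_streams <- function(cohort) {
  if (inherits(cohort, "smoking_cohort")) {
    lapply(seq_along(cohort$streams), function(i) {
      s <- cohort$streams[[i]]
      st <- event_stream(s$participant_id, s$fixes, s$reports, s$timezone,
                         metadata = cohort$metadata[i, , drop = FALSE])
      restrict_to_prequit(st, cohort$metadata$quit_datetime[i])
    })
  } else if (is.list(cohort) && all(vapply(cohort, inherits, logical(1), "event_stream"))) {
    cohort
  } else {
    stop("cohort must be a smoking_cohort or a list of event_streams", call. = FALSE)
  }
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("Feature-ablation modeling grid (Macro-F1)\n")
  cat(sprintf("  participants: %d | half-times: %s min | methods: %s | families: %s\n",
              length(unique(x$results$participant_id)),
              paste(x$half_times, collapse = "/"),
              paste(x$spatial_methods, collapse = ", "),
              paste(toupper(x$families), collapse = ", ")))
  if (!is.null(x$skips)) cat(sprintf("  skipped cells: %d\n", nrow(x$skips)))
  cat("\n")
  print(summary(x), ...)
  invisible(x)
}

#' @export
summary.ablation_result <- function(object, ...) {
  agg <- object$aggregate
  if (is.null(agg)) return(invisible(NULL))
  wide <- stats::reshape(
    agg[, c("spatial_method", "family", "half_time_min", "ablation", "mean_pct")],
    idvar = c("spatial_method", "family", "half_time_min"),
    timevar = "ablation", direction = "wide")
  names(wide) <- sub("mean_pct.", "", names(wide), fixed = TRUE)
  wide <- wide[order(wide$spatial_method, wide$family, -wide$half_time_min), ]
  rownames(wide) <- NULL
  wide
}
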