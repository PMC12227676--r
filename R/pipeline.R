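# End-to-end orchestration: simulate -> harmonize -> features -> model ->
# stats -> report, with a YAML-configurable entry point and publication-shaped
# report tables.

#' Default pipeline configuration
#'
#' A small demonstration configuration: 6 participants, one half-time
#' interval, logistic regression only. All keys can be overridden in a YAML
#' file passed to [run_pipeline()].
#'
#' @param seed master seed.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    generator = list(n_participants = 6L),
    harmonization = list(half_times = 15, bin_width_min = 15),
    spatial = list(methods = c("dbscan", "kmeans", "dfi"),
                   eps_m = 100, min_samples = 5L, k_range = c(2L, 10L)),
    modeling = list(families = "lr", mlp_epochs = 200L),
    stats = list(alpha = 0.05, association_bin_widths = c(15, 30),
                 run_associations = TRUE)
  )
}

validate_run_config <- function(config) {
  known <- c("seed", "generator", "harmonization", "spatial", "modeling", "stats")
  extra <- setdiff(names(config), known)
  if (length(extra)) {
    stop(sprintf("unknown configuration key: `%s`", extra[1]), call. = FALSE)
  }
  base <- default_run_config(config$seed %||% 1L)
  for (k in known[-1]) {
    base[[k]] <- utils::modifyList(base[[k]], config[[k]] %||% list())
  }
  base$seed <- as.integer(config$seed %||% 1L)
  gen_known <- names(formals(generator_config))
  extra_g <- setdiff(names(base$generator), gen_known)
  if (length(extra_g)) {
    stop(sprintf("unknown configuration key: `generator.%s`", extra_g[1]), call. = FALSE)
  }
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a `smoking_cohort` (without occupancy timelines; ground truth is
#'   attached when the `ground_truth/` subdirectory is present).
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stop("no metadata.csv in ", dir, call. = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  streams <- vector("list", nrow(meta))
  truth <- vector("list", nrow(meta))
  quit <- numeric(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    pid <- meta$participant_id[i]
    st <- parse_event_stream(file.path(dir, paste0(pid, "_gps.csv")),
                             file.path(dir, paste0(pid, "_reports.csv")),
                             meta[i, , drop = FALSE])
    quit[i] <- as.numeric(parse_iso8601(meta$quit_datetime[i], meta$timezone[i]))
    streams[[i]] <- list(participant_id = pid, fixes = st$fixes,
                         reports = st$reports, timezone = meta$timezone[i],
                         window_end = .POSIXct(quit[i], tz = meta$timezone[i]))
    gt_path <- file.path(dir, "ground_truth", paste0(pid, ".json"))
    if (file.exists(gt_path)) truth[[i]] <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
  }
  meta$quit_datetime <- .POSIXct(quit, tz = "UTC")
  structure(list(streams = streams, metadata = meta, ground_truth = truth,
                 config = NULL),
            class = "smoking_cohort")
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, builds sample tables, runs the ablation
#' modeling grid, the paired Wilcoxon comparisons (overall and per
#' enrollment-era subgroup), the time-location association analysis, and
#' writes all report tables plus a run manifest to `out_dir`. Rerunning with
#' the same configuration and seed reproduces the outputs.
#'
#' @param config a configuration list, or a path to a YAML file of
#'   overrides; see [default_run_config()].
#' @param out_dir output directory.
#' @param cohort_dir optional existing cohort directory to analyse instead
#'   of simulating.
#' @return (invisibly) a list with the cohort, grid, comparisons, subgroup
#'   comparisons, associations and output paths.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         cohort_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  if (is.null(cohort_dir)) {
    gen_cfg <- do.call(generator_config,
                       c(config$generator, list(seed = config$seed)))
    cohort <- generate_cohort(gen_cfg, out_dir = file.path(out_dir, "cohort"))
  } else {
    cohort <- read_cohort(cohort_dir)
  }

  specs <- list(
    lr = model_spec("lr", seed = config$seed),
    rf = model_spec("rf", seed = config$seed),
    mlp = model_spec("mlp", max_epochs = config$modeling$mlp_epochs,
                     seed = config$seed))
  sp_cfg <- lapply(c(dbscan = "dbscan", kmeans = "kmeans", dfi = "dfi"),
                   function(m) spatial_config(m, eps_m = config$spatial$eps_m,
                                              min_samples = config$spatial$min_samples,
                                              k_range = config$spatial$k_range,
                                              seed = config$seed))
  grid <- ablation_grid(cohort,
                        half_times = config$harmonization$half_times,
                        spatial_methods = config$spatial$methods,
                        families = config$modeling$families,
                        model_specs = specs, spatial_cfg = sp_cfg,
                        bin_width_min = config$harmonization$bin_width_min,
                        seed = config$seed)
  comparisons <- compare_ablations(grid)

  split <- covid_subgroup_split(cohort$metadata)
  group_comparisons <- list()
  for (g in c("during", "post")) {
    ids <- split[[g]]
    if (length(ids) == 0) next
    sub <- grid
    sub$results <- grid$results[grid$results$participant_id %in% ids, , drop = FALSE]
    if (nrow(sub$results) == 0) next
    group_comparisons[[g]] <- compare_ablations(sub)
  }

  associations <- NULL
  if (isTRUE(config$stats$run_associations)) {
    associations <- lapply(config$stats$association_bin_widths, function(bw) {
      adata <- association_data(cohort, half_time_min = config$harmonization$half_times[1],
                                bin_width_min = bw, spatial_cfg = sp_cfg$dbscan)
      association_analysis(adata, bin_width_min = bw,
                           alpha = config$stats$alpha)
    })
    names(associations) <- paste0("bw", config$stats$association_bin_widths)
  }

  run <- list(cohort = cohort, grid = grid, comparisons = comparisons,
              group_comparisons = group_comparisons,
              associations = associations, config = config,
              config_hash = cfg_hash, out_dir = out_dir)
  render_reports(run, out_dir)
  invisible(run)
}

# Assemble the per-sample data frame for the association analysis: DBSCAN
# cluster per sample, time bin at the requested width, smoking label.
association_data <- function(cohort, half_time_min = 15, bin_width_min = 15,
                             spatial_cfg = spatial_config("dbscan")) {
  streams <- cohort_streams(cohort)
  rows <- lapply(streams, function(s) {
    tab <- build_sample_table(s, half_time_min, bin_width_min)
    rep <- spatial_representation(tab, spatial_cfg)
    data.frame(participant_id = tab$participant_id, bin = tab$bin,
               cluster = rep$values, label = tab$label)
  })
  do.call(rbind, rows)
}

#' Write publication-shaped report tables for a pipeline run
#'
#' Produces the data-characteristics summary (per enrollment-era group and
#' overall), the ablation-grid table with "mean (SD)" percent cells and
#' significance stars, the sensitivity (subgroup) version, the raw results
#' and comparisons CSVs, the association summaries, and a JSON manifest
#' recording the configuration hash so every file is traceable to the run.
#'
#' @param run the list produced by [run_pipeline()].
#' @param out_dir output directory.
#' @return (invisibly) character vector of files written.
#' @export
render_reports <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }

  wr(characteristics_table(run$cohort), "data_characteristics.csv")
  if (!is.null(run$grid$results)) {
    wr(run$grid$results, "grid_results.csv")
    wr(run$grid$aggregate, "grid_aggregate.csv")
    wr(grid_report_table(run$grid, run$comparisons), "grid_table.csv")
  }
  wr(run$comparisons, "comparisons.csv")
  for (g in names(run$group_comparisons)) {
    wr(run$group_comparisons[[g]], sprintf("comparisons_%s.csv", g))
    wr(grid_report_table(run$grid, run$group_comparisons[[g]],
                         participants = covid_subgroup_split(run$cohort$metadata)[[g]]),
       sprintf("grid_table_%s.csv", g))
  }
  support <- list()
  for (nm in names(run$associations)) {
    a <- run$associations[[nm]]
    if (!is.null(a$associations)) wr(a$associations, sprintf("associations_%s.csv", nm))
    if (!is.null(a$support)) support[[nm]] <- a$support
  }
  if (length(support)) {
    jsonlite::write_json(support, file.path(out_dir, "support_summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    files <- c(files, file.path(out_dir, "support_summary.json"))
  }
  manifest <- list(config_hash = unname(run$config_hash),
                   seed = run$config$seed,
                   package_version = as.character(utils::packageVersion("geosmoke")),
                   files = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(files)
}

# "mean (SD)" percent cells with stars, one row per configuration and
# half-time, mirroring the published grid layout.
grid_report_table <- function(grid, comparisons, participants = NULL) {
  res <- grid$results
  if (!is.null(participants)) {
    res <- res[res$participant_id %in% participants, , drop = FALSE]
  }
  if (nrow(res) == 0) return(data.frame())
  cell <- function(v) sprintf("%.2f (%.2f)", 100 * mean(v), 100 * stats::sd(v))
  cfgs <- unique(res[, c("spatial_method", "family", "half_time_min")])
  cfgs <- cfgs[order(cfgs$spatial_method, cfgs$family, -cfgs$half_time_min), ]
  rows <- lapply(seq_len(nrow(cfgs)), function(i) {
    sel <- res$spatial_method == cfgs$spatial_method[i] &
      res$family == cfgs$family[i] & res$half_time_min == cfgs$half_time_min[i]
    sub <- res[sel, ]
    star_of <- function(abl) {
      cc <- comparisons[comparisons$spatial_method == cfgs$spatial_method[i] &
                          comparisons$family == cfgs$family[i] &
                          comparisons$half_time_min == cfgs$half_time_min[i] &
                          comparisons$excluded == abl, "stars"]
      if (length(cc)) cc[1] else ""
    }
    get <- function(abl) {
      v <- sub$mean_score[sub$ablation == abl]
      if (length(v)) cell(v) else "NA"
    }
    data.frame(
      method = sprintf("%s + %s", toupper(cfgs$spatial_method[i]),
                       toupper(cfgs$family[i])),
      half_time_min = cfgs$half_time_min[i],
      all_features = get("ALL"),
      location_excluded = paste0(get("NO_LOCATION"), star_of("NO_LOCATION")),
      time_excluded = paste0(get("NO_TIME"), star_of("NO_TIME")))
  })
  do.call(rbind, rows)
}

# Table of data characteristics: mean (SD) per enrollment-era group and
# overall, for fixes, events, modeling samples, smoking-labeled samples and
# DBSCAN cluster counts.
characteristics_table <- function(cohort, half_time_min = 15) {
  streams <- cohort_streams(cohort)
  per <- lapply(seq_along(streams), function(i) {
    s <- streams[[i]]
    tab <- build_sample_table(s, half_time_min)
    cl <- dbscan_clusters(s$fixes$lat, s$fixes$lon)
    data.frame(participant_id = s$participant_id,
               group = cohort$metadata$group[i],
               gps_positions = nrow(s$fixes),
               smoking_events = nrow(s$reports),
               all_samples = nrow(tab),
               smoking_samples = sum(tab$label == 1),
               dbscan_clusters = length(setdiff(unique(cl), -1L)))
  })
  per <- do.call(rbind, per)
  fmt <- function(v) sprintf("%.2f (%.2f)", mean(v), stats::sd(v))
  vars <- c("gps_positions", "smoking_events", "all_samples",
            "smoking_samples", "dbscan_clusters")
  groups <- list(all = per, during = per[per$group == "during", ],
                 post = per[per$group == "post", ])
  out <- data.frame(variable = vars)
  for (g in names(groups)) {
    gp <- groups[[g]]
    out[[g]] <- if (nrow(gp) >= 2) vapply(vars, function(v) fmt(gp[[v]]), character(1))
    else rep(NA_character_, length(vars))
  }
  out
}
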