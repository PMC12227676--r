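# Per-participant location representations: DBSCAN stay clusters, K-means
# stay clusters with silhouette-selected k, and distance-from-initial.

#' Spatial feature configuration
#'
#' @param method `"dbscan"`, `"kmeans"` or `"dfi"`.
#' @param eps_m DBSCAN neighborhood radius in meters. Default 100, the order
#'   of the app's movement-trigger granularity.
#' @param min_samples DBSCAN density threshold (neighbors counting the point
#'   itself). Default 5.
#' @param k_range inclusive integer range of candidate K-means cluster
#'   counts; lower bound >= 2. Default 2..10.
#' @param distance_model `"haversine"` or `"equirectangular"` for distance
#'   computations.
#' @param seed seed for the K-means restarts.
#' @return a validated `spatial_config` list.
#' @export
spatial_config <- function(method = c("dbscan", "kmeans", "dfi"),
                           eps_m = 100, min_samples = 5L,
                           k_range = c(2L, 10L),
                           distance_model = c("haversine", "equirectangular"),
                           seed = 1L) {
  method <- match.arg(method)
  distance_model <- match.arg(distance_model)
  if (!is_scalar_num(eps_m) || eps_m <= 0) stop_config("eps_m", "must be > 0")
  if (!is_count(min_samples) || min_samples < 1) {
    stop_config("min_samples", "must be an integer >= 1")
  }
  if (length(k_range) != 2 || !is_count(k_range[1]) || !is_count(k_range[2]) ||
      k_range[1] < 2 || k_range[1] > k_range[2]) {
    stop_config("k_range", "must be an increasing integer pair with lower bound >= 2")
  }
  structure(list(method = method, eps_m = eps_m,
                 min_samples = as.integer(min_samples),
                 k_range = as.integer(k_range),
                 distance_model = distance_model, seed = as.integer(seed)),
            class = "spatial_config")
}

#' DBSCAN clustering of GPS fixes
#'
#' Standard DBSCAN over great-circle distances: a point is a core point iff
#' at least `min_samples` points (itself included) lie within `eps_m`;
#' clusters are the connected components of core points under
#' eps-reachability together with their border points; unreachable points
#' are labeled noise (-1). Cluster ids are assigned in order of first
#' appearance, so the labeling is deterministic.
#'
#' @param lat,lon coordinate vectors (decimal degrees).
#' @param config a [spatial_config()].
#' @return integer labels: 0, 1, ... for clusters, -1 for noise.
#' @export
dbscan_clusters <- function(lat, lon, config = spatial_config("dbscan")) {
  n <- length(lat)
  if (n == 0) stop("dbscan requires at least one point", call. = FALSE)
  # neighborhoods from the pairwise great-circle distance matrix; fix counts
  # per participant are a few hundred, so the dense matrix is fine
  d <- great_circle_distance(rep(lat, each = n), rep(lon, each = n),
                             rep(lat, times = n), rep(lon, times = n),
                             config$distance_model)
  dim(d) <- c(n, n)
  within <- d <= config$eps_m
  deg <- colSums(within)
  core <- deg >= config$min_samples

  labels <- rep(-1L, n)
  cluster_id <- -1L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cluster_id <- cluster_id + 1L
    labels[i] <- cluster_id
    frontier <- i
    while (length(frontier)) {
      nb <- which(rowSums(within[, frontier, drop = FALSE]) > 0)
      fresh <- nb[labels[nb] == -1L]
      labels[fresh] <- cluster_id
      frontier <- fresh[core[fresh]]  # only core points expand further
    }
  }
  labels
}

#' Select the number of K-means clusters by silhouette
#'
#' Runs K-means for each feasible k in `k_range` (k below the number of
#' distinct points) on locally projected planar coordinates and returns the
#' k maximizing the mean silhouette width; ties go to the smaller k. With
#' fewer than 3 distinct points no k is feasible and the sentinel k = 1 is
#' returned with a warning.
#'
#' @param lat,lon coordinates.
#' @param k_range inclusive candidate range.
#' @param seed seed for K-means restarts.
#' @return list: `k` (chosen), `silhouette` (named vector of mean widths).
#' @export
silhouette_select_k <- function(lat, lon, k_range = c(2L, 10L), seed = 1L) {
  if (length(lat) == 0) stop("empty input", call. = FALSE)
  xy <- project_local(lat, lon)
  n_distinct <- nrow(unique(round(xy, 9)))
  ks <- seq(k_range[1], k_range[2])
  ks <- ks[ks < n_distinct]
  if (length(ks) == 0) {
    warning("fewer than 3 distinct points; falling back to a single cluster",
            call. = FALSE)
    return(list(k = 1L, silhouette = numeric(0)))
  }
  dmat <- stats::dist(xy)
  sil <- vapply(ks, function(k) {
    km <- with_seed(seed, stats::kmeans(xy, centers = k, nstart = 10L,
                                        iter.max = 100L))
    mean(cluster::silhouette(km$cluster, dmat)[, "sil_width"])
  }, numeric(1))
  names(sil) <- ks
  list(k = ks[which.max(sil)], silhouette = sil)  # which.max: smallest on ties
}

#' K-means stay clusters with silhouette-selected k
#'
#' K-means on locally projected planar coordinates (equirectangular about
#' the participant centroid), with the cluster count chosen by
#' [silhouette_select_k()], a fixed seed and 10 restarts. Labels are
#' relabeled in order of first appearance so reruns are stable.
#'
#' @param lat,lon coordinates.
#' @param config a [spatial_config()].
#' @return list: `labels` (0-based integer labels), `chosen_k`, `centers`
#'   (matrix in projected meters), `inertia` (total within-cluster sum of
#'   squares).
#' @export
kmeans_clusters <- function(lat, lon, config = spatial_config("kmeans")) {
  sel <- silhouette_select_k(lat, lon, config$k_range, config$seed)
  xy <- project_local(lat, lon)
  if (sel$k == 1L) {
    ctr <- matrix(colMeans(xy), nrow = 1)
    return(list(labels = rep(0L, length(lat)), chosen_k = 1L, centers = ctr,
                inertia = sum(sweep(xy, 2, ctr)^2)))
  }
  km <- with_seed(config$seed, stats::kmeans(xy, centers = sel$k, nstart = 10L,
                                             iter.max = 100L))
  # first-appearance relabeling
  first <- unique(km$cluster)
  remap <- integer(max(km$cluster)); remap[first] <- seq_along(first) - 1L
  list(labels = remap[km$cluster], chosen_k = as.integer(sel$k),
       centers = km$centers[first, , drop = FALSE],
       inertia = km$tot.withinss)
}

#' Distance from the initial recorded location
#'
#' Straight-line (great-circle) distance of every fix from the participant's
#' earliest fix.
#'
#' @param lat,lon coordinates, in time order.
#' @param distance_model `"haversine"` (default) or `"equirectangular"`.
#' @return numeric vector of meters; the first element is 0.
#' @export
distance_from_initial <- function(lat, lon, distance_model = "haversine") {
  if (length(lat) == 0) stop("empty input", call. = FALSE)
  great_circle_distance(lat[1], lon[1], lat, lon, distance_model)
}

#' Compute a spatial representation for a sample table
#'
#' Applies the configured method to the table's coordinates (all rows,
#' fallback samples included, since every sample must reach the classifier).
#'
#' @param sample_table a [build_sample_table()] result (or any data.frame
#'   with `lat`, `lon` in time order).
#' @param config a [spatial_config()].
#' @return a `spatial_representation`: list with `method`, `values`
#'   (integer labels or meters), and `chosen_k` for K-means.
#' @export
spatial_representation <- function(sample_table, config) {
  stopifnot(inherits(config, "spatial_config"))
  lat <- sample_table$lat; lon <- sample_table$lon
  out <- switch(config$method,
    dbscan = list(values = dbscan_clusters(lat, lon, config), chosen_k = NA_integer_),
    kmeans = {
      km <- kmeans_clusters(lat, lon, config)
      list(values = km$labels, chosen_k = km$chosen_k)
    },
    dfi = list(values = distance_from_initial(lat, lon, config$distance_model),
               chosen_k = NA_integer_)
  )
  structure(list(method = config$method, values = out$values,
                 chosen_k = out$chosen_k), class = "spatial_representation")
}

#' Encode a spatial representation as model feature columns
#'
#' Cluster labels become one-hot columns (DBSCAN noise gets its own column);
#' DFI becomes a single numeric column z-scored over the participant's
#' samples (a zero-variance column is passed as zeros). The encoding is
#' identical across model families.
#'
#' @param representation a [spatial_representation()].
#' @param levels optional fixed label set (training-time levels); labels
#'   unseen in `levels` encode as all-zero rows with a warning.
#' @return numeric matrix with one row per sample.
#' @export
encode_location_feature <- function(representation, levels = NULL) {
  v <- representation$values
  if (representation$method == "dfi") {
    s <- stats::sd(v)
    col <- if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    return(matrix(col, ncol = 1, dimnames = list(NULL, "dfi")))
  }
  if (is.null(levels)) levels <- sort(unique(v))
  m <- matrix(0, nrow = length(v), ncol = length(levels),
              dimnames = list(NULL, paste0("loc_", levels)))
  idx <- match(v, levels)
  if (anyNA(idx)) {
    warning("labels unseen in training encoded as all-zero rows", call. = FALSE)
  }
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}
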