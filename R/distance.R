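#' Great-circle distance between coordinate pairs
#'
#' Distance in meters between points on the WGS84 sphere, either by the
#' haversine formula (mean Earth radius 6371008.8 m) or by a local
#' equirectangular approximation (adequate at the city scale this package
#' works at, and the metric under which planar clustering is run).
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees; vectors recycle.
#' @param distance_model `"haversine"` (default) or `"equirectangular"`.
#' @return numeric vector of distances in meters.
#' @examples
#' great_circle_distance(45, -93, 46, -93)  # ~111.19 km
#' @export
great_circle_distance <- function(lat1, lon1, lat2, lon2,
                                  distance_model = c("haversine", "equirectangular")) {
  distance_model <- match.arg(distance_model)
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE)) {
    stop("latitude outside [-90, 90]", call. = FALSE)
  }
  if (any(abs(c(lon1, lon2)) > 180, na.rm = TRUE)) {
    stop("longitude outside [-180, 180]", call. = FALSE)
  }
  R <- 6371008.8
  rad <- pi / 180
  phi1 <- lat1 * rad; phi2 <- lat2 * rad
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  if (distance_model == "haversine") {
    a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
    a <- pmin(pmax(a, 0), 1)
    2 * R * asin(sqrt(a))
  } else {
    x <- dlam * cos((phi1 + phi2) / 2)
    R * sqrt(x * x + dphi * dphi)
  }
}

# Project lat/lon to local planar meters about a reference point
# (equirectangular): x east, y north. Used for K-means and silhouette.
project_local <- function(lat, lon, ref_lat = mean(lat), ref_lon = mean(lon)) {
  R <- 6371008.8
  rad <- pi / 180
  cbind(x = (lon - ref_lon) * rad * R * cos(ref_lat * rad),
        y = (lat - ref_lat) * rad * R)
}
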