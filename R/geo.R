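# Great-circle distances, snapping of samples to the river network, and
# along-network river distances. Coordinates are WGS84 lon/lat degrees;
# all distances are meters on a sphere of radius 6,371,008.8 m (IUGG mean).

EARTH_RADIUS_M <- 6371008.8

#' Great-circle (haversine) distance
#'
#' @param p1,p2 numeric `(lon, lat)` in degrees, or matrices of such rows.
#' @return distance(s) in meters.
#' @export
haversine_m <- function(p1, p2) {
  p1 <- rbind(p1); p2 <- rbind(p2)
  check_lonlat(p1); check_lonlat(p2)
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M)
}

check_lonlat <- function(p) {
  if (anyNA(p) || any(abs(p[, 1]) > 180) || any(abs(p[, 2]) > 90)) {
    stop("invalid lon/lat coordinates", call. = FALSE)
  }
  invisible(p)
}

#' Pairwise great-circle distance matrix for a sample set
#'
#' @param s sample data frame with columns `id`, `lon`, `lat`.
#' @return distance matrix in meters.
#' @export
haversine_matrix <- function(s) {
  s <- as_sample_set(s)
  p <- cbind(s$lon, s$lat)
  n <- nrow(p)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d[i, j] <- d[j, i] <- haversine_m(p[rep(i, length(j)), , drop = FALSE],
                                      p[j, , drop = FALSE])
  }
  dist_matrix(d, ids = s$id)
}

# normalize a sample table: id, lon, lat (+ optional basin, clade, snap_offset)
as_sample_set <- function(s) {
  s <- as.data.frame(s)
  need <- c("id", "lon", "lat")
  if (!all(need %in% names(s))) {
    stop("sample set needs columns id, lon, lat", call. = FALSE)
  }
  s$id <- as.character(s$id)
  if (anyDuplicated(s$id)) stop("duplicate sample ids", call. = FALSE)
  check_lonlat(cbind(s$lon, s$lat))
  if (is.null(s$basin)) s$basin <- NA
  if (is.null(s$clade)) s$clade <- NA
  if (is.null(s$snap_offset)) s$snap_offset <- 0
  s
}

#' Read / write a sample set as CSV
#'
#' Columns `id, lon, lat, basin, clade` (and `snap_offset` once snapped).
#'
#' @param s sample data frame.
#' @param path file path.
#' @return the sample data frame / `path` invisibly.
#' @export
write_sample_set <- function(s, path) {
  utils::write.csv(as_sample_set(s), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_sample_set
#' @export
read_sample_set <- function(path) {
  as_sample_set(utils::read.csv(path, colClasses = c(id = "character")))
}

#' Move samples to the nearest point on the river network
#'
#' Each sample is replaced by its nearest point on any arc (computed by
#' planar projection in a local equirectangular frame centered on the
#' sample), its `basin` label is set from the arc, and the great-circle
#' distance moved is recorded in `snap_offset`. The arc index and
#' along-arc position (m) are kept in columns `.arc` and `.s` for the
#' river-distance graph.
#'
#' @param s sample data frame (`id`, `lon`, `lat`, ...).
#' @param net a `river_network`.
#' @return the snapped sample data frame.
#' @export
snap_to_network <- function(s, net) {
  s <- as_sample_set(s)
  if (!inherits(net, "river_network")) stop("net must be a river_network", call. = FALSE)
  hit <- snap_points(s$lon, s$lat, net)
  s$lon <- hit$lon
  s$lat <- hit$lat
  s$basin <- net$basin_id[hit$arc]
  s$snap_offset <- hit$offset
  s$.arc <- hit$arc
  s$.s <- hit$s
  s
}

#' River-network distances between snapped samples
#'
#' Builds a graph whose nodes are the arc vertices plus the snapped sample
#' positions (arcs split at the insertion points) with edges weighted by
#' summed haversine polyline length, and returns shortest-path distances
#' along the network. Pairs of samples in disconnected components
#' (different basins) are `NA` — treated as missing downstream.
#'
#' @param s snapped sample data frame (from [snap_to_network()]).
#' @param net the `river_network` used for snapping.
#' @return distance matrix in meters with `NA` for cross-basin pairs.
#' @export
river_distance_matrix <- function(s, net) {
  s <- as_sample_set(s)
  if (is.null(s$.arc) || is.null(s$.s)) {
    stop("samples are not snapped; call snap_to_network() first", call. = FALSE)
  }
  g <- network_graph(net, points = list(id = s$id, arc = s$.arc, s = s$.s))
  keys <- paste0("pt:", s$id)
  d <- network_node_distances(g, keys)[, keys, drop = FALSE]
  d[is.infinite(d)] <- NA
  d <- (d + t(d)) / 2  # guard against float asymmetry in the search
  diag(d) <- 0
  dist_matrix(d, ids = s$id)
}
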