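# River networks: lists of polyline arcs (lon/lat degrees, WGS84), one
# tree-shaped connected component per drainage basin. Arcs meeting at a
# junction share an endpoint up to JUNCTION_TOL degrees.

JUNCTION_TOL <- 1e-6
METERS_PER_DEG <- pi * 6371008.8 / 180  # at the equator / along meridians

#' Construct a river network
#'
#' @param arcs list of polylines; each a numeric matrix with columns
#'   `lon`, `lat` (degrees) and at least 2 rows.
#' @param basin_id integer basin label per arc; arcs sharing an endpoint
#'   must share a basin id. If `NULL`, labels are inferred from the
#'   connected components of the arc graph.
#' @param outlets optional matrix (one row per basin: lon, lat) marking
#'   each basin's outlet; used by the altitude-surface generator.
#' @return object of class `river_network`.
#' @export
river_network <- function(arcs, basin_id = NULL, outlets = NULL) {
  if (length(arcs) == 0) stop("empty river network", call. = FALSE)
  arcs <- lapply(arcs, function(a) {
    a <- as.matrix(a)
    if (ncol(a) != 2 || nrow(a) < 2) {
      stop("each arc must be a matrix of >= 2 (lon, lat) rows", call. = FALSE)
    }
    colnames(a) <- c("lon", "lat")
    a
  })
  comp <- arc_components(arcs)
  if (is.null(basin_id)) {
    basin_id <- comp
  } else {
    basin_id <- as.integer(basin_id)
    if (length(basin_id) != length(arcs)) {
      stop("basin_id must have one label per arc", call. = FALSE)
    }
    if (any(tapply(basin_id, comp, function(x) length(unique(x))) != 1)) {
      stop("arcs sharing an endpoint must share a basin_id", call. = FALSE)
    }
  }
  structure(list(arcs = arcs, basin_id = basin_id, outlets = outlets),
            class = "river_network")
}

#' @export
print.river_network <- function(x, ...) {
  cat("river_network:", length(x$arcs), "arcs,",
      length(unique(x$basin_id)), "basins,",
      round(network_total_length(x) / 1000, 1), "km total\n")
  invisible(x)
}

node_key <- function(lon, lat) {
  sprintf("%.6f_%.6f", round(lon / JUNCTION_TOL) * JUNCTION_TOL,
          round(lat / JUNCTION_TOL) * JUNCTION_TOL)
}

# connected components of the arc-endpoint graph
arc_components <- function(arcs) {
  ends <- lapply(arcs, function(a) node_key(a[c(1, nrow(a)), 1], a[c(1, nrow(a)), 2]))
  nodes <- unique(unlist(ends))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  idx <- lapply(ends, match, nodes)
  g <- igraph::add_edges(g, unlist(idx))
  memb <- igraph::components(g)$membership
  vapply(idx, function(e) memb[e[1]], numeric(1))
}

# haversine length (m) of each segment of a polyline matrix
segment_lengths <- function(a) {
  n <- nrow(a)
  geosphere::distHaversine(a[-n, , drop = FALSE], a[-1, , drop = FALSE],
                           r = 6371008.8)
}

arc_length <- function(a) sum(segment_lengths(a))

#' Total network length in meters
#' @param net a `river_network`.
#' @return scalar meters.
#' @export
network_total_length <- function(net) {
  sum(vapply(net$arcs, arc_length, numeric(1)))
}

#' Write / read a river network as GeoJSON
#'
#' A `FeatureCollection` of `LineString` features with a `basin_id`
#' property. On reading, a missing `basin_id` is inferred from the
#' connected components.
#'
#' @param net a `river_network`.
#' @param path file path.
#' @return `read_river_network` returns the network; the writer returns
#'   `path` invisibly.
#' @export
write_river_network <- function(net, path) {
  feats <- lapply(seq_along(net$arcs), function(i) {
    list(type = "Feature",
         properties = list(basin_id = net$basin_id[i]),
         geometry = list(type = "LineString",
                         coordinates = unname(net$arcs[[i]])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' @rdname write_river_network
#' @export
read_river_network <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  arcs <- list(); basin <- integer(0); any_basin <- TRUE
  for (f in gj$features) {
    if (!identical(f$geometry$type, "LineString")) {
      stop("only LineString geometries are supported", call. = FALSE)
    }
    coords <- do.call(rbind, lapply(f$geometry$coordinates,
                                    function(p) c(p[[1]], p[[2]])))
    arcs[[length(arcs) + 1]] <- coords
    b <- f$properties$basin_id
    if (is.null(b)) any_basin <- FALSE else basin <- c(basin, as.integer(b))
  }
  river_network(arcs, basin_id = if (any_basin) basin else NULL)
}

# --- geometry: nearest point on the network -------------------------------

# Snap many points to a set of polylines. Returns per point: arc index,
# distance s (m, haversine-summed) from the arc start, snapped lon/lat and
# offset moved (m). Projection is planar in a local equirectangular frame
# centered on each point.
snap_points <- function(lon, lat, net) {
  n <- length(lon)
  best <- list(d2 = rep(Inf, n), arc = integer(n), s = numeric(n),
               lon = numeric(n), lat = numeric(n))
  coslat <- cos(lat * pi / 180)
  for (ai in seq_along(net$arcs)) {
    a <- net$arcs[[ai]]
    seglen <- segment_lengths(a)
    cum <- c(0, cumsum(seglen))
    for (si in seq_len(nrow(a) - 1)) {
      x1 <- (a[si, 1] - lon) * coslat; y1 <- a[si, 2] - lat
      x2 <- (a[si + 1, 1] - lon) * coslat; y2 <- a[si + 1, 2] - lat
      dx <- x2 - x1; dy <- y2 - y1
      len2 <- dx * dx + dy * dy
      t <- ifelse(len2 > 0, pmin(1, pmax(0, -(x1 * dx + y1 * dy) / len2)), 0)
      px <- x1 + t * dx; py <- y1 + t * dy
      d2 <- px * px + py * py
      hit <- d2 < best$d2
      if (any(hit)) {
        best$d2[hit] <- d2[hit]
        best$arc[hit] <- ai
        best$s[hit] <- cum[si] + t[hit] * seglen[si]
        best$lon[hit] <- a[si, 1] + t[hit] * (a[si + 1, 1] - a[si, 1])
        best$lat[hit] <- a[si, 2] + t[hit] * (a[si + 1, 2] - a[si, 2])
      }
    }
  }
  best$offset <- geosphere::distHaversine(cbind(lon, lat),
                                          cbind(best$lon, best$lat),
                                          r = 6371008.8)
  best
}

# igraph over arc vertices (+ optionally named extra points at (arc, s)
# positions, inserted by splitting the arc). Edge weights: haversine meters.
network_graph <- function(net, points = NULL) {
  edges <- character(0); weights <- numeric(0)
  for (ai in seq_along(net$arcs)) {
    a <- net$arcs[[ai]]
    seglen <- segment_lengths(a)
    cum <- c(0, cumsum(seglen))
    keys <- node_key(a[, 1], a[, 2])
    pos <- cum; labels <- keys
    if (!is.null(points)) {
      on_arc <- which(points$arc == ai)
      if (length(on_arc)) {
        pos <- c(pos, points$s[on_arc])
        labels <- c(labels, paste0("pt:", points$id[on_arc]))
        o <- order(pos)
        pos <- pos[o]; labels <- labels[o]
      }
    }
    for (k in seq_len(length(pos) - 1)) {
      edges <- c(edges, labels[k], labels[k + 1])
      weights <- c(weights, max(pos[k + 1] - pos[k], 0))
    }
  }
  g <- igraph::make_graph(edges, directed = FALSE)
  igraph::E(g)$weight <- weights
  g
}

# network distance (m) from given nodes to all nodes; Inf if disconnected
network_node_distances <- function(g, from) {
  igraph::distances(g, v = from, weights = igraph::E(g)$weight)
}

# per-basin outlet coordinates: recorded by the generator, else the first
# vertex of each basin's first arc
basin_outlets <- function(net) {
  basins <- sort(unique(net$basin_id))
  if (!is.null(net$outlets)) {
    out <- as.matrix(net$outlets)
    if (nrow(out) != length(basins)) stop("one outlet per basin expected", call. = FALSE)
    rownames(out) <- basins
    return(out)
  }
  out <- t(vapply(basins, function(b) {
    net$arcs[[which(net$basin_id == b)[1]]][1, ]
  }, numeric(2)))
  rownames(out) <- basins
  out
}
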