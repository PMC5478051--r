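# Altitude least-cost paths. The raster is turned into an 8-connected cell
# graph; each transition carries a conductance computed from the two cell
# altitudes, geo-corrected by dividing by the great-circle distance between
# the cell centers so that accumulated costs have length units.

#' Transition specification for least-cost paths
#'
#' @param conductance_fn function of two altitude vectors returning a
#'   positive conductance; the default `"inverse_mean_altitude"` is
#'   `1 / mean(h1, h2)` with altitudes floored, so higher terrain is more
#'   resistant.
#' @param altitude_floor altitudes are clamped below at this value (m > 0)
#'   before the conductance is evaluated.
#' @return object of class `transition_spec` (8-connected neighborhood).
#' @export
transition_spec <- function(conductance_fn = "inverse_mean_altitude",
                            altitude_floor = 1) {
  stopifnot(altitude_floor > 0)
  if (is.character(conductance_fn)) {
    conductance_fn <- switch(conductance_fn,
      inverse_mean_altitude = function(h1, h2) 2 / (h1 + h2),
      stop("unknown conductance function '", conductance_fn, "'", call. = FALSE))
  }
  stopifnot(is.function(conductance_fn))
  structure(list(conductance_fn = conductance_fn,
                 altitude_floor = altitude_floor,
                 neighborhood = 8L),
            class = "transition_spec")
}

# 8-connected transitions of an n_rows x n_cols grid. Returns from/to cell
# indices (column-major, each unordered pair once).
grid_neighbors <- function(n_rows, n_cols) {
  cell <- function(row, col) (col - 1) * n_rows + row
  from <- integer(0); to <- integer(0)
  for (drc in list(c(0, 1), c(1, 0), c(1, 1), c(-1, 1))) {
    rows <- seq_len(n_rows); cols <- seq_len(n_cols)
    r1 <- rows[rows + drc[1] >= 1 & rows + drc[1] <= n_rows]
    c1 <- cols[cols + drc[2] >= 1 & cols + drc[2] <= n_cols]
    if (!length(r1) || !length(c1)) next
    rr <- rep(r1, times = length(c1)); cc <- rep(c1, each = length(r1))
    from <- c(from, cell(rr, cc))
    to <- c(to, cell(rr + drc[1], cc + drc[2]))
  }
  cbind(from = from, to = to)
}

#' Least-cost-path distances across an altitude raster
#'
#' Edge cost between neighboring cells i, j is
#' `haversine(center_i, center_j) / conductance(h_i, h_j)`: the reciprocal
#' of the geo-corrected conductance. On a flat raster of altitude equal to
#' the conductance floor this reduces to the along-path great-circle
#' length. Sample points resolve to the center of their containing cell;
#' pairs sharing a cell have distance 0. `NA` (NODATA) cells are
#' impassable; pairs separated by them come back `NA` with a warning.
#'
#' @param s sample data frame (`id`, `lon`, `lat`); all points must fall
#'   inside the raster extent.
#' @param r an `altitude_raster`.
#' @param trans a [transition_spec()].
#' @return distance matrix of accumulated costs (m-equivalent units).
#' @export
lcp_distance_matrix <- function(s, r, trans = transition_spec()) {
  s <- as_sample_set(s)
  stopifnot(inherits(r, "altitude_raster"))
  stopifnot(inherits(trans, "transition_spec"))
  rc <- cell_index(r, s$lon, s$lat)
  if (anyNA(rc)) {
    stop("points outside the raster extent: ",
         paste(s$id[is.na(rc[, 1])], collapse = ", "), call. = FALSE)
  }
  # cell index (col-1)*n_rows+row is the native column-major order of values
  h <- pmax(r$values, trans$altitude_floor)
  passable <- !is.na(r$values)
  nb <- grid_neighbors(r$n_rows, r$n_cols)
  ok <- passable[nb[, 1]] & passable[nb[, 2]]
  nb <- nb[ok, , drop = FALSE]
  cond <- trans$conductance_fn(h[nb[, 1]], h[nb[, 2]])
  if (any(cond <= 0)) stop("conductance must be positive", call. = FALSE)
  rc_from <- cbind((nb[, 1] - 1) %% r$n_rows + 1, (nb[, 1] - 1) %/% r$n_rows + 1)
  rc_to <- cbind((nb[, 2] - 1) %% r$n_rows + 1, (nb[, 2] - 1) %/% r$n_rows + 1)
  step <- geosphere::distHaversine(cell_center(r, rc_from[, 1], rc_from[, 2]),
                                   cell_center(r, rc_to[, 1], rc_to[, 2]),
                                   r = EARTH_RADIUS_M)
  g <- igraph::make_empty_graph(n = r$n_rows * r$n_cols, directed = FALSE)
  g <- igraph::add_edges(g, t(nb))
  igraph::E(g)$weight <- step / cond
  cells <- (rc[, "col"] - 1) * r$n_rows + rc[, "row"]
  ucells <- unique(cells)
  du <- igraph::distances(g, v = ucells, to = ucells, weights = igraph::E(g)$weight)
  d <- du[match(cells, ucells), match(cells, ucells), drop = FALSE]
  if (any(is.infinite(d))) {
    warning("some sample pairs are separated by NODATA cells; returning NA")
    d[is.infinite(d)] <- NA
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dist_matrix(d, ids = s$id)
}
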