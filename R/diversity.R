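#' Spatially windowed nucleotide diversity
#'
#' For each sampling point, nucleotide diversity is computed over all
#' samples (including the focal one) lying within `radius` meters
#' (great-circle) of it. Windows with fewer than 2 samples get `NA`.
#'
#' @param a alignment; ids must match the sample table.
#' @param s sample data frame (`id`, `lon`, `lat`).
#' @param radius window radius in meters (>= 0).
#' @param deletion ambiguous-site handling, see [nucleotide_diversity()].
#' @return named numeric vector of per-point diversity values.
#' @export
windowed_diversity <- function(a, s, radius = 10000, deletion = "pairwise") {
  a <- alignment(a)
  s <- as_sample_set(s)
  if (!setequal(names(a), s$id)) {
    stop("alignment ids and sample ids do not match", call. = FALSE)
  }
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  geo <- haversine_matrix(s)
  vapply(s$id, function(k) {
    window <- s$id[geo[k, ] <= radius]
    if (length(window) < 2) return(NA_real_)
    nucleotide_diversity(a[window], deletion = deletion)
  }, numeric(1))
}

#' Inverse-distance-weighted interpolation onto a grid
#'
#' Interpolates point values onto a regular lon/lat grid whose cell size
#' approximates `grid_cell_m` meters on a local equirectangular lattice.
#' Cell values are `sum(v_i / d_i^power) / sum(1 / d_i^power)` with `d_i`
#' the great-circle distance from the cell center; a point within 1 m of
#' a center supplies its value exactly, and `NA`-valued points are
#' dropped. IDW is a convex combination, so interpolated values never
#' leave the range of the inputs.
#'
#' @param s sample data frame (`id`, `lon`, `lat`).
#' @param values named (or sample-ordered) point values; `NA` allowed.
#' @param grid_cell_m target cell edge in meters.
#' @param power IDW exponent (> 0).
#' @param extent bounding box `c(lon_min, lon_max, lat_min, lat_max)`;
#'   defaults to the padded point extent.
#' @return an `altitude_raster`-shaped grid of interpolated values (class
#'   `altitude_raster` is not used; this is a plain list with `origin`,
#'   `cell_size`, `values` and `power`).
#' @export
idw_interpolate <- function(s, values, grid_cell_m = 1000, power = 2,
                            extent = NULL) {
  s <- as_sample_set(s)
  if (!is.null(names(values))) values <- values[s$id]
  if (length(values) != nrow(s)) {
    stop("need one value per sample", call. = FALSE)
  }
  ok <- !is.na(values)
  if (!any(ok)) stop("no non-missing point values to interpolate", call. = FALSE)
  if (power <= 0) stop("power must be > 0", call. = FALSE)
  pts <- cbind(s$lon[ok], s$lat[ok])
  vals <- values[ok]
  if (is.null(extent)) {
    pad <- 2 * grid_cell_m / METERS_PER_DEG
    extent <- c(min(s$lon) - pad, max(s$lon) + pad,
                min(s$lat) - pad, max(s$lat) + pad)
  }
  mid_lat <- (extent[3] + extent[4]) / 2
  dlat <- grid_cell_m / METERS_PER_DEG
  dlon <- grid_cell_m / (METERS_PER_DEG * cos(mid_lat * pi / 180))
  n_cols <- max(1, ceiling((extent[2] - extent[1]) / dlon))
  n_rows <- max(1, ceiling((extent[4] - extent[3]) / dlat))
  grid <- matrix(NA_real_, n_rows, n_cols)
  for (row in seq_len(n_rows)) {
    lat_c <- extent[3] + (n_rows - row + 0.5) * dlat
    for (col in seq_len(n_cols)) {
      lon_c <- extent[1] + (col - 0.5) * dlon
      d <- geosphere::distHaversine(cbind(lon_c, lat_c), pts, r = EARTH_RADIUS_M)
      if (any(d < 1)) {
        grid[row, col] <- vals[which.min(d)]
      } else {
        w <- d^(-power)
        grid[row, col] <- sum(vals * w) / sum(w)
      }
    }
  }
  list(origin = c(extent[1], extent[3]),
       cell_size_lon = dlon, cell_size_lat = dlat,
       n_rows = n_rows, n_cols = n_cols, power = power, values = grid)
}

#' Write an interpolated diversity grid as an ESRI ASCII grid
#'
#' The ASC format has one square cell size; the grid's latitude cell size
#' is used (its longitude spacing approximates the same ground distance).
#'
#' @param g grid from [idw_interpolate()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_diversity_grid <- function(g, path) {
  r <- altitude_raster(g$origin, g$cell_size_lat,
                       ifelse(is.na(g$values), -9999, g$values))
  write_altitude_raster(r, path)
  invisible(path)
}

#' Per-basin summaries of diversity
#'
#' Either the mean of per-point windowed diversity values within each
#' basin (`mode = "mean_window"`) or a single pooled diversity over all of
#' a basin's sequences (`mode = "pooled"`).
#'
#' @param a alignment.
#' @param s sample data frame with a `basin` column.
#' @param radius window radius (m), used by `mean_window`.
#' @param mode `"mean_window"` (default) or `"pooled"`.
#' @return data frame with `basin`, `n`, `pi`.
#' @export
basin_diversity <- function(a, s, radius = 10000,
                            mode = c("mean_window", "pooled")) {
  mode <- match.arg(mode)
  a <- alignment(a)
  s <- as_sample_set(s)
  basins <- sort(unique(s$basin))
  pi_val <- if (mode == "mean_window") {
    w <- windowed_diversity(a, s, radius)
    vapply(basins, function(b) mean(w[s$id[s$basin == b]], na.rm = TRUE),
           numeric(1))
  } else {
    vapply(basins, function(b) {
      ids <- s$id[s$basin == b]
      if (length(ids) < 2) return(NA_real_)
      nucleotide_diversity(a[ids])
    }, numeric(1))
  }
  data.frame(basin = basins,
             n = vapply(basins, function(b) sum(s$basin == b), numeric(1)),
             pi = pi_val)
}
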