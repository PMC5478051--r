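# Altitude rasters: regular lon/lat grids of elevations (m). `values` is an
# n_rows x n_cols matrix stored row-major from the top, i.e. row 1 is the
# northernmost row, matching the ESRI ASCII grid layout.

#' Construct an altitude raster
#'
#' @param origin numeric `(lon, lat)` of the lower-left corner (degrees).
#' @param cell_size cell edge in degrees (> 0, square cells).
#' @param values elevation matrix (m), row 1 = northernmost row.
#' @return object of class `altitude_raster`.
#' @export
altitude_raster <- function(origin, cell_size, values) {
  stopifnot(length(origin) == 2, cell_size > 0)
  values <- as.matrix(values)
  if (any(is.nan(values) | is.infinite(values))) {
    stop("raster values must be finite (NA marks NODATA cells)", call. = FALSE)
  }
  structure(list(origin = as.numeric(origin), cell_size = as.numeric(cell_size),
                 n_rows = nrow(values), n_cols = ncol(values), values = values),
            class = "altitude_raster")
}

#' @export
print.altitude_raster <- function(x, ...) {
  cat("altitude_raster:", x$n_rows, "x", x$n_cols, "cells of", x$cell_size,
      "deg; elevation", round(min(x$values)), "-", round(max(x$values)), "m\n")
  invisible(x)
}

# cell centers: row (1 = top) / col -> lon/lat
cell_center <- function(r, row, col) {
  cbind(lon = r$origin[1] + (col - 0.5) * r$cell_size,
        lat = r$origin[2] + (r$n_rows - row + 0.5) * r$cell_size)
}

# lon/lat -> row/col of containing cell; NA if outside the extent
cell_index <- function(r, lon, lat) {
  col <- floor((lon - r$origin[1]) / r$cell_size) + 1
  row <- r$n_rows - floor((lat - r$origin[2]) / r$cell_size)
  bad <- col < 1 | col > r$n_cols | row < 1 | row > r$n_rows
  col[bad] <- NA; row[bad] <- NA
  cbind(row = row, col = col)
}

#' Write / read an altitude raster as an ESRI ASCII grid
#'
#' Standard `.asc` layout: a six-line header (`NCOLS`, `NROWS`,
#' `XLLCORNER`, `YLLCORNER`, `CELLSIZE`, `NODATA_VALUE`) followed by rows
#' of values from the northernmost row down.
#'
#' @param r an `altitude_raster`.
#' @param path file path.
#' @param nodata value representing missing cells on disk.
#' @return `read_altitude_raster` returns the raster; the writer returns
#'   `path` invisibly.
#' @export
write_altitude_raster <- function(r, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("NCOLS", r$n_cols), paste("NROWS", r$n_rows),
               paste("XLLCORNER", format(r$origin[1], digits = 12)),
               paste("YLLCORNER", format(r$origin[2], digits = 12)),
               paste("CELLSIZE", format(r$cell_size, digits = 12)),
               paste("NODATA_VALUE", nodata)), con)
  writeLines(apply(r$values, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_altitude_raster
#' @export
read_altitude_raster <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[toupper(kv[1])]] <- as.numeric(kv[2])
  }
  vals <- t(vapply(lines[-(1:6)][nzchar(trimws(lines[-(1:6)]))],
                   function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                   numeric(hdr$NCOLS), USE.NAMES = FALSE))
  vals[vals == hdr$NODATA_VALUE] <- NA
  altitude_raster(origin = c(hdr$XLLCORNER, hdr$YLLCORNER),
                  cell_size = hdr$CELLSIZE, values = vals)
}
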