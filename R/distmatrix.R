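#' Construct a validated symmetric distance matrix
#'
#' Distance matrices throughout the package are plain numeric matrices with
#' identical row and column names (the sample ids), a zero diagonal,
#' symmetric non-negative entries, and `NA` for pairs whose distance is
#' undefined (e.g. samples in disconnected river basins).
#'
#' @param values square numeric matrix.
#' @param ids character vector of sample ids; defaults to existing rownames.
#' @return the matrix with `ids` as dimnames, after validation.
#' @export
dist_matrix <- function(values, ids = rownames(values)) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate ids in distance matrix", call. = FALSE)
  dimnames(values) <- list(ids, ids)
  validate_dist_matrix(values)
  values
}

validate_dist_matrix <- function(m) {
  if (!isTRUE(all.equal(m, t(m)))) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(diag(m) != 0, na.rm = TRUE)) {
    stop("distance matrix diagonal must be zero", call. = FALSE)
  }
  if (any(m < 0, na.rm = TRUE)) {
    stop("distance matrix has negative entries", call. = FALSE)
  }
  invisible(m)
}

#' Read / write a distance matrix as CSV
#'
#' The CSV has an `id` first column and one column per id, in the same
#' order; missing (undefined) distances are serialized as `NA`.
#'
#' @param m distance matrix (see [dist_matrix()]).
#' @param path file path.
#' @return `read_dist_matrix` returns the matrix; `write_dist_matrix`
#'   returns `path` invisibly.
#' @export
write_dist_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = c(id = "character"))
  m <- as.matrix(df[, -1, drop = FALSE])
  dist_matrix(m, ids = df$id)
}

# Upper-triangle values of a distance matrix, row-major pair order.
upper_pairs <- function(m) m[upper.tri(m)]
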