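#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation over the off-diagonal pairs where both matrices are
#' non-missing, with significance from joint row/column permutations of
#' `B`. Missing entries travel with the permuted matrix, and the set of
#' valid pairs is recomputed for every permutation, which preserves the
#' pairing semantics when e.g. river distances are undefined between
#' basins. The p-value is two-tailed with add-one smoothing:
#' `p = min(1, 2 * min(#[r* >= r] + 1, #[r* <= r] + 1) / (n_perm + 1))`,
#' so its floor at 9,999 permutations is 0.0002.
#'
#' @param A,B distance matrices over the same ids in the same order; `NA`
#'   entries allowed.
#' @param n_perm number of random permutations (ignored if `exhaustive`).
#' @param seed integer RNG seed.
#' @param exhaustive if `TRUE`, enumerate all `n!` relabelings instead of
#'   sampling (feasible for small n); the add-one convention is dropped
#'   since the permutation distribution is exact.
#' @return list with `r`, `p`, `n_perm`, `n_pairs_used`.
#' @export
mantel_test <- function(A, B, n_perm = 9999, seed = 1L, exhaustive = FALSE) {
  A <- dist_matrix(A); B <- dist_matrix(B)
  if (!identical(rownames(A), rownames(B))) {
    stop("matrices must share the same ids in the same order", call. = FALSE)
  }
  n <- nrow(A)
  if (n < 4) stop("Mantel test needs at least 4 samples", call. = FALSE)
  ut <- upper.tri(A)
  r_obs <- mantel_r(A[ut], B[ut])
  if (exhaustive) {
    perms <- permutations_of(n)
    r_star <- vapply(perms, function(p) mantel_r(A[ut], B[p, p][ut]), numeric(1))
    n_used <- length(perms)
    p_val <- min(1, 2 * min(sum(r_star >= r_obs), sum(r_star <= r_obs)) / n_used)
  } else {
    set.seed(as.integer(seed))
    r_star <- vapply(seq_len(n_perm), function(k) {
      p <- sample.int(n)
      mantel_r(A[ut], B[p, p][ut])
    }, numeric(1))
    n_used <- n_perm
    p_val <- min(1, 2 * min(sum(r_star >= r_obs) + 1,
                            sum(r_star <= r_obs) + 1) / (n_perm + 1))
  }
  list(r = r_obs, p = p_val, n_perm = n_used,
       n_pairs_used = sum(!is.na(A[ut]) & !is.na(B[ut])))
}

# Pearson r over jointly non-missing pairs; errors on degenerate input
mantel_r <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) stop("fewer than 3 valid off-diagonal pairs", call. = FALSE)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
    stop("zero variance among valid pairs; Mantel r undefined", call. = FALSE)
  }
  stats::cor(a[ok], b[ok])
}

# all permutations of 1..n (n small)
permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}
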