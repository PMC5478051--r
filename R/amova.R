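#' One-way AMOVA from a distance matrix
#'
#' Analysis of molecular variance with a single grouping factor (e.g.
#' river basin): decomposes the sum of squared pairwise distances into
#' among- and within-group components, estimates the variance components
#' and Phi-ST, and attaches a permutation p-value from shuffling group
#' labels.
#'
#' Sums of squares follow the standard distance-matrix formulation:
#' `SSD_total = sum_{i<j} d_ij^2 / N`, `SSD_within = sum_g sum_{i<j in g}
#' d_ij^2 / n_g`, `SSD_among` their difference; `n'` is the average-size
#' coefficient `(N - sum n_g^2 / N) / (G - 1)`;
#' `sigma2_w = MSD_within`, `sigma2_a = (MSD_among - MSD_within) / n'`
#' (not truncated at 0, so the SSD decomposition stays exact), and
#' `Phi_ST = sigma2_a / (sigma2_a + sigma2_w)`.
#'
#' @param d complete distance matrix.
#' @param groups group label per id (named or in matrix order); >= 2
#'   groups, more samples than groups.
#' @param n_perm label permutations for the p-value.
#' @param seed integer RNG seed.
#' @return list with the SSD/MSD table, variance components, `phi_st`,
#'   `pct_among`, and permutation `p`.
#' @export
amova_oneway <- function(d, groups, n_perm = 999, seed = 1L) {
  d <- dist_matrix(d)
  if (anyNA(d)) {
    stop("distance matrix has missing entries; AMOVA needs a complete matrix",
         call. = FALSE)
  }
  n <- nrow(d)
  if (!is.null(names(groups))) groups <- groups[rownames(d)]
  if (length(groups) != n || anyNA(groups)) {
    stop("need one group label per sample", call. = FALSE)
  }
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) stop("AMOVA needs at least 2 groups", call. = FALSE)
  if (n <= length(unique(groups))) stop("need more samples than groups", call. = FALSE)
  obs <- amova_components(d, groups)
  set.seed(as.integer(seed))
  phi_star <- vapply(seq_len(n_perm), function(k) {
    amova_phi(d, sample(groups))
  }, numeric(1))
  obs$p <- (sum(phi_star >= obs$phi_st) + 1) / (n_perm + 1)
  obs$n_perm <- n_perm
  obs
}

amova_components <- function(d, groups) {
  d2 <- d^2
  n <- nrow(d)
  glev <- unique(groups)
  G <- length(glev)
  n_g <- vapply(glev, function(g) sum(groups == g), numeric(1))
  ssd_total <- sum(d2[upper.tri(d2)]) / n
  ssd_within <- sum(vapply(glev, function(g) {
    in_g <- groups == g
    sum(d2[in_g, in_g][upper.tri(d2[in_g, in_g, drop = FALSE])]) / sum(in_g)
  }, numeric(1)))
  ssd_among <- ssd_total - ssd_within
  df_among <- G - 1
  df_within <- n - G
  msd_among <- ssd_among / df_among
  msd_within <- ssd_within / df_within
  n_eff <- (n - sum(n_g^2) / n) / (G - 1)
  sigma2_w <- msd_within
  sigma2_a <- (msd_among - msd_within) / n_eff
  phi_st <- sigma2_a / (sigma2_a + sigma2_w)
  list(ssd_among = ssd_among, ssd_within = ssd_within, ssd_total = ssd_total,
       df_among = df_among, df_within = df_within,
       msd_among = msd_among, msd_within = msd_within, n_eff = n_eff,
       sigma2_a = sigma2_a, sigma2_w = sigma2_w, phi_st = phi_st,
       pct_among = 100 * phi_st, pct_within = 100 * (1 - phi_st))
}

amova_phi <- function(d, groups) {
  amova_components(d, groups)$phi_st
}
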