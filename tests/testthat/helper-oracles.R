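# Independent oracles used to cross-check the package's implementations.
# These deliberately share no code with the functions they verify.

# --- brute-force Dijkstra on an edge list (no igraph) ---------------------
# edges: data.frame/matrix with columns from, to (1-based node ids), w
oracle_dijkstra <- function(n_nodes, edges, source) {
  dist <- rep(Inf, n_nodes)
  dist[source] <- 0
  done <- rep(FALSE, n_nodes)
  adj <- vector("list", n_nodes)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]; w <- edges[k, 3]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    for (k in seq_len(NROW(adj[[u]]))) {
      v <- adj[[u]][k, 1]; w <- adj[[u]][k, 2]
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  dist
}

# --- tip-to-tip path-walk patristic distances (no cophenetic) -------------
oracle_patristic <- function(newick) {
  tr <- ape::read.tree(text = newick)
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  adj <- vector("list", n_node)
  for (k in seq_len(nrow(tr$edge))) {
    a <- tr$edge[k, 1]; b <- tr$edge[k, 2]; w <- tr$edge.length[k]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  walk <- function(from) {
    dist <- rep(NA_real_, n_node)
    dist[from] <- 0
    queue <- from
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (k in seq_len(NROW(adj[[u]]))) {
        v <- adj[[u]][k, 1]
        if (is.na(dist[v])) {
          dist[v] <- dist[u] + adj[[u]][k, 2]
          queue <- c(queue, v)
        }
      }
    }
    dist
  }
  d <- matrix(0, n_tip, n_tip, dimnames = list(tr$tip.label, tr$tip.label))
  for (i in seq_len(n_tip)) d[i, ] <- walk(i)[seq_len(n_tip)]
  d
}

# --- exhaustive Mantel enumeration (own permutation generator) ------------
oracle_all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    t(apply(sub, 1, function(p) append(p, n, after = pos - 1L)))
  }))
}

oracle_exhaustive_mantel_p <- function(A, B) {
  n <- nrow(A)
  ut <- upper.tri(A)
  r_of <- function(p) {
    a <- A[ut]; b <- B[p, p][ut]
    ok <- !is.na(a) & !is.na(b)
    stats::cor(a[ok], b[ok])
  }
  r_obs <- r_of(seq_len(n))
  perms <- oracle_all_perms(n)
  r_star <- apply(perms, 1, r_of)
  min(1, 2 * min(sum(r_star >= r_obs), sum(r_star <= r_obs)) / nrow(perms))
}

# --- spreadsheet-style AMOVA sums of squares ------------------------------
oracle_amova <- function(d, groups) {
  n <- nrow(d)
  glev <- unique(groups)
  G <- length(glev)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) tot <- tot + d[i, j]^2
  ssd_total <- tot / n
  ssd_within <- 0
  for (g in glev) {
    idx <- which(groups == g)
    acc <- 0
    if (length(idx) > 1) {
      for (i in idx) for (j in idx) if (i < j) acc <- acc + d[i, j]^2
    }
    ssd_within <- ssd_within + acc / length(idx)
  }
  ssd_among <- ssd_total - ssd_within
  msd_among <- ssd_among / (G - 1)
  msd_within <- ssd_within / (n - G)
  n_eff <- (n - sum(table(groups)^2) / n) / (G - 1)
  sigma2_a <- (msd_among - msd_within) / n_eff
  sigma2_w <- msd_within
  list(ssd_among = ssd_among, ssd_within = ssd_within, ssd_total = ssd_total,
       msd_among = msd_among, msd_within = msd_within, n_eff = n_eff,
       sigma2_a = sigma2_a, sigma2_w = sigma2_w,
       phi_st = sigma2_a / (sigma2_a + sigma2_w))
}

# --- HKY expected p-distance via matrix exponential (Matrix::expm) --------
oracle_hky_expected_p <- function(t_total, kappa, freqs) {
  q <- matrix(0, 4, 4)  # order A C G T
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    ts <- (i == 1 && j == 3) || (i == 3 && j == 1) ||
      (i == 2 && j == 4) || (i == 4 && j == 2)
    q[i, j] <- if (ts) kappa * freqs[j] else freqs[j]
  }
  diag(q) <- -rowSums(q)
  q <- q / (-sum(freqs * diag(q)))
  p <- as.matrix(Matrix::expm(q * t_total))
  1 - sum(freqs * diag(p))
}

# --- misc helpers ---------------------------------------------------------
# tiny Y-shaped network: trunk south->junction, two branches
fixture_y_network <- function() {
  river_network(list(
    rbind(c(0, 0), c(0, 0.1)),
    rbind(c(0, 0.1), c(-0.05, 0.2)),
    rbind(c(0, 0.1), c(0.05, 0.2))))
}

# random point sample table
fixture_points <- function(n, seed, lon0 = 0, lat0 = 45, spread = 0.5) {
  set.seed(seed)
  data.frame(id = sprintf("p%02d", seq_len(n)),
             lon = lon0 + runif(n, -spread, spread),
             lat = lat0 + runif(n, -spread, spread))
}

# random metric (euclidean in the plane) distance matrix
fixture_metric_matrix <- function(n, seed) {
  set.seed(seed)
  xy <- matrix(runif(2 * n), n, 2)
  dist_matrix(as.matrix(stats::dist(xy)), ids = paste0("m", seq_len(n)))
}
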