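test_that("generated networks are seeded, deterministic, and dendritic", {
  n1 <- gen_river_network(3, 4, 7)
  n2 <- gen_river_network(3, 4, 7)
  expect_identical(n1, n2)
  # degenerate depth: one arc, one component
  n0 <- gen_river_network(1, 0, 1)
  expect_equal(length(n0$arcs), 1)
  expect_equal(unique(n0$basin_id), 1)
  # per component, a tree: nodes - edges = 1 (checked by graph census)
  net <- gen_river_network(2, 3, 11)
  for (b in unique(net$basin_id)) {
    arcs <- net$arcs[net$basin_id == b]
    ends <- unlist(lapply(arcs, function(a) {
      apply(a[c(1, nrow(a)), ], 1, paste, collapse = "_")
    }))
    n_nodes <- length(unique(ends))
    n_edges <- length(arcs)
    expect_equal(n_nodes - n_edges, 1)
  }
  expect_error(gen_river_network(0, 2, 1), "n_basins")
})

test_that("altitude rasters floor at base and track network distance", {
  net1 <- gen_river_network(1, 0, 2)  # single straight river
  flat <- gen_altitude_raster(net1, gain = 0, ridge_height = 0, base = 300)
  expect_true(all(flat$values == 300))
  r <- gen_altitude_raster(net1, gain = 0.05, ridge_height = 0, base = 300)
  expect_true(min(r$values) >= 300)
  # on-river cells: elevation rank-correlates with distance from the outlet
  rows <- rep(seq_len(r$n_rows), times = r$n_cols)
  cols <- rep(seq_len(r$n_cols), each = r$n_rows)
  ctr <- cell_center(r, rows, cols)
  hit <- snap_points(ctr[, 1], ctr[, 2], net1)
  on_river <- sqrt(hit$d2) < r$cell_size / 2
  outlet <- net1$arcs[[1]][1, ]
  oracle_dist <- haversine_m(cbind(outlet[1], outlet[2]),
                             cbind(hit$lon, hit$lat))[on_river]
  elev <- r$values[cbind(rows, cols)][on_river]
  expect_gte(suppressWarnings(cor(elev, oracle_dist, method = "spearman")), 0.9)
  expect_error(gen_altitude_raster(list()), "river_network")
})

test_that("sample placement is on-network, seeded, and length-uniform", {
  net <- gen_river_network(2, 3, 19)
  s1 <- place_samples(net, 30, 5)
  s2 <- place_samples(net, 30, 5)
  expect_identical(s1, s2)
  hit <- snap_points(s1$lon, s1$lat, net)
  expect_true(all(hit$offset < 1e-9 * 111195))  # within 1e-9 degrees
  # two equal-length disconnected arcs: counts ~ Binomial(n, 1/2)
  two <- river_network(list(rbind(c(0, 0), c(0.5, 0)),
                            rbind(c(0, 1), c(0.5, 1))))
  s <- place_samples(two, 10000, 23)
  n1 <- sum(s$basin == 1)
  expect_lt(abs(n1 - 5000), 3 * sqrt(10000 * 0.25))
  expect_error(place_samples(net, 0, 1), ">= 1")
})

test_that("ibd trees reproduce noiseless additive distances exactly", {
  nwk <- "((A:1000,B:1500):500,(C:800,D:1200):500);"
  geo <- dist_matrix(oracle_patristic(nwk))
  alpha <- 1e-6
  tr <- gen_ibd_tree(geo, alpha, sigma = 0, seed = 1)
  expect_equal(patristic_distances(tr)[rownames(geo), colnames(geo)],
               alpha * unclass(geo), tolerance = 1e-9)
  # perfect monotone case: Mantel r = 1
  m <- mantel_test(patristic_distances(tr)[rownames(geo), colnames(geo)],
                   geo, n_perm = 99, seed = 1)
  expect_equal(m$r, 1.0, tolerance = 1e-12)
  # scale equivariance at sigma = 0
  tr10 <- gen_ibd_tree(dist_matrix(10 * unclass(geo), ids = rownames(geo)),
                       alpha, 0, seed = 1)
  expect_equal(patristic_distances(tr10)[rownames(geo), colnames(geo)],
               10 * patristic_distances(tr)[rownames(geo), colnames(geo)],
               tolerance = 1e-9)
  geo_na <- geo; geo_na[1, 2] <- geo_na[2, 1] <- NA
  expect_error(gen_ibd_tree(geo_na, alpha, 0, 1), "missing")
})

test_that("noisy ibd trees still carry strong distance signal", {
  pts <- fixture_points(30, 77)
  geo <- haversine_matrix(pts)
  rs <- vapply(1:20, function(k) {
    tr <- gen_ibd_tree(geo, 1e-6, 0.2, seed = 100 + k)
    d <- patristic_distances(tr)[rownames(geo), colnames(geo)]
    mantel_test(d, geo, n_perm = 19, seed = k)$r
  }, numeric(1))
  expect_gt(mean(rs), 0.8)
})

test_that("HKY simulation matches its closed-form expectations", {
  # zero branch lengths: all tips identical to the root draw
  tips <- simulate_sequences("(A:0,B:0,C:0);", 500, kappa = 2, seed = 4)
  expect_equal(length(unique(unclass(tips))), 1)
  # two tips at patristic distance 0.1: observed p-distance near expectation
  L <- 100000
  a <- simulate_sequences("(A:0.05,B:0.05);", L, kappa = 2, seed = 8)
  p_obs <- pairwise_p_distances(a)["A", "B"]
  p_exp <- oracle_hky_expected_p(0.1, 2, rep(0.25, 4))
  mc_se <- sqrt(p_exp * (1 - p_exp) / L)
  expect_lt(abs(p_obs - p_exp), 3 * mc_se)
  # unequal base frequencies are respected in the root draw
  freqs <- c(0.4, 0.3, 0.2, 0.1)
  b <- simulate_sequences("(A:0,B:0);", L, kappa = 2, base_freqs = freqs, seed = 5)
  counts <- table(factor(strsplit(unclass(b)[["A"]], "")[[1]],
                         levels = c("A", "C", "G", "T")))
  gof <- stats::chisq.test(as.vector(counts), p = freqs)
  expect_gt(gof$p.value, 0.001)
  expect_error(simulate_sequences("(A:0.1,B:-0.1);", 10, 2), "non-negative")
  expect_error(simulate_sequences("(A:0.1,B:0.1);", 0, 2), ">= 1")
})

test_that("HKY transition probabilities agree with an independent expm", {
  freqs <- c(0.35, 0.15, 0.3, 0.2)
  p_pkg <- hky_transition(0.37, 3, freqs)
  q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    ts <- (i + j == 4 && abs(i - j) == 2) || (i + j == 6 && abs(i - j) == 2)
    q[i, j] <- if (ts) 3 * freqs[j] else freqs[j]
  }
  diag(q) <- -rowSums(q)
  q <- q / (-sum(freqs * diag(q)))
  p_ref <- as.matrix(Matrix::expm(q * 0.37))
  expect_equal(p_pkg, p_ref, tolerance = 1e-9, ignore_attr = TRUE)
})
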