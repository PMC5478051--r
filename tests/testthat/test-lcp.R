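test_that("flat unit-altitude raster reduces LCP to along-path length", {
  r <- altitude_raster(c(0, 0), 0.01, matrix(1, 20, 20))
  # two points on the same grid row, at cell centers
  s <- data.frame(id = c("a", "b"), lon = c(0.035, 0.155), lat = c(0.105, 0.105))
  d <- lcp_distance_matrix(s, r)
  expect_equal(d["a", "b"], haversine_m(c(0.035, 0.105), c(0.155, 0.105)),
               tolerance = 0.01)
  expect_equal(lcp_distance_matrix(
    data.frame(id = c("x", "y"), lon = c(0.031, 0.039), lat = c(0.112, 0.118)),
    r)["x", "y"], 0)  # same cell
})

test_that("flat-raster LCP obeys the 8-connected elongation bound", {
  r <- altitude_raster(c(0, 0), 0.01, matrix(1, 25, 25))
  set.seed(13)
  centers <- cell_center(r, sample(25, 8, TRUE), sample(25, 8, TRUE))
  s <- data.frame(id = paste0("p", 1:8), lon = centers[, 1], lat = centers[, 2])
  d <- lcp_distance_matrix(s, r)
  h <- haversine_matrix(s)
  ut <- upper.tri(d) & h > 0
  expect_true(all(d[ut] >= h[ut] * (1 - 1e-6)))
  expect_true(all(d[ut] <= 1.09 * h[ut]))
})

test_that("LCP routes through a gap in a high-cost wall and matches Dijkstra", {
  vals <- matrix(1, 9, 9)
  vals[5, ] <- 10000   # wall across the middle row ...
  vals[5, 7] <- 1      # ... with one gap
  r <- altitude_raster(c(0, 0), 0.01, vals)
  s <- data.frame(id = c("s", "n"), lon = c(0.025, 0.025), lat = c(0.015, 0.075))
  d <- lcp_distance_matrix(s, r)
  # independent exhaustive shortest path over the same conductance graph
  n_rows <- 9; n_cols <- 9
  edges <- NULL
  for (row in 1:n_rows) for (col in 1:n_cols) {
    for (drc in list(c(0, 1), c(1, 0), c(1, 1), c(-1, 1))) {
      r2 <- row + drc[1]; c2 <- col + drc[2]
      if (r2 < 1 || r2 > n_rows || c2 < 1 || c2 > n_cols) next
      p1 <- cell_center(r, row, col); p2 <- cell_center(r, r2, c2)
      w <- haversine_m(p1, p2) / (2 / (vals[row, col] + vals[r2, c2]))
      edges <- rbind(edges, c((col - 1) * n_rows + row, (c2 - 1) * n_rows + r2, w))
    }
  }
  cell_s <- (floor(0.025 / 0.01)) * n_rows + (n_rows - floor(0.015 / 0.01))
  cell_n <- (floor(0.025 / 0.01)) * n_rows + (n_rows - floor(0.075 / 0.01))
  o <- oracle_dijkstra(n_rows * n_cols, edges, cell_s)
  expect_equal(d["s", "n"], o[cell_n], tolerance = 1e-9)
  # the gap makes the path cheaper than a straight crossing of the wall
  straight <- sum(vapply(1:6, function(k) {
    p1 <- cell_center(r, 9 - k + 1, 3); p2 <- cell_center(r, 9 - k, 3)
    haversine_m(p1, p2) / (2 / (vals[9 - k + 1, 3] + vals[9 - k, 3]))
  }, numeric(1)))
  expect_lt(d["s", "n"], straight)
})

test_that("raising altitude never shortens any least-cost path", {
  set.seed(17)
  vals <- matrix(runif(64, 100, 500), 8, 8)
  r1 <- altitude_raster(c(0, 0), 0.01, vals)
  s <- data.frame(id = paste0("p", 1:4),
                  lon = c(0.015, 0.075, 0.035, 0.065),
                  lat = c(0.015, 0.075, 0.055, 0.025))
  d1 <- lcp_distance_matrix(s, r1)
  vals2 <- vals
  vals2[4, 5] <- vals2[4, 5] + 400
  d2 <- lcp_distance_matrix(s, altitude_raster(c(0, 0), 0.01, vals2))
  expect_true(all(d2 >= d1 - 1e-9))
})

test_that("points off the raster are rejected and NODATA blocks paths", {
  r <- altitude_raster(c(0, 0), 0.01, matrix(1, 5, 5))
  expect_error(lcp_distance_matrix(
    data.frame(id = "far", lon = 2, lat = 2), r), "outside")
  vals <- matrix(1, 5, 5); vals[3, ] <- NA
  r2 <- altitude_raster(c(0, 0), 0.01, vals)
  s <- data.frame(id = c("a", "b"), lon = c(0.025, 0.025), lat = c(0.005, 0.045))
  expect_warning(d <- lcp_distance_matrix(s, r2), "NODATA")
  expect_true(is.na(d["a", "b"]))
})
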