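# Synthetic dendritic riverscapes: river networks grown as planar binary
# trees, altitude surfaces rising toward the headwaters with a ridge
# between basins, length-uniform sample placement, isolation-by-distance
# trees, and HKY sequence simulation. Every generator is a pure function
# of its arguments including the seed.

#' Default simulation configuration
#'
#' Bundles the knobs of the synthetic riverscape: number of basins and
#' branching depth of each dendritic network, sample count, the
#' isolation-by-distance slope `ibd_slope` (expected substitutions/site
#' per meter of geographic distance), the lognormal noise scale
#' `noise_sigma` on pairwise distances, which geographic distance drives
#' divergence (`"river"`, `"euclidean"` or `"lcp"`), and the HKY sequence
#' model (alignment length, transition/transversion ratio `kappa`, base
#' frequencies).
#'
#' @param seed integer RNG seed.
#' @param n_basins,branching_depth river-network shape parameters.
#' @param n_samples number of samples placed on the network.
#' @param ibd_slope substitutions/site per meter (>= 0).
#' @param noise_sigma lognormal sigma of multiplicative distance noise (>= 0).
#' @param generating_distance which distance drives genetic divergence.
#' @param seq_length alignment length in sites.
#' @param kappa HKY transition/transversion rate ratio (> 0).
#' @param base_freqs probabilities of A, C, G, T (sum to 1).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_basins = 2L,
                              branching_depth = 4L,
                              n_samples = 40L,
                              ibd_slope = 1e-6,
                              noise_sigma = 0.2,
                              generating_distance = c("river", "euclidean", "lcp"),
                              seq_length = 1066L,
                              kappa = 2,
                              base_freqs = rep(0.25, 4)) {
  generating_distance <- match.arg(generating_distance)
  stopifnot(ibd_slope >= 0, noise_sigma >= 0, kappa > 0, seq_length >= 1,
            n_basins >= 1, branching_depth >= 0, n_samples >= 1)
  if (abs(sum(base_freqs) - 1) > 1e-9 || length(base_freqs) != 4 ||
      any(base_freqs < 0)) {
    stop("base_freqs must be 4 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_basins = as.integer(n_basins),
                 branching_depth = as.integer(branching_depth),
                 n_samples = as.integer(n_samples), ibd_slope = ibd_slope,
                 noise_sigma = noise_sigma,
                 generating_distance = generating_distance,
                 seq_length = as.integer(seq_length), kappa = kappa,
                 base_freqs = base_freqs),
            class = "simulation_config")
}

#' Generate a dendritic river network
#'
#' Each basin is a planar binary tree grown upstream from its outlet: a
#' trunk heading north, then at every junction two child arcs at random
#' angles off the parent heading, arc length decaying by a fixed factor
#' per level (headwaters end up near the divide). Basins are laid out
#' side by side along a parallel.
#'
#' @param n_basins number of basins (connected components), >= 1.
#' @param branching_depth branching levels above the trunk (0 = a single
#'   arc per basin).
#' @param seed integer RNG seed; output is a pure function of the inputs.
#' @param origin `(lon, lat)` of the first outlet.
#' @param basin_spacing longitude offset between outlets (degrees); the
#'   default places adjacent basins close enough that their headwaters
#'   interdigitate near the shared divide, as real neighboring drainages
#'   do.
#' @param trunk_length trunk arc length (degrees).
#' @param length_decay per-level geometric decay of arc length.
#' @return a `river_network` with recorded outlets.
#' @export
gen_river_network <- function(n_basins, branching_depth, seed,
                              origin = c(-6, 42), basin_spacing = 0.4,
                              trunk_length = 0.15, length_decay = 0.6) {
  stopifnot(n_basins >= 1, branching_depth >= 0)
  set.seed(as.integer(seed))
  arcs <- list(); basin <- integer(0)
  for (b in seq_len(n_basins)) {
    outlet <- c(origin[1] + (b - 1) * basin_spacing, origin[2])
    grow <- function(from, heading, len, level) {
      to <- from + len * c(sin(heading), cos(heading))
      arcs[[length(arcs) + 1]] <<- rbind(from, to)
      basin[length(basin) + 1] <<- b
      if (level < branching_depth) {
        spread <- stats::runif(2, pi / 6, pi / 3)
        grow(to, heading - spread[1], len * length_decay, level + 1)
        grow(to, heading + spread[2], len * length_decay, level + 1)
      }
    }
    grow(outlet, heading = 0, len = trunk_length, level = 0)
  }
  outlets <- cbind(origin[1] + (seq_len(n_basins) - 1) * basin_spacing,
                   origin[2])
  river_network(arcs, basin_id = basin, outlets = outlets)
}

# network distance (m) from the basin outlet for positions (arc, s)
outlet_distance <- function(net, arc, s) {
  g <- network_graph(net)
  out <- basin_outlets(net)
  dist_out <- network_node_distances(g, node_key(out[, 1], out[, 2]))
  basins <- as.character(sort(unique(net$basin_id)))
  start_key <- vapply(net$arcs, function(a) node_key(a[1, 1], a[1, 2]), character(1))
  bi <- match(as.character(net$basin_id[arc]), basins)
  dist_out[cbind(bi, match(start_key[arc], colnames(dist_out)))] + s
}

#' Generate an altitude raster over a river network
#'
#' Elevation of each cell is `base + gain * (along-network distance from
#' the basin outlet to the nearest point of the network)` plus a Gaussian
#' ridge midway between adjacent basins, so altitude rises toward the
#' headwaters and a divide separates the basins. The grid covers the
#' network bounding box padded by 2 cells.
#'
#' @param net a `river_network`.
#' @param cell_size cell edge in degrees.
#' @param base valley-floor elevation (m).
#' @param gain elevation gain per meter of network distance from the
#'   outlet (m/m).
#' @param ridge_height peak height (m) of the inter-basin ridge; 0
#'   disables it.
#' @param ridge_width Gaussian width of the ridge (degrees longitude).
#' @return an `altitude_raster`.
#' @export
gen_altitude_raster <- function(net, cell_size = 0.02, base = 400,
                                gain = 0.04, ridge_height = 500,
                                ridge_width = 0.1) {
  if (!inherits(net, "river_network")) stop("net must be a river_network", call. = FALSE)
  stopifnot(cell_size > 0, base > 0, gain >= 0, ridge_height >= 0)
  xy <- do.call(rbind, net$arcs)
  xmin <- min(xy[, 1]) - 2 * cell_size; xmax <- max(xy[, 1]) + 2 * cell_size
  ymin <- min(xy[, 2]) - 2 * cell_size; ymax <- max(xy[, 2]) + 2 * cell_size
  n_cols <- ceiling((xmax - xmin) / cell_size)
  n_rows <- ceiling((ymax - ymin) / cell_size)
  rr <- rep(seq_len(n_rows), times = n_cols)
  cc <- rep(seq_len(n_cols), each = n_rows)
  skel <- altitude_raster(c(xmin, ymin), cell_size,
                          matrix(base, n_rows, n_cols))
  ctr <- cell_center(skel, rr, cc)
  hit <- snap_points(ctr[, 1], ctr[, 2], net)
  elev <- base + gain * outlet_distance(net, hit$arc, hit$s)
  out <- basin_outlets(net)
  if (ridge_height > 0 && nrow(out) > 1) {
    lons <- sort(out[, 1])
    for (k in seq_len(length(lons) - 1)) {
      mid <- (lons[k] + lons[k + 1]) / 2
      elev <- elev + ridge_height * exp(-((ctr[, 1] - mid) / ridge_width)^2)
    }
  }
  vals <- matrix(base, n_rows, n_cols)
  vals[cbind(rr, cc)] <- elev
  altitude_raster(c(xmin, ymin), cell_size, vals)
}

#' Place samples length-uniformly on a river network
#'
#' Positions are drawn uniformly over total network length, so each arc
#' receives samples in proportion to its length. Samples carry the arc's
#' basin id, a clade label derived from the basin, and the snapping
#' columns (`.arc`, `.s`) already filled in.
#'
#' @param net a `river_network`.
#' @param n number of samples (>= 1).
#' @param seed integer RNG seed.
#' @return sample data frame (`id, lon, lat, basin, clade, snap_offset`).
#' @export
place_samples <- function(net, n, seed) {
  if (!inherits(net, "river_network")) stop("net must be a river_network", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  lens <- vapply(net$arcs, arc_length, numeric(1))
  cum <- c(0, cumsum(lens))
  u <- sort(stats::runif(n)) * cum[length(cum)]
  arc <- findInterval(u, cum, rightmost.closed = TRUE)
  s <- u - cum[arc]
  lon <- numeric(n); lat <- numeric(n)
  for (k in seq_len(n)) {
    a <- net$arcs[[arc[k]]]
    seglen <- segment_lengths(a)
    segcum <- c(0, cumsum(seglen))
    si <- max(1, findInterval(min(s[k], segcum[length(segcum)]), segcum,
                              rightmost.closed = TRUE))
    t_frac <- if (seglen[si] > 0) (s[k] - segcum[si]) / seglen[si] else 0
    lon[k] <- a[si, 1] + t_frac * (a[si + 1, 1] - a[si, 1])
    lat[k] <- a[si, 2] + t_frac * (a[si + 1, 2] - a[si, 2])
  }
  data.frame(id = sprintf("s%03d", seq_len(n)), lon = lon, lat = lat,
             basin = net$basin_id[arc],
             clade = paste0("A", net$basin_id[arc]),
             snap_offset = 0, .arc = arc, .s = s)
}

#' Build an isolation-by-distance tree from a geographic distance matrix
#'
#' Target genetic distances are `ibd_slope * geo * eps` with `eps`
#' lognormal(0, sigma^2) multiplicative noise, symmetrized by averaging;
#' the tree is then built by neighbor joining (negative branch lengths
#' clamped to 0). With `sigma = 0` and an additive `geo`, the patristic
#' distances of the output equal `ibd_slope * geo` exactly.
#'
#' @param geo complete symmetric distance matrix (m).
#' @param ibd_slope substitutions/site per meter.
#' @param sigma lognormal noise scale (0 = none).
#' @param seed integer RNG seed.
#' @return Newick string.
#' @export
gen_ibd_tree <- function(geo, ibd_slope, sigma, seed) {
  geo <- dist_matrix(geo)
  if (anyNA(geo)) stop("geo has missing entries; generative matrix must be complete",
                       call. = FALSE)
  stopifnot(ibd_slope >= 0, sigma >= 0)
  set.seed(as.integer(seed))
  n <- nrow(geo)
  eps <- matrix(exp(stats::rnorm(n * n, 0, sigma)), n, n)
  g <- ibd_slope * geo * eps
  g <- (g + t(g)) / 2
  diag(g) <- 0
  nj_tree(dist_matrix(g, ids = rownames(geo)))
}

# HKY transition probability matrix P(t): closed form via spectral
# decomposition of the reversible rate matrix, scaled to one expected
# substitution per site per unit branch length.
hky_transition <- function(t_len, kappa, base_freqs) {
  if (t_len == 0) return(diag(4))
  q <- hky_rate_matrix(kappa, base_freqs)
  pihalf <- sqrt(base_freqs)
  sym <- diag(pihalf) %*% q %*% diag(1 / pihalf)
  sym <- (sym + t(sym)) / 2
  e <- eigen(sym, symmetric = TRUE)
  p <- diag(1 / pihalf) %*% e$vectors %*% diag(exp(e$values * t_len)) %*%
    t(e$vectors) %*% diag(pihalf)
  p[p < 0] <- 0
  p / rowSums(p)
}

hky_rate_matrix <- function(kappa, base_freqs) {
  transversion <- matrix(1, 4, 4)
  transversion[1, 3] <- transversion[3, 1] <- kappa  # A <-> G
  transversion[2, 4] <- transversion[4, 2] <- kappa  # C <-> T
  q <- transversion * rep(base_freqs, each = 4)
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  mu <- -sum(base_freqs * diag(q))
  q / mu
}

#' Simulate sequences along a tree under the HKY model
#'
#' The root sequence is drawn from `base_freqs`; each site then evolves
#' independently down the tree using exact HKY transition probabilities
#' for each branch length (expected substitutions/site).
#'
#' @param tree Newick string or `phylo` with non-negative branch lengths.
#' @param L alignment length in sites (>= 1).
#' @param kappa transition/transversion rate ratio.
#' @param base_freqs probabilities of A, C, G, T.
#' @param seed integer RNG seed.
#' @return a `dna_alignment` keyed by tip label.
#' @export
simulate_sequences <- function(tree, L, kappa, base_freqs = rep(0.25, 4), seed = 1L) {
  tr <- as_phylo(tree)
  if (L < 1) stop("L must be >= 1", call. = FALSE)
  if (is.null(tr$edge.length) || any(tr$edge.length < 0)) {
    stop("tree must have non-negative branch lengths on all edges", call. = FALSE)
  }
  if (abs(sum(base_freqs) - 1) > 1e-9) stop("base_freqs must sum to 1", call. = FALSE)
  set.seed(as.integer(seed))
  tr <- stats::reorder(tr)  # cladewise: parents precede children
  n_tip <- length(tr$tip.label)
  root <- n_tip + 1L
  states <- matrix(NA_integer_, n_tip + tr$Nnode, L)
  states[root, ] <- sample.int(4L, L, replace = TRUE, prob = base_freqs)
  for (k in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[k, 1]; child <- tr$edge[k, 2]
    p <- hky_transition(tr$edge.length[k], kappa, base_freqs)
    child_state <- integer(L)
    for (st in 1:4) {
      at <- which(states[parent, ] == st)
      if (length(at)) {
        child_state[at] <- sample.int(4L, length(at), replace = TRUE, prob = p[st, ])
      }
    }
    states[child, ] <- child_state
  }
  seqs <- apply(states[seq_len(n_tip), , drop = FALSE], 1,
                function(rw) paste(c("A", "C", "G", "T")[rw], collapse = ""))
  alignment(stats::setNames(seqs, tr$tip.label))
}
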