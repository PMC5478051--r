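# End-to-end orchestration: inputs (files or simulation) -> snapping ->
# three geographic distance matrices -> genetic distances -> Mantel tests,
# AMOVA, diversity mapping -> report.

# stage-specific seeds derived from one global seed (kept < 2^31)
stage_seed <- function(seed, k) {
  (as.integer(seed) %% 100000L) * 1000L + k
}

#' Analysis configuration
#'
#' Exactly one of `paths` (real inputs) or `sim` (a
#' [simulation_config()]) must be supplied.
#'
#' `paths` is a list with elements: `alignment` (FASTA) or `fragments`
#' (character vector of 2 FASTA paths to concatenate), `samples` (CSV),
#' `network` (GeoJSON), `raster` (ESRI ASCII grid), and optionally `tree`
#' (Newick; if absent, a neighbor-joining tree is built from pairwise
#' p-distances).
#'
#' @param paths input file list, or `NULL`.
#' @param sim a `simulation_config`, or `NULL`.
#' @param mantel_n_perm permutations for each Mantel test.
#' @param amova_n_perm permutations for the AMOVA p-value.
#' @param window_radius_m radius of the diversity window (m).
#' @param grid_cell_m interpolation grid cell (m).
#' @param idw_power IDW exponent.
#' @param clade_filter optional clade label; samples from other clades are
#'   dropped before any statistic.
#' @param basin_scope optional basin label restricting the whole analysis
#'   to one basin.
#' @param euclidean_on `"snapped"` (default) or `"original"` coordinates
#'   for the great-circle matrix.
#' @param map_diversity compute the windowed-diversity IDW map (can be
#'   switched off for speed in replicated experiments).
#' @param seed global seed; stage seeds are derived from it.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(paths = NULL, sim = NULL,
                            mantel_n_perm = 9999, amova_n_perm = 999,
                            window_radius_m = 10000, grid_cell_m = 1000,
                            idw_power = 2, clade_filter = NULL,
                            basin_scope = NULL,
                            euclidean_on = c("snapped", "original"),
                            map_diversity = TRUE, seed = 1L) {
  if (is.null(paths) == is.null(sim)) {
    stop("exactly one of 'paths' or 'sim' must be given", call. = FALSE)
  }
  if (!is.null(sim) && !inherits(sim, "simulation_config")) {
    stop("'sim' must be a simulation_config", call. = FALSE)
  }
  structure(list(paths = paths, sim = sim,
                 mantel_n_perm = mantel_n_perm, amova_n_perm = amova_n_perm,
                 window_radius_m = window_radius_m, grid_cell_m = grid_cell_m,
                 idw_power = idw_power, clade_filter = clade_filter,
                 basin_scope = basin_scope,
                 euclidean_on = match.arg(euclidean_on),
                 map_diversity = isTRUE(map_diversity),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

# simulate the full input bundle prescribed by a simulation_config
simulate_inputs <- function(sim, seed) {
  net <- gen_river_network(sim$n_basins, sim$branching_depth,
                           seed = stage_seed(seed, 1L))
  raster <- gen_altitude_raster(net)
  samples <- place_samples(net, sim$n_samples, seed = stage_seed(seed, 2L))
  geo <- switch(sim$generating_distance,
    euclidean = haversine_matrix(samples),
    lcp = lcp_distance_matrix(samples, raster),
    river = {
      d <- river_distance_matrix(samples, net)
      complete_river_distances(d, samples, net)
    })
  tree <- gen_ibd_tree(geo, sim$ibd_slope, sim$noise_sigma,
                       seed = stage_seed(seed, 3L))
  aln <- simulate_sequences(tree, sim$seq_length, sim$kappa, sim$base_freqs,
                            seed = stage_seed(seed, 4L))
  list(network = net, raster = raster, samples = samples, alignment = aln,
       tree = NULL)  # the analysis re-infers its tree from the sequences
}

# generative completion of cross-basin river distances: basins joined at
# the sea, i.e. own outlet + great-circle between outlets + other outlet
complete_river_distances <- function(d, samples, net) {
  if (!anyNA(d)) return(d)
  out <- basin_outlets(net)
  to_outlet <- outlet_distance(net, samples$.arc, samples$.s)
  bi <- match(as.character(samples$basin), rownames(out))
  for (i in seq_len(nrow(d) - 1)) {
    for (j in (i + 1):nrow(d)) {
      if (is.na(d[i, j])) {
        sea <- haversine_m(out[bi[i], ], out[bi[j], ])
        d[i, j] <- d[j, i] <- to_outlet[i] + sea + to_outlet[j]
      }
    }
  }
  d
}

read_inputs <- function(paths) {
  aln <- if (!is.null(paths$alignment)) {
    read_alignment(paths$alignment)
  } else if (!is.null(paths$fragments)) {
    stopifnot(length(paths$fragments) == 2)
    concat_alignments(read_alignment(paths$fragments[1]),
                      read_alignment(paths$fragments[2]))
  } else {
    stop("paths needs 'alignment' or 'fragments'", call. = FALSE)
  }
  list(network = read_river_network(paths$network),
       raster = read_altitude_raster(paths$raster),
       samples = read_sample_set(paths$samples),
       alignment = aln,
       tree = if (!is.null(paths$tree)) readLines(paths$tree, warn = FALSE) else NULL)
}

#' Run the full riverscape isolation-by-distance analysis
#'
#' Snaps the samples to the river network, computes the three geographic
#' distance matrices (great-circle, altitude least-cost path, river
#' network), extracts patristic genetic distances from the supplied tree
#' (or a neighbor-joining tree built from pairwise p-distances), runs the
#' three Mantel tests, a one-way AMOVA with basin as factor (skipped with
#' a warning when fewer than 2 basins remain), and the windowed-diversity
#' map. Fully deterministic given the config seed.
#'
#' @param cfg an [analysis_config()].
#' @param out_dir optional directory; when given, all matrices, grids and
#'   the JSON report are written there.
#' @return an `ibd_report` list.
#' @export
run_full_analysis <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "analysis_config"))
  inputs <- if (!is.null(cfg$sim)) {
    simulate_inputs(cfg$sim, cfg$seed)
  } else {
    read_inputs(cfg$paths)
  }
  samples <- as_sample_set(inputs$samples)
  aln <- alignment(inputs$alignment)
  if (!setequal(samples$id, names(aln))) {
    stop("sample ids and alignment ids do not match; offenders: ",
         paste(union(setdiff(samples$id, names(aln)),
                     setdiff(names(aln), samples$id)), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(cfg$clade_filter)) {
    samples <- samples[samples$clade %in% cfg$clade_filter, , drop = FALSE]
  }
  if (!is.null(cfg$basin_scope)) {
    samples <- samples[samples$basin %in% cfg$basin_scope, , drop = FALSE]
  }
  if (nrow(samples) < 4) stop("fewer than 4 samples after filtering", call. = FALSE)
  aln <- alignment(unclass(aln)[samples$id])

  snapped <- snap_to_network(samples, inputs$network)
  euc_pts <- if (cfg$euclidean_on == "snapped") snapped else samples
  d_euclid <- haversine_matrix(euc_pts)
  d_river <- river_distance_matrix(snapped, inputs$network)
  d_lcp <- lcp_distance_matrix(snapped, inputs$raster)

  tree <- if (!is.null(inputs$tree)) inputs$tree else nj_tree(pairwise_p_distances(aln))
  d_gen <- patristic_distances(tree)
  if (!setequal(rownames(d_gen), samples$id)) {
    stop("tree tips and sample ids do not match; offenders: ",
         paste(union(setdiff(rownames(d_gen), samples$id),
                     setdiff(samples$id, rownames(d_gen))), collapse = ", "),
         call. = FALSE)
  }
  d_gen <- dist_matrix(d_gen[samples$id, samples$id])

  mantel <- list(
    euclidean = mantel_test(d_gen, d_euclid, cfg$mantel_n_perm,
                            seed = stage_seed(cfg$seed, 10L)),
    lcp = mantel_test(d_gen, d_lcp, cfg$mantel_n_perm,
                      seed = stage_seed(cfg$seed, 11L)),
    river = mantel_test(d_gen, d_river, cfg$mantel_n_perm,
                        seed = stage_seed(cfg$seed, 12L)))

  amova <- if (length(unique(snapped$basin)) >= 2) {
    amova_oneway(d_gen, stats::setNames(snapped$basin, snapped$id),
                 cfg$amova_n_perm, seed = stage_seed(cfg$seed, 13L))
  } else {
    warning("fewer than 2 basins; AMOVA skipped")
    NULL
  }

  window_pi <- windowed_diversity(aln, snapped, cfg$window_radius_m)
  basin_pi <- basin_diversity(aln, snapped, cfg$window_radius_m)
  pi_grid <- if (cfg$map_diversity && any(!is.na(window_pi))) {
    idw_interpolate(snapped, window_pi, cfg$grid_cell_m, cfg$idw_power)
  } else {
    NULL
  }

  report <- structure(list(
    n_samples = nrow(snapped),
    ids = snapped$id,
    n_haplotypes = find_haplotypes(aln)$n_haplotypes,
    mantel = mantel,
    amova = amova,
    window_pi = window_pi,
    basin_pi = basin_pi,
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("paths", "sim"))]),
    class = "ibd_report")

  if (!is.null(out_dir)) {
    write_run_artifacts(out_dir, report, snapped,
                        list(euclidean = d_euclid, lcp = d_lcp,
                             river = d_river, genetic = d_gen),
                        tree, aln, pi_grid)
  }
  report$pi_grid <- pi_grid
  report
}

write_run_artifacts <- function(out_dir, report, snapped, matrices, tree,
                                aln, pi_grid) {
  dir.create(file.path(out_dir, "matrices"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "grids"), showWarnings = FALSE)
  for (nm in names(matrices)) {
    write_dist_matrix(matrices[[nm]], file.path(out_dir, "matrices",
                                                paste0(nm, ".csv")))
  }
  write_sample_set(snapped[setdiff(names(snapped), c(".arc", ".s"))],
                   file.path(out_dir, "samples_snapped.csv"))
  writeLines(tree, file.path(out_dir, "tree.nwk"))
  write_alignment(aln, file.path(out_dir, "alignment.fasta"))
  if (!is.null(pi_grid)) {
    write_diversity_grid(pi_grid, file.path(out_dir, "grids", "diversity.asc"))
  }
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' @export
print.ibd_report <- function(x, ...) {
  cat("Riverscape IBD analysis:", x$n_samples, "samples,",
      x$n_haplotypes, "haplotypes\n")
  for (nm in names(x$mantel)) {
    m <- x$mantel[[nm]]
    cat(sprintf("  Mantel %-9s vs genetic: r = %+.3f  p = %.4f  (%d pairs)\n",
                nm, m$r, m$p, m$n_pairs_used))
  }
  if (!is.null(x$amova)) {
    cat(sprintf("  AMOVA: %.1f%% of variance among basins (Phi_ST = %.3f, p = %.3f)\n",
                x$amova$pct_among, x$amova$phi_st, x$amova$p))
  }
  cat("  per-basin mean windowed pi:\n")
  print(x$basin_pi, row.names = FALSE)
  invisible(x)
}

#' Parameter-recovery experiment over seeded replicates
#'
#' Repeats simulate-then-analyze: sequences are generated under
#' isolation by distance along a chosen geographic distance, and each
#' replicate records the Mantel correlation of the re-inferred genetic
#' distances with all three candidate distances. The winner column names
#' the distance with the largest correlation; with a sufficient IBD slope
#' the generating distance should win in most replicates.
#'
#' @param sim a [simulation_config()]; its `seed` seeds replicate 1.
#' @param reps number of replicates (>= 1).
#' @param mantel_n_perm permutations per Mantel test (the comparison uses
#'   r, so a modest count suffices).
#' @return data frame with one row per replicate (`seed`, `r_euclid`,
#'   `r_lcp`, `r_river`, `p_euclid`, `p_lcp`, `p_river`, `winner`) and a
#'   `winner_fraction` attribute.
#' @export
recovery_experiment <- function(sim, reps = 20, mantel_n_perm = 199) {
  stopifnot(inherits(sim, "simulation_config"), reps >= 1)
  rows <- lapply(seq_len(reps), function(k) {
    seed_k <- sim$seed + k - 1L
    cfg <- analysis_config(sim = sim, mantel_n_perm = mantel_n_perm,
                           amova_n_perm = 99, map_diversity = FALSE,
                           seed = seed_k)
    rep_report <- run_full_analysis(cfg)
    r <- vapply(rep_report$mantel, `[[`, numeric(1), "r")
    p <- vapply(rep_report$mantel, `[[`, numeric(1), "p")
    data.frame(seed = seed_k, r_euclid = r[["euclidean"]], r_lcp = r[["lcp"]],
               r_river = r[["river"]], p_euclid = p[["euclidean"]],
               p_lcp = p[["lcp"]], p_river = p[["river"]],
               winner = c("euclidean", "lcp", "river")[which.max(
                 c(r[["euclidean"]], r[["lcp"]], r[["river"]]))])
  })
  out <- do.call(rbind, rows)
  attr(out, "winner_fraction") <- table(factor(out$winner,
    levels = c("euclidean", "lcp", "river"))) / nrow(out)
  out
}
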