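#' Specification for a synthetic spatial tissue
#'
#' Describes a desk-scale spatially clustered tissue: cells fall into
#' Gaussian spatial blobs (clusters), each cluster expresses its own marker
#' program, and designated sender/receiver cluster pairs carry boosted
#' ligand-receptor co-expression. All randomness derives from `seed`.
#'
#' @param n_cells number of cells (default 150).
#' @param n_genes number of genes (default 60).
#' @param n_clusters number of transcriptional clusters (expression
#'   programs; default 3, at least 2).
#' @param niches_per_cluster number of spatially separate niches (blobs)
#'   each cluster occupies (default 2). Values above 1 plant
#'   transcriptionally similar but spatially distant cell populations —
#'   the situation in real tissue where one cell type recurs in several
#'   locations — so that the transcriptional-similarity view carries
#'   information the spatial view cannot supply and multi-view fusion is
#'   genuinely exercised.
#' @param cluster_radius radius of the circle the niche centers sit on,
#'   in spatial units (default 5).
#' @param cluster_spread standard deviation of cell positions around their
#'   niche center (default 1.5).
#' @param effect_size mean log-fold elevation of cluster marker genes over
#'   the baseline (default 2).
#' @param n_lr_pairs number of planted ligand-receptor gene pairs
#'   (default 3; requires `2 * n_lr_pairs <= n_genes`).
#' @param lr_boost log-fold elevation of ligand genes in sender cells and
#'   receptor genes in receiver cells (default 2; 0 disables the planted
#'   signaling channel, useful for permutation-test calibration).
#' @param noise_sigma standard deviation of the multiplicative log-normal
#'   noise (default 0.3).
#' @param truth_knn number of within-cluster nearest neighbors counted as
#'   ground-truth proximity edges (default 5).
#' @param lr_dist_cap maximum distance for ground-truth sender-receiver
#'   edges (default 2 spatial units, a few cell diameters: the range of
#'   short-range signaling).
#' @param seed integer random seed (default 7).
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_cells = 150L, n_genes = 60L, n_clusters = 3L,
                            niches_per_cluster = 2L, cluster_radius = 5,
                            cluster_spread = 1.5, effect_size = 2,
                            n_lr_pairs = 3L, lr_boost = 2,
                            noise_sigma = 0.3, truth_knn = 5L,
                            lr_dist_cap = 2, seed = 7L) {
  if (n_clusters < 2L) stop("n_clusters must be >= 2")
  if (niches_per_cluster < 1L) stop("niches_per_cluster must be >= 1")
  if (effect_size <= 0) stop("effect_size must be > 0")
  if (2L * n_lr_pairs > n_genes) stop("need 2 * n_lr_pairs <= n_genes")
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_clusters = as.integer(n_clusters),
                 niches_per_cluster = as.integer(niches_per_cluster),
                 cluster_radius = cluster_radius,
                 cluster_spread = cluster_spread, effect_size = effect_size,
                 n_lr_pairs = as.integer(n_lr_pairs), lr_boost = lr_boost,
                 noise_sigma = noise_sigma, truth_knn = as.integer(truth_knn),
                 lr_dist_cap = lr_dist_cap, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a spatially clustered tissue with planted interactions
#'
#' Coordinates are drawn per cluster from Gaussian blobs whose centers sit
#' on a circle. Expression is a baseline mean times cluster-program and
#' ligand-receptor elevations, under multiplicative log-normal noise.
#'
#' Each planted signaling channel is short-range: it is assigned to one
#' cluster whose cells split into spatially intermingled sender and
#' receiver roles (as in juxtacrine or short-range paracrine signaling
#' between two interleaved cell populations). Senders express the channel's
#' ligand, receivers its receptor, so ligand-receptor co-expression is
#' spatially co-located — the signal a proximity-weighted co-expression
#' score can recover, and the one its permutation null destroys.
#'
#' The ground truth holds cluster labels and the planted interaction
#' edges: within-cluster k-nearest-neighbor proximity edges plus all
#' sender-receiver cell pairs closer than the distance cap.
#'
#' @param spec a [simulation_spec()].
#' @return A list with elements:
#'   * `dataset`: a [spatial_dataset()] with cluster labels.
#'   * `truth`: list with `labels` (cluster id per cell), `edges`
#'     (two-column matrix of undirected ground-truth pairs, i < j),
#'     `lr_pairs` (data frame of planted ligand/receptor gene symbols with
#'     the channel's cluster), `sender_cells`/`receiver_cells` (per-channel
#'     cell index lists), and `marker_genes` (marker gene indices per
#'     cluster).
#' @export
simulate_dataset <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells; g <- spec$n_genes; kc <- spec$n_clusters
  nb <- kc * spec$niches_per_cluster  # spatial niches, round-robin programs

  niche <- rep(seq_len(nb), length.out = n)
  cl <- (niche - 1L) %% kc + 1L       # cluster = expression program
  ang <- 2 * pi * (seq_len(nb) - 1) / nb
  centers <- cbind(spec$cluster_radius * cos(ang),
                   spec$cluster_radius * sin(ang))
  coords <- centers[niche, , drop = FALSE] +
    matrix(stats::rnorm(2 * n, sd = spec$cluster_spread), n, 2)

  gene_names <- sprintf("g%03d", seq_len(g))
  # reserve the first 2 * n_lr_pairs genes as ligand/receptor pairs
  lig_idx <- seq_len(spec$n_lr_pairs) * 2L - 1L
  rec_idx <- lig_idx + 1L
  channel_cluster <- (seq_len(spec$n_lr_pairs) - 1L) %% kc + 1L
  # disjoint marker programs over the remaining genes
  rest <- setdiff(seq_len(g), c(lig_idx, rec_idx))
  marker <- split(rest, rep(seq_len(kc), length.out = length(rest)))

  logmu <- matrix(0, n, g)
  for (c_id in seq_len(kc)) {
    logmu[cl == c_id, marker[[c_id]]] <-
      logmu[cl == c_id, marker[[c_id]]] + spec$effect_size
  }
  # intermingled sender/receiver roles within each channel's cluster
  sender_cells <- vector("list", spec$n_lr_pairs)
  receiver_cells <- vector("list", spec$n_lr_pairs)
  for (p in seq_len(spec$n_lr_pairs)) {
    members <- which(cl == channel_cluster[p])
    role <- sample(rep_len(c(TRUE, FALSE), length(members)))
    sender_cells[[p]] <- members[role]
    receiver_cells[[p]] <- members[!role]
    logmu[sender_cells[[p]], lig_idx[p]] <-
      logmu[sender_cells[[p]], lig_idx[p]] + spec$lr_boost
    logmu[receiver_cells[[p]], rec_idx[p]] <-
      logmu[receiver_cells[[p]], rec_idx[p]] + spec$lr_boost
  }
  expr <- exp(logmu + matrix(stats::rnorm(n * g, sd = spec$noise_sigma), n, g))

  ds <- spatial_dataset(expr, coords, gene_names = gene_names,
                        cell_ids = sprintf("cell_%04d", seq_len(n)),
                        labels = paste0("cluster_", cl))

  d <- as.matrix(stats::dist(coords))
  edges <- list()
  for (i in seq_len(n)) {
    same <- which(cl == cl[i] & seq_len(n) != i)
    if (length(same)) {
      nb <- same[order(d[i, same])][seq_len(min(spec$truth_knn, length(same)))]
      edges[[length(edges) + 1L]] <- cbind(pmin(i, nb), pmax(i, nb))
    }
  }
  for (p in seq_len(spec$n_lr_pairs)) {
    s_cells <- sender_cells[[p]]; r_cells <- receiver_cells[[p]]
    dd <- d[s_cells, r_cells, drop = FALSE]
    hit <- which(dd <= spec$lr_dist_cap, arr.ind = TRUE)
    if (nrow(hit)) {
      i <- s_cells[hit[, 1L]]; j <- r_cells[hit[, 2L]]
      edges[[length(edges) + 1L]] <- cbind(pmin(i, j), pmax(i, j))
    }
  }
  edges <- unique(do.call(rbind, edges))
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  colnames(edges) <- c("i", "j")

  truth <- list(labels = cl, niche = niche, edges = edges,
                lr_pairs = data.frame(ligand = gene_names[lig_idx],
                                      receptor = gene_names[rec_idx],
                                      cluster = channel_cluster,
                                      stringsAsFactors = FALSE),
                sender_cells = sender_cells,
                receiver_cells = receiver_cells,
                marker_genes = marker)
  list(dataset = ds, truth = truth)
}

#' Ligand-receptor database matching a simulation
#'
#' Returns the planted ligand/receptor gene pairs of a [simulation_spec()]
#' as an [lr_db()], standing in for a curated database on synthetic data.
#'
#' @param spec a [simulation_spec()].
#' @return An `lr_db` with `spec$n_lr_pairs` disjoint pairs.
#' @export
make_toy_lr_db <- function(spec = simulation_spec()) {
  gene_names <- sprintf("g%03d", seq_len(spec$n_genes))
  lig <- seq_len(spec$n_lr_pairs) * 2L - 1L
  lr_db(gene_names[lig], gene_names[lig + 1L])
}
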