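# Construction of the three cell-level view graphs: spatial proximity,
# ligand-receptor signaling, and transcriptional similarity. Each view is a
# weighted affinity matrix W plus a row-wise top-k binarized adjacency A.

#' Construct a view graph
#'
#' @param W nonnegative N x N weight matrix.
#' @param A binary N x N adjacency (dgCMatrix or base matrix).
#' @param view one of `"spatial"`, `"lr"`, `"similarity"`.
#' @return An object of class `view_graph` with elements `W`, `A`, `view`.
#' @export
view_graph <- function(W, A, view = c("spatial", "lr", "similarity")) {
  view <- match.arg(view)
  W <- as.matrix(W)
  if (any(!is.finite(W))) stop("view weights must be finite")
  if (any(W < 0)) stop("view weights must be nonnegative")
  A <- Matrix::drop0(methods::as(Matrix::Matrix(A, sparse = TRUE),
                                 "generalMatrix"))
  if (any(Matrix::diag(A) != 0)) stop("adjacency must have a zero diagonal")
  structure(list(W = W, A = A, view = view), class = "view_graph")
}

#' @export
print.view_graph <- function(x, ...) {
  cat("view_graph [", x$view, "]: ", nrow(x$W), " cells, ",
      Matrix::nnzero(x$A), " directed edges\n", sep = "")
  invisible(x)
}

.pairwise_dist <- function(x) as.matrix(stats::dist(x))

# mean nearest-neighbor distance; the characteristic spacing of the tissue
mean_nn_distance <- function(coords) {
  d <- .pairwise_dist(coords)
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}

#' Adaptive Gaussian spatial kernel
#'
#' Computes `W[i, j] = exp(-d_ij^2 / (2 * sigma_i^2))` where `sigma_i` is
#' the distance from cell i to its `m`-th nearest neighbor, so the kernel
#' bandwidth adapts to local density: tight in dense regions, wide in sparse
#' ones. Coincident points (`sigma_i = 0`) fall back to `eps`. The matrix is
#' generally asymmetric because the bandwidth is row-specific; the diagonal
#' is zero.
#'
#' @param coords N x 2 coordinate matrix, N >= 2.
#' @param m neighbor rank defining the bandwidth (default 1, the nearest
#'   neighbor).
#' @param eps stability constant replacing zero bandwidths.
#' @return N x N weight matrix.
#' @export
spatial_kernel <- function(coords, m = 1L, eps = 1e-8) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 cells")
  if (m > n - 1L) stop("bandwidth rank m must be <= N - 1")
  d <- .pairwise_dist(coords)
  dd <- d
  diag(dd) <- Inf
  sigma <- apply(dd, 1L, function(r) sort(r)[m])
  sigma[sigma == 0] <- eps
  W <- exp(-d^2 / (2 * sigma^2))
  diag(W) <- 0
  W
}

#' Row-wise top-k sparsification
#'
#' Keeps, for each row, the k largest strictly positive off-diagonal
#' weights as edges. Rows with fewer than k positive weights keep only the
#' positive ones (zero affinity is no evidence of interaction). Ties break
#' toward the smaller column index, making the result deterministic.
#'
#' @param W N x N weight matrix.
#' @param k edges kept per row (>= 1).
#' @param exclude_self drop the diagonal before selection (default TRUE).
#' @return Sparse binary N x N adjacency.
#' @export
topk_sparsify <- function(W, k, exclude_self = TRUE) {
  W <- as.matrix(W)
  if (k < 1L) stop("k must be >= 1")
  n <- nrow(W)
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(n)) {
    w <- W[i, ]
    if (exclude_self) w[i] <- -Inf
    cand <- which(w > 0)
    if (!length(cand)) next
    keep <- cand[order(-w[cand], cand)][seq_len(min(k, length(cand)))]
    ii <- c(ii, rep.int(i, length(keep)))
    jj <- c(jj, keep)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
}

#' Build the spatial proximity view
#'
#' Adaptive Gaussian kernel on the coordinates, sparsified to the
#' `cfg$k_neighbors` most spatially relevant neighbors per cell.
#'
#' @param ds a [spatial_dataset()].
#' @param cfg a [model_config()].
#' @return A `view_graph` with tag `"spatial"`.
#' @export
build_spatial_graph <- function(ds, cfg = model_config()) {
  W <- spatial_kernel(ds$coords, m = cfg$bandwidth_rank)
  view_graph(W, topk_sparsify(W, cfg$k_neighbors), "spatial")
}

#' Score one ligand-receptor pair across all cell pairs
#'
#' `S[i, j] = El(i) * Er(j) * exp(-d_ij^2 / (2 sigma^2))`: the product of
#' the normalized ligand expression in the sender cell i and receptor
#' expression in the receiver cell j, damped by spatial distance with a
#' single global bandwidth. Directed (rows send, columns receive); diagonal
#' zero.
#'
#' @param expr_norm N x G normalized expression matrix (min-max per gene
#'   recommended so scores stay in `[0, 1]`).
#' @param coords N x 2 coordinates.
#' @param pair length-2 integer vector `(ligand column, receptor column)`.
#' @param sigma_global positive kernel bandwidth; defaults to the mean
#'   nearest-neighbor distance.
#' @return N x N score matrix.
#' @export
lr_pair_score <- function(expr_norm, coords, pair,
                          sigma_global = mean_nn_distance(coords)) {
  if (sigma_global <= 0) sigma_global <- 1e-8
  d <- .pairwise_dist(coords)
  S <- outer(expr_norm[, pair[1L]], expr_norm[, pair[2L]]) *
    exp(-d^2 / (2 * sigma_global^2))
  diag(S) <- 0
  S
}

#' Permutation p-value for a ligand-receptor pair
#'
#' The observed statistic is the total pair score summed over all ordered
#' cell pairs. The null permutes the receptor expression vector across
#' cells (re-pairing expression with positions) and recomputes the
#' statistic. The add-one Monte-Carlo convention gives
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, always in `(0, 1]`.
#'
#' @param score_obs observed statistic (sum of the score matrix).
#' @param expr_norm,coords,pair,sigma_global as in [lr_pair_score()].
#' @param n_perm number of permutations (>= 1).
#' @param rng_seed integer seed.
#' @return p-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(score_obs, expr_norm, coords, pair,
                               sigma_global = mean_nn_distance(coords),
                               n_perm = 100L, rng_seed = 1L) {
  stopifnot(n_perm >= 1L)
  if (sigma_global <= 0) sigma_global <- 1e-8
  d <- .pairwise_dist(coords)
  kern <- exp(-d^2 / (2 * sigma_global^2))
  diag(kern) <- 0
  el <- expr_norm[, pair[1L]]
  er <- expr_norm[, pair[2L]]
  set.seed(rng_seed)
  n_ge <- 0L
  for (b in seq_len(n_perm)) {
    er_p <- er[sample.int(length(er))]
    stat <- sum(outer(el, er_p) * kern)
    if (stat >= score_obs) n_ge <- n_ge + 1L
  }
  (1 + n_ge) / (1 + n_perm)
}

#' Build the ligand-receptor signaling view
#'
#' Per mappable database pair, scores all directed cell pairs with
#' [lr_pair_score()] (on min-max normalized expression) and tests the total
#' score against a receptor-permutation null. The view weight matrix is the
#' elementwise sum of the score matrices of the significant pairs
#' (`p < alpha`), sparsified to the top `cfg$k_neighbors` outgoing edges per
#' cell. Pairs whose genes are absent from the dataset are skipped with a
#' message.
#'
#' @param ds a [spatial_dataset()].
#' @param db an [lr_db()].
#' @param cfg a [model_config()] (uses `alpha`, `n_perm`, `k_neighbors`,
#'   `seed`).
#' @return A `view_graph` with tag `"lr"`; attribute `score_table` holds the
#'   per-pair statistic and p-value.
#' @export
build_lr_graph <- function(ds, db, cfg = model_config()) {
  idx_l <- match(db$ligand, ds$gene_names)
  idx_r <- match(db$receptor, ds$gene_names)
  ok <- !is.na(idx_l) & !is.na(idx_r)
  if (!any(ok)) {
    stop("no ligand-receptor pair maps to the dataset's genes; ",
         "supply a matching (e.g. toy) LR database")
  }
  skipped <- which(!ok)
  if (length(skipped)) {
    message(length(skipped), " LR pair(s) skipped (genes absent): ",
            paste(db$ligand[skipped], db$receptor[skipped], sep = "-",
                  collapse = ", "))
  }
  expr_mm <- normalize_expression(ds$expr, "minmax_per_gene")
  sigma <- mean_nn_distance(ds$coords)
  tab <- data.frame(ligand = db$ligand[ok], receptor = db$receptor[ok],
                    statistic = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  n <- nrow(ds$expr)
  W <- matrix(0, n, n)
  scores <- vector("list", sum(ok))
  for (q in seq_len(sum(ok))) {
    pr <- c(idx_l[ok][q], idx_r[ok][q])
    S <- lr_pair_score(expr_mm, ds$coords, pr, sigma)
    tab$statistic[q] <- sum(S)
    tab$p_value[q] <- permutation_pvalue(tab$statistic[q], expr_mm,
                                         ds$coords, pr, sigma,
                                         n_perm = cfg$n_perm,
                                         rng_seed = cfg$seed + q)
    scores[[q]] <- S
  }
  tab$significant <- tab$p_value < cfg$alpha
  for (q in which(tab$significant)) W <- W + scores[[q]]
  if (all(W == 0)) {
    stop("empty LR graph: no ligand-receptor pair is significant at alpha = ",
         cfg$alpha)
  }
  g <- view_graph(W, topk_sparsify(W, cfg$k_neighbors), "lr")
  attr(g, "score_table") <- tab
  g
}

#' Conditional similarity kernel
#'
#' `P(j | i) = exp(-max(0, d_ij - rho_i) / (sigma_i + eps))`: probability
#' that cell i regards j as a neighbor, saturating at 1 for anything at
#' least as close as i's nearest neighbor and decaying on the scale of i's
#' k-th neighbor distance.
#'
#' @param d_ij distance(s) from i to j.
#' @param rho_i distance from i to its nearest neighbor.
#' @param sigma_i distance from i to its k-th nearest neighbor.
#' @param eps stability constant.
#' @return Value(s) in `(0, 1]`.
#' @export
conditional_similarity <- function(d_ij, rho_i, sigma_i, eps = 1e-8) {
  exp(-pmax(d_ij - rho_i, 0) / (sigma_i + eps))
}

#' Symmetrize directed conditional similarities
#'
#' Probabilistic OR: `p + q - p * q`. Commutative, monotone in each
#' argument, bounded in `[0, 1]`, with 1 absorbing.
#'
#' @param p_ij,p_ji conditional similarities in `[0, 1]`.
#' @return Symmetric similarity.
#' @export
symmetrize_similarity <- function(p_ij, p_ji) {
  p_ij + p_ji - p_ij * p_ji
}

#' Build the transcriptional similarity view
#'
#' Z-scores the expression matrix, projects it to `cfg$pca_dim` principal
#' components (clipped to `min(N - 1, G)`), and computes pairwise Euclidean
#' distances in that embedding. Per-cell local density parameters `rho_i`
#' (nearest-neighbor distance) and `sigma_i` (k-th neighbor distance, k =
#' `knn_for_sigma`) feed the conditional kernel, symmetrized by
#' probabilistic OR, then sparsified per row.
#'
#' @param ds a [spatial_dataset()].
#' @param cfg a [model_config()].
#' @param knn_for_sigma neighbor rank for `sigma_i` (defaults to
#'   `cfg$k_neighbors`; reduced with a warning when `>= N - 1`).
#' @return A `view_graph` with tag `"similarity"` and a symmetric weight
#'   matrix.
#' @export
build_similarity_graph <- function(ds, cfg = model_config(),
                                   knn_for_sigma = cfg$k_neighbors) {
  n <- nrow(ds$expr)
  if (n < 3L) stop("similarity graph needs at least 3 cells")
  if (knn_for_sigma >= n - 1L) {
    warning("knn_for_sigma reduced from ", knn_for_sigma, " to ", n - 2L)
    knn_for_sigma <- n - 2L
  }
  z <- normalize_expression(ds$expr, "zscore_per_gene")
  ncomp <- min(cfg$pca_dim, n - 1L, ncol(z))
  xs <- stats::prcomp(z, center = TRUE, scale. = FALSE)$x[, seq_len(ncomp),
                                                          drop = FALSE]
  d <- .pairwise_dist(xs)
  dd <- d
  diag(dd) <- Inf
  srt <- apply(dd, 1L, sort)
  rho <- srt[1L, ]
  sigma <- srt[knn_for_sigma, ]
  # row i uses rho[i], sigma[i] (column-major recycling divides row-wise)
  P <- exp(-pmax(sweep(d, 1L, rho), 0) / (sigma + 1e-8))
  W <- symmetrize_similarity(P, t(P))
  diag(W) <- 0
  view_graph(W, topk_sparsify(W, cfg$k_neighbors), "similarity")
}
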