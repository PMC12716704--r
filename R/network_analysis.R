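# Downstream characterization of a reconstructed interaction network:
# high-confidence edge thresholding, spatial distance statistics, topology,
# and hub calling.

#' Keep the top-scoring fraction of candidate edges
#'
#' Ranks all unique off-diagonal pairs (i < j) by decoded score and retains
#' the `ceiling(fraction * P)` strongest, ties broken by (i, j) order. The
#' default fraction 0.05 keeps the top 5% of high-confidence interactions.
#'
#' @param A_hat N x N symmetric score matrix (decoded probabilities).
#' @param fraction fraction of pairs to keep, in (0, 1].
#' @param coords optional N x 2 coordinates stored as node metadata.
#' @param labels optional per-cell labels stored as node metadata.
#' @return An object of class `interaction_network`: data frame `edges`
#'   with columns `i`, `j`, `score` (i < j), plus `n`, `coords`, `labels`.
#' @export
threshold_top_edges <- function(A_hat, fraction = 0.05, coords = NULL,
                                labels = NULL) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  A_hat <- as.matrix(A_hat)
  n <- nrow(A_hat)
  ut <- which(upper.tri(A_hat), arr.ind = TRUE)
  s <- A_hat[ut]
  keep <- order(-s, ut[, 1L], ut[, 2L])[seq_len(ceiling(fraction * nrow(ut)))]
  edges <- data.frame(i = ut[keep, 1L], j = ut[keep, 2L], score = s[keep])
  edges <- edges[order(edges$i, edges$j), ]
  rownames(edges) <- NULL
  structure(list(edges = edges, n = n, coords = coords, labels = labels),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction_network:", x$n, "cells,", nrow(x$edges), "edges\n")
  invisible(x)
}

# two-sample KS statistic: sup over pooled points of |ECDF1 - ECDF2|
.ks_statistic <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(p) mean(a <= p) - mean(b <= p), 0)))
}

#' Compare intra- vs inter-cluster interaction distances
#'
#' Splits the Euclidean lengths of the network's edges by whether both
#' endpoints share a label, and compares the two distance distributions
#' with a two-sample Kolmogorov-Smirnov test (statistic computed as the
#' supremum ECDF difference; asymptotic p-value).
#'
#' @param net an `interaction_network` with coordinates.
#' @param labels per-cell labels (defaults to the network's metadata).
#' @return List with `statistic`, `p_value`, `intra` and `inter` distance
#'   vectors.
#' @export
intra_inter_distance_test <- function(net, labels = net$labels) {
  if (is.null(net$coords)) stop("network carries no coordinates")
  if (is.null(labels)) stop("labels are required")
  e <- net$edges
  d <- sqrt(rowSums((net$coords[e$i, , drop = FALSE] -
                       net$coords[e$j, , drop = FALSE])^2))
  intra <- d[labels[e$i] == labels[e$j]]
  inter <- d[labels[e$i] != labels[e$j]]
  if (!length(intra)) stop("no intra-cluster edges in the network")
  if (!length(inter)) stop("no inter-cluster edges in the network")
  stat <- .ks_statistic(intra, inter)
  p <- suppressWarnings(stats::ks.test(intra, inter)$p.value)
  list(statistic = stat, p_value = p, intra = intra, inter = inter)
}

#' Degree and closeness centrality of the interaction network
#'
#' Degree counts incident edges. Closeness uses the component-normalized
#' form `(n_reachable - 1) / sum(shortest path lengths)` within each
#' node's connected component; isolated nodes get 0.
#'
#' @param net an `interaction_network`.
#' @return Data frame with columns `node`, `degree`, `closeness`.
#' @export
topology_stats <- function(net) {
  if (!nrow(net$edges)) stop("network is empty")
  g <- igraph::graph_from_edgelist(as.matrix(net$edges[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, net$n - igraph::vcount(g)))
  deg <- igraph::degree(g)
  dmat <- igraph::distances(g)
  clo <- vapply(seq_len(net$n), function(v) {
    reach <- which(is.finite(dmat[v, ]) & seq_len(net$n) != v)
    if (!length(reach)) return(0)
    length(reach) / sum(dmat[v, reach])
  }, 0)
  data.frame(node = seq_len(net$n), degree = deg, closeness = clo)
}

#' Identify hub cells
#'
#' Nodes whose interaction degree strictly exceeds the threshold
#' (default 10), interpreted as local communication centers.
#'
#' @param net an `interaction_network`.
#' @param degree_threshold nonnegative degree cutoff.
#' @return Integer vector of hub node indices.
#' @export
find_hubs <- function(net, degree_threshold = 10L) {
  if (degree_threshold < 0) stop("threshold must be >= 0")
  ts <- topology_stats(net)
  ts$node[ts$degree > degree_threshold]
}
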