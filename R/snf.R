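# Similarity Network Fusion: merges the cell-level affinity matrices into a
# consensus similarity network that supervises training (and is never a
# model input).

# full transition matrix with the 1/2-diagonal convention:
# P[i, j] = W[i, j] / (2 * sum_{k != i} W[i, k]) off the diagonal, 1/2 on it
.snf_full_kernel <- function(W) {
  n <- nrow(W)
  off <- W
  diag(off) <- 0
  rs <- rowSums(off)
  rs[rs == 0] <- 1
  P <- off / (2 * rs)
  diag(P) <- 0.5
  P
}

# kNN-masked local kernel: rows renormalized over the K strongest neighbors
.snf_local_kernel <- function(W, K) {
  n <- nrow(W)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- W[i, ]
    w[i] <- -Inf
    nb <- order(-w, seq_len(n))[seq_len(K)]
    tot <- sum(W[i, nb])
    if (tot > 0) S[i, nb] <- W[i, nb] / tot
  }
  S
}

#' Fuse affinity matrices by similarity network fusion
#'
#' Implements the cross-view diffusion of Wang et al.: each view's affinity
#' matrix yields a full transition matrix `P_v` (row-normalized with the
#' 1/2-diagonal convention) and a k-nearest-neighbor-masked local kernel
#' `S_v`; the update `P_v <- S_v %*% mean(other P) %*% t(S_v)` (followed by
#' renormalization, which keeps the iteration on the transition-matrix
#' scale) runs for `t` rounds, and the fused network is the symmetrized
#' mean of the final `P_v`.
#'
#' @param W_list list of two or more N x N nonnegative affinity matrices.
#' @param K neighbors of the local kernel (default 20, clipped to N - 1).
#' @param t diffusion iterations (default 20).
#' @return Symmetric nonnegative N x N fused matrix.
#' @export
snf_fuse <- function(W_list, K = 20L, t = 20L) {
  if (length(W_list) < 2L) stop("need at least two views")
  n <- nrow(W_list[[1L]])
  for (W in W_list) {
    if (!all(dim(W) == c(n, n))) stop("all views must be N x N with equal N")
  }
  K <- min(K, n - 1L)
  P <- lapply(W_list, .snf_full_kernel)
  S <- lapply(W_list, .snf_local_kernel, K = K)
  nv <- length(W_list)
  for (it in seq_len(t)) {
    Pnew <- vector("list", nv)
    for (v in seq_len(nv)) {
      others <- Reduce(`+`, P[-v]) / (nv - 1L)
      Pnew[[v]] <- .snf_full_kernel(S[[v]] %*% others %*% t(S[[v]]))
    }
    P <- Pnew
  }
  fused <- Reduce(`+`, P) / nv
  (fused + t(fused)) / 2
}

#' Build the consensus supervision target
#'
#' Fuses the spatial, ligand-receptor, and transcriptional-similarity
#' weight matrices with [snf_fuse()], binarizes per row by keeping the top
#' `cfg$k_neighbors` fused neighbors, and symmetrizes by logical OR. The
#' result supervises the reconstruction loss only; it is never an input
#' graph to the model.
#'
#' @param graphs named list with `view_graph`s `spatial`, `lr`,
#'   `similarity`.
#' @param cfg a [model_config()].
#' @return An object of class `target_adjacency`: list with `A` (sparse
#'   symmetric binary matrix, zero diagonal) and `fused` (the continuous
#'   fused network).
#' @export
build_target <- function(graphs, cfg = model_config()) {
  for (v in c("spatial", "lr", "similarity")) {
    if (is.null(graphs[[v]])) stop("missing view: ", v)
  }
  fused <- snf_fuse(list(graphs$spatial$W, graphs$lr$W, graphs$similarity$W),
                    K = cfg$snf_K, t = cfg$snf_t)
  A <- topk_sparsify(fused, cfg$k_neighbors)
  A <- methods::as(methods::as(A + Matrix::t(A), "generalMatrix"),
                   "nMatrix")  # logical OR; general storage before summary
  tr <- Matrix::summary(methods::as(A, "TsparseMatrix"))
  A <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = 1, dims = dim(A))
  Matrix::diag(A) <- 0
  A <- Matrix::drop0(A)
  if (Matrix::nnzero(A) == 0) stop("target adjacency has no edges")
  structure(list(A = A, fused = fused), class = "target_adjacency")
}
#' @export
print.target_adjacency <- function(x, ...) {
  cat("target_adjacency:", nrow(x$A), "cells,",
      Matrix::nnzero(x$A) / 2, "undirected edges\n")
  invisible(x)
}
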