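# View-specific two-layer GCN encoders and self-attention pooling of gene
# embeddings to cell level. These are the plain numeric forms; the trainer
# replays the same arithmetic on the autodiff tape (R/model.R).

#' Symmetrically normalized adjacency with self-loops
#'
#' Computes `D^{-1/2} (A + I) D^{-1/2}` where `D` is the degree matrix of
#' `A + I` (the renormalization trick). Self-loops guarantee every degree is
#' at least 1, so isolated nodes are safe.
#'
#' @param A square (sparse) adjacency matrix.
#' @return Sparse normalized propagation matrix.
#' @export
gcn_normalize <- function(A) {
  A <- Matrix::Matrix(A, sparse = TRUE)
  n <- nrow(A)
  At <- A + Matrix::Diagonal(n)
  dh <- 1 / sqrt(Matrix::rowSums(At))
  Matrix::Diagonal(n, dh) %*% At %*% Matrix::Diagonal(n, dh)
}

#' One graph-convolution layer
#'
#' `activation(D^{-1/2} (A + I) D^{-1/2} %*% Z %*% W)`, the standard GCN
#' propagation rule without bias terms.
#'
#' @param A adjacency matrix (binary; self-loops added internally).
#' @param Z node feature matrix (rows match `A`).
#' @param W weight matrix.
#' @param activation `"relu"`, `"linear"`, or `"tanh"`.
#' @return Transformed node features.
#' @export
gcn_layer <- function(A, Z, W, activation = c("relu", "linear", "tanh")) {
  activation <- match.arg(activation)
  if (nrow(A) != nrow(Z)) stop("A and Z row counts differ")
  out <- as.matrix(gcn_normalize(A) %*% (Z %*% W))
  switch(activation,
         relu = pmax(out, 0),
         linear = out,
         tanh = tanh(out))
}

#' Two-layer GCN encoder
#'
#' Bottleneck architecture: the first layer (ReLU) projects node features
#' into a wider hidden space, the second (linear) maps them into the shared
#' latent space (32-dimensional by default configuration).
#'
#' @param graph a `view_graph`, `gene_block_graph`, or adjacency matrix.
#' @param X input node features.
#' @param params list with weight matrices `W0`
#'   (input x hidden) and `W1` (hidden x latent).
#' @return Latent node features (N x latent for cell graphs, M x latent for
#'   the gene graph).
#' @export
gcn_encode <- function(graph, X, params) {
  A <- if (inherits(graph, "view_graph")) graph$A
       else if (inherits(graph, "gene_block_graph")) graph$A_g
       else graph
  h <- gcn_layer(A, X, params$W0, "relu")
  gcn_layer(A, h, params$W1, "linear")
}

#' Attention pooling of gene embeddings to cell level
#'
#' Scores each gene node of a cell with a shared two-layer MLP (tanh
#' nonlinearity), softmax-normalizes the scores over the cell's k genes,
#' and returns the attention-weighted sum of the gene embeddings, one row
#' per cell. The output always lies in the convex hull of the cell's gene
#' embeddings.
#'
#' @param E_g either an N x k x d array of per-cell gene embeddings or an
#'   M x d matrix with a `groups` vector.
#' @param mlp list with `W1` (d x h) and `W2` (h x 1) scorer weights.
#' @param groups integer cell index per row when `E_g` is a matrix.
#' @return N x d pooled matrix; attribute `beta` holds the attention
#'   weights.
#' @export
attention_pool <- function(E_g, mlp, groups = NULL) {
  if (is.array(E_g) && length(dim(E_g)) == 3L) {
    dm <- dim(E_g)
    # flatten N x k x d so rows are (cell, gene) with cells contiguous
    E <- do.call(rbind, lapply(seq_len(dm[1L]),
                               function(i) matrix(E_g[i, , ], dm[2L])))
    groups <- rep(seq_len(dm[1L]), each = dm[2L])
  } else {
    E <- as.matrix(E_g)
    if (is.null(groups)) stop("matrix input needs a groups vector")
  }
  if (ncol(mlp$W2) != 1L) stop("scorer must output one logit per gene node")
  s <- as.vector(tanh(E %*% mlp$W1) %*% mlp$W2)
  mx <- stats::ave(s, groups, FUN = max)
  e <- exp(s - mx)
  beta <- e / stats::ave(e, groups, FUN = sum)
  out <- rowsum(E * beta, groups, reorder = TRUE)
  attr(out, "beta") <- beta
  out
}
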