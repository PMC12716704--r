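# Contrastive regularization aligning each cell-view embedding with the
# pooled gene-level embedding, plus the center-alignment loss on the final
# embedding. All similarities are dot products of L2-normalized rows
# (cosine).

.l2norm_rows <- function(x, eps = 1e-12) x / (sqrt(rowSums(x^2)) + eps)

#' Symmetric InfoNCE loss between two embedding sets
#'
#' Rows are L2-normalized, pairwise cosine similarities are scaled by the
#' temperature `tau`, and the matched pair (row i of both sets) is treated
#' as the positive against all in-batch candidates. The loss averages the
#' cell-to-gene and gene-to-cell directions.
#'
#' @param Z_v,Z_g N x d embedding matrices (matched by row).
#' @param tau temperature (> 0).
#' @return Nonnegative scalar; `log(N)` when all embeddings are identical.
#' @export
info_nce <- function(Z_v, Z_g, tau = 0.3) {
  n <- nrow(Z_v)
  if (n == 0L) stop("empty embedding set")
  if (n != nrow(Z_g)) stop("embedding sets must have equal N")
  S <- tcrossprod(.l2norm_rows(Z_v), .l2norm_rows(Z_g)) / tau
  ce <- function(M) {
    mx <- apply(M, 1L, max)
    mean(mx + log(rowSums(exp(M - mx))) - diag(M))
  }
  (ce(S) + ce(t(S))) / 2
}

#' Select hard negatives for an anchor
#'
#' Returns the indices of the `n_hard` candidates most cosine-similar to
#' the anchor, excluding the matched index. Ties break toward the smaller
#' index.
#'
#' @param anchor length-d numeric vector.
#' @param candidates N x d candidate matrix.
#' @param n_hard negatives to select.
#' @param exclude index of the matched candidate (excluded from selection).
#' @return Integer vector of at most `n_hard` indices.
#' @export
select_hard_negatives <- function(anchor, candidates, n_hard = 5L,
                                  exclude = NULL) {
  a <- anchor / sqrt(sum(anchor^2) + 1e-12)
  sims <- as.vector(.l2norm_rows(candidates) %*% a)
  idx <- seq_along(sims)
  if (!is.null(exclude)) idx <- idx[idx != exclude]
  idx[order(-sims[idx], idx)][seq_len(min(n_hard, length(idx)))]
}

# N x n_hard index matrix of hard negatives per row of S (cosine matrix),
# excluding the diagonal; NA-padded
.hard_neg_matrix <- function(S, n_hard) {
  n <- nrow(S)
  out <- matrix(NA_integer_, n, max(1L, min(n_hard, n - 1L)))
  for (i in seq_len(n)) {
    idx <- setdiff(seq_len(n), i)
    sel <- idx[order(-S[i, idx], idx)][seq_len(min(n_hard, n - 1L))]
    out[i, seq_along(sel)] <- sel
  }
  out
}

#' Margin-based contrastive loss over hard negatives
#'
#' Mean over anchors of the hinge `max(0, sim(anchor, negative) -
#' sim(anchor, positive) + m)` summed over each anchor's hard-negative set,
#' with both directions (cell anchors against gene negatives and gene
#' anchors against cell negatives) added.
#'
#' @param Z_v,Z_g N x d embedding matrices.
#' @param m margin.
#' @param n_hard hard negatives per anchor (most-similar non-matches).
#' @param negatives optional list with precomputed index matrices `Hg`
#'   (gene-side negatives per cell anchor) and `Hv` (cell-side negatives
#'   per gene anchor); overrides `n_hard`.
#' @return Nonnegative scalar.
#' @export
margin_loss <- function(Z_v, Z_g, m = 0.1, n_hard = 5L, negatives = NULL) {
  S <- tcrossprod(.l2norm_rows(Z_v), .l2norm_rows(Z_g))
  if (is.null(negatives)) {
    negatives <- list(Hg = .hard_neg_matrix(S, n_hard),
                      Hv = .hard_neg_matrix(t(S), n_hard))
  }
  hinge_sum <- function(M, negs) {
    tot <- 0
    pos <- diag(M)
    for (col in seq_len(ncol(negs))) {
      j <- negs[, col]
      okr <- which(!is.na(j))
      h <- M[cbind(okr, j[okr])] - pos[okr] + m
      tot <- tot + sum(pmax(h, 0))
    }
    tot
  }
  (hinge_sum(S, negatives$Hg) + hinge_sum(t(S), negatives$Hv)) / nrow(S)
}

#' Combined contrastive regularization over the enabled views
#'
#' Sum over views of `InfoNCE + lambda * margin loss`, each view aligned
#' against the shared pooled gene embedding.
#'
#' @param views named list of N x d cell-view embeddings (any nonempty
#'   subset of spatial / lr / similarity).
#' @param Z_g pooled gene embedding (N x d).
#' @param cfg a [model_config()] (uses `tau`, `margin`, `lambda_margin`,
#'   `n_hard`).
#' @return Scalar loss.
#' @export
contrastive_loss <- function(views, Z_g, cfg = model_config()) {
  if (!length(views)) stop("need at least one view")
  tot <- 0
  for (Z_v in views) {
    tot <- tot + info_nce(Z_v, Z_g, cfg$tau) +
      cfg$lambda_margin * margin_loss(Z_v, Z_g, cfg$margin, cfg$n_hard)
  }
  tot
}

#' Center-alignment loss
#'
#' Pulls every final embedding toward the projection of the dataset's mean
#' expression profile: `mean_i || Z[i, ] - P(mean(X_c)) ||^2` where `P` is
#' a bias-free linear map from gene space to the latent space.
#'
#' @param Z_final N x d final embeddings.
#' @param X_c N x G expression features.
#' @param P G x d projection matrix.
#' @return Nonnegative scalar.
#' @export
center_alignment_loss <- function(Z_final, X_c, P) {
  a <- as.vector(colMeans(X_c) %*% P)
  r <- sweep(Z_final, 2L, a)
  mean(rowSums(r^2))
}
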