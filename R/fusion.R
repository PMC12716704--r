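# Cell-gene cross-attention fusion: each cell view queries the pooled gene
# embeddings through multi-head scaled dot-product attention, is refined by
# a residual + layer-norm + feed-forward block, and the three branch
# outputs are combined by a gated (per-cell softmax) convex mixture.

.softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

.layernorm_rows <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  v <- rowMeans((x - mu)^2)
  xhat <- (x - mu) / sqrt(v + eps)
  sweep(sweep(xhat, 2L, as.vector(gamma), "*"), 2L, as.vector(beta), "+")
}

.gelu <- function(x) x * stats::pnorm(x)

#' Multi-head cell-gene cross-attention branch
#'
#' One cell view serves as the query; the pooled gene embeddings serve as
#' keys and values. Per head h, `alpha[i, j] = softmax_j(Q_h(i) . K_h(j) /
#' sqrt(d_k))` attends over all N gene slots, head outputs are concatenated
#' and projected by `W_o`. Every attention row sums to 1.
#'
#' @param Z_c N x d query view embedding.
#' @param Z_g N x d pooled gene embeddings (keys/values).
#' @param params list with `W_q`, `W_k`, `W_v`, `W_o` (each d x d; the
#'   first three are sliced into per-head d x d_k blocks).
#' @param H number of heads (d must be divisible by H).
#' @return N x d fused matrix (pre-residual); attribute `attention` holds
#'   the per-head attention matrices.
#' @export
cross_attention_branch <- function(Z_c, Z_g, params, H = 4L) {
  d <- ncol(Z_c)
  if (d %% H != 0L) stop("latent dim ", d, " not divisible by heads ", H)
  dk <- d %/% H
  Q <- Z_c %*% params$W_q
  K <- Z_g %*% params$W_k
  V <- Z_g %*% params$W_v
  outs <- vector("list", H)
  attn <- vector("list", H)
  for (h in seq_len(H)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    A <- .softmax_rows(tcrossprod(Q[, idx, drop = FALSE],
                                  K[, idx, drop = FALSE]) / sqrt(dk))
    attn[[h]] <- A
    outs[[h]] <- A %*% V[, idx, drop = FALSE]
  }
  out <- do.call(cbind, outs) %*% params$W_o
  attr(out, "attention") <- attn
  out
}

#' Residual + layer-norm + feed-forward refinement
#'
#' `y = LayerNorm(Z_c + Z_attn)` followed by `y + FFN(y)` with
#' `FFN(x) = W_2 GELU(W_1 x + b_1) + b_2` (position-wise, 4d hidden). The
#' second residual preserves representational stability; zero-variance rows
#' are guarded by the layer-norm epsilon.
#'
#' @param Z_attn N x d attention output.
#' @param Z_c N x d residual source (the query view).
#' @param params list with `ln_gamma`, `ln_beta` (1 x d), `W1` (d x 4d),
#'   `b1` (1 x 4d), `W2` (4d x d), `b2` (1 x d).
#' @return N x d refined matrix.
#' @export
transformer_block <- function(Z_attn, Z_c, params) {
  y <- .layernorm_rows(Z_c + Z_attn, params$ln_gamma, params$ln_beta)
  ffn <- sweep(.gelu(sweep(y %*% params$W1, 2L, as.vector(params$b1), "+")) %*%
                 params$W2, 2L, as.vector(params$b2), "+")
  y + ffn
}

#' Gated fusion of branch outputs
#'
#' A lightweight two-layer MLP maps the concatenated branch outputs to one
#' logit per branch; per-cell softmax weights then form a convex
#' combination `Z_final = sum_k w_k * Z_fk`. The weights are returned for
#' interpretation.
#'
#' @param branches list of N x d branch matrices (2 or more).
#' @param gate list with `W1` (nb*d x h), `b1` (1 x h), `W2` (h x nb),
#'   `b2` (1 x nb).
#' @return N x d fused matrix; attribute `weights` is the N x nb gate
#'   weight matrix (rows on the probability simplex).
#' @export
gated_fusion <- function(branches, gate) {
  nb <- length(branches)
  if (nb < 2L) stop("gated fusion needs at least two branches")
  cc <- do.call(cbind, branches)
  h <- tanh(sweep(cc %*% gate$W1, 2L, as.vector(gate$b1), "+"))
  w <- .softmax_rows(sweep(h %*% gate$W2, 2L, as.vector(gate$b2), "+"))
  out <- Reduce(`+`, lapply(seq_len(nb),
                            function(k) branches[[k]] * w[, k]))
  attr(out, "weights") <- w
  out
}
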