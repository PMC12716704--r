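#' Model and pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Defaults follow
#' the method's standard settings: `k_neighbors = 5` nearest neighbors in
#' every cell-level graph, `k_genes = 30` genes retained per cell,
#' 32-dimensional shared latent space, 4 attention heads, temperature
#' `tau = 0.3`, margin `0.1` weighted by `lambda_margin = 0.1`, contrastive
#' and alignment loss weights `0.1`, and up to 120 training epochs with
#' early stopping.
#'
#' @param k_neighbors neighbors kept per cell when sparsifying view graphs.
#' @param k_genes genes selected per cell for the gene-level block graph.
#' @param latent_dim shared latent dimension (must be divisible by `heads`).
#' @param hidden_dim hidden width of the two-layer GCN encoders.
#' @param gene_embed_dim node2vec-style embedding dimension for gene nodes.
#' @param heads number of cross-attention heads.
#' @param tau InfoNCE temperature.
#' @param margin margin of the hinge contrastive term.
#' @param lambda_margin weight of the margin term inside the contrastive
#'   loss.
#' @param n_hard hard negatives per anchor.
#' @param w_contrast,w_align weights of the contrastive and center-alignment
#'   terms in the total loss (reconstruction has weight 1).
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience (consecutive epochs without a
#'   validation-loss improvement).
#' @param warmup epochs excluded from early-stopping monitoring; the
#'   validation loss passes through transient dips during initial
#'   convergence that would otherwise trip the patience counter.
#' @param learning_rate Adam learning rate.
#' @param bandwidth_rank neighbor rank m used for the adaptive spatial
#'   kernel bandwidth (distance to the m-th nearest neighbor).
#' @param alpha significance level of the ligand-receptor permutation test.
#' @param n_perm permutations for the ligand-receptor test.
#' @param pca_dim PCA dimension of the auxiliary similarity embedding.
#' @param r_min absolute-correlation threshold of the default per-cell
#'   gene-network estimator.
#' @param snf_K,snf_t neighbors and iterations of similarity network fusion.
#' @param n2v_walks,n2v_length,n2v_window,n2v_p,n2v_q random-walk
#'   hyperparameters of the gene-node embedding.
#' @param seed integer seed controlling all randomness.
#' @param use_attention,use_contrast,use_align ablation switches for the
#'   cell-gene attention module, the contrastive regularization, and the
#'   center-alignment loss.
#' @param views_enabled character subset of
#'   `c("spatial", "lr", "similarity", "gene")`; which input graphs the
#'   model consumes (the supervision target always fuses all three
#'   cell-level views).
#' @return An object of class `model_config`.
#' @export
model_config <- function(k_neighbors = 5L, k_genes = 30L, latent_dim = 32L,
                         hidden_dim = 128L, gene_embed_dim = 64L, heads = 4L,
                         tau = 0.3, margin = 0.1, lambda_margin = 0.1,
                         n_hard = 5L, w_contrast = 0.1, w_align = 0.1,
                         epochs = 120L, patience = 10L, warmup = 20L,
                         learning_rate = 1e-3,
                         bandwidth_rank = 1L, alpha = 0.05, n_perm = 100L,
                         pca_dim = 32L, r_min = 0.6, snf_K = 20L, snf_t = 20L,
                         n2v_walks = 10L, n2v_length = 20L, n2v_window = 5L,
                         n2v_p = 1, n2v_q = 1, seed = 1L,
                         use_attention = TRUE, use_contrast = TRUE,
                         use_align = TRUE,
                         views_enabled = c("spatial", "lr", "similarity",
                                           "gene")) {
  if (latent_dim %% heads != 0L) {
    stop("latent_dim (", latent_dim, ") must be divisible by heads (",
         heads, ")")
  }
  if (tau <= 0) stop("tau must be > 0")
  for (w in c(margin, lambda_margin, w_contrast, w_align)) {
    if (w < 0) stop("loss weights and margin must be >= 0")
  }
  views_enabled <- match.arg(views_enabled,
                             c("spatial", "lr", "similarity", "gene"),
                             several.ok = TRUE)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 k_genes = as.integer(k_genes),
                 latent_dim = as.integer(latent_dim),
                 hidden_dim = as.integer(hidden_dim),
                 gene_embed_dim = as.integer(gene_embed_dim),
                 heads = as.integer(heads), tau = tau, margin = margin,
                 lambda_margin = lambda_margin, n_hard = as.integer(n_hard),
                 w_contrast = w_contrast, w_align = w_align,
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 warmup = as.integer(warmup),
                 learning_rate = learning_rate,
                 bandwidth_rank = as.integer(bandwidth_rank), alpha = alpha,
                 n_perm = as.integer(n_perm), pca_dim = as.integer(pca_dim),
                 r_min = r_min, snf_K = as.integer(snf_K),
                 snf_t = as.integer(snf_t), n2v_walks = as.integer(n2v_walks),
                 n2v_length = as.integer(n2v_length),
                 n2v_window = as.integer(n2v_window), n2v_p = n2v_p,
                 n2v_q = n2v_q, seed = as.integer(seed),
                 use_attention = isTRUE(use_attention),
                 use_contrast = isTRUE(use_contrast),
                 use_align = isTRUE(use_align),
                 views_enabled = views_enabled),
            class = "model_config")
}
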