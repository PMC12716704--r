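# End-to-end model assembly: parameter initialization and the forward pass
# replayed on the autodiff tape. The numeric modules (encoders.R, fusion.R,
# alignment.R) define the same arithmetic; tests assert the two paths agree.

.cell_views <- function(cfg) {
  intersect(cfg$views_enabled, c("spatial", "lr", "similarity"))
}

.gene_enabled <- function(cfg) "gene" %in% cfg$views_enabled

.glorot <- function(nr, nc) {
  a <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

#' Initialize model parameters
#'
#' Glorot-uniform weights for every trainable matrix the enabled
#' architecture needs; layer-norm scales start at 1, all biases at 0.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [model_config()].
#' @param G number of genes (input feature dimension of the cell views).
#' @return Named list of parameter matrices.
#' @export
model_init <- function(cfg, G) {
  set.seed(cfg$seed)
  d <- cfg$latent_dim
  p <- list()
  views <- .cell_views(cfg)
  if (!length(views)) stop("at least one cell-level view must be enabled")
  for (v in views) {
    p[[paste0("enc_W0_", v)]] <- .glorot(G, cfg$hidden_dim)
    p[[paste0("enc_W1_", v)]] <- .glorot(cfg$hidden_dim, d)
  }
  gene_on <- .gene_enabled(cfg)
  if (gene_on) {
    p$enc_W0_gene <- .glorot(cfg$gene_embed_dim, cfg$hidden_dim)
    p$enc_W1_gene <- .glorot(cfg$hidden_dim, d)
    p$pool_W1 <- .glorot(d, 16L)
    p$pool_W2 <- .glorot(16L, 1L)
  }
  n_branch <- length(views)
  if (cfg$use_attention && gene_on) {
    for (v in views) {
      p[[paste0("att_Wq_", v)]] <- .glorot(d, d)
      p[[paste0("att_Wk_", v)]] <- .glorot(d, d)
      p[[paste0("att_Wv_", v)]] <- .glorot(d, d)
      p[[paste0("att_Wo_", v)]] <- .glorot(d, d)
      p[[paste0("ln_g_", v)]] <- matrix(1, 1L, d)
      p[[paste0("ln_b_", v)]] <- matrix(0, 1L, d)
      p[[paste0("ffn_W1_", v)]] <- .glorot(d, 4L * d)
      p[[paste0("ffn_b1_", v)]] <- matrix(0, 1L, 4L * d)
      p[[paste0("ffn_W2_", v)]] <- .glorot(4L * d, d)
      p[[paste0("ffn_b2_", v)]] <- matrix(0, 1L, d)
    }
  } else if (gene_on) {
    # no-attention ablation: mean of views concatenated with the pooled
    # gene embedding, through a linear map
    p$fb_W <- .glorot(2L * d, d)
    n_branch <- 0L
  }
  if (n_branch >= 2L) {
    p$gate_W1 <- .glorot(n_branch * d, 16L)
    p$gate_b1 <- matrix(0, 1L, 16L)
    p$gate_W2 <- .glorot(16L, n_branch)
    p$gate_b2 <- matrix(0, 1L, n_branch)
  }
  if (cfg$use_align) p$P_proj <- .glorot(G, d)
  p
}

#' Assemble model inputs from data and graphs
#'
#' Precomputes the constants of the forward pass: expression features
#' (library-size log1p, then per-gene z-scoring so every gene contributes
#' on a comparable scale — without it the cluster marker programs dominate
#' and the within-cluster variation that distinguishes neighboring cells is
#' numerically invisible to the encoders), symmetrically normalized
#' adjacencies for every enabled view, and the gene-node features/groups.
#' The center-alignment anchor uses the unscaled log1p mean profile, so it
#' remains the projected mean expression of the tissue.
#'
#' @param ds a [spatial_dataset()].
#' @param graphs named list of `view_graph`s (`spatial`, `lr`,
#'   `similarity`).
#' @param gene_graph a [gene_block_graph()] or NULL when the gene view is
#'   disabled.
#' @param cfg a [model_config()].
#' @return List of constants consumed by [model_forward()].
#' @export
prepare_model_inputs <- function(ds, graphs, gene_graph, cfg) {
  Xl <- normalize_expression(ds$expr, "library_size_log1p")
  Xc <- normalize_expression(Xl, "zscore_per_gene")
  views <- .cell_views(cfg)
  Ahat <- lapply(views, function(v) {
    if (is.null(graphs[[v]])) stop("view graph missing: ", v)
    gcn_normalize(graphs[[v]]$A)
  })
  names(Ahat) <- views
  out <- list(Xc = Xc, Ahat = Ahat, n = nrow(Xc), G = ncol(Xc),
              xbar = matrix(colMeans(Xl), 1L))
  if (.gene_enabled(cfg)) {
    if (is.null(gene_graph)) stop("gene view enabled but gene_graph is NULL")
    out$Ahat_g <- gcn_normalize(gene_graph$A_g)
    out$Xg <- gene_graph$X_g
    out$groups <- gene_graph$groups
  }
  out
}

# two-layer GCN on the tape: relu(Ahat (X W0)) then linear second layer
.ag_gcn <- function(tape, Ahat, X, W0, W1) {
  h <- ag_relu(tape, ag_mm(tape, Ahat, ag_mm(tape, X, W0)))
  ag_mm(tape, Ahat, ag_mm(tape, h, W1))
}

#' Forward pass on the autodiff tape
#'
#' Runs the full architecture for the enabled views and ablation switches:
#' view/gene GCN encoders, attention pooling of gene nodes, contrastive
#' regularization, cell-gene cross-attention with gated fusion (or its
#' documented fallbacks), edge-level reconstruction loss, and the
#' center-alignment loss.
#'
#' @param params named parameter list from [model_init()].
#' @param inputs constants from [prepare_model_inputs()].
#' @param cfg a [model_config()].
#' @param edges optional list `ei`, `ej`, `y` (training edge list with 0/1
#'   labels); when NULL, no reconstruction loss is computed and `total` is
#'   only the enabled regularizers (or NULL if none).
#' @return List with the tape, per-parameter node ids, the `total`,
#'   `recon`, `contrast`, `align` loss nodes (NULL where disabled), the
#'   `Z_final` node, the gate weight matrix (`gate_w`), and per-view
#'   attention matrices.
#' @export
model_forward <- function(params, inputs, cfg, edges = NULL) {
  tape <- ag_tape()
  pn <- lapply(params, function(x) ag_param(tape, x))
  views <- .cell_views(cfg)
  gene_on <- .gene_enabled(cfg)
  d <- cfg$latent_dim

  Zv <- lapply(views, function(v) {
    .ag_gcn(tape, inputs$Ahat[[v]], inputs$Xc,
            pn[[paste0("enc_W0_", v)]], pn[[paste0("enc_W1_", v)]])
  })
  names(Zv) <- views

  Zg_prime <- NULL
  if (gene_on) {
    Zg_nodes <- .ag_gcn(tape, inputs$Ahat_g, inputs$Xg,
                        pn$enc_W0_gene, pn$enc_W1_gene)
    s <- ag_mm(tape, ag_tanh(tape, ag_mm(tape, Zg_nodes, pn$pool_W1)),
               pn$pool_W2)
    beta <- ag_groupsoftmax(tape, s, inputs$groups)
    Zg_prime <- ag_grouppool(tape, Zg_nodes, beta, inputs$groups, inputs$n)
  }

  contrast <- NULL
  if (cfg$use_contrast && gene_on && length(views)) {
    terms <- list(); wts <- numeric(0)
    Zg_n <- ag_l2norm_rows(tape, Zg_prime)
    for (v in views) {
      Zv_n <- ag_l2norm_rows(tape, Zv[[v]])
      S <- ag_mmt(tape, Zv_n, Zg_n)            # cosine similarities
      St <- ag_transpose(tape, S)
      Stau <- ag_scale(tape, S, 1 / cfg$tau)
      Stau_t <- ag_scale(tape, St, 1 / cfg$tau)
      Hg <- .hard_neg_matrix(S$value, cfg$n_hard)
      Hv <- .hard_neg_matrix(t(S$value), cfg$n_hard)
      terms <- c(terms, list(ag_ce_diag(tape, Stau),
                             ag_ce_diag(tape, Stau_t),
                             ag_hinge_negs(tape, S, Hg, cfg$margin),
                             ag_hinge_negs(tape, St, Hv, cfg$margin)))
      wts <- c(wts, 0.5, 0.5, cfg$lambda_margin, cfg$lambda_margin)
    }
    contrast <- ag_wsum(tape, terms, wts)
  }

  gate_w <- NULL
  attention <- NULL
  if (cfg$use_attention && gene_on) {
    dk <- d %/% cfg$heads
    branches <- list()
    attention <- list()
    for (v in views) {
      Q <- ag_mm(tape, Zv[[v]], pn[[paste0("att_Wq_", v)]])
      K <- ag_mm(tape, Zg_prime, pn[[paste0("att_Wk_", v)]])
      V <- ag_mm(tape, Zg_prime, pn[[paste0("att_Wv_", v)]])
      heads <- list()
      att_v <- list()
      for (h in seq_len(cfg$heads)) {
        idx <- ((h - 1L) * dk + 1L):(h * dk)
        Sh <- ag_scale(tape, ag_mmt(tape, ag_cols(tape, Q, idx),
                                    ag_cols(tape, K, idx)), 1 / sqrt(dk))
        Ah <- ag_rowsoftmax(tape, Sh)
        att_v[[h]] <- Ah$value
        heads[[h]] <- ag_mm(tape, Ah, ag_cols(tape, V, idx))
      }
      attention[[v]] <- att_v
      O <- ag_mm(tape, ag_concat_cols(tape, heads),
                 pn[[paste0("att_Wo_", v)]])
      y <- ag_layernorm(tape, ag_add(tape, Zv[[v]], O),
                        pn[[paste0("ln_g_", v)]], pn[[paste0("ln_b_", v)]])
      ffn <- ag_addbias(tape,
                        ag_mm(tape,
                              ag_gelu(tape,
                                      ag_addbias(tape,
                                                 ag_mm(tape, y,
                                                       pn[[paste0("ffn_W1_", v)]]),
                                                 pn[[paste0("ffn_b1_", v)]])),
                              pn[[paste0("ffn_W2_", v)]]),
                        pn[[paste0("ffn_b2_", v)]])
      branches[[v]] <- ag_add(tape, y, ffn)
    }
    if (length(branches) >= 2L) {
      cc <- ag_concat_cols(tape, branches)
      hsz <- ag_tanh(tape, ag_addbias(tape, ag_mm(tape, cc, pn$gate_W1),
                                      pn$gate_b1))
      wmat <- ag_rowsoftmax(tape, ag_addbias(tape,
                                             ag_mm(tape, hsz, pn$gate_W2),
                                             pn$gate_b2))
      gate_w <- wmat$value
      parts <- lapply(seq_along(branches), function(k) {
        ag_rowscale(tape, branches[[k]], ag_cols(tape, wmat, k))
      })
      Z_final <- Reduce(function(a, b) ag_add(tape, a, b), parts)
    } else {
      Z_final <- branches[[1L]]
      gate_w <- matrix(1, inputs$n, 1L)
    }
  } else if (gene_on) {
    mean_views <- ag_scale(tape,
                           Reduce(function(a, b) ag_add(tape, a, b), Zv),
                           1 / length(Zv))
    Z_final <- ag_mm(tape, ag_concat_cols(tape, list(mean_views, Zg_prime)),
                     pn$fb_W)
  } else {
    if (length(Zv) >= 2L) {
      cc <- ag_concat_cols(tape, Zv)
      hsz <- ag_tanh(tape, ag_addbias(tape, ag_mm(tape, cc, pn$gate_W1),
                                      pn$gate_b1))
      wmat <- ag_rowsoftmax(tape, ag_addbias(tape,
                                             ag_mm(tape, hsz, pn$gate_W2),
                                             pn$gate_b2))
      gate_w <- wmat$value
      parts <- lapply(seq_along(Zv), function(k) {
        ag_rowscale(tape, Zv[[k]], ag_cols(tape, wmat, k))
      })
      Z_final <- Reduce(function(a, b) ag_add(tape, a, b), parts)
    } else {
      Z_final <- Zv[[1L]]
    }
  }

  recon <- NULL
  if (!is.null(edges)) {
    recon <- ag_bce_edges(tape, Z_final, edges$ei, edges$ej, edges$y)
  }
  align <- NULL
  if (cfg$use_align) {
    anchor <- ag_mm(tape, inputs$xbar, pn$P_proj)
    align <- ag_center_loss(tape, Z_final, anchor)
  }
  terms <- list(); wts <- numeric(0)
  if (!is.null(recon)) { terms <- c(terms, list(recon)); wts <- c(wts, 1) }
  if (!is.null(contrast)) {
    terms <- c(terms, list(contrast)); wts <- c(wts, cfg$w_contrast)
  }
  if (!is.null(align)) {
    terms <- c(terms, list(align)); wts <- c(wts, cfg$w_align)
  }
  total <- if (length(terms)) ag_wsum(tape, terms, wts) else NULL

  list(tape = tape, param_nodes = pn, total = total, recon = recon,
       contrast = contrast, align = align, Z_final = Z_final,
       gate_w = gate_w, attention = attention)
}

#' Final cell embeddings for a trained model
#'
#' @param params trained parameter list.
#' @param inputs constants from [prepare_model_inputs()].
#' @param cfg a [model_config()].
#' @return N x latent_dim embedding matrix.
#' @export
model_embed <- function(params, inputs, cfg) {
  model_forward(params, inputs, cfg)$Z_final$value
}

#' Inner-product edge decoder
#'
#' `A_hat[i, j] = sigmoid(z_i . z_j)`: exactly symmetric, entries in
#' (0, 1).
#'
#' @param Z_final N x d embedding matrix.
#' @return N x N probability matrix.
#' @export
decode_adjacency <- function(Z_final) {
  stats::plogis(tcrossprod(as.matrix(Z_final)))
}
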