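# Edge-level split protocol, reconstruction loss, training loop with early
# stopping, and link-prediction metrics.

#' Split target edges into train/validation/test with sampled negatives
#'
#' Enumerates the unique undirected positive edges (i < j) of the target
#' adjacency, holds out `round(r * E)` for testing and
#' `round(val_fraction * remainder)` for validation (R's round-half-to-even
#' rule), and samples one negative (non-edge, non-self) pair per positive,
#' uniformly without replacement and disjointly across partitions.
#'
#' @param target a `target_adjacency` (or sparse/dense binary symmetric
#'   matrix).
#' @param r held-out test fraction, in (0, 1).
#' @param val_fraction fraction of the non-test positives used for
#'   validation (default 0.05).
#' @param seed integer seed.
#' @return An object of class `edge_split`: lists `train_pos`, `val_pos`,
#'   `test_pos`, `train_neg`, `val_neg`, `test_neg` (two-column index
#'   matrices), plus `n`, `r`, `seed`.
#' @export
split_edges <- function(target, r, val_fraction = 0.05, seed = 1L) {
  A <- if (inherits(target, "target_adjacency")) target$A else target
  A <- as.matrix(A) != 0
  n <- nrow(A)
  if (r <= 0 || r >= 1) stop("r must be in (0, 1)")
  ut <- upper.tri(A)
  pos <- which(A & ut, arr.ind = TRUE)
  E <- nrow(pos)
  n_test <- round(r * E)
  n_val <- round(val_fraction * (E - n_test))
  n_train <- E - n_test - n_val
  if (n_train < 1L) stop("split leaves no training edges (E = ", E, ")")
  set.seed(seed)
  ord <- sample.int(E)
  idx_test <- ord[seq_len(n_test)]
  idx_val <- ord[n_test + seq_len(n_val)]
  idx_train <- ord[-seq_len(n_test + n_val)]
  neg_all <- which(!A & ut, arr.ind = TRUE)
  if (nrow(neg_all) < E) stop("not enough non-edges to sample negatives")
  neg <- neg_all[sample.int(nrow(neg_all), E), , drop = FALSE]
  two_col <- function(m) {
    m <- m[, 1:2, drop = FALSE]
    colnames(m) <- c("i", "j")
    m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  }
  structure(list(
    train_pos = two_col(pos[idx_train, , drop = FALSE]),
    val_pos = two_col(pos[idx_val, , drop = FALSE]),
    test_pos = two_col(pos[idx_test, , drop = FALSE]),
    train_neg = two_col(neg[seq_len(n_train), , drop = FALSE]),
    val_neg = two_col(neg[n_train + seq_len(n_val), , drop = FALSE]),
    test_neg = two_col(neg[n_train + n_val + seq_len(n_test), ,
                           drop = FALSE]),
    n = n, r = r, seed = as.integer(seed)), class = "edge_split")
}

#' @export
print.edge_split <- function(x, ...) {
  cat("edge_split: ", nrow(x$train_pos), " train / ", nrow(x$val_pos),
      " val / ", nrow(x$test_pos), " test positives (r = ", x$r, ")\n",
      sep = "")
  invisible(x)
}

#' Binary cross-entropy reconstruction loss
#'
#' With `edges = NULL`, the exact full-matrix form: mean BCE between the
#' decoded adjacency and the target over all N^2 entries. With an edge
#' list, the mean BCE over those pairs only (the sampled-edge training
#' mode). Probabilities are clipped to `[eps, 1 - eps]`.
#'
#' @param Z_final N x d embeddings.
#' @param target target adjacency (any binary matrix form) — used for
#'   labels in full-matrix mode.
#' @param edges optional list with `ei`, `ej`, `y`.
#' @param eps clipping constant (default 1e-7).
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(Z_final, target, edges = NULL, eps = 1e-7) {
  A_hat <- decode_adjacency(Z_final)
  A_hat <- pmin(pmax(A_hat, eps), 1 - eps)
  if (is.null(edges)) {
    A <- if (inherits(target, "target_adjacency")) target$A else target
    A <- as.matrix(A) != 0
    -mean(A * log(A_hat) + (1 - A) * log(1 - A_hat))
  } else {
    if (!length(edges$ei)) stop("empty edge set")
    p <- A_hat[cbind(edges$ei, edges$ej)]
    -mean(edges$y * log(p) + (1 - edges$y) * log(1 - p))
  }
}

#' Weighted total training objective
#'
#' `L_total = w1 * L_recon + w2 * L_contrast + w3 * L_align`, default
#' weights (1, 0.1, 0.1).
#'
#' @param recon,contrast,align loss components (use 0 for a disabled
#'   term).
#' @param weights length-3 nonnegative weight vector.
#' @return Scalar.
#' @export
total_loss <- function(recon, contrast = 0, align = 0,
                       weights = c(1, 0.1, 0.1)) {
  sum(weights * c(recon, contrast, align))
}

# ---- metrics ----

# step-interpolated average precision; tied scores form one threshold block
.ap_step <- function(y, s) {
  o <- order(-s)
  y <- y[o]; ss <- s[o]
  tp <- cumsum(y)
  ends <- which(!duplicated(ss, fromLast = TRUE))  # last index per block
  prec <- tp[ends] / ends
  rec <- tp[ends] / sum(y)
  sum((rec - c(0, rec[-length(rec)])) * prec)
}

.auroc_mw <- function(y, s) {
  r <- rank(s)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.auprc_trapezoid <- function(y, s) {
  o <- order(-s)
  y <- y[o]; ss <- s[o]
  tp <- cumsum(y)
  ends <- which(!duplicated(ss, fromLast = TRUE))
  prec <- c(1, tp[ends] / ends)
  rec <- c(0, tp[ends] / sum(y))
  sum(diff(rec) * (prec[-1] + prec[-length(prec)]) / 2)
}

#' Link-prediction metrics on the held-out test edges
#'
#' Scores every test positive and negative pair with the decoded edge
#' probability and reports average precision (step-interpolated
#' precision-recall sum), AUROC (Mann-Whitney rank form), AUPRC
#' (trapezoidal), and thresholded F1 / precision / recall.
#'
#' @param x either an N x d embedding matrix or an N x N decoded
#'   probability matrix.
#' @param split an [split_edges()] result.
#' @param threshold classification threshold (default 0.5).
#' @param partition which partition to score (default `"test"`).
#' @return An object of class `metrics_report`: named list with `ap`,
#'   `auroc`, `auprc`, `f1`, `precision`, `recall`, `n_pos`, `n_neg`.
#' @export
evaluate_reconstruction <- function(x, split, threshold = 0.5,
                                    partition = c("test", "val", "train")) {
  partition <- match.arg(partition)
  pos <- split[[paste0(partition, "_pos")]]
  neg <- split[[paste0(partition, "_neg")]]
  if (!nrow(pos) || !nrow(neg)) {
    stop("partition '", partition, "' has a single class; cannot score")
  }
  x <- as.matrix(x)
  A_hat <- if (nrow(x) == ncol(x) && nrow(x) == split$n) x
           else decode_adjacency(x)
  s <- c(A_hat[pos], A_hat[neg])
  y <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
  pred <- as.integer(s >= threshold)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(ap = .ap_step(y, s), auroc = .auroc_mw(y, s),
                 auprc = .auprc_trapezoid(y, s), f1 = f1,
                 precision = precision, recall = recall,
                 n_pos = nrow(pos), n_neg = nrow(neg)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("AP %.3f | AUROC %.3f | AUPRC %.3f | F1 %.3f (P %.3f, R %.3f)\n",
              x$ap, x$auroc, x$auprc, x$f1, x$precision, x$recall))
  invisible(x)
}

#' Train the multi-view graph autoencoder
#'
#' Full-batch Adam on the weighted total loss over the training edge set
#' (train positives plus their sampled negatives). The validation BCE loss
#' is monitored each epoch and controls the training duration: training
#' halts once it has failed to improve for `cfg$patience` consecutive
#' epochs. Validation AP is also recorded per epoch in the history. The
#' parameters returned are those of the last epoch trained — on validation
#' sets of a few dozen pairs the per-epoch AP is far too quantized to rank
#' epochs (its quantum is several percent), which is also why the continuous
#' loss, not the AP, drives the stopping rule. Deterministic given
#' `cfg$seed`. Test edges never enter the loss.
#'
#' @param ds a [spatial_dataset()].
#' @param graphs named list of `view_graph`s.
#' @param gene_graph a [gene_block_graph()] (or NULL if the gene view is
#'   disabled).
#' @param target a `target_adjacency`.
#' @param cfg a [model_config()].
#' @param split an [split_edges()] result.
#' @return An object of class `trained_model`: `params` (best epoch),
#'   `history` (per-epoch data frame of losses and validation AP),
#'   `best_epoch`, `cfg`, `inputs`.
#' @export
train_model <- function(ds, graphs, gene_graph, target, cfg, split) {
  inputs <- prepare_model_inputs(ds, graphs, gene_graph, cfg)
  params <- model_init(cfg, inputs$G)
  opt <- adam_state(params)
  edges <- list(ei = c(split$train_pos[, 1L], split$train_neg[, 1L]),
                ej = c(split$train_pos[, 2L], split$train_neg[, 2L]),
                y = c(rep(1, nrow(split$train_pos)),
                      rep(0, nrow(split$train_neg))))
  val_i <- c(split$val_pos[, 1L], split$val_neg[, 1L])
  val_j <- c(split$val_pos[, 2L], split$val_neg[, 2L])
  val_y <- c(rep(1, nrow(split$val_pos)), rep(0, nrow(split$val_neg)))
  has_val <- length(val_y) > 0 && length(unique(val_y)) == 2L
  best_loss <- Inf; wait <- 0L
  hist <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    fw <- model_forward(params, inputs, cfg, edges)
    tot <- as.numeric(fw$total$value)
    if (!is.finite(tot)) {
      stop("training diverged at epoch ", epoch, " (loss = ", tot, ")")
    }
    Z <- fw$Z_final$value
    val_ap <- NA_real_; val_loss <- NA_real_
    if (has_val) {
      lg <- rowSums(Z[val_i, , drop = FALSE] * Z[val_j, , drop = FALSE])
      sc <- stats::plogis(lg)
      val_ap <- .ap_step(val_y, sc)
      val_loss <- mean(pmax(lg, 0) - val_y * lg + log1p(exp(-abs(lg))))
    }
    hist[[epoch]] <- data.frame(
      epoch = epoch, total = tot,
      recon = if (is.null(fw$recon)) NA_real_ else as.numeric(fw$recon$value),
      contrast = if (is.null(fw$contrast)) NA_real_
                 else as.numeric(fw$contrast$value),
      align = if (is.null(fw$align)) NA_real_ else as.numeric(fw$align$value),
      val_loss = val_loss, val_ap = val_ap)
    if (has_val && epoch > cfg$warmup) {
      if (val_loss < best_loss) {
        best_loss <- val_loss; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) {
          hist <- hist[seq_len(epoch)]
          break
        }
      }
    }
    if (epoch == cfg$epochs) break  # returned params match the last row
    grads_all <- ag_backward(fw$tape, fw$total)
    grads <- lapply(fw$param_nodes, function(nd) grads_all[[nd$id]])
    up <- adam_step(opt, params, grads, lr = cfg$learning_rate)
    opt <- up$state; params <- up$params
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  structure(list(params = params, history = history,
                 best_epoch = nrow(history), cfg = cfg, inputs = inputs),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat("trained_model:", nrow(x$history), "epochs (best at",
      x$best_epoch, ")\n")
  invisible(x)
}

#' Repeat the split/train/evaluate pipeline over seeds
#'
#' Graph construction is deterministic given the data, so the graphs and
#' target are built once; each seed then draws its own edge split and
#' parameter initialization, and the per-seed test metrics are aggregated
#' as mean and standard deviation.
#'
#' @param ds a [spatial_dataset()].
#' @param db an [lr_db()].
#' @param cfg a [model_config()].
#' @param seeds integer vector of seeds (>= 2 for a standard deviation).
#' @param r held-out test fraction.
#' @param graphs,gene_graph,target optional prebuilt objects (rebuilt from
#'   `ds`/`db` when NULL).
#' @return List with `per_seed` (data frame of per-seed metrics) and
#'   `summary` (mean and sd per metric).
#' @export
run_replicates <- function(ds, db, cfg = model_config(), seeds = 1:5,
                           r = 0.3, graphs = NULL, gene_graph = NULL,
                           target = NULL) {
  if (is.null(graphs)) {
    graphs <- list(spatial = build_spatial_graph(ds, cfg),
                   lr = build_lr_graph(ds, db, cfg),
                   similarity = build_similarity_graph(ds, cfg))
  }
  if (is.null(gene_graph) && .gene_enabled(cfg)) {
    gene_graph <- build_gene_graph(ds, db, cfg)
  }
  if (is.null(target)) target <- build_target(graphs, cfg)
  rows <- lapply(seeds, function(s) {
    cfg_s <- cfg
    cfg_s$seed <- as.integer(s)
    split <- split_edges(target, r = r, seed = s)
    fit <- train_model(ds, graphs, gene_graph, target, cfg_s, split)
    Z <- model_embed(fit$params, fit$inputs, cfg_s)
    m <- evaluate_reconstruction(Z, split)
    data.frame(seed = s, ap = m$ap, auroc = m$auroc, auprc = m$auprc,
               f1 = m$f1, precision = m$precision, recall = m$recall)
  })
  per_seed <- do.call(rbind, rows)
  met <- c("ap", "auroc", "auprc", "f1", "precision", "recall")
  summary <- data.frame(
    metric = met,
    mean = vapply(met, function(m) mean(per_seed[[m]]), 0),
    sd = vapply(met, function(m) stats::sd(per_seed[[m]]), 0))
  list(per_seed = per_seed, summary = summary)
}
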