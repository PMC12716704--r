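test_that("inner-product decoder is exactly symmetric with closed-form entries", {
  # orthogonal rows: sigmoid(0) = 0.5 off-diagonal
  Z <- diag(4)
  A <- decode_adjacency(Z)
  expect_equal(A[upper.tri(A)], rep(0.5, 6))
  # ||z||^2 = ln 3 on equal rows: sigmoid(ln 3) = 0.75
  z <- sqrt(log(3) / 2)
  A2 <- decode_adjacency(rbind(c(z, z), c(z, z)))
  expect_equal(A2[1, 2], 0.75, tolerance = 1e-12)

  set.seed(71)
  Zr <- matrix(rnorm(4 * 32, sd = 0.4), 4, 32)
  Ar <- decode_adjacency(Zr)
  expect_equal(max(abs(Ar - t(Ar))), 0)
  expect_equal(Ar, 1 / (1 + exp(-Zr %*% t(Zr))), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_true(all(Ar > 0 & Ar < 1))
})

test_that("reconstruction loss matches hand-summed BCE in both modes", {
  set.seed(72)
  Z <- matrix(rnorm(5 * 3, sd = 0.7), 5, 3)
  A <- matrix(0, 5, 5)
  A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1
  # full-matrix mode: mean over all 25 entries
  P <- pmin(pmax(decode_adjacency(Z), 1e-7), 1 - 1e-7)
  want <- -mean(A * log(P) + (1 - A) * log(1 - P))
  expect_equal(reconstruction_loss(Z, A), want, tolerance = 1e-12)

  # edge-list mode: 5 hand-picked edges
  edges <- list(ei = c(1L, 2L, 3L, 1L, 4L), ej = c(2L, 3L, 4L, 5L, 5L),
                y = c(1, 0, 1, 0, 0))
  ww <- -mean(edges$y * log(P[cbind(edges$ei, edges$ej)]) +
                (1 - edges$y) * log(1 - P[cbind(edges$ei, edges$ej)]))
  expect_equal(reconstruction_loss(Z, A, edges), ww, tolerance = 1e-12)
  expect_error(reconstruction_loss(Z, A, list(ei = integer(0),
                                              ej = integer(0), y = numeric(0))),
               "empty")
  # constant 0.5 predictions: ln 2 for any labels
  expect_equal(reconstruction_loss(matrix(0, 5, 3), A), log(2),
               tolerance = 1e-6)
})

test_that("total loss applies the (1, 0.1, 0.1) weighting", {
  expect_equal(total_loss(1, 2, 3), 1 + 0.2 + 0.3)
  expect_equal(total_loss(1.5, 0, 0), 1.5)
  expect_equal(total_loss(1, 2, 3, weights = c(1, 0, 0)), 1)
})

test_that("edge splits have the stated sizes and disjointness invariants", {
  # E = 100 -> 30 test, round(0.05 * 70) = 4 val (round-half-to-even), 66 train
  set.seed(73)
  n <- 40L
  A <- matrix(0, n, n)
  pairs <- which(upper.tri(A), arr.ind = TRUE)
  sel <- pairs[sample.int(nrow(pairs), 100L), ]
  A[sel] <- 1
  A <- pmax(A, t(A))
  sp <- split_edges(A, r = 0.3, val_fraction = 0.05, seed = 9L)
  expect_equal(nrow(sp$test_pos), 30L)
  expect_equal(nrow(sp$val_pos), 4L)
  expect_equal(nrow(sp$train_pos), 66L)
  expect_equal(nrow(sp$test_neg), 30L)

  key <- function(m) paste(m[, 1], m[, 2])
  all_pos <- c(key(sp$train_pos), key(sp$val_pos), key(sp$test_pos))
  expect_equal(anyDuplicated(all_pos), 0L)
  all_neg <- c(key(sp$train_neg), key(sp$val_neg), key(sp$test_neg))
  expect_equal(anyDuplicated(all_neg), 0L)
  expect_length(intersect(all_neg, key(which(A == 1, arr.ind = TRUE))), 0L)
  # same seed reproduces the split exactly
  sp2 <- split_edges(A, r = 0.3, val_fraction = 0.05, seed = 9L)
  expect_identical(sp, sp2)
  expect_error(split_edges(A, r = 0.999), "training")
})

test_that("metrics match closed forms and a hand-built PR curve", {
  # perfectly separated scores
  sp <- list(test_pos = cbind(i = c(1L, 1L), j = c(2L, 3L)),
             test_neg = cbind(i = c(2L, 3L), j = c(3L, 4L)), n = 4L)
  class(sp) <- "edge_split"
  A_hat <- matrix(0.1, 4, 4)
  A_hat[1, 2] <- A_hat[2, 1] <- 0.9
  A_hat[1, 3] <- A_hat[3, 1] <- 0.8
  m <- evaluate_reconstruction(A_hat, sp)
  expect_equal(m$ap, 1)
  expect_equal(m$auroc, 1)
  expect_equal(m$f1, 1)

  # constant scores on balanced labels: one tied block, AP = prevalence
  mc <- evaluate_reconstruction(matrix(0.5, 4, 4), sp)
  expect_equal(mc$auroc, 0.5)
  expect_equal(mc$ap, 0.5)

  # 6 hand-scored edges: AP equals the manual precision-recall sum
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  labels <- c(1, 0, 1, 1, 0, 0)
  # precision at each positive rank: 1/1, 2/3, 3/4
  want_ap <- mean(c(1 / 1, 2 / 3, 3 / 4))
  expect_equal(ccinet:::.ap_step(labels, scores), want_ap,
               tolerance = 1e-12)
  # AUROC by explicit pair counting
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  want_auc <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_equal(ccinet:::.auroc_mw(labels, scores), want_auc,
               tolerance = 1e-12)
})

test_that("short training improves test AP over the untrained model and stops properly", {
  sim <- fixture_sim()
  ds <- sim$dataset
  db <- make_toy_lr_db(simulation_spec())
  cfg <- model_config(epochs = 25L, n_perm = 49L, patience = 25L)
  graphs <- list(spatial = build_spatial_graph(ds, cfg),
                 lr = build_lr_graph(ds, db, cfg),
                 similarity = build_similarity_graph(ds, cfg))
  gg <- build_gene_graph(ds, db, cfg)
  tgt <- build_target(graphs, cfg)
  split <- split_edges(tgt, r = 0.3, seed = 7L)

  inputs <- prepare_model_inputs(ds, graphs, gg, cfg)
  Z0 <- model_embed(model_init(cfg, inputs$G), inputs, cfg)
  ap0 <- evaluate_reconstruction(Z0, split)$ap

  fit <- train_model(ds, graphs, gg, tgt, cfg, split)
  expect_lte(nrow(fit$history), 25L)
  Z1 <- model_embed(fit$params, fit$inputs, cfg)
  ap1 <- evaluate_reconstruction(Z1, split)$ap
  expect_gt(ap1, ap0)

  # determinism: identical config and seed reproduce the history exactly
  fit2 <- train_model(ds, graphs, gg, tgt, cfg, split)
  expect_identical(fit$history, fit2$history)

  # test edges never influence training: shuffling the test partition's
  # labels leaves the trajectory identical
  split_shuf <- split
  tmp <- split_shuf$test_pos
  split_shuf$test_pos <- split_shuf$test_neg
  split_shuf$test_neg <- tmp
  fit3 <- train_model(ds, graphs, gg, tgt, cfg, split_shuf)
  expect_identical(fit$history[, c("total", "recon", "contrast", "align")],
                   fit3$history[, c("total", "recon", "contrast", "align")])
})

test_that("replicate aggregation equals an external mean/sd", {
  sim <- fixture_sim()
  ds <- sim$dataset
  db <- make_toy_lr_db(simulation_spec())
  cfg <- model_config(epochs = 8L, n_perm = 49L)
  res <- run_replicates(ds, db, cfg, seeds = c(1L, 2L), r = 0.3)
  expect_equal(nrow(res$per_seed), 2L)
  expect_equal(res$summary$mean[res$summary$metric == "ap"],
               mean(res$per_seed$ap), tolerance = 1e-12)
  expect_equal(res$summary$sd[res$summary$metric == "ap"],
               stats::sd(res$per_seed$ap), tolerance = 1e-12)
  expect_true(all(res$per_seed$ap >= 0 & res$per_seed$ap <= 1))
})
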