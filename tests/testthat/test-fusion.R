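test_that("cross-attention rows are simplices and match a hand-computed 2x2 case", {
  set.seed(61)
  d <- 8L; n <- 5L
  params <- list(W_q = matrix(rnorm(d * d, sd = 0.3), d, d),
                 W_k = matrix(rnorm(d * d, sd = 0.3), d, d),
                 W_v = matrix(rnorm(d * d, sd = 0.3), d, d),
                 W_o = matrix(rnorm(d * d, sd = 0.3), d, d))
  Zc <- matrix(rnorm(n * d), n, d); Zg <- matrix(rnorm(n * d), n, d)
  out <- cross_attention_branch(Zc, Zg, params, H = 2L)
  for (A in attr(out, "attention")) {
    expect_equal(rowSums(A), rep(1, n), tolerance = 1e-12)
    expect_true(all(A > 0))
  }
  # all gene rows identical: output constant across query cells
  Zg1 <- matrix(rep(rnorm(d), each = n), n, d)
  outc <- cross_attention_branch(Zc, Zg1, params, H = 2L)
  expect_lt(max(abs(sweep(outc, 2, outc[1, ]))), 1e-12)

  # N = 2, H = 1, identity projections: plain 2x2 softmax attention
  Zc2 <- rbind(c(1, 0), c(0, 1)); Zg2 <- rbind(c(2, 0), c(0, 1))
  id <- list(W_q = diag(2), W_k = diag(2), W_v = diag(2), W_o = diag(2))
  got <- cross_attention_branch(Zc2, Zg2, id, H = 1L)
  S <- Zc2 %*% t(Zg2) / sqrt(2)
  A <- exp(S) / rowSums(exp(S))
  expect_equal(got, A %*% Zg2, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("transformer block equals a step-by-step oracle", {
  set.seed(62)
  d <- 8L
  params <- list(ln_gamma = matrix(runif(d, 0.5, 1.5), 1, d),
                 ln_beta = matrix(rnorm(d, sd = 0.1), 1, d),
                 W1 = matrix(rnorm(d * 4 * d, sd = 0.2), d, 4 * d),
                 b1 = matrix(rnorm(4 * d, sd = 0.1), 1, 4 * d),
                 W2 = matrix(rnorm(4 * d * d, sd = 0.2), 4 * d, d),
                 b2 = matrix(rnorm(d, sd = 0.1), 1, d))
  Zc <- matrix(rnorm(2 * d), 2, d); Za <- matrix(rnorm(2 * d), 2, d)
  got <- transformer_block(Za, Zc, params)
  x <- Zc + Za
  mu <- rowMeans(x); v <- rowMeans((x - mu)^2)
  y <- sweep(sweep((x - mu) / sqrt(v + 1e-5), 2,
                   as.vector(params$ln_gamma), "*"),
             2, as.vector(params$ln_beta), "+")
  h <- sweep(y %*% params$W1, 2, as.vector(params$b1), "+")
  h <- h * pnorm(h)
  want <- y + sweep(h %*% params$W2, 2, as.vector(params$b2), "+")
  expect_lt(max(abs(got - want)), 1e-6)

  # zero FFN weights: block reduces to the layer norm
  p0 <- params
  p0$W1[] <- 0; p0$W2[] <- 0; p0$b1[] <- 0; p0$b2[] <- 0
  expect_equal(transformer_block(Za, Zc, p0), y, tolerance = 1e-12,
               ignore_attr = TRUE)
  # zero-variance rows stay finite through the epsilon guard
  const <- matrix(3, 2, d)
  expect_true(all(is.finite(transformer_block(const, const * 0, params))))
})

test_that("gated fusion weights live on the simplex and mix convexly", {
  set.seed(63)
  d <- 6L; n <- 4L
  gate <- list(W1 = matrix(rnorm(3 * d * 5, sd = 0.3), 3 * d, 5),
               b1 = matrix(0, 1, 5),
               W2 = matrix(rnorm(5 * 3, sd = 0.3), 5, 3),
               b2 = matrix(0, 1, 3))
  Zs <- lapply(1:3, function(i) matrix(rnorm(n * d), n, d))
  out <- gated_fusion(Zs, gate)
  w <- attr(out, "weights")
  expect_equal(rowSums(w), rep(1, n), tolerance = 1e-12)
  expect_true(all(w > 0))

  # identical branches: convexity returns them unchanged
  same <- gated_fusion(list(Zs[[1]], Zs[[1]], Zs[[1]]), gate)
  expect_equal(same, Zs[[1]], ignore_attr = TRUE, tolerance = 1e-12)

  # zero gate: logits equal -> arithmetic mean of branches
  gate0 <- list(W1 = matrix(0, 3 * d, 5), b1 = matrix(0, 1, 5),
                W2 = matrix(0, 5, 3), b2 = matrix(0, 1, 3))
  mix <- gated_fusion(Zs, gate0)
  expect_equal(mix, (Zs[[1]] + Zs[[2]] + Zs[[3]]) / 3, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(attr(mix, "weights")[1, ], rep(1 / 3, 3), tolerance = 1e-12)

  # fixed logits (ln 2, 0, 0) on one cell: weights (0.5, 0.25, 0.25)
  gate_fix <- list(W1 = matrix(0, 3 * d, 5), b1 = matrix(0, 1, 5),
                   W2 = matrix(0, 5, 3),
                   b2 = matrix(c(log(2), 0, 0), 1, 3))
  one <- lapply(1:3, function(i) matrix(rnorm(d), 1, d))
  got <- gated_fusion(one, gate_fix)
  expect_equal(attr(got, "weights")[1, ], c(0.5, 0.25, 0.25),
               tolerance = 1e-12)
  expect_equal(got, 0.5 * one[[1]] + 0.25 * one[[2]] + 0.25 * one[[3]],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("the tape forward reproduces the numeric fusion modules", {
  # one full forward pass: tape values equal the numeric implementations
  ds <- tiny_dataset()
  db <- lr_db(ds$gene_names[1], ds$gene_names[5])
  cfg <- model_config(k_neighbors = 3L, k_genes = 4L, n_perm = 19L,
                      heads = 4L, seed = 2L)
  graphs <- list(spatial = build_spatial_graph(ds, cfg),
                 lr = build_spatial_graph(ds, cfg),
                 similarity = build_similarity_graph(ds, cfg))
  graphs$lr$view <- "lr"
  gg <- build_gene_graph(ds, db, cfg)
  inputs <- prepare_model_inputs(ds, graphs, gg, cfg)
  params <- model_init(cfg, inputs$G)
  fw <- model_forward(params, inputs, cfg)

  # numeric recomputation of one branch
  Zd <- gcn_encode(graphs$spatial, inputs$Xc,
                   list(W0 = params$enc_W0_spatial,
                        W1 = params$enc_W1_spatial))
  Zg_nodes <- gcn_encode(gg, inputs$Xg,
                         list(W0 = params$enc_W0_gene,
                              W1 = params$enc_W1_gene))
  Zg_p <- attention_pool(Zg_nodes, list(W1 = params$pool_W1,
                                        W2 = params$pool_W2),
                         groups = inputs$groups)
  att <- cross_attention_branch(Zd, Zg_p,
                                list(W_q = params$att_Wq_spatial,
                                     W_k = params$att_Wk_spatial,
                                     W_v = params$att_Wv_spatial,
                                     W_o = params$att_Wo_spatial),
                                H = cfg$heads)
  branch <- transformer_block(att, Zd,
                              list(ln_gamma = params$ln_g_spatial,
                                   ln_beta = params$ln_b_spatial,
                                   W1 = params$ffn_W1_spatial,
                                   b1 = params$ffn_b1_spatial,
                                   W2 = params$ffn_W2_spatial,
                                   b2 = params$ffn_b2_spatial))
  # gate weights from the tape are a simplex, and Z_final is their mix
  expect_equal(rowSums(fw$gate_w), rep(1, 10), tolerance = 1e-10)
  # the spatial branch value inside the tape equals the numeric one:
  # reconstruct Z_final from numeric branches and tape gate weights
  branches <- list()
  for (v in c("spatial", "lr", "similarity")) {
    Zv <- gcn_encode(graphs[[v]], inputs$Xc,
                     list(W0 = params[[paste0("enc_W0_", v)]],
                          W1 = params[[paste0("enc_W1_", v)]]))
    attv <- cross_attention_branch(Zv, Zg_p,
                                   list(W_q = params[[paste0("att_Wq_", v)]],
                                        W_k = params[[paste0("att_Wk_", v)]],
                                        W_v = params[[paste0("att_Wv_", v)]],
                                        W_o = params[[paste0("att_Wo_", v)]]),
                                   H = cfg$heads)
    branches[[v]] <- transformer_block(
      attv, Zv, list(ln_gamma = params[[paste0("ln_g_", v)]],
                     ln_beta = params[[paste0("ln_b_", v)]],
                     W1 = params[[paste0("ffn_W1_", v)]],
                     b1 = params[[paste0("ffn_b1_", v)]],
                     W2 = params[[paste0("ffn_W2_", v)]],
                     b2 = params[[paste0("ffn_b2_", v)]]))
  }
  want <- Reduce(`+`, lapply(1:3, function(k) {
    branches[[k]] * fw$gate_w[, k]
  }))
  expect_lt(max(abs(fw$Z_final$value - want)), 1e-8)
})
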