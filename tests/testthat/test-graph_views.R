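# View-graph construction against brute-force oracles.

test_that("adaptive spatial kernel matches the closed form and a double loop", {
  # two cells at distance d: sigma_1 = sigma_2 = d -> W = exp(-1/2)
  W2 <- spatial_kernel(rbind(c(0, 0), c(3, 0)))
  expect_equal(W2[1, 2], exp(-0.5))
  expect_equal(W2[2, 1], exp(-0.5))
  expect_equal(diag(W2), c(0, 0), ignore_attr = TRUE)

  # coincident cells: eps-guarded bandwidth, d = 0 -> W = exp(0) = 1
  Wc <- spatial_kernel(rbind(c(1, 1), c(1, 1)))
  expect_equal(Wc[1, 2], 1)

  # random instance vs an independent double loop with per-row bandwidth
  set.seed(21)
  xy <- matrix(runif(12, 0, 5), 6, 2)
  W <- spatial_kernel(xy, m = 1)
  for (i in 1:6) {
    di <- sqrt(colSums((t(xy) - xy[i, ])^2))
    sig <- min(di[-i])
    for (j in 1:6) {
      want <- if (i == j) 0 else exp(-di[j]^2 / (2 * sig^2))
      expect_equal(W[i, j], want, tolerance = 1e-12)
    }
  }
  expect_error(spatial_kernel(matrix(0, 1, 2)), "at least 2")
})

test_that("top-k sparsification equals a sort-based oracle with index ties", {
  w <- matrix(0, 1, 3)
  w[1, ] <- c(0.9, 0.1, 0.5)
  # single row embedded in a 3x3: keep only the strongest entry
  W <- rbind(c(0, 0.9, 0.5), c(0.9, 0, 0.1), c(0.5, 0.1, 0))
  A1 <- as.matrix(topk_sparsify(W, 1))
  expect_equal(A1[1, ], c(0, 1, 0))

  # k >= N - 1 with all-positive weights: complete digraph minus loops
  Wp <- matrix(runif(16) + 0.1, 4, 4)
  Ak <- as.matrix(topk_sparsify(Wp, 5))
  expect_equal(Ak, 1 - diag(4), ignore_attr = TRUE)

  set.seed(22)
  W8 <- matrix(runif(64), 8, 8) * matrix(rbinom(64, 1, 0.7), 8, 8)
  A <- as.matrix(topk_sparsify(W8, 3))
  for (i in 1:8) {
    w <- W8[i, ]; w[i] <- 0
    pos <- which(w > 0)
    keep <- pos[order(-w[pos], pos)][seq_len(min(3, length(pos)))]
    want <- rep(0, 8); want[keep] <- 1
    expect_equal(A[i, ], want, ignore_attr = TRUE)
  }
  expect_equal(diag(A), rep(0, 8), ignore_attr = TRUE)
  expect_true(all(Matrix::rowSums(topk_sparsify(W8, 3)) <= 3))
})

test_that("spatial view graph respects k and handles collinear toys", {
  ds2 <- spatial_dataset(matrix(1:4, 2, 2), rbind(c(0, 0), c(1, 0)))
  g2 <- build_spatial_graph(ds2)
  expect_equal(as.matrix(g2$A), rbind(c(0, 1), c(1, 0)), ignore_attr = TRUE)

  # 3 collinear cells at x = 0, 1, 3: middle keeps both neighbors
  ds3 <- spatial_dataset(matrix(1:6, 3, 2), cbind(c(0, 1, 3), 0))
  g3 <- build_spatial_graph(ds3)
  expect_equal(as.matrix(g3$A)[2, ], c(1, 0, 1), ignore_attr = TRUE)
  W <- g3$W
  expect_gt(W[1, 2], W[1, 3])  # endpoint ranks near neighbor first
  expect_gt(W[3, 2], W[3, 1])
  expect_equal(model_config()$k_neighbors, 5L)
})

test_that("LR pair scores match a brute-force triple loop", {
  ds <- tiny_dataset()
  en <- normalize_expression(ds$expr, "minmax_per_gene")
  sg <- ccinet:::mean_nn_distance(ds$coords)
  S <- lr_pair_score(en, ds$coords, c(1L, 5L), sg)
  d <- as.matrix(dist(ds$coords))
  for (i in 1:4) for (j in 1:10) {
    want <- if (i == j) 0 else
      en[i, 1] * en[j, 5] * exp(-d[i, j]^2 / (2 * sg^2))
    expect_equal(S[i, j], want, tolerance = 1e-12)
  }
  # zero ligand in a cell zeroes its outgoing row
  en0 <- en; en0[3, 1] <- 0
  expect_equal(max(abs(lr_pair_score(en0, ds$coords, c(1L, 5L), sg)[3, ])), 0)
})

test_that("permutation p-value follows the add-one convention and converges to the exhaustive null", {
  ds <- tiny_dataset()
  en <- normalize_expression(ds$expr, "minmax_per_gene")
  # observed above every permuted value: p = 1 / (1 + n_perm)
  huge <- 1e9
  p <- permutation_pvalue(huge, en, ds$coords, c(1L, 5L), n_perm = 99L)
  expect_equal(p, 0.01)
  # observed 0: all null scores >= 0 -> p = 1
  p0 <- permutation_pvalue(0, en, ds$coords, c(1L, 5L), n_perm = 49L)
  expect_equal(p0, 1)

  # 4 cells: Monte-Carlo p approaches the exhaustive 24-permutation p
  set.seed(33)
  xy <- matrix(runif(8), 4, 2)
  e4 <- matrix(runif(8), 4, 2)
  sg <- ccinet:::mean_nn_distance(xy)
  kern <- exp(-as.matrix(dist(xy))^2 / (2 * sg^2)); diag(kern) <- 0
  stat <- function(er) sum(outer(e4[, 1], er) * kern)
  obs <- stat(e4[, 2])
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4L), ]
  exact <- mean(apply(perms, 1, function(pp) stat(e4[, 2][pp]) >= obs))
  mc <- permutation_pvalue(obs, e4, xy, c(1L, 2L), sg, n_perm = 4000L,
                           rng_seed = 1L)
  expect_lt(abs(mc - exact), 0.03)
})

test_that("LR graph aggregates exactly the significant per-pair score matrices", {
  sim <- fixture_sim()
  ds <- sim$dataset
  db <- make_toy_lr_db(simulation_spec())
  cfg <- model_config(n_perm = 49L)
  g <- build_lr_graph(ds, db, cfg)
  tab <- attr(g, "score_table")
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
  en <- normalize_expression(ds$expr, "minmax_per_gene")
  sg <- ccinet:::mean_nn_distance(ds$coords)
  Wsum <- matrix(0, nrow(ds$expr), nrow(ds$expr))
  for (q in which(tab$significant)) {
    pr <- c(match(tab$ligand[q], ds$gene_names),
            match(tab$receptor[q], ds$gene_names))
    Wsum <- Wsum + lr_pair_score(en, ds$coords, pr, sg)
  }
  expect_equal(g$W, Wsum, tolerance = 1e-12, ignore_attr = TRUE)

  # unmappable database is an explicit error advising a toy DB
  expect_error(build_lr_graph(ds, lr_db("ZZZ1", "ZZZ2"), cfg), "toy")
})

test_that("conditional similarity kernel and its OR-symmetrization obey the closed forms", {
  expect_equal(conditional_similarity(0.5, 1, 2), 1)      # d <= rho
  expect_equal(conditional_similarity(3, 1, 2, eps = 0), exp(-1))
  set.seed(5)
  d <- runif(1, 1, 4); r <- runif(1, 0, 1); s <- runif(1, 0.5, 2)
  expect_equal(conditional_similarity(d, r, s, 1e-8),
               exp(-max(0, d - r) / (s + 1e-8)))

  expect_equal(symmetrize_similarity(1, 0.3), 1)
  expect_equal(symmetrize_similarity(0, 0), 0)
  expect_equal(symmetrize_similarity(0.5, 0.5), 0.75)
  # commutative, monotone, bounded on random pairs
  set.seed(6)
  p <- runif(50); q <- runif(50)
  expect_equal(symmetrize_similarity(p, q), symmetrize_similarity(q, p))
  expect_true(all(symmetrize_similarity(p, q) >= pmax(p, q) - 1e-15))
  expect_true(all(symmetrize_similarity(p, q) <= 1 + 1e-15))
})

test_that("similarity graph is symmetric and concentrates within clusters", {
  ds <- tiny_dataset()
  g <- build_similarity_graph(ds, model_config())
  expect_equal(g$W, t(g$W), tolerance = 1e-12)
  cl <- ds$labels
  same <- outer(cl, cl, "==") & upper.tri(g$W)
  diff <- outer(cl, cl, "!=") & upper.tri(g$W)
  expect_gt(mean(g$W[same]), mean(g$W[diff]))

  # two identical expression profiles get similarity 1
  expr <- ds$expr
  expr[2, ] <- expr[1, ]
  ds2 <- spatial_dataset(expr, ds$coords)
  g2 <- build_similarity_graph(ds2, model_config())
  expect_equal(g2$W[1, 2], 1, tolerance = 1e-8)
})
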