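test_that("top-edge thresholding matches a full sort and is monotone in the fraction", {
  set.seed(81)
  n <- 15L
  Z <- matrix(rnorm(n * 4), n, 4)
  A_hat <- decode_adjacency(Z)
  net5 <- threshold_top_edges(A_hat, 0.05)
  P <- n * (n - 1) / 2
  expect_equal(nrow(net5$edges), ceiling(0.05 * P))
  # oracle: full sort of the upper triangle
  ut <- which(upper.tri(A_hat), arr.ind = TRUE)
  s <- A_hat[ut]
  want <- order(-s, ut[, 1], ut[, 2])[seq_len(ceiling(0.05 * P))]
  got_keys <- paste(net5$edges$i, net5$edges$j)
  expect_setequal(got_keys, paste(ut[want, 1], ut[want, 2]))

  # fraction = 1 keeps every pair; monotone nesting for f1 <= f2
  net_all <- threshold_top_edges(A_hat, 1)
  expect_equal(nrow(net_all$edges), P)
  net20 <- threshold_top_edges(A_hat, 0.2)
  expect_true(all(got_keys %in% paste(net20$edges$i, net20$edges$j)))
  expect_error(threshold_top_edges(A_hat, 0), "fraction")
})

test_that("KS statistic equals the brute-force ECDF supremum", {
  expect_equal(ccinet:::.ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ccinet:::.ks_statistic(c(1, 2, 3), c(11, 12, 13)), 1)
  set.seed(82)
  a <- rnorm(20); b <- rnorm(30, mean = 0.5)
  pts <- sort(c(a, b))
  want <- max(abs(vapply(pts, function(p) mean(a <= p) - mean(b <= p), 0)))
  expect_equal(ccinet:::.ks_statistic(a, b), want, tolerance = 1e-12)
  # matches the standard two-sample test statistic
  expect_equal(ccinet:::.ks_statistic(a, b),
               unname(suppressWarnings(stats::ks.test(a, b)$statistic)),
               tolerance = 1e-12)
  # invariant to monotone transforms
  expect_equal(ccinet:::.ks_statistic(exp(a), exp(b)),
               ccinet:::.ks_statistic(a, b))
})

test_that("distance test separates short intra from long inter edges", {
  # two spatial groups; intra edges are short, inter edges span the gap
  set.seed(84)
  coords <- rbind(cbind(rnorm(6, 0, 0.3), rnorm(6, 0, 0.3)),
                  cbind(rnorm(6, 10, 0.3), rnorm(6, 0, 0.3)))
  labels <- rep(c("a", "b"), each = 6)
  edges <- data.frame(i = c(1L, 2L, 7L, 8L, 1L, 2L, 3L),
                      j = c(2L, 3L, 8L, 9L, 7L, 8L, 9L), score = 1)
  net <- structure(list(edges = edges, n = 12L, coords = coords,
                        labels = labels),
                   class = "interaction_network")
  res <- intra_inter_distance_test(net)
  expect_equal(res$statistic, 1)  # disjoint supports
  expect_lt(res$p_value, 0.1)
  expect_length(res$intra, 4L)
  expect_length(res$inter, 3L)

  # a group with no edges is a named error
  net_intra <- net
  net_intra$edges <- edges[1:4, ]
  expect_error(intra_inter_distance_test(net_intra), "inter")
})

test_that("topology stats match hand-computed stars and paths plus a BFS oracle", {
  # star on 5 nodes
  star <- structure(list(edges = data.frame(i = rep(1L, 4), j = 2:5,
                                            score = 1),
                         n = 5L, coords = NULL, labels = NULL),
                    class = "interaction_network")
  ts <- topology_stats(star)
  expect_equal(ts$degree, c(4, 1, 1, 1, 1))
  expect_equal(ts$closeness[1], 1)
  # path on 3 nodes: middle closeness 1, ends 2/3
  path <- structure(list(edges = data.frame(i = c(1L, 2L), j = c(2L, 3L),
                                            score = 1),
                         n = 3L, coords = NULL, labels = NULL),
                    class = "interaction_network")
  tp <- topology_stats(path)
  expect_equal(tp$closeness, c(2 / 3, 1, 2 / 3))

  # random graph vs igraph-independent BFS closeness oracle
  set.seed(83)
  n <- 12L
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sel <- pairs[sample.int(nrow(pairs), 14L), ]
  net <- structure(list(edges = data.frame(i = sel[, 1], j = sel[, 2],
                                           score = 1),
                        n = n, coords = NULL, labels = NULL),
                   class = "interaction_network")
  ts <- topology_stats(net)
  adj <- matrix(FALSE, n, n)
  adj[sel] <- TRUE; adj <- adj | t(adj)
  bfs_dist <- function(v) {
    d <- rep(Inf, n); d[v] <- 0; q <- v
    while (length(q)) {
      u <- q[1]; q <- q[-1]
      for (w in which(adj[u, ])) if (d[w] > d[u] + 1) {
        d[w] <- d[u] + 1; q <- c(q, w)
      }
    }
    d
  }
  for (v in seq_len(n)) {
    expect_equal(ts$degree[v], sum(adj[v, ]))
    d <- bfs_dist(v)
    reach <- which(is.finite(d) & seq_len(n) != v)
    want <- if (length(reach)) length(reach) / sum(d[reach]) else 0
    expect_equal(ts$closeness[v], want, tolerance = 1e-12)
  }

  # hubs: strict degree filter; threshold 0 keeps all non-isolated nodes
  expect_setequal(find_hubs(net, 0L), which(rowSums(adj) > 0))
  expect_setequal(find_hubs(star, 3L), 1L)
  expect_length(find_hubs(star, 10L), 0L)
})
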