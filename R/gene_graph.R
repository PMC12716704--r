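# Per-cell gene-regulatory block graph: gene selection, a pluggable GRN
# provider, and node2vec-style embeddings of the stacked gene nodes.

#' Construct a gene-level block graph
#'
#' Holds the block-diagonal gene-gene adjacency over `M = N * k_genes` gene
#' nodes (one block per cell), the gene-node feature matrix, and the per-cell
#' map of selected gene indices.
#'
#' @param A_g M x M binary block-diagonal adjacency.
#' @param gene_map list of length N; element i is the ordered integer vector
#'   of the `k_genes` dataset gene columns selected for cell i.
#' @param X_g optional M x d gene-node feature matrix.
#' @return An object of class `gene_block_graph` with elements `A_g`,
#'   `X_g`, `gene_map`, `groups` (cell index of each gene node) and
#'   `k_genes`.
#' @export
gene_block_graph <- function(A_g, gene_map, X_g = NULL) {
  k <- unique(lengths(gene_map))
  if (length(k) != 1L) stop("every cell block must have the same size")
  n <- length(gene_map)
  m <- n * k
  A_g <- methods::as(Matrix::Matrix(A_g, sparse = TRUE), "generalMatrix")
  if (nrow(A_g) != m || ncol(A_g) != m) {
    stop("A_g must be ", m, " x ", m, " for ", n, " cells x ", k, " genes")
  }
  groups <- rep(seq_len(n), each = k)
  tr <- Matrix::summary(A_g)
  if (any(groups[tr$i] != groups[tr$j])) {
    stop("A_g links gene nodes of different cells; blocks must be diagonal")
  }
  if (!is.null(X_g)) {
    X_g <- as.matrix(X_g)
    if (nrow(X_g) != m) stop("X_g must have ", m, " rows")
    if (any(!is.finite(X_g))) stop("X_g must be finite")
  }
  structure(list(A_g = A_g, X_g = X_g, gene_map = gene_map,
                 groups = groups, k_genes = k),
            class = "gene_block_graph")
}

#' Select genes per cell, prioritizing ligand-receptor pairs
#'
#' For each cell, database pairs whose two genes both occur in the dataset
#' are ranked by the cell's expression of the pair maximum and included
#' whole (paired retention) while they fit; once the next pair would
#' overflow the budget, remaining slots are filled with the cell's most
#' highly expressed genes not already chosen. Exactly `k_genes` genes per
#' cell.
#'
#' @param ds a [spatial_dataset()].
#' @param db an [lr_db()] (may be empty).
#' @param k_genes genes retained per cell (default 30; must be `<= G`).
#' @return List of length N of ordered integer gene-column vectors.
#' @export
select_genes_per_cell <- function(ds, db, k_genes = 30L) {
  g <- ncol(ds$expr)
  if (k_genes > g) stop("k_genes (", k_genes, ") exceeds gene count (", g, ")")
  if (k_genes == g) {
    return(rep(list(seq_len(g)), nrow(ds$expr)))
  }
  il <- match(db$ligand, ds$gene_names)
  ir <- match(db$receptor, ds$gene_names)
  ok <- which(!is.na(il) & !is.na(ir))
  lapply(seq_len(nrow(ds$expr)), function(i) {
    e <- ds$expr[i, ]
    sel <- integer(0)
    if (length(ok)) {
      score <- pmax(e[il[ok]], e[ir[ok]])
      for (q in ok[order(-score, ok)]) {
        add <- setdiff(c(il[q], ir[q]), sel)
        if (length(sel) + length(add) > k_genes) break
        sel <- c(sel, add)
      }
    }
    if (length(sel) < k_genes) {
      rest <- setdiff(seq_len(g), sel)
      fill <- rest[order(-e[rest], rest)]
      sel <- c(sel, fill[seq_len(k_genes - length(sel))])
    }
    sel
  })
}

#' Infer per-cell gene networks (block-diagonal)
#'
#' The gene-network source is pluggable. The `default_corr` provider
#' estimates, for each cell, absolute Pearson correlations between its
#' selected genes over the cell's spatial neighborhood (the cell plus its
#' `k_neighbors` nearest neighbors) and keeps `|r| >= r_min` as edges.
#' The `external_mtx` provider loads a precomputed block-diagonal adjacency
#' (e.g. the output of a dedicated single-cell GRN method) from a
#' MatrixMarket file and validates its block structure. Edges whose
#' endpoints form a database ligand-receptor pair are annotated as directed
#' ligand-to-receptor in the `lr_directed` attribute.
#'
#' @param ds a [spatial_dataset()].
#' @param gene_map output of [select_genes_per_cell()].
#' @param provider `"default_corr"` or `"external_mtx"`.
#' @param cfg a [model_config()] (uses `k_neighbors`, `r_min`).
#' @param external_path MTX path for the external provider.
#' @param db optional [lr_db()] for directionality annotation.
#' @return Sparse binary M x M block-diagonal adjacency; attribute
#'   `lr_directed` is a data frame of directed ligand-to-receptor node
#'   pairs.
#' @export
infer_cell_grns <- function(ds, gene_map,
                            provider = c("default_corr", "external_mtx"),
                            cfg = model_config(), external_path = NULL,
                            db = NULL) {
  provider <- match.arg(provider)
  n <- length(gene_map)
  k <- length(gene_map[[1L]])
  m <- n * k
  if (provider == "external_mtx") {
    if (is.null(external_path)) stop("external_mtx provider needs a path")
    A_g <- methods::as(Matrix::Matrix(Matrix::readMM(external_path),
                                      sparse = TRUE), "generalMatrix")
    if (nrow(A_g) != m) stop("external matrix has ", nrow(A_g),
                             " rows; expected ", m)
    groups <- rep(seq_len(n), each = k)
    tr <- Matrix::summary(A_g)
    if (any(groups[tr$i] != groups[tr$j])) {
      stop("external matrix has entries linking different cells' blocks")
    }
    A_g <- methods::as(A_g, "nMatrix")
    A_g <- Matrix::sparseMatrix(i = Matrix::summary(A_g)$i,
                                j = Matrix::summary(A_g)$j, x = 1,
                                dims = c(m, m))
  } else {
    d <- .pairwise_dist(ds$coords)
    diag(d) <- Inf
    ii <- integer(0); jj <- integer(0)
    for (c_id in seq_len(n)) {
      nbr <- c(c_id, order(d[c_id, ])[seq_len(min(cfg$k_neighbors,
                                                  n - 1L))])
      sub <- ds$expr[nbr, gene_map[[c_id]], drop = FALSE]
      r <- suppressWarnings(stats::cor(sub))
      r[is.na(r)] <- 0
      diag(r) <- 0
      hit <- which(abs(r) >= cfg$r_min, arr.ind = TRUE)
      if (nrow(hit)) {
        off <- (c_id - 1L) * k
        ii <- c(ii, off + hit[, 1L])
        jj <- c(jj, off + hit[, 2L])
      }
    }
    A_g <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(m, m))
  }
  lr_dir <- data.frame(from = integer(0), to = integer(0))
  if (!is.null(db) && nrow(db)) {
    key <- paste0(db$ligand, "\r", db$receptor)
    tr <- Matrix::summary(A_g)
    if (nrow(tr)) {
      gi <- unlist(gene_map)
      ek <- paste0(ds$gene_names[gi[tr$i]], "\r", ds$gene_names[gi[tr$j]])
      dir_hit <- ek %in% key
      lr_dir <- data.frame(from = tr$i[dir_hit], to = tr$j[dir_hit])
    }
  }
  attr(A_g, "lr_directed") <- lr_dir
  A_g
}

# Uniform (p = q = 1) random walks, vectorized over all walkers; biased
# (p, q) walks fall back to a per-step loop.
.random_walks <- function(adj_list, n_walks, walk_len, p = 1, q = 1) {
  m <- length(adj_list)
  deg <- lengths(adj_list)
  starts <- rep(which(deg > 0L), each = n_walks)
  if (!length(starts)) return(matrix(integer(0), 0L, walk_len))
  nw <- length(starts)
  walks <- matrix(0L, nw, walk_len)
  walks[, 1L] <- starts
  if (p == 1 && q == 1) {
    nb_flat <- unlist(adj_list, use.names = FALSE)
    nb_start <- c(0L, cumsum(deg))[seq_len(m)]
    cur <- starts
    for (s in seq_len(walk_len - 1L)) {
      pick <- nb_start[cur] + floor(stats::runif(nw) * deg[cur]) + 1L
      cur <- nb_flat[pick]
      walks[, s + 1L] <- cur
    }
  } else {
    for (w in seq_len(nw)) {
      cur <- starts[w]; prev <- 0L
      for (s in seq_len(walk_len - 1L)) {
        nbs <- adj_list[[cur]]
        wt <- rep(1, length(nbs))
        if (prev > 0L) {
          wt[nbs == prev] <- 1 / p
          far <- !(nbs %in% adj_list[[prev]]) & nbs != prev
          wt[far] <- 1 / q
        }
        nxt <- nbs[sample.int(length(nbs), 1L, prob = wt)]
        walks[w, s + 1L] <- nxt
        prev <- cur; cur <- nxt
      }
    }
  }
  walks
}

# window co-occurrence counts from a walk matrix, as a sparse M x M matrix
.cooccurrence <- function(walks, window, m) {
  if (!nrow(walks)) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = double(0),
                                dims = c(m, m)))
  }
  len <- ncol(walks)
  ii <- list(); jj <- list()
  for (off in seq_len(min(window, len - 1L))) {
    a <- as.vector(walks[, seq_len(len - off), drop = FALSE])
    b <- as.vector(walks[, seq_len(len - off) + off, drop = FALSE])
    ii[[off]] <- c(a, b); jj[[off]] <- c(b, a)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1, dims = c(m, m))
}

# full-batch skip-gram with negative sampling on one connected component's
# co-occurrence counts; returns the input-vector embedding
.sgns_fit <- function(C, d, n_neg = 5L, iters = 150L, lr = 0.05) {
  nc <- nrow(C)
  tot <- sum(C)
  if (tot == 0) return(matrix(0, nc, d))
  rs <- Matrix::rowSums(C)
  uq <- Matrix::colSums(C)^0.75
  uq <- uq / sum(uq)
  U <- matrix(stats::runif(nc * d, -0.5, 0.5) / d, nc, d)
  V <- matrix(stats::runif(nc * d, -0.5, 0.5) / d, nc, d)
  Cd <- as.matrix(C)
  Neg <- n_neg * outer(rs, uq)
  st <- adam_state(list(U = U, V = V))
  for (it in seq_len(iters)) {
    S <- tcrossprod(U, V)
    P <- 1 / (1 + exp(-S))
    dS <- (-Cd * (1 - P) + Neg * P) / tot
    gr <- list(U = dS %*% V, V = crossprod(dS, U))
    up <- adam_step(st, list(U = U, V = V), gr, lr = lr)
    st <- up$state; U <- up$params$U; V <- up$params$V
  }
  U
}

#' Embed gene nodes with random walks and skip-gram
#'
#' node2vec-style embeddings of the block-diagonal gene graph: biased
#' second-order random walks (defaults `p = 1`, `q = 1`, 10 walks per node
#' of length 20) generate window-5 co-occurrence statistics, and a
#' skip-gram model with negative sampling is fit to them per connected
#' component (blocks are disconnected, so components never span cells).
#' Isolated nodes receive the zero vector. Deterministic given `seed`.
#'
#' @param A_g sparse binary (block-diagonal) adjacency.
#' @param d embedding dimension (default 64).
#' @param n2v list overriding walk parameters `walks`, `length`, `window`,
#'   `p`, `q`.
#' @param seed integer seed.
#' @return M x d numeric feature matrix.
#' @export
embed_gene_nodes <- function(A_g, d = 64L, n2v = list(), seed = 1L) {
  par <- utils::modifyList(list(walks = 10L, length = 20L, window = 5L,
                                p = 1, q = 1), n2v)
  m <- nrow(A_g)
  # force general storage: summary() of a symmetric-class Matrix returns
  # only one triangle, which would truncate the adjacency lists
  sym <- methods::as(methods::as(A_g + Matrix::t(A_g), "generalMatrix"),
                     "nMatrix")
  tr <- Matrix::summary(methods::as(sym, "TsparseMatrix"))
  adj_list <- split(tr$j, factor(tr$i, levels = seq_len(m)))
  adj_list <- lapply(adj_list, function(v) v[v != 0])
  set.seed(seed)
  walks <- .random_walks(adj_list, par$walks, par$length, par$p, par$q)
  C <- .cooccurrence(walks, par$window, m)
  X <- matrix(0, m, d)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(sym, mode = "undirected"))
  for (c_id in seq_len(comp$no)) {
    nodes <- which(comp$membership == c_id)
    if (length(nodes) < 2L) next
    X[nodes, ] <- .sgns_fit(C[nodes, nodes, drop = FALSE], d)
  }
  X
}

#' Build the full gene-level block graph
#'
#' Convenience wrapper: selects genes per cell, infers per-cell gene
#' networks with the requested provider, and embeds the gene nodes.
#'
#' @param ds a [spatial_dataset()].
#' @param db an [lr_db()].
#' @param cfg a [model_config()].
#' @param provider,external_path passed to [infer_cell_grns()].
#' @return A [gene_block_graph()] with `X_g` filled in.
#' @export
build_gene_graph <- function(ds, db, cfg = model_config(),
                             provider = "default_corr",
                             external_path = NULL) {
  gene_map <- select_genes_per_cell(ds, db, min(cfg$k_genes, ncol(ds$expr)))
  A_g <- infer_cell_grns(ds, gene_map, provider, cfg,
                         external_path = external_path, db = db)
  X_g <- embed_gene_nodes(A_g, cfg$gene_embed_dim,
                          n2v = list(walks = cfg$n2v_walks,
                                     length = cfg$n2v_length,
                                     window = cfg$n2v_window,
                                     p = cfg$n2v_p, q = cfg$n2v_q),
                          seed = cfg$seed)
  gene_block_graph(A_g, gene_map, X_g)
}
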