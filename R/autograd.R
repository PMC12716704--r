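# Minimal reverse-mode automatic differentiation on matrices.
#
# The model trainer records a tape of matrix operations per forward pass and
# backpropagates vector-Jacobian products through it. Values are base dense
# matrices; constants (e.g. normalized adjacencies) may be Matrix sparse
# objects and are never differentiated. Only the operations the model needs
# are implemented; each op stores a closure computing the gradients of its
# parents given the gradient of its output.

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  class(t) <- "ag_tape"
  t
}

.ag_push <- function(tape, value, parents = integer(0), vjp = NULL) {
  # force all promises BEFORE reserving the id: a lazily evaluated nested
  # op call would otherwise push its own node after ours and collide
  force(value); force(parents); force(vjp)
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- list(parents = parents, vjp = vjp)
  tape$n <- n
  structure(list(id = n, value = value), class = "ag_node")
}

.v <- function(x) if (inherits(x, "ag_node")) x$value else x
.i <- function(x) if (inherits(x, "ag_node")) x$id else 0L

is_ag_node <- function(x) inherits(x, "ag_node")

#' @noRd
ag_param <- function(tape, value) {
  .ag_push(tape, as.matrix(value))
}

# Backward pass: returns list of gradients indexed by node id (NULL where
# no gradient flows). `seed` defaults to d(loss)/d(loss) = 1 for scalars.
ag_backward <- function(tape, node, seed = NULL) {
  grads <- vector("list", tape$n)
  if (is.null(seed)) seed <- matrix(1, nrow(node$value), ncol(node$value))
  grads[[node$id]] <- seed
  for (i in seq.int(node$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- tape$nodes[[i]]
    if (is.null(nd$vjp) || length(nd$parents) == 0L) next
    pg <- nd$vjp(g)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[j]
      if (p == 0L || is.null(pg[[j]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  grads
}

.dense <- function(x) if (is.matrix(x)) x else as.matrix(x)

# ---- arithmetic ----

ag_mm <- function(tape, a, b) {
  va <- .v(a); vb <- .v(b)
  ia <- .i(a); ib <- .i(b)
  .ag_push(tape, .dense(va %*% vb), c(ia, ib), function(g) {
    list(if (ia) .dense(Matrix::tcrossprod(g, vb)) else NULL,
         if (ib) .dense(Matrix::crossprod(va, g)) else NULL)
  })
}

# a %*% t(b)
ag_mmt <- function(tape, a, b) {
  va <- .v(a); vb <- .v(b)
  ia <- .i(a); ib <- .i(b)
  .ag_push(tape, .dense(Matrix::tcrossprod(va, vb)), c(ia, ib), function(g) {
    list(if (ia) .dense(g %*% vb) else NULL,
         if (ib) .dense(Matrix::crossprod(g, va)) else NULL)
  })
}

ag_add <- function(tape, a, b) {
  .ag_push(tape, .v(a) + .v(b), c(.i(a), .i(b)),
           function(g) list(g, g))
}

ag_sub <- function(tape, a, b) {
  .ag_push(tape, .v(a) - .v(b), c(.i(a), .i(b)),
           function(g) list(g, -g))
}

ag_scale <- function(tape, a, s) {
  .ag_push(tape, .v(a) * s, .i(a), function(g) list(g * s))
}

ag_mul <- function(tape, a, b) {
  va <- .v(a); vb <- .v(b)
  .ag_push(tape, va * vb, c(.i(a), .i(b)),
           function(g) list(g * vb, g * va))
}

# broadcast a 1 x d bias over the rows of a
ag_addbias <- function(tape, a, b) {
  va <- .v(a); vb <- .v(b)
  .ag_push(tape, sweep(va, 2L, as.vector(vb), "+"), c(.i(a), .i(b)),
           function(g) list(g, matrix(colSums(g), 1L)))
}

ag_transpose <- function(tape, a) {
  .ag_push(tape, t(.v(a)), .i(a), function(g) list(t(g)))
}

ag_cols <- function(tape, a, idx) {
  va <- .v(a)
  .ag_push(tape, va[, idx, drop = FALSE], .i(a), function(g) {
    out <- matrix(0, nrow(va), ncol(va))
    out[, idx] <- g
    list(out)
  })
}

ag_concat_cols <- function(tape, xs) {
  vals <- lapply(xs, .v)
  widths <- vapply(vals, ncol, 0L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  .ag_push(tape, do.call(cbind, vals), vapply(xs, .i, 0L), function(g) {
    lapply(seq_along(xs), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

# ---- nonlinearities ----

ag_relu <- function(tape, a) {
  va <- .v(a); mask <- va > 0
  .ag_push(tape, va * mask, .i(a), function(g) list(g * mask))
}

ag_tanh <- function(tape, a) {
  y <- tanh(.v(a))
  .ag_push(tape, y, .i(a), function(g) list(g * (1 - y^2)))
}

# exact GELU: x * Phi(x)
ag_gelu <- function(tape, a) {
  va <- .v(a)
  ph <- stats::pnorm(va)
  .ag_push(tape, va * ph, .i(a), function(g) {
    list(g * (ph + va * stats::dnorm(va)))
  })
}

ag_sigmoid <- function(tape, a) {
  y <- 1 / (1 + exp(-.v(a)))
  .ag_push(tape, y, .i(a), function(g) list(g * y * (1 - y)))
}

# ---- row-wise normalizations ----

ag_rowsoftmax <- function(tape, a) {
  va <- .v(a)
  m <- apply(va, 1L, max)
  e <- exp(va - m)
  p <- e / rowSums(e)
  .ag_push(tape, p, .i(a), function(g) {
    list(p * (g - rowSums(g * p)))
  })
}

ag_l2norm_rows <- function(tape, a, eps = 1e-12) {
  va <- .v(a)
  nrm <- sqrt(rowSums(va^2)) + eps
  y <- va / nrm
  .ag_push(tape, y, .i(a), function(g) {
    list((g - y * rowSums(g * y)) / nrm)
  })
}

# row-wise layer normalization with scale gamma and shift beta (both 1 x d)
ag_layernorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  vx <- .v(x); vg <- as.vector(.v(gamma)); vb <- as.vector(.v(beta))
  d <- ncol(vx)
  mu <- rowMeans(vx)
  xc <- vx - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  y <- sweep(sweep(xhat, 2L, vg, "*"), 2L, vb, "+")
  .ag_push(tape, y, c(.i(x), .i(gamma), .i(beta)), function(g) {
    gx <- sweep(g, 2L, vg, "*")
    dx <- istd * (gx - rowMeans(gx) - xhat * rowMeans(gx * xhat))
    list(dx,
         matrix(colSums(g * xhat), 1L),
         matrix(colSums(g), 1L))
  })
}

# scale each row of Z by the matching entry of the N x 1 column w
ag_rowscale <- function(tape, z, w) {
  vz <- .v(z); vw <- as.vector(.v(w))
  .ag_push(tape, vz * vw, c(.i(z), .i(w)), function(g) {
    list(g * vw, matrix(rowSums(g * vz), ncol = 1L))
  })
}

# ---- grouped (per-cell) ops over stacked gene nodes ----

# softmax within contiguous groups; s is M x 1, groups an integer vector
ag_groupsoftmax <- function(tape, s, groups) {
  vs <- as.vector(.v(s))
  mx <- stats::ave(vs, groups, FUN = max)
  e <- exp(vs - mx)
  tot <- stats::ave(e, groups, FUN = sum)
  p <- e / tot
  .ag_push(tape, matrix(p, ncol = 1L), .i(s), function(g) {
    gv <- as.vector(g)
    dot <- stats::ave(gv * p, groups, FUN = sum)
    list(matrix(p * (gv - dot), ncol = 1L))
  })
}

# out[c, ] = sum over rows r with groups[r] == c of beta[r] * E[r, ]
ag_grouppool <- function(tape, e, beta, groups, n_groups) {
  ve <- .v(e); vb <- as.vector(.v(beta))
  out <- rowsum(ve * vb, groups, reorder = TRUE)
  stopifnot(nrow(out) == n_groups)
  .ag_push(tape, .dense(out), c(.i(e), .i(beta)), function(g) {
    gg <- g[groups, , drop = FALSE]
    list(gg * vb, matrix(rowSums(gg * ve), ncol = 1L))
  })
}

# ---- scalar losses ----

# mean over rows of [logsumexp(S[i, ]) - S[i, i]] (cross-entropy with the
# diagonal as the positive class); the InfoNCE building block
ag_ce_diag <- function(tape, s) {
  vs <- .v(s)
  n <- nrow(vs)
  m <- apply(vs, 1L, max)
  e <- exp(vs - m)
  p <- e / rowSums(e)
  val <- mean(m + log(rowSums(e)) - diag(vs))
  .ag_push(tape, matrix(val, 1L, 1L), .i(s), function(g) {
    gs <- as.numeric(g)
    d <- p
    diag(d) <- diag(d) - 1
    list(gs * d / n)
  })
}

# hinge loss sum over hard negatives: (1/N) sum_i sum_{j in neg[i, ]}
# max(0, S[i, j] - S[i, i] + m); neg is an N x n_hard index matrix (NA pads)
ag_hinge_negs <- function(tape, s, neg, m) {
  vs <- .v(s)
  n <- nrow(vs)
  pos <- diag(vs)
  act <- matrix(FALSE, nrow(neg), ncol(neg))
  tot <- 0
  for (col in seq_len(ncol(neg))) {
    j <- neg[, col]
    ok <- !is.na(j)
    h <- vs[cbind(which(ok), j[ok])] - pos[ok] + m
    hit <- h > 0
    act[which(ok)[hit], col] <- TRUE
    tot <- tot + sum(h[hit])
  }
  .ag_push(tape, matrix(tot / n, 1L, 1L), .i(s), function(g) {
    gs <- as.numeric(g) / n
    d <- matrix(0, n, n)
    for (col in seq_len(ncol(neg))) {
      rows <- which(act[, col])
      if (length(rows)) {
        d[cbind(rows, neg[rows, col])] <- d[cbind(rows, neg[rows, col])] + gs
        d[cbind(rows, rows)] <- d[cbind(rows, rows)] - gs
      }
    }
    list(d)
  })
}

# numerically stable mean binary cross-entropy with logits z_i . z_j over an
# explicit edge list
ag_bce_edges <- function(tape, z, ei, ej, y) {
  vz <- .v(z)
  n <- nrow(vz)
  l <- rowSums(vz[ei, , drop = FALSE] * vz[ej, , drop = FALSE])
  val <- mean(pmax(l, 0) - y * l + log1p(exp(-abs(l))))
  .ag_push(tape, matrix(val, 1L, 1L), .i(z), function(g) {
    gs <- as.numeric(g)
    dl <- gs * (1 / (1 + exp(-l)) - y) / length(l)
    dz <- matrix(0, n, ncol(vz))
    a1 <- rowsum(dl * vz[ej, , drop = FALSE], ei, reorder = FALSE)
    dz[as.integer(rownames(a1)), ] <- dz[as.integer(rownames(a1)), ] + a1
    a2 <- rowsum(dl * vz[ei, , drop = FALSE], ej, reorder = FALSE)
    dz[as.integer(rownames(a2)), ] <- dz[as.integer(rownames(a2)), ] + a2
    list(dz)
  })
}

# mean over rows of || Z[i, ] - a ||^2 with a a 1 x d anchor
ag_center_loss <- function(tape, z, a) {
  vz <- .v(z); va <- as.vector(.v(a))
  n <- nrow(vz)
  r <- sweep(vz, 2L, va)
  .ag_push(tape, matrix(sum(r^2) / n, 1L, 1L), c(.i(z), .i(a)), function(g) {
    gs <- as.numeric(g)
    list(gs * 2 * r / n, matrix(-gs * 2 * colSums(r) / n, 1L))
  })
}

# weighted sum of 1 x 1 scalar nodes
ag_wsum <- function(tape, xs, w) {
  vals <- vapply(xs, function(x) as.numeric(.v(x)), 0)
  .ag_push(tape, matrix(sum(vals * w), 1L, 1L), vapply(xs, .i, 0L),
           function(g) {
             gs <- as.numeric(g)
             lapply(w, function(wi) matrix(gs * wi, 1L, 1L))
           })
}

# ---- Adam optimizer ----

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(state, params, grads, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(state = state, params = params)
}
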