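# Shared fixtures built in code. Small deterministic datasets and a
# central-difference gradient checker for the autodiff tape.

# tiny labelled dataset: two well-separated spatial/expression clusters
tiny_dataset <- function(n_per = 5L, g = 8L, seed = 42L) {
  set.seed(seed)
  n <- 2L * n_per
  cl <- rep(1:2, each = n_per)
  coords <- cbind(stats::rnorm(n, mean = c(0, 10)[cl], sd = 0.5),
                  stats::rnorm(n, sd = 0.5))
  mu <- matrix(0.5, n, g)
  mu[cl == 1, 1:(g / 2)] <- 4
  mu[cl == 2, (g / 2 + 1):g] <- 4
  expr <- mu * exp(matrix(stats::rnorm(n * g, sd = 0.2), n, g))
  spatial_dataset(expr, coords, labels = paste0("c", cl))
}

# default desk-scale fixture used by the training tests
fixture_sim <- function(seed = 7L) simulate_dataset(simulation_spec(seed = seed))

# numerical gradient of f (scalar-valued) wrt matrix x by central differences
num_grad <- function(f, x, h = 1e-5) {
  g <- x * 0
  for (k in seq_along(x)) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    g[k] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# check the tape gradient of `build(tape, params)` (returning a scalar node)
# against central differences for every parameter in `params`
expect_grad_match <- function(build, params, tol = 1e-5) {
  tape <- ccinet:::ag_tape()
  pn <- lapply(params, function(p) ccinet:::ag_param(tape, p))
  out <- build(tape, pn)
  grads <- ccinet:::ag_backward(tape, out)
  for (nm in names(params)) {
    got <- grads[[pn[[nm]]$id]]
    want <- num_grad(function(x) {
      t2 <- ccinet:::ag_tape()
      p2 <- lapply(params, function(p) ccinet:::ag_param(t2, p))
      p2[[nm]] <- ccinet:::ag_param(t2, x)
      as.numeric(build(t2, p2)$value)
    }, params[[nm]])
    expect_lt(max(abs(got - want)), tol, label = paste("grad", nm))
  }
}
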