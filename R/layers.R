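# Minimal dense-network primitives with explicit forward caches and
# backward passes. Parameters are plain lists of matrices/vectors so that
# gradient structures, Adam moments and finite-difference checks can all
# reuse the same nested-list walkers.

init_linear <- function(n_in, n_out) {
  # He-style fan-in scaling, suited to leaky-rectifier activations
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

linear_forward <- function(X, lin) {
  list(out = X %*% lin$W + matrix(lin$b, nrow(X), length(lin$b), byrow = TRUE),
       X = X)
}

# returns list(grads = list(W, b), dX)
linear_backward <- function(dY, cache, lin) {
  list(grads = list(W = crossprod(cache$X, dY), b = colSums(dY)),
       dX = dY %*% t(lin$W))
}

lrelu_forward <- function(X, slope = 0.01) {
  list(out = ifelse(X > 0, X, slope * X), pos = X > 0)
}

lrelu_backward <- function(dY, cache, slope = 0.01) {
  dY * ifelse(cache$pos, 1, slope)
}

init_batchnorm <- function(n) {
  list(gamma = rep(1, n), beta = numeric(n))
}

init_batchnorm_state <- function(n) {
  list(running_mean = numeric(n), running_var = rep(1, n))
}

# Train mode normalizes with batch statistics (ML variance) and updates the
# running statistics; eval mode uses the running statistics.
batchnorm_forward <- function(X, bn, state, mode = c("train", "eval"),
                              eps = 1e-5, momentum = 0.1) {
  mode <- match.arg(mode)
  n <- nrow(X)
  if (mode == "train") {
    mu <- colMeans(X)
    va <- colMeans(sweep(X, 2L, mu)^2)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(X, 2L, mu), 2L, inv_sd, "*")
  out <- sweep(sweep(xhat, 2L, bn$gamma, "*"), 2L, bn$beta, "+")
  list(out = out, xhat = xhat, inv_sd = inv_sd, Xc = sweep(X, 2L, mu),
       mode = mode, state = state)
}

batchnorm_backward <- function(dY, cache, bn) {
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, bn$gamma, "*")
  if (cache$mode == "eval") {
    dX <- sweep(dxhat, 2L, cache$inv_sd, "*")
  } else {
    n <- nrow(dY)
    # batch statistics are functions of X: full train-mode gradient
    dvar <- colSums(dxhat * cache$Xc) * (-0.5) * cache$inv_sd^3
    dmu <- -colSums(sweep(dxhat, 2L, cache$inv_sd, "*")) +
      dvar * (-2) * colMeans(cache$Xc)
    dX <- sweep(dxhat, 2L, cache$inv_sd, "*") +
      sweep(cache$Xc, 2L, 2 * dvar / n, "*") +
      matrix(dmu / n, n, ncol(dY), byrow = TRUE)
  }
  list(grads = list(gamma = dgamma, beta = dbeta), dX = dX)
}

# --- nested-list parameter walkers ------------------------------------------

param_map <- function(x, f) {
  if (is.list(x)) lapply(x, param_map, f = f) else f(x)
}

param_map2 <- function(x, y, f) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- param_map2(x[[i]], y[[i]], f)
    out
  } else f(x, y)
}

param_zeros_like <- function(x) param_map(x, function(v) v * 0)

param_add <- function(x, y) param_map2(x, y, `+`)

param_max_abs_diff <- function(x, y) {
  if (is.list(x)) max(vapply(seq_along(x),
                             function(i) param_max_abs_diff(x[[i]], y[[i]]),
                             numeric(1)))
  else if (length(x) == 0) 0
  else max(abs(x - y))
}
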