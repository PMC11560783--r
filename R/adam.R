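# Adam optimizer over nested parameter lists, with two learning-rate
# groups: the common extractor trains at a smaller rate than the
# discriminator and branch networks (it receives gradients from every
# domain, so a small rate keeps it stable).

adam_init <- function(params) {
  list(m = param_zeros_like(params), v = param_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr_common, lr_other,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t

  walk <- function(p, g, m, v, lr) {
    if (is.list(p)) {
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]], lr)
        p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
      }
      list(p = p, m = m, v = v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      list(p = p, m = m, v = v)
    }
  }

  for (grp in names(params)) {
    lr <- if (grp == "common") lr_common else lr_other
    r <- walk(params[[grp]], grads[[grp]], state$m[[grp]], state$v[[grp]], lr)
    params[[grp]] <- r$p; state$m[[grp]] <- r$m; state$v[[grp]] <- r$v
  }
  list(params = params, state = state)
}
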