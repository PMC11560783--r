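# Internal numerical helpers shared across modules.

# log with the argument floored at eps, so log(0) never produces -Inf.
clamped_log <- function(x, eps = 1e-12) {
  log(pmax(x, eps))
}

# Numerically stable row-wise softmax.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

softmax_vec <- function(z) {
  stopifnot(all(is.finite(z)))
  e <- exp(z - max(z))
  e / sum(e)
}

# Derive a child RNG seed from a root seed and a stream index. All module
# randomness flows from one root seed through this scheme, so that full runs
# are reproducible and independent components get decorrelated streams.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(root, stream) {
  as.integer((as.numeric(root) %% 2147483399 * 48271 + as.numeric(stream) * 7919) %% 2147483399)
}

leaky_relu <- function(x, slope = 0.01) {
  ifelse(x > 0, x, slope * x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
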