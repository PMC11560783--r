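# Shared fixture builders. Everything is generated in code at test time.

# A tiny multi-domain benchmark for fast training tests.
tiny_domains <- function(seed = 1L, n_source_domains = 2L, n_classes = 3L,
                         samples_per_class = 30L, feature_dim = 8L,
                         class_separation = 4, domain_shift = 0.5,
                         noise_sd = 0.8) {
  generate_domains(simulation_config(
    n_source_domains = n_source_domains, n_classes = n_classes,
    samples_per_class = samples_per_class, feature_dim = feature_dim,
    class_separation = class_separation, domain_shift = domain_shift,
    noise_sd = noise_sd, seed = seed))
}

# A fast training configuration with a small network.
tiny_train_config <- function(seed = 1L, epochs = 3L, batch_size = 16L, ...) {
  train_config(batch_size = batch_size, epochs = epochs,
               hidden = c(16L, 8L), branch_dim = 4L, seed = seed, ...)
}

# Sinusoid recording helper for filter tests.
sine_recording <- function(freqs, fs = 200, seconds = 10, label = NA) {
  t <- seq(1 / fs, seconds, by = 1 / fs)
  sig <- do.call(rbind, lapply(freqs, function(f) sin(2 * pi * f * t)))
  eeg_recording(sig, fs, label = label)
}

rms <- function(x) sqrt(mean(x^2))

# Nearest-class-mean classifier: an adaptation-free reference model used as
# an independent check on the synthetic generator.
nearest_mean_fit <- function(X, y) {
  classes <- sort(unique(y))
  centers <- t(vapply(classes,
                      function(c) colMeans(X[y == c, , drop = FALSE]),
                      numeric(ncol(X))))
  list(classes = classes, centers = centers)
}

nearest_mean_predict <- function(fit, X) {
  d2 <- vapply(seq_len(nrow(fit$centers)), function(i) {
    rowSums(sweep(X, 2L, fit$centers[i, ])^2)
  }, numeric(nrow(X)))
  fit$classes[max.col(-d2, ties.method = "first")]
}
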