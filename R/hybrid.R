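#' Cosine similarity between source and target batches
#'
#' Entry `(j, k)` is the cosine of the flattened feature vectors of source
#' sample `j` and target sample `k`:
#' `s_jk = <x_j, t_k> / (||x_j|| * ||t_k||)`. Channels x bands matrices are
#' flattened, so the matrix product is the Frobenius inner product.
#'
#' @param source_feats,target_feats numeric matrices, one sample per row,
#'   identical feature dimension, no zero-norm rows.
#' @return list with `raw` (the similarity matrix, entries in `[-1, 1]`),
#'   `normalized` (row-wise softmax of `raw`, each row a probability
#'   vector), and `match_index` (per source row, the target index of
#'   highest similarity; ties broken by lowest index).
#' @export
cosine_similarity_matrix <- function(source_feats, target_feats) {
  source_feats <- as.matrix(source_feats)
  target_feats <- as.matrix(target_feats)
  if (ncol(source_feats) != ncol(target_feats))
    stop("source and target feature dimensions differ")
  ns <- sqrt(rowSums(source_feats^2))
  nt <- sqrt(rowSums(target_feats^2))
  if (any(ns == 0))
    stop(sprintf("zero-norm source sample at index %d", which(ns == 0)[1]))
  if (any(nt == 0))
    stop(sprintf("zero-norm target sample at index %d", which(nt == 0)[1]))
  raw <- (source_feats %*% t(target_feats)) / outer(ns, nt)
  raw <- pmin(pmax(raw, -1), 1)
  list(raw = raw,
       normalized = softmax_rows(raw),
       match_index = max.col(raw, ties.method = "first"))
}

#' Softmax-normalize a similarity row
#'
#' Turns one row of raw cosine similarities into a probability vector over
#' the target batch. Order-preserving, so the argmax is unchanged.
#'
#' @param raw_row numeric vector of finite similarities.
#' @return probability vector summing to 1.
#' @export
normalize_similarity <- function(raw_row) {
  softmax_vec(raw_row)
}

#' Build a hybrid sample set for one source batch
#'
#' The per-batch replacement for a source domain: the source batch is
#' shuffled (so the retained half is a fresh random half each step), the
#' first `ceiling(M_b / 2)` samples are kept verbatim, and each remaining
#' sample `x_j` is replaced by the mixture
#' `lam * x_j + (1 - lam) * x_tilde_j`, where `x_tilde_j` is the target
#' sample of the batch with the highest cosine similarity to `x_j` (ties:
#' lowest target index). All samples keep the source labels, which act as
#' pseudo-labels for the target information blended in.
#'
#' Uses the current RNG state for the shuffle; seed the session (or pass
#' `shuffle = FALSE`) for reproducibility.
#'
#' @param source_feats `M_b x p` source batch (rows are samples).
#' @param source_labels integer labels of the source batch.
#' @param target_feats `M_b x p` target batch.
#' @param lam hybrid parameter `lambda` in `[0, 1]`; 1 reproduces pure
#'   source samples. Defaults 0.8 (cross-subject optimum) / 0.6
#'   (cross-session) are set in [default_config()].
#' @param shuffle randomize the source order first (default `TRUE`).
#' @param order explicit source permutation to use instead of drawing one
#'   (overrides `shuffle`); used by the training loop, which pre-draws all
#'   permutations per epoch.
#' @return list of class `hybrid_batch` with `features`, `labels`,
#'   `n_verbatim`, `match_index` (NA for verbatim rows), `similarity`
#'   (the [cosine_similarity_matrix()] result) and `lam`.
#' @export
build_hybrid_batch <- function(source_feats, source_labels, target_feats,
                               lam, shuffle = TRUE, order = NULL) {
  source_feats <- as.matrix(source_feats)
  target_feats <- as.matrix(target_feats)
  Mb <- nrow(source_feats)
  if (nrow(target_feats) != Mb)
    stop(sprintf("batch sizes differ: source %d, target %d",
                 Mb, nrow(target_feats)))
  if (length(source_labels) != Mb)
    stop("source batch must be fully labeled")
  if (lam < 0 || lam > 1) stop("lam must lie in [0, 1]")

  ord <- order %||% (if (shuffle) sample.int(Mb) else seq_len(Mb))
  X <- source_feats[ord, , drop = FALSE]
  y <- source_labels[ord]

  sim <- cosine_similarity_matrix(X, target_feats)
  n_keep <- ceiling(Mb / 2)
  H <- X
  match_index <- rep(NA_integer_, Mb)
  if (n_keep < Mb) {
    j <- (n_keep + 1L):Mb
    match_index[j] <- sim$match_index[j]
    H[j, ] <- lam * X[j, , drop = FALSE] +
      (1 - lam) * target_feats[match_index[j], , drop = FALSE]
  }
  structure(list(features = H, labels = y, n_verbatim = n_keep,
                 match_index = match_index, similarity = sim, lam = lam,
                 order = ord),
            class = "hybrid_batch")
}
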