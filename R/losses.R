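#' Loss configuration
#'
#' Weights of the total training objective
#' `L_total = L_cls + lambda1 * L_dis + lambda2(p) * L_mmd + lambda3 * L_ce`,
#' where `lambda2` follows the dynamic schedule [lambda2()] of training
#' progress `p`. The ablation switches zero out individual terms.
#'
#' @param lambda1 weight of the domain-discrimination loss (default 0.1).
#' @param lambda3 weight of the conditional-entropy loss (default 0.1).
#' @param mmd_kernel `"linear"` (squared distance between feature means)
#'   or `"rbf"` (multi-kernel Gaussian MMD^2).
#' @param use_dis,use_ce,use_mmd ablation switches; `FALSE` forces the
#'   respective weight to 0.
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(lambda1 = 0.1, lambda3 = 0.1,
                        mmd_kernel = c("linear", "rbf"),
                        use_dis = TRUE, use_ce = TRUE, use_mmd = TRUE) {
  stopifnot(lambda1 >= 0, lambda3 >= 0)
  structure(list(lambda1 = if (use_dis) lambda1 else 0,
                 lambda3 = if (use_ce) lambda3 else 0,
                 mmd_kernel = match.arg(mmd_kernel),
                 use_dis = use_dis, use_ce = use_ce, use_mmd = use_mmd),
            class = "loss_config")
}

#' Classification loss over hybrid sample sets
#'
#' Sum over branches of the mean cross-entropy between each branch's
#' predictions on its hybrid set and the (pseudo-)labels inherited from the
#' source domain: for each sample the negative log-probability of the true
#' class, with the log input clamped at `1e-12`.
#'
#' @param prob_list list of `M x C` probability matrices, one per branch.
#' @param label_list list of integer label vectors in `0..C-1`.
#' @return non-negative scalar (nats).
#' @export
classification_loss <- function(prob_list, label_list) {
  stopifnot(length(prob_list) == length(label_list))
  total <- 0
  for (i in seq_along(prob_list)) {
    P <- prob_list[[i]]
    y <- as.integer(label_list[[i]])
    if (any(y < 0L) || any(y >= ncol(P)))
      stop("label out of range 0..C-1")
    total <- total - mean(clamped_log(P[cbind(seq_len(nrow(P)), y + 1L)]))
  }
  total
}

#' Domain discrimination loss
#'
#' Cross-entropy of the discriminator's domain posteriors against the true
#' hybrid-set of origin, averaged within each hybrid set and summed over
#' the `N` sets. With a single domain the loss is identically zero.
#'
#' @param dprob_list list of `M x N` domain-probability matrices; element
#'   `i` holds the posteriors for samples of hybrid set `i`.
#' @return non-negative scalar (nats).
#' @export
domain_loss <- function(dprob_list) {
  N <- length(dprob_list)
  total <- 0
  for (i in seq_len(N)) {
    P <- dprob_list[[i]]
    if (i > ncol(P)) stop("domain index exceeds discriminator output width")
    total <- total - mean(clamped_log(P[, i]))
  }
  if (N == 1L) 0 else total
}

#' Maximum mean discrepancy between branch features
#'
#' Per branch, the discrepancy between the domain-specific features of the
#' hybrid set and of the target batch, summed over branches. The default
#' linear kernel is the squared Euclidean norm of the difference between
#' the two feature means; the `"rbf"` option is a standard multi-kernel
#' Gaussian MMD^2 estimate (5 bandwidths around the median pairwise
#' distance).
#'
#' @param fS_list list of `M_i x q` source-side feature matrices.
#' @param fS_target_list list of `M_t x q` target-side feature matrices
#'   (same branch order).
#' @param kernel `"linear"` or `"rbf"`.
#' @return non-negative scalar under the linear kernel.
#' @export
mmd_loss <- function(fS_list, fS_target_list, kernel = c("linear", "rbf")) {
  kernel <- match.arg(kernel)
  stopifnot(length(fS_list) == length(fS_target_list))
  total <- 0
  for (i in seq_along(fS_list)) {
    S <- as.matrix(fS_list[[i]]); T_ <- as.matrix(fS_target_list[[i]])
    if (nrow(S) == 0L || nrow(T_) == 0L) stop("empty feature batch")
    if (kernel == "linear") {
      diff <- colMeans(S) - colMeans(T_)
      total <- total + sum(diff^2)
    } else {
      total <- total + rbf_mmd2(S, T_)
    }
  }
  total
}

# Biased multi-kernel Gaussian MMD^2 with median-heuristic bandwidths.
rbf_mmd2 <- function(S, T_, n_kernels = 5L) {
  Z <- rbind(S, T_)
  d2 <- as.matrix(stats::dist(Z))^2
  med <- stats::median(d2[upper.tri(d2)])
  if (med <= 0) med <- 1
  sigmas <- med * 2^((seq_len(n_kernels)) - (n_kernels + 1L) / 2)
  ns <- nrow(S); nt <- nrow(T_)
  K <- 0
  for (s2 in sigmas) K <- K + exp(-d2 / s2)
  K <- K / n_kernels
  mean(K[seq_len(ns), seq_len(ns)]) +
    mean(K[ns + seq_len(nt), ns + seq_len(nt)]) -
    2 * mean(K[seq_len(ns), ns + seq_len(nt)])
}

#' Conditional-entropy loss on target predictions
#'
#' Sum over branches of the mean Shannon entropy (nats) of each branch's
#' predicted class distribution on the unlabeled target batch, with
#' `x * log(x)` taken as 0 at `x = 0`. Minimizing it sharpens target
#' predictions, pushing decision boundaries out of dense target regions.
#' Bounded by `0 <= L_ce <= N * log(C)`.
#'
#' @param prob_list list of `M x C` target probability matrices, one per
#'   branch.
#' @return scalar in `[0, N * log(C)]`.
#' @export
conditional_entropy_loss <- function(prob_list) {
  total <- 0
  for (P in prob_list) {
    h <- -rowSums(ifelse(P > 0, P * log(P), 0))
    total <- total + mean(h)
  }
  total
}

#' Dynamic MMD weight schedule
#'
#' `lambda2(p) = 2 / (1 + exp(-10 p)) - 1` for training progress
#' `p in [0, 1]` (values outside are clipped). Starts at 0 so early epochs
#' focus on classification, and saturates near 1 so marginal alignment
#' strengthens as training proceeds.
#'
#' @param p training progress, `current_epoch / total_epochs`.
#' @return weight in `[0, 1)`.
#' @export
lambda2 <- function(p) {
  p <- pmin(pmax(p, 0), 1)
  2 / (1 + exp(-10 * p)) - 1
}

#' Combine the loss terms
#'
#' @param cls,dis,mmd,ce the four component losses.
#' @param config a [loss_config()].
#' @param progress training progress in `[0, 1]` (drives [lambda2()]).
#' @return a `loss_breakdown` list with the components, the weights used,
#'   and `total = cls + lambda1 * dis + lambda2 * mmd + lambda3 * ce`.
#' @export
total_loss <- function(cls, dis, mmd, ce, config, progress) {
  stopifnot(inherits(config, "loss_config"))
  l2 <- if (config$use_mmd %||% TRUE) lambda2(progress) else 0
  structure(list(cls = cls, dis = dis, mmd = mmd, ce = ce,
                 lambda1 = config$lambda1, lambda2 = l2,
                 lambda3 = config$lambda3,
                 total = cls + config$lambda1 * dis + l2 * mmd +
                   config$lambda3 * ce),
            class = "loss_breakdown")
}
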