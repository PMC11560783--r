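#' Training configuration
#'
#' Collects every scalar of the optimization problem. Defaults follow the
#' 3-class cross-subject setup: batch size 64, 50 epochs, Adam with
#' learning rate 5e-4 for the common extractor and 5e-3 elsewhere, hybrid
#' parameter `lambda = 0.8`, gradient-reversal coefficient 0.8, and loss
#' weights `lambda1 = lambda3 = 0.1` with the dynamic [lambda2()] schedule.
#' For cross-session runs the recommended hybrid parameter is 0.6; 4-class
#' setups train for 200 epochs.
#'
#' @param batch_size per-domain batch size `M_b` (even values recommended:
#'   the hybrid set splits into two exact halves).
#' @param epochs number of passes over the smallest domain.
#' @param lr_common,lr_other Adam learning rates for the common extractor
#'   and for everything else.
#' @param hybrid_lambda hybrid mixing parameter in `[0, 1]`.
#' @param hybrid_enabled ablation switch; `FALSE` feeds raw source batches.
#' @param grl_lambda gradient-reversal coefficient.
#' @param hidden common-extractor widths.
#' @param branch_dim branch feature width.
#' @param loss a [loss_config()].
#' @param discriminate_target also feed target-domain features to the
#'   domain discriminator, as an extra (N+1)-th domain class. Off by
#'   default: the discrimination loss is defined over the hybrid sets
#'   only, which already carry target information.
#' @param seed root seed for initialization and data ordering.
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, epochs = 50L, lr_common = 5e-4,
                         lr_other = 5e-3, hybrid_lambda = 0.8,
                         hybrid_enabled = TRUE, grl_lambda = 0.8,
                         hidden = c(256L, 128L, 64L), branch_dim = 32L,
                         loss = loss_config(), discriminate_target = FALSE,
                         seed = 1L) {
  stopifnot(batch_size >= 2L, epochs >= 1L, lr_common > 0, lr_other > 0,
            hybrid_lambda >= 0, hybrid_lambda <= 1, grl_lambda >= 0,
            inherits(loss, "loss_config"))
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 lr_common = lr_common, lr_other = lr_other,
                 hybrid_lambda = hybrid_lambda,
                 hybrid_enabled = isTRUE(hybrid_enabled),
                 grl_lambda = grl_lambda,
                 hidden = as.integer(hidden),
                 branch_dim = as.integer(branch_dim),
                 loss = loss,
                 discriminate_target = isTRUE(discriminate_target),
                 seed = as.integer(seed)),
            class = "train_config")
}

onehot <- function(y, C) {
  Y <- matrix(0, length(y), C)
  Y[cbind(seq_along(y), y + 1L)] <- 1
  Y
}

# Gradient of the biased multi-kernel Gaussian MMD^2 w.r.t. both feature
# sets. The median-heuristic bandwidth is treated as a constant
# (stop-gradient), the usual convention; pass `bandwidth_base` to pin it.
rbf_mmd2_grad <- function(S, T_, n_kernels = 5L, bandwidth_base = NULL) {
  ns <- nrow(S); nt <- nrow(T_)
  Z <- rbind(S, T_)
  d2 <- as.matrix(stats::dist(Z))^2
  med <- bandwidth_base %||% stats::median(d2[upper.tri(d2)])
  if (med <= 0) med <- 1
  sigmas <- med * 2^((seq_len(n_kernels)) - (n_kernels + 1L) / 2)
  W <- 0  # sum over kernels of K / sigma (shows up in dK = -2 K (a-b)/sigma)
  K <- 0
  for (s2 in sigmas) {
    Ks <- exp(-d2 / s2)
    K <- K + Ks
    W <- W + Ks / s2
  }
  K <- K / n_kernels; W <- W / n_kernels
  iS <- seq_len(ns); iT <- ns + seq_len(nt)
  loss <- mean(K[iS, iS]) + mean(K[iT, iT]) - 2 * mean(K[iS, iT])
  # d/dA mean K(A,B) at row j: sum_k W_jk * (-2)(A_j - B_k) / (na*nb)
  pair_grad <- function(Wblk, A, B, sign) {
    # returns gradient for rows of A from block between A (rows) and B (cols)
    g <- -2 * (A * rowSums(Wblk) - Wblk %*% B) / length(Wblk)
    sign * g
  }
  dS <- 2 * pair_grad(W[iS, iS, drop = FALSE], S, S, 1) -
    2 * pair_grad(W[iS, iT, drop = FALSE], S, T_, 1)
  dT <- 2 * pair_grad(W[iT, iT, drop = FALSE], T_, T_, 1) -
    2 * pair_grad(W[iT, iS, drop = FALSE], T_, S, 1)
  list(loss = loss, dS = dS, dT = dT)
}

# One optimization step: forward all parts, compute the four losses, and
# backpropagate the weighted total into a gradient structure matching
# model$params. `batches` is a list of N lists(X, y); `perms` the pre-drawn
# per-domain shuffles for hybridization.
shmda_step <- function(model, batches, target_X, config, l2w, perms = NULL) {
  N <- model$arch$n_domains
  C <- model$arch$n_classes
  w <- config$loss
  lam1 <- w$lambda1
  lam3 <- w$lambda3
  kernel <- w$mmd_kernel
  use_dis <- lam1 > 0 && N > 1L
  dis_target <- use_dis && isTRUE(config$discriminate_target)
  # the target batch feeds only the MMD and conditional-entropy terms (plus
  # hybridization, which reads raw features, not network outputs); with both
  # terms off the target is never forwarded -- plain supervised training
  use_target <- (w$use_mmd %||% TRUE) || lam3 > 0 || dis_target

  # hybrid sample sets replace the raw source batches
  hybrids <- vector("list", N)
  for (i in seq_len(N)) {
    if (config$hybrid_enabled) {
      hb <- build_hybrid_batch(batches[[i]]$X, batches[[i]]$y, target_X,
                               config$hybrid_lambda,
                               order = if (is.null(perms)) NULL else perms[[i]])
      hybrids[[i]] <- list(X = hb$features, y = hb$labels)
    } else {
      hybrids[[i]] <- list(X = batches[[i]]$X, y = batches[[i]]$y)
    }
  }

  cf <- lapply(hybrids, function(b) common_forward(b$X, model))
  cf_t <- if (use_target) common_forward(target_X, model)

  df <- if (use_dis) lapply(cf, function(z) discriminator_forward(z$out, model))

  bf <- bt <- vector("list", N)
  for (i in seq_len(N)) {
    bf[[i]] <- branch_forward(cf[[i]]$out, i, model, "train")
    model$bn[[i]] <- bf[[i]]$bn_state
    if (use_target) {
      bt[[i]] <- branch_forward(cf_t$out, i, model, "train")
      model$bn[[i]] <- bt[[i]]$bn_state
    }
  }

  df_t <- if (dis_target) discriminator_forward(cf_t$out, model)

  cls <- classification_loss(lapply(bf, `[[`, "probs"),
                             lapply(hybrids, `[[`, "y"))
  dis <- if (!use_dis) 0
  else if (dis_target)
    domain_loss(c(lapply(df, `[[`, "probs"), list(df_t$probs)))
  else domain_loss(lapply(df, `[[`, "probs"))
  mmd_pairs <- if (use_target && kernel == "rbf")
    lapply(seq_len(N), function(i) rbf_mmd2_grad(bf[[i]]$f_S, bt[[i]]$f_S))
  mmdv <- if (!use_target) 0
  else if (kernel == "rbf")
    sum(vapply(mmd_pairs, `[[`, numeric(1), "loss"))
  else
    mmd_loss(lapply(bf, `[[`, "f_S"), lapply(bt, `[[`, "f_S"), "linear")
  ce <- if (use_target)
    conditional_entropy_loss(lapply(bt, `[[`, "probs")) else 0

  # ---- backward ----
  grads <- param_zeros_like(model$params)
  d_fI_t <- 0
  Mt <- nrow(target_X)

  for (i in seq_len(N)) {
    Mb <- nrow(hybrids[[i]]$X)
    # classification: softmax + cross-entropy
    dlog_s <- (bf[[i]]$probs - onehot(hybrids[[i]]$y, C)) / Mb
    # MMD directly on the branch features
    if (use_target && l2w > 0) {
      if (kernel == "rbf") {
        d_fS_s <- l2w * mmd_pairs[[i]]$dS
        d_fS_t <- l2w * mmd_pairs[[i]]$dT
      } else {
        diff <- colMeans(bf[[i]]$f_S) - colMeans(bt[[i]]$f_S)
        d_fS_s <- matrix(l2w * 2 * diff / Mb, Mb, length(diff), byrow = TRUE)
        d_fS_t <- matrix(-l2w * 2 * diff / Mt, Mt, length(diff), byrow = TRUE)
      }
    } else {
      d_fS_s <- matrix(0, Mb, model$arch$branch_dim)
      d_fS_t <- matrix(0, Mt, model$arch$branch_dim)
    }

    bb_s <- branch_backward(dlog_s, d_fS_s, bf[[i]]$cache, i, model)
    grads$branches[[i]] <- param_add(grads$branches[[i]], bb_s$grads)
    d_fI_i <- bb_s$dX
    if (use_target) {
      # conditional entropy on the target predictions
      P <- bt[[i]]$probs
      H_row <- -rowSums(ifelse(P > 0, P * log(P), 0))
      dlog_t <- lam3 * (-P * (clamped_log(P, 1e-300) + H_row)) / Mt
      bb_t <- branch_backward(dlog_t, d_fS_t, bt[[i]]$cache, i, model)
      grads$branches[[i]] <- param_add(grads$branches[[i]], bb_t$grads)
      d_fI_t <- d_fI_t + bb_t$dX
    }

    if (use_dis) {
      Nd <- model$arch$disc_classes
      dZ <- lam1 * (df[[i]]$probs - onehot(rep.int(i - 1L, Mb), Nd)) / Mb
      db <- discriminator_backward(dZ, df[[i]]$cache, model)
      grads$disc <- param_add(grads$disc, db$grads)
      # gradient reversal: the common extractor sees the reversed gradient
      d_fI_i <- d_fI_i + grl_backward(db$dX, model$arch$grl_lambda)
    }

    grads$common <- param_add(grads$common,
                              common_backward(d_fI_i, cf[[i]]$cache, model)$grads)
  }
  if (dis_target) {
    Nd <- model$arch$disc_classes
    dZt <- lam1 * (df_t$probs - onehot(rep.int(Nd - 1L, Mt), Nd)) / Mt
    dbt <- discriminator_backward(dZt, df_t$cache, model)
    grads$disc <- param_add(grads$disc, dbt$grads)
    d_fI_t <- d_fI_t + grl_backward(dbt$dX, model$arch$grl_lambda)
  }
  if (use_target)
    grads$common <- param_add(grads$common,
                              common_backward(d_fI_t, cf_t$cache, model)$grads)

  list(grads = grads, model = model,
       losses = c(cls = cls, dis = dis, mmd = mmdv, ce = ce,
                  total = cls + lam1 * dis + l2w * mmdv + lam3 * ce))
}

#' Train an SH-MDA model
#'
#' Full optimization loop. Per step, one batch of `M_b` samples is drawn
#' from every source domain and from the target; each source batch is
#' replaced by its hybrid sample set; the batches pass through the common
#' extractor, the gradient-reversed domain discriminator, and their branch
#' networks alongside the target batch; the weighted total of
#' classification, domain-discrimination, MMD and conditional-entropy
#' losses is minimized by one Adam step with the two learning-rate groups.
#' The MMD weight follows the [lambda2()] schedule of epoch progress.
#'
#' An epoch is `floor(min(domain sizes) / M_b)` steps; every domain is
#' independently reshuffled each epoch, and the target is resampled with
#' replacement if it is smaller than an epoch requires. Fully reproducible
#' from `config$seed`. The target's `labels` field must be empty and its
#' `eval_labels` field is never read here: pass `eval_labels` explicitly to
#' record a per-epoch accuracy trace.
#'
#' @param sources list of labeled [domain_dataset()]s (the `N` source
#'   domains).
#' @param target unlabeled [domain_dataset()].
#' @param config a [train_config()].
#' @param eval_labels optional integer labels for per-epoch target accuracy
#'   (diagnostics only; never used in optimization).
#' @return list of class `shmda_fit` with `model` and `history` (one row
#'   per epoch: loss components, `lambda2`, optional accuracy).
#' @export
train_shmda <- function(sources, target, config = train_config(),
                        eval_labels = NULL) {
  stopifnot(inherits(config, "train_config"), length(sources) >= 1L)
  for (s in sources)
    if (is.null(s$labels)) stop("every source domain must be labeled")
  if (!is.null(target$labels))
    stop("the target domain must be unlabeled (see strip_labels())")
  p <- ncol(sources[[1]]$features)
  if (ncol(target$features) != p ||
      any(vapply(sources, function(s) ncol(s$features), integer(1)) != p))
    stop("all domains must share one feature dimension")
  N <- length(sources)
  C <- max(vapply(sources, function(s) s$n_classes, integer(1)))
  Mb <- config$batch_size
  sizes <- vapply(sources, n_samples, integer(1))
  Mt <- n_samples(target)
  steps <- min(sizes, Mt) %/% Mb
  if (steps < 1L)
    stop(sprintf("smallest domain (%d samples) is below one batch (%d)",
                 min(sizes, Mt), Mb))

  model <- shmda_model(p, N, C, hidden = config$hidden,
                       branch_dim = config$branch_dim,
                       grl_lambda = config$grl_lambda,
                       disc_classes = N + as.integer(
                         isTRUE(config$discriminate_target) && N > 1L),
                       seed = derive_seed(config$seed, 2L))
  opt <- adam_init(model$params)
  use_mmd <- config$loss$use_mmd %||% TRUE

  history <- data.frame(epoch = seq_len(config$epochs), cls = NA_real_,
                        dis = NA_real_, mmd = NA_real_, ce = NA_real_,
                        total = NA_real_, lambda2 = NA_real_,
                        accuracy = NA_real_)

  set.seed(derive_seed(config$seed, 3L))
  for (epoch in seq_len(config$epochs)) {
    l2w <- if (use_mmd) lambda2(epoch / config$epochs) else 0
    src_ord <- lapply(sizes, sample.int)
    need <- steps * Mb
    tgt_idx <- if (Mt >= need) sample.int(Mt)[seq_len(need)]
    else sample.int(Mt, need, replace = TRUE)
    # pre-draw hybrid permutations so RNG use is identical across ablations
    perms <- lapply(seq_len(steps),
                    function(s) lapply(seq_len(N), function(i) sample.int(Mb)))

    ep_loss <- numeric(5)
    for (s in seq_len(steps)) {
      rows <- ((s - 1L) * Mb + 1L):(s * Mb)
      batches <- lapply(seq_len(N), function(i) {
        idx <- src_ord[[i]][rows]
        list(X = sources[[i]]$features[idx, , drop = FALSE],
             y = sources[[i]]$labels[idx])
      })
      tX <- target$features[tgt_idx[rows], , drop = FALSE]
      st <- shmda_step(model, batches, tX, config, l2w, perms[[s]])
      model <- st$model
      upd <- adam_step(model$params, st$grads, opt,
                       config$lr_common, config$lr_other)
      model$params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + st$losses
    }
    history[epoch, c("cls", "dis", "mmd", "ce", "total")] <- ep_loss / steps
    history$lambda2[epoch] <- l2w
    if (!is.null(eval_labels))
      history$accuracy[epoch] <-
        mean(predict_labels(model, target$features)$labels == eval_labels)
  }
  structure(list(model = model, history = history, config = config),
            class = "shmda_fit")
}

#' @export
print.shmda_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<shmda_fit> %d epochs | final losses: cls %.4f, dis %.4f, mmd %.4f, ce %.4f (total %.4f)\n",
    nrow(x$history), h$cls, h$dis, h$mmd, h$ce, h$total))
  invisible(x)
}
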