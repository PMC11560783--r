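#' Construct an SH-MDA network
#'
#' The network has three parts:
#' \itemize{
#'   \item a \emph{common feature extractor}: a three-layer MLP
#'     `input_dim -> 256 -> 128 -> 64` with a leaky rectifier
#'     (negative slope 0.01) after each affine map, producing
#'     domain-invariant features;
#'   \item a \emph{domain discriminator}: two affine layers `64 -> 32 -> N`
#'     with a leaky rectifier between and a softmax over the `N` source
#'     domains, fed through a gradient reversal layer so its training
#'     signal is adversarial for the common extractor;
#'   \item `N` \emph{branch networks}, one per source domain: a branch
#'     feature extractor (affine `64 -> 32`, batch normalization with
#'     `eps = 1e-5`, leaky rectifier) and a branch task classifier (affine
#'     `32 -> C`, softmax).
#' }
#' Weights use He fan-in initialization from the supplied seed.
#'
#' @param input_dim flattened feature dimension (310 for 62 channels x 5
#'   bands; synthetic benchmarks may use fewer).
#' @param n_domains number of source domains `N` (>= 1).
#' @param n_classes number of emotion categories `C` (>= 2).
#' @param hidden widths of the common extractor layers.
#' @param branch_dim width of the branch feature extractors.
#' @param grl_lambda gradient-reversal coefficient (default 0.8).
#' @param disc_classes number of discriminator outputs; defaults to
#'   `n_domains` (hybrid sets only). `n_domains + 1` adds a class for
#'   target-domain features when the discriminator is trained on them too.
#' @param seed RNG seed for initialization.
#' @return an object of class `shmda_model` with elements `params`
#'   (trainable parameters), `bn` (per-branch batch-norm running
#'   statistics) and `arch`.
#' @export
shmda_model <- function(input_dim, n_domains, n_classes,
                        hidden = c(256L, 128L, 64L), branch_dim = 32L,
                        grl_lambda = 0.8, disc_classes = n_domains,
                        seed = 1L) {
  stopifnot(n_domains >= 1L, n_classes >= 2L, length(hidden) >= 1L,
            disc_classes >= n_domains)
  set.seed(derive_seed(seed, 11L))
  dims <- c(input_dim, hidden)
  common <- lapply(seq_len(length(dims) - 1L),
                   function(i) init_linear(dims[i], dims[i + 1L]))
  f_dim <- dims[length(dims)]
  disc <- list(l1 = init_linear(f_dim, branch_dim),
               l2 = init_linear(branch_dim, disc_classes))
  branches <- lapply(seq_len(n_domains), function(i) {
    list(fe = init_linear(f_dim, branch_dim),
         bn = init_batchnorm(branch_dim),
         cl = init_linear(branch_dim, n_classes))
  })
  structure(
    list(params = list(common = common, disc = disc, branches = branches),
         bn = lapply(seq_len(n_domains),
                     function(i) init_batchnorm_state(branch_dim)),
         arch = list(input_dim = as.integer(input_dim),
                     n_domains = as.integer(n_domains),
                     n_classes = as.integer(n_classes),
                     hidden = as.integer(hidden),
                     branch_dim = as.integer(branch_dim),
                     disc_classes = as.integer(disc_classes),
                     grl_lambda = grl_lambda, slope = 0.01, seed = seed)),
    class = "shmda_model")
}

#' @export
print.shmda_model <- function(x, ...) {
  a <- x$arch
  cat(sprintf(
    "<shmda_model> common %s | discriminator %d->%d->%d (GRL lambda=%g) | %d branches %d->%d->%d\n",
    paste(c(a$input_dim, a$hidden), collapse = "->"),
    a$hidden[length(a$hidden)], a$branch_dim, a$disc_classes, a$grl_lambda,
    a$n_domains, a$hidden[length(a$hidden)], a$branch_dim, a$n_classes))
  invisible(x)
}

check_input_dim <- function(X, expected, what = "input") {
  if (ncol(X) != expected)
    stop(sprintf("%s dimension mismatch: expected %d, got %d",
                 what, expected, ncol(X)))
}

#' Common feature extractor forward pass
#'
#' Maps a batch of flattened feature samples to 64-d domain-invariant
#' features. Deterministic (no dropout, no normalization in this block).
#'
#' @param X `n x input_dim` matrix.
#' @param model an [shmda_model()].
#' @return list with `out` (`n x 64` features) and `cache` (for backprop).
#' @export
common_forward <- function(X, model) {
  X <- as.matrix(X)
  check_input_dim(X, model$arch$input_dim)
  slope <- model$arch$slope
  cache <- vector("list", length(model$params$common))
  out <- X
  for (i in seq_along(model$params$common)) {
    lf <- linear_forward(out, model$params$common[[i]])
    af <- lrelu_forward(lf$out, slope)
    cache[[i]] <- list(lin = lf, act = af)
    out <- af$out
  }
  list(out = out, cache = cache)
}

common_backward <- function(dY, cache, model) {
  slope <- model$arch$slope
  grads <- vector("list", length(cache))
  for (i in rev(seq_along(cache))) {
    dY <- lrelu_backward(dY, cache[[i]]$act, slope)
    lb <- linear_backward(dY, cache[[i]]$lin, model$params$common[[i]])
    grads[[i]] <- lb$grads
    dY <- lb$dX
  }
  list(grads = grads, dX = dY)
}

#' Gradient reversal layer
#'
#' Identity on the forward pass; on the backward pass the upstream gradient
#' is the downstream gradient multiplied by `-lambda_grl`, which turns the
#' domain discriminator's minimization into an adversarial signal for the
#' common extractor. [grl_forward()] and [grl_backward()] expose the two
#' halves of the contract explicitly.
#'
#' @param f feature matrix (forward) or gradient matrix (backward).
#' @param lambda_grl non-negative reversal coefficient.
#' @return `grl_forward`: `f` unchanged; `grl_backward`: `-lambda_grl * f`.
#' @export
grl_forward <- function(f, lambda_grl) {
  stopifnot(lambda_grl >= 0)
  f
}

#' @rdname grl_forward
#' @export
grl_backward <- function(f, lambda_grl) {
  stopifnot(lambda_grl >= 0)
  -lambda_grl * f
}

#' Domain discriminator forward pass
#'
#' @param f_I `n x 64` domain-invariant features.
#' @param model an [shmda_model()].
#' @return list with `probs` (`n x N` softmax domain probabilities) and
#'   `cache`.
#' @export
discriminator_forward <- function(f_I, model) {
  f_I <- as.matrix(f_I)
  check_input_dim(f_I, model$arch$hidden[length(model$arch$hidden)],
                  "discriminator input")
  slope <- model$arch$slope
  l1 <- linear_forward(f_I, model$params$disc$l1)
  a1 <- lrelu_forward(l1$out, slope)
  l2 <- linear_forward(a1$out, model$params$disc$l2)
  list(probs = softmax_rows(l2$out), cache = list(l1 = l1, a1 = a1, l2 = l2))
}

# dZ is the gradient w.r.t. the pre-softmax logits
discriminator_backward <- function(dZ, cache, model) {
  slope <- model$arch$slope
  b2 <- linear_backward(dZ, cache$l2, model$params$disc$l2)
  dA <- lrelu_backward(b2$dX, cache$a1, slope)
  b1 <- linear_backward(dA, cache$l1, model$params$disc$l1)
  list(grads = list(l1 = b1$grads, l2 = b2$grads), dX = b1$dX)
}

#' Branch network forward pass
#'
#' Runs the `i`-th branch feature extractor (affine, batch normalization,
#' leaky rectifier) and task classifier (affine, softmax). In train mode
#' batch normalization uses batch statistics and updates the running
#' statistics; in eval mode it uses the stored running statistics, so two
#' eval passes on the same input are identical.
#'
#' @param f_I `n x 64` domain-invariant features.
#' @param i branch index in `1..N`.
#' @param model an [shmda_model()].
#' @param mode `"train"` or `"eval"`.
#' @return list with `f_S` (`n x 32` domain-specific features), `probs`
#'   (`n x C` class probabilities), `cache`, and `bn_state` (updated
#'   running statistics; callers in train mode must store it back).
#' @export
branch_forward <- function(f_I, i, model, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (i < 1L || i > model$arch$n_domains)
    stop(sprintf("invalid branch index %d (N = %d)", i, model$arch$n_domains))
  f_I <- as.matrix(f_I)
  check_input_dim(f_I, model$arch$hidden[length(model$arch$hidden)],
                  "branch input")
  slope <- model$arch$slope
  br <- model$params$branches[[i]]
  l1 <- linear_forward(f_I, br$fe)
  bnf <- batchnorm_forward(l1$out, br$bn, model$bn[[i]], mode)
  a1 <- lrelu_forward(bnf$out, slope)
  cl <- linear_forward(a1$out, br$cl)
  list(f_S = a1$out, probs = softmax_rows(cl$out),
       cache = list(l1 = l1, bnf = bnf, a1 = a1, cl = cl),
       bn_state = bnf$state)
}

# d_logits: gradient w.r.t. classifier logits; d_fS: extra gradient arriving
# directly at f_S (e.g. from the MMD term). Returns branch param grads + dX.
branch_backward <- function(d_logits, d_fS, cache, i, model) {
  slope <- model$arch$slope
  br <- model$params$branches[[i]]
  bc <- linear_backward(d_logits, cache$cl, br$cl)
  dfS <- bc$dX + d_fS
  dbn_out <- lrelu_backward(dfS, cache$a1, slope)
  bb <- batchnorm_backward(dbn_out, cache$bnf, br$bn)
  b1 <- linear_backward(bb$dX, cache$l1, br$fe)
  list(grads = list(fe = b1$grads, bn = bb$grads, cl = bc$grads),
       dX = b1$dX)
}

#' Predict target emotion labels
#'
#' Runs the common extractor and all `N` branches in eval mode and averages
#' the `N` class-probability distributions; the predicted label is the
#' argmax of the average (ties broken by lowest class index).
#'
#' @param model a trained [shmda_model()].
#' @param X `n x input_dim` feature matrix.
#' @return list with `probs` (`n x C` averaged probabilities) and `labels`
#'   (integer predictions in `0..C-1`).
#' @export
predict_labels <- function(model, X) {
  f_I <- common_forward(X, model)$out
  N <- model$arch$n_domains
  probs <- 0
  for (i in seq_len(N))
    probs <- probs + branch_forward(f_I, i, model, "eval")$probs
  probs <- probs / N
  list(probs = probs, labels = max.col(probs, ties.method = "first") - 1L)
}
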