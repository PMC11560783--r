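#' Synthetic multi-domain benchmark configuration
#'
#' Describes a family of labeled source domains plus one unlabeled target
#' domain with class-conditional Gaussian clusters and controlled per-domain
#' distribution shift. The defaults define the package's standard synthetic
#' benchmark: 4 source domains, 3 classes, 200 samples per class and domain,
#' class separation 3, domain shift 1, unit noise.
#'
#' @param n_source_domains number of labeled source domains `N`.
#' @param n_classes number of classes `C`.
#' @param samples_per_class samples per class in every domain.
#' @param feature_dim feature dimensionality `p` (must be `>= n_classes` so
#'   the class means fit on orthogonal axes).
#' @param class_separation Euclidean distance between any two class means.
#' @param domain_shift magnitude of the per-domain affine perturbation:
#'   scales both the random rotation away from identity and the norm of a
#'   random translation.
#' @param noise_sd isotropic within-class standard deviation.
#' @param seed root seed; every domain draws from a derived stream.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_source_domains = 4L, n_classes = 3L,
                              samples_per_class = 200L, feature_dim = 20L,
                              class_separation = 3, domain_shift = 1,
                              noise_sd = 1, seed = 1L) {
  cfg <- list(n_source_domains = as.integer(n_source_domains),
              n_classes = as.integer(n_classes),
              samples_per_class = as.integer(samples_per_class),
              feature_dim = as.integer(feature_dim),
              class_separation = class_separation,
              domain_shift = domain_shift,
              noise_sd = noise_sd, seed = as.integer(seed))
  with(cfg, {
    if (n_source_domains < 1L || n_classes < 2L || samples_per_class < 1L ||
        feature_dim < 1L)
      stop("all counts must be positive (and n_classes >= 2)")
    if (class_separation < 0 || domain_shift < 0 || noise_sd < 0)
      stop("separation, shift and noise_sd must be >= 0")
  })
  structure(cfg, class = "simulation_config")
}

# Random rotation of controlled magnitude: Cayley transform
# R = (I - s/2 A)^{-1} (I + s/2 A) of a random skew-symmetric direction A
# normalized to unit spectral norm. R is exactly orthogonal, equals the
# identity at s = 0, and rotates its principal plane by 2 * atan(s / 2)
# (~53 degrees at s = 1), with the remaining planes rotated less. So
# `shift` sets the rotation magnitude on a unit scale: marginals move
# measurably while class geometry stays recoverable -- the covariate-shift
# regime domain adaptation addresses.
random_rotation <- function(p, shift) {
  if (shift == 0) return(diag(p))
  G <- matrix(stats::rnorm(p * p), p, p)
  A <- (G - t(G)) / 2
  A <- A / max(svd(A, nu = 0, nv = 0)$d)
  solve(diag(p) - (shift / 2) * A, diag(p) + (shift / 2) * A)
}

#' Generate a synthetic multi-domain benchmark
#'
#' Draws class-conditional isotropic Gaussian clusters around shared class
#' means (pairwise distance `class_separation`, placed on orthogonal axes),
#' then applies to each domain -- every source and the target alike -- its
#' own random affine map: a rotation scaled away from identity by
#' `domain_shift` plus a translation of norm `domain_shift`. This mimics the
#' subject-to-subject shift regime domain adaptation addresses: class
#' geometry is preserved within each domain while marginals move between
#' domains.
#'
#' Target ground truth is returned in the evaluation-only `eval_labels`
#' field; the target's `labels` field is `NULL`, so training code cannot
#' read it. Fully reproducible from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with elements `sources` (list of labeled
#'   [domain_dataset()]s) and `target` (unlabeled dataset carrying
#'   `eval_labels`).
#' @export
generate_domains <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  p <- config$feature_dim; C <- config$n_classes
  if (p < C)
    stop("feature_dim < n_classes: class means cannot be placed on orthogonal axes")
  npc <- config$samples_per_class
  # orthogonal-axis class means with pairwise distance = class_separation
  a <- config$class_separation / sqrt(2)
  mu <- matrix(0, C, p)
  mu[cbind(seq_len(C), seq_len(C))] <- a

  make_domain <- function(k, id, labeled) {
    set.seed(derive_seed(config$seed, k))
    Q <- random_rotation(p, config$domain_shift)
    tr <- stats::rnorm(p)
    tr <- config$domain_shift * tr / sqrt(sum(tr^2))
    X <- do.call(rbind, lapply(seq_len(C), function(c) {
      sweep(matrix(stats::rnorm(npc * p, sd = config$noise_sd), npc, p),
            2L, mu[c, ], "+")
    }))
    y <- rep.int(0:(C - 1L), rep.int(npc, C))
    X <- X %*% t(Q) + matrix(tr, nrow(X), p, byrow = TRUE)
    domain_dataset(X,
                   labels = if (labeled) y else NULL,
                   eval_labels = if (labeled) NULL else y,
                   domain_id = id, n_classes = C)
  }

  N <- config$n_source_domains
  sources <- lapply(seq_len(N), function(k) make_domain(k, k, labeled = TRUE))
  target <- make_domain(N + 1L, "target", labeled = FALSE)
  list(sources = sources, target = target)
}

#' Inject class confusion into a target dataset
#'
#' Moves a fraction of one class's samples toward the other class's
#' empirical mean (full displacement by the mean difference), emulating a
#' pair of genuinely confusable emotion categories. Exactly
#' `floor(overlap * n)` samples of `confusion[1]` are displaced; at
#' `overlap = 1` the two clusters coincide.
#'
#' @param target a [domain_dataset()] with `eval_labels` (or labels).
#' @param confusion length-2 vector of class ids `(from, toward)`.
#' @param overlap fraction in `[0, 1]` of `from`-class samples to displace.
#' @param seed seed for choosing which samples move.
#' @return the modified dataset.
#' @export
inject_label_structure <- function(target, confusion, overlap, seed = 1L) {
  stopifnot(inherits(target, "domain_dataset"),
            length(confusion) == 2L, overlap >= 0, overlap <= 1)
  lab <- target$eval_labels %||% target$labels
  if (is.null(lab)) stop("target carries no labels to structure")
  if (!all(confusion %in% lab))
    stop(sprintf("unknown class id(s): %s",
                 paste(setdiff(confusion, lab), collapse = ", ")))
  if (overlap == 0) return(target)
  i_from <- which(lab == confusion[1])
  i_to <- which(lab == confusion[2])
  k <- floor(overlap * length(i_from))
  if (k == 0L) return(target)
  set.seed(derive_seed(seed, 97L))
  moved <- if (k == length(i_from)) i_from else sample(i_from, k)
  delta <- colMeans(target$features[i_to, , drop = FALSE]) -
    colMeans(target$features[i_from, , drop = FALSE])
  target$features[moved, ] <- sweep(target$features[moved, , drop = FALSE],
                                    2L, delta, "+")
  target
}
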