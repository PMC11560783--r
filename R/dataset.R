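#' Domain dataset
#'
#' A set of feature samples from one domain (one subject-session, or one
#' synthetic domain). Features are stored as an `n x p` matrix of flattened
#' channels x bands values; `p = m * d`.
#'
#' Labels are optional: a labeled dataset carries integer emotion ids in
#' `0..C-1`; the unlabeled target domain carries `labels = NULL`. Ground
#' truth for a synthetic target lives in the separate `eval_labels` field,
#' which training code never reads -- it exists purely for scoring.
#'
#' @param features numeric `n x p` matrix, all entries finite.
#' @param labels integer vector of length `n` in `0..C-1`, or `NULL`.
#' @param domain_id domain identifier.
#' @param m,d channels and bands factorization of `p` (optional; defaults to
#'   `p x 1`).
#' @param n_classes number of emotion categories `C`; inferred from labels
#'   when omitted.
#' @param eval_labels held-out ground-truth labels for evaluation only.
#' @param subject,session optional identifiers.
#' @return an object of class `domain_dataset`.
#' @export
domain_dataset <- function(features, labels = NULL, domain_id = 1L,
                           m = NULL, d = NULL, n_classes = NULL,
                           eval_labels = NULL, subject = NA, session = NA) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (nrow(features) > 0L && !all(is.finite(features)))
    stop("features must be finite")
  if (is.null(m)) { m <- ncol(features); d <- 1L }
  if (m * d != ncol(features))
    stop(sprintf("m * d = %d does not match feature dimension %d",
                 m * d, ncol(features)))
  check_lab <- function(lab, what) {
    if (is.null(lab)) return(NULL)
    lab <- as.integer(lab)
    if (length(lab) != nrow(features))
      stop(sprintf("%s length %d != number of samples %d",
                   what, length(lab), nrow(features)))
    if (any(lab < 0L)) stop(sprintf("%s must be non-negative class ids", what))
    lab
  }
  labels <- check_lab(labels, "labels")
  eval_labels <- check_lab(eval_labels, "eval_labels")
  if (is.null(n_classes)) {
    known <- c(labels, eval_labels)
    n_classes <- if (length(known)) max(known) + 1L else NA_integer_
  }
  if (!is.na(n_classes) && !is.null(labels) && any(labels >= n_classes))
    stop("labels must lie in 0..C-1")
  structure(
    list(features = features, labels = labels, domain_id = domain_id,
         m = as.integer(m), d = as.integer(d),
         n_classes = as.integer(n_classes), eval_labels = eval_labels,
         subject = subject, session = session),
    class = "domain_dataset")
}

#' @export
print.domain_dataset <- function(x, ...) {
  cat(sprintf("<domain_dataset> domain %s: %d samples x %d features (%d ch x %d bands), %s\n",
              as.character(x$domain_id), nrow(x$features), ncol(x$features),
              x$m, x$d,
              if (is.null(x$labels)) "unlabeled" else
                sprintf("%d classes", x$n_classes)))
  invisible(x)
}

#' Number of samples in a domain dataset
#' @param dataset a [domain_dataset()].
#' @return integer sample count.
#' @export
n_samples <- function(dataset) nrow(dataset$features)

#' Strip labels from a dataset
#'
#' Returns an unlabeled copy, moving any training labels into `eval_labels`
#' so protocols can score predictions while the training loop sees an
#' unlabeled target.
#'
#' @param dataset a [domain_dataset()].
#' @return the unlabeled dataset.
#' @export
strip_labels <- function(dataset) {
  if (!is.null(dataset$labels)) {
    dataset$eval_labels <- dataset$labels
    dataset$labels <- NULL
  }
  dataset
}
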