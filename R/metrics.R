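#' Classification metrics
#'
#' Accuracy, macro-averaged sensitivity (recall), specificity and F1, all
#' one-vs-rest, plus the `C x C` confusion matrix (rows = truth, columns =
#' prediction). A class absent from the truth has undefined recall/F1 and
#' is excluded from the macro means with a warning.
#'
#' @param truth,pred integer label vectors in `0..C-1`, equal length.
#' @param n_classes number of classes `C`.
#' @return an object of class `metric_report` with fields `accuracy`,
#'   `sensitivity`, `specificity`, `f1`, `confusion`, `per_class` and `n`.
#' @export
compute_metrics <- function(truth, pred, n_classes) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  C <- as.integer(n_classes)
  if (any(c(truth, pred) < 0L) || any(c(truth, pred) >= C))
    stop("labels out of range 0..C-1")
  n <- length(truth)
  lv <- 0:(C - 1L)
  confusion <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  confusion <- matrix(as.integer(confusion), C, C,
                      dimnames = list(truth = lv, pred = lv))

  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp
  fp <- colSums(confusion) - tp
  tn <- n - tp - fn - fp
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  specificity <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  f1 <- ifelse(!is.na(recall) & !is.na(precision) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall),
               ifelse(is.na(recall), NA_real_, 0))
  present <- rowSums(confusion) > 0
  if (!all(present))
    warning(sprintf("class(es) %s absent from truth; excluded from macro means",
                    paste(lv[!present], collapse = ", ")))
  structure(
    list(accuracy = sum(tp) / n,
         sensitivity = mean(recall[present]),
         specificity = mean(specificity[present]),
         f1 = mean(f1[present]),
         confusion = confusion,
         per_class = data.frame(class = lv, recall = recall,
                                precision = precision,
                                specificity = specificity, f1 = f1),
         n = n),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> n = %d | accuracy %.2f%% | sensitivity %.2f%% | specificity %.2f%% | F1 %.2f%%\n",
    x$n, 100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity,
    100 * x$f1))
  invisible(x)
}

#' Aggregate metric reports across tasks
#'
#' Mean and population (divide-by-n) standard deviation of the per-task
#' accuracies, macro means of the other rates, and the pooled confusion
#' matrix (element-wise sum over tasks).
#'
#' @param reports list of [compute_metrics()] reports.
#' @return list with `mean_accuracy`, `sd_accuracy`, `mean_sensitivity`,
#'   `mean_specificity`, `mean_f1`, `pooled_confusion`,
#'   `pooled` (a [compute_metrics()]-style report recomputed from the
#'   pooled confusion counts) and `accuracies`.
#' @export
aggregate_reports <- function(reports) {
  stopifnot(length(reports) >= 1L)
  acc <- vapply(reports, `[[`, numeric(1), "accuracy")
  pooled_conf <- Reduce(`+`, lapply(reports, `[[`, "confusion"))
  n <- sum(pooled_conf)
  tp <- diag(pooled_conf)
  fn <- rowSums(pooled_conf) - tp
  fp <- colSums(pooled_conf) - tp
  tn <- n - tp - fn - fp
  recall <- tp / pmax(tp + fn, 1)
  precision <- tp / pmax(tp + fp, 1)
  list(mean_accuracy = mean(acc),
       sd_accuracy = sqrt(mean((acc - mean(acc))^2)),
       mean_sensitivity = mean(vapply(reports, `[[`, numeric(1), "sensitivity")),
       mean_specificity = mean(vapply(reports, `[[`, numeric(1), "specificity")),
       mean_f1 = mean(vapply(reports, `[[`, numeric(1), "f1")),
       pooled_confusion = pooled_conf,
       pooled = list(accuracy = sum(tp) / n,
                     sensitivity = mean(recall),
                     specificity = mean(tn / pmax(tn + fp, 1)),
                     f1 = mean(2 * precision * recall /
                                 pmax(precision + recall, 1e-12))),
       accuracies = acc)
}
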