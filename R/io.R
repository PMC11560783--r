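#' Write a feature dataset to CSV
#'
#' Flat full-precision CSV: metadata columns (`domain_id`, `subject`,
#' `session`, and `label` if the dataset is labeled) followed by one
#' column per flattened channel x band feature. Feature values round-trip
#' losslessly (written with 17 significant digits, enough to reconstruct
#' every double exactly).
#'
#' @param dataset a [domain_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_features <- function(dataset, path) {
  stopifnot(inherits(dataset, "domain_dataset"))
  X <- dataset$features
  if (is.null(colnames(X)))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  meta <- data.table::data.table(
    domain_id = rep(as.character(dataset$domain_id), nrow(X)),
    subject = rep(as.character(dataset$subject), nrow(X)),
    session = rep(as.character(dataset$session), nrow(X)))
  if (!is.null(dataset$labels)) meta$label <- dataset$labels
  Xc <- data.table::as.data.table(
    matrix(sprintf("%.17g", X), nrow(X), ncol(X),
           dimnames = list(NULL, colnames(X))))
  dt <- cbind(meta, Xc)
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' Read a feature dataset from CSV
#'
#' Inverse of [write_features()]. A file without a `label` column yields
#' an unlabeled dataset. Any column not in the metadata set
#' (`domain_id`, `subject`, `session`, `label`) is treated as a feature.
#'
#' @param path CSV file path.
#' @param m,d optional channels x bands factorization of the feature
#'   columns.
#' @return a [domain_dataset()].
#' @export
read_features <- function(path, m = NULL, d = NULL) {
  dt <- data.table::fread(path)
  meta_cols <- intersect(c("domain_id", "subject", "session", "label"),
                         names(dt))
  feat_cols <- setdiff(names(dt), meta_cols)
  if (length(feat_cols) == 0L)
    stop("schema error: no feature columns found")
  X <- as.matrix(dt[, feat_cols, with = FALSE])
  if (!is.numeric(X)) stop("schema error: non-numeric feature columns")
  pick <- function(col, default) {
    if (col %in% meta_cols) dt[[col]][1] else default
  }
  domain_dataset(X,
                 labels = if ("label" %in% meta_cols) dt$label else NULL,
                 domain_id = pick("domain_id", 1L),
                 m = m, d = d,
                 subject = pick("subject", NA),
                 session = pick("session", NA))
}
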