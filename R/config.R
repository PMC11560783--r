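#' Default run configuration
#'
#' The nested configuration consumed by [load_config()] and the command
#' line front end. Every default with a published optimum uses it:
#' `hybrid$lambda = 0.8` (0.6 recommended for cross-session runs),
#' `loss$lambda1 = loss$lambda3 = 0.1`, `model$grl_lambda = 0.8`,
#' `train$batch_size = 64`, learning rates 5e-4 (common extractor) and
#' 5e-3 (elsewhere).
#'
#' @return nested named list of class `shmda_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    features = list(window_seconds = 1, bands = "default"),
    hybrid = list(lambda = 0.8, enabled = TRUE),
    model = list(hidden = c(256L, 128L, 64L), branch_dim = 32L,
                 grl_lambda = 0.8),
    loss = list(lambda1 = 0.1, lambda3 = 0.1, mmd_kernel = "linear",
                use_dis = TRUE, use_ce = TRUE),
    train = list(batch_size = 64L, epochs = 50L, lr_common = 5e-4,
                 lr_other = 5e-3)),
    class = "shmda_config")
}

check_config_keys <- function(cfg, ref, path = "") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s",
                 paste0(path, unknown, collapse = ", ")))
  for (nm in names(cfg)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])))
      check_config_keys(as.list(cfg[[nm]]), ref[[nm]], paste0(path, nm, "."))
  }
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

validate_config <- function(cfg) {
  with(cfg, {
    if (hybrid$lambda < 0 || hybrid$lambda > 1)
      stop("hybrid.lambda must lie in [0, 1]")
    if (model$grl_lambda < 0) stop("model.grl_lambda must be >= 0")
    if (loss$lambda1 < 0 || loss$lambda3 < 0)
      stop("loss weights must be >= 0")
    if (!loss$mmd_kernel %in% c("linear", "rbf"))
      stop("loss.mmd_kernel must be 'linear' or 'rbf'")
    if (train$batch_size < 2L) stop("train.batch_size must be >= 2")
    if (train$epochs < 1L) stop("train.epochs must be >= 1")
    if (train$lr_common <= 0 || train$lr_other <= 0)
      stop("learning rates must be > 0")
    if (features$window_seconds <= 0)
      stop("features.window_seconds must be > 0")
  })
  invisible(cfg)
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON, a YAML subset) file, fills unset keys with
#' [default_config()] values, rejects unknown keys, and validates ranges.
#' An empty file yields the full default configuration.
#'
#' @param path file path.
#' @return a validated `shmda_config`.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  base <- default_config()
  check_config_keys(user, base)
  cfg <- merge_config(base, user)
  class(cfg) <- "shmda_config"
  validate_config(cfg)
  cfg
}

#' Save a run configuration
#'
#' Writes the fully resolved configuration as YAML next to run outputs so
#' every run is reproducible from its echo.
#'
#' @param cfg a `shmda_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Build a [train_config()] from a run configuration
#'
#' @param cfg a `shmda_config` (see [default_config()]).
#' @return a [train_config()].
#' @export
as_train_config <- function(cfg) {
  validate_config(cfg)
  train_config(batch_size = cfg$train$batch_size,
               epochs = cfg$train$epochs,
               lr_common = cfg$train$lr_common,
               lr_other = cfg$train$lr_other,
               hybrid_lambda = cfg$hybrid$lambda,
               hybrid_enabled = cfg$hybrid$enabled,
               grl_lambda = cfg$model$grl_lambda,
               hidden = cfg$model$hidden,
               branch_dim = cfg$model$branch_dim,
               loss = loss_config(lambda1 = cfg$loss$lambda1,
                                  lambda3 = cfg$loss$lambda3,
                                  mmd_kernel = cfg$loss$mmd_kernel,
                                  use_dis = cfg$loss$use_dis,
                                  use_ce = cfg$loss$use_ce),
               seed = cfg$seed)
}
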