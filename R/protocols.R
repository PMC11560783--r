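# Evaluation protocols: leave-one-subject-out, cross-session, ablations,
# and the no-adaptation baseline they are compared against.

fit_and_score <- function(sources, target_labeled, config) {
  truth <- target_labeled$labels %||% target_labeled$eval_labels
  if (is.null(truth)) stop("target carries no ground truth to score against")
  fit <- train_shmda(sources, strip_labels(target_labeled), config)
  pred <- predict_labels(fit$model, target_labeled$features)
  C <- max(fit$model$arch$n_classes, max(truth) + 1L)
  list(fit = fit, report = compute_metrics(truth, pred$labels, C))
}

#' Leave-one-subject-out cross-subject evaluation
#'
#' Within each session, every subject in turn becomes the unlabeled target
#' domain and the remaining `k - 1` subjects are the labeled sources. A
#' subject's accuracy is the mean over sessions; the final result is the
#' mean (and population sd) over subjects. A subject missing from a
#' session is skipped with a warning.
#'
#' @param sessions named list of sessions; each session is a named list of
#'   labeled [domain_dataset()]s, one per subject (names identify
#'   subjects across sessions).
#' @param config a [train_config()]; each task derives its own seed from
#'   `config$seed` so tasks are independent but reproducible.
#' @return list with `tasks` (per session x subject: report + accuracy),
#'   `subject_accuracy`, `mean_accuracy`, `sd_accuracy`, and `summary`
#'   (an [aggregate_reports()] over all tasks).
#' @export
loso_cross_subject <- function(sessions, config = train_config()) {
  stopifnot(length(sessions) >= 1L)
  subjects <- unique(unlist(lapply(sessions, names)))
  if (length(subjects) < 2L) stop("LOSO needs at least 2 subjects")
  tasks <- list()
  task_id <- 0L
  for (sn in names(sessions)) {
    sess <- sessions[[sn]]
    for (subj in subjects) {
      if (is.null(sess[[subj]])) {
        warning(sprintf("subject %s missing from session %s: task skipped",
                        subj, sn))
        next
      }
      task_id <- task_id + 1L
      cfg <- config
      cfg$seed <- derive_seed(config$seed, task_id)
      res <- fit_and_score(sess[names(sess) != subj], sess[[subj]], cfg)
      tasks[[length(tasks) + 1L]] <-
        list(session = sn, subject = subj, report = res$report,
             accuracy = res$report$accuracy,
             n_sources = length(sess) - 1L)
    }
  }
  subj_acc <- vapply(subjects, function(s) {
    mean(vapply(Filter(function(t) t$subject == s, tasks),
                `[[`, numeric(1), "accuracy"))
  }, numeric(1))
  list(tasks = tasks,
       subject_accuracy = subj_acc,
       mean_accuracy = mean(subj_acc),
       sd_accuracy = sqrt(mean((subj_acc - mean(subj_acc))^2)),
       summary = aggregate_reports(lapply(tasks, `[[`, "report")))
}

#' Cross-session evaluation for one subject
#'
#' Each session serves as the unlabeled target once, with the remaining
#' sessions as labeled sources. Reports per-target-session accuracy and
#' the mean. With the default configuration consider setting
#' `hybrid_lambda = 0.6`, the recommended value for this protocol.
#'
#' @param subject_sessions list of at least 2 labeled [domain_dataset()]s,
#'   the sessions of one subject.
#' @param config a [train_config()].
#' @return list with `tasks` (per target session), `session_accuracy` and
#'   `mean_accuracy`.
#' @export
cross_session <- function(subject_sessions, config = train_config(hybrid_lambda = 0.6)) {
  k <- length(subject_sessions)
  if (k < 2L) stop("cross-session evaluation needs at least 2 sessions")
  if (is.null(names(subject_sessions)))
    names(subject_sessions) <- paste0("session", seq_len(k))
  tasks <- lapply(seq_len(k), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 300L + i)
    res <- fit_and_score(subject_sessions[-i], subject_sessions[[i]], cfg)
    list(target_session = names(subject_sessions)[i], report = res$report,
         accuracy = res$report$accuracy, n_sources = k - 1L)
  })
  acc <- vapply(tasks, `[[`, numeric(1), "accuracy")
  names(acc) <- names(subject_sessions)
  list(tasks = tasks, session_accuracy = acc, mean_accuracy = mean(acc))
}

ablation_variants <- function(config) {
  list(
    full = config,
    wo_ce = within_config(config, loss = loss_config(
      lambda1 = config$loss$lambda1, lambda3 = config$loss$lambda3,
      mmd_kernel = config$loss$mmd_kernel, use_dis = config$loss$use_dis,
      use_ce = FALSE)),
    wo_hybrid = within_config(config, hybrid_enabled = FALSE),
    wo_dis = within_config(config, loss = loss_config(
      lambda1 = config$loss$lambda1, lambda3 = config$loss$lambda3,
      mmd_kernel = config$loss$mmd_kernel, use_dis = FALSE,
      use_ce = config$loss$use_ce)),
    wo_ce_hybrid = within_config(
      within_config(config, hybrid_enabled = FALSE),
      loss = loss_config(
        lambda1 = config$loss$lambda1, lambda3 = config$loss$lambda3,
        mmd_kernel = config$loss$mmd_kernel, use_dis = config$loss$use_dis,
        use_ce = FALSE)))
}

within_config <- function(config, ...) {
  mods <- list(...)
  for (nm in names(mods)) config[[nm]] <- mods[[nm]]
  config
}

#' Ablation study
#'
#' Trains five variants under identical seeds and data order and reports
#' the target accuracy of each: the full model; without the
#' conditional-entropy loss; without sample hybridization (raw source
#' batches); without the domain-discrimination loss; and without both
#' conditional entropy and hybridization.
#'
#' @param sources list of labeled [domain_dataset()]s.
#' @param target unlabeled [domain_dataset()] carrying `eval_labels` (or a
#'   labeled dataset).
#' @param config a [train_config()].
#' @return data.frame with columns `variant` and `accuracy`.
#' @export
run_ablation <- function(sources, target, config = train_config()) {
  variants <- ablation_variants(config)
  acc <- vapply(variants, function(cfg) {
    fit_and_score(sources, target, cfg)$report$accuracy
  }, numeric(1))
  data.frame(variant = names(variants), accuracy = unname(acc))
}

#' Pool source domains into one dataset
#'
#' Concatenates the samples of several labeled domains, discarding domain
#' structure.
#'
#' @param sources list of labeled [domain_dataset()]s.
#' @return one labeled [domain_dataset()].
#' @export
pool_sources <- function(sources) {
  domain_dataset(do.call(rbind, lapply(sources, function(s) s$features)),
                 labels = unlist(lapply(sources, function(s) s$labels)),
                 domain_id = "pooled",
                 n_classes = max(vapply(sources, function(s) s$n_classes,
                                        integer(1))))
}

#' No-adaptation pooled-source baseline
#'
#' The standard source-only comparison point: all source domains are pooled
#' into a single labeled dataset and the same network (one branch, since
#' there is one pooled domain) is trained with every adaptation mechanism
#' off -- no hybridization, no domain discriminator, no MMD, no
#' conditional entropy -- so the target is never seen during training.
#'
#' @param sources list of labeled [domain_dataset()]s.
#' @param target unlabeled [domain_dataset()] with `eval_labels` (or
#'   labeled).
#' @param config a [train_config()].
#' @return the [compute_metrics()] report on the target.
#' @export
no_adaptation_baseline <- function(sources, target, config = train_config()) {
  cfg <- within_config(config,
                       hybrid_enabled = FALSE,
                       loss = loss_config(mmd_kernel = config$loss$mmd_kernel,
                                          use_dis = FALSE, use_ce = FALSE,
                                          use_mmd = FALSE))
  fit_and_score(list(pool_sources(sources)), target, cfg)$report
}
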