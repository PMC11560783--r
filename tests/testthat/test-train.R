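test_that("training is bit-for-bit reproducible from the seed", {
  d <- tiny_domains(seed = 2L)
  cfg <- tiny_train_config(seed = 7L, epochs = 3L)
  a <- train_shmda(d$sources, d$target, cfg)
  b <- train_shmda(d$sources, d$target, cfg)
  expect_identical(a$history, b$history)
  expect_identical(a$model$params, b$model$params)
  expect_identical(a$model$bn, b$model$bn)
})

test_that("target labels cannot leak into training", {
  d <- tiny_domains(seed = 3L)
  cfg <- tiny_train_config(seed = 5L, epochs = 2L)
  a <- train_shmda(d$sources, d$target, cfg)
  permuted <- d$target
  permuted$eval_labels <- sample(permuted$eval_labels)
  b <- train_shmda(d$sources, permuted, cfg)
  expect_identical(a$model$params, b$model$params)
  expect_identical(a$history, b$history)
  # a labeled target is refused outright
  labeled <- d$target
  labeled$labels <- labeled$eval_labels
  expect_error(train_shmda(d$sources, labeled, cfg), "unlabeled")
})

test_that("the two learning-rate groups scale the first update as configured", {
  d <- tiny_domains(seed = 4L)
  cfg <- tiny_train_config(seed = 9L, epochs = 1L)
  cfg$epochs <- 1L
  # rebuild the initial model exactly as train_shmda does
  init <- shmda_model(ncol(d$sources[[1]]$features), length(d$sources), 3L,
                      hidden = cfg$hidden, branch_dim = cfg$branch_dim,
                      grl_lambda = cfg$grl_lambda,
                      seed = shmda:::derive_seed(cfg$seed, 2L))
  one_step <- cfg
  one_step$batch_size <- min(vapply(d$sources, n_samples, integer(1)))
  fit <- train_shmda(d$sources, d$target, one_step)
  # Adam's first step moves each coordinate by at most lr (and by ~lr
  # wherever the gradient is non-negligible)
  d_common <- shmda:::param_max_abs_diff(fit$model$params$common,
                                         init$params$common)
  d_disc <- shmda:::param_max_abs_diff(fit$model$params$disc,
                                       init$params$disc)
  expect_equal(d_common, cfg$lr_common, tolerance = 0.01)
  expect_equal(d_disc, cfg$lr_other, tolerance = 0.01)
})

test_that("separable data is learned: classification loss halves", {
  d <- tiny_domains(seed = 6L, domain_shift = 0, noise_sd = 0.5,
                    samples_per_class = 20L)
  cfg <- tiny_train_config(seed = 11L, epochs = 25L)
  fit <- train_shmda(d$sources, d$target, cfg,
                     eval_labels = d$target$eval_labels)
  h <- fit$history
  expect_lt(h$cls[nrow(h)], 0.5 * h$cls[1])
  expect_gt(h$accuracy[nrow(h)], 0.9)
})

test_that("lambda = 1 with all auxiliary weights zero reduces to supervised training", {
  d <- tiny_domains(seed = 8L)
  base <- tiny_train_config(seed = 13L, epochs = 2L)
  off <- loss_config(use_dis = FALSE, use_ce = FALSE, use_mmd = FALSE)
  cfg_hybrid1 <- shmda:::within_config(base, hybrid_lambda = 1,
                                       loss = off)
  cfg_plain <- shmda:::within_config(base, hybrid_enabled = FALSE,
                                     loss = off)
  a <- train_shmda(d$sources, d$target, cfg_hybrid1)
  b <- train_shmda(d$sources, d$target, cfg_plain)
  # identical sample sets per batch (order permuted, which every loss term
  # is invariant to), so the trajectories coincide up to float summation
  expect_equal(a$history$cls, b$history$cls, tolerance = 1e-6)
  expect_equal(shmda:::param_max_abs_diff(a$model$params, b$model$params),
               0, tolerance = 1e-6)
})

test_that("training validates its inputs", {
  d <- tiny_domains(seed = 10L)
  cfg <- tiny_train_config()
  unlabeled_src <- list(strip_labels(d$sources[[1]]))
  expect_error(train_shmda(unlabeled_src, d$target, cfg), "labeled")
  small <- tiny_train_config(batch_size = 512L)
  expect_error(train_shmda(d$sources, d$target, small), "below one batch")
  shrunk <- d$target
  shrunk$features <- shrunk$features[, 1:3]
  expect_error(train_shmda(d$sources, shrunk, cfg), "feature dimension")
})

test_that("target discrimination adds an (N+1)-th domain class when enabled", {
  d <- tiny_domains(seed = 20L)
  cfg <- tiny_train_config(seed = 27L, epochs = 2L,
                           discriminate_target = TRUE)
  fit <- train_shmda(d$sources, d$target, cfg)
  expect_equal(fit$model$arch$disc_classes, length(d$sources) + 1L)
  expect_equal(ncol(fit$model$params$disc$l2$W), length(d$sources) + 1L)
  # off by default: discriminator width N
  fit0 <- train_shmda(d$sources, d$target,
                      tiny_train_config(seed = 27L, epochs = 1L))
  expect_equal(fit0$model$arch$disc_classes, length(d$sources))
})

test_that("the lambda2 trace follows the epoch schedule", {
  d <- tiny_domains(seed = 12L)
  cfg <- tiny_train_config(seed = 15L, epochs = 4L)
  fit <- train_shmda(d$sources, d$target, cfg)
  expect_equal(fit$history$lambda2, lambda2((1:4) / 4))
})
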