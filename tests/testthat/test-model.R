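test_that("the common extractor maps 310-d inputs to 64-d features", {
  m <- shmda_model(310, n_domains = 4, n_classes = 3, seed = 1)
  X <- matrix(rnorm(5 * 310), 5)
  f <- common_forward(X, m)$out
  expect_equal(dim(f), c(5L, 64L))
  # eval-mode determinism: bit-identical repeat passes
  expect_identical(f, common_forward(X, m)$out)
  expect_error(common_forward(matrix(0, 2, 100), m), "expected 310, got 100")
})

test_that("zero parameters give zero common features and uniform posteriors", {
  m <- shmda_model(12, n_domains = 4, n_classes = 3, hidden = c(8, 6),
                   branch_dim = 4, seed = 2)
  m$params <- shmda:::param_zeros_like(m$params)
  X <- matrix(rnorm(3 * 12), 3)
  f <- common_forward(X, m)$out
  expect_true(all(f == 0))
  d <- discriminator_forward(f, m)$probs
  expect_equal(d, matrix(1 / 4, 3, 4))
})

test_that("discriminator and branch outputs live on the probability simplex", {
  m <- shmda_model(20, n_domains = 3, n_classes = 4, hidden = c(10, 6),
                   branch_dim = 5, seed = 3)
  X <- matrix(rnorm(7 * 20), 7)
  f <- common_forward(X, m)$out
  d <- discriminator_forward(f, m)$probs
  expect_equal(rowSums(d), rep(1, 7), tolerance = 1e-6)
  expect_true(all(d > 0 & d < 1))
  for (i in 1:3) {
    br <- branch_forward(f, i, m, "eval")
    expect_equal(ncol(br$probs), 4L)
    expect_equal(ncol(br$f_S), 5L)
    expect_equal(rowSums(br$probs), rep(1, 7), tolerance = 1e-6)
    expect_true(all(br$probs >= 0))
  }
  # 3-class configuration
  m3 <- shmda_model(20, n_domains = 2, n_classes = 3, hidden = c(10, 6),
                    branch_dim = 5, seed = 3)
  f3 <- common_forward(X, m3)$out
  expect_equal(ncol(branch_forward(f3, 1, m3, "eval")$probs), 3L)
  expect_error(branch_forward(f, 9, m), "invalid branch index")
})

test_that("batch normalization distinguishes train and eval statistics", {
  m <- shmda_model(6, n_domains = 1, n_classes = 2, hidden = c(5, 4),
                   branch_dim = 3, seed = 4)
  X <- matrix(rnorm(10 * 6, mean = 2), 10)
  f <- common_forward(X, m)$out
  tr <- branch_forward(f, 1, m, "train")
  expect_false(isTRUE(all.equal(tr$bn_state$running_mean,
                                m$bn[[1]]$running_mean)))
  ev1 <- branch_forward(f, 1, m, "eval")
  ev2 <- branch_forward(f, 1, m, "eval")
  expect_identical(ev1$probs, ev2$probs)
})

test_that("parameter counts match the architecture arithmetic", {
  m <- shmda_model(310, n_domains = 4, n_classes = 3, seed = 5)
  n_common <- sum(vapply(m$params$common,
                         function(l) length(l$W) + length(l$b), numeric(1)))
  expect_equal(n_common, 310 * 256 + 256 + 256 * 128 + 128 + 128 * 64 + 64)
  n_disc <- length(m$params$disc$l1$W) + length(m$params$disc$l1$b) +
    length(m$params$disc$l2$W) + length(m$params$disc$l2$b)
  expect_equal(n_disc, 64 * 32 + 32 + 32 * 4 + 4)
  br <- m$params$branches[[1]]
  expect_equal(length(br$fe$W) + length(br$fe$b), 64 * 32 + 32)
  expect_equal(length(br$bn$gamma) + length(br$bn$beta), 64)
  expect_equal(length(br$cl$W) + length(br$cl$b), 32 * 3 + 3)
})

test_that("the gradient reversal layer is the identity forward and scales backward", {
  f <- matrix(rnorm(12), 3)
  for (lam in c(0, 0.5, 0.8)) {
    expect_identical(grl_forward(f, lam), f)
    expect_equal(grl_backward(f, lam), -lam * f)
  }
})

test_that("gradients through the gradient reversal layer equal -lambda times the plain gradient", {
  set.seed(6)
  m <- shmda_model(8, n_domains = 3, n_classes = 2, hidden = c(6, 5),
                   branch_dim = 4, seed = 7)
  f <- matrix(rnorm(4 * 5), 4)
  # analytic gradient of the domain loss w.r.t. the discriminator input
  fw <- discriminator_forward(f, m)
  dZ <- (fw$probs - shmda:::onehot(rep(0L, nrow(f)), 3)) / nrow(f)
  plain <- discriminator_backward(dZ, fw$cache, m)$dX
  # finite-difference check that the plain gradient is itself correct
  loss_at <- function(fm) {
    p <- discriminator_forward(fm, m)$probs
    -mean(log(p[, 1]))
  }
  for (j in sample(length(f), 4)) {
    h <- 1e-6
    fp <- f; fp[j] <- fp[j] + h
    fm_ <- f; fm_[j] <- fm_[j] - h
    expect_equal((loss_at(fp) - loss_at(fm_)) / (2 * h), plain[j],
                 tolerance = 1e-6)
  }
  # the GRL contract at several coefficients
  for (lam in c(0, 0.5, 0.8)) {
    expect_equal(grl_backward(plain, lam), -lam * plain, tolerance = 1e-12)
  }
})

test_that("analytic training gradients agree with finite differences", {
  set.seed(8)
  N <- 2; C <- 3; p <- 7; Mb <- 6
  model <- shmda_model(p, N, C, hidden = c(5, 4), branch_dim = 3, seed = 9)
  batches <- lapply(1:N, function(i)
    list(X = matrix(rnorm(Mb * p), Mb), y = sample(0:(C - 1), Mb, TRUE)))
  tX <- matrix(rnorm(Mb * p), Mb)
  cfg <- train_config(batch_size = Mb, hybrid_enabled = FALSE,
                      hidden = c(5, 4), branch_dim = 3,
                      loss = loss_config(use_dis = FALSE))
  l2w <- 0.7
  st <- shmda:::shmda_step(model, batches, tX, cfg, l2w)
  total_at <- function(m) shmda:::shmda_step(m, batches, tX, cfg, l2w)$losses["total"]

  check <- function(getter, setter, analytic) {
    vals <- getter(model)
    for (j in sample(length(vals), 3)) {
      h <- 1e-5
      mp <- setter(model, j, h)
      mm <- setter(model, j, -h)
      fd <- (total_at(mp) - total_at(mm)) / (2 * h)
      expect_equal(unname(fd), analytic[j], tolerance = 1e-4)
    }
  }
  check(function(m) m$params$common[[1]]$W,
        function(m, j, h) { m$params$common[[1]]$W[j] <- m$params$common[[1]]$W[j] + h; m },
        st$grads$common[[1]]$W)
  check(function(m) m$params$branches[[1]]$fe$W,
        function(m, j, h) { m$params$branches[[1]]$fe$W[j] <- m$params$branches[[1]]$fe$W[j] + h; m },
        st$grads$branches[[1]]$fe$W)
  check(function(m) m$params$branches[[2]]$bn$gamma,
        function(m, j, h) { m$params$branches[[2]]$bn$gamma[j] <- m$params$branches[[2]]$bn$gamma[j] + h; m },
        st$grads$branches[[2]]$bn$gamma)
  check(function(m) m$params$branches[[1]]$cl$b,
        function(m, j, h) { m$params$branches[[1]]$cl$b[j] <- m$params$branches[[1]]$cl$b[j] + h; m },
        st$grads$branches[[1]]$cl$b)
})

test_that("prediction averages the branch posteriors with lowest-index tie-breaks", {
  # zero parameters: every branch outputs the uniform distribution, whose
  # average is uniform, so the tie-break must pick class 0
  m <- shmda_model(5, n_domains = 3, n_classes = 4, hidden = c(4, 3),
                   branch_dim = 2, seed = 10)
  m$params <- shmda:::param_zeros_like(m$params)
  m$params$branches <- lapply(m$params$branches, function(b) {
    b$bn$gamma[] <- 1; b
  })
  pr <- predict_labels(m, matrix(rnorm(6 * 5), 6))
  expect_equal(pr$probs, matrix(0.25, 6, 4))
  expect_equal(pr$labels, rep(0L, 6))
  # averaged vectors stay on the simplex for a trained-like model
  m2 <- shmda_model(5, n_domains = 2, n_classes = 3, hidden = c(4, 3),
                    branch_dim = 2, seed = 11)
  pr2 <- predict_labels(m2, matrix(rnorm(6 * 5), 6))
  expect_equal(rowSums(pr2$probs), rep(1, 6), tolerance = 1e-6)
})
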