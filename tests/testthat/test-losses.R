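test_that("classification loss matches hand-computed cross-entropies", {
  # perfect predictions
  P <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(classification_loss(list(P), list(c(0L, 1L))), 0)
  # single branch, single sample, true-class probability 0.5
  expect_equal(classification_loss(list(rbind(c(0.5, 0.5))), list(0L)),
               log(2))
  # uniform prediction over 4 classes, two branches: log(4) each
  U <- matrix(0.25, 3, 4)
  expect_equal(classification_loss(list(U, U), list(rep(1L, 3), rep(2L, 3))),
               2 * log(4))
  expect_error(classification_loss(list(U), list(rep(9L, 3))),
               "label out of range")
})

test_that("domain loss matches hand-computed values and degenerates at N = 1", {
  perfect <- lapply(1:3, function(i) {
    P <- matrix(0, 2, 3); P[, i] <- 1; P
  })
  expect_equal(domain_loss(perfect), 0)
  uniform <- lapply(1:4, function(i) matrix(0.25, 2, 4))
  expect_equal(domain_loss(uniform), 4 * log(4))
  expect_equal(domain_loss(list(matrix(1, 5, 1))), 0)
})

test_that("linear MMD matches a brute-force mean-difference oracle", {
  # identical batches
  S <- matrix(rnorm(20), 5)
  expect_equal(mmd_loss(list(S), list(S)), 0)
  # hand example: means (0,0) vs (1,0)
  src <- rbind(c(-1, 0), c(1, 0))
  tgt <- rbind(c(0, 0), c(2, 0))
  expect_equal(mmd_loss(list(src), list(tgt)), 1)
  # brute-force double-loop oracle on random batch pairs
  set.seed(31)
  for (rep in 1:50) {
    ns <- sample(2:9, 1); nt <- sample(2:9, 1); q <- sample(2:5, 1)
    A <- matrix(rnorm(ns * q), ns); B <- matrix(rnorm(nt * q), nt)
    oracle <- 0
    for (k in seq_len(q)) {
      ma <- 0; for (i in seq_len(ns)) ma <- ma + A[i, k] / ns
      mb <- 0; for (i in seq_len(nt)) mb <- mb + B[i, k] / nt
      oracle <- oracle + (ma - mb)^2
    }
    expect_equal(mmd_loss(list(A), list(B)), oracle, tolerance = 1e-10)
  }
})

test_that("linear MMD is non-negative and zero only at equal means", {
  set.seed(37)
  for (rep in 1:10) {
    A <- matrix(rnorm(12), 4); B <- matrix(rnorm(12), 4)
    v <- mmd_loss(list(A), list(B))
    expect_gte(v, 0)
    # recentre B onto A's mean: the loss vanishes identically
    B2 <- sweep(B, 2, colMeans(B) - colMeans(A))
    expect_equal(mmd_loss(list(A), list(B2)), 0, tolerance = 1e-12)
  }
})

test_that("RBF MMD vanishes for identical batches and detects shifted ones", {
  set.seed(41)
  S <- matrix(rnorm(30), 10)
  expect_equal(mmd_loss(list(S), list(S), kernel = "rbf"), 0,
               tolerance = 1e-12)
  Tshift <- S + 3
  expect_gt(mmd_loss(list(S), list(Tshift), kernel = "rbf"),
            mmd_loss(list(S), list(S + 0.1), kernel = "rbf"))
})

test_that("conditional entropy matches closed forms and its bounds", {
  onehot <- rbind(c(1, 0, 0), c(0, 0, 1))
  expect_equal(conditional_entropy_loss(list(onehot)), 0)
  expect_equal(conditional_entropy_loss(list(matrix(1 / 3, 4, 3))), log(3))
  # sharpening a prediction never increases the entropy
  soft <- rbind(c(0.5, 0.3, 0.2))
  sharp <- rbind(c(0.7, 0.2, 0.1))
  expect_lt(conditional_entropy_loss(list(sharp)),
            conditional_entropy_loss(list(soft)))
  # bounds over random simplex matrices, several branches
  set.seed(43)
  for (rep in 1:20) {
    N <- sample(1:4, 1); C <- sample(2:5, 1)
    probs <- lapply(seq_len(N), function(i) {
      Z <- matrix(rexp(6 * C), 6); Z / rowSums(Z)
    })
    v <- conditional_entropy_loss(probs)
    expect_gte(v, 0)
    expect_lte(v, N * log(C) + 1e-12)
  }
})

test_that("the lambda2 schedule matches its closed form and is monotone", {
  expect_equal(lambda2(0), 0)
  expect_equal(lambda2(0.5), 2 / (1 + exp(-5)) - 1)
  expect_equal(lambda2(0.5), 0.98661, tolerance = 1e-5)
  expect_equal(lambda2(1), 0.99991, tolerance = 1e-5)
  grid <- lambda2(seq(0, 1, length.out = 100))
  expect_true(all(diff(grid) > 0))
  # out-of-range progress is clipped
  expect_equal(lambda2(-1), 0)
  expect_equal(lambda2(2), lambda2(1))
})

test_that("the total loss combines components with the configured weights", {
  cfg <- loss_config()
  z <- total_loss(0, 0, 0, 0, cfg, 0.5)
  expect_equal(z$total, 0)
  b <- total_loss(1, 1, 1, 1, cfg, 1)
  expect_equal(b$total, 1 + 0.1 + lambda2(1) + 0.1, tolerance = 1e-9)
  expect_equal(b$total, 2.19991, tolerance = 1e-4)
  # ablation switches zero out exactly the named component
  b_nodis <- total_loss(1, 1, 1, 1, loss_config(use_dis = FALSE), 1)
  expect_equal(b$total - b_nodis$total, 0.1)
  b_noce <- total_loss(1, 1, 1, 1, loss_config(use_ce = FALSE), 1)
  expect_equal(b$total - b_noce$total, 0.1)
  b_nommd <- total_loss(1, 1, 1, 1, loss_config(use_mmd = FALSE), 1)
  expect_equal(b$total - b_nommd$total, lambda2(1))
})

test_that("RBF MMD gradients agree with finite differences at fixed bandwidth", {
  set.seed(47)
  S <- matrix(rnorm(12), 4); T_ <- matrix(rnorm(15), 5)
  base <- 2.0
  g <- shmda:::rbf_mmd2_grad(S, T_, bandwidth_base = base)
  for (j in sample(length(S), 3)) {
    h <- 1e-6
    Sp <- S; Sp[j] <- Sp[j] + h
    Sm <- S; Sm[j] <- Sm[j] - h
    fd <- (shmda:::rbf_mmd2_grad(Sp, T_, bandwidth_base = base)$loss -
             shmda:::rbf_mmd2_grad(Sm, T_, bandwidth_base = base)$loss) / (2 * h)
    expect_equal(fd, g$dS[j], tolerance = 1e-4)
  }
  for (j in sample(length(T_), 3)) {
    h <- 1e-6
    Tp <- T_; Tp[j] <- Tp[j] + h
    Tm <- T_; Tm[j] <- Tm[j] - h
    fd <- (shmda:::rbf_mmd2_grad(S, Tp, bandwidth_base = base)$loss -
             shmda:::rbf_mmd2_grad(S, Tm, bandwidth_base = base)$loss) / (2 * h)
    expect_equal(fd, g$dT[j], tolerance = 1e-4)
  }
})
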