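test_that("Q reproduces the three-class worked example exactly", {
  classes <- c(1, 1, 2, 2, 3, 3)
  Q <- build_Q(labels = classes, atom_class = classes)
  expected <- rbind(c(1, 1, 0, 0, 0, 0),
                    c(1, 1, 0, 0, 0, 0),
                    c(0, 0, 1, 1, 0, 0),
                    c(0, 0, 1, 1, 0, 0),
                    c(0, 0, 0, 0, 1, 1),
                    c(0, 0, 0, 0, 1, 1))
  expect_identical(Q, expected * 1)
})

test_that("Q handles single-class and rectangular cases", {
  expect_identical(build_Q(rep(1, 4), rep(1, 3)), matrix(1, 3, 4))
  Q <- build_Q(labels = c(1, 2), atom_class = c(1, 1, 2, 2))
  expect_identical(Q[, 1], c(1, 1, 0, 0))
  expect_identical(Q[, 2], c(0, 0, 1, 1))
  expect_error(build_Q(c(1, NA), c(1, 2)), "NA")
})

test_that("H is the one-hot indicator with the documented shapes", {
  expect_identical(build_H(1:3, 3), diag(3) * 1)
  H <- build_H(c(1, 1, 2, 2, 3, 3), 3)
  expect_identical(H[1, ], c(1, 1, 0, 0, 0, 0))
  expect_identical(H[2, ], c(0, 0, 1, 1, 0, 0))
  expect_identical(H[3, ], c(0, 0, 0, 0, 1, 1))
  expect_identical(dim(build_H(integer(0), 3)), c(3L, 0L))
  expect_error(build_H(c(1, 4), 3), "1..m")
})

test_that("weight normalization lives on the open simplex", {
  w <- normalize_weights(0.6, 0.3)
  expect_equal(w$gamma, 0.1)
  w2 <- normalize_weights(0.33, 0.33)
  expect_equal(w2$gamma, 0.34)
  expect_error(normalize_weights(0.9, 0.2), "weights")
  expect_error(normalize_weights(-0.1, 0.5), "weights")
  expect_error(objective_weights(0.5, 0.4, 0.2), "sum to 1")
})

test_that("transform initialization matches the closed-form ridge oracle", {
  set.seed(51)
  K <- 6; N <- 20; m <- 3
  X0 <- matrix(stats::rnorm(K * N), K, N)
  Q <- matrix(stats::rbinom(K * N, 1, 0.3), K, N)
  H <- matrix(stats::rbinom(m * N, 1, 0.3), m, N)
  lam <- 1e-4
  tr <- init_transforms(X0, Q, H, lam)
  W_oracle <- H %*% t(X0) %*% solve(X0 %*% t(X0) + lam * diag(K))
  expect_equal(tr$W0, W_oracle, tolerance = 1e-8)
  # orthonormal rows, no ridge: A0 = Q X0'
  X_orth <- qr.Q(qr(matrix(stats::rnorm(N * K), N, K)))  # N x K, orth cols
  X0o <- t(X_orth)
  tro <- init_transforms(X0o, Q, H, 0)
  expect_equal(tro$A0, Q %*% t(X0o) %*% solve(X0o %*% t(X0o)),
               tolerance = 1e-8)
  # enormous ridge shrinks everything to zero
  trb <- init_transforms(X0, Q, H, 1e12)
  expect_lt(max(abs(trb$A0)), 1e-6)
  # singular system without ridge is refused with advice
  Xs <- matrix(0, K, N); Xs[1, ] <- 1
  expect_error(init_transforms(Xs, Q, H, 0), "lambda")
})

test_that("label-consistent training separates Gaussian blobs perfectly", {
  blobs <- make_blobs(n_per = 20, d = 6, sep = 4, seed = 52)
  Y <- t(blobs$X)                      # signals in columns
  Y <- Y / max(sqrt(colSums(Y^2)))     # keep scales tame
  fit <- lcksvd_train(Y, blobs$y, objective_weights(0.6, 0.3), K = 8,
                      T = 2, n_iter = 10, seed = 1)
  pred <- lcksvd_classify(fit, Y)
  expect_equal(accuracy(pred$labels, blobs$y), 100)
  expect_equal(colSums(fit$D^2), rep(1, 8), tolerance = 1e-8)
})

test_that("with alpha near 1 the learned dictionary matches plain K-SVD", {
  set.seed(53)
  n <- 10; N <- 40
  Y <- matrix(stats::rnorm(n * N), n, N)
  labels <- rep(1:2, each = 20)
  eps <- 1e-6
  w <- objective_weights(1 - 2 * eps, eps, eps)
  fit <- lcksvd_train(Y, labels, w, K = 6, T = 2, n_iter = 5, seed = 9)
  D0 <- init_dictionary(Y, labels, K = 6, seed = 9)
  ref <- ksvd_fit(Y, D0, T = 2, n_iter = 5)
  cors <- abs(colSums(fit$D * ref$dictionary$atoms))
  expect_true(all(cors > 1 - 1e-3))
})

test_that("training runs under every weighting of the accuracy study", {
  feat <- extract_steady_state_max(simulate_response_set(sampling_design(seed = 54)))
  sp <- stratified_split(feat, 2 / 3, seed = 54)
  kc <- kernel_config(sp$train$values)
  Yemb <- t(empirical_kernel_map(kc, sp$train$values))
  y <- as.integer(sp$train$labels)
  for (w in list(c(0.6, 0.3), c(0.3, 0.6), c(0.1, 0.3), c(0.33, 0.33))) {
    fit <- lcksvd_train(Yemb, y, normalize_weights(w[1], w[2]),
                        K = 8, T = 3, n_iter = 3, seed = 1)
    expect_s3_class(fit, "lcksvd_fit")
  }
  expect_error(lcksvd_train(Yemb, y, objective_weights(0.6, 0.3), K = 3,
                            T = 3, n_iter = 2, seed = 1), "classes")
})

test_that("the stacked objective never increases across atom sweeps", {
  set.seed(55)
  Y <- matrix(stats::rnorm(8 * 30), 8, 30)
  labels <- rep(1:3, each = 10)
  fit <- lcksvd_train(Y, labels, objective_weights(0.5, 0.3), K = 6,
                      T = 2, n_iter = 6, seed = 2)
  tr <- fit$objective_trace
  for (it in unique(tr$iter)) {
    expect_lte(tr$objective[tr$iter == it & tr$stage == "update"],
               tr$objective[tr$iter == it & tr$stage == "code"] + 1e-8)
  }
})

test_that("raising the classification weight never hurts separable training accuracy", {
  for (s in 1:10) {
    blobs <- make_blobs(n_per = 12, d = 5, sep = 4, seed = 500 + s)
    Y <- t(blobs$X) / 5
    acc <- sapply(c(0.1, 0.8), function(g) {
      w <- objective_weights((1 - g) / 2, (1 - g) / 2, g)
      fit <- lcksvd_train(Y, blobs$y, w, K = 6, T = 2, n_iter = 6, seed = s)
      accuracy(lcksvd_classify(fit, Y)$labels, blobs$y)
    })
    expect_gte(acc[2], acc[1])
  }
})

test_that("classification ties break toward the lowest class index", {
  fit <- structure(list(D = diag(4), W = rbind(c(1, 1, 0, 0), c(1, 1, 0, 0)),
                        T = 1L), class = "lcksvd_fit")
  res <- lcksvd_classify(fit, matrix(c(1, 0, 0, 0), 4, 1))
  expect_equal(res$labels, 1L)
})

test_that("accuracy follows the percent convention of the field", {
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(accuracy(c(1, 1), c(2, 2)), 0)
  expect_equal(accuracy(c(rep(1, 31), 2), c(rep(1, 31), 1)), 96.875)
  expect_equal(round(accuracy(c(rep(1, 31), 2), c(rep(1, 31), 1)), 1), 96.9)
  expect_error(accuracy(integer(0), integer(0)), "empty")
  expect_error(accuracy(1:3, 1:4), "length")
})
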