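test_that("dictionary initialization selects and normalizes training columns", {
  set.seed(41)
  Y <- matrix(stats::rnorm(6 * 10), 6, 10) * 3
  d_all <- init_dictionary(Y, K = 10, seed = 1, strategy = "random_samples")
  # K = N: every sample becomes an atom, normalized
  expect_equal(ncol(d_all$atoms), 10)
  expect_equal(colSums(d_all$atoms^2), rep(1, 10))
  expect_equal(abs(stats::cor(as.vector(d_all$atoms),
                              as.vector(sweep(Y, 2, sqrt(colSums(Y^2)), "/")))),
               1)
  expect_error(init_dictionary(Y, K = 11, seed = 1,
                               strategy = "random_samples"), "exceeds")
})

test_that("class-balanced initialization follows the quota rule", {
  set.seed(42)
  Y <- matrix(stats::rnorm(5 * 12), 5, 12)
  labels <- rep(1:3, each = 4)
  d6 <- init_dictionary(Y, labels, K = 6, seed = 1)
  expect_equal(d6$atom_class, rep(1:3, each = 2))
  # remainder atoms go to the first classes
  d7 <- init_dictionary(Y, labels, K = 7, seed = 1)
  expect_equal(d7$atom_class, c(1, 1, 1, 2, 2, 3, 3))
  # different seeds select different columns
  d_a <- init_dictionary(Y, labels, K = 6, seed = 1)
  d_b <- init_dictionary(Y, labels, K = 6, seed = 2)
  expect_false(identical(d_a$source_index, d_b$source_index))
})

test_that("the rank-1 atom update matches the SVD tail-energy oracle", {
  set.seed(43)
  for (rep in 1:10) {
    n <- 6; K <- 8; N <- 30
    D <- matrix(stats::rnorm(n * K), n, K)
    D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
    Y <- matrix(stats::rnorm(n * N), n, N)
    X <- omp_batch(D, Y, T = 2)$codes
    k <- sample(K, 1)
    omega <- which(X[k, ] != 0)
    if (length(omega) == 0) next
    # independent restricted-error computation
    Ek <- Y[, omega, drop = FALSE] -
      D[, -k, drop = FALSE] %*% X[-k, omega, drop = FALSE]
    sv <- svd(Ek)
    upd <- update_atom(Y, D, X, k)
    expect_equal(sum(upd$d^2), 1)
    err2 <- sum((Ek - upd$d %*% t(upd$x[omega]))^2)
    expect_equal(err2, sum(sv$d[-1]^2), tolerance = 1e-8)
  }
})

test_that("a single-user atom update reduces to the normalized residual column", {
  set.seed(44)
  n <- 5; K <- 4; N <- 6
  D <- matrix(stats::rnorm(n * K), n, K)
  D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
  X <- matrix(0, K, N)
  X[2, 3] <- 1.7                      # atom 2 used by sample 3 only
  Y <- matrix(stats::rnorm(n * N), n, N)
  r <- Y[, 3] - D[, -2] %*% X[-2, 3]
  upd <- update_atom(Y, D, X, 2)
  s <- sign(r[which(abs(r) > 1e-12)[1]])
  expect_equal(upd$d, as.vector(s * r / sqrt(sum(r^2))))
  expect_equal(upd$x[3], s * sqrt(sum(r^2)))
  expect_error(update_atom(Y, D, X, 9), "out of range")
})

test_that("an exactly rank-1 restricted error is annihilated", {
  set.seed(45)
  n <- 5; N <- 7
  u <- stats::rnorm(n); u <- u / sqrt(sum(u^2))
  v <- stats::rnorm(N)
  D <- cbind(u, diag(n)[, 1:2])
  D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
  X <- rbind(stats::rnorm(N), 0, 0)   # only atom 1 used, all samples
  Y <- D[, 1] %*% t(X[1, ]) + 0       # E_1 = Y - 0 = rank-1 already
  upd <- update_atom(Y, D, X, 1)
  expect_equal(sum((Y - upd$d %*% t(upd$x))^2), 0, tolerance = 1e-16)
})

test_that("unused atoms are replaced by the worst-reconstructed signal", {
  set.seed(46)
  n <- 4; K <- 3; N <- 5
  D <- diag(n)[, 1:K]
  X <- matrix(0, K, N)
  X[1, ] <- 1; X[2, ] <- 1            # atom 3 unused
  Y <- matrix(stats::rnorm(n * N), n, N)
  j_worst <- which.max(colSums((Y - D %*% X)^2))
  upd <- update_atom(Y, D, X, 3)
  expect_equal(abs(sum(upd$d * Y[, j_worst])), sqrt(sum(Y[, j_worst]^2)),
               tolerance = 1e-12)
  expect_equal(upd$x, rep(0, N))
})

test_that("a spanning dictionary drives the objective to zero in one sweep", {
  set.seed(47)
  n <- 4
  Y <- matrix(stats::rnorm(n * n), n, n)
  D0 <- init_dictionary(Y, K = n, seed = 1, strategy = "random_samples")
  fit <- ksvd_fit(Y, D0, T = n, n_iter = 1)
  expect_lt(utils::tail(fit$objective_trace$objective, 1), 1e-10)
})

test_that("atom-update sweeps never increase the objective (20 seeded problems)", {
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 8; K <- 10; N <- 40
    Y <- matrix(stats::rnorm(n * N), n, N)
    D0 <- init_dictionary(Y, K = K, seed = s, strategy = "random_samples")
    fit <- ksvd_fit(Y, D0, T = 3, n_iter = 5)
    tr <- fit$objective_trace
    for (it in unique(tr$iter)) {
      after_code <- tr$objective[tr$iter == it & tr$stage == "code"]
      after_update <- tr$objective[tr$iter == it & tr$stage == "update"]
      expect_lte(after_update, after_code + 1e-8)
    }
    expect_equal(colSums(fit$dictionary$atoms^2), rep(1, K))
  }
})

test_that("the incoherent benchmark dictionary honors its coherence bound", {
  set.seed(48)
  D <- random_incoherent_dictionary(8, 20, mu_max = 0.5)
  expect_equal(colSums(D^2), rep(1, 20))
  expect_lte(frame_coherence(D), 0.5)
})
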