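# Independent reference implementations used as oracles.  These are written
# against the textbook definitions, deliberately on different code paths
# than the package (normal equations instead of QR, explicit loops instead
# of vectorization), so agreement is evidence, not tautology.

# brute-force greedy OMP: argmax |d' r|, least squares by normal equations;
# returns the selection trajectory so equivalence can be checked
# selection-for-selection
greedy_omp_reference <- function(D, y, T) {
  support <- integer(0)
  r <- y
  for (step in seq_len(T)) {
    cors <- rep(-Inf, ncol(D))
    for (j in seq_len(ncol(D)))
      if (!(j %in% support)) cors[j] <- abs(sum(D[, j] * r))
    j_star <- which.max(cors)
    support <- c(support, j_star)
    Ds <- D[, support, drop = FALSE]
    coef <- solve(t(Ds) %*% Ds, t(Ds) %*% y)
    r <- y - Ds %*% coef
  }
  x <- numeric(ncol(D))
  x[support] <- coef
  list(support = support, code = x, residual = sqrt(sum(r^2)))
}

# exhaustive least squares over every size-T support
best_support_exhaustive <- function(D, y, T) {
  combs <- utils::combn(ncol(D), T)
  best <- NULL; best_err <- Inf
  for (i in seq_len(ncol(combs))) {
    S <- combs[, i]
    Ds <- D[, S, drop = FALSE]
    coef <- solve(t(Ds) %*% Ds, t(Ds) %*% y)
    err <- sum((y - Ds %*% coef)^2)
    if (err < best_err) {
      best_err <- err
      best <- list(support = S, coef = as.vector(coef), err = err)
    }
  }
  best
}

# unit-norm frame with low mutual coherence via alternating projection
# between the set of Gram matrices with bounded off-diagonals and the set
# of rank-n PSD matrices with unit diagonal
low_coherence_frame <- function(n, K, mu_target, seed, max_iter = 20000L) {
  set.seed(seed)
  D <- matrix(stats::rnorm(n * K), n, K)
  D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
  best <- Inf; bestD <- D
  for (it in seq_len(max_iter)) {
    G <- crossprod(D)
    off <- G - diag(K)
    mu <- max(abs(off))
    if (mu < best) {
      best <- mu; bestD <- D
      if (best <= mu_target) break
    }
    th <- mu * 0.99
    idx <- abs(off) > th
    G[idx] <- sign(G[idx]) * th
    diag(G) <- 1
    e <- eigen(G, symmetric = TRUE)
    Dn <- diag(sqrt(pmax(e$values[seq_len(n)], 0))) %*%
      t(e$vectors[, seq_len(n)])
    D <- sweep(Dn, 2, sqrt(colSums(Dn^2)), "/")
  }
  bestD
}

frame_coherence <- function(D) {
  G <- abs(crossprod(D)); diag(G) <- 0; max(G)
}

# greedy matching of true atoms to learned atoms by |correlation|
atom_recovery_count <- function(D_true, D_learned, threshold = 0.99) {
  C <- abs(crossprod(D_true, D_learned))
  rec <- 0L
  for (i in seq_len(ncol(D_true))) {
    ij <- which(C == max(C), arr.ind = TRUE)[1, ]
    if (C[ij[1], ij[2]] > threshold) rec <- rec + 1L
    C[ij[1], ] <- -1; C[, ij[2]] <- -1
  }
  rec
}

# two linearly separable Gaussian blobs with centers in opposite
# directions (+-sep/2 on every coordinate).  Direction-based sparse coding
# needs the class centers to differ in direction, not only magnitude: a
# blob centered at the origin has uniformly random sample directions, and
# two centers on the same ray collapse onto one atom direction after
# normalization.
make_blobs <- function(n_per = 20, d = 6, sep = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per * d, mean = -sep / 2), n_per, d),
             matrix(stats::rnorm(n_per * d, mean = sep / 2), n_per, d))
  list(X = X, y = rep(1:2, each = n_per))
}
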