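#' Orthogonal matching pursuit
#'
#' Greedy sparse coder for `y ~ D x` with `||x||_0 <= T`: at each step the
#' atom most correlated (in absolute value) with the current residual is
#' added to the support, the coefficients are re-solved by QR least squares
#' on the accumulated support, and the residual is updated.  Stops after `T`
#' atoms or when the residual norm falls below `tol * ||y||`.  On equal
#' correlations the lowest atom index wins, so the result is deterministic.
#'
#' @param D Dictionary, `n x K` matrix with unit-norm columns
#'   (tolerance 1e-8).
#' @param y Signal of length `n`.
#' @param T Sparsity bound, `1 <= T <= min(n, K)`.
#' @param tol Relative residual tolerance for early stopping.
#' @return Numeric vector of length `K` (the sparse code); the residual is
#'   orthogonal to the selected atoms.
#' @export
omp <- function(D, y, T, tol = 1e-10) {
  D <- as.matrix(D)
  check_unit_columns(D)
  n <- nrow(D); K <- ncol(D)
  T <- as.integer(T)
  if (T < 1 || T > min(n, K))
    stop("T must satisfy 1 <= T <= min(n, K)", call. = FALSE)
  if (length(y) != n) stop("length(y) must equal nrow(D)", call. = FALSE)
  x <- numeric(K)
  ynorm <- sqrt(sum(y^2))
  if (ynorm == 0) return(x)
  r <- y
  support <- integer(0)
  for (step in seq_len(T)) {
    if (sqrt(sum(r^2)) < tol * ynorm) break
    corr <- abs(crossprod(D, r))
    corr[support] <- -Inf
    j <- which.max(corr)           # first max = lowest index on ties
    support <- c(support, j)
    Ds <- D[, support, drop = FALSE]
    coef <- qr.coef(qr(Ds), y)
    coef[is.na(coef)] <- 0
    r <- y - Ds %*% coef
  }
  x[support] <- coef
  x
}

#' Batch orthogonal matching pursuit
#'
#' Codes every column of `Y` independently with [omp()]; column order does
#' not matter.
#'
#' @param D Dictionary with unit-norm columns.
#' @param Y Signals, `n x N` matrix (one column per signal).
#' @param T Sparsity bound.
#' @param tol Relative residual tolerance.
#' @return Object of class `sparse_code_matrix`: list with `codes`
#'   (`K x N`), `sparsity_T` and `support` (list of per-column index sets).
#' @export
omp_batch <- function(D, Y, T, tol = 1e-10) {
  D <- as.matrix(D); Y <- as.matrix(Y)
  check_unit_columns(D)
  n <- nrow(D); K <- ncol(D); N <- ncol(Y)
  T <- as.integer(T)
  if (T < 1 || T > min(n, K))
    stop("T must satisfy 1 <= T <= min(n, K)", call. = FALSE)
  if (nrow(Y) != n) stop("nrow(Y) must equal nrow(D)", call. = FALSE)
  X <- matrix(0, K, N)
  if (N > 0) {
    # vectorized greedy: one correlation pass for all still-active columns
    R <- Y
    ynorm <- sqrt(colSums(Y^2))
    supports <- vector("list", N)
    active <- which(ynorm > 0)
    for (step in seq_len(T)) {
      if (length(active) == 0) break
      C <- abs(crossprod(D, R[, active, drop = FALSE]))
      for (a in seq_along(active)) {
        i <- active[a]
        ci <- C[, a]
        ci[supports[[i]]] <- -Inf
        supports[[i]] <- c(supports[[i]], which.max(ci))
      }
      still <- logical(length(active))
      for (a in seq_along(active)) {
        i <- active[a]
        Ds <- D[, supports[[i]], drop = FALSE]
        coef <- qr.coef(qr(Ds), Y[, i])
        coef[is.na(coef)] <- 0
        r <- Y[, i] - Ds %*% coef
        R[, i] <- r
        X[supports[[i]], i] <- coef
        still[a] <- sqrt(sum(r^2)) >= tol * ynorm[i]
      }
      active <- active[still]
    }
    for (i in seq_len(N)) supports[[i]] <- sort(supports[[i]])
  }
  structure(list(codes = X, sparsity_T = T,
                 support = if (N > 0) supports else list()),
            class = "sparse_code_matrix")
}

check_unit_columns <- function(D, tol = 1e-8) {
  nrm <- sqrt(colSums(D^2))
  if (any(abs(nrm - 1) > tol))
    stop("dictionary columns must be unit-norm (tolerance 1e-8)",
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.sparse_code_matrix <- function(x, ...) {
  cat(sprintf("sparse_code_matrix: %d atoms x %d signals, T = %d, mean nnz = %.2f\n",
              nrow(x$codes), ncol(x$codes), x$sparsity_T,
              if (ncol(x$codes)) mean(colSums(x$codes != 0)) else 0))
  invisible(x)
}
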