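#' Initialize a dictionary from training signals
#'
#' Atoms are normalized copies of selected training columns.  The
#' `class_balanced_samples` strategy draws `floor(K/m)` atoms per class
#' (one extra for the first `K mod m` classes) and records the class of
#' every atom, which the label-consistent machinery needs; for E-nose data,
#' where sensors are cross-sensitive and the signal redundant, seeding atoms
#' from real responses works much better than random atoms.
#'
#' @param Y Training signals, `n x N` matrix (one column per sample).
#' @param labels Class index per sample (integers `1..m`); required by
#'   `class_balanced_samples`.
#' @param K Number of atoms, `K <= N`.
#' @param seed Integer seed for the selection.
#' @param strategy `"class_balanced_samples"` or `"random_samples"`.
#' @return Object of class `dictionary`: list with `atoms` (`n x K`,
#'   unit-norm columns), `atom_class` (or `NULL`), `init_strategy`.
#' @export
init_dictionary <- function(Y, labels = NULL, K, seed = 1L,
                            strategy = c("class_balanced_samples",
                                         "random_samples")) {
  strategy <- match.arg(strategy)
  Y <- as.matrix(Y)
  N <- ncol(Y)
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (K > N)
    stop("K exceeds the number of training samples", call. = FALSE)
  set.seed(seed)
  atom_class <- NULL
  if (strategy == "random_samples") {
    sel <- sort(sample(N, K))
  } else {
    if (is.null(labels) || length(labels) != N)
      stop("class_balanced_samples needs one label per column of Y",
           call. = FALSE)
    classes <- sort(unique(labels))
    m <- length(classes)
    quota <- rep(K %/% m, m)
    extra <- K %% m
    if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
    sel <- integer(0); atom_class <- integer(0)
    for (ci in seq_len(m)) {
      idx <- which(labels == classes[ci])
      if (quota[ci] > length(idx))
        stop(sprintf("class %s has too few samples for its atom quota",
                     classes[ci]), call. = FALSE)
      sel <- c(sel, sample(idx, quota[ci]))
      atom_class <- c(atom_class, rep(classes[ci], quota[ci]))
    }
  }
  atoms <- Y[, sel, drop = FALSE]
  nrm <- sqrt(colSums(atoms^2))
  if (any(nrm < 1e-12))
    stop("selected training signals include a zero column", call. = FALSE)
  atoms <- sweep(atoms, 2, nrm, "/")
  dimnames(atoms) <- NULL
  structure(list(atoms = atoms, atom_class = atom_class,
                 init_strategy = strategy, source_index = sel),
            class = "dictionary")
}

#' @export
print.dictionary <- function(x, ...) {
  cat(sprintf("dictionary: %d x %d (%s)\n", nrow(x$atoms), ncol(x$atoms),
              x$init_strategy))
  invisible(x)
}

# leading singular triplet; full SVD for small problems, power iteration
# (on E E^T) above `threshold` to avoid the full decomposition
leading_triplet <- function(E, threshold = 200L, tol = 1e-10,
                            max_iter = 500L) {
  if (min(dim(E)) <= threshold) {
    sv <- svd(E, nu = 1, nv = 1)
    return(list(u = sv$u[, 1], d = sv$d[1], v = sv$v[, 1]))
  }
  u <- E[, which.max(colSums(E^2))]
  u <- u / sqrt(sum(u^2))
  d_old <- 0
  for (it in seq_len(max_iter)) {
    v <- crossprod(E, u)
    v <- v / sqrt(sum(v^2))
    Ev <- E %*% v
    d <- sqrt(sum(Ev^2))
    u <- Ev / d
    if (abs(d - d_old) < tol * max(d, 1)) break
    d_old <- d
  }
  list(u = as.vector(u), d = d, v = as.vector(v))
}

# flip sign so the first component of d with |.| > 1e-12 is positive
fix_sign <- function(u) {
  i <- which(abs(u) > 1e-12)[1]
  if (!is.na(i) && u[i] < 0) -1 else 1
}

#' Rank-1 K-SVD atom update
#'
#' Updates atom `k` and its coefficient row given fixed codes for all other
#' atoms.  Let `omega_k` be the samples whose code uses atom `k`.  The
#' restricted error matrix `E_kR = (Y - sum_{i != k} d_i x^T_i)[, omega_k]`
#' is decomposed by SVD; the new atom is the leading left singular vector
#' and the restricted coefficients the leading singular value times the
#' leading right singular vector.  The sign is fixed so the first nonzero
#' entry of the atom is positive.  An unused atom (`omega_k` empty) is
#' replaced by the normalized worst-reconstructed training signal with zero
#' coefficients.
#'
#' @param Y Signals, `n x N`.
#' @param D Current dictionary, `n x K`.
#' @param X Current sparse codes, `K x N`.
#' @param k Atom index to update.
#' @return List with `d` (new unit-norm atom), `x` (full-length coefficient
#'   row, zeros outside `omega_k`) and `omega` (the support samples).
#' @export
update_atom <- function(Y, D, X, k) {
  Y <- as.matrix(Y); D <- as.matrix(D); X <- as.matrix(X)
  K <- ncol(D)
  if (k < 1 || k > K) stop("atom index out of range", call. = FALSE)
  omega <- which(X[k, ] != 0)
  xrow <- numeric(ncol(Y))
  if (length(omega) == 0) {
    resid2 <- colSums((Y - D %*% X)^2)
    j <- which.max(resid2)
    d <- Y[, j]
    nrm <- sqrt(sum(d^2))
    if (nrm < 1e-12) d <- c(1, numeric(nrow(Y) - 1L)) else d <- d / nrm
    d <- d * fix_sign(d)
    return(list(d = d, x = xrow, omega = omega))
  }
  # E_k restricted to the using samples, without atom k's contribution
  Ek <- Y[, omega, drop = FALSE] -
    D[, -k, drop = FALSE] %*% X[-k, omega, drop = FALSE]
  tr <- leading_triplet(Ek)
  s <- fix_sign(tr$u)
  d <- tr$u * s
  xrow[omega] <- s * tr$d * tr$v
  list(d = d, x = xrow, omega = omega)
}

#' Random unit-norm dictionary with bounded mutual coherence
#'
#' Draws Gaussian random atoms, rejecting any atom whose absolute
#' correlation with an already-accepted atom exceeds `mu_max`.  Ground
#' truths for dictionary-recovery benchmarks need such a bound: two
#' near-parallel true atoms cannot both be identified at high correlation,
#' so an unconstrained random dictionary makes recovery ill-posed for some
#' draws.
#'
#' @param n Signal dimension.
#' @param K Number of atoms.
#' @param mu_max Maximum allowed pairwise coherence (default 0.6).
#' @param max_tries Rejection attempts per atom before giving up.
#' @return `n x K` matrix with unit-norm columns.  Uses the current RNG
#'   stream.
#' @export
random_incoherent_dictionary <- function(n, K, mu_max = 0.6,
                                         max_tries = 10000L) {
  D <- matrix(0, n, K)
  for (k in seq_len(K)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      d <- stats::rnorm(n); d <- d / sqrt(sum(d^2))
      if (k == 1 ||
          max(abs(crossprod(D[, seq_len(k - 1), drop = FALSE], d))) <= mu_max) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      stop("could not reach the requested coherence bound", call. = FALSE)
    D[, k] <- d
  }
  D
}

#' K-SVD dictionary learning
#'
#' Alternates batch OMP sparse coding with a full ascending-index sweep of
#' rank-1 atom updates, recording the Frobenius reconstruction error
#' `||Y - D X||_F` after each half-step.  The atom-update half-step can
#' never increase the objective.
#'
#' With `clear` set, a dictionary-clearing pass follows each update sweep
#' (except during the final `polish` iterations): atoms too coherent with
#' another atom (`max_coherence`) or used by fewer than `min_usage`
#' signals are replaced by the normalized residual of the currently
#' worst-reconstructed signals — the usual escape from duplicate-atom
#' local minima.  Clearing changes the codes, so the recorded objective
#' refers to the state before the pass.
#'
#' @param Y Signals, `n x N`.
#' @param D0 Initial dictionary (a `dictionary` object or a plain matrix
#'   with unit-norm columns).
#' @param T Sparsity bound passed to [omp_batch()].
#' @param n_iter Number of coding/update iterations (>= 1).
#' @param tol Early-stop tolerance on the objective.
#' @param clear `NULL` (default, no clearing) or a list with any of
#'   `max_coherence` (default 0.75), `min_usage` (default 4), `polish`
#'   (default 10, clearing-free final iterations).
#' @return List with `dictionary` (a `dictionary` object), `codes` (a
#'   `sparse_code_matrix`), and `objective_trace` (data.frame with columns
#'   `iter`, `stage`, `objective`).
#' @export
ksvd_fit <- function(Y, D0, T, n_iter = 30, tol = 1e-12, clear = NULL) {
  Y <- as.matrix(Y)
  if (inherits(D0, "dictionary")) {
    D <- D0$atoms
    atom_class <- D0$atom_class
    strategy <- D0$init_strategy
  } else {
    D <- as.matrix(D0)
    atom_class <- NULL
    strategy <- "user"
  }
  check_unit_columns(D)
  n_iter <- as.integer(n_iter)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  K <- ncol(D)
  trace <- vector("list", 2L * n_iter)
  X <- NULL
  for (it in seq_len(n_iter)) {
    sc <- omp_batch(D, Y, T)
    X <- sc$codes
    obj_code <- norm(Y - D %*% X, "F")
    trace[[2L * it - 1L]] <- data.frame(iter = it, stage = "code",
                                        objective = obj_code)
    for (k in seq_len(K)) {
      upd <- update_atom(Y, D, X, k)
      D[, k] <- upd$d
      X[k, ] <- upd$x
    }
    obj_upd <- norm(Y - D %*% X, "F")
    trace[[2L * it]] <- data.frame(iter = it, stage = "update",
                                   objective = obj_upd)
    if (obj_upd < tol) break
    if (!is.null(clear)) {
      coh <- if (is.null(clear$max_coherence)) 0.75 else clear$max_coherence
      usg <- if (is.null(clear$min_usage)) 4L else clear$min_usage
      pol <- if (is.null(clear$polish)) 10L else clear$polish
      if (it <= n_iter - pol) {
        R <- Y - D %*% X
        ord <- order(colSums(R^2), decreasing = TRUE)
        ri <- 1L
        G <- abs(crossprod(D)); diag(G) <- 0
        for (k in seq_len(K)) {
          if (ri > ncol(Y)) break
          if (max(G[k, ]) > coh || sum(X[k, ] != 0) < usg) {
            d <- R[, ord[ri]]; ri <- ri + 1L
            if (sqrt(sum(d^2)) < 1e-10) next
            D[, k] <- d / sqrt(sum(d^2))
            X[k, ] <- 0
            G[k, ] <- 0; G[, k] <- 0
          }
        }
      }
    }
  }
  trace <- do.call(rbind, trace[!vapply(trace, is.null, logical(1))])
  dict <- structure(list(atoms = D, atom_class = atom_class,
                         init_strategy = strategy),
                    class = "dictionary")
  codes <- structure(list(codes = X, sparsity_T = as.integer(T),
                          support = apply(X, 2, function(col)
                            which(col != 0), simplify = FALSE)),
                     class = "sparse_code_matrix")
  list(dictionary = dict, codes = codes, objective_trace = trace)
}
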