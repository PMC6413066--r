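#' Discriminative sparse-code targets Q
#'
#' `Q[k, i] = 1` when atom `k` and sample `i` carry the same class label,
#' else 0: the ideal "label-consistent" code in which every sample loads
#' exactly on the atoms of its own class.
#'
#' @param labels Class label per sample.
#' @param atom_class Class label per dictionary atom.
#' @return Binary matrix `K x N`.
#' @export
build_Q <- function(labels, atom_class) {
  if (anyNA(labels) || anyNA(atom_class))
    stop("labels and atom_class must not contain NA", call. = FALSE)
  if (length(atom_class) == 0 || length(labels) == 0)
    stop("labels and atom_class must be non-empty", call. = FALSE)
  if (!any(as.character(labels) %in% as.character(atom_class)))
    stop("labels and atom_class share no classes", call. = FALSE)
  Q <- outer(as.character(atom_class), as.character(labels), "==") * 1
  dimnames(Q) <- NULL
  Q
}

#' One-hot class indicator matrix H
#'
#' Column `i` is the one-hot vector of sample `i`'s class: `H[c, i] = 1`
#' iff `labels[i] == c`.
#'
#' @param labels Integer class labels in `1..m`.
#' @param m Number of classes.
#' @return Binary matrix `m x N` (possibly zero columns wide).
#' @export
build_H <- function(labels, m) {
  m <- as.integer(m)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) > 0 &&
      (anyNA(labels) || any(labels < 1) || any(labels > m)))
    stop("labels must lie in 1..m", call. = FALSE)
  H <- matrix(0, m, length(labels))
  if (length(labels) > 0)
    H[cbind(labels, seq_along(labels))] <- 1
  H
}

#' Objective weights on the simplex
#'
#' The three terms of the training objective — reconstruction
#' `alpha ||Y - DX||^2`, discriminative sparse-code error
#' `beta ||Q - AX||^2` and classification error `gamma ||H - WX||^2` — are
#' weighted on the open simplex: `alpha + beta + gamma = 1` with every
#' weight in `(0, 1)`.
#'
#' @param alpha,beta Weights in `(0, 1)`.
#' @param gamma Optional; when omitted, `gamma = 1 - alpha - beta`
#'   (the normalization rule).
#' @return Object of class `objective_weights`.
#' @export
objective_weights <- function(alpha, beta, gamma = NULL) {
  if (is.null(gamma)) gamma <- 1 - alpha - beta
  w <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(w)) || any(w <= 0) || any(w >= 1))
    stop("objective weights must lie strictly in (0, 1) and sum to 1",
         call. = FALSE)
  if (abs(sum(w) - 1) > 1e-12)
    stop("objective weights must sum to 1", call. = FALSE)
  structure(as.list(w), class = "objective_weights")
}

#' @rdname objective_weights
#' @param alpha_raw,beta_raw Raw weights; `gamma` is derived.
#' @export
normalize_weights <- function(alpha_raw, beta_raw) {
  objective_weights(alpha_raw, beta_raw)
}

#' @export
print.objective_weights <- function(x, ...) {
  cat(sprintf("objective weights: alpha = %.4f, beta = %.4f, gamma = %.4f\n",
              x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Ridge initialization of the transform A and classifier W
#'
#' Given initial sparse codes `X0` of the training data, both the linear
#' code transform `A` (targets `Q`) and the linear classifier `W` (targets
#' `H`) are initialized by ridge regression:
#' `A0 = Q X0' (X0 X0' + lambda I)^-1`, and likewise for `W0`.
#'
#' @param X0 Sparse codes, `K x N`.
#' @param Q Discriminative targets, `K x N`.
#' @param H Class indicators, `m x N`.
#' @param lambda_ridge Ridge penalty (default 1e-4); 0 is allowed only for
#'   nonsingular `X0 X0'`.
#' @return List with `A0` (`K x K`) and `W0` (`m x K`).
#' @export
init_transforms <- function(X0, Q, H, lambda_ridge = 1e-4) {
  X0 <- as.matrix(X0)
  K <- nrow(X0)
  G <- tcrossprod(X0) + diag(lambda_ridge, K)
  sol <- tryCatch(solve(G), error = function(e)
    stop("X0 X0' is singular; use lambda_ridge > 0", call. = FALSE))
  list(A0 = as.matrix(Q) %*% t(X0) %*% sol,
       W0 = as.matrix(H) %*% t(X0) %*% sol)
}

#' Train a label-consistent K-SVD model
#'
#' Minimizes
#' `alpha ||Y - DX||^2 + beta ||Q - AX||^2 + gamma ||H - WX||^2`
#' subject to `||x_i||_0 <= T` by the stacked-system trick: K-SVD is run on
#' `Y_new = (sqrt(alpha) Y; sqrt(beta) Q; sqrt(gamma) H)` with the stacked
#' dictionary `D_new = (sqrt(alpha) D; sqrt(beta) A; sqrt(gamma) W)`
#' (columns normalized), then `D`, `A`, `W` are unstacked, rescaled by the
#' stacking constants and de-normalized per column (`d/||d||`, `a/||d||`,
#' `w/||d||`) so that coding against unit-norm atoms matches the classifier
#' scale.
#'
#' @param Y Training signals (already embedded, if a kernel is used),
#'   `n x N` with one column per sample.
#' @param labels Integer class labels `1..m`.
#' @param weights An [objective_weights()] object.
#' @param K Number of atoms, `K >= m`.
#' @param T Sparsity bound.
#' @param n_iter K-SVD iterations.
#' @param seed Seed for the class-balanced dictionary initialization.
#' @param lambda_init Ridge penalty for [init_transforms()].
#' @return Object of class `lcksvd_fit`: list with `D`, `A`, `W`,
#'   `atom_class`, `weights`, `T`, `objective_trace`.
#' @export
lcksvd_train <- function(Y, labels, weights, K, T, n_iter = 30, seed = 1L,
                         lambda_init = 1e-4) {
  stopifnot(inherits(weights, "objective_weights"))
  Y <- as.matrix(Y)
  labels <- as.integer(labels)
  m <- length(unique(labels))
  if (K < m)
    stop("K must be at least the number of classes", call. = FALSE)
  D0 <- init_dictionary(Y, labels, K, seed, "class_balanced_samples")
  Q <- build_Q(labels, D0$atom_class)
  H <- build_H(labels, max(labels))
  X0 <- omp_batch(D0$atoms, Y, T)$codes
  tr0 <- init_transforms(X0, Q, H, lambda_init)

  sa <- sqrt(weights$alpha); sb <- sqrt(weights$beta); sg <- sqrt(weights$gamma)
  n <- nrow(Y); mH <- nrow(H)
  Ynew <- rbind(sa * Y, sb * Q, sg * H)
  Dnew <- rbind(sa * D0$atoms, sb * tr0$A0, sg * tr0$W0)
  nrm <- sqrt(colSums(Dnew^2))
  Dnew <- sweep(Dnew, 2, nrm, "/")

  fit <- ksvd_fit(Ynew, Dnew, T, n_iter)
  Dn <- fit$dictionary$atoms
  Dblk <- Dn[seq_len(n), , drop = FALSE] / sa
  Ablk <- Dn[n + seq_len(K), , drop = FALSE] / sb
  Wblk <- Dn[n + K + seq_len(mH), , drop = FALSE] / sg
  cn <- sqrt(colSums(Dblk^2))
  cn[cn < 1e-12] <- 1
  structure(list(
    D = sweep(Dblk, 2, cn, "/"),
    A = sweep(Ablk, 2, cn, "/"),
    W = sweep(Wblk, 2, cn, "/"),
    atom_class = D0$atom_class,
    weights = weights,
    T = as.integer(T),
    objective_trace = fit$objective_trace
  ), class = "lcksvd_fit")
}

#' Sparse-code and classify embedded signals
#'
#' Codes each column of `Y` with OMP against the model dictionary and
#' applies the linear classifier `W`; the predicted class is the argmax of
#' the scores, ties broken toward the lowest class index.
#'
#' @param fit An `lcksvd_fit`.
#' @param Y Embedded signals, one column per sample.
#' @return List with `labels`, `scores` (`m x N`), `codes` (`K x N`).
#' @export
lcksvd_classify <- function(fit, Y) {
  stopifnot(inherits(fit, "lcksvd_fit"))
  X <- omp_batch(fit$D, as.matrix(Y), fit$T)$codes
  S <- fit$W %*% X
  lab <- apply(S, 2, which.max)      # which.max: lowest index on ties
  list(labels = as.integer(lab), scores = S, codes = X)
}

#' Classification accuracy in percent
#'
#' @param predicted,truth Equal-length label vectors.
#' @return `100 * matches / total`.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) == 0 || length(truth) == 0)
    stop("cannot compute accuracy of empty predictions", call. = FALSE)
  if (length(predicted) != length(truth))
    stop("predicted and truth differ in length", call. = FALSE)
  100 * mean(as.character(predicted) == as.character(truth))
}
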