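#' RBF kernel between two feature vectors
#'
#' `k(xi, xj) = exp(-||xi - xj||^2 / sigma^2)`, where `sigma` is the scale
#' factor controlling how the data spread out in the implicit
#' high-dimensional space.
#'
#' @param xi,xj Numeric vectors of equal length.
#' @param sigma Positive kernel scale.
#' @return Similarity in `(0, 1]`.
#' @export
rbf_kernel <- function(xi, xj, sigma) {
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be positive", call. = FALSE)
  if (length(xi) != length(xj))
    stop("xi and xj must have the same length", call. = FALSE)
  exp(-sum((xi - xj)^2) / sigma^2)
}

#' RBF kernel matrix between two sets of feature rows
#'
#' @param X1,X2 Numeric matrices with samples in rows and a common feature
#'   dimension.
#' @param sigma Positive kernel scale.
#' @return `nrow(X1)` x `nrow(X2)` similarity matrix.
#' @export
kernel_matrix <- function(X1, X2, sigma) {
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be positive", call. = FALSE)
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (ncol(X1) != ncol(X2))
    stop("feature dimensions do not match", call. = FALSE)
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  d2 <- pmax(d2, 0)
  exp(-d2 / sigma^2)
}

#' Kernel configuration: scale, reference set and standardization
#'
#' Freezes everything needed to embed new samples: the per-sensor centering
#' and scaling constants estimated on the training set, the standardized
#' training rows used as landmarks, and the kernel scale `sigma`.
#'
#' @param reference Numeric matrix of raw (masked) training features,
#'   samples in rows.
#' @param sigma Positive kernel scale, or `NULL` to use the median
#'   heuristic: `sigma = sqrt(median ||xi - xj||^2)` over standardized
#'   training pairs.
#' @return Object of class `kernel_config` with elements `sigma`, `center`,
#'   `scale`, `reference` (standardized rows).
#' @export
kernel_config <- function(reference, sigma = NULL) {
  reference <- as.matrix(reference)
  if (nrow(reference) == 0)
    stop("reference set must be non-empty", call. = FALSE)
  ctr <- unname(colMeans(reference))
  scl <- unname(apply(reference, 2, stats::sd))
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  ref_s <- sweep(sweep(reference, 2, ctr), 2, scl, "/")
  dimnames(ref_s) <- NULL
  if (is.null(sigma)) {
    d2 <- as.vector(stats::dist(ref_s))^2
    sigma <- sqrt(stats::median(d2[d2 > 0]))
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be positive", call. = FALSE)
  structure(list(sigma = sigma, center = ctr, scale = scl,
                 reference = ref_s),
            class = "kernel_config")
}

#' Empirical kernel map
#'
#' Embeds each row of `X` as its vector of RBF similarities to the
#' reference (training) rows, after applying the frozen standardization.
#' Applied to the training set itself this returns the (symmetric) Gram
#' matrix; the embedding dimension equals the reference-set size.
#'
#' @param config A [kernel_config()].
#' @param X Numeric matrix of raw feature rows.
#' @return `nrow(X)` x `nrow(reference)` matrix of similarities.
#' @export
empirical_kernel_map <- function(config, X) {
  stopifnot(inherits(config, "kernel_config"))
  X <- as.matrix(X)
  if (ncol(X) != length(config$center))
    stop("feature dimension does not match kernel reference", call. = FALSE)
  Xs <- sweep(sweep(X, 2, config$center), 2, config$scale, "/")
  kernel_matrix(Xs, config$reference, config$sigma)
}
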