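#' Train an extreme learning machine
#'
#' Single-hidden-layer network with random fixed hidden weights: input
#' weights and biases are drawn from a seeded uniform(-1, 1), the hidden
#' output is `G = sigmoid(X W' + b)`, and the output weights solve a ridge
#' regression from `G` onto one-hot class targets.  Used as the
#' pattern-recognition stage for plain K-SVD sparse codes, which have no
#' classifier of their own.
#'
#' @param X Feature or sparse-code matrix, samples in rows.
#' @param labels Class label per sample.
#' @param L Hidden units (default 100).
#' @param lambda_ridge Ridge penalty on the output solve (default 1e-3).
#' @param seed Integer seed; the same seed gives the identical model.
#' @return Object of class `elm_model`.
#' @export
elm_train <- function(X, labels, L = 100, lambda_ridge = 1e-3, seed = 1L) {
  X <- as.matrix(X)
  L <- as.integer(L)
  if (L < 1) stop("L must be >= 1", call. = FALSE)
  if (length(labels) != nrow(X))
    stop("labels must have one entry per row of X", call. = FALSE)
  classes <- sort(unique(labels))
  yi <- match(labels, classes)
  set.seed(seed)
  Win <- matrix(stats::runif(L * ncol(X), -1, 1), L, ncol(X))
  b <- stats::runif(L, -1, 1)
  G <- stats::plogis(X %*% t(Win) + matrix(b, nrow(X), L, byrow = TRUE))
  Tg <- matrix(0, nrow(X), length(classes))
  Tg[cbind(seq_len(nrow(X)), yi)] <- 1
  A <- crossprod(G) + diag(lambda_ridge, L)
  beta <- tryCatch(solve(A, crossprod(G, Tg)), error = function(e)
    stop("hidden-layer system is singular; use lambda_ridge > 0",
         call. = FALSE))
  structure(list(input_weights = Win, biases = b,
                 output_weights = t(beta), classes = classes,
                 L = L, lambda_ridge = lambda_ridge, seed = seed,
                 activation = "sigmoid"),
            class = "elm_model")
}

#' Predict classes with a trained ELM
#'
#' Argmax of the output scores; ties break toward the lowest class index.
#'
#' @param model An `elm_model`.
#' @param X Feature matrix, samples in rows.
#' @return Vector of predicted labels (same type as the training labels).
#' @export
elm_predict <- function(model, X) {
  stopifnot(inherits(model, "elm_model"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$input_weights))
    stop("feature dimension does not match the model", call. = FALSE)
  G <- stats::plogis(X %*% t(model$input_weights) +
                       matrix(model$biases, nrow(X), model$L, byrow = TRUE))
  S <- G %*% t(model$output_weights)
  model$classes[apply(S, 1, which.max)]
}
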