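#' Apply a binary sensor-selection mask
#'
#' Drops the feature columns whose bit is 0.  The mask is how the
#' redundant, cross-sensitive part of the array is removed before the
#' dictionary is initialized; at least one sensor must stay selected.
#'
#' @param features An `enose_features` object or plain matrix.
#' @param bits Logical/0-1 vector, one bit per sensor.
#' @return The masked object, sensor names preserved for kept columns.
#' @export
apply_sensor_mask <- function(features, bits) {
  bits <- as.logical(bits)
  vals <- if (inherits(features, "enose_features")) features$values
          else as.matrix(features)
  if (length(bits) != ncol(vals))
    stop("mask length must equal the sensor count", call. = FALSE)
  if (!any(bits))
    stop("sensor mask must select at least one sensor", call. = FALSE)
  kept <- vals[, bits, drop = FALSE]
  if (inherits(features, "enose_features"))
    enose_features(kept, features$labels, features$sensor_names[bits])
  else kept
}

#' E-LCKSVD run configuration
#'
#' Bundles every tunable of the pipeline.  `weights`, `sigma` and
#' `sensor_mask` may each be set to the string `"optimize"` to hand them to
#' the swarm in [e_lcksvd_optimize()].
#'
#' @param K Dictionary size (default 16).
#' @param T Sparsity bound (default 4).
#' @param n_iter K-SVD iterations (default 15).
#' @param weights An [objective_weights()], or `"optimize"`.  The default
#'   is the configuration found best for juice storage-day data
#'   (`alpha = 0.7661`, `beta = 0.0351`).
#' @param sigma Kernel scale, `NULL` for the median heuristic, or
#'   `"optimize"`.
#' @param sensor_mask Logical vector, `NULL` for all sensors, or
#'   `"optimize"`.
#' @param kernel Use the RBF empirical kernel map (`TRUE`) or learn in the
#'   raw standardized feature space (`FALSE`).
#' @param sigma_range Search range for `sigma` under optimization.
#' @param lambda_init Ridge penalty for the transform/classifier init.
#' @param seed Integer seed.
#' @return A list of class `elcksvd_config`.
#' @export
elcksvd_config <- function(K = 16, T = 4, n_iter = 15,
                           weights = objective_weights(0.7661, 0.0351),
                           sigma = NULL, sensor_mask = NULL,
                           kernel = TRUE, sigma_range = c(1e-2, 1e3),
                           lambda_init = 1e-4, seed = 1L) {
  structure(list(K = as.integer(K), T = as.integer(T),
                 n_iter = as.integer(n_iter), weights = weights,
                 sigma = sigma, sensor_mask = sensor_mask,
                 kernel = isTRUE(kernel), sigma_range = sigma_range,
                 lambda_init = lambda_init, seed = as.integer(seed)),
            class = "elcksvd_config")
}

is_optimize <- function(x) identical(x, "optimize")

#' Fit the full E-LCKSVD pipeline
#'
#' Runs mask -> per-sensor z-score standardization (training statistics
#' only) -> RBF empirical kernel map -> label-consistent K-SVD, and wraps
#' the result in a self-contained model that can classify raw feature rows.
#'
#' @param train An `enose_features` object (training split).
#' @param config An [elcksvd_config()] with no `"optimize"` placeholders.
#' @param test Optional `enose_features` test split for the report.
#' @return List with `model` (class `elcksvd_model`) and `report`
#'   (train/test accuracy, objective trace, config echo).
#' @export
e_lcksvd_fit <- function(train, config = elcksvd_config(), test = NULL) {
  stopifnot(inherits(train, "enose_features"))
  if (is_optimize(config[["weights"]]) || is_optimize(config[["sigma"]]) ||
      is_optimize(config[["sensor_mask"]]))
    stop("config still contains \"optimize\" placeholders; use e_lcksvd_optimize",
         call. = FALSE)
  mask <- config[["sensor_mask"]]
  if (is.null(mask)) mask <- rep(TRUE, ncol(train$values))
  mask <- as.logical(mask)
  masked <- apply_sensor_mask(train, mask)
  class_labels <- unique(train$labels)          # first-seen order
  y <- match(train$labels, class_labels)

  if (config$kernel) {
    kc <- kernel_config(masked$values, config[["sigma"]])
    Yemb <- t(empirical_kernel_map(kc, masked$values))
  } else {
    kc <- NULL
    ctr <- unname(colMeans(masked$values))
    scl <- unname(apply(masked$values, 2, stats::sd))
    scl[!is.finite(scl) | scl < 1e-12] <- 1
    Yemb <- t(sweep(sweep(masked$values, 2, ctr), 2, scl, "/"))
  }
  fit <- lcksvd_train(Yemb, y, config[["weights"]], config$K, config$T,
                      config$n_iter, config$seed, config$lambda_init)
  model <- structure(list(
    D = fit$D, A = fit$A, W = fit$W,
    atom_class = fit$atom_class,
    weights = fit$weights, T = fit$T,
    kernel = kc,
    standardize = if (is.null(kc)) list(center = ctr, scale = scl) else NULL,
    sensor_mask = mask,
    class_labels = class_labels,
    sensor_names = train$sensor_names,
    objective_trace = fit$objective_trace
  ), class = "elcksvd_model")

  pred_tr <- predict(model, train)
  report <- list(
    train_accuracy = accuracy(pred_tr, train$labels),
    test_accuracy = if (!is.null(test))
      accuracy(predict(model, test), test$labels) else NA_real_,
    objective_trace = fit$objective_trace,
    config = config
  )
  list(model = model, report = report)
}

#' Embed raw features the way a model expects
#' @keywords internal
model_embed <- function(model, values) {
  vals <- apply_sensor_mask(values, model$sensor_mask)
  if (!is.null(model$kernel)) {
    t(empirical_kernel_map(model$kernel, vals))
  } else {
    t(sweep(sweep(vals, 2, model$standardize$center), 2,
            model$standardize$scale, "/"))
  }
}

#' Classify new samples with a fitted E-LCKSVD model
#'
#' Applies the stored sensor mask, standardization and kernel map, sparse
#' codes the embedded samples against the model dictionary, and takes the
#' argmax of the linear classifier scores (lowest class index on ties).
#'
#' @param object An `elcksvd_model`.
#' @param newdata An `enose_features` object or feature matrix with the
#'   full (unmasked) sensor columns.
#' @param type `"class"` (default), `"scores"` or `"codes"`.
#' @param ... Unused.
#' @return Predicted labels, score matrix, or sparse-code matrix.
#' @export
predict.elcksvd_model <- function(object, newdata,
                                  type = c("class", "scores", "codes"),
                                  ...) {
  type <- match.arg(type)
  vals <- if (inherits(newdata, "enose_features")) newdata$values
          else as.matrix(newdata)
  if (ncol(vals) != length(object$sensor_mask))
    stop("newdata has the wrong number of sensor columns", call. = FALSE)
  Yemb <- model_embed(object, vals)
  res <- lcksvd_classify(
    structure(list(D = object$D, W = object$W, T = object$T),
              class = "lcksvd_fit"), Yemb)
  switch(type,
         class = object$class_labels[res$labels],
         scores = res$scores,
         codes = res$codes)
}

#' @export
print.elcksvd_model <- function(x, ...) {
  cat(sprintf("E-LCKSVD model: %d atoms, T = %d, %d classes, %d/%d sensors, %s\n",
              ncol(x$D), x$T, length(x$class_labels),
              sum(x$sensor_mask), length(x$sensor_mask),
              if (is.null(x$kernel)) "linear"
              else sprintf("RBF kernel (sigma = %.3g, %d landmarks)",
                           x$kernel$sigma, nrow(x$kernel$reference))))
  invisible(x)
}

# stratified k-fold assignment, reproducible under seed
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# cross-validated accuracy of one resolved configuration
cv_fitness <- function(train, config, k = 4, seed = 1L) {
  fold <- stratified_folds(train$labels, k, seed)
  accs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- enose_features(train$values[fold != f, , drop = FALSE],
                         train$labels[fold != f], train$sensor_names)
    te <- enose_features(train$values[fold == f, , drop = FALSE],
                         train$labels[fold == f], train$sensor_names)
    fit <- tryCatch(e_lcksvd_fit(tr, config, te),
                    error = function(e) NULL)
    accs[f] <- if (is.null(fit)) 0 else fit$report$test_accuracy
  }
  mean(accs)
}

#' Jointly optimize weights, kernel scale and sensor mask
#'
#' Wraps [e_lcksvd_fit()] in a swarm fitness — the k-fold cross-validated
#' accuracy on the training split (no test data touched) — and searches
#' the 19-dimensional mixed encoding (3 weight logits, 1 kernel-scale
#' coordinate, 15 sensor bits) with the configured strategy.  Fields of
#' `config` not marked `"optimize"` stay frozen: their encoding dimensions
#' are collapsed so all particles agree there.  The best decoded
#' parameters are refitted on the full training split.
#'
#' @param train Training `enose_features`.
#' @param config An [elcksvd_config()] with at least one field set to
#'   `"optimize"`.
#' @param swarm A [swarm_config()]; `n_dim` is forced to
#'   `4 + n_sensors`.
#' @param cv_folds Folds for the fitness (default 4).
#' @param test Optional test split for the final report only.
#' @return List with `model`, `report`, `best` (decoded parameters) and
#'   `trace` (best CV fitness per iteration).
#' @export
e_lcksvd_optimize <- function(train, config = elcksvd_config(
                                weights = "optimize", sigma = "optimize",
                                sensor_mask = "optimize"),
                              swarm = swarm_config(n_dim = 4 +
                                                     ncol(train$values)),
                              cv_folds = 4, test = NULL) {
  stopifnot(inherits(train, "enose_features"),
            inherits(swarm, "swarm_config"))
  n_sens <- ncol(train$values)
  opt_w <- is_optimize(config[["weights"]])
  opt_s <- is_optimize(config[["sigma"]])
  opt_m <- is_optimize(config[["sensor_mask"]])
  if (!(opt_w || opt_s || opt_m))
    stop("nothing to optimize: mark weights, sigma or sensor_mask",
         call. = FALSE)

  n_dim <- 4L + n_sens
  lo <- rep_len(swarm$lower, n_dim); hi <- rep_len(swarm$upper, n_dim)
  orig_lo4 <- lo[4]; orig_hi4 <- hi[4]
  lo[4 + seq_len(n_sens)] <- pmax(lo[4 + seq_len(n_sens)], -1)
  hi[4 + seq_len(n_sens)] <- pmin(hi[4 + seq_len(n_sens)], 1)
  # freeze dimensions of parameters that are not optimized
  if (!opt_w) {
    z <- log(c(config[["weights"]]$alpha, config[["weights"]]$beta,
               config[["weights"]]$gamma))
    lo[1:3] <- z; hi[1:3] <- z + 1e-9
  }
  if (!opt_s) {
    sr <- config$sigma_range
    sig <- if (is.null(config[["sigma"]]))
      kernel_config(train$values, NULL)$sigma else config[["sigma"]]
    sig <- min(max(sig, sr[1]), sr[2])
    s01 <- (log(sig) - log(sr[1])) / (log(sr[2]) - log(sr[1]))
    p4 <- orig_lo4 + s01 * (orig_hi4 - orig_lo4)
    lo[4] <- p4; hi[4] <- p4 + 1e-9
  }
  if (!opt_m) {
    mk <- config[["sensor_mask"]]
    if (is.null(mk)) mk <- rep(TRUE, n_sens)
    v <- ifelse(as.logical(mk), 0.5, -0.5)
    lo[4 + seq_len(n_sens)] <- v
    hi[4 + seq_len(n_sens)] <- v + 1e-9
  }
  sw <- swarm
  sw$n_dim <- n_dim; sw$lower <- lo; sw$upper <- hi

  decode <- function(pos)
    decode_particle(pos, lower = c(0, 0, 0, orig_lo4),
                    upper = c(0, 0, 0, orig_hi4),
                    sigma_range = config$sigma_range, n_bits = n_sens)
  resolved <- function(dec) {
    cfg <- config
    # [ <- list(...) keeps NULL-valued elements instead of deleting them
    cfg["weights"] <- list(if (opt_w) dec$weights else config[["weights"]])
    cfg["sigma"] <- list(if (opt_s) dec$sigma else config[["sigma"]])
    cfg["sensor_mask"] <- list(if (opt_m) dec$bits
                               else config[["sensor_mask"]])
    cfg
  }
  fitness <- function(dec)
    cv_fitness(train, resolved(dec), cv_folds, seed = config$seed)

  # warm start: the incumbent configuration enters as the first particle,
  # so the search can only move away from it for a better CV fitness
  inc <- numeric(n_dim)
  w0 <- if (opt_w) objective_weights(0.7661, 0.0351) else config[["weights"]]
  inc[1:3] <- log(c(w0$alpha, w0$beta, w0$gamma))
  sr <- config$sigma_range
  sig0 <- if (opt_s || is.null(config[["sigma"]]))
    kernel_config(train$values, NULL)$sigma else config[["sigma"]]
  sig0 <- min(max(sig0, sr[1]), sr[2])
  s01 <- (log(sig0) - log(sr[1])) / (log(sr[2]) - log(sr[1]))
  inc[4] <- orig_lo4 + s01 * (orig_hi4 - orig_lo4)
  mk0 <- if (opt_m || is.null(config[["sensor_mask"]]))
    rep(TRUE, n_sens) else as.logical(config[["sensor_mask"]])
  inc[4 + seq_len(n_sens)] <- ifelse(mk0, 0.5, -0.5)

  res <- swarm_optimize(fitness, sw, decode, init = matrix(inc, 1))
  best_cfg <- resolved(res$best)
  final <- e_lcksvd_fit(train, best_cfg, test)
  final$best <- res$best
  final$trace <- res$history
  final$best_cv_accuracy <- res$best_fitness
  final
}
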