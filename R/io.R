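#' Read and write feature matrices as CSV
#'
#' The feature CSV has one row per sample, a header of sensor names and a
#' final `label` column.  Values round-trip to at least 12 significant
#' digits; labels round-trip exactly.
#'
#' @param features An `enose_features` object.
#' @param path File path.
#' @return `read_features_csv` returns an `enose_features` object;
#'   `write_features_csv` returns `path` invisibly.
#' @export
write_features_csv <- function(features, path) {
  stopifnot(inherits(features, "enose_features"))
  df <- as.data.frame(apply(features$values, 2, function(col)
    sprintf("%.15g", col), simplify = FALSE), check.names = FALSE)
  df$label <- as.character(features$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  if (!"label" %in% names(df))
    stop("feature CSV is missing the 'label' column", call. = FALSE)
  labels <- df$label
  df$label <- NULL
  if (ncol(df) == 0)
    stop("feature CSV has no sensor columns", call. = FALSE)
  vals <- vapply(df, as.numeric, numeric(nrow(df)))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(NULL, names(df)))
  if (anyNA(vals))
    stop("feature CSV contains non-numeric sensor values", call. = FALSE)
  suppressWarnings({
    li <- as.integer(labels)
    if (!anyNA(li) && all(li == as.numeric(labels))) labels <- li
  })
  enose_features(vals, labels, names(df))
}

#' Read and write response curves as long-format CSV
#'
#' Columns: `sample_id`, `class`, `sensor`, `time_min`, `voltage`.
#'
#' @param curves A `response_curve_set`.
#' @param path File path.
#' @return `write_curves_csv` returns `path` invisibly;
#'   `read_curves_csv` returns a data.frame in the long format.
#' @export
write_curves_csv <- function(curves, path) {
  stopifnot(inherits(curves, "response_curve_set"))
  d <- dim(curves$curves)
  long <- data.frame(
    sample_id = rep(seq_len(d[1]), times = d[2] * d[3]),
    class = rep(curves$labels, times = d[2] * d[3]),
    sensor = rep(rep(curves$sensor_names, each = d[1]), times = d[3]),
    time_min = rep(curves$time_min, each = d[1] * d[2]),
    voltage = sprintf("%.15g", as.vector(curves$curves))
  )
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curves_csv
#' @export
read_curves_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("sample_id", "class", "sensor", "time_min", "voltage")
  if (!all(need %in% names(df)))
    stop("curves CSV must have columns sample_id, class, sensor, time_min, voltage",
         call. = FALSE)
  df
}

fmt_num <- function(x) sprintf("%.17g", x)

array_to_json <- function(a) {
  list(dim = if (is.matrix(a)) dim(a) else length(a),
       data = fmt_num(as.vector(a)))
}

json_to_array <- function(j) {
  v <- as.numeric(j$data)
  d <- as.integer(j$dim)
  if (length(d) == 2) matrix(v, d[1], d[2]) else v
}

#' Save and load an E-LCKSVD model
#'
#' The model is written as a JSON archive with every numeric array stored
#' at full precision (`%.17g`), so a load after save is bit-exact.
#'
#' @param model An `elcksvd_model`.
#' @param path File path (`.json`).
#' @return `load_model` returns the model; `save_model` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "elcksvd_model"))
  obj <- list(
    format = "elcksvd_model", version = 1L,
    D = array_to_json(model$D),
    A = array_to_json(model$A),
    W = array_to_json(model$W),
    atom_class = model$atom_class,
    weights = list(alpha = fmt_num(model$weights$alpha),
                   beta = fmt_num(model$weights$beta),
                   gamma = fmt_num(model$weights$gamma)),
    T = model$T,
    sensor_mask = as.integer(model$sensor_mask),
    class_labels = as.character(model$class_labels),
    class_labels_type = class(model$class_labels)[1],
    sensor_names = model$sensor_names,
    kernel = if (!is.null(model$kernel)) list(
      sigma = fmt_num(model$kernel$sigma),
      center = fmt_num(model$kernel$center),
      scale = fmt_num(model$kernel$scale),
      reference = array_to_json(model$kernel$reference)
    ) else NULL,
    standardize = if (!is.null(model$standardize)) list(
      center = fmt_num(model$standardize$center),
      scale = fmt_num(model$standardize$scale)
    ) else NULL
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"),
             path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "elcksvd_model"))
    stop("not an elcksvd model archive", call. = FALSE)
  cl <- obj$class_labels
  if (identical(obj$class_labels_type, "integer")) cl <- as.integer(cl)
  if (identical(obj$class_labels_type, "numeric")) cl <- as.numeric(cl)
  structure(list(
    D = json_to_array(obj$D),
    A = json_to_array(obj$A),
    W = json_to_array(obj$W),
    atom_class = as.integer(obj$atom_class),
    weights = objective_weights(as.numeric(obj$weights$alpha),
                                as.numeric(obj$weights$beta),
                                as.numeric(obj$weights$gamma)),
    T = as.integer(obj$T),
    kernel = if (!is.null(obj$kernel)) structure(list(
      sigma = as.numeric(obj$kernel$sigma),
      center = as.numeric(obj$kernel$center),
      scale = as.numeric(obj$kernel$scale),
      reference = json_to_array(obj$kernel$reference)
    ), class = "kernel_config") else NULL,
    standardize = if (!is.null(obj$standardize)) list(
      center = as.numeric(obj$standardize$center),
      scale = as.numeric(obj$standardize$scale)
    ) else NULL,
    sensor_mask = as.logical(obj$sensor_mask),
    class_labels = cl,
    sensor_names = obj$sensor_names,
    objective_trace = NULL
  ), class = "elcksvd_model")
}
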