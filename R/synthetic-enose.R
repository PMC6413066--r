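#' Default metal-oxide sensor array
#'
#' Model names of the 15 commercial MOS gas sensors the simulator emulates
#' (Figaro TGS and Winsen MQ/MS/MP series, the arrays typically used in
#' food-odor electronic noses).
#'
#' @return Character vector of 15 sensor names.
#' @export
default_sensor_names <- function() {
  c("TGS813", "TGS816", "TGS822", "TGS2600", "TGS2602", "TGS2610C",
    "TGS2611E", "TGS2620", "MQ135A", "MQ135", "MQ136", "MQ137",
    "MS1100", "MP4", "MP503")
}

#' Sampling design for a synthetic electronic-nose experiment
#'
#' Describes one storage-day study: each class corresponds to one sampling
#' session (juice stored for a different number of days), each session fills
#' `vessels_per_session` vessels, and every vessel is measured
#' `reps_per_vessel` times.  A measurement exposes the sensor array to clean
#' air (baseline), then to the headspace gas (injection), then to clean air
#' again (recovery).
#'
#' @param n_classes Number of storage-day groups (sampling sessions).
#' @param vessels_per_session Vessels filled per session.
#' @param reps_per_vessel Repeated measurements per vessel.
#' @param n_sensors Number of MOS sensors in the array.
#' @param baseline_minutes,injection_minutes,recovery_minutes Phase durations
#'   in minutes; all must be positive.
#' @param sample_rate Sampling rate of the acquisition system, points/minute.
#' @param noise_sd Standard deviation of additive white measurement noise
#'   on the sampled voltages, volts.
#' @param sensitivity_sd Fractional per-measurement sensitivity jitter of
#'   each sensor (measurement-to-measurement repeatability of MOS sensors,
#'   typically 5-10 percent); multiplies the response amplitude.
#' @param nonlinearity Strength in `[0, 1]` of the nonlinear components of
#'   the sensor response (class-signature interactions and concentration
#'   power laws). At 0 the class-conditional feature means are affine in the
#'   class signature.
#' @param seed Integer seed; the same design yields bit-identical data.
#' @return An object of class `sampling_design`.
#' @export
sampling_design <- function(n_classes = 4, vessels_per_session = 4,
                            reps_per_vessel = 6, n_sensors = 15,
                            baseline_minutes = 5, injection_minutes = 7,
                            recovery_minutes = 5, sample_rate = 10,
                            noise_sd = 0.05, sensitivity_sd = 0.06,
                            nonlinearity = 1, seed = 1L) {
  counts <- c(n_classes = n_classes, vessels_per_session = vessels_per_session,
              reps_per_vessel = reps_per_vessel, n_sensors = n_sensors,
              sample_rate = sample_rate)
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts)))
    stop("invalid design: all counts must be integers >= 1", call. = FALSE)
  durs <- c(baseline_minutes, injection_minutes, recovery_minutes)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("invalid design: phase durations must be positive", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("invalid design: noise_sd must be >= 0", call. = FALSE)
  if (!is.finite(sensitivity_sd) || sensitivity_sd < 0)
    stop("invalid design: sensitivity_sd must be >= 0", call. = FALSE)
  if (!is.finite(nonlinearity) || nonlinearity < 0 || nonlinearity > 1)
    stop("invalid design: nonlinearity must lie in [0, 1]", call. = FALSE)
  structure(list(
    n_classes = as.integer(n_classes),
    vessels_per_session = as.integer(vessels_per_session),
    reps_per_vessel = as.integer(reps_per_vessel),
    n_sensors = as.integer(n_sensors),
    baseline_minutes = baseline_minutes,
    injection_minutes = injection_minutes,
    recovery_minutes = recovery_minutes,
    sample_rate = sample_rate,
    noise_sd = noise_sd,
    sensitivity_sd = sensitivity_sd,
    nonlinearity = nonlinearity,
    seed = as.integer(seed)
  ), class = "sampling_design")
}

#' @export
print.sampling_design <- function(x, ...) {
  n <- x$n_classes * x$vessels_per_session * x$reps_per_vessel
  cat(sprintf(
    "E-nose sampling design: %d classes x %d vessels x %d reps = %d samples\n",
    x$n_classes, x$vessels_per_session, x$reps_per_vessel, n))
  cat(sprintf("  %d sensors; %g + %g + %g min at %g pts/min; noise sd %g V; nonlinearity %g\n",
              x$n_sensors, x$baseline_minutes, x$injection_minutes,
              x$recovery_minutes, x$sample_rate, x$noise_sd, x$nonlinearity))
  invisible(x)
}

#' Simulate electronic-nose response curves
#'
#' Generates per-sample, per-sensor voltage time series following the
#' three-phase protocol: the curve sits at the sensor baseline during the
#' clean-air phase, rises along a saturating logistic profile toward
#' baseline + amplitude during gas injection, and decays exponentially back
#' to baseline during recovery.
#'
#' The amplitude of sensor s for a sample of class c is `L[s,] %*% g[,c]`,
#' where the latent class signatures `g[,c]` lie on an aging trajectory:
#' affine in the storage-time coordinate when `nonlinearity = 0`, bent by a
#' quadratic curvature term as `nonlinearity` grows, so that intermediate
#' storage-day classes approach convex combinations of their neighbours and
#' are no longer cleanly separated by linear coding.  The loadings `L` are
#' shared across sensors (cross-sensitivity, hence correlated, redundant
#' feature columns).  Each measurement additionally carries a random
#' headspace concentration factor entering through sensor-specific power
#' laws (exponents shrink below 1 as `nonlinearity` grows) and a small
#' per-vessel intercept.
#'
#' @param design A [sampling_design()].
#' @return An object of class `response_curve_set` with elements `curves`
#'   (array samples x sensors x timepoints), `labels`, `time_min`,
#'   `phase_boundaries` (indices `baseline_end`, `injection_end`),
#'   `vessel`, `sensor_names` and `design`.
#' @export
simulate_response_set <- function(design) {
  if (!inherits(design, "sampling_design"))
    design <- do.call(sampling_design, as.list(design))
  set.seed(design$seed)
  m <- design$n_classes
  ns <- design$n_sensors
  n <- m * design$vessels_per_session * design$reps_per_vessel
  total_min <- design$baseline_minutes + design$injection_minutes +
    design$recovery_minutes
  nt <- round(total_min * design$sample_rate)
  tm <- seq_len(nt) / design$sample_rate
  b_end <- round(design$baseline_minutes * design$sample_rate)
  i_end <- round((design$baseline_minutes + design$injection_minutes) *
                   design$sample_rate)

  # latent structure drawn once per design seed.  Storage-day classes sit
  # on an aging trajectory in volatile space: the latent class signature
  # g(u) is affine in storage time u for nonlinearity = 0 and bends with a
  # quadratic curvature term as nonlinearity grows, so intermediate classes
  # approach convex combinations of their neighbours — entangled for linear
  # coding, resolvable from local (kernel) neighbourhoods
  p <- 3L                                    # latent aroma factors
  u <- seq(0, 1, length.out = m)             # storage-time coordinate
  a0 <- stats::runif(p, 0.3, 0.8)            # trajectory origin
  b0 <- stats::runif(p, -1, 1) * 0.7         # trajectory direction
  q0 <- stats::runif(p, -1, 1) * 0.7         # trajectory curvature
  g <- vapply(u, function(ui)
    a0 + b0 * ui + design$nonlinearity * q0 * 4 * ui * (1 - ui),
    numeric(p))                              # class signatures, p x m
  L <- matrix(stats::runif(ns * p, 0.2, 1), ns, p)  # shared sensor loadings
  amp0 <- pmax(L %*% g, 0.05)                # sensors x classes, volts

  baseline <- stats::runif(ns, 0.4, 0.8)            # volts
  k_rise <- stats::runif(ns, 1.5, 2.5)              # logistic rate, 1/min
  t_mid <- stats::runif(ns, 1.0, 1.8)               # logistic midpoint, min
  tau_rec <- stats::runif(ns, 0.5, 0.8)             # recovery time const, min
  # concentration power-law exponents; all 1 when nonlinearity = 0
  expo <- 1 - design$nonlinearity * stats::runif(ns, 0.2, 0.7)

  labels <- rep(seq_len(m), each = design$vessels_per_session *
                  design$reps_per_vessel)
  vessel_within <- rep(rep(seq_len(design$vessels_per_session),
                           each = design$reps_per_vessel), times = m)
  vessel <- (labels - 1L) * design$vessels_per_session + vessel_within
  n_vessels <- m * design$vessels_per_session
  vessel_fx <- stats::rnorm(n_vessels, 0, 0.05)
  conc <- stats::runif(n, 0.8, 1.2)                 # headspace concentration

  # normalized logistic rise over the injection phase, 0 at injection start
  t_inj0 <- design$baseline_minutes
  t_rec0 <- t_inj0 + design$injection_minutes
  curves <- array(0, dim = c(n, ns, nt))
  shape <- matrix(0, ns, nt)    # per-sensor unit-amplitude profile
  for (s in seq_len(ns)) {
    prof <- numeric(nt)
    inj <- tm > t_inj0 & tm <= t_rec0
    rec <- tm > t_rec0
    s0 <- stats::plogis(-k_rise[s] * t_mid[s])
    prof[inj] <- (stats::plogis(k_rise[s] * (tm[inj] - t_inj0 - t_mid[s])) - s0) /
      (1 - s0)
    s_end <- (stats::plogis(k_rise[s] * (design$injection_minutes - t_mid[s])) - s0) /
      (1 - s0)
    prof[rec] <- s_end * exp(-(tm[rec] - t_rec0) / tau_rec[s])
    shape[s, ] <- prof
  }
  for (i in seq_len(n)) {
    jit <- 1 + stats::rnorm(ns, 0, design$sensitivity_sd)
    amp_i <- amp0[, labels[i]] * conc[i]^expo * jit  # sensor amplitudes, V
    base_i <- baseline + vessel_fx[vessel[i]]
    # length-ns vectors recycle down the columns of the ns x nt profile,
    # so each sensor row gets its own baseline and amplitude
    sig <- base_i + amp_i * shape
    noise <- matrix(stats::rnorm(ns * nt, 0, design$noise_sd), ns, nt)
    curves[i, , ] <- sig + noise
  }
  structure(list(
    curves = curves,
    labels = labels,
    time_min = tm,
    phase_boundaries = c(baseline_end = b_end, injection_end = i_end),
    vessel = vessel,
    sensor_names = if (ns == 15L) default_sensor_names()
                   else sprintf("S%02d", seq_len(ns)),
    design = design
  ), class = "response_curve_set")
}

#' @export
print.response_curve_set <- function(x, ...) {
  d <- dim(x$curves)
  cat(sprintf("response_curve_set: %d samples x %d sensors x %d timepoints, %d classes\n",
              d[1], d[2], d[3], length(unique(x$labels))))
  invisible(x)
}

#' Extract steady-state maximum features
#'
#' Reduces each response curve to the maximum voltage reached inside a
#' window (by default the gas-injection phase, where the saturated response
#' is the steady state), producing the samples x sensors feature matrix the
#' dictionary-learning pipeline consumes.
#'
#' @param curves A `response_curve_set`.
#' @param window Either the name of a phase (`"injection"`, `"baseline"`,
#'   `"recovery"`) or an integer vector of timepoint indices.
#' @return An object of class `enose_features`: list with `values`
#'   (samples x sensors matrix, sensor names as column names), `labels` and
#'   `sensor_names`.
#' @export
extract_steady_state_max <- function(curves, window = "injection") {
  stopifnot(inherits(curves, "response_curve_set"))
  nt <- dim(curves$curves)[3]
  if (is.character(window)) {
    pb <- curves$phase_boundaries
    idx <- switch(match.arg(window, c("injection", "baseline", "recovery")),
      baseline  = seq_len(pb[["baseline_end"]]),
      injection = (pb[["baseline_end"]] + 1L):pb[["injection_end"]],
      recovery  = (pb[["injection_end"]] + 1L):nt)
  } else {
    idx <- as.integer(window)
    if (length(idx) == 0) stop("empty steady-state window", call. = FALSE)
    if (any(idx < 1 | idx > nt))
      stop("steady-state window outside recorded timepoints", call. = FALSE)
  }
  if (length(idx) == 0) stop("empty steady-state window", call. = FALSE)
  vals <- apply(curves$curves[, , idx, drop = FALSE], c(1, 2), max)
  colnames(vals) <- curves$sensor_names
  enose_features(vals, curves$labels)
}

#' Construct a feature matrix object
#'
#' @param values Numeric matrix, samples x sensors.
#' @param labels Class label per sample (any atomic type).
#' @param sensor_names Optional sensor names; defaults to column names.
#' @return An `enose_features` object.
#' @export
enose_features <- function(values, labels, sensor_names = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(sensor_names))
    sensor_names <- sprintf("S%02d", seq_len(ncol(values)))
  if (anyNA(values) || any(!is.finite(values)))
    stop("feature matrix contains missing or non-finite values", call. = FALSE)
  if (length(labels) != nrow(values))
    stop("labels must have one entry per sample", call. = FALSE)
  colnames(values) <- sensor_names
  structure(list(values = values, labels = labels,
                 sensor_names = sensor_names),
            class = "enose_features")
}

#' @export
print.enose_features <- function(x, ...) {
  cat(sprintf("enose_features: %d samples x %d sensors, %d classes\n",
              nrow(x$values), ncol(x$values), length(unique(x$labels))))
  invisible(x)
}

#' @export
dim.enose_features <- function(x) dim(x$values)

#' Stratified train/test split
#'
#' Splits the samples of each class independently: `round(train_fraction *
#' n_class)` samples per class are drawn into the training set (but each
#' class always keeps at least one sample on both sides), the rest form the
#' test set.  The split is exhaustive, disjoint and reproducible under
#' `seed`.
#'
#' @param features An `enose_features` object.
#' @param train_fraction Fraction of each class assigned to training,
#'   strictly between 0 and 1 (default 2/3).
#' @param seed Integer seed.
#' @return List with elements `train` and `test` (both `enose_features`) and
#'   the index vectors `train_idx`, `test_idx`.
#' @export
stratified_split <- function(features, train_fraction = 2 / 3, seed = 1L) {
  stopifnot(inherits(features, "enose_features"))
  if (!is.finite(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  tab <- table(features$labels)
  if (any(tab < 2))
    stop("every class needs at least 2 samples to split", call. = FALSE)
  set.seed(seed)
  train_idx <- integer(0)
  for (cl in names(tab)) {
    idx <- which(as.character(features$labels) == cl)
    n_tr <- round(train_fraction * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(nrow(features$values)), train_idx)
  subset_feat <- function(i)
    enose_features(features$values[i, , drop = FALSE], features$labels[i],
                   features$sensor_names)
  list(train = subset_feat(train_idx), test = subset_feat(test_idx),
       train_idx = train_idx, test_idx = test_idx)
}
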