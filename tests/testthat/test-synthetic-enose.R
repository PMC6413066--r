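test_that("invalid designs are rejected", {
  expect_error(sampling_design(n_classes = 0), "counts")
  expect_error(sampling_design(baseline_minutes = 0), "durations")
  expect_error(sampling_design(injection_minutes = -1), "durations")
  expect_error(sampling_design(noise_sd = -0.1), "noise_sd")
  expect_error(sampling_design(nonlinearity = 1.5), "nonlinearity")
})

test_that("the default design reproduces the storage-day study layout", {
  des <- sampling_design(seed = 3)
  rcs <- simulate_response_set(des)
  # 4 classes x 4 vessels x 6 reps = 96 samples; 24 per sampling session
  expect_equal(dim(rcs$curves)[1], 96)
  expect_equal(as.vector(table(rcs$labels)), rep(24, 4))
  expect_equal(dim(rcs$curves)[2], 15)
  # (5 + 7 + 5) min at 10 points/min
  expect_equal(dim(rcs$curves)[3], 170)
  expect_true(all(is.finite(rcs$curves)))
})

test_that("simulation is reproducible under the design seed", {
  a <- simulate_response_set(sampling_design(seed = 11))
  b <- simulate_response_set(sampling_design(seed = 11))
  c <- simulate_response_set(sampling_design(seed = 12))
  expect_identical(a$curves, b$curves)
  expect_false(identical(a$curves, c$curves))
})

test_that("noiseless curves saturate at baseline + amplitude and recover", {
  des <- sampling_design(noise_sd = 0, sensitivity_sd = 0, seed = 5)
  rcs <- simulate_response_set(des)
  i_end <- rcs$phase_boundaries[["injection_end"]]
  b_end <- rcs$phase_boundaries[["baseline_end"]]
  nt <- dim(rcs$curves)[3]
  for (i in c(1, 50)) {
    for (s in c(1, 8, 15)) {
      base <- rcs$curves[i, s, b_end]        # flat baseline phase
      peak <- max(rcs$curves[i, s, (b_end + 1):i_end])
      at_end <- rcs$curves[i, s, i_end]
      amp <- peak - base
      # logistic profile saturated: end-of-injection within 1% of the peak
      expect_lt(abs(at_end - (base + amp)), 0.01 * max(amp, 1))
      # decayed back to baseline at the end of recovery
      expect_lt(abs(rcs$curves[i, s, nt] - base), 0.01)
    }
  }
})

test_that("curves return to baseline within the noise floor", {
  des <- sampling_design(noise_sd = 0.02, sensitivity_sd = 0, seed = 9)
  rcs <- simulate_response_set(des)
  b_end <- rcs$phase_boundaries[["baseline_end"]]
  nt <- dim(rcs$curves)[3]
  dev <- abs(rcs$curves[, , nt] - rcs$curves[, , b_end])
  # individual points carry two independent noise draws; 99% of curves
  # must be back within 3 sd of the (noisy) baseline reading
  expect_lt(unname(stats::quantile(dev, 0.99)), 3 * sqrt(2) * 0.02)
})

test_that("steady-state maximum extraction matches a manual max", {
  rcs <- simulate_response_set(sampling_design(seed = 2))
  feat <- extract_steady_state_max(rcs)
  expect_equal(dim(feat$values), c(96, 15))
  expect_equal(feat$labels, rcs$labels)
  b_end <- rcs$phase_boundaries[["baseline_end"]]
  i_end <- rcs$phase_boundaries[["injection_end"]]
  expect_equal(unname(feat$values[7, 3]),
               max(rcs$curves[7, 3, (b_end + 1):i_end]))
  # explicit index window, constant-curve and error branches
  one <- extract_steady_state_max(rcs, window = 42L)
  expect_equal(unname(one$values[5, 5]), rcs$curves[5, 5, 42])
  expect_error(extract_steady_state_max(rcs, window = integer(0)), "empty")
  expect_error(extract_steady_state_max(rcs, window = 10000L), "window")
})

test_that("a triangular peak inside the window is picked up exactly", {
  rcs <- simulate_response_set(sampling_design(seed = 2))
  b_end <- rcs$phase_boundaries[["baseline_end"]]
  h <- 7.5
  rcs$curves[1, 1, ] <- 0
  rcs$curves[1, 1, b_end + 10] <- h
  feat <- extract_steady_state_max(rcs)
  expect_equal(unname(feat$values[1, 1]), h)
})

test_that("the stratified split honors the 2/3 rule and conserves samples", {
  feat <- extract_steady_state_max(simulate_response_set(sampling_design(seed = 4)))
  sp <- stratified_split(feat, 2 / 3, seed = 4)
  expect_equal(nrow(sp$train$values), 64)           # 16 x 4
  expect_equal(as.vector(table(sp$test$labels)), rep(8, 4))
  expect_equal(sort(c(sp$train_idx, sp$test_idx)), 1:96)
  # reproducible
  sp2 <- stratified_split(feat, 2 / 3, seed = 4)
  expect_identical(sp$train_idx, sp2$train_idx)
  expect_error(stratified_split(feat, 1.2), "between")
  expect_error(stratified_split(feat, 0), "between")
})

test_that("tiny classes keep one sample on each side of the split", {
  vals <- matrix(stats::rnorm(8 * 3), 8, 3)
  feat <- enose_features(vals, rep(1:4, each = 2))
  sp <- stratified_split(feat, 1 - 1e-9, seed = 1)
  expect_equal(as.vector(table(sp$train$labels)), rep(1, 4))
  expect_equal(as.vector(table(sp$test$labels)), rep(1, 4))
})

test_that("with nonlinearity 0 the class centroids are collinear", {
  des <- sampling_design(nonlinearity = 0, noise_sd = 0,
                         sensitivity_sd = 0, seed = 6)
  feat <- extract_steady_state_max(simulate_response_set(des))
  cm <- sapply(1:4, function(c) colMeans(feat$values[feat$labels == c, ]))
  centered <- cm - rowMeans(cm)
  sv <- svd(centered)$d
  # centroids lie on a line through feature space (affine in storage time)
  expect_gt(sv[1]^2 / sum(sv^2), 0.99)
})

test_that("sensor columns are correlated (cross-sensitivity)", {
  feat <- extract_steady_state_max(simulate_response_set(sampling_design(seed = 8)))
  C <- stats::cor(feat$values)
  off <- C[upper.tri(C)]
  expect_gt(mean(off), 0.5)
})
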