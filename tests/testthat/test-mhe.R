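# Shared noiseless fixture estimation run (window 7)
fit_noiseless <- function() memo("fit_noiseless", function() {
  run_mhe(as_measurement_stream(fixture_ref()),
          mhe_problem(fixture_model(), window = 7))
})

test_that("noiseless self-consistency: the estimator recovers its own reference", {
  ref <- fixture_ref()
  fit <- fit_noiseless()
  expect_lt(rmse(fit, ref, "angles"), 0.01)       # deg
  expect_lt(rmse(fit, ref, "forces"), 1)          # N
  expect_lt(rmse(fit, ref, "markers") * 1000, 0.01)  # mm
  expect_gt(fit$convergence_rate, 0.8)
})

test_that("stored estimates are dynamically consistent under one-step integration", {
  fit <- fit_noiseless()
  expect_lt(consistency_residual(fit), 1e-6)
})

test_that("estimated controls and states respect their bounds", {
  fit <- fit_noiseless()
  expect_true(all(fit$controls >= -1e-8 & fit$controls <= 1 + 1e-8))
  cmod <- compile_model(fixture_model())
  q <- fit$states[1:2, ]
  expect_true(all(sweep(q, 1, cmod$qmin, ">=") | abs(q - cmod$qmin) < 1e-8))
  expect_true(all(sweep(q, 1, cmod$qmax, "<=") | abs(q - cmod$qmax) < 1e-8))
  a <- fit$states[5:10, ]
  expect_true(all(a >= -1e-8 & a <= 1 + 1e-8))
})

test_that("the stepping interface implements window queue semantics", {
  ref <- fixture_ref()
  stream <- as_measurement_stream(ref)
  prob <- mhe_problem(fixture_model(), window = 7)
  frames <- list(markers = stream$markers[, 1:7], emg = stream$emg[, 1:7],
                 time = stream$time[1:7])
  est <- mhe_init(prob, frames, stream$dt, 1)
  t0 <- est$buffer$time
  s <- mhe_step(est, list(markers = stream$markers[, 8],
                          emg = stream$emg[, 8], time = stream$time[8]))
  expect_equal(ncol(est$buffer$markers), 7)            # length unchanged
  expect_equal(est$buffer$time[1], t0[2])              # oldest gone
  expect_equal(est$buffer$time[7], stream$time[8])     # newest present
  # initial state of the new window is chained from the previous solution
  expect_true(is.numeric(s$x) && length(s$x) == 10)
  # stepping agrees with the batch loop
  fit <- fit_noiseless()
  expect_equal(s$x, fit$states[, 2], tolerance = 1e-6)
})

test_that("warm starting reduces solver iterations relative to cold starts", {
  ref <- fixture_ref()
  stream <- as_measurement_stream(ref)
  prob <- mhe_problem(fixture_model(), window = 7)
  fit <- fit_noiseless()
  warm_iters <- median(fit$iterations[-1])
  # cold-start the same windows through the stepping interface
  cmod <- compile_model(fixture_model())
  cold <- sapply(seq(10, 60, by = 10), function(s) {
    frames <- list(markers = stream$markers[, s + 0:6],
                   emg = stream$emg[, s + 0:6], time = stream$time[s + 0:6])
    est <- mhe_init(prob, frames, stream$dt, 1)
    est$solution$iterations
  })
  expect_lt(warm_iters, median(cold))
})

test_that("the least-squared-excitation variant ignores EMG data", {
  ref <- fixture_ref()
  stream <- as_measurement_stream(ref)
  stream_scrambled <- stream
  set.seed(31)
  stream_scrambled$emg <- matrix(runif(length(stream$emg)),
                                 nrow(stream$emg))
  prob <- mhe_problem(fixture_model(), window = 5,
                      weights = cost_weights("min_excitation"))
  short <- function(s) {
    s$markers <- s$markers[, 1:30]; s$emg <- s$emg[, 1:30]
    s$time <- s$time[1:30]; s
  }
  f1 <- run_mhe(short(stream), prob)
  f2 <- run_mhe(short(stream_scrambled), prob)
  expect_equal(f1$states, f2$states, tolerance = 1e-10)
})

test_that("marker weight presets follow the variant", {
  expect_equal(cost_weights("track_emg_high_marker")$omega_m, 1e9)
  expect_equal(cost_weights("track_emg_low_marker")$omega_m, 1e7)
  expect_equal(cost_weights("min_excitation")$omega_m, 1e9)
})

test_that("full-window estimation solves the whole horizon consistently", {
  ref <- fixture_ref()
  stream <- as_measurement_stream(ref)
  short <- function(s, n) {
    s$markers <- s$markers[, 1:n]; s$emg <- s$emg[, 1:n]
    s$time <- s$time[1:n]; s
  }
  prob <- mhe_problem(fixture_model(), window = 12)
  full <- full_window_estimate(short(stream, 40), prob)
  expect_lt(consistency_residual(full), 1e-6)
  expect_lt(rmse(full, ref, "angles"), 0.01)
  # offline estimate is at least as accurate as the moving-horizon one on
  # the same stream
  # both estimators sit at the solver floor on noiseless data; the offline
  # solve must be at least as accurate up to that floor
  mhe <- run_mhe(short(stream, 40), prob)
  expect_lte(rmse(full, ref, "markers"),
             max(rmse(mhe, ref, "markers"), 1e-6))
  expect_lte(rmse(full, ref, "angles"),
             max(rmse(mhe, ref, "angles"), 1e-3))
})

test_that("subsampling keeps every k-th frame and rescales time", {
  ref <- fixture_ref()
  stream <- as_measurement_stream(ref)
  s4 <- subsample_stream(stream, 4)
  expect_equal(ncol(s4$markers), ceiling(ncol(stream$markers) / 4))
  expect_equal(s4$dt, stream$dt * 4)
  expect_equal(s4$time[1:3], stream$time[c(1, 5, 9)])
  expect_identical(subsample_stream(stream, 1), stream)
  # timestamps of stored estimates join the reference grid exactly
  fit <- run_mhe(s4, mhe_problem(fixture_model(), window = 5))
  expect_true(all(round(fit$time, 9) %in% round(ref$time, 9)))
})

test_that("estimation is deterministic and validates its inputs", {
  ref <- fixture_ref()
  stream <- as_measurement_stream(ref)
  short <- function(s, n) {
    s$markers <- s$markers[, 1:n]; s$emg <- s$emg[, 1:n]
    s$time <- s$time[1:n]; s
  }
  prob <- mhe_problem(fixture_model(), window = 5)
  f1 <- run_mhe(short(stream, 25), prob)
  f2 <- run_mhe(short(stream, 25), prob)
  expect_identical(f1$states, f2$states)
  expect_identical(f1$controls, f2$controls)
  bad <- short(stream, 25)
  bad$emg <- bad$emg[1:5, ]
  expect_error(run_mhe(bad, prob), "channel mismatch")
  expect_error(run_mhe(short(stream, 4), prob), "shorter than window")
})

test_that("the activation-driven formulation also recovers the reference kinematics", {
  ref <- fixture_ref()
  stream <- as_measurement_stream(ref)
  stream$markers <- stream$markers[, 1:60]
  stream$emg <- stream$emg[, 1:60]
  stream$time <- stream$time[1:60]
  fit <- run_mhe(stream, mhe_problem(fixture_model(), window = 7,
                                     formulation = "activation"))
  expect_lt(rmse(fit, ref, "angles"), 0.05)
  expect_lt(consistency_residual(fit), 1e-6)
  expect_equal(nrow(fit$states), 4)       # q, qdot only
})
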