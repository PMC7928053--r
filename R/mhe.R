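#' Cost weights for the estimation problem
#'
#' Three running-cost variants: EMG + marker tracking with a high
#' (`omega_m = 1e9`) or low (`omega_m = 1e7`) marker weight, or marker
#' tracking with least-squared muscle excitations (no EMG term). All variants
#' carry regularization on the joint velocities (`omega_rx`, markers already
#' pin the angles) and on the controls (`omega_ru`), plus a joint-limit
#' penalty weight used by the condensed solver.
#'
#' @param variant `"track_emg_high_marker"`, `"track_emg_low_marker"` or
#'   `"min_excitation"`.
#' @param omega_m marker tracking weight; default set by variant (1e9 / 1e7 /
#'   1e9).
#' @param omega_e EMG tracking (or excitation-minimization) weight.
#' @param omega_rx,omega_ru regularization weights on joint velocities and
#'   controls.
#' @param omega_lim joint-limit penalty weight.
#' @return A `cost_weights` list.
#' @export
cost_weights <- function(variant = c("track_emg_high_marker",
                                     "track_emg_low_marker",
                                     "min_excitation"),
                         omega_m = NULL, omega_e = 1e3, omega_rx = 10,
                         omega_ru = 1, omega_lim = 1e6) {
  variant <- match.arg(variant)
  if (is.null(omega_m))
    omega_m <- switch(variant, track_emg_low_marker = 1e7, 1e9)
  stopifnot(omega_m >= 0, omega_e >= 0, omega_rx >= 0, omega_ru >= 0)
  structure(list(variant = variant, omega_m = omega_m, omega_e = omega_e,
                 omega_rx = omega_rx, omega_ru = omega_ru,
                 omega_lim = omega_lim),
            class = "cost_weights")
}

#' Moving-horizon estimation problem configuration
#'
#' @param model a `msk_model`.
#' @param window window size in frames (a window of `N` frames spans `N - 1`
#'   shooting intervals).
#' @param formulation `"excitation"` (states q, qdot, a; controls =
#'   excitations) or `"activation"` (states q, qdot; controls = activations,
#'   EMG shifted by the electromechanical delay before buffering).
#' @param weights a [cost_weights()].
#' @param max_iterations solver iteration cap per window.
#' @return An `mhe_problem` list.
#' @export
mhe_problem <- function(model, window = 7,
                        formulation = c("excitation", "activation"),
                        weights = cost_weights(), max_iterations = 50) {
  stopifnot(window >= 2)
  structure(list(model = model, window = as.integer(window),
                 formulation = match.arg(formulation), weights = weights,
                 max_iterations = as.integer(max_iterations)),
            class = "mhe_problem")
}

solver_opts <- function(problem, dt, nsub) {
  w <- problem$weights
  list(dt = dt, nsub = as.integer(nsub),
       formulation = if (problem$formulation == "excitation") 0L else 1L,
       variant = if (w$variant == "min_excitation") 1L else 0L,
       wm = w$omega_m, we = w$omega_e, wrx = w$omega_rx, wru = w$omega_ru,
       wlim = w$omega_lim, maxit = problem$max_iterations)
}

#' Measurement stream from a reference dataset
#'
#' Packs the clean marker trajectories and excitation envelopes of a
#' reference dataset into the time-stamped stream consumed by the estimator.
#'
#' @param ref a `ref_dataset`.
#' @return A `measurement_stream`: `time`, `markers` (3*nmark x T), `emg`
#'   (nmus x T, last excitation held), `dt`, `subsample_factor`.
#' @export
as_measurement_stream <- function(ref) {
  Tn <- length(ref$time)
  emg <- cbind(ref$excitations, ref$excitations[, ncol(ref$excitations)])
  structure(list(time = ref$time, dt = ref$dt, markers = ref$markers,
                 emg = emg, marker_names = cm(ref$model)$marker_names,
                 muscle_names = cm(ref$model)$muscle_names,
                 subsample_factor = 1L),
            class = "measurement_stream")
}

#' Subsample a measurement stream
#'
#' Keeps every k-th frame starting at frame 0 and scales the frame period,
#' simulating a slower real-time acquisition.
#'
#' @param stream a `measurement_stream`.
#' @param factor integer subsampling factor `k >= 1`.
#' @return The subsampled stream; `subsample_factor` multiplied by `k`.
#' @export
subsample_stream <- function(stream, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1) return(stream)
  idx <- seq(1, length(stream$time), by = factor)
  stream$time <- stream$time[idx]
  stream$markers <- stream$markers[, idx, drop = FALSE]
  stream$emg <- stream$emg[, idx, drop = FALSE]
  stream$dt <- stream$dt * factor
  stream$subsample_factor <- stream$subsample_factor * factor
  stream
}

check_stream <- function(stream, cmod) {
  if (nrow(stream$markers) != 3 * cmod$nmark)
    abort("stream/model marker channel mismatch")
  if (nrow(stream$emg) != cmod$nmus)
    abort("stream/model EMG channel mismatch")
  if (any(diff(stream$time) <= 0)) abort("timestamps must strictly increase")
  invisible(stream)
}

# initial state guess: marker-fit inverse kinematics on the first frames,
# finite-difference velocity, activations from the first EMG sample (a
# level prior for the excitation-minimizing variant, which never reads EMG)
initial_state_guess <- function(cmod, stream, formulation,
                                variant = "track_emg_high_marker") {
  qmid <- (cmod$qmin + cmod$qmax) / 2
  q0 <- as.numeric(cpp_inverse_kinematics(cmod, stream$markers[, 1], qmid))
  q1 <- as.numeric(cpp_inverse_kinematics(cmod, stream$markers[, 2], q0))
  qd0 <- (q1 - q0) / stream$dt
  if (formulation == "excitation") {
    a0 <- if (variant == "min_excitation") rep(0.1, cmod$nmus)
    else pmin(pmax(stream$emg[, 1], 0), 1)
    c(q0, qd0, a0)
  } else {
    c(q0, qd0)
  }
}

emg_delay_shift <- function(stream, delay) {
  shift <- floor(delay / stream$dt + 0.5)
  if (shift >= 1) {
    Tn <- ncol(stream$emg)
    stream$emg <- cbind(stream$emg[, rep(1, shift), drop = FALSE],
                        stream$emg[, seq_len(Tn - shift), drop = FALSE])
  }
  stream
}

#' Run the moving-horizon estimator over a measurement stream
#'
#' Solves the first window with a free initial state (initialized by marker
#' inverse kinematics), then slides the window one frame at a time: the
#' oldest measurement is discarded, the initial-state equality constraint is
#' set to the previous solution's second state (dynamic consistency by
#' chaining), the solver is warm-started from the shifted previous solution,
#' and the first state/control of each solved window is stored. A solve
#' counts as converged when the optimizer meets its tolerances within the
#' iteration cap and joint limits are respected to 1e-6; the run is
#' "achieved" when more than 90% of solves converge.
#'
#' @param stream a `measurement_stream` (possibly subsampled).
#' @param problem an [mhe_problem()].
#' @param nsub internal RK4 steps per shooting interval; defaults to the
#'   stream's subsampling factor so the integration step stays at the native
#'   rate.
#' @return An `mhe_fit`: stored states/controls, derived muscle forces,
#'   per-solve convergence flags, iteration counts and timing log.
#' @export
run_mhe <- function(stream, problem, nsub = NULL) {
  cmod <- cm(problem$model)
  check_stream(stream, cmod)
  N <- problem$window
  if (ncol(stream$markers) <= N) abort("stream shorter than window")
  nsub <- as.integer(nsub %||% stream$subsample_factor)
  if (problem$formulation == "activation")
    stream <- emg_delay_shift(stream, max(cmod$delay))
  x0 <- initial_state_guess(cmod, stream, problem$formulation,
                            problem$weights$variant)
  U0 <- stream$emg[, seq_len(N - 1), drop = FALSE]
  if (problem$weights$variant == "min_excitation")
    U0 <- matrix(0.1, cmod$nmus, N - 1)
  res <- cpp_run_mhe(cmod, solver_opts(problem, stream$dt, nsub),
                     stream$markers, stream$emg, N, x0, U0)
  new_mhe_fit(res, stream, problem, nsub)
}

new_mhe_fit <- function(res, stream, problem, nsub, offline = FALSE) {
  cmod <- cm(problem$model)
  nq <- cmod$nq
  nstep <- ncol(res$X)
  forces <- if (problem$formulation == "excitation") {
    states_to_forces(cmod, res$X)
  } else {
    vapply(seq_len(nstep), function(k) {
      geo <- cpp_muscle_geometry(cmod, res$X[seq_len(nq), k],
                                 res$X[nq + seq_len(nq), k])
      as.numeric(cpp_hill_forces(cmod, res$U[, k], geo$lmt, geo$vmt))
    }, numeric(cmod$nmus))
  }
  structure(
    list(time = stream$time[seq_len(nstep)], states = res$X,
         controls = res$U, forces = forces,
         converged = as.logical(res$converged),
         iterations = as.integer(res$iterations),
         cost = as.numeric(res$cost), ms = as.numeric(res$ms),
         convergence_rate = mean(res$converged),
         achieved = mean(res$converged) > 0.9,
         window = problem$window, dt = stream$dt, nsub = nsub,
         formulation = problem$formulation,
         variant = problem$weights$variant, problem = problem,
         offline = offline,
         X_last = res$X_last, U_last = res$U_last),
    class = "mhe_fit")
}

#' @export
print.mhe_fit <- function(x, ...) {
  cat("<mhe_fit> ", if (x$offline) "full-window" else
    paste0("window ", x$window), ", ", x$formulation, "-driven, ",
    x$variant, "\n", sep = "")
  cat("  ", length(x$time), " stored estimates at dt = ", x$dt, " s; ",
      "convergence ", sprintf("%.1f%%", 100 * x$convergence_rate),
      if (x$achieved) " (achieved)" else " (not achieved)", "\n", sep = "")
  invisible(x)
}

#' Initialize a live moving-horizon estimator
#'
#' Lower-level stepping interface mirroring the estimation loop: initialize
#' with the first `N` frames (free initial state), then feed one
#' [mhe_step()] per new measurement. [run_mhe()] is the batch equivalent.
#'
#' @param problem an [mhe_problem()].
#' @param frames list with `markers` (3*nmark x N), `emg` (nmus x N),
#'   `time` (N).
#' @param dt frame period (s).
#' @param nsub internal RK4 steps per interval.
#' @return An `mhe_state` environment holding the buffer and last solution.
#' @export
mhe_init <- function(problem, frames, dt, nsub = 1) {
  cmod <- cm(problem$model)
  N <- problem$window
  stopifnot(ncol(frames$markers) == N)
  est <- new.env(parent = emptyenv())
  est$problem <- problem
  est$opts <- solver_opts(problem, dt, nsub)
  est$buffer <- frames
  pseudo <- list(markers = frames$markers, emg = frames$emg, dt = dt)
  x0 <- initial_state_guess(cmod, pseudo, problem$formulation,
                            problem$weights$variant)
  U0 <- frames$emg[, seq_len(N - 1), drop = FALSE]
  if (problem$weights$variant == "min_excitation")
    U0 <- matrix(0.1, cmod$nmus, N - 1)
  sol <- cpp_solve_window(cmod, est$opts, frames$markers, frames$emg,
                          NULL, x0, U0)
  est$solution <- sol
  est$stored <- list(x = sol$X[, 1], u = sol$U[, 1],
                     converged = sol$converged)
  class(est) <- "mhe_state"
  est
}

#' Advance the moving-horizon estimator by one measurement
#'
#' Shifts the buffer (oldest frame out, new frame in), imposes the previous
#' solution's second state as the initial-state equality constraint, warm
#' starts from the shifted previous controls, solves, and stores the first
#' state/control. On solver failure the shifted previous solution is the
#' fallback estimate and the step is flagged non-converged.
#'
#' @param est an `mhe_state` from [mhe_init()].
#' @param frame list with `markers` (3*nmark), `emg` (nmus), `time`.
#' @return List with the stored `x`, `u`, `converged`; the state is updated
#'   in place.
#' @export
mhe_step <- function(est, frame) {
  N <- est$problem$window
  cmod <- cm(est$problem$model)
  est$buffer$markers <- cbind(est$buffer$markers[, -1, drop = FALSE],
                              frame$markers)
  est$buffer$emg <- cbind(est$buffer$emg[, -1, drop = FALSE], frame$emg)
  est$buffer$time <- c(est$buffer$time[-1], frame$time)
  prev <- est$solution
  x0 <- prev$X[, 2]
  Uw <- if (N >= 3)
    cbind(prev$U[, -1, drop = FALSE], prev$U[, N - 1, drop = FALSE])
  else prev$U
  sol <- cpp_solve_window(cmod, est$opts, est$buffer$markers,
                          est$buffer$emg, x0, x0, Uw)
  est$solution <- sol
  est$stored <- list(x = sol$X[, 1], u = sol$U[, 1], converged = sol$converged)
  est$stored
}

#' Offline full-window estimate
#'
#' One tracking problem over the entire stream (free initial state); the
#' offline baseline the moving-horizon estimator is compared against.
#'
#' @inheritParams run_mhe
#' @return An `mhe_fit` whose stored trajectory is the whole solved horizon.
#' @export
full_window_estimate <- function(stream, problem, nsub = NULL) {
  cmod <- cm(problem$model)
  check_stream(stream, cmod)
  nsub <- as.integer(nsub %||% stream$subsample_factor)
  if (problem$formulation == "activation")
    stream <- emg_delay_shift(stream, max(cmod$delay))
  Tn <- ncol(stream$markers)
  x0 <- initial_state_guess(cmod, stream, problem$formulation,
                            problem$weights$variant)
  U0 <- stream$emg[, seq_len(Tn - 1), drop = FALSE]
  if (problem$weights$variant == "min_excitation")
    U0 <- matrix(0.1, cmod$nmus, Tn - 1)
  problem2 <- problem
  problem2$max_iterations <- max(problem$max_iterations, 100L)
  sol <- cpp_solve_window(cmod, solver_opts(problem2, stream$dt, nsub),
                          stream$markers, stream$emg, NULL, x0, U0)
  res <- list(X = sol$X, U = cbind(sol$U, sol$U[, Tn - 1]),
              converged = rep(sol$converged, Tn),
              iterations = rep(sol$iterations, Tn),
              cost = rep(sol$cost, Tn), ms = rep(NA_real_, Tn),
              X_last = sol$X, U_last = sol$U)
  fit <- new_mhe_fit(res, stream, problem, nsub, offline = TRUE)
  fit$controls <- fit$controls[, seq_len(Tn), drop = FALSE]
  fit
}

#' One-step dynamic-consistency residual of stored estimates
#'
#' Integrates each stored state with its stored control and compares with
#' the next stored state; the headline property separating this estimator
#' from static optimization. Zero (to floating-point noise) by construction
#' of the initial-state chaining.
#'
#' @param fit an `mhe_fit`.
#' @return Max abs one-step residual.
#' @export
consistency_residual <- function(fit) {
  cmod <- cm(fit$problem$model)
  form <- if (fit$formulation == "excitation") 0L else 1L
  worst <- 0
  for (k in seq_len(length(fit$time) - 1)) {
    xk <- cpp_integrate_interval(cmod, fit$states[, k], fit$controls[, k],
                                 fit$dt, fit$nsub, form)
    worst <- max(worst, max(abs(xk - fit$states[, k + 1])))
  }
  worst
}
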