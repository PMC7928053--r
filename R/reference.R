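#' Cyclic reference task
#'
#' Smooth cyclic joint trajectories built from one sine per DoF, with
#' frequencies that are integer multiples of `1/duration` so the motion is
#' exactly periodic. Defaults encode an elbow flexion-extension cycle with
#' modest forward shoulder elevation (two elbow cycles and one shoulder cycle
#' per period); the shoulder elevation stays well away from the z-x-z
#' kinematic singularity at zero elevation.
#'
#' @param model a `msk_model` (4-DoF arm and 2-DoF planar fixture have
#'   built-in defaults).
#' @param mid,amp,cycles,phase per-DoF sine parameters
#'   `q_j(t) = mid_j + amp_j * sin(2*pi*cycles_j*t/duration + phase_j)`.
#' @return An object of class `reference_task` with analytic `q`, `qd`, `qdd`
#'   functions of (t, duration).
#' @export
cyclic_arm_task <- function(model, mid = NULL, amp = NULL, cycles = NULL,
                            phase = NULL) {
  nq <- cm(model)$nq
  if (is.null(mid)) {
    if (nq == 4) {
      mid <- c(0.0, 0.7, 0.05, 1.05); amp <- c(0.15, 0.22, 0.10, 0.45)
      cycles <- c(1, 1, 1, 2); phase <- c(0, 1.3, 2.1, 0)
    } else if (nq == 2) {
      mid <- c(0.6, 1.0); amp <- c(0.3, 0.4)
      cycles <- c(1, 2); phase <- c(0, 0.8)
    } else {
      abort("no default task for this model; supply mid/amp/cycles/phase")
    }
  }
  structure(list(mid = mid, amp = amp, cycles = cycles, phase = phase,
                 q = function(t, duration) {
                   w <- 2 * pi * cycles / duration
                   t(vapply(t, function(ti) mid + amp * sin(w * ti + phase),
                            numeric(length(mid))))
                 },
                 qd = function(t, duration) {
                   w <- 2 * pi * cycles / duration
                   t(vapply(t, function(ti) amp * w * cos(w * ti + phase),
                            numeric(length(mid))))
                 },
                 qdd = function(t, duration) {
                   w <- 2 * pi * cycles / duration
                   t(vapply(t, function(ti) -amp * w^2 * sin(w * ti + phase),
                            numeric(length(mid))))
                 }),
            class = "reference_task")
}

#' Reference-generation weights
#'
#' @param wq,wqd node-tracking weights on joint angles / velocities in the
#'   per-interval projection solves. `wqd = NULL` uses `wq * dt^2`, which
#'   critically damps the closed-loop correction of the angle error (a
#'   discrete double integrator) and makes the warm-up cycles contract fast.
#' @param wv regularization on the torque-space correction coordinates.
#' @param wtau torque-matching weight of the static redundancy stage.
#' @param w_floor preference weight holding co-contracting elements at their
#'   excitation floor.
#' @return list of weights.
#' @export
ref_weights <- function(wq = 1e9, wqd = NULL, wv = 0.1,
                        wtau = 1e6, w_floor = 25) {
  list(wq = wq, wqd = wqd, wv = wv, wtau = wtau, w_floor = w_floor)
}

cocontraction_floor <- function(level) {
  switch(match.arg(level, c("none", "low", "mid", "high")),
         none = 0, low = 0.1, mid = 0.2, high = 0.3)
}

#' Generate a dynamically consistent cyclic reference dataset
#'
#' Simulates the study's ground-truth data: a cyclic arm motion at a fixed
#' node rate together with the muscle excitations that produce it, at one of
#' four co-contraction levels imposed as excitation floors on the
#' triceps/biceps agonist-antagonist pair. The trajectory is produced in two
#' stages: (i) an analytic plan — inverse-dynamics torques of the task
#' trajectory resolved into activations by a bounded static redundancy
#' least-squares at every node, excitations recovered through inverse
#' activation dynamics — and (ii) a stagewise optimal tracking projection
#' that picks each interval's constant excitation vector so the RK4 rollout
#' lands exactly on the planned nodes. The result satisfies the discrete
#' dynamics by construction (zero continuity defects) and is cyclic to
#' tracking tolerance.
#'
#' @param model a `msk_model`.
#' @param duration motion duration (s).
#' @param n_nodes number of shooting intervals (node rate =
#'   `n_nodes/duration` Hz; the study condition is 800 nodes over 8 s,
#'   i.e. 100 Hz).
#' @param cocontraction `"none"`, `"low"`, `"mid"` or `"high"` (excitation
#'   floors 0, 0.1, 0.2, 0.3 on the co-contraction pair).
#' @param task a [cyclic_arm_task()]; default built from the model.
#' @param weights a [ref_weights()] list.
#' @param cocontraction_muscles character vector of muscle names forming the
#'   agonist/antagonist pair; default matches triceps/biceps names.
#' @param seed stored in the dataset provenance (generation is
#'   deterministic).
#' @return A `ref_dataset`: time grid, states (q, qdot, a), excitations,
#'   muscle forces, marker trajectories, and provenance.
#' @export
generate_reference <- function(model, duration = 8, n_nodes = 800,
                               cocontraction = "none", task = NULL,
                               weights = ref_weights(),
                               cocontraction_muscles = NULL, seed = 0L) {
  stopifnot(duration > 0, n_nodes >= 2)
  cmod <- cm(model)
  nq <- cmod$nq; nmus <- cmod$nmus
  task <- task %||% cyclic_arm_task(model)
  floor_level <- cocontraction_floor(cocontraction)
  if (is.null(cocontraction_muscles))
    cocontraction_muscles <- grep("TRI|BIC", cmod$muscle_names, value = TRUE)
  if (floor_level > 0 && length(cocontraction_muscles) == 0)
    abort("no co-contraction muscles found; pass cocontraction_muscles")
  cc_idx <- match(cocontraction_muscles, cmod$muscle_names)

  dt <- duration / n_nodes
  tt <- seq(0, duration, by = dt)           # n_nodes + 1 nodes
  Q <- task$q(tt, duration); Qd <- task$qd(tt, duration)
  Qdd <- task$qdd(tt, duration)
  lim_ok <- sweep(Q, 2, cmod$qmin, ">") & sweep(Q, 2, cmod$qmax, "<")
  if (!all(lim_ok)) abort("task trajectory violates joint limits")

  # stage 1: static redundancy plan (two passes to make the floor one-sided)
  a_pref <- rep(0.01, nmus); w_pref <- rep(1, nmus)
  A_plan <- matrix(0, nmus, n_nodes + 1)
  for (k in seq_len(n_nodes + 1)) {
    a1 <- cpp_static_activation(cmod, Q[k, ], Qd[k, ], Qdd[k, ],
                                a_pref, w_pref, weights$wtau)
    if (floor_level > 0) {
      a_pref2 <- a_pref; w_pref2 <- w_pref
      a_pref2[cc_idx] <- pmax(floor_level, a1[cc_idx])
      w_pref2[cc_idx] <- weights$w_floor
      a1 <- cpp_static_activation(cmod, Q[k, ], Qd[k, ], Qdd[k, ],
                                  a_pref2, w_pref2, weights$wtau)
    }
    A_plan[, k] <- a1
  }
  # inverse activation dynamics (cyclic central differences)
  ip <- c(n_nodes, seq_len(n_nodes))          # k-1 with cyclic wrap
  im <- c(seq(2, n_nodes + 1), 2)             # k+1 with cyclic wrap
  Adot <- (A_plan[, im, drop = FALSE] - A_plan[, ip, drop = FALSE]) / (2 * dt)
  tau_eff <- ifelse(Adot >= 0, cmod$tact, cmod$tdeact)
  E_plan <- pmin(pmax(A_plan + tau_eff * Adot, 0), 1)[, seq_len(n_nodes), drop = FALSE]

  # stage 2: receding one-interval optimal tracking of the plan. The control
  # correction acts through a fixed torque-pattern matrix (damped
  # pseudo-inverse of the mid-pose torque gains), so each node solve is
  # square with no redundant null space. With one interval, angles and
  # velocities cannot both be landed exactly, so the controller carries a
  # small periodic forced error; we simulate warm-up cycles and keep the
  # last cycle, the periodic steady state of the closed loop.
  weights$wqd <- weights$wqd %||% weights$wq * dt^2
  Bc <- correction_patterns(cmod, task$mid %||% Q[1, ])
  n_cycles <- 1L + (warmup_cycles <- 2L)
  idx_nodes <- c(rep(seq_len(n_nodes), n_cycles), n_nodes + 1L)
  Q2 <- Q[idx_nodes, , drop = FALSE]; Qd2 <- Qd[idx_nodes, , drop = FALSE]
  E2 <- E_plan[, rep(seq_len(n_nodes), n_cycles), drop = FALSE]
  x0 <- c(Q[1, ], Qd[1, ], A_plan[, 1])
  sol <- cpp_track_reference(cmod, x0, t(Q2), t(Qd2), E2, Bc, dt, 1L,
                             weights$wq, weights$wqd, weights$wv)
  keep <- warmup_cycles * n_nodes + seq_len(n_nodes + 1L)
  X <- sol$X[, keep, drop = FALSE]
  U <- sol$U[, warmup_cycles * n_nodes + seq_len(n_nodes), drop = FALSE]
  forces <- states_to_forces(cmod, X)
  markers <- apply(X[seq_len(nq), , drop = FALSE], 2,
                   function(q) fk_markers_flat(cmod, q))
  structure(
    list(model = model, time = tt, dt = dt, duration = duration,
         n_nodes = n_nodes, states = X, excitations = U, forces = forces,
         markers = markers, cocontraction = cocontraction,
         cocontraction_muscles = cocontraction_muscles,
         task = task[c("mid", "amp", "cycles", "phase")],
         weights = weights, seed = seed,
         config_hash = hash(list(cmod, duration, n_nodes, cocontraction,
                                 task[c("mid", "amp", "cycles", "phase")],
                                 weights))),
    class = "ref_dataset")
}

# Damped pseudo-inverse of the activation-to-torque gain matrix at a posture:
# columns are muscle-space patterns realizing one unit of torque per DoF.
correction_patterns <- function(cmod, q) {
  qd0 <- rep(0, cmod$nq)
  geo <- cpp_muscle_geometry(cmod, q, qd0)
  R <- t(geo$moment_arms)                       # nq x nmus
  F0 <- as.numeric(cpp_hill_forces(cmod, rep(0, cmod$nmus), geo$lmt, geo$vmt))
  B <- vapply(seq_len(cmod$nmus), function(j) {
    aj <- rep(0, cmod$nmus); aj[j] <- 1
    R %*% (cpp_hill_forces(cmod, aj, geo$lmt, geo$vmt) - F0)
  }, numeric(cmod$nq))                          # nq x nmus torque gains
  lam <- 1e-3 * mean(diag(B %*% t(B)))
  t(B) %*% solve(B %*% t(B) + lam * diag(cmod$nq))
}

# Hill forces along a state trajectory (columns are states)
states_to_forces <- function(cmod, X) {
  nq <- cmod$nq
  apply(X, 2, function(x) {
    geo <- cpp_muscle_geometry(cmod, x[seq_len(nq)], x[nq + seq_len(nq)])
    as.numeric(cpp_hill_forces(cmod, x[2 * nq + seq_len(cmod$nmus)],
                               geo$lmt, geo$vmt))
  })
}

#' Recompute muscle forces of a reference dataset
#'
#' Evaluates the Hill model along the stored state trajectory; the ground
#' truth used by the force RMSE.
#'
#' @param model a `msk_model`.
#' @param ref a `ref_dataset`.
#' @return Matrix (muscles x nodes) of non-negative tendon forces (N).
#' @export
extract_muscle_forces <- function(model, ref) {
  states_to_forces(cm(model), ref$states)
}

#' @export
print.ref_dataset <- function(x, ...) {
  cat("<ref_dataset> ", x$n_nodes, " intervals over ", x$duration,
      " s (", round(1 / x$dt), " Hz), co-contraction: ", x$cocontraction,
      "\n", sep = "")
  invisible(x)
}

#' Maximum one-step integration defect of a reference dataset
#'
#' Re-integrates every interval with the stored control and compares to the
#' stored next state; zero (to floating-point noise) by construction.
#'
#' @param ref a `ref_dataset`.
#' @return max abs defect across states and intervals.
#' @export
reference_defect <- function(ref) {
  cmod <- cm(ref$model)
  X <- ref$states
  worst <- 0
  for (k in seq_len(ncol(ref$excitations))) {
    xk <- cpp_integrate_interval(cmod, X[, k], ref$excitations[, k],
                                 ref$dt, 1L, 0L)
    worst <- max(worst, max(abs(xk - X[, k + 1])))
  }
  worst
}
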