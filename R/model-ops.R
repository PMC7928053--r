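#' Forward kinematics
#'
#' Maps a joint configuration to global marker positions and homogeneous
#' segment-frame transforms.
#'
#' @param model a `msk_model`.
#' @param q joint angles (rad), length `nq`.
#' @return A list with `markers` (tibble: marker, x, y, z in m) and `frames`
#'   (list of 4x4 homogeneous transforms, one per joint frame).
#' @export
forward_kinematics <- function(model, q) {
  cmod <- cm(model)
  if (length(q) != cmod$nq || !all(is.finite(q))) abort("q must be finite, length nq")
  out <- cpp_forward_kinematics(cmod, q)
  mk <- tibble::tibble(marker = cmod$marker_names,
                       x = out$markers[, 1], y = out$markers[, 2],
                       z = out$markers[, 3])
  list(markers = mk, frames = setNames(out$frames, cmod$joint_names))
}

# marker positions as a flat length-3*nmark vector (x,y,z per marker)
fk_markers_flat <- function(cmodel, q) {
  as.numeric(t(cpp_forward_kinematics(cmodel, q)$markers))
}

#' Musculotendon geometry
#'
#' Polyline musculotendon lengths, lengthening velocities and the moment-arm
#' matrix `R = -d l_mt / d q`.
#'
#' @param model a `msk_model`.
#' @param q,qdot joint angles (rad) and velocities (rad/s).
#' @return A tibble with one row per muscle (`muscle`, `lmt`, `vmt`) and the
#'   moment-arm matrix in attribute `"moment_arms"` (muscles x joints, m);
#'   also returned as list columns via [tidyr::unnest()]-friendly shape.
#' @export
musculotendon_geometry <- function(model, q, qdot = rep(0, length(q))) {
  cmod <- cm(model)
  geo <- cpp_muscle_geometry(cmod, q, qdot)
  out <- tibble::tibble(muscle = cmod$muscle_names, lmt = as.numeric(geo$lmt),
                        vmt = as.numeric(geo$vmt))
  ma <- geo$moment_arms
  dimnames(ma) <- list(cmod$muscle_names, cmod$joint_names)
  attr(out, "moment_arms") <- ma
  out
}

#' Hill-type tendon force
#'
#' Rigid-tendon Hill model: `F = F_iso_max (a f_l f_v + f_p)` with fiber
#' length `l_mt - l_ts`, Gaussian active force-length, hyperbolic
#' force-velocity and a C2 passive curve anchored at `f_p(1) = 0`.
#'
#' @param model a `msk_model`.
#' @param a activations in `[0, 1]` (length `nmus`).
#' @param lmt,vmt musculotendon lengths (m) and velocities (m/s).
#' @return Tendon forces in N (length `nmus`), non-negative.
#' @export
hill_force <- function(model, a, lmt, vmt = rep(0, length(lmt))) {
  cmod <- cm(model)
  if (any(a < 0 | a > 1)) abort("activations must lie in [0, 1]")
  if (any(lmt <= cmod$lts)) abort("non-physical geometry: l_mt <= tendon slack length")
  as.numeric(cpp_hill_forces(cmod, a, lmt, vmt))
}

#' First-order activation dynamics
#'
#' `da/dt = (e - a) / tau` with `tau = tact` during activation (`e >= a`) and
#' `tau = tdeact` during deactivation, blended by a smooth switch so the
#' right-hand side stays differentiable for the optimizer.
#'
#' @param model a `msk_model`.
#' @param a activations, `e` excitations, both in `[0, 1]`.
#' @param e excitations.
#' @return `da/dt` (1/s), length `nmus`.
#' @export
activation_dynamics <- function(model, a, e) {
  as.numeric(cpp_activation_rate(cm(model), pmin(pmax(a, 0), 1),
                                 pmin(pmax(e, 0), 1)))
}

#' Forward dynamics
#'
#' Muscle-actuated rigid-body dynamics: joint torques from the moment-arm
#' transpose times Hill forces, accelerations from the joint-space equations
#' of motion (mass matrix and nonlinear effects computed by recursive
#' Newton-Euler), plus activation dynamics in the excitation-driven
#' formulation.
#'
#' @param model a `msk_model`.
#' @param x state: `c(q, qdot)` (activation-driven) or `c(q, qdot, a)`
#'   (excitation-driven).
#' @param u controls: activations or excitations, in `[0, 1]`.
#' @param formulation `"excitation"` or `"activation"`.
#' @return `dx/dt`.
#' @export
forward_dynamics <- function(model, x, u, formulation = "excitation") {
  f <- match.arg(formulation, c("excitation", "activation"))
  as.numeric(cpp_forward_dynamics(cm(model), x, u,
                                  if (f == "excitation") 0L else 1L))
}

#' Integrate one shooting interval
#'
#' Explicit 4th-order Runge-Kutta with piecewise-constant control.
#'
#' @inheritParams forward_dynamics
#' @param x0 initial state.
#' @param dt interval length (s).
#' @param n_steps number of internal RK4 steps.
#' @return State at `t = dt`.
#' @export
integrate_interval <- function(model, x0, u, dt, n_steps = 1,
                               formulation = "excitation") {
  if (dt < 0 || n_steps < 1) abort("need dt >= 0 and n_steps >= 1")
  if (dt == 0) return(x0)
  f <- match.arg(formulation, c("excitation", "activation"))
  as.numeric(cpp_integrate_interval(cm(model), x0, u, dt, as.integer(n_steps),
                                    if (f == "excitation") 0L else 1L))
}

#' Inverse dynamics (joint torques from a prescribed motion)
#'
#' @param model a `msk_model`.
#' @param q,qdot,qddot configuration, velocity, acceleration.
#' @param gravity include gravity (default TRUE).
#' @return Generalized joint torques (N m).
#' @export
inverse_dynamics <- function(model, q, qdot, qddot, gravity = TRUE) {
  as.numeric(cpp_inverse_dynamics(cm(model), q, qdot, qddot, gravity))
}
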