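# Independent oracles used across the suite. These re-derive quantities by
# different algorithms than the package core (explicit rotation-matrix
# chains, Jacobian-projection dynamics, finite differences) so agreement is
# evidence, not tautology.

# Explicit homogeneous-transform chain for marker positions.
fk_oracle <- function(model, q) {
  cmod <- compile_model(model)
  rot <- function(axis, th) {
    ux <- axis[1]; uy <- axis[2]; uz <- axis[3]
    c <- cos(th); s <- sin(th); C <- 1 - c
    matrix(c(c + ux^2 * C, ux * uy * C - uz * s, ux * uz * C + uy * s,
             uy * ux * C + uz * s, c + uy^2 * C, uy * uz * C - ux * s,
             uz * ux * C - uy * s, uz * uy * C + ux * s, c + uz^2 * C),
           3, 3, byrow = TRUE)
  }
  nq <- cmod$nq
  Rw <- vector("list", nq); ow <- vector("list", nq)
  for (i in seq_len(nq)) {
    p <- cmod$joint_parent[i] + 1          # 1-based; 0 -> world
    Rp <- if (p >= 1) Rw[[p]] else diag(3)
    op <- if (p >= 1) ow[[p]] else c(0, 0, 0)
    ow[[i]] <- op + Rp %*% cmod$joint_trans[, i]
    Rw[[i]] <- Rp %*% rot(cmod$joint_axis[, i], q[i])
  }
  t(vapply(seq_len(cmod$nmark), function(k) {
    j <- cmod$marker_joint[k] + 1
    if (j >= 1) as.numeric(ow[[j]] + Rw[[j]] %*% cmod$marker_loc[, k])
    else cmod$marker_loc[, k]
  }, numeric(3)))
}

# Body Jacobians (linear at com, angular) of every massive body, computed
# from the oracle's own frame chain.
body_jacobians_oracle <- function(cmod, q) {
  rot <- function(axis, th) {
    ux <- axis[1]; uy <- axis[2]; uz <- axis[3]
    c <- cos(th); s <- sin(th); C <- 1 - c
    matrix(c(c + ux^2 * C, ux * uy * C - uz * s, ux * uz * C + uy * s,
             uy * ux * C + uz * s, c + uy^2 * C, uy * uz * C - ux * s,
             uz * ux * C - uy * s, uz * uy * C + ux * s, c + uz^2 * C),
           3, 3, byrow = TRUE)
  }
  nq <- cmod$nq
  Rw <- vector("list", nq); ow <- vector("list", nq); sw <- vector("list", nq)
  anc <- vector("list", nq)
  for (i in seq_len(nq)) {
    p <- cmod$joint_parent[i] + 1
    Rp <- if (p >= 1) Rw[[p]] else diag(3)
    op <- if (p >= 1) ow[[p]] else c(0, 0, 0)
    ow[[i]] <- as.numeric(op + Rp %*% cmod$joint_trans[, i])
    sw[[i]] <- as.numeric(Rp %*% cmod$joint_axis[, i])
    Rw[[i]] <- Rp %*% rot(cmod$joint_axis[, i], q[i])
    anc[[i]] <- if (p >= 1) c(anc[[p]], i) else i
  }
  lapply(seq_along(cmod$body_mass), function(b) {
    j <- cmod$body_joint[b] + 1
    cw <- as.numeric(ow[[j]] + Rw[[j]] %*% cmod$body_com[, b])
    Jv <- matrix(0, 3, nq); Jw <- matrix(0, 3, nq)
    for (i in anc[[j]]) {
      Jw[, i] <- sw[[i]]
      Jv[, i] <- pracma::cross(sw[[i]], cw - ow[[i]])
    }
    Iw <- Rw[[j]] %*% matrix(cmod$body_inertia[, b], 3, 3) %*% t(Rw[[j]])
    list(Jv = Jv, Jw = Jw, com = cw, mass = cmod$body_mass[b], Iw = Iw,
         joints = anc[[j]], ow = ow, sw = sw, Rw = Rw, j = j)
  })
}

# Forward-dynamics oracle by Jacobian projection: M from body Jacobians,
# bias forces from exact Jacobian time-derivatives (closed form via frame
# kinematics), gravity from J_v^T m g. Muscle torques from the package's
# geometry (shared input, as the oracle checks the rigid-body solve).
forward_dynamics_oracle <- function(model, x, u) {
  cmod <- compile_model(model)
  nq <- cmod$nq
  q <- x[seq_len(nq)]; qd <- x[nq + seq_len(nq)]
  a <- x[2 * nq + seq_len(cmod$nmus)]
  bodies <- body_jacobians_oracle(cmod, q)
  M <- matrix(0, nq, nq)
  bias <- numeric(nq)
  grav <- numeric(nq)
  for (b in bodies) {
    M <- M + b$mass * t(b$Jv) %*% b$Jv + t(b$Jw) %*% b$Iw %*% b$Jw
    omega <- as.numeric(b$Jw %*% qd)
    # exact Jdot columns: sdot = w_i x s_i, odot_i = J_{o_i} qd, cdot = Jv qd
    cdot <- as.numeric(b$Jv %*% qd)
    Jvdot <- matrix(0, 3, nq); Jwdot <- matrix(0, 3, nq)
    for (i in b$joints) {
      wi <- numeric(3)   # angular velocity of joint-i frame = sum_{k<=i} s_k qd_k
      for (k in b$joints[b$joints <= i]) wi <- wi + b$sw[[k]] * qd[k]
      sdot <- pracma::cross(wi - b$sw[[i]] * qd[i] * 0, b$sw[[i]])  # s_i moves with parent chain incl. own? axis fixed in frame i
      # s_i is rigid in the frame of joint i's parent rotation: its rate is
      # (sum_{k < i, k ancestor} s_k qd_k + s_i qd_i) x s_i; the s_i term
      # vanishes (parallel), so using wi is exact.
      sdot <- pracma::cross(wi, b$sw[[i]])
      odot <- numeric(3) # velocity of o_i
      for (k in b$joints[b$joints < i]) {
        odot <- odot + pracma::cross(b$sw[[k]], b$ow[[i]] - b$ow[[k]]) * qd[k]
      }
      Jvdot[, i] <- pracma::cross(sdot, b$com - b$ow[[i]]) +
        pracma::cross(b$sw[[i]], cdot - odot)
      Jwdot[, i] <- sdot
    }
    alpha_bias <- as.numeric(Jwdot %*% qd)
    acc_bias <- as.numeric(Jvdot %*% qd)
    bias <- bias + b$mass * t(b$Jv) %*% acc_bias +
      t(b$Jw) %*% (b$Iw %*% alpha_bias + pracma::cross(omega, as.numeric(b$Iw %*% omega)))
    grav <- grav + b$mass * t(b$Jv) %*% cmod$gravity
  }
  geo <- musculotendon_geometry(model, q, qd)
  Fm <- mhemuscle:::cpp_hill_forces(cmod, a, geo$lmt, geo$vmt)
  tau_mus <- as.numeric(t(attr(geo, "moment_arms")) %*% Fm)
  qdd <- solve(M, tau_mus + as.numeric(grav) - as.numeric(bias))
  list(qdd = as.numeric(qdd), M = M)
}

# Central finite differences of musculotendon length w.r.t. q.
moment_arm_fd_oracle <- function(model, q, h = 1e-6) {
  nq <- length(q)
  -vapply(seq_len(nq), function(j) {
    qp <- q; qm <- q
    qp[j] <- qp[j] + h; qm[j] <- qm[j] - h
    (musculotendon_geometry(model, qp)$lmt -
       musculotendon_geometry(model, qm)$lmt) / (2 * h)
  }, numeric(length(compile_model(model)$fmax)))
}

# Mean norm of an isotropic 3-D Gaussian with per-axis std s (chi_3 mean).
chi3_mean <- function(s) s * sqrt(2) * gamma(2) / gamma(1.5)

# Total mechanical energy (kinetic via the Jacobian oracle + gravitational).
mech_energy_oracle <- function(model, q, qd) {
  cmod <- compile_model(model)
  bodies <- body_jacobians_oracle(cmod, q)
  e <- 0
  for (b in bodies) {
    v <- as.numeric(b$Jv %*% qd); w <- as.numeric(b$Jw %*% qd)
    e <- e + 0.5 * b$mass * sum(v^2) + 0.5 * sum(w * (b$Iw %*% w)) -
      b$mass * sum(cmod$gravity * b$com)
  }
  e
}
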