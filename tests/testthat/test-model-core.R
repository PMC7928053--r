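test_that("model builders produce valid models with the documented structure", {
  a <- arm_fixture()
  cmod <- compile_model(a)
  expect_equal(cmod$nq, 4)
  expect_equal(cmod$nmus, 19)
  expect_equal(cmod$nmark, 8)
  expect_equal(cmod$qmin, c(-pi / 2, -2, -pi / 2, -0.5))
  expect_equal(cmod$qmax, c(pi / 2, pi / 2, pi / 2, 2.1))
  parents <- vapply(a$markers, `[[`, "", "segment")
  expect_true(all(parents %in% c("humerus", "ulna", "radius")))
  expect_true(all(vapply(a$muscles, function(m) length(m$points), 0L) >= 2))
  p <- fixture_model()
  expect_equal(compile_model(p)$nq, 2)
  expect_equal(compile_model(p)$nmus, 6)
  expect_equal(compile_model(p)$nmark, 4)
})

test_that("model validation rejects broken definitions", {
  a <- arm_fixture()
  bad <- a
  bad$markers[[1]]$segment <- "scapula"
  expect_error(validate_model(bad), "unknown segment")
  bad <- a
  bad$muscles[[1]]$points <- bad$muscles[[1]]$points[1]
  expect_error(validate_model(bad), ">= 2 path points")
  bad <- a
  bad$muscles[[2]]$tact <- 0.2        # slower than deactivation
  expect_error(validate_model(bad), "tact <= tdeact")
})

test_that("forward kinematics matches an explicit transform-chain oracle", {
  set.seed(11)
  for (model in list(fixture_model(), arm_fixture())) {
    for (i in 1:25) {
      q <- as.numeric(random_q(model))
      fk <- forward_kinematics(model, q)
      expect_equal(nrow(fk$markers), compile_model(model)$nmark)
      got <- as.matrix(fk$markers[, c("x", "y", "z")])
      expect_lt(max(abs(got - fk_oracle(model, q))), 1e-10)
    }
  }
  # neutral configuration of a world-fixed chain: frames reduce to offsets
  p <- fixture_model()
  fk0 <- forward_kinematics(p, c(0, 0))
  expect_equal(fk0$markers$z[1], -0.15)
  expect_equal(unname(fk0$frames[[1]][1:3, 1:3]), diag(3))
})

test_that("moment arms equal -dl/dq by central finite differences", {
  set.seed(12)
  for (model in list(fixture_model(), arm_fixture())) {
    for (i in 1:50) {
      q <- as.numeric(random_q(model))
      geo <- musculotendon_geometry(model, q)
      expect_lt(max(abs(attr(geo, "moment_arms") - moment_arm_fd_oracle(model, q))),
                1e-6)
    }
  }
})

test_that("muscle geometry has the expected structural zeros and errors", {
  a <- arm_fixture()
  q <- c(0.1, 0.8, 0.05, 1.2)
  ma <- attr(musculotendon_geometry(a, q), "moment_arms")
  # elbow-only muscles exert no shoulder moment
  for (mu in c("BRD", "BRA")) expect_equal(unname(ma[mu, 1:3]), c(0, 0, 0))
  # shoulder-only muscles exert no elbow moment
  for (mu in c("DELT1", "SUPSP", "PECM1")) expect_equal(unname(ma[mu, 4]), 0)
  # velocities follow the moment arms: vmt = -R qdot
  qd <- c(0.3, -0.2, 0.1, 0.5)
  geo <- musculotendon_geometry(a, q, qd)
  expect_equal(geo$vmt, as.numeric(-attr(geo, "moment_arms") %*% qd),
               tolerance = 1e-12)
  # a muscle whose path rides on one segment has constant length
  one_seg <- msk_model(
    segments = list(
      mhemuscle:::seg("base", "world", c(0, 0, 0)),
      mhemuscle:::seg("arm", "base", c(0, 0, 0), mass = 1, com = c(0, 0, -0.1),
                      inertia = c(0.01, 0.01, 0.01),
                      joints = list(mhemuscle:::jnt("j1", c(1, 0, 0), c(-1, 1))))),
    markers = list(mhemuscle:::mrk("M1", "arm", c(0, 0, -0.2))),
    muscles = list(mhemuscle:::mus("RIGID", list(
      mhemuscle:::pp("arm", c(0, 0.02, -0.05)),
      mhemuscle:::pp("arm", c(0, 0.02, -0.15))), 100, 0.05, lts = 0.01)))
  for (qq in c(-0.5, 0, 0.7)) {
    geo1 <- musculotendon_geometry(one_seg, qq)
    expect_equal(geo1$lmt, 0.1, tolerance = 1e-12)
    expect_equal(unname(attr(geo1, "moment_arms")[1, 1]), 0, tolerance = 1e-12)
  }
})

test_that("Hill force curves satisfy their anchors and positivity", {
  p <- fixture_model()
  cmod <- compile_model(p)
  lmt_opt <- cmod$lts + cmod$lopt              # fiber at optimum, per muscle
  # a = 1, fiber at optimum, static: F = F_iso_max
  expect_equal(hill_force(p, rep(1, 6), lmt_opt), cmod$fmax,
               tolerance = 1e-12)
  # a = 0 at optimum: passive term anchored at zero
  expect_equal(hill_force(p, rep(0, 6), lmt_opt), rep(0, 6),
               tolerance = 1e-12)
  # max shortening kills the active term (f_v(-1) = 0)
  expect_equal(hill_force(p, rep(1, 6), lmt_opt,
                          -cmod$vmax * cmod$lopt), rep(0, 6),
               tolerance = 1e-9)
  # positivity across the physiological envelope
  set.seed(13)
  for (i in 1:200) {
    lt <- runif(1, 0.5, 1.5); vt <- runif(1, -1, 1)
    f <- hill_force(p, rep(runif(1), 6), cmod$lts + lt * cmod$lopt,
                    vt * cmod$vmax * cmod$lopt)
    expect_true(all(f >= 0))
  }
  expect_error(hill_force(p, rep(0.5, 6), cmod$lts * 0.9), "non-physical")
  expect_error(hill_force(p, rep(1.5, 6), lmt_opt), "\\[0, 1\\]")
})

test_that("activation dynamics has the documented fixed point and rates", {
  p <- fixture_model()
  cmod <- compile_model(p)
  a <- rep(0.4, 6)
  expect_equal(activation_dynamics(p, a, a), rep(0, 6), tolerance = 1e-12)
  r <- activation_dynamics(p, rep(0, 6), rep(1, 6))
  expect_equal(r, 1 / cmod$tact, tolerance = 1e-3)
  # step response reaches 63.2% after ~tact when integrated at 1 ms
  aa <- 0
  h <- 1e-3
  steps <- round(cmod$tact[1] / h)
  for (i in seq_len(steps))
    aa <- aa + h * activation_dynamics(p, c(aa, rep(0, 5)), c(1, rep(0, 5)))[1]
  expect_equal(aa, 1 - exp(-1), tolerance = 0.05)
  # boundedness: trajectories stay in [0, 1] under extreme inputs
  set.seed(14)
  for (rep in 1:20) {
    aa <- runif(6)
    e <- round(runif(6))
    for (i in 1:300) {
      aa <- aa + 1e-3 * activation_dynamics(p, aa, e)
      expect_true(all(aa >= -1e-12 & aa <= 1 + 1e-12))
    }
  }
})

test_that("forward dynamics matches the Jacobian-projection oracle", {
  set.seed(15)
  for (model in list(fixture_model(), arm_fixture())) {
    cmod <- compile_model(model)
    nq <- cmod$nq
    for (i in 1:25) {
      q <- as.numeric(random_q(model))
      qd <- runif(nq, -2, 2)
      a <- runif(cmod$nmus)
      u <- runif(cmod$nmus)
      x <- c(q, qd, a)
      xdot <- forward_dynamics(model, x, u)
      expect_equal(xdot[seq_len(nq)], qd)
      orc <- forward_dynamics_oracle(model, x, u)
      expect_lt(max(abs(xdot[nq + seq_len(nq)] - orc$qdd)), 1e-8)
    }
  }
})

test_that("unforced equilibrium yields zero acceleration", {
  p0 <- planar_arm_model()
  p0$gravity <- c(0, 0, 0)
  p0$passive_scale <- 0
  p0$compiled <- compile_model(p0)
  x <- c(0.6, 1.0, 0, 0, rep(0, 6))
  xdot <- forward_dynamics(p0, x, rep(0, 6))
  expect_equal(xdot, rep(0, 2 + 2 + 6), tolerance = 1e-12)
})

test_that("joint torques are the moment-arm transpose times muscle forces", {
  a <- arm_fixture()
  cmod <- compile_model(a)
  q <- c(0, 0.7, 0, 1); qd <- rep(0, 4)
  act <- runif(19, 0, 1)
  geo <- musculotendon_geometry(a, q, qd)
  Fm <- hill_force(a, act, geo$lmt, geo$vmt)
  expect_length(Fm, 19)
  expect_true(all(Fm >= 0))
  tau <- t(attr(geo, "moment_arms")) %*% Fm          # 4x19 times 19
  expect_length(as.numeric(tau), 4)
  # consistency with the equations of motion: M qdd + nle = tau
  xdot <- forward_dynamics(a, c(q, qd, act), rep(0, 19))
  lhs <- inverse_dynamics(a, q, qd, xdot[5:8])
  expect_equal(as.numeric(tau), lhs, tolerance = 1e-8)
})

test_that("RK4 integration is 4th order and matches an adaptive integrator", {
  p <- fixture_model()
  x0 <- c(0.6, 1.0, 0.2, -0.3, rep(0.2, 6))
  u <- rep(0.3, 6)
  expect_equal(integrate_interval(p, x0, u, 0), x0)
  # Richardson order check: halving h shrinks the endpoint change ~2^4
  x1 <- integrate_interval(p, x0, u, 0.02, 1)
  x2 <- integrate_interval(p, x0, u, 0.02, 2)
  x4 <- integrate_interval(p, x0, u, 0.02, 4)
  e1 <- max(abs(x1 - x4)); e2 <- max(abs(x2 - x4))
  expect_gt(e1 / e2, 8)    # asymptotic ratio ~ 16/..; generous lower bound
  # dense-integrator oracle over 10 ms
  sol <- deSolve::lsoda(
    y = x0, times = c(0, 0.01),
    func = function(t, y, parms) list(forward_dynamics(p, y, u)),
    rtol = 1e-11, atol = 1e-12)
  expect_lt(max(abs(integrate_interval(p, x0, u, 0.01, 20) -
                      sol[2, -1])), 1e-6)
})

test_that("the unforced frictionless chain conserves mechanical energy", {
  p0 <- planar_arm_model()
  p0$passive_scale <- 0
  p0$compiled <- compile_model(p0)
  x <- c(0.6, 1.0, 0.5, -0.5, rep(0, 6))
  e0 <- mech_energy_oracle(p0, x[1:2], x[3:4])
  for (i in seq_len(1000))
    x <- integrate_interval(p0, x, rep(0, 6), 1e-3, 1)
  e1 <- mech_energy_oracle(p0, x[1:2], x[3:4])
  expect_lt(abs(e1 - e0), 1e-5)
})
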