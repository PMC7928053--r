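#' Musculoskeletal model objects
#'
#' A `msk_model` describes a serial-chain arm: segments with inertial
#' parameters, revolute joints with limits, skin markers, and Hill-type muscle
#' elements whose lines of action are polylines through origin, optional via
#' points and insertion. All quantities are SI (m, kg, s, rad, N); angles are
#' radians everywhere except explicit reporting boundaries.
#'
#' @param segments list of segment definitions (`name`, `parent`,
#'   `translation`, `mass`, `com`, `inertia`, `joints`).
#' @param markers list of markers (`name`, `segment`, `position`).
#' @param muscles list of muscle elements (`name`, `points`, `fmax`, `lopt`,
#'   `lts`, `vmax`, `tact`, `tdeact`, `delay`).
#' @param gravity gravity vector in m/s^2.
#' @param name model name.
#' @param passive_scale scale on the passive force-length curve (1 = on).
#' @param act_switch_k steepness of the smooth activation/deactivation switch.
#' @return A validated `msk_model`.
#' @export
msk_model <- function(segments, markers, muscles, gravity = c(0, 0, -9.81),
                      name = "model", passive_scale = 1,
                      act_switch_k = 100) {
  model <- structure(
    list(name = name, gravity = as.numeric(gravity), segments = segments,
         markers = markers, muscles = muscles,
         passive_scale = passive_scale, act_switch_k = act_switch_k),
    class = "msk_model")
  validate_model(model)
  model$compiled <- compile_model(model)
  model
}

#' @export
print.msk_model <- function(x, ...) {
  cm <- x$compiled %||% compile_model(x)
  cat("<msk_model> ", x$name, "\n", sep = "")
  cat("  ", cm$nq, " DoF, ", cm$nmus, " muscle elements, ",
      cm$nmark, " markers\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a musculoskeletal model
#'
#' Checks the structural invariants: referenced segments exist, every muscle
#' path has at least two points, Hill parameters are positive,
#' activation time constants satisfy `0 < tact <= tdeact`, and joint limits
#' are ordered.
#'
#' @param model a `msk_model`.
#' @return `model`, invisibly; errors on violation.
#' @export
validate_model <- function(model) {
  seg_names <- vapply(model$segments, `[[`, "", "name")
  if (anyDuplicated(seg_names)) abort("duplicate segment names")
  for (seg in model$segments) {
    if (!identical(seg$parent, "world") && !seg$parent %in% seg_names)
      abort(paste0("segment '", seg$name, "' references unknown parent '",
                   seg$parent, "'"))
    for (j in seg$joints %||% list()) {
      if (length(j$axis) != 3 || abs(sqrt(sum(j$axis^2)) - 1) > 1e-6)
        abort(paste0("joint '", j$name, "' axis must be a unit 3-vector"))
      if (j$limits[1] >= j$limits[2])
        abort(paste0("joint '", j$name, "' limits must be increasing"))
    }
  }
  for (mk in model$markers)
    if (!mk$segment %in% seg_names)
      abort(paste0("marker '", mk$name, "' references unknown segment '",
                   mk$segment, "'"))
  for (mu in model$muscles) {
    if (length(mu$points) < 2)
      abort(paste0("muscle '", mu$name, "' needs >= 2 path points"))
    for (p in mu$points)
      if (!p$segment %in% seg_names)
        abort(paste0("muscle '", mu$name, "' references unknown segment '",
                     p$segment, "'"))
    with(mu, {
      if (fmax <= 0 || lopt <= 0 || vmax <= 0)
        abort(paste0("muscle '", name, "': fmax, lopt, vmax must be > 0"))
      if (tact <= 0 || tact > tdeact)
        abort(paste0("muscle '", name, "': need 0 < tact <= tdeact"))
    })
  }
  invisible(model)
}

#' Compile a model to the flat numeric form used by the solver backend
#'
#' Fixed (joint-less) segments are folded into their nearest jointed ancestor
#' frame; a segment with several joints expands into a chain of coincident
#' revolute frames.
#'
#' @param model a `msk_model`.
#' @return A flat list of arrays (internal representation).
#' @export
compile_model <- function(model) {
  seg_names <- vapply(model$segments, `[[`, "", "name")
  anchor <- list(world = list(joint = -1L, offset = c(0, 0, 0)))
  joint_parent <- integer(); joint_trans <- NULL; joint_axis <- NULL
  qmin <- numeric(); qmax <- numeric(); joint_names <- character()
  body_joint <- integer(); body_mass <- numeric()
  body_com <- NULL; body_inertia <- NULL
  for (seg in model$segments) {
    pa <- anchor[[seg$parent]]
    if (is.null(pa)) abort(paste0("parent '", seg$parent, "' defined after child"))
    trans <- pa$offset + as.numeric(seg$translation)
    joints <- seg$joints %||% list()
    if (length(joints) > 0) {
      for (i in seq_along(joints)) {
        j <- joints[[i]]
        joint_parent <- c(joint_parent, if (i == 1) pa$joint else length(joint_parent) - 1L)
        joint_trans <- cbind(joint_trans, if (i == 1) trans else c(0, 0, 0))
        joint_axis <- cbind(joint_axis, as.numeric(j$axis))
        qmin <- c(qmin, j$limits[1]); qmax <- c(qmax, j$limits[2])
        joint_names <- c(joint_names, j$name)
      }
      anchor[[seg$name]] <- list(joint = length(joint_parent) - 1L, offset = c(0, 0, 0))
    } else {
      anchor[[seg$name]] <- list(joint = pa$joint, offset = trans)
    }
    if ((seg$mass %||% 0) > 0) {
      a <- anchor[[seg$name]]
      body_joint <- c(body_joint, a$joint)
      body_mass <- c(body_mass, seg$mass)
      body_com <- cbind(body_com, a$offset + as.numeric(seg$com))
      inert <- seg$inertia
      if (is.null(dim(inert))) inert <- diag(as.numeric(inert), 3)
      body_inertia <- cbind(body_inertia, as.numeric(inert))
    }
  }
  mk_joint <- integer(); mk_loc <- NULL
  for (mk in model$markers) {
    a <- anchor[[mk$segment]]
    mk_joint <- c(mk_joint, a$joint)
    mk_loc <- cbind(mk_loc, a$offset + as.numeric(mk$position))
  }
  mus_npts <- integer(); pt_joint <- integer(); pt_loc <- NULL
  for (mu in model$muscles) {
    mus_npts <- c(mus_npts, length(mu$points))
    for (p in mu$points) {
      a <- anchor[[p$segment]]
      pt_joint <- c(pt_joint, a$joint)
      pt_loc <- cbind(pt_loc, a$offset + as.numeric(p$position))
    }
  }
  num <- function(field) vapply(model$muscles, function(m) as.numeric(m[[field]]), 0)
  list(nq = length(qmin), nmus = length(model$muscles), nmark = length(model$markers),
       joint_parent = joint_parent, joint_trans = joint_trans,
       joint_axis = joint_axis, qmin = qmin, qmax = qmax,
       joint_names = joint_names,
       body_joint = body_joint, body_mass = body_mass, body_com = body_com,
       body_inertia = body_inertia,
       marker_joint = mk_joint, marker_loc = mk_loc,
       marker_names = vapply(model$markers, `[[`, "", "name"),
       mus_npts = mus_npts, mus_pt_joint = pt_joint, mus_pt_loc = pt_loc,
       muscle_names = vapply(model$muscles, `[[`, "", "name"),
       fmax = num("fmax"), lopt = num("lopt"), lts = num("lts"),
       vmax = num("vmax"), tact = num("tact"), tdeact = num("tdeact"),
       delay = num("delay"),
       gravity = model$gravity, passive_scale = model$passive_scale,
       act_switch_k = model$act_switch_k)
}

cm <- function(model) model$compiled %||% compile_model(model)

seg <- function(name, parent, translation, mass = 0, com = c(0, 0, 0),
                inertia = c(0, 0, 0), joints = list()) {
  list(name = name, parent = parent, translation = translation, mass = mass,
       com = com, inertia = inertia, joints = joints)
}

jnt <- function(name, axis, limits) list(name = name, axis = axis, limits = limits)

mrk <- function(name, segment, position) {
  list(name = name, segment = segment, position = position)
}

mus <- function(name, points, fmax, lopt, lts = NA_real_, vmax = 10,
                tact = 0.015, tdeact = 0.060, delay = 0.020) {
  list(name = name, points = points, fmax = fmax, lopt = lopt, lts = lts,
       vmax = vmax, tact = tact, tdeact = tdeact, delay = delay)
}

pp <- function(segment, position) list(segment = segment, position = position)

#' Four-DoF, 19-muscle arm model
#'
#' A right-arm model with a fixed thorax, a humerus attached by three revolute
#' glenohumeral DoFs (plane of elevation, elevation, axial rotation; a z-x-z
#' sequence) and a forearm attached by elbow flexion. Eight markers sit on
#' humerus, ulna and radius; 19 Hill-type lines of action (pectoralis major
#' x3, latissimus dorsi x3, deltoid x3, supraspinatus, infraspinatus,
#' subscapularis, triceps x3, brachioradialis, brachialis, biceps x2) actuate
#' it. Maximal isometric forces and optimal fiber lengths follow the Holzbaur
#' upper-limb literature values; path-point coordinates and inertial
#' parameters are simplified synthetic placements, and tendon slack lengths
#' are calibrated at build time so each fiber sits at its optimal length in
#' the mid-range posture `q_mid` (see Details).
#'
#' @details Joint limits are `[-pi/2, pi/2]`, `[-2, pi/2]`, `[-pi/2, pi/2]`
#'   and `[-0.5, 2.1]` rad. The z-x-z shoulder sequence is singular at zero
#'   elevation, so reference tasks keep elevation away from 0.
#' @param q_mid posture used to calibrate tendon slack lengths.
#' @return A `msk_model` with 4 DoF, 19 muscles, 8 markers.
#' @export
arm_model <- function(q_mid = c(0, 0.7, 0, 1.0)) {
  shoulder <- list(
    jnt("gh_plane_elev", c(0, 0, 1), c(-pi / 2, pi / 2)),
    jnt("gh_elev", c(1, 0, 0), c(-2, pi / 2)),
    jnt("gh_axial", c(0, 0, 1), c(-pi / 2, pi / 2)))
  segments <- list(
    seg("thorax", "world", c(0, 0, 0)),
    seg("humerus", "thorax", c(0, 0, 0), mass = 2.05,
        com = c(0, 0, -0.14), inertia = c(0.016, 0.016, 0.003),
        joints = shoulder),
    seg("ulna", "humerus", c(0, 0, -0.30), mass = 1.55,
        com = c(0, 0, -0.19), inertia = c(0.022, 0.022, 0.0025),
        joints = list(jnt("elbow_flex", c(1, 0, 0), c(-0.5, 2.1)))),
    seg("radius", "ulna", c(0.02, 0.01, -0.02)))
  markers <- list(
    mrk("DELT_TUB", "humerus", c(0.035, 0.005, -0.12)),
    mrk("MID_ARM", "humerus", c(0.0, 0.035, -0.17)),
    mrk("EPIC_M", "humerus", c(-0.045, 0.0, -0.28)),
    mrk("EPIC_L", "humerus", c(0.045, 0.0, -0.28)),
    mrk("OLECRANON", "ulna", c(0.0, -0.045, 0.01)),
    mrk("ULNA_STY", "ulna", c(-0.01, -0.02, -0.25)),
    mrk("LOW_ARM", "ulna", c(0.0, 0.03, -0.16)),
    mrk("RAD_STY", "radius", c(0.02, 0.02, -0.22)))
  muscles <- list(
    mus("PECM1", list(pp("thorax", c(-0.05, 0.05, 0.0)),
                      pp("humerus", c(0.01, 0.022, -0.02)),
                      pp("humerus", c(0.02, 0.012, -0.05))), 364, 0.144),
    mus("PECM2", list(pp("thorax", c(-0.06, 0.055, -0.04)),
                      pp("humerus", c(0.01, 0.022, -0.025)),
                      pp("humerus", c(0.02, 0.012, -0.05))), 516, 0.138),
    mus("PECM3", list(pp("thorax", c(-0.06, 0.05, -0.09)),
                      pp("humerus", c(0.01, 0.02, -0.03)),
                      pp("humerus", c(0.02, 0.012, -0.05))), 390, 0.138),
    mus("LAT1", list(pp("thorax", c(-0.08, -0.04, -0.10)),
                     pp("humerus", c(0.0, -0.02, -0.03)),
                     pp("humerus", c(0.01, 0.005, -0.05))), 267, 0.254),
    mus("LAT2", list(pp("thorax", c(-0.08, -0.045, -0.16)),
                     pp("humerus", c(0.0, -0.02, -0.035)),
                     pp("humerus", c(0.01, 0.005, -0.05))), 243, 0.232),
    mus("LAT3", list(pp("thorax", c(-0.07, -0.05, -0.22)),
                     pp("humerus", c(0.0, -0.02, -0.04)),
                     pp("humerus", c(0.01, 0.005, -0.05))), 202, 0.279),
    mus("DELT1", list(pp("thorax", c(0.01, 0.035, 0.02)),
                      pp("humerus", c(0.03, 0.01, -0.11))), 1142, 0.098),
    mus("DELT2", list(pp("thorax", c(0.025, 0.0, 0.025)),
                      pp("humerus", c(0.032, 0.0, -0.11))), 1142, 0.108),
    mus("DELT3", list(pp("thorax", c(0.0, -0.04, 0.015)),
                      pp("humerus", c(0.025, -0.01, -0.11))), 260, 0.137),
    mus("SUPSP", list(pp("thorax", c(-0.05, -0.01, 0.01)),
                      pp("humerus", c(0.012, 0.0, 0.025)),
                      pp("humerus", c(0.028, 0.005, -0.015))), 487, 0.068),
    mus("INFSP", list(pp("thorax", c(-0.06, -0.035, -0.02)),
                      pp("humerus", c(0.0, -0.028, -0.005)),
                      pp("humerus", c(0.025, -0.012, -0.02))), 1210, 0.076),
    mus("SUBSC", list(pp("thorax", c(-0.06, 0.01, -0.02)),
                      pp("humerus", c(0.0, 0.025, -0.005)),
                      pp("humerus", c(0.022, 0.015, -0.02))), 1378, 0.087),
    mus("TRIlong", list(pp("thorax", c(-0.02, -0.03, -0.02)),
                        pp("humerus", c(0.0, -0.028, -0.26)),
                        pp("ulna", c(0.0, -0.04, 0.005))), 799, 0.134),
    mus("TRIlat", list(pp("humerus", c(0.01, -0.02, -0.10)),
                       pp("humerus", c(0.0, -0.028, -0.26)),
                       pp("ulna", c(0.0, -0.04, 0.005))), 625, 0.114),
    mus("TRImed", list(pp("humerus", c(-0.01, -0.02, -0.15)),
                       pp("humerus", c(0.0, -0.028, -0.26)),
                       pp("ulna", c(0.0, -0.04, 0.005))), 620, 0.114),
    mus("BRD", list(pp("humerus", c(0.03, 0.01, -0.26)),
                    pp("radius", c(0.015, 0.02, -0.20))), 262, 0.173),
    mus("BRA", list(pp("humerus", c(0.0, 0.012, -0.17)),
                    pp("ulna", c(0.0, 0.018, -0.035))), 987, 0.086),
    mus("BIClong", list(pp("thorax", c(0.015, 0.02, 0.01)),
                        pp("humerus", c(0.015, 0.025, -0.05)),
                        pp("radius", c(-0.01, 0.01, -0.03))), 625, 0.116),
    mus("BICshort", list(pp("thorax", c(-0.01, 0.03, -0.01)),
                         pp("humerus", c(0.008, 0.028, -0.05)),
                         pp("radius", c(-0.01, 0.012, -0.03))), 435, 0.132))
  build_with_slack(segments, markers, muscles, q_mid, name = "arm_4dof_19mus")
}

#' Two-DoF, six-muscle planar arm fixture
#'
#' A fast sagittal-plane fixture with shoulder and elbow flexion, four
#' markers and six muscle elements (mono-articular flexor/extensor at each
#' joint plus a bi-articular pair). It shares the full model schema and is
#' intended for quick solver and property tests.
#'
#' @param q_mid posture used to calibrate tendon slack lengths.
#' @return A `msk_model` with 2 DoF, 6 muscles, 4 markers.
#' @export
planar_arm_model <- function(q_mid = c(0.6, 1.0)) {
  segments <- list(
    seg("base", "world", c(0, 0, 0)),
    seg("upperarm", "base", c(0, 0, 0), mass = 2.0,
        com = c(0, 0, -0.13), inertia = c(0.015, 0.015, 0.002),
        joints = list(jnt("shoulder_flex", c(1, 0, 0), c(-1.0, 2.5)))),
    seg("forearm", "upperarm", c(0, 0, -0.30), mass = 1.5,
        com = c(0, 0, -0.17), inertia = c(0.02, 0.02, 0.002),
        joints = list(jnt("elbow_flex", c(1, 0, 0), c(-0.5, 2.1)))))
  markers <- list(
    mrk("UPA1", "upperarm", c(0.02, 0.0, -0.15)),
    mrk("UPA2", "upperarm", c(0.0, 0.02, -0.28)),
    mrk("FRA1", "forearm", c(0.02, 0.0, -0.12)),
    mrk("FRA2", "forearm", c(0.0, 0.02, -0.24)))
  muscles <- list(
    mus("SHFLX", list(pp("base", c(0, 0.05, 0.02)),
                      pp("upperarm", c(0, 0.02, -0.10))), 800, 0.10),
    mus("SHEXT", list(pp("base", c(0, -0.05, 0.02)),
                      pp("upperarm", c(0, -0.02, -0.10))), 700, 0.10),
    mus("ELFLX", list(pp("upperarm", c(0, 0.015, -0.15)),
                      pp("forearm", c(0, 0.02, -0.04))), 900, 0.09),
    mus("ELEXT", list(pp("upperarm", c(0, -0.015, -0.12)),
                      pp("upperarm", c(0, -0.03, -0.29)),
                      pp("forearm", c(0, -0.035, 0.01))), 800, 0.10),
    mus("BIFLX", list(pp("base", c(0, 0.03, 0.01)),
                      pp("upperarm", c(0, 0.025, -0.15)),
                      pp("forearm", c(0, 0.02, -0.05))), 500, 0.12),
    mus("BIEXT", list(pp("base", c(0, -0.03, 0.0)),
                      pp("upperarm", c(0, -0.028, -0.29)),
                      pp("forearm", c(0, -0.035, 0.01))), 500, 0.13))
  build_with_slack(segments, markers, muscles, q_mid, name = "planar_2dof_6mus")
}

# Calibrate tendon slack so the fiber is at optimal length in posture q_mid;
# optimal fiber lengths longer than ~70% of the mid-pose path are shortened
# to keep slack positive.
build_with_slack <- function(segments, markers, muscles, q_mid, name) {
  for (i in seq_along(muscles)) muscles[[i]]$lts <- 0
  m0 <- msk_model(segments, markers, muscles, name = name)
  geo <- cpp_muscle_geometry(cm(m0), q_mid, rep(0, cm(m0)$nq))
  for (i in seq_along(muscles)) {
    lmt_mid <- geo$lmt[i]
    lopt <- min(muscles[[i]]$lopt, 0.7 * lmt_mid)
    muscles[[i]]$lopt <- lopt
    muscles[[i]]$lts <- lmt_mid - lopt
  }
  msk_model(segments, markers, muscles, name = name)
}
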