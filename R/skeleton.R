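#' @useDynLib mocapfit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils head tail
NULL

JOINT_TYPES <- c(free6 = 0L, ball3 = 1L, universal2 = 2L, revolute1 = 3L)
JOINT_NDOF <- c(free6 = 6L, ball3 = 3L, universal2 = 2L, revolute1 = 1L)

#' Construct an articulated rigid-body skeleton
#'
#' A skeleton is a tree of body segments connected by joints, rooted at a
#' single segment carried by a 6-DOF free joint (three translations in the
#' parent/world frame followed by intrinsic XYZ Euler rotations). Each
#' segment can be scaled independently along its three local axes, giving a
#' scale vector `s` of length `3 * n_segments`; scales multiply joint
#' offsets, marker offsets and the segment centre of mass componentwise,
#' and rescale the inertia tensor consistently with the implied second
#' moments of the mass distribution.
#'
#' @param segments list of lists with fields `name`, `mass` (kg),
#'   `com` (3-vector, m, local unscaled frame), `inertia` (3x3, kg m^2, at
#'   the COM in the local frame).
#' @param joints list of lists with fields `name`, `type` (one of
#'   `"free6"`, `"ball3"`, `"universal2"`, `"revolute1"`), `parent` (segment
#'   name, or `NA` for the root joint), `child`, and optionally
#'   `parent_offset`, `child_offset` (3-vectors, m, unscaled),
#'   `parent_orient`, `child_orient` (XYZ Euler angles, rad, fixed frame
#'   rotations) and `axes` (list of unit 3-vectors for revolute/universal
#'   joints).
#' @param markers list of lists with fields `label`, `segment`,
#'   `offset` (3-vector, m, unscaled local frame) and `anatomical`
#'   (logical; anatomical markers receive a tight registration prior,
#'   tracking markers a loose one).
#' @param gravity world gravity vector, m/s^2.
#' @return an object of class `skeleton`.
#' @export
skeleton <- function(segments, joints, markers, gravity = c(0, -9.81, 0)) {
  seg_names <- vapply(segments, function(s) s$name, character(1))
  if (anyDuplicated(seg_names)) stop("duplicated segment names")
  ns <- length(segments)

  child_of <- vapply(joints, function(j) j$child, character(1))
  if (anyDuplicated(child_of)) stop("segment with more than one parent joint")
  if (!setequal(child_of, seg_names))
    stop("every segment must be the child of exactly one joint")

  parent_of <- vapply(joints, function(j) {
    if (is.null(j[["parent"]]) || is.na(j[["parent"]])) NA_character_ else j[["parent"]]
  }, character(1))
  root <- child_of[is.na(parent_of)]
  if (length(root) != 1L) stop("skeleton must have exactly one root joint")
  root_type <- vapply(joints, function(j) j$type, character(1))[is.na(parent_of)]
  if (root_type != "free6") stop("root joint must be of type free6")

  # topological order (parents before children); also detects cycles
  order <- root
  repeat {
    nxt <- child_of[!is.na(parent_of) & parent_of %in% order &
                      !(child_of %in% order)]
    if (!length(nxt)) break
    order <- c(order, nxt)
  }
  if (length(order) != ns)
    stop("joint graph is not a tree reaching every segment (cycle or orphan)")

  seg_idx <- match(order, seg_names)
  segments <- segments[seg_idx]
  seg_names <- order
  joints <- joints[match(order, child_of)]

  jt <- vapply(joints, function(j) j$type, character(1))
  if (!all(jt %in% names(JOINT_TYPES)))
    stop("unsupported joint type: ", paste(setdiff(jt, names(JOINT_TYPES)),
                                           collapse = ", "))
  ndof <- unname(JOINT_NDOF[jt])
  dof0 <- cumsum(c(0L, head(ndof, -1L)))
  nq <- sum(ndof)

  get3 <- function(x, default = c(0, 0, 0)) {
    if (is.null(x)) default else {
      stopifnot(length(x) == 3); as.numeric(x)
    }
  }
  poff <- vapply(joints, function(j) get3(j$parent_offset), numeric(3))
  coff <- vapply(joints, function(j) get3(j$child_offset), numeric(3))
  porient <- array(0, c(3, 3, ns))
  corient <- array(0, c(3, 3, ns))
  axes <- array(0, c(3, 3, ns))
  for (i in seq_len(ns)) {
    porient[, , i] <- euler_xyz(get3(joints[[i]]$parent_orient))
    corient[, , i] <- euler_xyz(get3(joints[[i]]$child_orient))
    ax <- diag(3)
    if (!is.null(joints[[i]]$axes)) {
      given <- joints[[i]]$axes
      for (k in seq_along(given)) ax[, k] <- as.numeric(given[[k]])
    }
    nrm <- sqrt(colSums(ax^2))
    if (jt[i] %in% c("revolute1", "universal2")) {
      need <- JOINT_NDOF[[jt[i]]]
      if (any(abs(nrm[seq_len(need)] - 1) > 1e-8))
        stop("joint axes must be unit norm for joint ", joints[[i]]$name)
      if (jt[i] == "universal2" &&
          abs(abs(sum(ax[, 1] * ax[, 2])) - 1) < 1e-8)
        stop("universal2 axes must be linearly independent")
    }
    axes[, , i] <- ax
  }

  mass0 <- vapply(segments, function(s) as.numeric(s$mass), numeric(1))
  if (any(mass0 <= 0)) stop("non-positive segment mass")
  com <- vapply(segments, function(s) get3(s$com), numeric(3))
  inertia0 <- array(0, c(3, 3, ns))
  for (i in seq_len(ns)) {
    I <- segments[[i]]$inertia
    if (is.null(I)) I <- diag(1e-3, 3)
    I <- matrix(as.numeric(I), 3, 3)
    if (max(abs(I - t(I))) > 1e-10) stop("inertia must be symmetric")
    ev <- eigen(I, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("inertia must be positive definite (segment ",
                           seg_names[i], ")")
    # second moments implied by the principal moments must be >= 0 for the
    # per-axis rescaling rule to stay physical
    p <- c(-I[1, 1] + I[2, 2] + I[3, 3],
           I[1, 1] - I[2, 2] + I[3, 3],
           I[1, 1] + I[2, 2] - I[3, 3]) / 2
    if (any(p < -1e-12))
      stop("inertia violates the triangle inequality (segment ",
           seg_names[i], ")")
    inertia0[, , i] <- I
  }

  labels <- vapply(markers, function(m) m$label, character(1))
  if (anyDuplicated(labels)) stop("duplicated marker label")
  mseg <- vapply(markers, function(m) m$segment, character(1))
  unknown <- setdiff(mseg, seg_names)
  if (length(unknown)) stop("marker on unknown segment: ",
                            paste(unknown, collapse = ", "))
  pbar <- vapply(markers, function(m) get3(m$offset), numeric(3))
  anatomical <- vapply(markers, function(m) isTRUE(m$anatomical), logical(1))

  dof_names <- unlist(lapply(seq_len(ns), function(i) {
    suff <- switch(jt[i],
                   free6 = c("tx", "ty", "tz", "rx", "ry", "rz"),
                   ball3 = c("rx", "ry", "rz"),
                   universal2 = c("r1", "r2"),
                   revolute1 = "r")
    paste(joints[[i]]$name, suff, sep = "_")
  }))

  obj <- list(
    seg_names = seg_names,
    joint_names = vapply(joints, function(j) j$name, character(1)),
    parent = match(ifelse(is.na(parent_of), NA, parent_of)[
      match(seg_names, child_of)], seg_names) - 1L,
    jtype = unname(JOINT_TYPES[jt]),
    ndof = ndof, dof0 = dof0, nq = nq,
    dof_names = dof_names,
    poff = poff, coff = coff, porient = porient, corient = corient,
    axes = axes,
    mass0 = mass0, com = com, inertia0 = inertia0,
    marker_labels = labels, marker_seg = match(mseg, seg_names) - 1L,
    pbar = pbar, anatomical = anatomical,
    gravity = as.numeric(gravity),
    scale_dim = 3L * ns
  )
  obj$parent[is.na(obj$parent)] <- -1L
  class(obj) <- "skeleton"
  obj$compiled <- skel_compile(obj)
  obj
}

#' @export
print.skeleton <- function(x, ...) {
  cat("skeleton:", length(x$seg_names), "segments,", x$nq, "DOF,",
      length(x$marker_labels), "markers, scale_dim =", x$scale_dim, "\n")
  invisible(x)
}

# Flat list handed to the C++ kernels.
skel_compile <- function(skel) {
  list(ns = length(skel$seg_names), nq = skel$nq,
       parent = skel$parent, jtype = skel$jtype,
       dof0 = skel$dof0, ndof = skel$ndof,
       poff = skel$poff, coff = skel$coff,
       porient = skel$porient, corient = skel$corient, axes = skel$axes,
       com = skel$com, mass0 = skel$mass0, inertia0 = skel$inertia0,
       gravity = skel$gravity, marker_seg = skel$marker_seg)
}

n_segments <- function(skel) length(skel$seg_names)

#' Default (unit) scale vector for a skeleton
#' @param skel a `skeleton`.
#' @return numeric vector of ones, length `skel$scale_dim`.
#' @export
default_scales <- function(skel) rep(1, skel$scale_dim)

euler_xyz <- function(a) {
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

check_dims <- function(skel, s, q) {
  if (length(s) != skel$scale_dim)
    stop("scale vector has length ", length(s), ", expected ",
         skel$scale_dim)
  if (length(q) != skel$nq)
    stop("pose vector has length ", length(q), ", expected ", skel$nq)
}

# indices (1-based) of rotational "middle" Euler angles subject to gimbal lock
gimbal_dofs <- function(skel) {
  out <- integer(0)
  for (i in seq_along(skel$jtype)) {
    if (skel$jtype[i] == 0L) out <- c(out, skel$dof0[i] + 5L)
    if (skel$jtype[i] == 1L) out <- c(out, skel$dof0[i] + 2L)
  }
  out
}

warn_if_gimbal <- function(skel, q) {
  g <- gimbal_dofs(skel)
  if (length(g)) {
    bad <- abs(q[g]) > 80 * pi / 180
    if (any(bad))
      warning("Euler middle angle beyond 80 degrees (gimbal proximity) at ",
              paste(skel$dof_names[g[bad]], collapse = ", "))
  }
  invisible(NULL)
}

#' Forward kinematics
#'
#' @param skel a `skeleton`.
#' @param s scale vector (length `skel$scale_dim`).
#' @param q pose vector (length `skel$nq`).
#' @param warn_gimbal warn when an XYZ-Euler middle angle exceeds 80 degrees.
#' @return list with `origins` (n_segments x 3 world positions) and
#'   `rotations` (3 x 3 x n_segments world orientation matrices).
#' @export
forward_kinematics <- function(skel, s, q, warn_gimbal = TRUE) {
  check_dims(skel, s, q)
  if (warn_gimbal) warn_if_gimbal(skel, q)
  fk <- cpp_fk(skel$compiled, s, q)
  rownames(fk$o) <- skel$seg_names
  list(origins = fk$o, rotations = fk$R)
}

#' World marker positions
#'
#' Applies segment scaling componentwise to the local marker offsets and
#' maps them through forward kinematics.
#'
#' @inheritParams forward_kinematics
#' @param p 3 x M matrix of local marker offsets (defaults to the nominal
#'   marker set `skel$pbar`).
#' @return M x 3 matrix of world positions, rownames the marker labels.
#' @export
marker_world_positions <- function(skel, s, q, p = skel$pbar) {
  check_dims(skel, s, q)
  stopifnot(ncol(p) == length(skel$marker_labels), nrow(p) == 3)
  X <- cpp_markers(skel$compiled, s, q, p)
  rownames(X) <- skel$marker_labels
  X
}

#' Analytic marker Jacobians
#'
#' Partial derivatives of the stacked world marker positions (x1 y1 z1 x2
#' ...) with respect to the pose `q`, the scales `s` and the local offsets
#' `p`. The `p` blocks are block-diagonal `R_segment %*% diag(s_segment)`
#' matrices, returned as a 3 x 3 x M array of segment rotations plus the
#' scale factors.
#'
#' @inheritParams marker_world_positions
#' @return list with `x` (M x 3 positions), `Jq` (3M x nq), `Js` (3M x 3ns)
#'   and `R` (3 x 3 x M world rotations of each marker's segment).
#' @export
fk_jacobians <- function(skel, s, q, p = skel$pbar) {
  check_dims(skel, s, q)
  cpp_marker_jac(skel$compiled, s, q, p)
}

#' Whole-body centre of mass
#'
#' @inheritParams forward_kinematics
#' @param masses per-segment masses, kg (default: model masses).
#' @return world COM position (3-vector).
#' @export
com_position <- function(skel, s, masses = skel$mass0, q) {
  check_dims(skel, s, q)
  if (any(masses <= 0) || sum(masses) == 0) stop("masses must be positive")
  drop(cpp_com(skel$compiled, s, masses, q))
}

#' COM trajectory over a pose trajectory
#' @inheritParams com_position
#' @param Q T x nq pose trajectory.
#' @return T x 3 matrix of COM positions.
#' @export
com_trajectory <- function(skel, s, masses = skel$mass0, Q) {
  if (any(masses <= 0)) stop("masses must be positive")
  cpp_com_traj(skel$compiled, s, masses, Q)
}

#' Generalized mass matrix
#'
#' Assembled from per-segment spatial Jacobians (equivalent to the
#' composite-rigid-body mass matrix); always symmetric.
#'
#' @inheritParams com_position
#' @return nq x nq symmetric positive definite matrix.
#' @export
mass_matrix <- function(skel, s, masses = skel$mass0, q) {
  check_dims(skel, s, q)
  cpp_mass_matrix(skel$compiled, s, masses, q)
}

#' Inverse dynamics
#'
#' Computes the generalized forces `tau` satisfying the equations of motion
#' `M(q) qdd + c(q, qd) = tau + J^T f_ext`. The first six components (the
#' root free joint) are the residual wrench: forces along the world axes
#' and moments conjugate to the root Euler rates. Use [root_residual()] to
#' convert the latter to a world-frame moment vector.
#'
#' @inheritParams com_position
#' @param qd,qdd generalized velocity and acceleration (see
#'   [fd_derivatives()] for the finite-difference convention).
#' @param external_wrenches 6 x n_segments matrix: world force (rows 1-3)
#'   and world moment about the world origin (rows 4-6) applied to each
#'   segment; see [wrench_at_point()]. Default: no external load.
#' @return generalized force vector tau (length nq), named by DOF.
#' @export
inverse_dynamics <- function(skel, s, masses = skel$mass0, q, qd, qdd,
                             external_wrenches = NULL) {
  check_dims(skel, s, q)
  stopifnot(length(qd) == skel$nq, length(qdd) == skel$nq)
  ext <- external_wrenches
  if (is.null(ext)) ext <- matrix(0, 6, n_segments(skel))
  stopifnot(nrow(ext) == 6, ncol(ext) == n_segments(skel))
  tau <- drop(cpp_inverse_dynamics(skel$compiled, s, masses, q, qd, qdd, ext))
  names(tau) <- skel$dof_names
  tau
}

#' External wrench from a force applied at a point
#'
#' @param force world force 3-vector (N).
#' @param point world application point (m).
#' @param free_moment additional couple (N m), world frame.
#' @return 6-vector (force, moment about the world origin) matching the
#'   `external_wrenches` convention of [inverse_dynamics()].
#' @export
wrench_at_point <- function(force, point, free_moment = c(0, 0, 0)) {
  c(force, cross3(point, force) + free_moment)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# World axes of the root rotational DOFs (columns; generally non-orthogonal
# for Euler parameterizations).
root_euler_axes <- function(skel, q) {
  fk <- cpp_fk(skel$compiled, default_scales(skel), q)
  fk$dof_axis[, 4:6, drop = FALSE]
}

#' Root residual wrench in physical units
#'
#' Converts the six root components of an inverse-dynamics solution into a
#' world-frame force (N) and moment about the root joint (N m). The
#' rotational generalized forces are conjugate to Euler-angle rates, so
#' they are mapped through the inverse transpose of the root axis matrix.
#'
#' @param skel a `skeleton`.
#' @param q pose at which `tau` was computed.
#' @param tau generalized force vector from [inverse_dynamics()].
#' @return list with `force` and `torque`, world-frame 3-vectors.
#' @export
root_residual <- function(skel, q, tau) {
  E <- root_euler_axes(skel, q)
  list(force = unname(tau[1:3]),
       torque = drop(solve(t(E), tau[4:6])))
}

#' Finite-difference velocities and accelerations
#'
#' Central differences in the interior; the first and last samples reuse
#' their neighbour's difference so that dynamically consistent synthetic
#' data stays consistent under the same convention.
#'
#' @param Q T x nq pose trajectory.
#' @param dt sample interval, s.
#' @return list with `qd` and `qdd`, both T x nq.
#' @export
fd_derivatives <- function(Q, dt) {
  T <- nrow(Q)
  if (T < 3) stop("need at least 3 frames for finite differences")
  qd <- matrix(0, T, ncol(Q))
  qd[2:(T - 1), ] <- (Q[3:T, , drop = FALSE] -
                        Q[1:(T - 2), , drop = FALSE]) / (2 * dt)
  qd[1, ] <- (Q[2, ] - Q[1, ]) / dt
  qd[T, ] <- (Q[T, ] - Q[T - 1, ]) / dt
  qdd <- matrix(0, T, ncol(Q))
  qdd[2:(T - 1), ] <- (Q[3:T, , drop = FALSE] -
                         2 * Q[2:(T - 1), , drop = FALSE] +
                         Q[1:(T - 2), , drop = FALSE]) / dt^2
  qdd[1, ] <- qdd[2, ]
  qdd[T, ] <- qdd[T - 1, ]
  list(qd = qd, qdd = qdd)
}

#' Forward-dynamics acceleration
#'
#' Solves `M(q) qdd = tau + Q_ext - c(q, qd)`; the validation counterpart
#' of [inverse_dynamics()].
#'
#' @inheritParams inverse_dynamics
#' @param tau generalized forces.
#' @return acceleration vector qdd.
#' @export
forward_dynamics_accel <- function(skel, s, masses = skel$mass0, q, qd, tau,
                                   external_wrenches = NULL) {
  M <- mass_matrix(skel, s, masses, q)
  bias <- inverse_dynamics(skel, s, masses, q, qd, rep(0, skel$nq),
                           external_wrenches = NULL)
  Qe <- rep(0, skel$nq)
  if (!is.null(external_wrenches))
    Qe <- drop(cpp_ext_gen_forces(skel$compiled, s, q, external_wrenches))
  drop(solve(M, tau + Qe - bias))
}

#' Semi-explicit (symplectic) Euler integration of free dynamics
#'
#' Integrates `qd <- qd + qdd dt; q <- q + qd dt` under constant
#' generalized forces; used by the energy-consistency checks.
#'
#' @inheritParams forward_dynamics_accel
#' @param q0,qd0 initial state.
#' @param dt step, s.
#' @param n_steps number of steps.
#' @return list of trajectories `Q`, `Qd` ((n_steps + 1) x nq).
#' @export
integrate_free <- function(skel, s, masses = skel$mass0, q0, qd0, dt,
                           n_steps, tau = rep(0, skel$nq)) {
  nq <- skel$nq
  Q <- matrix(0, n_steps + 1, nq)
  Qd <- matrix(0, n_steps + 1, nq)
  q <- q0; qd <- qd0
  Q[1, ] <- q; Qd[1, ] <- qd
  cm <- skel$compiled
  ext <- matrix(0, 6, n_segments(skel))
  for (k in seq_len(n_steps)) {
    M <- cpp_mass_matrix(cm, s, masses, q)
    bias <- cpp_inverse_dynamics(cm, s, masses, q, qd, rep(0, nq), ext)
    qdd <- drop(solve(M, tau - bias))
    qd <- qd + qdd * dt
    q <- q + qd * dt
    Q[k + 1, ] <- q; Qd[k + 1, ] <- qd
  }
  list(Q = Q, Qd = Qd)
}

#' Kinetic energy of a pose/velocity state
#' @inheritParams forward_dynamics_accel
#' @return scalar kinetic energy, J.
#' @export
kinetic_energy <- function(skel, s, masses = skel$mass0, q, qd) {
  0.5 * drop(t(qd) %*% mass_matrix(skel, s, masses, q) %*% qd)
}
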