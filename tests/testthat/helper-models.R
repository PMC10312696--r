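# Shared fixtures and independent oracles.  All fixtures are built in
# code; nothing is read from disk except files the tests write themselves.

# -- small articulated chain covering every joint type ----------------------
mk_chain <- function() {
  segs <- list(
    list(name = "base", mass = 2, com = c(0.1, -0.2, 0.05),
         inertia = diag(c(0.02, 0.03, 0.04))),
    list(name = "link1", mass = 1.5, com = c(0, -0.25, 0),
         inertia = diag(c(0.03, 0.01, 0.03))),
    list(name = "link2", mass = 0.8, com = c(0, -0.15, 0.02),
         inertia = matrix(c(0.02, 0.001, 0, 0.001, 0.015, 0.002,
                            0, 0.002, 0.025), 3, 3)),
    list(name = "link3", mass = 0.5, com = c(0, -0.1, 0),
         inertia = diag(c(0.006, 0.004, 0.006))))
  jts <- list(
    list(name = "root", type = "free6", parent = NA, child = "base"),
    list(name = "j1", type = "ball3", parent = "base", child = "link1",
         parent_offset = c(0.1, -0.4, 0.0), child_offset = c(0, 0.02, 0),
         parent_orient = c(0.1, -0.2, 0.3)),
    list(name = "j2", type = "universal2", parent = "link1",
         child = "link2", parent_offset = c(0, -0.5, 0),
         axes = list(c(0, 0, 1), c(1, 0, 0)),
         child_orient = c(0, 0.1, 0)),
    list(name = "j3", type = "revolute1", parent = "link2",
         child = "link3", parent_offset = c(0, -0.3, 0.05),
         axes = list(c(0, 1, 0) / 1)))
  mks <- list(
    list(label = "M1", segment = "base", offset = c(0.1, 0, 0.05),
         anatomical = TRUE),
    list(label = "M2", segment = "link1", offset = c(0.02, -0.3, 0),
         anatomical = FALSE),
    list(label = "M3", segment = "link2", offset = c(0, -0.2, 0.03),
         anatomical = TRUE),
    list(label = "M4", segment = "link3", offset = c(0.05, -0.05, 0),
         anatomical = FALSE))
  skeleton(segs, jts, mks)
}

# single free-floating box with >= 3 non-collinear markers
mk_free_body <- function(gravity = c(0, -9.81, 0)) {
  skeleton(
    list(list(name = "box", mass = 3, com = c(0.02, 0.01, -0.03),
              inertia = diag(c(0.02, 0.03, 0.04)))),
    list(list(name = "root", type = "free6", parent = NA, child = "box")),
    list(list(label = "A", segment = "box", offset = c(0.1, 0, 0),
              anatomical = TRUE),
         list(label = "B", segment = "box", offset = c(0, 0.12, 0.02),
              anatomical = TRUE),
         list(label = "C", segment = "box", offset = c(-0.05, 0.03, 0.1),
              anatomical = TRUE),
         list(label = "D", segment = "box", offset = c(0.04, -0.08, -0.06),
              anatomical = FALSE)),
    gravity = gravity)
}

mk_pendulum <- function() {
  skeleton(
    list(list(name = "base", mass = 1, com = c(0, -0.1, 0),
              inertia = diag(1e-3, 3)),
         list(name = "rod", mass = 0.5, com = c(0, -0.25, 0),
              inertia = diag(c(0.01, 1e-3, 0.01)))),
    list(list(name = "root", type = "free6", parent = NA, child = "base"),
         list(name = "hinge", type = "revolute1", parent = "base",
              child = "rod", parent_offset = c(0, -0.2, 0),
              axes = list(c(0, 0, 1)))),
    list(list(label = "P1", segment = "base", offset = c(0.05, 0, 0),
              anatomical = TRUE),
         list(label = "P2", segment = "rod", offset = c(0, -0.4, 0),
              anatomical = TRUE)))
}

# -- independent oracles ----------------------------------------------------

rot_axis_R <- function(u, a) {
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
}
euler_xyz_R <- function(a) {
  rot_axis_R(c(1, 0, 0), a[1]) %*% rot_axis_R(c(0, 1, 0), a[2]) %*%
    rot_axis_R(c(0, 0, 1), a[3])
}

# explicit per-joint homogeneous transform chain (independent of the
# package's FK implementation)
oracle_fk <- function(skel, s, q) {
  ns <- length(skel$seg_names)
  Rs <- array(0, c(3, 3, ns)); os <- matrix(0, ns, 3)
  for (i in seq_len(ns)) {
    p_ <- skel$parent[i] + 1
    Rp <- if (p_ > 0) Rs[, , p_] else diag(3)
    op <- if (p_ > 0) os[p_, ] else c(0, 0, 0)
    sp <- if (p_ > 0) s[(3 * p_ - 2):(3 * p_)] else rep(1, 3)
    si <- s[(3 * i - 2):(3 * i)]
    anchor <- op + Rp %*% (sp * skel$poff[, i])
    Rj0 <- Rp %*% skel$porient[, , i]
    d0 <- skel$dof0[i]
    ty <- skel$jtype[i]
    if (ty == 0) {
      anchor <- anchor + Rj0 %*% q[d0 + 1:3]
      Rq <- euler_xyz_R(q[d0 + 4:6])
    } else if (ty == 1) {
      Rq <- euler_xyz_R(q[d0 + 1:3])
    } else if (ty == 2) {
      Rq <- rot_axis_R(skel$axes[, 1, i], q[d0 + 1]) %*%
        rot_axis_R(skel$axes[, 2, i], q[d0 + 2])
    } else Rq <- rot_axis_R(skel$axes[, 1, i], q[d0 + 1])
    Ri <- Rj0 %*% Rq %*% t(skel$corient[, , i])
    os[i, ] <- anchor - Ri %*% (si * skel$coff[, i])
    Rs[, , i] <- Ri
  }
  list(o = os, R = Rs)
}

oracle_markers <- function(skel, s, q, p = skel$pbar) {
  fk <- oracle_fk(skel, s, q)
  t(vapply(seq_along(skel$marker_labels), function(i) {
    b <- skel$marker_seg[i] + 1
    drop(fk$o[b, ] + fk$R[, , b] %*% (s[(3 * b - 2):(3 * b)] * p[, i]))
  }, numeric(3)))
}

# central finite differences of a vector-valued function
fd_jac <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(k) {
    e <- rep(0, length(x)); e[k] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, f(x))
}

stack_rows <- function(X) as.vector(t(X))

# rigid registration oracle (Kabsch / orthogonal Procrustes)
oracle_kabsch <- function(fixed, moving) {
  cf <- colMeans(fixed); cm <- colMeans(moving)
  H <- t(sweep(fixed, 2, cf)) %*% sweep(moving, 2, cm)
  sv <- svd(H)
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  list(R = R, d = drop(cm - R %*% cf))
}

# -- cached synthetic gait trial (expensive pieces shared across files) -----
.trial_cache <- new.env(parent = emptyenv())

cached_gait_trial <- function(seed = 3, duration_s = 1.5, ...) {
  key <- paste0("trial_", seed, "_", duration_s, "_",
                paste(unlist(list(...)), collapse = "_"))
  if (is.null(.trial_cache[[key]])) {
    skel <- cached_gait_skel()
    .trial_cache[[key]] <- make_trial(skel, seed = seed,
                                      duration_s = duration_s,
                                      prior = cached_gait_prior(), ...)
  }
  .trial_cache[[key]]
}

cached_gait_skel <- function() {
  if (is.null(.trial_cache$skel)) .trial_cache$skel <- skeleton_gait9()
  .trial_cache$skel
}

cached_gait_prior <- function() {
  if (is.null(.trial_cache$prior))
    .trial_cache$prior <- synthetic_scaling_prior(cached_gait_skel())
  .trial_cache$prior
}
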