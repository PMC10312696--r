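test_that("skeleton validation rejects malformed models", {
  segs <- list(list(name = "a", mass = 1, com = c(0, 0, 0),
                    inertia = diag(0.01, 3)))
  root <- list(list(name = "root", type = "free6", parent = NA,
                    child = "a"))
  mk <- function(lab) list(label = lab, segment = "a",
                           offset = c(0.1, 0, 0), anatomical = TRUE)
  # duplicated marker label
  expect_error(skeleton(segs, root, list(mk("X"), mk("X"))),
               "duplicated marker")
  # marker on unknown segment
  bad <- mk("X"); bad$segment <- "ghost"
  expect_error(skeleton(segs, root, list(bad)), "unknown segment")
  # non-positive mass
  segs2 <- segs; segs2[[1]]$mass <- 0
  expect_error(skeleton(segs2, root, list(mk("X"))), "mass")
  # cycle / orphan in the joint graph
  segs3 <- c(segs, list(list(name = "b", mass = 1, com = c(0, 0, 0),
                             inertia = diag(0.01, 3))))
  jts3 <- c(root, list(list(name = "jb", type = "revolute1",
                            parent = "b", child = "b",
                            axes = list(c(0, 0, 1)))))
  expect_error(skeleton(segs3, jts3, list(mk("X"))))
  # unsupported joint type
  jts4 <- c(root, list(list(name = "jb", type = "helical",
                            parent = "a", child = "b")))
  expect_error(skeleton(segs3, jts4, list(mk("X"))), "unsupported joint")
  # non-positive-definite inertia
  segs5 <- segs; segs5[[1]]$inertia <- diag(c(0.01, -0.01, 0.01))
  expect_error(skeleton(segs5, root, list(mk("X"))), "positive definite")
})

test_that("forward kinematics matches the transform-chain oracle", {
  skel <- mk_chain()
  set.seed(11)
  # identity case: q = 0, s = 1 puts every segment at its default place
  fk0 <- forward_kinematics(skel, default_scales(skel), rep(0, skel$nq))
  or0 <- oracle_fk(skel, default_scales(skel), rep(0, skel$nq))
  expect_lt(max(abs(fk0$origins - or0$o)), 1e-14)
  for (rep in 1:10) {
    s <- 1 + 0.2 * runif(skel$scale_dim, -1, 1)
    q <- 0.5 * rnorm(skel$nq)
    fk <- forward_kinematics(skel, s, q, warn_gimbal = FALSE)
    or <- oracle_fk(skel, s, q)
    expect_lt(max(abs(fk$origins - or$o)), 1e-12)
    expect_lt(max(abs(fk$rotations - or$R)), 1e-12)
    expect_lt(max(abs(marker_world_positions(skel, s, q) -
                        oracle_markers(skel, s, q))), 1e-12)
  }
})

test_that("FK is equivariant under rigid root transforms", {
  skel <- mk_chain()
  set.seed(12)
  for (rep in 1:20) {
    q <- 0.4 * rnorm(skel$nq)
    q[1:6] <- 0
    s <- 1 + 0.15 * runif(skel$scale_dim, -1, 1)
    X0 <- marker_world_positions(skel, s, q)
    tr <- rnorm(3); th <- 0.6 * rnorm(3)
    q2 <- q; q2[1:3] <- tr; q2[4:6] <- th
    X2 <- marker_world_positions(skel, s, q2)
    R <- euler_xyz_R(th)
    expect_lt(max(abs(X2 - (t(R %*% t(X0)) +
                              matrix(tr, nrow(X0), 3, byrow = TRUE)))),
              1e-10)
  }
})

test_that("marker scaling is componentwise in the segment frame", {
  skel <- mk_chain()
  q <- rep(0, skel$nq)
  s <- default_scales(skel)
  X1 <- marker_world_positions(skel, s, q)
  s2 <- s; s2[1:3] <- 2 # double the root segment's scale
  X2 <- marker_world_positions(skel, s2, q)
  fk <- forward_kinematics(skel, s2, q)
  # root-segment marker offset from the segment origin doubles
  i <- 1 # marker M1 on base
  o <- fk$origins[1, ]
  expect_equal(X2[i, ] - o, 2 * (X1[i, ] - o), tolerance = 1e-12)
})

test_that("analytic Jacobians match central finite differences", {
  skel <- mk_chain()
  set.seed(13)
  worst <- 0
  for (rep in 1:100) {
    s <- 1 + 0.2 * runif(skel$scale_dim, -1, 1)
    q <- 0.5 * rnorm(skel$nq)
    p <- skel$pbar + 0.02 * rnorm(length(skel$pbar))
    J <- fk_jacobians(skel, s, q, p)
    scale_ref <- max(1, max(abs(J$Jq)), max(abs(J$Js)))
    Jq_fd <- fd_jac(function(qq) stack_rows(
      marker_world_positions(skel, s, qq, p)), q)
    Js_fd <- fd_jac(function(ss) stack_rows(
      marker_world_positions(skel, ss, q, p)), s)
    worst <- max(worst, max(abs(J$Jq - Jq_fd)) / scale_ref,
                 max(abs(J$Js - Js_fd)) / scale_ref)
  }
  expect_lt(worst, 1e-6)
})

test_that("Jacobian structure: root translation and revolute columns", {
  skel <- mk_chain()
  set.seed(14)
  q <- 0.4 * rnorm(skel$nq)
  s <- default_scales(skel)
  J <- fk_jacobians(skel, s, q)
  M <- length(skel$marker_labels)
  # root translational columns are stacked identity blocks
  for (i in seq_len(M))
    expect_equal(J$Jq[3 * i - 2:0, 1:3], diag(3), tolerance = 1e-12)
  # revolute column equals omega x (x - joint center)
  fk <- mocapfit:::cpp_fk(skel$compiled, s, q)
  d_rev <- skel$dof0[4] + 1 # j3 revolute dof (segment 4)
  w <- fk$dof_axis[, d_rev]; cjt <- fk$dof_anchor[, d_rev]
  x4 <- marker_world_positions(skel, s, q)[4, ] # marker on link3
  expect_equal(J$Jq[10:12, d_rev],
               c(w[2] * (x4[3] - cjt[3]) - w[3] * (x4[2] - cjt[2]),
                 w[3] * (x4[1] - cjt[1]) - w[1] * (x4[3] - cjt[3]),
                 w[1] * (x4[2] - cjt[2]) - w[2] * (x4[1] - cjt[1])),
               tolerance = 1e-10)
  # the p-block is R diag(s): check via finite differences on p
  p <- skel$pbar
  Jp_fd <- fd_jac(function(pp) stack_rows(
    marker_world_positions(skel, s, q, matrix(pp, 3))), as.vector(p))
  for (i in seq_len(M)) {
    b <- skel$marker_seg[i] + 1
    blk <- J$R[, , i] %*% diag(s[(3 * b - 2):(3 * b)])
    expect_equal(Jp_fd[3 * i - 2:0, 3 * i - 2:0], blk, tolerance = 1e-6)
  }
})

test_that("centre of mass matches a direct-summation oracle", {
  skel <- mk_chain()
  # single segment: COM is that segment's world COM
  one <- mk_free_body()
  q1 <- c(0.2, -0.1, 0.3, 0.1, 0.5, -0.2)
  fk <- oracle_fk(one, rep(1, 3), q1)
  expect_equal(com_position(one, rep(1, 3), one$mass0, q1),
               drop(fk$o[1, ] + fk$R[, , 1] %*% one$com[, 1]),
               tolerance = 1e-12)
  # randomized chain vs independent mass-weighted loop
  set.seed(15)
  for (rep in 1:10) {
    s <- 1 + 0.2 * runif(skel$scale_dim, -1, 1)
    q <- 0.5 * rnorm(skel$nq)
    m <- runif(4, 0.5, 3)
    fk <- oracle_fk(skel, s, q)
    acc <- c(0, 0, 0)
    for (b in 1:4) {
      cb <- fk$o[b, ] + fk$R[, , b] %*%
        (s[(3 * b - 2):(3 * b)] * skel$com[, b])
      acc <- acc + m[b] * cb
    }
    expect_equal(com_position(skel, s, m, q), drop(acc / sum(m)),
                 tolerance = 1e-12)
  }
})

test_that("mass matrix is SPD, symmetric and energy-consistent", {
  skel <- mk_chain()
  set.seed(16)
  # free body translational block is m I
  fb <- mk_free_body()
  Mfb <- mass_matrix(fb, rep(1, 3), fb$mass0, rep(0.3, 6))
  expect_equal(Mfb[1:3, 1:3], diag(fb$mass0[1], 3), tolerance = 1e-12)
  for (rep in 1:100) {
    s <- 1 + 0.2 * runif(skel$scale_dim, -1, 1)
    q <- 0.6 * rnorm(skel$nq)
    M <- mass_matrix(skel, s, skel$mass0, q)
    expect_lt(max(abs(M - t(M))), 1e-10)
    expect_gt(min(eigen(M, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
  # 1/2 qd' M qd equals summed per-body kinetic energies from finite
  # differences of the body motion
  for (rep in 1:5) {
    s <- 1 + 0.2 * runif(skel$scale_dim, -1, 1)
    q <- 0.5 * rnorm(skel$nq); qd <- rnorm(skel$nq)
    h <- 1e-7
    f0 <- oracle_fk(skel, s, q); f1 <- oracle_fk(skel, s, q + h * qd)
    KE <- 0
    for (b in 1:4) {
      sb <- s[(3 * b - 2):(3 * b)]
      c0 <- f0$o[b, ] + f0$R[, , b] %*% (sb * skel$com[, b])
      c1 <- f1$o[b, ] + f1$R[, , b] %*% (sb * skel$com[, b])
      v <- (c1 - c0) / h
      W <- ((f1$R[, , b] - f0$R[, , b]) / h) %*% t(f0$R[, , b])
      w <- c(W[3, 2], W[1, 3], W[2, 1])
      I0 <- skel$inertia0[, , b]
      pm <- c(-I0[1, 1] + I0[2, 2] + I0[3, 3],
              I0[1, 1] - I0[2, 2] + I0[3, 3],
              I0[1, 1] + I0[2, 2] - I0[3, 3]) / 2 * sb^2
      Is <- diag(c(pm[2] + pm[3], pm[1] + pm[3], pm[1] + pm[2]))
      Is[1, 2] <- Is[2, 1] <- sb[1] * sb[2] * I0[1, 2]
      Is[1, 3] <- Is[3, 1] <- sb[1] * sb[3] * I0[1, 3]
      Is[2, 3] <- Is[3, 2] <- sb[2] * sb[3] * I0[2, 3]
      Iw <- f0$R[, , b] %*% Is %*% t(f0$R[, , b])
      KE <- KE + 0.5 * skel$mass0[b] * sum(v^2) + 0.5 * sum(w * (Iw %*% w))
    }
    expect_equal(kinetic_energy(skel, s, skel$mass0, q, qd), KE,
                 tolerance = 1e-5)
  }
})

test_that("inverse dynamics: trivial cases and static equilibrium", {
  # zero gravity, zero motion, zero load -> zero generalized forces
  fb0 <- mk_free_body(gravity = c(0, 0, 0))
  tau <- inverse_dynamics(fb0, rep(1, 3), fb0$mass0, rep(0, 6),
                          rep(0, 6), rep(0, 6))
  expect_equal(unname(tau), rep(0, 6))
  # static pose under gravity with support through the COM
  skel <- mk_chain()
  s <- 1 + 0.1 * runif(skel$scale_dim)
  q0 <- rep(0, skel$nq); z <- rep(0, skel$nq)
  com <- com_position(skel, s, skel$mass0, q0)
  ext <- matrix(0, 6, 4)
  ext[, 1] <- wrench_at_point(-sum(skel$mass0) * skel$gravity, com)
  tau <- inverse_dynamics(skel, s, skel$mass0, q0, z, z, ext)
  expect_lt(max(abs(tau[1:6])), 1e-8)
})

test_that("inverse dynamics matches the finite-difference Lagrangian
           oracle and forward dynamics", {
  skel <- mk_chain()
  set.seed(17)
  Vpot <- function(s, q) {
    fk <- oracle_fk(skel, s, q)
    -sum(vapply(1:4, function(b) {
      cb <- fk$o[b, ] + fk$R[, , b] %*%
        (s[(3 * b - 2):(3 * b)] * skel$com[, b])
      skel$mass0[b] * sum(skel$gravity * cb)
    }, numeric(1)))
  }
  for (rep in 1:3) {
    s <- 1 + 0.15 * runif(skel$scale_dim, -1, 1)
    q <- 0.4 * rnorm(skel$nq)
    qd <- rnorm(skel$nq); qdd <- rnorm(skel$nq)
    L <- function(qq, qqd) kinetic_energy(skel, s, skel$mass0, qq, qqd) -
      Vpot(s, qq)
    h <- 1e-5
    tau_id <- inverse_dynamics(skel, s, skel$mass0, q, qd, qdd)
    nq <- skel$nq
    tau_or <- vapply(seq_len(nq), function(k) {
      e <- rep(0, nq); e[k] <- h
      dLdqd <- function(qq, qqd) (L(qq, qqd + e) - L(qq, qqd - e)) / (2 * h)
      ddt <- (dLdqd(q + qd * h, qd + qdd * h) -
                dLdqd(q - qd * h, qd - qdd * h)) / (2 * h)
      ddt - (L(q + e, qd) - L(q - e, qd)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(tau_id - tau_or)) / max(abs(tau_id)), 1e-5)
    # ID -> FD round trip reproduces the acceleration
    qdd2 <- forward_dynamics_accel(skel, s, skel$mass0, q, qd, tau_id)
    expect_lt(max(abs(qdd2 - qdd)), 1e-8)
  }
})

test_that("semi-explicit integration conserves energy to 0.1 % over 1 s", {
  skel <- mk_pendulum()
  skel0 <- skeleton(
    list(list(name = "base", mass = 1, com = c(0, -0.1, 0),
              inertia = diag(1e-3, 3)),
         list(name = "rod", mass = 0.5, com = c(0, -0.25, 0),
              inertia = diag(c(0.01, 1e-3, 0.01)))),
    list(list(name = "root", type = "free6", parent = NA, child = "base"),
         list(name = "hinge", type = "revolute1", parent = "base",
              child = "rod", parent_offset = c(0, -0.2, 0),
              axes = list(c(0, 0, 1)))),
    list(list(label = "P1", segment = "base", offset = c(0.05, 0, 0),
              anatomical = TRUE)),
    gravity = c(0, 0, 0))
  s <- rep(1, 6)
  q0 <- c(0, 0, 0, 0.1, 0.2, 0.05, 0.4)
  qd0 <- c(0.1, -0.05, 0.2, 0.3, -0.2, 0.25, 1.5)
  E0 <- kinetic_energy(skel0, s, skel0$mass0, q0, qd0)
  out <- integrate_free(skel0, s, skel0$mass0, q0, qd0, dt = 1e-4,
                        n_steps = 10000)
  E1 <- kinetic_energy(skel0, s, skel0$mass0,
                       out$Q[10001, ], out$Qd[10001, ])
  expect_lt(abs(E1 - E0) / E0, 1e-3)
})

test_that("root_residual converts Euler-conjugate torques to world
           moments", {
  skel <- mk_chain()
  set.seed(18)
  q <- 0.3 * rnorm(skel$nq)
  s <- default_scales(skel)
  # a pure couple N applied to the base maps back to itself
  N <- c(2, -1, 3)
  ext <- matrix(0, 6, 4)
  ext[4:6, 1] <- N # moment about world origin with zero force = couple
  Qe <- drop(mocapfit:::cpp_ext_gen_forces(skel$compiled, s, q, ext))
  rr <- root_residual(skel, q, Qe)
  expect_equal(rr$torque, N, tolerance = 1e-10)
  expect_equal(rr$force, c(0, 0, 0), tolerance = 1e-12)
})
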