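test_that("minimum-jerk smoothing is exact on zero-jerk input and
           matches a dense normal-equation oracle", {
  T <- 50
  tgrid <- seq(0, 1, length.out = T)
  # linear trajectories have zero jerk: output identical
  Qlin <- cbind(2 + 3 * tgrid, -1 + 0.5 * tgrid)
  expect_lt(max(abs(smooth_min_jerk(Qlin, 0.01, 1) - Qlin)), 1e-10)
  # dense oracle: explicit third-difference matrix + solve
  set.seed(51)
  Q <- matrix(rnorm(T * 2), T)
  D <- diff(diag(T), differences = 3)
  for (w in c(0.1, 1, 10)) {
    or <- solve(crossprod(D) + w * diag(T), w * Q)
    expect_lt(max(abs(smooth_min_jerk(Q, 0.01, w) - or)), 1e-8)
  }
  # decreasing tracking weight decreases total squared jerk
  jerks <- vapply(c(10, 1, 0.1), function(w)
    mocapfit:::total_sq_jerk(smooth_min_jerk(Q, 0.01, w)), numeric(1))
  expect_true(all(diff(jerks) < 0))
})

test_that("COM system reproduces the semi-explicit integrator exactly", {
  # T = 1 degenerate case
  sys1 <- build_com_system(matrix(c(1, 2, 3), 1, 3), 0.01)
  expect_equal(sys1$A, cbind(diag(3), matrix(0, 3, 4)))
  expect_equal(sys1$b, rep(0, 3))
  set.seed(52)
  T <- 40; dt <- 0.01
  g <- c(0, -9.81, 0)
  f <- matrix(rnorm(T * 3, 0, 300), T)
  sys <- build_com_system(f, dt, g)
  # independent step-by-step integrator
  oracle <- function(zeta) {
    z <- zeta[1:3]; zd <- zeta[4:6]; mu <- zeta[7]
    Z <- matrix(0, T, 3); Z[1, ] <- z
    for (t in 1:(T - 1)) {
      zd <- zd + (mu * f[t, ] + g) * dt
      z <- z + zd * dt
      Z[t + 1, ] <- z
    }
    as.vector(t(Z))
  }
  for (rep in 1:5) {
    zeta <- c(rnorm(3), rnorm(3), 1 / runif(1, 50, 90))
    expect_lt(max(abs(sys$A %*% zeta + sys$b - oracle(zeta))), 1e-12)
  }
  # column-oracle identity: columns of A are sensitivities of the
  # integrated trajectory to the entries of zeta
  zeta0 <- c(0.1, 0.9, 0, 0.5, 0, -0.2, 1 / 70)
  for (k in 1:7) {
    e <- rep(0, 7); e[k] <- 1e-6
    col_fd <- (oracle(zeta0 + e) - oracle(zeta0 - e)) / 2e-6
    expect_lt(max(abs(sys$A[, k] - col_fd)), 1e-8)
  }
  # zero forces: the inverse-mass column vanishes
  sys0 <- build_com_system(matrix(0, T, 3), dt, g)
  expect_true(all(sys0$A[, 7] == 0))
})

test_that("com_linear_fit recovers self-consistent trajectories exactly
           and scales inversely with force", {
  set.seed(53)
  T <- 60; dt <- 0.01
  f <- matrix(rnorm(T * 3, 0, 200), T)
  f[, 2] <- f[, 2] + 700
  sys <- build_com_system(f, dt)
  zeta_true <- c(0.2, 0.95, -0.1, 0.4, 0.02, -0.3, 1 / 70)
  Zhat <- matrix(drop(sys$A %*% zeta_true + sys$b), T, 3, byrow = TRUE)
  cf <- com_linear_fit(Zhat, sys$A, sys$b)
  expect_lt(max(abs(cf$zeta - zeta_true)), 1e-9)
  expect_equal(cf$mass, 70, tolerance = 1e-9)
  # doubling all forces halves mu, doubling the recovered mass
  sys2 <- build_com_system(2 * f, dt)
  cf2 <- com_linear_fit(Zhat, sys2$A, sys2$b)
  expect_equal(cf2$mass, 140, tolerance = 1e-8)
  # zero forces: unidentifiable mass is an explicit error
  sys0 <- build_com_system(matrix(0, T, 3), dt)
  expect_error(com_linear_fit(Zhat, sys0$A, sys0$b), "unidentifiable")
  # 5 mm observation noise, T = 300: mass within 5 % over 20 draws
  T2 <- 300
  f2 <- matrix(rnorm(T2 * 3, 0, 150), T2); f2[, 2] <- f2[, 2] + 700
  sysn <- build_com_system(f2, dt)
  Zt <- matrix(drop(sysn$A %*% zeta_true + sysn$b), T2, 3, byrow = TRUE)
  masses <- vapply(1:20, function(i) {
    com_linear_fit(Zt + matrix(rnorm(T2 * 3, 0, 5e-3), T2),
                   sysn$A, sysn$b)$mass
  }, numeric(1))
  expect_lt(abs(mean(masses) - 70) / 70, 0.05)
})

test_that("apply_root_translation shifts the COM exactly", {
  skel <- cached_gait_skel()
  tr <- cached_gait_trial()
  truth <- tr$truth
  s <- truth$subject$s_true; m <- truth$subject$masses_true
  Q <- truth$Q[1:30, ]
  Zhat <- com_trajectory(skel, s, m, Q)
  # identity
  expect_equal(apply_root_translation(Q, Zhat, skel, s, m), Q)
  # constant offset shifts the root by exactly d
  d <- c(0.05, -0.02, 0.01)
  Q2 <- apply_root_translation(Q, sweep(Zhat, 2, d, "+"), skel, s, m)
  expect_equal(Q2[, 1:3], sweep(Q[, 1:3], 2, d, "+"), tolerance = 1e-12)
  expect_equal(Q2[, -(1:3)], Q[, -(1:3)])
  # random target: post-condition holds to 1e-9
  set.seed(54)
  Zt <- Zhat + matrix(rnorm(90, 0, 0.02), 30)
  Q3 <- apply_root_translation(Q, Zt, skel, s, m)
  expect_lt(max(abs(com_trajectory(skel, s, m, Q3) - Zt)), 1e-9)
})

test_that("build_root_system has the documented block structure and
           matches a linearized-integrator oracle", {
  skel <- cached_gait_skel()
  tr <- cached_gait_trial()
  truth <- tr$truth
  s <- truth$subject$s_true; m <- truth$subject$masses_true
  T <- 25; dt <- truth$dt
  Q <- truth$Q[1:T, ]
  ext <- mocapfit:::ext_cube(skel, lapply(truth$wrenches, function(w)
    w[1:T, ]), truth$foot_segments)
  sys <- build_root_system(skel, s, m, Q, ext, dt)
  # upper-left quadrant equals the COM system's first six columns;
  # upper-right quadrant is zero
  ftot <- t(vapply(1:T, function(t) rowSums(matrix(ext[1:3, , t], 3)),
                   numeric(3)))
  A_com <- build_com_system(ftot, dt, skel$gravity)$A
  expect_equal(sys$Atil[1:(3 * T), 1:6], A_com[, 1:6], tolerance = 1e-12)
  expect_true(all(sys$Atil[1:(3 * T), 7:12] == 0))
  # zero forces: the lower-left quadrant vanishes
  sys0 <- build_root_system(skel, s, m, Q, ext * 0, dt)
  expect_true(all(abs(sys0$Atil[3 * T + 1:(3 * T), 1:6]) < 1e-12))
  # linearized-integrator oracle: for random xi, Atil xi + btil equals
  # step-by-step integration of the stated linearized dynamics
  lin <- sys$lin
  mass <- sum(m)
  oracle <- function(xi) {
    z <- xi[1:3]; zd <- xi[4:6]; th <- xi[7:9]; thd <- xi[10:12]
    Z <- matrix(0, T, 3); TH <- matrix(0, T, 3)
    Z[1, ] <- z; TH[1, ] <- th
    for (t in 1:(T - 1)) {
      zdd <- ftot[t, ] / mass + skel$gravity
      thdd <- lin$thdd_ref[t, ] +
        drop(lin$K[, , t] %*% (Z[t, ] - sys$Z_ref[t, ]))
      zd <- zd + zdd * dt; z <- z + zd * dt
      thd <- thd + thdd * dt; th <- th + thd * dt
      Z[t + 1, ] <- z; TH[t + 1, ] <- th
    }
    c(as.vector(t(Z)), as.vector(t(TH)))
  }
  set.seed(55)
  for (rep in 1:5) {
    xi <- c(Q[1, 1:3] + 0.1 * rnorm(3), rnorm(3), 0.2 * rnorm(3),
            rnorm(3))
    expect_lt(max(abs(sys$Atil %*% xi + sys$btil - oracle(xi))), 1e-10)
  }
  # column-oracle identity on the linearized model
  xi0 <- c(Q[1, 1:3], rep(0.1, 3), Q[1, 4:6], rep(0, 3))
  for (k in 1:12) {
    e <- rep(0, 12); e[k] <- 1e-6
    col_fd <- (oracle(xi0 + e) - oracle(xi0 - e)) / 2e-6
    expect_lt(max(abs(sys$Atil[, k] - col_fd)), 1e-8)
  }
})

test_that("root_angular_fit converges quickly on consistent data and
           integrates pure initial conditions without applied moments", {
  skel <- cached_gait_skel()
  tr <- cached_gait_trial()
  truth <- tr$truth
  s <- truth$subject$s_true; m <- truth$subject$masses_true
  ext <- mocapfit:::ext_cube(skel, truth$wrenches, truth$foot_segments)
  raf <- root_angular_fit(skel, s, m, truth$Q, ext, truth$dt)
  expect_true(raf$converged)
  expect_lt(raf$iterations, 30)
  # the consistent trajectory is (nearly) a fixed point
  expect_lt(max(abs(raf$Q - truth$Q)), 5e-3)
  # torque-free spinning box with COM at the origin: Theta follows pure
  # initial-condition integration (no gravity moment, no load)
  fb <- mk_free_body(gravity = c(0, -9.81, 0))
  fb0 <- skeleton(
    list(list(name = "box", mass = 3, com = c(0, 0, 0),
              inertia = diag(c(0.03, 0.03, 0.03)))),
    list(list(name = "root", type = "free6", parent = NA, child = "box")),
    list(list(label = "A", segment = "box", offset = c(0.1, 0, 0),
              anatomical = TRUE)),
    gravity = c(0, -9.81, 0))
  T <- 30; dt <- 0.01
  Q0 <- matrix(0, T, 6)
  Q0[, 2] <- 1 - 0.5 * 9.81 * ((1:T - 1) * dt)^2 # free fall
  Q0[, 4] <- 0.3 + 0.5 * (1:T - 1) * dt          # constant spin rate
  ext0 <- array(0, c(6, 1, T))
  sys <- build_root_system(fb0, rep(1, 3), fb0$mass0, Q0, ext0, dt)
  xi <- c(Q0[1, 1:3], c(0, -9.81 * dt / 2, 0) * 0, Q0[1, 4:6],
          c(0.5, 0, 0))
  xi[4:6] <- c(0, 0, 0)
  Xi <- drop(sys$Atil %*% xi + sys$btil)
  TH <- matrix(Xi[3 * T + 1:(3 * T)], T, 3, byrow = TRUE)
  expect_equal(TH[, 1], 0.3 + 0.5 * (1:T - 1) * dt, tolerance = 1e-8)
})

test_that("final_dynamics_map is a near-fixed-point on consistent truth
           and recovers inflated masses", {
  skel <- cached_gait_skel()
  prior <- cached_gait_prior()
  tr <- cached_gait_trial()
  truth <- tr$truth
  s <- truth$subject$s_true; p <- truth$subject$p_true
  m <- truth$subject$masses_true
  ext <- mocapfit:::ext_cube(skel, truth$wrenches, truth$foot_segments)
  fin <- final_dynamics_map(skel, prior, tr$trial$markers, ext, s, p,
                            truth$Q, m, m_target = sum(m), dt = truth$dt,
                            max_outer = 3)
  expect_lt(max(abs(fin$masses - m) / m), 0.01)
  expect_lt(fin$normalized_force_pct, 0.01)
  expect_lt(fin$normalized_torque_pct, 0.01)
  expect_lte(fin$objective, fin$objective_init)
  # masses inflated 10 % while the loads match the true mass: the total
  # mass comes back within 2 % (the COM-fit target carries the truth)
  fin2 <- final_dynamics_map(skel, prior, tr$trial$markers, ext, s, p,
                             truth$Q, 1.1 * m, m_target = sum(m),
                             dt = truth$dt, max_outer = 3)
  expect_lt(abs(sum(fin2$masses) - sum(m)) / sum(m), 0.02)
})

test_that("increasing the residual penalty weight does not increase the
           final RMS residual", {
  skel <- cached_gait_skel()
  prior <- cached_gait_prior()
  tr <- cached_gait_trial()
  truth <- tr$truth
  ext <- mocapfit:::ext_cube(skel, truth$wrenches, truth$foot_segments)
  # start from a smoothly perturbed trajectory so there is residual to
  # remove (smooth, like a real kinematic-stage error, so the finite-
  # difference accelerations stay physical)
  set.seed(56)
  Q0 <- truth$Q
  tt <- seq_len(nrow(Q0)) / 100
  for (k in 1:6)
    Q0[, k] <- Q0[, k] + 0.004 * sin(2 * pi * runif(1, 0.5, 2) * tt +
                                       2 * pi * runif(1))
  rms <- vapply(c(4, 1, 0.25), function(sig) {
    fin <- final_dynamics_map(skel, prior, tr$trial$markers, ext,
                              truth$subject$s_true,
                              truth$subject$p_true, Q0,
                              truth$subject$masses_true,
                              m_target = sum(truth$subject$masses_true),
                              dt = truth$dt, sigma_force = sig,
                              sigma_torque = sig, max_outer = 20)
    sqrt(mean(fin$residual^2))
  }, numeric(1))
  expect_true(all(diff(rms) <= 1e-8))
})

test_that("residual_report normalizes and thresholds correctly", {
  # zero residual: 0 % and pass
  mkres <- function(force_series, torque_series, peak, comh) {
    structure(list(
      normalized_force_pct = 100 *
        sqrt(mean(rowSums(force_series^2))) / peak,
      normalized_torque_pct = 100 *
        sqrt(mean(rowSums(torque_series^2))) / (peak * comh)),
      class = "dynamics_fit")
  }
  z <- matrix(0, 10, 3)
  rep0 <- residual_report(mkres(z, z, 700, 0.95))
  expect_equal(rep0$force_pct, 0)
  expect_true(rep0$pass)
  # constant 14 N residual with 700 N peak -> 2.0 %
  cst <- matrix(rep(c(14, 0, 0), each = 10), 10)
  rep1 <- residual_report(mkres(cst, z, 700, 0.95))
  expect_equal(rep1$force_pct, 2, tolerance = 1e-12)
  # random series vs flat-loop oracle through the real pipeline path
  skel <- cached_gait_skel()
  tr <- cached_gait_trial()
  truth <- tr$truth
  T <- 20
  set.seed(57)
  rho <- matrix(rnorm(T * 6, 0, 2), T)
  ext <- mocapfit:::ext_cube(skel, lapply(truth$wrenches, function(w)
    w[1:T, ]), truth$foot_segments)
  nr <- mocapfit:::normalize_residuals(skel, truth$Q[1:T, ], rho, ext,
                                       truth$subject$s_true,
                                       truth$subject$masses_true)
  # oracle: loop over frames, convert, accumulate
  fs <- 0; ts <- 0
  for (t in 1:T) {
    rr <- root_residual(skel, truth$Q[t, ], rho[t, ])
    fs <- fs + sum(rr$force^2); ts <- ts + sum(rr$torque^2)
  }
  grf <- vapply(1:T, function(t)
    sqrt(sum(rowSums(matrix(ext[1:3, , t], 3))^2)), numeric(1))
  comh <- mean(com_trajectory(skel, truth$subject$s_true,
                              truth$subject$masses_true,
                              truth$Q[1:T, ])[, 2])
  expect_equal(nr$force_pct, 100 * sqrt(fs / T) / max(grf),
               tolerance = 1e-12)
  expect_equal(nr$torque_pct, 100 * sqrt(ts / T) / (max(grf) * comh),
               tolerance = 1e-12)
  # zero peak GRF: undefined normalization errors out
  expect_error(mocapfit:::normalize_residuals(skel, truth$Q[1:T, ], rho,
                                              ext * 0,
                                              truth$subject$s_true,
                                              truth$subject$masses_true),
               "zero peak")
})
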