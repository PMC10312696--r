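#' Minimum-jerk smoothing of joint trajectories
#'
#' Per-coordinate quadratic smoothing: minimize the sum of squared third
#' finite differences plus `tracking_weight` times the squared deviation
#' from the input, solved exactly by one sparse linear system per
#' coordinate. Lower tracking weights smooth harder. A trajectory that is
#' linear in time has zero jerk and passes through unchanged.
#'
#' @param Q T x nq pose trajectory.
#' @param dt sample interval (unused by the unit-free objective; kept for
#'   interface symmetry with the other trajectory operations).
#' @param tracking_weight weight of the data-tracking term (default 1).
#' @return smoothed T x nq matrix.
#' @export
smooth_min_jerk <- function(Q, dt = NULL, tracking_weight = 1) {
  T <- nrow(Q)
  if (T < 4) stop("need at least 4 frames to penalize jerk")
  D <- Matrix::bandSparse(T - 3, T,
                          k = 0:3,
                          diagonals = list(rep(-1, T - 3), rep(3, T - 3),
                                           rep(-3, T - 3), rep(1, T - 3)))
  H <- Matrix::crossprod(D) + tracking_weight *
    Matrix::Diagonal(T)
  as.matrix(Matrix::solve(H, tracking_weight * Q))
}

total_sq_jerk <- function(Q) {
  T <- nrow(Q)
  d3 <- Q[4:T, , drop = FALSE] - 3 * Q[3:(T - 1), , drop = FALSE] +
    3 * Q[2:(T - 2), , drop = FALSE] - Q[1:(T - 3), , drop = FALSE]
  sum(d3^2)
}

#' Linear system mapping COM initial conditions and inverse mass to the
#' COM trajectory
#'
#' Under semi-explicit Euler integration of `zdd = mu f + g` (`mu` the
#' inverse mass), the whole COM trajectory is affine in `zeta = (z1, zd1,
#' mu)`: `Z = A zeta + b`. Row block t is `[I, (t-1) dt I, dt^2
#' sum_{i<t}(t-i) f_i]`, with the matching gravity integral in `b`.
#'
#' @param forces T x 3 matrix of total ground reaction force per frame
#'   (N), synchronized at the marker rate.
#' @param dt integration step, s.
#' @param gravity gravity vector (m/s^2).
#' @return list with `A` (3T x 7) and `b` (3T).
#' @export
build_com_system <- function(forces, dt, gravity = c(0, -9.81, 0)) {
  T <- nrow(forces)
  if (T < 1) stop("empty force trajectory")
  A <- matrix(0, 3 * T, 7)
  b <- numeric(3 * T)
  I3 <- diag(3)
  # cumulative sums for sum_{i<t} (t - i) f_i = t * S1_{t-1} - S2_{t-1}
  cs_f <- apply(forces, 2, cumsum)                 # S1_t = sum_{i<=t} f_i
  cs_if <- apply(forces * seq_len(T), 2, cumsum)   # S2_t = sum i f_i
  for (t in seq_len(T)) {
    rows <- 3 * (t - 1) + 1:3
    A[rows, 1:3] <- I3
    A[rows, 4:6] <- (t - 1) * dt * I3
    if (t > 1) {
      fint <- t * cs_f[t - 1, ] - cs_if[t - 1, ]
      A[rows, 7] <- dt^2 * fint
      b[rows] <- dt^2 * (t * (t - 1) / 2) * gravity
    }
  }
  list(A = A, b = b)
}

# step-by-step semi-explicit integrator (reference/dual implementation)
integrate_com <- function(zeta, forces, dt, gravity = c(0, -9.81, 0)) {
  T <- nrow(forces)
  z <- zeta[1:3]; zd <- zeta[4:6]; mu <- zeta[7]
  Z <- matrix(0, T, 3)
  Z[1, ] <- z
  for (t in seq_len(T - 1)) {
    zd <- zd + (mu * forces[t, ] + gravity) * dt
    z <- z + zd * dt
    Z[t + 1, ] <- z
  }
  Z
}

pinv_solve <- function(A, y, rcond = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > rcond * sv$d[1]
  sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep])
}

#' Least-squares fit of COM initial conditions and total mass
#'
#' Minimum-norm pseudo-inverse solution `zeta = A^+ (Zhat - b)`; exact on
#' COM trajectories generated by the same integrator. The recovered mass
#' is `1/mu`.
#'
#' @param Zhat T x 3 observed COM trajectory (from the kinematic fit).
#' @param A,b system from [build_com_system()].
#' @return list with `zeta`, `mass`, `Z` (fitted trajectory), and
#'   `lsq_residual` (RMS m).
#' @export
com_linear_fit <- function(Zhat, A, b) {
  if (all(A[, 7] == 0))
    stop("all ground reaction forces are zero: total mass is ",
         "unidentifiable (the inverse-mass column of A vanishes)")
  y <- as.vector(t(Zhat)) - b
  zeta <- drop(pinv_solve(A, y))
  mu <- zeta[7]
  if (!is.finite(mu) || mu <= 0)
    warning("non-physical inverse mass (mu <= 0) from the COM fit")
  Zfit <- matrix(drop(A %*% zeta + b), ncol = 3, byrow = TRUE)
  list(zeta = zeta, mass = 1 / mu, Z = Zfit,
       lsq_residual = sqrt(mean((Zfit - Zhat)^2)))
}

#' Shift the root translation so the model COM follows a target trajectory
#'
#' Adds `Z_t - Zhat_t` to the root translational coordinates per frame,
#' leaving all other coordinates untouched; because the COM is rigidly
#' carried by the root translation, the updated model COM equals `Z`
#' exactly.
#'
#' @param Q T x nq pose trajectory.
#' @param Z T x 3 target COM trajectory.
#' @param skel,s,masses model for computing the current COM.
#' @return updated Q.
#' @export
apply_root_translation <- function(Q, Z, skel, s, masses = skel$mass0) {
  Zhat <- com_trajectory(skel, s, masses, Q)
  Q[, 1:3] <- Q[, 1:3] + (Z - Zhat)
  Q
}

skew <- function(v) matrix(c(0, v[3], -v[2], -v[3], 0, v[1],
                             v[2], -v[1], 0), 3, 3)

# per-frame linearization data for the root angular system
root_lin_data <- function(skel, s, masses, Q, ext, dt) {
  T <- nrow(Q)
  der <- fd_derivatives(Q, dt)
  Tau <- cpp_id_traj(skel$compiled, s, masses, Q, der$qd, der$qdd, ext)
  K <- array(0, c(3, 3, T))
  thdd_ref <- matrix(0, T, 3)
  for (t in seq_len(T)) {
    Mq <- cpp_mass_matrix(skel$compiled, s, masses, Q[t, ])
    Mtt <- Mq[4:6, 4:6]
    E <- root_euler_axes(skel, Q[t, ])
    ftot <- rowSums(matrix(ext[1:3, , t], 3))
    # sensitivity of root-rotation acceleration to a rigid COM shift dz:
    # the COP stays fixed in the world, so the generalized rotational
    # force changes by E' (f x dz) = E' skew(f) dz
    K[, , t] <- solve(Mtt, t(E) %*% skew(ftot))
    thdd_ref[t, ] <- der$qdd[t, 4:6] - solve(Mtt, Tau[t, 4:6])
  }
  list(K = K, thdd_ref = thdd_ref, tau = Tau, der = der)
}

#' Linearized root-dynamics system
#'
#' Builds the 6T x 12 map from the root initial conditions `xi = (z1,
#' zd1, theta1, thetad1)` to the stacked trajectory `Xi = (Z, Theta)` of
#' COM positions and root rotational coordinates, linearizing the coupling
#' of the ground-reaction moments to a rigid COM shift (the mass matrix
#' and Coriolis terms are frozen at the current trajectory estimate). The
#' upper-left quadrant coincides with the first six columns of the COM
#' system; the upper-right quadrant is zero because the COM trajectory
#' does not depend on the root orientation initial conditions.
#'
#' @param skel,s,masses model.
#' @param Q current T x nq trajectory (linearization point).
#' @param ext 6 x n_segments x T external wrench cube (world origin
#'   moments), with centres of pressure fixed from the force data.
#' @param dt step, s.
#' @param mass total mass used for the COM rows (default `sum(masses)`).
#' @return list with `Atil` (6T x 12), `btil` (6T), and the reference
#'   trajectories `Z_ref`, `Theta_ref`.
#' @export
build_root_system <- function(skel, s, masses, Q, ext, dt,
                              mass = sum(masses)) {
  T <- nrow(Q)
  lin <- root_lin_data(skel, s, masses, Q, ext, dt)
  ftot <- t(apply(ext, 3, function(e) rowSums(matrix(e[1:3, ], 3))))
  if (T == 1) ftot <- matrix(ftot, 1, 3)
  grav <- skel$gravity
  Z_ref <- com_trajectory(skel, s, masses, Q)
  Theta_ref <- Q[, 4:6, drop = FALSE]

  Atil <- matrix(0, 6 * T, 12)
  btil <- numeric(6 * T)
  I3 <- diag(3)
  # --- COM rows (same structure as build_com_system, mass fixed) ---
  acc <- sweep(ftot / mass, 2, grav, "+")  # per-frame zdd
  cs_a <- apply(acc, 2, cumsum)
  cs_ia <- apply(acc * seq_len(T), 2, cumsum)
  for (t in seq_len(T)) {
    rows <- 3 * (t - 1) + 1:3
    Atil[rows, 1:3] <- I3
    Atil[rows, 4:6] <- (t - 1) * dt * I3
    if (t > 1)
      btil[rows] <- dt^2 * (t * cs_a[t - 1, ] - cs_ia[t - 1, ])
  }
  # --- rotation rows ---
  # theta_t = theta1 + (t-1) dt thetad1
  #           + dt^2 sum_{i<t} (t-i) [thdd_ref_i + K_i (z_i - z_ref_i)]
  # with z_i = z1 + (i-1) dt zd1 + btil_z,i
  off <- 3 * T
  A1 <- matrix(0, 3, 3); A2 <- matrix(0, 3, 3) # sums of K_i, i*K_i
  A3 <- matrix(0, 3, 3); A4 <- matrix(0, 3, 3) # sums of (i-1)K_i, i(i-1)K_i
  bv1 <- numeric(3); bv2 <- numeric(3)         # sums of c_i, i*c_i
  for (t in seq_len(T)) {
    rows <- off + 3 * (t - 1) + 1:3
    Atil[rows, 7:9] <- I3
    Atil[rows, 10:12] <- (t - 1) * dt * I3
    if (t > 1) {
      Atil[rows, 1:3] <- dt^2 * (t * A1 - A2)
      Atil[rows, 4:6] <- dt^3 * (t * A3 - A4)
      btil[rows] <- dt^2 * (t * bv1 - bv2)
    }
    Kt <- lin$K[, , t]
    zrows <- 3 * (t - 1) + 1:3
    ct <- lin$thdd_ref[t, ] + Kt %*% (btil[zrows] - Z_ref[t, ])
    A1 <- A1 + Kt;            A2 <- A2 + t * Kt
    A3 <- A3 + (t - 1) * Kt;  A4 <- A4 + t * (t - 1) * Kt
    bv1 <- bv1 + drop(ct);    bv2 <- bv2 + t * drop(ct)
  }
  list(Atil = Atil, btil = btil, Z_ref = Z_ref, Theta_ref = Theta_ref,
       lin = lin)
}

#' Iterative root angular/COM fit
#'
#' Alternates solving `xi = Atil^+ (Xihat - btil)` with rebuilding the
#' linearized system at the updated trajectory until the stacked
#' trajectory `Xi` converges in max-norm. The observed `Xihat` (COM and
#' root rotations of the kinematic solution) stays fixed throughout; the
#' fitted `Xi` is written back into the root coordinates of `Q`.
#'
#' @inheritParams build_root_system
#' @param tol convergence tolerance on `max |delta Xi|` (m, rad).
#' @param max_iter outer iteration cap.
#' @return list with `Q` (updated trajectory), `xi`, `Xi`, `iterations`,
#'   `converged`.
#' @export
root_angular_fit <- function(skel, s, masses, Q, ext, dt,
                             mass = sum(masses), tol = 1e-6,
                             max_iter = 100) {
  T <- nrow(Q)
  Zhat <- com_trajectory(skel, s, masses, Q)
  Xihat <- c(as.vector(t(Zhat)), as.vector(t(Q[, 4:6, drop = FALSE])))
  Qc <- Q
  Xi_prev <- NULL
  iterations <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iterations <- it
    sys <- build_root_system(skel, s, masses, Qc, ext, dt, mass)
    xi <- drop(pinv_solve(sys$Atil, Xihat - sys$btil))
    Xi <- drop(sys$Atil %*% xi + sys$btil)
    Znew <- matrix(Xi[seq_len(3 * T)], T, 3, byrow = TRUE)
    Thnew <- matrix(Xi[-seq_len(3 * T)], T, 3, byrow = TRUE)
    Qc[, 4:6] <- Thnew
    Qc <- apply_root_translation(Qc, Znew, skel, s, masses)
    if (!is.null(Xi_prev) && max(abs(Xi - Xi_prev)) <= tol) {
      converged <- TRUE
      break
    }
    Xi_prev <- Xi
  }
  list(Q = Qc, xi = xi, Xi = Xi, iterations = iterations,
       converged = converged)
}

# ---- final residual-minimizing optimization ------------------------------

# residual wrench (root 6 rows of ID) over the trajectory
residual_trajectory <- function(skel, s, masses, Q, ext, dt) {
  der <- fd_derivatives(Q, dt)
  Tau <- cpp_id_traj(skel$compiled, s, masses, Q, der$qd, der$qdd, ext)
  Tau[, 1:6, drop = FALSE]
}

# per-segment-mass basis of the residual: rho_t = B_t m - qext_t
residual_mass_basis <- function(skel, s, Q, ext, dt) {
  der <- fd_derivatives(Q, dt)
  ns <- n_segments(skel)
  T <- nrow(Q)
  zero_ext <- array(0, c(6, ns, T))
  B <- array(0, c(T, 6, ns))
  for (b in seq_len(ns)) {
    m1 <- rep(1e-9, ns) # numerically zero but keeps solvers happy
    m1[b] <- 1
    Tau <- cpp_id_traj(skel$compiled, s, m1, Q, der$qd, der$qdd, zero_ext)
    B[, , b] <- Tau[, 1:6]
  }
  qext <- matrix(0, T, 6)
  for (t in seq_len(T))
    qext[t, ] <- cpp_ext_gen_forces(skel$compiled, s, Q[t, ],
                                    ext[, , t])[1:6]
  list(B = B, qext = qext)
}

solve_masses <- function(skel, s, Q, ext, dt, m_target, m_cur,
                         sigma_f = 1, w_total = 1e4, w_reg = 1) {
  mb <- residual_mass_basis(skel, s, Q, ext, dt)
  ns <- n_segments(skel)
  T <- nrow(Q)
  A <- matrix(0, 6 * T, ns)
  for (b in seq_len(ns)) A[, b] <- as.vector(t(mb$B[, , b]))
  y <- as.vector(t(mb$qext))
  A <- A / sigma_f; y <- y / sigma_f
  A <- rbind(A, sqrt(w_total) * matrix(1, 1, ns),
             sqrt(w_reg) * diag(ns))
  y <- c(y, sqrt(w_total) * m_target, sqrt(w_reg) * m_cur)
  m <- drop(solve(crossprod(A), crossprod(A, y)))
  # positivity floor; the w_total row keeps the total near the linear
  # COM-fit estimate
  pmax(m, 0.2 * m_cur)
}

# full final-map objective
final_objective <- function(skel, prior, mo, s, p, Q, ext, dt, masses,
                            w, sigma_f, sigma_t, m_target, w_total) {
  rho <- residual_trajectory(skel, s, masses, Q, ext, dt)
  res_term <- 0.5 * sum(sweep(rho, 2, c(rep(sigma_f, 3),
                                        rep(sigma_t, 3)), "/")^2)
  map_objective(skel, prior, mo, s, p, Q, w) + res_term +
    0.5 * w_total * (sum(masses) - m_target)^2
}

#' Final dynamics optimization: masses, scales, registrations, kinematics
#'
#' Jointly tunes segment masses, scales, marker offsets and the root
#' trajectory to minimize marker error plus a Gaussian penalty on the
#' residual root wrench, starting from the physically consistent
#' initialization of [root_angular_fit()]. The inner-IK stationarity
#' constraint of the kinematic stage is dropped: kinematics may deviate
#' slightly from the marker-optimal solution to reach dynamic
#' consistency. Because the residual wrench lives entirely in the root
#' free-joint subspace, the kinematic tuning is confined to the six root
#' coordinates per frame (non-root joint angles keep their
#' marker-optimal values); masses enter the residual linearly and are
#' re-solved in closed form, with the total mass held near the linear
#' COM-fit estimate.
#'
#' @param skel a [skeleton()].
#' @param prior a [scaling_prior()].
#' @param traj marker observations.
#' @param ext external wrench cube (6 x ns x T) from
#'   [assign_forces_to_feet()] wrenches.
#' @param s,p,Q initialization from the kinematic + root fitting stages.
#' @param masses0 initial segment masses.
#' @param m_target total-mass estimate from [com_linear_fit()].
#' @param dt step, s.
#' @param weights marker/prior noise model ([map_weights()]).
#' @param sigma_force,sigma_torque residual penalty SDs (N, N m).
#' @param max_outer outer block iterations.
#' @param verbose print objective values.
#' @return object of class `dynamics_fit`: tuned `s`, `p`, `Q`, `masses`,
#'   residual series and normalized metrics, marker errors, torques.
#' @export
final_dynamics_map <- function(skel, prior, traj, ext, s, p, Q, masses0,
                               m_target = sum(masses0), dt,
                               weights = map_weights(),
                               sigma_force = 1, sigma_torque = 1,
                               max_outer = 6, verbose = FALSE) {
  mo <- traj_to_model_order(skel, traj)
  T <- nrow(Q)
  w <- weights
  masses <- masses0
  w_total <- 1e4
  obj <- function(s_, p_, Q_, m_) {
    final_objective(skel, prior, mo, s_, p_, Q_, ext, dt, m_, w,
                    sigma_force, sigma_torque, m_target, w_total)
  }
  f <- obj(s, p, Q, masses)
  f_init <- f
  hist <- f
  nsd <- skel$scale_dim
  M <- length(skel$marker_labels)
  lambda <- 1e-4
  for (outer in seq_len(max_outer)) {
    # --- masses: linear in the residual, solved in closed form ---
    m_new <- solve_masses(skel, s, Q, ext, dt, m_target, masses,
                          sigma_f = sigma_force)
    fn <- obj(s, p, Q, m_new)
    if (is.finite(fn) && fn <= f) {
      masses <- m_new; f <- fn
    }
    # --- root trajectory + scales + offsets: damped Gauss-Newton ---
    gn <- final_root_scale_step(skel, prior, mo, s, p, Q, ext, dt,
                                masses, w, sigma_force, sigma_torque,
                                lambda, obj, f)
    s <- gn$s; p <- gn$p; Q <- gn$Q; f <- gn$f; lambda <- gn$lambda
    hist <- c(hist, f)
    if (verbose) message("final map outer ", outer, ": ", signif(f, 8))
    if (length(hist) > 2 &&
        (hist[length(hist) - 1] - f) < 1e-6 * (1 + f)) break
  }
  rho <- residual_trajectory(skel, s, masses, Q, ext, dt)
  res <- normalize_residuals(skel, Q, rho, ext, s, masses)
  rep <- marker_error_report(skel, s, p, Q, traj)
  der <- fd_derivatives(Q, dt)
  Tau <- cpp_id_traj(skel$compiled, s, masses, Q, der$qd, der$qdd, ext)
  colnames(Tau) <- skel$dof_names
  structure(list(s = s, p = p, Q = Q, masses = masses, dt = dt,
                 residual = rho,
                 residual_force = res$force_series,
                 residual_torque = res$torque_series,
                 normalized_force_pct = res$force_pct,
                 normalized_torque_pct = res$torque_pct,
                 peak_grf = res$peak_grf, com_height = res$com_height,
                 marker_rmse = rep$rmse, marker_max = rep$max,
                 torques = Tau, objective = f, objective_init = f_init,
                 objective_history = hist, report = rep),
            class = "dynamics_fit")
}

#' @export
print.dynamics_fit <- function(x, ...) {
  cat("dynamics_fit:", nrow(x$Q), "frames | total mass",
      signif(sum(x$masses), 4), "kg | residual force",
      signif(x$normalized_force_pct, 3), "% | residual torque",
      signif(x$normalized_torque_pct, 3), "% | marker RMSE",
      signif(x$marker_rmse * 100, 3), "cm\n")
  invisible(x)
}

# one damped GN step over x = (droot (6T), ds, dp); comb finite
# differences give the dynamics Jacobian w.r.t. the root coordinates
# (the residual at frame t only sees frames t-1..t+1 through the
# finite-difference accelerations), one-sided FD for s; the marker terms
# use analytic Jacobians and are the only rows touching p. The normal
# equations are small enough (6T + 27 + 3M) to solve densely.
final_root_scale_step <- function(skel, prior, mo, s, p, Q, ext, dt,
                                  masses, w, sigma_f, sigma_t, lambda,
                                  obj, f_cur) {
  T <- nrow(Q)
  nsd <- skel$scale_dim
  M <- length(skel$marker_labels)
  nx <- 6 * T + nsd + 3 * M
  is_ <- 6 * T + seq_len(nsd)       # s columns
  ip_ <- function(i) 6 * T + nsd + 3 * (i - 1) + 1:3
  wres <- c(rep(sigma_f, 3), rep(sigma_t, 3))
  rho0 <- sweep(residual_trajectory(skel, s, masses, Q, ext, dt), 2,
                wres, "/")
  # dynamics Jacobian wrt root coords via comb perturbations
  hq <- 1e-6
  Jdyn_root <- array(0, c(T, 6, 3, 6)) # frame, res comp, rel offset, dof
  for (k in 1:6) {
    for (ph in 0:3) {
      idx <- seq(1 + ph, T, by = 4)
      Qp <- Q
      Qp[idx, k] <- Qp[idx, k] + hq
      rhop <- sweep(residual_trajectory(skel, s, masses, Qp, ext, dt), 2,
                    wres, "/")
      dr <- (rhop - rho0) / hq
      for (t in idx) {
        for (rel in -1:1) {
          tt <- t + rel
          if (tt >= 1 && tt <= T)
            Jdyn_root[tt, , rel + 2, k] <- dr[tt, ]
        }
      }
    }
  }
  # dynamics Jacobian wrt s (one-sided FD)
  hs <- 1e-6
  Jdyn_s <- array(0, c(T, 6, nsd))
  for (j in seq_len(nsd)) {
    sp <- s; sp[j] <- sp[j] + hs
    rhop <- sweep(residual_trajectory(skel, sp, masses, Q, ext, dt), 2,
                  wres, "/")
    Jdyn_s[, , j] <- (rhop - rho0) / hs
  }
  H <- matrix(0, nx, nx)
  g <- numeric(nx)
  for (t in seq_len(T)) {
    # dynamics rows of frame t: root cols at t-1..t+1 plus s
    rel_ok <- (t + (-1:1)) >= 1 & (t + (-1:1)) <= T
    cols <- c(unlist(lapply(which(rel_ok), function(r)
      6 * (t + r - 3) + 1:6)), is_)
    # column block for the root at frame t+d holds the sensitivity of
    # residual row t, which the comb stored in slot (t - (t+d)) + 2
    Jt <- cbind(do.call(cbind, lapply(which(rel_ok), function(r)
      Jdyn_root[t, , 4 - r, ])), Jdyn_s[t, , ])
    H[cols, cols] <- H[cols, cols] + crossprod(Jt)
    g[cols] <- g[cols] + crossprod(Jt, rho0[t, ])
  }
  sig_p <- ifelse(skel$anatomical, w$sigma_p_anat, w$sigma_p_track)
  for (t in seq_len(T)) {
    mj <- cpp_marker_jac(skel$compiled, s, Q[t, ], p)
    pres <- which(mo$present[t, ])
    if (!length(pres)) next
    idx <- as.vector(vapply(pres, function(i) as.integer(3 * i - 2:0), integer(3)))
    idx <- sort(idx)
    r <- (as.vector(t(mj$x)) - as.vector(t(mo$xobs[t, , ])))[idx] /
      w$sigma_marker
    cols <- c(6 * (t - 1) + 1:6, is_,
              unlist(lapply(pres, ip_)))
    Jm <- matrix(0, length(idx), length(cols))
    Jm[, 1:6] <- mj$Jq[idx, 1:6, drop = FALSE] / w$sigma_marker
    Jm[, 6 + seq_len(nsd)] <- mj$Js[idx, , drop = FALSE] / w$sigma_marker
    for (k in seq_along(pres)) {
      i <- pres[k]
      b <- skel$marker_seg[i] + 1L
      Jm[3 * k - 2:0, 6 + nsd + 3 * (k - 1) + 1:3] <-
        mj$R[, , i] %*% diag(s[(3 * b - 2):(3 * b)]) / w$sigma_marker
    }
    H[cols, cols] <- H[cols, cols] + crossprod(Jm)
    g[cols] <- g[cols] + crossprod(Jm, r)
  }
  # priors on s and p
  Sinv <- solve(prior$cov)
  H[is_, is_] <- H[is_, is_] + Sinv
  g[is_] <- g[is_] + drop(Sinv %*% (s - prior$mean))
  dp_pr <- sweep(p - skel$pbar, 2, sig_p, "/")
  for (i in seq_len(M)) {
    H[ip_(i), ip_(i)] <- H[ip_(i), ip_(i)] + diag(1 / sig_p[i]^2, 3)
    g[ip_(i)] <- g[ip_(i)] + dp_pr[, i] / sig_p[i]
  }
  f <- f_cur
  dH <- diag(H)
  for (k in 1:10) {
    step <- tryCatch(
      solve(H + lambda * diag(dH + 1e-8, nx), -g),
      error = function(e) NULL)
    if (!is.null(step)) {
      Qn <- Q
      Qn[, 1:6] <- Qn[, 1:6] + matrix(step[seq_len(6 * T)], T, 6,
                                      byrow = TRUE)
      sn <- s + step[is_]
      pn <- p + matrix(step[-seq_len(6 * T + nsd)], 3, M)
      fn <- tryCatch(obj(sn, pn, Qn, masses), error = function(e) Inf)
      if (is.finite(fn) && fn <= f) {
        return(list(s = sn, p = pn, Q = Qn, f = fn,
                    lambda = max(lambda / 5, 1e-8)))
      }
    }
    lambda <- lambda * 10
  }
  list(s = s, p = p, Q = Q, f = f, lambda = lambda)
}

normalize_residuals <- function(skel, Q, rho, ext, s, masses) {
  T <- nrow(Q)
  force_series <- matrix(0, T, 3)
  torque_series <- matrix(0, T, 3)
  for (t in seq_len(T)) {
    rr <- root_residual(skel, Q[t, ], rho[t, ])
    force_series[t, ] <- rr$force
    torque_series[t, ] <- rr$torque
  }
  grf_mag <- apply(ext, 3, function(e) sqrt(sum(rowSums(matrix(e[1:3, ],
                                                               3))^2)))
  peak <- max(grf_mag)
  if (peak <= 0) stop("zero peak ground reaction force: residual ",
                      "normalization undefined")
  comh <- mean(com_trajectory(skel, s, masses, Q)[, 2])
  list(force_series = force_series, torque_series = torque_series,
       force_pct = 100 * sqrt(mean(rowSums(force_series^2))) / peak,
       torque_pct = 100 * sqrt(mean(rowSums(torque_series^2))) /
         (peak * comh),
       peak_grf = peak, com_height = comh)
}

#' Residual pass/fail report
#'
#' RMS residual force as a percentage of the peak total ground reaction
#' force, and RMS residual torque as a percentage of (peak GRF x mean COM
#' height), compared against configurable thresholds in the spirit of the
#' standard simulation-credibility recommendations.
#'
#' @param result a `dynamics_fit`.
#' @param thresholds list with `force_pct` and `torque_pct` (defaults 5
#'   and 1).
#' @return list with the two normalized metrics, the thresholds, per-
#'   metric pass flags and overall `pass`.
#' @export
residual_report <- function(result,
                            thresholds = list(force_pct = 5,
                                              torque_pct = 1)) {
  fp <- result$normalized_force_pct
  tp <- result$normalized_torque_pct
  list(force_pct = fp, torque_pct = tp, thresholds = thresholds,
       force_pass = fp <= thresholds$force_pct,
       torque_pass = tp <= thresholds$torque_pct,
       pass = fp <= thresholds$force_pct && tp <= thresholds$torque_pct)
}
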