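#' @title Synthetic ground-truth gait trials
#' @description
#' Every optimization stage in the package is validated against trials
#' whose answers are known: a subject sampled from the scaling prior, a
#' smooth gait-like motion, markers synthesized by forward kinematics
#' (with optional noise and occlusion), and ground reaction forces
#' constructed by inverse dynamics so the root residual wrench is zero at
#' every frame by construction.
#' @name synthetic_data
NULL

box_inertia <- function(m, d) {
  diag(m / 12 * c(d[2]^2 + d[3]^2, d[1]^2 + d[3]^2, d[1]^2 + d[2]^2))
}
cyl_inertia_y <- function(m, r, l) {
  diag(c(m * (3 * r^2 + l^2) / 12, m * r^2 / 2,
         m * (3 * r^2 + l^2) / 12))
}

#' Nine-segment legged skeleton for gait
#'
#' Pelvis (root, 6-DOF free joint), torso and head, and two
#' thigh/shank/foot chains: 23 DOF in total (ball hips and lumbar,
#' revolute knees, universal ankles and neck). Dimensions, masses and
#' inertias approximate a 1.77 m, 75 kg adult with box/cylinder segment
#' geometry; a 38-marker set mixes anatomical and tracking markers with
#' at least three markers per segment. World frame: x forward, y up,
#' z right.
#'
#' @return a [skeleton()].
#' @export
skeleton_gait9 <- function() {
  segs <- list(
    list(name = "pelvis", mass = 10.6, com = c(0, 0.02, 0),
         inertia = box_inertia(10.6, c(0.20, 0.15, 0.28))),
    list(name = "torso", mass = 26.6, com = c(0, 0.22, 0),
         inertia = box_inertia(26.6, c(0.25, 0.50, 0.30))),
    list(name = "head", mass = 6.1, com = c(0, 0.12, 0),
         inertia = diag(0.4 * 6.1 * 0.11^2, 3)),
    list(name = "thigh_r", mass = 10.0, com = c(0, -0.18, 0),
         inertia = cyl_inertia_y(10.0, 0.07, 0.42)),
    list(name = "shank_r", mass = 3.25, com = c(0, -0.19, 0),
         inertia = cyl_inertia_y(3.25, 0.045, 0.43)),
    list(name = "foot_r", mass = 1.0, com = c(0.06, -0.05, 0),
         inertia = box_inertia(1.0, c(0.22, 0.08, 0.10))),
    list(name = "thigh_l", mass = 10.0, com = c(0, -0.18, 0),
         inertia = cyl_inertia_y(10.0, 0.07, 0.42)),
    list(name = "shank_l", mass = 3.25, com = c(0, -0.19, 0),
         inertia = cyl_inertia_y(3.25, 0.045, 0.43)),
    list(name = "foot_l", mass = 1.0, com = c(0.06, -0.05, 0),
         inertia = box_inertia(1.0, c(0.22, 0.08, 0.10))))
  jts <- list(
    list(name = "ground_pelvis", type = "free6", parent = NA,
         child = "pelvis"),
    list(name = "lumbar", type = "ball3", parent = "pelvis",
         child = "torso", parent_offset = c(0, 0.10, 0)),
    list(name = "neck", type = "universal2", parent = "torso",
         child = "head", parent_offset = c(0, 0.45, 0),
         axes = list(c(0, 0, 1), c(1, 0, 0))),
    list(name = "hip_r", type = "ball3", parent = "pelvis",
         child = "thigh_r", parent_offset = c(0, -0.07, 0.09)),
    list(name = "knee_r", type = "revolute1", parent = "thigh_r",
         child = "shank_r", parent_offset = c(0, -0.42, 0),
         axes = list(c(0, 0, 1))),
    list(name = "ankle_r", type = "universal2", parent = "shank_r",
         child = "foot_r", parent_offset = c(0, -0.43, 0),
         axes = list(c(0, 0, 1), c(1, 0, 0))),
    list(name = "hip_l", type = "ball3", parent = "pelvis",
         child = "thigh_l", parent_offset = c(0, -0.07, -0.09)),
    list(name = "knee_l", type = "revolute1", parent = "thigh_l",
         child = "shank_l", parent_offset = c(0, -0.42, 0),
         axes = list(c(0, 0, 1))),
    list(name = "ankle_l", type = "universal2", parent = "shank_l",
         child = "foot_l", parent_offset = c(0, -0.43, 0),
         axes = list(c(0, 0, 1), c(1, 0, 0))))
  mk <- function(label, seg, off, anat = FALSE)
    list(label = label, segment = seg, offset = off, anatomical = anat)
  mirror <- function(m, lab) {
    m$label <- lab; m$offset[3] <- -m$offset[3]
    m$segment <- sub("_r$", "_l", m$segment)
    m
  }
  right <- list(
    mk("RTHI", "thigh_r", c(0.03, -0.20, 0.06)),
    mk("RTH2", "thigh_r", c(-0.02, -0.30, 0.05)),
    mk("RKNE", "thigh_r", c(0.00, -0.42, 0.06), TRUE),
    mk("RMKN", "thigh_r", c(0.00, -0.42, -0.05), TRUE),
    mk("RTIB", "shank_r", c(0.02, -0.15, 0.05)),
    mk("RTB2", "shank_r", c(-0.02, -0.28, 0.04)),
    mk("RANK", "shank_r", c(0.00, -0.43, 0.04), TRUE),
    mk("RMMA", "shank_r", c(0.00, -0.42, -0.04), TRUE),
    mk("RHEE", "foot_r", c(-0.06, -0.02, 0.00), TRUE),
    mk("RTOE", "foot_r", c(0.17, -0.055, -0.01), TRUE),
    mk("RMT5", "foot_r", c(0.08, -0.05, 0.055), TRUE),
    mk("RMT1", "foot_r", c(0.08, -0.05, -0.035), TRUE))
  left <- mapply(mirror, right,
                 c("LTHI", "LTH2", "LKNE", "LMKN", "LTIB", "LTB2",
                   "LANK", "LMMA", "LHEE", "LTOE", "LMT5", "LMT1"),
                 SIMPLIFY = FALSE)
  mks <- c(list(
    mk("RASI", "pelvis", c(0.08, 0.02, 0.12), TRUE),
    mk("LASI", "pelvis", c(0.08, 0.02, -0.12), TRUE),
    mk("RPSI", "pelvis", c(-0.10, 0.03, 0.05), TRUE),
    mk("LPSI", "pelvis", c(-0.10, 0.03, -0.05), TRUE),
    mk("STRN", "torso", c(0.09, 0.30, 0.00), TRUE),
    mk("C7", "torso", c(-0.07, 0.42, 0.00), TRUE),
    mk("RSHO", "torso", c(0.00, 0.43, 0.18), TRUE),
    mk("LSHO", "torso", c(0.00, 0.43, -0.18), TRUE),
    mk("T10", "torso", c(-0.08, 0.20, 0.00)),
    mk("CLAV", "torso", c(0.08, 0.40, 0.00)),
    mk("RFHD", "head", c(0.08, 0.12, 0.05), TRUE),
    mk("LFHD", "head", c(0.08, 0.12, -0.05), TRUE),
    mk("RBHD", "head", c(-0.09, 0.10, 0.05)),
    mk("LBHD", "head", c(-0.09, 0.10, -0.05))),
    right, left)
  skeleton(segs, jts, mks)
}

# linear functionals mapping the gait9 scale vector to standing height
# and total mass (used by the synthetic prior's covariate block)
gait9_height_map <- function(skel) {
  a <- numeric(skel$scale_dim)
  put <- function(seg, coef) {
    i <- match(seg, skel$seg_names)
    a[3 * i - 1] <<- a[3 * i - 1] + coef # y component
  }
  put("foot_r", 0.04); put("foot_l", 0.04)
  put("shank_r", 0.215); put("shank_l", 0.215)
  put("thigh_r", 0.21); put("thigh_l", 0.21)
  put("pelvis", 0.17); put("torso", 0.45); put("head", 0.22)
  list(a = a, h0 = 1.77 - sum(a)) # affine part so a's + h0 = 1.77 at s = 1
}

gait9_weight_map <- function(skel) {
  frac <- skel$mass0 / sum(skel$mass0)
  b <- rep(frac / 3, each = 3) * sum(skel$mass0)
  list(b = b, w0 = sum(skel$mass0) - sum(b))
}

#' Synthetic anthropometric scaling prior
#'
#' Stand-in for a prior fit to a real anthropometric survey (which cannot
#' be redistributed): a factor-structured Gaussian over the per-axis
#' scales with a shared stature factor, a per-segment factor shared
#' across axes and bilateral pairs, and independent per-axis noise,
#' giving realistic positive correlations (bilateral symmetry,
#' covariation with overall size). A joint covariate block over
#' (s, height, weight) is built from linearized height/mass functionals
#' of the scale vector, enabling conditioning on subject metadata.
#'
#' @param skel the [skeleton_gait9()] (or compatible) skeleton.
#' @param sd marginal SD of each scale component (default 0.05).
#' @return a [scaling_prior()] with covariate block `"any"`.
#' @export
synthetic_scaling_prior <- function(skel = skeleton_gait9(), sd = 0.05) {
  ns <- n_segments(skel)
  d <- skel$scale_dim
  pair <- sub("_[rl]$", "", skel$seg_names)
  # loadings: global factor, segment-pair factor, residual
  wg <- 0.6; wseg <- 0.6
  wres <- sqrt(1 - wg^2 - wseg^2)
  L <- matrix(0, d, 1 + length(unique(pair)))
  L[, 1] <- wg
  for (k in seq_along(unique(pair))) {
    segs <- which(pair == unique(pair)[k])
    for (i in segs) L[3 * (i - 1) + 1:3, 1 + k] <- wseg
  }
  cov_s <- sd^2 * (L %*% t(L) + diag(wres^2, d))
  hm <- gait9_height_map(skel)
  wm <- gait9_weight_map(skel)
  Ab <- rbind(hm$a, wm$b)
  noise <- diag(c(0.005^2, 1.0^2))
  cov_full <- rbind(cbind(cov_s, cov_s %*% t(Ab)),
                    cbind(Ab %*% cov_s, Ab %*% cov_s %*% t(Ab) + noise))
  mean_full <- c(rep(1, d), hm$h0 + sum(hm$a), wm$w0 + sum(wm$b))
  scaling_prior(rep(1, d), cov_s,
                covariate_block = list(any = list(mean = mean_full,
                                                  cov = cov_full)))
}

#' Sample a ground-truth subject
#'
#' Draws true scales from the prior, perturbs the nominal marker offsets
#' (anatomical markers get half the SD; perturbations are truncated at
#' `max_offset`), and derives total mass/height from the same linearized
#' functionals the prior uses, distributing mass by the model's standard
#' segment fractions.
#'
#' @param skel a [skeleton_gait9()]-compatible skeleton.
#' @param prior a [scaling_prior()].
#' @param offset_sd marker offset perturbation SD, m (default 1 cm).
#' @param max_offset truncation bound on each offset component (default
#'   2 cm).
#' @param seed RNG seed.
#' @return list with `s_true`, `p_true`, `masses_true`, `height`,
#'   `weight`, `seed`.
#' @export
sample_subject <- function(skel, prior = synthetic_scaling_prior(skel),
                           offset_sd = 0.01, max_offset = 0.02,
                           seed = 1) {
  set.seed(seed)
  Lc <- chol(prior$cov)
  s <- drop(prior$mean + t(Lc) %*% rnorm(skel$scale_dim))
  # keep scales physical
  s <- pmin(pmax(s, 0.8), 1.25)
  M <- length(skel$marker_labels)
  sds <- ifelse(skel$anatomical, offset_sd / 2, offset_sd)
  dp <- matrix(rnorm(3 * M), 3, M) * rep(sds, each = 3)
  dp <- pmin(pmax(dp, -max_offset), max_offset)
  p_true <- skel$pbar + dp
  hm <- gait9_height_map(skel)
  wm <- gait9_weight_map(skel)
  height <- hm$h0 + sum(hm$a * s)
  weight <- wm$w0 + sum(wm$b * s)
  masses <- skel$mass0 / sum(skel$mass0) * weight
  list(s_true = s, p_true = p_true, masses_true = masses,
       height = height, weight = weight, seed = seed)
}

ramp01 <- function(x) 0.5 * (1 - cos(pi * pmin(pmax(x, 0), 1)))

# stance weight of the right foot over the cycle fraction (duty 0.6,
# double stance on [0, 0.1) and [0.5, 0.6))
stance_weight_r <- function(frac) {
  w <- numeric(length(frac))
  w[frac < 0.1] <- ramp01(frac[frac < 0.1] / 0.1)
  w[frac >= 0.1 & frac < 0.5] <- 1
  i <- frac >= 0.5 & frac < 0.6
  w[i] <- 1 - ramp01((frac[i] - 0.5) / 0.1)
  w
}

#' Generate a smooth gait-like joint trajectory
#'
#' Band-limited periodic joint trajectories with alternating stance and
#' forward pelvis progression: sinusoidal hip flexion, a raised-cosine
#' knee-flexion bump during swing (lifting the swing foot clear of the
#' ground), small ankle, lumbar, neck and pelvis oscillations. Left and
#' right legs are half-period phase-shifted copies. Amplitudes are
#' jittered a few percent per seed. The trajectory is twice continuously
#' differentiable by construction.
#'
#' The walking dynamics are kinematically prescribed, not physically
#' simulated: ground reaction forces are derived afterwards so the trial
#' is dynamically consistent regardless (see
#' [synthesize_consistent_grf()]); stance feet may glide slightly, which
#' real gait does not do.
#'
#' @param skel a [skeleton_gait9()]-compatible skeleton.
#' @param s scale vector of the subject.
#' @param duration_s trial length, s (default 2.5).
#' @param rate_hz sampling rate, Hz (default 100).
#' @param speed forward speed, m/s (default 0.8).
#' @param stride_hz stride (full cycle) frequency, Hz (default 1).
#' @param seed RNG seed for the amplitude jitter.
#' @return list with `Q` (T x nq), `dt`, `frac` (cycle fraction per
#'   frame), `w_r`, `w_l` (per-frame stance weights), `stance`
#'   (T x 2 logical: right/left foot loaded).
#' @export
generate_gait_motion <- function(skel, s = default_scales(skel),
                                 duration_s = 2.5, rate_hz = 100,
                                 speed = 0.8, stride_hz = 1, seed = 1) {
  set.seed(seed + 1000L)
  dt <- 1 / rate_hz
  T <- round(duration_s * rate_hz)
  tv <- (seq_len(T) - 1) * dt
  frac <- (tv * stride_hz) %% 1
  frac_l <- (frac + 0.5) %% 1
  jit <- function(x) x * (1 + runif(1, -0.08, 0.08))
  sy <- function(seg) s[3 * (match(seg, skel$seg_names) - 1) + 2]

  hipA <- jit(0.30); kneeA <- jit(0.75); ankA <- jit(0.10)
  ph <- 2 * pi * frac
  hip_flex_r <- hipA * cos(ph)
  hip_flex_l <- hipA * cos(2 * pi * frac_l)
  knee_bump <- function(fr) {
    b <- numeric(length(fr))
    i <- fr >= 0.6
    b[i] <- sin(pi * (fr[i] - 0.6) / 0.4)^2
    b
  }
  knee_r <- -kneeA * knee_bump(frac) - 0.05 * (1 - cos(ph)) / 2
  knee_l <- -kneeA * knee_bump(frac_l) -
    0.05 * (1 - cos(2 * pi * frac_l)) / 2
  ank_r <- ankA * sin(ph + 1.0)
  ank_l <- ankA * sin(2 * pi * frac_l + 1.0)

  leg_len <- 0.07 * sy("pelvis") + 0.42 * sy("thigh_r") +
    0.43 * sy("shank_r") + 0.07 * sy("foot_r")
  pelv_h <- leg_len * 0.985

  Q <- matrix(0, T, skel$nq)
  colnames(Q) <- skel$dof_names
  setq <- function(name, v) Q[, name] <<- v
  setq("ground_pelvis_tx", speed * tv + 0.02 * sin(ph))
  setq("ground_pelvis_ty", pelv_h + 0.015 * sin(2 * ph))
  setq("ground_pelvis_tz", 0.025 * cos(ph))
  setq("ground_pelvis_rx", 0.03 * sin(ph))
  setq("ground_pelvis_ry", -0.05 * sin(ph))
  setq("ground_pelvis_rz", 0.04 + 0.02 * sin(2 * ph))
  setq("lumbar_rx", -0.02 * sin(ph))
  setq("lumbar_ry", 0.05 * sin(ph))
  setq("lumbar_rz", -0.03 - 0.015 * sin(2 * ph))
  setq("neck_r1", 0.02 * sin(ph + 0.5))
  setq("neck_r2", 0.02 * cos(ph))
  setq("hip_r_rx", 0.04 * sin(ph + 0.3))
  setq("hip_r_ry", 0.03 * sin(ph))
  setq("hip_r_rz", hip_flex_r)
  setq("knee_r_r", knee_r)
  setq("ankle_r_r1", ank_r)
  setq("ankle_r_r2", 0.03 * sin(ph + 0.7))
  setq("hip_l_rx", -0.04 * sin(2 * pi * frac_l + 0.3))
  setq("hip_l_ry", -0.03 * sin(2 * pi * frac_l))
  setq("hip_l_rz", hip_flex_l)
  setq("knee_l_r", knee_l)
  setq("ankle_l_r1", ank_l)
  setq("ankle_l_r2", -0.03 * sin(2 * pi * frac_l + 0.7))

  w_r <- stance_weight_r(frac)
  w_l <- 1 - w_r
  list(Q = Q, dt = dt, frac = frac, w_r = w_r, w_l = w_l,
       stance = cbind(r = w_r > 1e-9, l = w_l > 1e-9))
}

#' Synthesize marker observations by forward kinematics
#'
#' @param skel,s_true,p_true,Q subject truth and motion.
#' @param rate_hz marker rate, Hz.
#' @param noise_sd isotropic Gaussian noise SD per coordinate, m
#'   (default 0: the stated evaluation regime uses noise-free markers).
#' @param occlusion_rate independent per-marker-frame masking probability
#'   (default 0).
#' @param seed RNG seed.
#' @return a [marker_trajectories()].
#' @export
synthesize_markers <- function(skel, s_true, p_true, Q, rate_hz,
                               noise_sd = 0, occlusion_rate = 0,
                               seed = 1) {
  set.seed(seed + 2000L)
  T <- nrow(Q)
  M <- length(skel$marker_labels)
  X <- cpp_markers_traj(skel$compiled, s_true, Q, p_true)
  frames <- array(0, c(T, M, 3))
  for (i in seq_len(M)) frames[, i, ] <- X[, c(3 * i - 2, 3 * i - 1, 3 * i)]
  if (noise_sd > 0)
    frames <- frames + array(rnorm(length(frames), 0, noise_sd),
                             dim(frames))
  present <- matrix(TRUE, T, M)
  if (occlusion_rate > 0)
    present <- matrix(runif(T * M) >= occlusion_rate, T, M)
  marker_trajectories(skel$marker_labels, frames, present, rate = rate_hz)
}

#' Dynamically consistent ground reaction forces for a prescribed motion
#'
#' Computes, frame by frame, the total external wrench the feet must
#' transmit so that inverse dynamics of the prescribed motion yields an
#' exactly zero root residual, then splits it between the stance feet
#' with the smooth stance weights and converts each share into a ground-
#' plane centre of pressure, force and free moment (the component of the
#' required moment parallel to the force, which no COP placement can
#' produce). Frames where a foot's share is negligible get a zero record.
#'
#' @param skel,s,masses,Q subject and motion (Q at marker rate).
#' @param dt sample interval, s.
#' @param w_r,w_l per-frame stance weights (right/left), summing to 1.
#' @param plate_corners list of two 4 x 3 corner matrices (right lane,
#'   left lane).
#' @param rate_hz plate rate (defaults to the marker rate so the records
#'   are exact samples of the constructed loads).
#' @return list with `wrenches` (per foot T x 6, world-origin moments),
#'   `plates` (two [force_plate()] records), `torques` (T x nq full
#'   inverse-dynamics generalized forces with the loads applied — the
#'   ground-truth joint torques), `residual_check` (max abs root residual).
#' @export
synthesize_consistent_grf <- function(skel, s, masses, Q, dt, w_r, w_l,
                                      plate_corners = gait_plate_corners(),
                                      rate_hz = 1 / dt) {
  T <- nrow(Q)
  der <- fd_derivatives(Q, dt)
  ns <- n_segments(skel)
  zero_ext <- array(0, c(6, ns, T))
  tau0 <- cpp_id_traj(skel$compiled, s, masses, Q, der$qd, der$qdd,
                      zero_ext)
  feet <- c("foot_r", "foot_l")
  wr_list <- list(matrix(0, T, 6), matrix(0, T, 6))
  force <- list(matrix(0, T, 3), matrix(0, T, 3))
  cop <- list(matrix(0, T, 3), matrix(0, T, 3))
  freem <- list(matrix(0, T, 3), matrix(0, T, 3))
  wts <- cbind(w_r, w_l)
  for (t in seq_len(T)) {
    F_req <- tau0[t, 1:3]
    E <- root_euler_axes(skel, Q[t, ])
    fk <- cpp_fk(skel$compiled, s, Q[t, ])
    anchor <- Q[t, 1:3] # root joint anchor (world translation)
    m_req <- drop(solve(t(E), tau0[t, 4:6])) + cross3(anchor, F_req)
    if (max(abs(wts[t, ])) < 1e-12 && sqrt(sum(F_req^2)) > 1e-6)
      stop("frame ", t, " needs ground support but no foot is in stance")
    for (f in 1:2) {
      w <- wts[t, f]
      if (w < 1e-9) next
      Ff <- w * F_req
      M0 <- w * m_req
      nf2 <- sum(Ff^2)
      fo <- fk$o[match(feet[f], skel$seg_names), ]
      if (nf2 > 1e-10 && abs(Ff[2]) > 1) {
        # ground intersection of the force line of action
        c0 <- cross3(Ff, M0) / nf2
        cpt <- c0 - c0[2] / Ff[2] * Ff
      } else {
        cpt <- c(fo[1], 0, fo[3])
      }
      # keep the COP inside the foot outline (and hence its plate lane);
      # whatever moment a real walker would resolve through COP placement
      # and lateral sway goes into a synthetic 3-D free moment instead,
      # which keeps the wrench -- and the zero residual -- exact
      cpt[1] <- min(max(cpt[1], fo[1] - 0.08), fo[1] + 0.18)
      cpt[3] <- min(max(cpt[3], fo[3] - 0.06), fo[3] + 0.06)
      pc <- plate_corners[[f]]
      cpt[1] <- min(max(cpt[1], min(pc[, 1]) + 0.01), max(pc[, 1]) - 0.01)
      cpt[3] <- min(max(cpt[3], min(pc[, 3]) + 0.01), max(pc[, 3]) - 0.01)
      mf <- M0 - cross3(cpt, Ff)
      force[[f]][t, ] <- Ff
      cop[[f]][t, ] <- cpt
      freem[[f]][t, ] <- mf
      wr_list[[f]][t, ] <- wrench_at_point(Ff, cpt, mf)
    }
  }
  ext <- ext_cube(skel, wr_list, feet)
  tau <- cpp_id_traj(skel$compiled, s, masses, Q, der$qd, der$qdd, ext)
  plates <- lapply(1:2, function(f)
    force_plate(f, plate_corners[[f]], force[[f]], freem[[f]], cop[[f]],
                rate_hz))
  colnames(tau) <- skel$dof_names
  list(wrenches = wr_list, plates = plates, torques = tau,
       foot_segments = feet,
       residual_check = max(abs(tau[, 1:6])))
}

#' Default two-lane plate geometry for synthetic gait
#' @param length_x plate length along the walking direction, m.
#' @return list of two 4 x 3 corner matrices (right lane z > 0, left
#'   lane z < 0).
#' @export
gait_plate_corners <- function(length_x = c(-0.6, 3.6)) {
  mkp <- function(z1, z2)
    matrix(c(length_x[1], 0, z1, length_x[2], 0, z1,
             length_x[2], 0, z2, length_x[1], 0, z2),
           4, 3, byrow = TRUE)
  list(mkp(0.005, 0.6), mkp(-0.6, -0.005))
}

#' Build a complete synthetic trial with known truth
#'
#' Samples a subject, generates gait, synthesizes markers and consistent
#' ground reaction forces, and optionally writes the whole bundle (TRC
#' markers, GRF MOT, plate JSON, truth JSON) to a directory in exactly
#' the formats the readers consume. Defaults encode the synthetic
#' evaluation regime: noise-free markers, no occlusion, ~5% SD scale
#' perturbations from the prior and marker-offset perturbations of
#' 1 cm SD truncated at 2 cm.
#'
#' @param skel a [skeleton_gait9()]-compatible skeleton.
#' @param seed trial seed (drives subject, motion jitter, noise).
#' @param duration_s,rate_hz trial length and marker rate.
#' @param noise_sd,occlusion_rate marker noise model (defaults 0).
#' @param offset_sd marker registration perturbation SD.
#' @param speed walking speed, m/s.
#' @param dir optional output directory for the file bundle.
#' @param prior scaling prior to sample from.
#' @return list with `trial` (a [trial_data()]), `truth` (subject, `Q`,
#'   torques, wrenches, stance weights), and `paths` when written.
#' @export
make_trial <- function(skel = skeleton_gait9(), seed = 1,
                       duration_s = 2.5, rate_hz = 100, noise_sd = 0,
                       occlusion_rate = 0, offset_sd = 0.01, speed = 0.8,
                       dir = NULL, prior = synthetic_scaling_prior(skel)) {
  subj <- sample_subject(skel, prior, offset_sd = offset_sd, seed = seed)
  mot <- generate_gait_motion(skel, subj$s_true, duration_s, rate_hz,
                              speed = speed, seed = seed)
  traj <- synthesize_markers(skel, subj$s_true, subj$p_true, mot$Q,
                             rate_hz, noise_sd, occlusion_rate,
                             seed = seed)
  grf <- synthesize_consistent_grf(skel, subj$s_true, subj$masses_true,
                                   mot$Q, mot$dt, mot$w_r, mot$w_l)
  plate_cfg <- list(plates = lapply(1:2, function(k)
    list(id = k, corners = grf$plates[[k]]$corners)),
    cop_units = "m", force_units = "N", torque_units = "Nm")
  trial <- trial_data(traj, grf$plates,
                      meta = list(height = subj$height,
                                  weight = subj$weight))
  truth <- list(subject = subj, Q = mot$Q, dt = mot$dt,
                frac = mot$frac, w_r = mot$w_r, w_l = mot$w_l,
                stance = mot$stance,
                torques = grf$torques, wrenches = grf$wrenches,
                foot_segments = grf$foot_segments,
                residual_check = grf$residual_check)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(trc = file.path(dir, "markers.trc"),
                  grf = file.path(dir, "grf.mot"),
                  plates = file.path(dir, "plates.json"),
                  truth = file.path(dir, "truth.json"))
    write_trc(traj, paths$trc)
    write_grf_mot(grf$plates, paths$grf)
    save_plate_config(plate_cfg, paths$plates)
    jsonlite::write_json(
      list(seed = seed, s_true = subj$s_true,
           p_true = apply(subj$p_true, 2, c, simplify = FALSE),
           masses_true = subj$masses_true, height = subj$height,
           weight = subj$weight,
           Q = apply(mot$Q, 1, c, simplify = FALSE),
           dof_names = skel$dof_names),
      paths$truth, auto_unbox = TRUE, digits = NA)
  }
  list(trial = trial, truth = truth, plate_config = plate_cfg,
       paths = paths)
}
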