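test_that("sample_subject: determinism, truncation and prior statistics", {
  skel <- cached_gait_skel()
  prior <- cached_gait_prior()
  a <- sample_subject(skel, prior, seed = 3)
  b <- sample_subject(skel, prior, seed = 3)
  expect_identical(a, b)
  # zero offset SD leaves the nominal registration untouched
  c0 <- sample_subject(skel, prior, offset_sd = 0, seed = 4)
  expect_equal(c0$p_true, skel$pbar)
  # perturbations respect the 2 cm truncation
  d <- sample_subject(skel, prior, offset_sd = 0.02, seed = 5)
  expect_lte(max(abs(d$p_true - skel$pbar)), 0.02 + 1e-12)
  # empirical scale SD across draws matches the prior diagonal (10 %)
  draws <- vapply(1:1000, function(i)
    sample_subject(skel, prior, seed = i)$s_true, numeric(skel$scale_dim))
  emp_sd <- apply(draws, 1, sd)
  expect_lt(max(abs(emp_sd - sqrt(diag(prior$cov))) /
                  sqrt(diag(prior$cov))), 0.10)
})

test_that("gait motion generator: shape, smoothness and bilateral
           symmetry", {
  skel <- cached_gait_skel()
  mot <- generate_gait_motion(skel, duration_s = 2, rate_hz = 100,
                              seed = 2)
  expect_equal(nrow(mot$Q), 200)
  expect_identical(mot$Q,
                   generate_gait_motion(skel, duration_s = 2,
                                        rate_hz = 100, seed = 2)$Q)
  # twice differentiable in practice: bounded second differences
  qdd <- diff(mot$Q, differences = 2) / mot$dt^2
  expect_lt(max(abs(qdd)), 200)
  # left/right joint trajectories are half-period shifted copies
  half <- 50 # stride_hz = 1 at 100 Hz
  rng <- 1:(200 - half)
  expect_lt(max(abs(mot$Q[rng + half, "hip_l_rz"] -
                      mot$Q[rng, "hip_r_rz"])), 1e-8)
  expect_lt(max(abs(mot$Q[rng + half, "knee_l_r"] -
                      mot$Q[rng, "knee_r_r"])), 1e-8)
  # stance schedule always supports the body
  expect_true(all(mot$w_r + mot$w_l > 1 - 1e-12))
})

test_that("marker synthesis: exact FK, occlusion statistics and noise
           level", {
  skel <- cached_gait_skel()
  tr <- cached_gait_trial()
  truth <- tr$truth
  Q <- truth$Q
  s <- truth$subject$s_true; p <- truth$subject$p_true
  clean <- synthesize_markers(skel, s, p, Q, 100)
  t0 <- 7
  expect_equal(clean$frames[t0, , ],
               unname(marker_world_positions(skel, s, Q[t0, ], p)),
               tolerance = 1e-12)
  # occlusion count within 3 sigma of the binomial mean
  occ <- synthesize_markers(skel, s, p, Q, 100, occlusion_rate = 0.1,
                            seed = 8)
  n <- length(occ$present)
  expect_lt(abs(sum(!occ$present) - 0.1 * n), 3 * sqrt(n * 0.1 * 0.9))
  # noise RMSE ~ sd * sqrt(3) per marker position (chi distribution)
  noisy <- synthesize_markers(skel, s, p, Q, 100, noise_sd = 2e-3,
                              seed = 9)
  rmse <- sqrt(mean(rowSums((noisy$frames - clean$frames)^2,
                            dims = 2)))
  expect_lt(abs(rmse - 2e-3 * sqrt(3)) / (2e-3 * sqrt(3)), 0.1)
})

test_that("consistent GRF synthesis: statics, double stance and the
           zero-residual invariant", {
  skel <- cached_gait_skel()
  prior <- cached_gait_prior()
  subj <- sample_subject(skel, prior, seed = 11)
  s <- subj$s_true; m <- subj$masses_true
  # static single stance: adduct both hips until the right foot stands
  # under the whole-body COM, as a one-legged stander would
  T <- 12; dt <- 0.01
  q0 <- rep(0, skel$nq)
  q0[2] <- 0.99
  hips <- match(c("hip_r_rx", "hip_l_rx"), skel$dof_names)
  zgap <- function(a) {
    q <- q0; q[hips] <- a
    fk <- forward_kinematics(skel, s, q, warn_gimbal = FALSE)
    fk$origins["foot_r", 3] - com_position(skel, s, m, q)[3]
  }
  q0[hips] <- stats::uniroot(zgap, c(0, 0.5))$root
  Q <- matrix(q0, T, skel$nq, byrow = TRUE)
  # one wide plate under the stance foot (the stander straddles the
  # default lane boundary)
  wide <- list(matrix(c(-1, 0, -0.5, 1, 0, -0.5, 1, 0, 0.5, -1, 0, 0.5),
                      4, 3, byrow = TRUE),
               matrix(c(-1, 0, -2, 1, 0, -2, 1, 0, -1, -1, 0, -1),
                      4, 3, byrow = TRUE))
  grf <- synthesize_consistent_grf(skel, s, m, Q, dt,
                                   w_r = rep(1, T), w_l = rep(0, T),
                                   plate_corners = wide)
  expect_lt(grf$residual_check, 1e-8)
  t0 <- 6
  expect_equal(grf$plates[[1]]$force[t0, ],
               -sum(m) * skel$gravity, tolerance = 1e-6)
  com <- com_position(skel, s, m, Q[t0, ])
  expect_lt(max(abs(grf$plates[[1]]$cop[t0, c(1, 3)] - com[c(1, 3)])),
            1e-6)
  expect_true(all(abs(grf$plates[[2]]$force) < 1e-12))
  # 50/50 double stance splits the wrench evenly
  grf2 <- synthesize_consistent_grf(skel, s, m, Q, dt,
                                    w_r = rep(0.5, T), w_l = rep(0.5, T))
  expect_lt(grf2$residual_check, 1e-8)
  expect_equal(grf2$plates[[1]]$force[t0, ],
               grf2$plates[[2]]$force[t0, ], tolerance = 1e-9)
  # full gait trial: the defining invariant, every frame
  tr <- cached_gait_trial()
  expect_lt(tr$truth$residual_check, 1e-8)
  # a motion that needs support with no stance foot is rejected
  expect_error(synthesize_consistent_grf(skel, s, m, Q, dt,
                                         w_r = rep(0, T),
                                         w_l = rep(0, T)),
               "no foot is in stance")
})

test_that("generated trials exercise both plates, both stance types and
           in-lane COPs", {
  tr <- cached_gait_trial(seed = 4, duration_s = 2.0)
  truth <- tr$truth
  single_r <- truth$w_r > 1 - 1e-9
  single_l <- truth$w_l > 1 - 1e-9
  double <- truth$w_r > 0.05 & truth$w_l > 0.05
  expect_gt(sum(single_r), 0)
  expect_gt(sum(single_l), 0)
  expect_gt(sum(double), 0)
  for (k in 1:2) {
    pl <- tr$trial$plates[[k]]
    loaded <- sqrt(rowSums(pl$force^2)) > 10
    expect_gt(sum(loaded), 10)
    inside <- vapply(which(loaded), function(t)
      mocapfit:::point_in_polygon_xz(pl$cop[t, ], pl$corners),
      logical(1))
    expect_true(all(inside))
  }
  # occlusion produces at least one masked span when requested
  occ <- cached_gait_trial(seed = 4, duration_s = 1.0,
                           occlusion_rate = 0.05)
  expect_gt(sum(!occ$trial$markers$present), 0)
})

test_that("make_trial bundles are deterministic and round-trip through
           the file formats", {
  skel <- cached_gait_skel()
  prior <- cached_gait_prior()
  d1 <- withr::local_tempdir()
  t1 <- make_trial(skel, seed = 6, duration_s = 1.0, prior = prior,
                   dir = d1)
  t2 <- make_trial(skel, seed = 6, duration_s = 1.0, prior = prior)
  expect_equal(t1$truth$Q, t2$truth$Q)
  expect_equal(t1$trial$markers$frames, t2$trial$markers$frames)
  # reload through the readers: lossless to write precision
  traj <- read_trc(t1$paths$trc)
  expect_equal(traj$frames[traj$present],
               t1$trial$markers$frames[t1$trial$markers$present],
               tolerance = 1e-9)
  pls <- read_grf_mot(t1$paths$grf, t1$paths$plates)
  expect_equal(pls[[1]]$force, unname(t1$trial$plates[[1]]$force),
               tolerance = 1e-7, ignore_attr = TRUE)
  # truth sidecar holds the exact motion
  doc <- jsonlite::fromJSON(t1$paths$truth)
  expect_equal(unname(doc$Q), unname(t1$truth$Q), tolerance = 1e-12)
})
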