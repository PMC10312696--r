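test_that("condition_prior implements partitioned-Gaussian conditioning", {
  # random 6-dim joint Gaussian: 4 'scale' dims + 2 covariates
  set.seed(41)
  A <- matrix(rnorm(36), 6)
  S <- crossprod(A) + diag(0.5, 6)
  mu <- rnorm(6)
  prior <- scaling_prior(mu[1:4], S[1:4, 1:4],
                         covariate_block = list(any = list(mean = mu,
                                                           cov = S)))
  h <- mu[5] + 0.7; w <- mu[6] - 1.1
  post <- condition_prior(prior, height = h, weight = w)
  # textbook formula, written out independently
  S_ab <- S[1:4, 5:6]; S_bb <- S[5:6, 5:6]
  mu_or <- mu[1:4] + S_ab %*% solve(S_bb, c(h, w) - mu[5:6])
  S_or <- S[1:4, 1:4] - S_ab %*% solve(S_bb, t(S_ab))
  expect_equal(post$mean, drop(mu_or), tolerance = 1e-10)
  expect_equal(post$cov, 0.5 * (S_or + t(S_or)), tolerance = 1e-10)
  # conditioning on the mean leaves the mean unchanged
  post0 <- condition_prior(prior, height = mu[5], weight = mu[6])
  expect_equal(post0$mean, mu[1:4], tolerance = 1e-12)
  # posterior covariance is smaller in the PSD order
  expect_gte(min(eigen(prior$cov - post$cov, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-10)
  # absent covariates: unchanged; extreme covariate: clamped + warning
  expect_identical(condition_prior(prior), prior)
  expect_warning(condition_prior(prior, height = mu[5] + 50 *
                                   sqrt(S[5, 5])), "clamp")
})

test_that("init_marker_offsets returns the nominal registration", {
  skel <- cached_gait_skel()
  expect_identical(init_marker_offsets(skel), skel$pbar)
  # round trip through FK at q = 0 reproduces the nominal layout
  X <- marker_world_positions(skel, default_scales(skel),
                              rep(0, skel$nq), init_marker_offsets(skel))
  expect_equal(X, marker_world_positions(skel, default_scales(skel),
                                         rep(0, skel$nq)))
})

test_that("init_scales recovers known scales from clean data and scales
           with the data", {
  skel <- cached_gait_skel()
  prior <- cached_gait_prior()
  # markers generated with nominal offsets and known scales
  tr <- cached_gait_trial(seed = 7, duration_s = 1.2, offset_sd = 0)
  truth <- tr$truth
  groups <- mocapfit:::joint_marker_groups(skel)
  geometry <- lapply(names(groups), function(jn)
    estimate_joint_geometry(tr$trial$markers, jn, groups[[jn]]$parent,
                            groups[[jn]]$child))
  names(geometry) <- names(groups)
  sc <- init_scales(skel, geometry, tr$trial$markers, skel$pbar, prior)
  expect_lt(max(abs(sc$s - truth$subject$s_true) /
                  truth$subject$s_true), 0.01)
  # uniform similarity: scaling the world by k scales s by k
  k <- 1.07
  traj_k <- tr$trial$markers
  traj_k$frames <- traj_k$frames * k
  geometry_k <- lapply(names(groups), function(jn)
    estimate_joint_geometry(traj_k, jn, groups[[jn]]$parent,
                            groups[[jn]]$child))
  names(geometry_k) <- names(groups)
  sc_k <- init_scales(skel, geometry_k, traj_k, skel$pbar, prior)
  expect_lt(max(abs(sc_k$s - k * sc$s) / sc$s), 0.015)
  # without any usable geometry the prior mean is the declared fallback
  none <- lapply(geometry, function(g) {
    g$mode <- "none"; g$sphere_residual <- Inf; g$cond <- Inf
    g$axis <- NULL
    g
  })
  expect_warning(sc0 <- init_scales(skel, none, tr$trial$markers,
                                    skel$pbar, prior), "prior mean")
  expect_equal(sc0$s, prior$mean)
})

test_that("inverse kinematics recovers exact poses and matches the rigid
           registration oracle", {
  skel <- cached_gait_skel()
  tr <- cached_gait_trial(seed = 7, duration_s = 1.2, offset_sd = 0)
  truth <- tr$truth
  sub <- mocapfit:::subsample_traj(tr$trial$markers, seq(1, 60, by = 4))
  ik <- init_poses(skel, truth$subject$s_true, truth$subject$p_true, sub)
  expect_lt(ik$marker_rmse, 1e-6)
  # single free body: IK equals closed-form Kabsch registration
  fb <- mk_free_body()
  q_true <- c(0.3, 1.1, -0.2, 0.25, -0.4, 0.6)
  X <- marker_world_positions(fb, rep(1, 3), q_true)
  traj1 <- marker_trajectories(fb$marker_labels,
                               array(X, c(1, nrow(X), 3)), rate = 100)
  ikf <- init_poses(fb, rep(1, 3), fb$pbar, traj1)
  X0 <- marker_world_positions(fb, rep(1, 3), rep(0, 6))
  kb <- oracle_kabsch(X0, X)
  Xik <- marker_world_positions(fb, rep(1, 3), ikf$Q[1, ])
  expect_lt(max(abs(Xik - (t(kb$R %*% t(X0)) +
                             matrix(kb$d, nrow(X0), 3, byrow = TRUE)))),
            1e-8)
  # fully masked middle frame copies its predecessor and is flagged
  tr3 <- mocapfit:::subsample_traj(tr$trial$markers, 1:9)
  tr3$present[5, ] <- FALSE
  tr3$frames[5, , ] <- NA
  ik3 <- init_poses(skel, truth$subject$s_true, truth$subject$p_true, tr3)
  expect_equal(ik3$flagged, 5L)
  expect_equal(ik3$Q[5, ], ik3$Q[4, ])
})

test_that("bilevel MAP fit: noise-free recovery, stationarity and
           objective decrease", {
  # data generated from a skeleton at the prior mean with nominal
  # offsets: the posterior mode coincides with the generating truth
  skel <- cached_gait_skel()
  prior <- cached_gait_prior()
  s_true <- prior$mean
  mot <- generate_gait_motion(skel, s_true, duration_s = 0.8,
                              rate_hz = 100, seed = 30)
  traj <- synthesize_markers(skel, s_true, skel$pbar, mot$Q, 100)
  s0 <- s_true * (1 + 0.02 * rep_len(c(1, -1), skel$scale_dim))
  fit <- bilevel_map_fit(skel, prior, traj, s0, skel$pbar)
  expect_lt(fit$marker_rmse, 1e-3)
  expect_lt(max(abs(fit$s - s_true)), 0.01)
  expect_lt(fit$stationarity_norm, 1e-6)
  expect_lte(fit$objective, fit$objective_init)
  expect_true(all(diff(fit$objective_history) <= 1e-8))
})

test_that("tightening the scale prior pulls the fitted scales toward the
           prior mean", {
  skel <- cached_gait_skel()
  prior <- cached_gait_prior()
  tr <- cached_gait_trial(seed = 8, duration_s = 0.6, noise_sd = 2e-3)
  truth <- tr$truth
  sub <- mocapfit:::subsample_traj(tr$trial$markers, 1:30)
  dist <- vapply(c(1, 100, 10000), function(shrink) {
    pr <- scaling_prior(prior$mean, prior$cov / shrink)
    fit <- bilevel_map_fit(skel, pr, sub, truth$subject$s_true,
                           skel$pbar, max_outer = 8)
    sqrt(sum((fit$s - pr$mean)^2))
  }, numeric(1))
  expect_true(all(diff(dist) <= 1e-6))
})

test_that("marker_error_report matches direct computation", {
  skel <- cached_gait_skel()
  tr <- cached_gait_trial(seed = 7, duration_s = 1.2, offset_sd = 0)
  truth <- tr$truth
  sub <- mocapfit:::subsample_traj(tr$trial$markers, 1:20)
  s <- truth$subject$s_true; p <- truth$subject$p_true
  Q <- truth$Q[1:20, ]
  # model markers exactly at observations
  rep0 <- marker_error_report(skel, s, p, Q, sub)
  expect_lt(rep0$rmse, 1e-12)
  expect_lt(rep0$max, 1e-12)
  # one marker displaced 3 cm in 1 of 20 frames
  sub2 <- sub
  sub2$frames[7, 3, ] <- sub2$frames[7, 3, ] + c(0.03, 0, 0)
  rep2 <- marker_error_report(skel, s, p, Q, sub2)
  expect_equal(rep2$max, 0.03, tolerance = 1e-9)
  M <- length(skel$marker_labels)
  expect_equal(rep2$rmse, sqrt(0.03^2 / (20 * M)), tolerance = 1e-9)
  # random case vs flat-loop oracle
  set.seed(42)
  sub3 <- sub
  sub3$frames <- sub3$frames + array(rnorm(length(sub3$frames), 0, 5e-3),
                                     dim(sub3$frames))
  rep3 <- marker_error_report(skel, s, p, Q, sub3)
  sq <- c()
  for (t in 1:20) {
    X <- marker_world_positions(skel, s, Q[t, ], p)
    for (i in seq_len(M)) {
      j <- match(skel$marker_labels[i], sub3$labels)
      if (sub3$present[t, j])
        sq <- c(sq, sum((X[i, ] - sub3$frames[t, j, ])^2))
    }
  }
  expect_equal(rep3$rmse, sqrt(mean(sq)), tolerance = 1e-12)
  expect_equal(rep3$max, sqrt(max(sq)), tolerance = 1e-12)
})

test_that("recovery properties: parameters, anatomical-vs-tracking and
           missing data", {
  skel <- cached_gait_skel()
  prior <- cached_gait_prior()
  s_rms <- c(); p_rms <- c(); anat_move <- c(); track_move <- c()
  for (seed in 1:4) {
    tr <- cached_gait_trial(seed = seed + 20, duration_s = 1.0,
                            noise_sd = 2e-3)
    truth <- tr$truth
    groups <- mocapfit:::joint_marker_groups(skel)
    geometry <- lapply(names(groups), function(jn)
      estimate_joint_geometry(tr$trial$markers, jn,
                              groups[[jn]]$parent, groups[[jn]]$child))
    names(geometry) <- names(groups)
    sc <- init_scales(skel, geometry, tr$trial$markers, skel$pbar, prior)
    fit <- bilevel_map_fit(skel, prior, tr$trial$markers, sc$s,
                           skel$pbar, max_outer = 15)
    s_rms <- c(s_rms, sqrt(mean((fit$s - truth$subject$s_true)^2)))
    p_rms <- c(p_rms, sqrt(mean((fit$p - truth$subject$p_true)^2)))
    anat_move <- c(anat_move,
                   sqrt(mean((fit$p - skel$pbar)[, skel$anatomical]^2)))
    track_move <- c(track_move,
                    sqrt(mean((fit$p - skel$pbar)[, !skel$anatomical]^2)))
  }
  expect_lt(mean(s_rms), 0.025)      # scales within 2.5 % RMS
  expect_lt(mean(p_rms), 5e-3)       # offsets within 5 mm RMS
  # anatomical offsets move less than tracking offsets on average
  expect_lt(mean(anat_move), mean(track_move))

  # masking 20 % of marker-frames changes the RMSE on the remaining
  # frames by <= 20 %
  tr <- cached_gait_trial(seed = 25, duration_s = 1.0, noise_sd = 2e-3)
  truth <- tr$truth
  fit_full <- bilevel_map_fit(skel, prior, tr$trial$markers,
                              truth$subject$s_true, skel$pbar,
                              max_outer = 8)
  masked <- tr$trial$markers
  set.seed(99)
  drop_mask <- matrix(runif(length(masked$present)) < 0.2,
                      nrow(masked$present))
  masked$present[drop_mask] <- FALSE
  masked$frames[array(rep(drop_mask, 3),
                      dim(masked$frames))] <- NA
  fit_mask <- bilevel_map_fit(skel, prior, masked,
                              truth$subject$s_true, skel$pbar,
                              max_outer = 8)
  expect_lt(abs(fit_mask$marker_rmse - fit_full$marker_rmse) /
              fit_full$marker_rmse, 0.2)
})
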