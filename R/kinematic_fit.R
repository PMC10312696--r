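#' Anthropometric scaling prior
#'
#' Multivariate Gaussian over the per-axis segment scale vector `s`,
#' optionally with a joint covariate block over (s, height, weight) per
#' sex so the prior can be conditioned on subject metadata before any
#' optimization. The package ships a synthetic prior (see
#' [synthetic_scaling_prior()]); parameters estimated from a real
#' anthropometric survey can be supplied through the same structure.
#'
#' @param mean scale-dimension mean vector.
#' @param cov SPD covariance matrix.
#' @param covariate_block optional named list (per sex, or `"any"`) of
#'   lists with `mean` (length scale_dim + 2: scales, height, weight) and
#'   `cov` (SPD).
#' @return object of class `scaling_prior`.
#' @export
scaling_prior <- function(mean, cov, covariate_block = NULL) {
  stopifnot(length(mean) == nrow(cov), isTRUE(all.equal(cov, t(cov))))
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("prior covariance must be SPD")
  structure(list(mean = as.numeric(mean), cov = cov,
                 covariate_block = covariate_block),
            class = "scaling_prior")
}

#' @export
print.scaling_prior <- function(x, ...) {
  cat("scaling_prior: dim", length(x$mean),
      if (!is.null(x$covariate_block)) "with covariate block" else "", "\n")
  invisible(x)
}

#' Condition the scaling prior on subject covariates
#'
#' Standard partitioned-Gaussian conditioning of the scale block on any
#' observed subset of (height, weight). Covariates farther than 5 SD from
#' the block marginal are clamped with a warning. Without a covariate
#' block, or without any observed covariate, the prior is returned
#' unchanged.
#'
#' @param prior a [scaling_prior()].
#' @param height,weight observed covariates (m, kg), or `NULL`.
#' @param sex `"male"`, `"female"` or `NULL` (uses the `"any"` block).
#' @return conditioned [scaling_prior()] (without covariate block).
#' @export
condition_prior <- function(prior, height = NULL, weight = NULL,
                            sex = NULL) {
  if (is.null(prior$covariate_block) ||
      (is.null(height) && is.null(weight)))
    return(prior)
  blk <- prior$covariate_block[[if (is.null(sex)) "any" else sex]]
  if (is.null(blk)) blk <- prior$covariate_block[["any"]]
  if (is.null(blk)) stop("no covariate block for sex = ", sex)
  d <- length(blk$mean) - 2L
  obs_idx <- integer(0); obs_val <- numeric(0)
  for (k in seq_along(c("height", "weight"))) {
    v <- list(height, weight)[[k]]
    if (!is.null(v)) {
      i <- d + k
      sdv <- sqrt(blk$cov[i, i])
      if (abs(v - blk$mean[i]) > 5 * sdv) {
        warning("covariate ", c("height", "weight")[k],
                " outside the plausible range; clamping to 5 SD")
        v <- blk$mean[i] + sign(v - blk$mean[i]) * 5 * sdv
      }
      obs_idx <- c(obs_idx, i); obs_val <- c(obs_val, v)
    }
  }
  A <- seq_len(d)
  S_ab <- blk$cov[A, obs_idx, drop = FALSE]
  S_bb <- blk$cov[obs_idx, obs_idx, drop = FALSE]
  K <- S_ab %*% solve(S_bb)
  mu <- blk$mean[A] + drop(K %*% (obs_val - blk$mean[obs_idx]))
  S <- blk$cov[A, A] - K %*% t(S_ab)
  scaling_prior(mu, 0.5 * (S + t(S)))
}

#' Initial marker offsets
#'
#' Trivial by design: the experimenter-provided (or model default) marker
#' placements are the best available initial registration.
#'
#' @param skel a [skeleton()].
#' @return 3 x M matrix, the nominal offsets.
#' @export
init_marker_offsets <- function(skel) skel$pbar

# ---- inverse kinematics ---------------------------------------------------

# One-frame damped Gauss-Newton IK on the marker least-squares objective.
# Returns q and the gradient norm of the (unhalved) marker objective.
ik_frame <- function(skel, s, p, xobs, present, q0, max_iter = 50,
                     grad_tol = 1e-10) {
  q <- q0
  idx <- which(rep(present, each = 3))
  lambda <- 1e-8
  f_of <- function(qq) {
    X <- cpp_markers(skel$compiled, s, qq, p)
    sum((t(X)[idx] - xobs[idx])^2)
  }
  f <- f_of(q)
  for (it in seq_len(max_iter)) {
    mj <- cpp_marker_jac(skel$compiled, s, q, p)
    r <- as.vector(t(mj$x))[idx] - xobs[idx]
    J <- mj$Jq[idx, , drop = FALSE]
    g <- 2 * crossprod(J, r)
    if (sqrt(sum(g^2)) <= grad_tol) break
    H <- crossprod(J)
    ok <- FALSE
    for (k in 1:10) {
      step <- tryCatch(solve(H + lambda * (diag(diag(H)) + 1e-10 * diag(ncol(H))), -crossprod(J, r)),
                       error = function(e) NULL)
      if (!is.null(step)) {
        qn <- q + drop(step)
        fn <- f_of(qn)
        if (is.finite(fn) && fn <= f) {
          q <- qn; f <- fn; lambda <- max(lambda / 5, 1e-12); ok <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!ok) break
  }
  mj <- cpp_marker_jac(skel$compiled, s, q, p)
  r <- as.vector(t(mj$x))[idx] - xobs[idx]
  g <- 2 * crossprod(mj$Jq[idx, , drop = FALSE], r)
  list(q = q, f = f, grad_norm = sqrt(sum(g^2)))
}

# crude root initialization for the first frame: translate the model so
# the mean of the visible model markers matches the observations
root_translation_init <- function(skel, s, p, xobs, present) {
  q <- rep(0, skel$nq)
  X <- cpp_markers(skel$compiled, s, q, p)
  d <- colMeans(xobs[present, , drop = FALSE]) -
    colMeans(X[present, , drop = FALSE])
  q[1:3] <- d
  q
}

#' Inverse kinematics over a trajectory
#'
#' Per-frame damped Gauss-Newton on the marker least-squares objective,
#' warm-started from the previous frame; masked markers are dropped from
#' the sum. Frames with fewer than 3 visible markers copy their
#' neighbour's pose and are flagged.
#'
#' @param skel a [skeleton()].
#' @param s scale vector.
#' @param p 3 x M local marker offsets.
#' @param traj a [marker_trajectories()] whose labels cover the model
#'   marker set (missing labels are treated as always-occluded).
#' @param q_init optional T x nq warm start.
#' @param grad_tol stationarity tolerance on the per-frame gradient norm.
#' @return list with `Q` (T x nq), `flagged` (frames with insufficient
#'   markers), `grad_norms`, `marker_rmse`.
#' @export
init_poses <- function(skel, s, p, traj, q_init = NULL, grad_tol = 1e-10) {
  ord <- match(skel$marker_labels, traj$labels)
  T <- n_frames(traj)
  M <- length(skel$marker_labels)
  Q <- matrix(0, T, skel$nq)
  flagged <- integer(0)
  grad_norms <- numeric(T)
  sq_sum <- 0; n_obs <- 0
  q_prev <- NULL
  for (t in seq_len(T)) {
    present <- !is.na(ord) & traj$present[t, ifelse(is.na(ord), 1, ord)]
    xobs <- matrix(NA_real_, M, 3)
    xobs[present, ] <- traj$frames[t, ord[present], ]
    if (sum(present) < 3) {
      Q[t, ] <- if (!is.null(q_prev)) q_prev else rep(0, skel$nq)
      flagged <- c(flagged, t)
      next
    }
    q0 <- if (!is.null(q_init)) q_init[t, ]
    else if (!is.null(q_prev)) q_prev
    else root_translation_init(skel, s, p, xobs, present)
    sol <- ik_frame(skel, s, p, t(xobs), present, q0, grad_tol = grad_tol)
    Q[t, ] <- sol$q
    q_prev <- sol$q
    grad_norms[t] <- sol$grad_norm
    sq_sum <- sq_sum + sol$f
    n_obs <- n_obs + sum(present)
  }
  # flagged leading frames inherit the first solved pose
  if (length(flagged) && flagged[1] == 1) {
    first_ok <- setdiff(seq_len(T), flagged)[1]
    for (t in rev(seq_len(first_ok - 1))) Q[t, ] <- Q[t + 1, ]
  }
  warn_if_gimbal(skel, Q[ceiling(T / 2), ])
  list(Q = Q, flagged = flagged, grad_norms = grad_norms,
       marker_rmse = sqrt(sq_sum / max(n_obs, 1)))
}

# observation array helpers: xobs_all (T x M x 3), present (T x M) in
# model marker order
traj_to_model_order <- function(skel, traj) {
  ord <- match(skel$marker_labels, traj$labels)
  if (anyNA(ord))
    warning("trajectory is missing model markers: ",
            paste(skel$marker_labels[is.na(ord)], collapse = ", "))
  T <- n_frames(traj)
  M <- length(skel$marker_labels)
  xobs <- array(NA_real_, c(T, M, 3))
  present <- matrix(FALSE, T, M)
  for (i in seq_len(M)) {
    if (is.na(ord[i])) next
    present[, i] <- traj$present[, ord[i]]
    xobs[, i, ] <- traj$frames[, ord[i], ]
  }
  list(xobs = xobs, present = present)
}

#' Initialize body segment scales from functional joint geometry
#'
#' Nonlinear least squares over the scales `s` (and one scalar `alpha`
#' per axis-classified joint) of a combined objective on a subsample of
#' frames: a marker term keeping the scaled model close to the
#' observations, plus a joint term pulling each model joint center onto
#' its estimated functional center (sphere mode) or axis line `c_t +
#' alpha a_t` (axis mode). Poses are re-solved by coarse inverse
#' kinematics between scale updates, since neither is known first. A weak
#' pull toward the prior mean regularizes scale directions the data do
#' not constrain.
#'
#' @param skel a [skeleton()].
#' @param geometry named list of `joint_geometry_estimate`s (names are
#'   joint names of `skel`).
#' @param traj a [marker_trajectories()].
#' @param p 3 x M marker offsets (Step 1 output).
#' @param prior a [scaling_prior()] (possibly conditioned).
#' @param n_frames number of subsampled frames (default 30).
#' @param max_iter outer Gauss-Newton iterations (default 25).
#' @param joint_weight weight of the joint-geometry term relative to the
#'   marker term (default 1).
#' @return list with `s`, `alpha` (named per axis joint), `q_sub`,
#'   `frames`.
#' @export
init_scales <- function(skel, geometry, traj, p = skel$pbar, prior,
                        n_frames = 30, max_iter = 25, joint_weight = 1,
                        s0 = NULL, q0 = NULL) {
  T <- dim(traj$frames)[1]
  frames <- unique(round(seq(1, T, length.out = min(n_frames, T))))
  mo <- traj_to_model_order(skel, traj)
  geometry <- geometry[vapply(geometry, function(g)
    classify_joint_geometry(g) != "none", logical(1))]
  modes <- vapply(geometry, classify_joint_geometry, character(1))
  jidx <- match(names(geometry), skel$joint_names)
  if (anyNA(jidx)) stop("geometry for unknown joint")
  if (!length(geometry)) {
    warning("no joint with usable functional geometry; ",
            "falling back to the prior mean scales")
    return(list(s = prior$mean, alpha = numeric(0), q_sub = NULL,
                frames = frames))
  }
  n_axis <- sum(modes == "axis")
  ax_ids <- which(modes == "axis")
  # per-joint world center/axis at the subsampled frames
  geo_at <- lapply(seq_along(geometry), function(k) {
    g <- geometry[[k]]
    gi <- match(frames, g$frames)
    keep <- !is.na(gi)
    list(frames = which(keep),
         centers = g$centers[gi[keep], , drop = FALSE],
         axis = if (!is.null(g$axis)) g$axis[gi[keep], , drop = FALSE])
  })

  nsd <- skel$scale_dim
  nq <- skel$nq
  nx <- nsd + n_axis
  wd <- 1 / 0.01 # data terms weighted by a 1 cm marker SD
  sw <- wd * sqrt(joint_weight)
  s <- prior$mean
  # closed-form pre-initialization from inter-joint-center distances:
  # the distance between two functional joint centers attached to the
  # same segment is pose-invariant and equals the scaled model offset,
  # so axis-dominated offsets yield direct per-axis scale estimates
  pre <- joint_distance_scales(skel, geometry, jidx)
  s[pre$idx] <- pre$value
  if (!is.null(s0)) s <- s0
  alpha <- rep(0, n_axis)
  W <- chol(solve(prior$cov)) * 0.05 # weak pull on unobservable scales
  sub <- subsample_traj(traj, frames)
  ik <- init_poses(skel, s, p, sub, q_init = q0, grad_tol = 1e-8)
  Qs <- ik$Q
  nf <- length(frames)

  objective <- function(s_, a_, Q_) {
    val <- 0
    for (ti in seq_len(nf)) {
      X <- cpp_markers(skel$compiled, s_, Q_[ti, ], p)
      pres <- mo$present[frames[ti], ]
      val <- val + wd^2 * sum((X[pres, , drop = FALSE] -
                                 mo$xobs[frames[ti], pres, ])^2)
      fk <- cpp_fk(skel$compiled, s_, Q_[ti, ])
      for (k in seq_along(geometry)) {
        gi <- match(ti, geo_at[[k]]$frames)
        if (is.na(gi)) next
        anc <- fk$dof_anchor[, skel$dof0[jidx[k]] + 1]
        ct <- geo_at[[k]]$centers[gi, ]
        d <- anc - ct
        if (modes[k] == "axis")
          d <- d - a_[match(k, ax_ids)] * geo_at[[k]]$axis[gi, ]
        val <- val + wd^2 * joint_weight * sum(d^2)
      }
    }
    val + sum((W %*% (s_ - prior$mean))^2)
  }

  # world point Jacobian (3 x nq) of a point fixed to segment `seg`
  point_jac <- function(fk, seg, x) {
    J <- matrix(0, 3, nq)
    g <- seg
    while (g >= 1) {
      d0 <- skel$dof0[g]
      for (kk in seq_len(skel$ndof[g])) {
        d <- d0 + kk
        if (fk$dof_rot[d] == 1) {
          J[, d] <- cross3(fk$dof_axis[, d], x - fk$dof_anchor[, d])
        } else {
          J[, d] <- fk$dof_axis[, d]
        }
      }
      g <- skel$parent[g] + 1L
    }
    J
  }

  f <- objective(s, alpha, Qs)
  lambda <- 1e-6
  # outer restarts: a fresh frame-by-frame IK sweep at the current scales
  # lets poses hop out of basins the joint Gauss-Newton cannot leave
  for (restart in 1:3) {
  if (restart > 1) {
    ik <- init_poses(skel, s, p, sub, grad_tol = 1e-8)
    fn <- objective(s, alpha, ik$Q)
    if (fn < f) {
      Qs <- ik$Q; f <- fn
    }
  }
  for (iter in seq_len(max_iter)) {
    Hqq <- vector("list", nf); Hqx <- vector("list", nf)
    gq <- vector("list", nf)
    Hxx <- crossprod(rbind(cbind(W, matrix(0, nrow(W), n_axis))))
    gx <- c(crossprod(W, drop(W %*% (s - prior$mean))), rep(0, n_axis))
    for (ti in seq_len(nf)) {
      mj <- cpp_marker_jac(skel$compiled, s, Qs[ti, ], p)
      fk <- cpp_fk(skel$compiled, s, Qs[ti, ])
      pres <- mo$present[frames[ti], ]
      idx <- which(rep(pres, each = 3))
      r <- wd *
        (as.vector(t(mj$x)) - as.vector(t(mo$xobs[frames[ti], , ])))[idx]
      Jq <- wd * mj$Jq[idx, , drop = FALSE]
      Jx <- cbind(wd * mj$Js[idx, , drop = FALSE],
                  matrix(0, length(idx), n_axis))
      for (k in seq_along(geometry)) {
        gi <- match(ti, geo_at[[k]]$frames)
        if (is.na(gi)) next
        seg <- jidx[k]
        anc <- fk$dof_anchor[, skel$dof0[seg] + 1]
        ct <- geo_at[[k]]$centers[gi, ]
        # the anchor is fixed to the PARENT segment
        Jq_a <- if (skel$parent[seg] >= 0)
          point_jac(fk, skel$parent[seg] + 1L, anc)
        else matrix(0, 3, nq)
        dA <- anchor_scale_jac(skel, s, Qs[ti, ], seg)
        r2 <- anc - ct
        Jx2 <- cbind(dA, matrix(0, 3, n_axis))
        if (modes[k] == "axis") {
          ai <- match(k, ax_ids)
          av <- geo_at[[k]]$axis[gi, ]
          r2 <- r2 - alpha[ai] * av
          Jx2[, nsd + ai] <- -av
        }
        r <- c(r, sw * r2)
        Jq <- rbind(Jq, sw * Jq_a)
        Jx <- rbind(Jx, sw * Jx2)
      }
      Hqq[[ti]] <- crossprod(Jq)
      Hqx[[ti]] <- crossprod(Jq, Jx)
      gq[[ti]] <- crossprod(Jq, r)
      Hxx <- Hxx + crossprod(Jx)
      gx <- gx + crossprod(Jx, r)
    }
    accepted <- FALSE
    for (kk in 1:12) {
      Hs <- Hxx; gs <- gx
      chols <- vector("list", nf)
      ok <- TRUE
      for (ti in seq_len(nf)) {
        Hd <- Hqq[[ti]] + lambda * (diag(diag(Hqq[[ti]])) +
                                      1e-10 * diag(nq))
        ch <- tryCatch(chol(Hd), error = function(e) NULL)
        if (is.null(ch)) { ok <- FALSE; break }
        W1 <- backsolve(ch, forwardsolve(t(ch), Hqx[[ti]]))
        Hs <- Hs - crossprod(Hqx[[ti]], W1)
        gs <- gs - crossprod(Hqx[[ti]],
                             backsolve(ch, forwardsolve(t(ch), gq[[ti]])))
        chols[[ti]] <- ch
      }
      dx <- if (ok) tryCatch(
        solve(Hs + lambda * (diag(diag(Hs)) + 1e-10 * diag(nx)), -gs),
        error = function(e) NULL) else NULL
      if (!is.null(dx)) {
        sn <- s + dx[seq_len(nsd)]
        an <- alpha + dx[-seq_len(nsd)]
        Qn <- Qs
        for (ti in seq_len(nf)) {
          rhs <- -(gq[[ti]] + Hqx[[ti]] %*% dx)
          Qn[ti, ] <- Qs[ti, ] +
            drop(backsolve(chols[[ti]],
                           forwardsolve(t(chols[[ti]]), rhs)))
        }
        fn <- objective(sn, an, Qn)
        if (is.finite(fn) && fn <= f) {
          conv <- (f - fn) < 1e-10 * (1 + f)
          s <- sn; alpha <- an; Qs <- Qn; f <- fn
          lambda <- max(lambda / 5, 1e-10)
          accepted <- if (conv) "converged" else TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (identical(accepted, "converged") || isFALSE(accepted)) break
  }
  }
  names(alpha) <- names(geometry)[ax_ids]
  list(s = s, alpha = alpha, q_sub = Qs, frames = frames)
}

# Per-axis scale estimates from mean distances between estimated joint
# centers. Two cases per pair of estimated joints: a chain (one joint's
# child segment carries the other joint) measures that segment's scaled
# parent offset; siblings under a common parent measure the scaled offset
# difference. Only offsets dominated by a single axis are used.
joint_distance_scales <- function(skel, geometry, jidx) {
  est_idx <- list(); est_val <- list()
  add <- function(seg, vec_model, dist_obs) {
    ax <- which.max(abs(vec_model))
    if (abs(vec_model[ax]) < 0.9 * sqrt(sum(vec_model^2)) ||
        abs(vec_model[ax]) < 1e-6)
      return()
    est_idx[[length(est_idx) + 1]] <<- 3L * (seg - 1L) + ax
    est_val[[length(est_val) + 1]] <<- dist_obs / abs(vec_model[ax])
  }
  # distance between the estimated joint loci: point-point for two
  # sphere fits, point-to-line / line-to-line when an axis fit leaves
  # the center free along its axis
  mean_dist <- function(g1, g2) {
    common <- intersect(g1$frames, g2$frames)
    if (length(common) < 10) return(NA_real_)
    i1 <- match(common, g1$frames); i2 <- match(common, g2$frames)
    d <- vapply(seq_along(common), function(k) {
      p1 <- g1$centers[i1[k], ]; p2 <- g2$centers[i2[k], ]
      a1 <- if (!is.null(g1$axis)) g1$axis[i1[k], ]
      a2 <- if (!is.null(g2$axis)) g2$axis[i2[k], ]
      v <- p2 - p1
      if (is.null(a1) && is.null(a2)) return(sqrt(sum(v^2)))
      if (!is.null(a1) && !is.null(a2)) {
        n <- cross3(a1, a2)
        if (sqrt(sum(n^2)) > 0.2) # genuinely skew lines
          return(abs(sum(v * n)) / sqrt(sum(n^2)))
        a2 <- NULL # near-parallel: fall through to point-line
      }
      a <- if (!is.null(a1)) a1 else a2
      sqrt(max(sum(v^2) - sum(v * a)^2, 0))
    }, numeric(1))
    mean(d)
  }
  rep_axis <- function(g) {
    if (is.null(g$axis)) return(NULL)
    a <- colMeans(g$axis)
    a / sqrt(sum(a^2))
  }
  # the projected distance only measures the offset component
  # perpendicular to any involved axis, so require near-orthogonality
  ortho_ok <- function(vec, ga, gb) {
    u <- vec / sqrt(sum(vec^2))
    all(vapply(list(rep_axis(ga), rep_axis(gb)), function(a)
      is.null(a) || abs(sum(u * a)) < 0.3, logical(1)))
  }
  n <- length(geometry)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      sa <- jidx[a]; sb <- jidx[b] # child segment index of each joint
      if (skel$parent[sb] + 1L == sa) {
        # chain: joint b hangs off joint a's child segment sa
        vec <- skel$poff[, sb]
        if (sum(vec^2) > 0 && ortho_ok(vec, geometry[[a]],
                                       geometry[[b]])) {
          d <- mean_dist(geometry[[a]], geometry[[b]])
          if (!is.na(d)) add(sa, vec, d)
        }
      } else if (b > a && skel$parent[sa] == skel$parent[sb] &&
                 skel$parent[sa] >= 0) {
        vec <- skel$poff[, sa] - skel$poff[, sb]
        if (sum(vec^2) > 0 && ortho_ok(vec, geometry[[a]],
                                       geometry[[b]])) {
          d <- mean_dist(geometry[[a]], geometry[[b]])
          if (!is.na(d)) add(skel$parent[sa] + 1L, vec, d)
        }
      }
    }
  }
  if (!length(est_idx))
    return(list(idx = integer(0), value = numeric(0)))
  idx <- unlist(est_idx); val <- unlist(est_val)
  agg <- tapply(val, idx, mean)
  list(idx = as.integer(names(agg)), value = as.numeric(agg))
}

# d(anchor of segment seg's joint)/ds: origin derivative of the parent
# plus the scaled parent offset direction
anchor_scale_jac <- function(skel, s, q, seg) {
  # reuse marker machinery: anchor = parent origin + Rp (sp * poff)
  # = origin derivative of a virtual marker at poff on the parent; for the
  # root (no parent) the anchor does not depend on s
  pidx <- skel$parent[seg] + 1L
  if (pidx == 0) return(matrix(0, 3, skel$scale_dim))
  ps <- fk_origin_scale_jac(skel, s, q)
  dA <- ps[[pidx]]
  fkx <- cpp_fk(skel$compiled, s, q)
  Rp <- fkx$R[, , pidx]
  for (ax in 1:3)
    dA[, 3 * (pidx - 1) + ax] <- dA[, 3 * (pidx - 1) + ax] +
      Rp[, ax] * skel$poff[ax, seg]
  dA
}

# per-segment 3 x scale_dim origin sensitivities (R-side mirror of the
# C++ dO propagation), cached per call
fk_origin_scale_jac <- function(skel, s, q) {
  fkx <- cpp_fk(skel$compiled, s, q)
  ns <- n_segments(skel)
  out <- vector("list", ns)
  for (i in seq_len(ns)) {
    p <- skel$parent[i] + 1L
    dO <- if (p > 0) out[[p]] else matrix(0, 3, skel$scale_dim)
    if (p > 0) {
      Rp <- fkx$R[, , p]
      for (ax in 1:3)
        dO[, 3 * (p - 1) + ax] <- dO[, 3 * (p - 1) + ax] +
          Rp[, ax] * skel$poff[ax, i]
    }
    Ri <- fkx$R[, , i]
    for (ax in 1:3)
      dO[, 3 * (i - 1) + ax] <- dO[, 3 * (i - 1) + ax] -
        Ri[, ax] * skel$coff[ax, i]
    out[[i]] <- dO
  }
  out
}

subsample_traj <- function(traj, frames) {
  marker_trajectories(traj$labels,
                      traj$frames[frames, , , drop = FALSE],
                      traj$present[frames, , drop = FALSE],
                      rate = traj$rate, time = traj$time[frames])
}

# ---- bilevel MAP ----------------------------------------------------------

#' Noise model of the MAP objective
#'
#' Gaussian SDs defining the relative weights of the marker data term and
#' the marker-offset priors: marker observation SD 1 cm; anatomical
#' marker offsets 5 mm (they are placed on bony landmarks and should
#' barely move); tracking marker offsets 5 cm (placed anywhere on the
#' segment).
#'
#' @param sigma_marker marker observation SD, m.
#' @param sigma_p_anat,sigma_p_track offset prior SDs, m.
#' @return list of the three SDs.
#' @export
map_weights <- function(sigma_marker = 0.01, sigma_p_anat = 0.005,
                        sigma_p_track = 0.05) {
  list(sigma_marker = sigma_marker, sigma_p_anat = sigma_p_anat,
       sigma_p_track = sigma_p_track)
}

map_objective <- function(skel, prior, mo, s, p, Q, w) {
  T <- nrow(Q)
  data_term <- 0
  for (t in seq_len(T)) {
    X <- cpp_markers(skel$compiled, s, Q[t, ], p)
    pres <- mo$present[t, ]
    d <- X[pres, , drop = FALSE] - mo$xobs[t, pres, ]
    data_term <- data_term + sum(d^2)
  }
  Sinv <- solve(prior$cov)
  ds <- s - prior$mean
  sig_p <- ifelse(skel$anatomical, w$sigma_p_anat, w$sigma_p_track)
  dp <- sweep(p - skel$pbar, 2, sig_p, "/")
  0.5 * data_term / w$sigma_marker^2 +
    0.5 * drop(t(ds) %*% Sinv %*% ds) + 0.5 * sum(dp^2)
}

#' Bilevel MAP fit of scales, marker registrations and kinematics
#'
#' Maximizes the posterior of (s, p, q_1:T) given marker observations:
#' a Gaussian marker likelihood (the weighted inverse-kinematics data
#' term), the anthropometric scale prior and a Gaussian marker-offset
#' prior that constrains anatomical markers much more tightly than
#' tracking markers. The bilevel structure -- poses are themselves the
#' argmin of the inner IK problem -- is enforced by exact block-coordinate
#' descent: each outer iteration re-solves the per-frame inner IK to
#' stationarity and then takes damped Gauss-Newton steps in (s, p) that
#' can only decrease the full objective. At the solution, the per-frame
#' gradient of the data term with respect to each pose (the inner-problem
#' stationarity condition) is below `grad_tol`.
#'
#' @param skel a [skeleton()].
#' @param prior a [scaling_prior()] (conditioned if metadata is known).
#' @param traj a [marker_trajectories()].
#' @param s0,p0,q0 initialization (Steps 1-3); `q0` may be `NULL` to run
#'   IK internally.
#' @param weights noise model from [map_weights()]: marker SD 1 cm,
#'   anatomical offset SD 5 mm, tracking offset SD 5 cm by default.
#' @param max_outer maximum outer Gauss-Newton iterations.
#' @param grad_tol stationarity tolerance for the inner IK gradient.
#' @param verbose print objective per outer iteration.
#' @return object of class `kinematic_fit`: `s`, `p`, `Q`, `dt`,
#'   `marker_rmse`, `marker_max`, `stationarity_norm`, `objective`,
#'   `objective_history`, `report` (see [marker_error_report()]).
#' @export
bilevel_map_fit <- function(skel, prior, traj, s0, p0, q0 = NULL,
                            weights = map_weights(), max_outer = 30,
                            grad_tol = 1e-6, verbose = FALSE) {
  mo <- traj_to_model_order(skel, traj)
  T <- n_frames(traj)
  s <- s0; p <- p0
  ik <- init_poses(skel, s, p, traj, q_init = q0, grad_tol = 1e-10)
  Q <- ik$Q
  w <- weights
  f <- map_objective(skel, prior, mo, s, p, Q, w)
  f_init <- f
  hist <- f
  Sinv <- solve(prior$cov)
  sig_p <- ifelse(skel$anatomical, w$sigma_p_anat, w$sigma_p_track)
  nsd <- skel$scale_dim
  nq <- skel$nq
  M <- length(skel$marker_labels)
  nx <- nsd + 3 * M
  lambda <- 1e-6
  for (outer in seq_len(max_outer)) {
    # One joint Gauss-Newton step over (s, p, q_1:T): the per-frame pose
    # blocks are eliminated by a Schur complement (variable projection),
    # so the reduced system has only the nx = 27 + 3M global unknowns.
    Hqq <- vector("list", T); Hqx <- vector("list", T)
    gq <- vector("list", T)
    Hxx <- matrix(0, nx, nx); gx <- numeric(nx)
    for (t in seq_len(T)) {
      mj <- cpp_marker_jac(skel$compiled, s, Q[t, ], p)
      pres <- mo$present[t, ]
      idx <- which(rep(pres, each = 3))
      if (!length(idx)) { Hqq[[t]] <- NULL; next }
      r <- (as.vector(t(mj$x)) - as.vector(t(mo$xobs[t, , ])))[idx] /
        w$sigma_marker
      Jq <- mj$Jq[idx, , drop = FALSE] / w$sigma_marker
      Jx <- matrix(0, length(idx), nx)
      Jx[, seq_len(nsd)] <- mj$Js[idx, , drop = FALSE] / w$sigma_marker
      row <- 0
      for (i in which(pres)) {
        b <- skel$marker_seg[i] + 1L
        sb <- s[(3 * b - 2):(3 * b)]
        Jx[row + 1:3, nsd + 3 * (i - 1) + 1:3] <-
          mj$R[, , i] %*% diag(sb) / w$sigma_marker
        row <- row + 3
      }
      Hqq[[t]] <- crossprod(Jq)
      Hqx[[t]] <- crossprod(Jq, Jx)
      gq[[t]] <- crossprod(Jq, r)
      Hxx <- Hxx + crossprod(Jx)
      gx <- gx + crossprod(Jx, r)
    }
    # priors on s and p
    Hxx[seq_len(nsd), seq_len(nsd)] <-
      Hxx[seq_len(nsd), seq_len(nsd)] + Sinv
    gx[seq_len(nsd)] <- gx[seq_len(nsd)] + drop(Sinv %*% (s - prior$mean))
    dp_pr <- sweep(p - skel$pbar, 2, sig_p, "/")
    for (i in seq_len(M)) {
      ii <- nsd + 3 * (i - 1) + 1:3
      Hxx[ii, ii] <- Hxx[ii, ii] + diag(1 / sig_p[i]^2, 3)
      gx[ii] <- gx[ii] + dp_pr[, i] / sig_p[i]
    }
    accepted <- FALSE
    for (k in 1:12) {
      Hs <- Hxx; gs <- gx
      dq_parts <- vector("list", T)
      ok <- TRUE
      for (t in seq_len(T)) {
        if (is.null(Hqq[[t]])) next
        Hd <- Hqq[[t]] + lambda * (diag(diag(Hqq[[t]])) +
                                     1e-10 * diag(nq))
        ch <- tryCatch(chol(Hd), error = function(e) NULL)
        if (is.null(ch)) { ok <- FALSE; break }
        W1 <- backsolve(ch, forwardsolve(t(ch), Hqx[[t]]))
        w1g <- backsolve(ch, forwardsolve(t(ch), gq[[t]]))
        Hs <- Hs - crossprod(Hqx[[t]], W1)
        gs <- gs - crossprod(Hqx[[t]], w1g)
        dq_parts[[t]] <- list(ch = ch)
      }
      dx <- if (ok) tryCatch(
        solve(Hs + lambda * (diag(diag(Hs)) + 1e-10 * diag(nx)), -gs),
        error = function(e) NULL) else NULL
      if (!is.null(dx)) {
        sn <- s + dx[seq_len(nsd)]
        pn <- p + matrix(dx[-seq_len(nsd)], 3, M)
        Qn <- Q
        for (t in seq_len(T)) {
          if (is.null(Hqq[[t]])) next
          rhs <- -(gq[[t]] + Hqx[[t]] %*% dx)
          ch <- dq_parts[[t]]$ch
          Qn[t, ] <- Q[t, ] + drop(backsolve(ch, forwardsolve(t(ch), rhs)))
        }
        fn <- map_objective(skel, prior, mo, sn, pn, Qn, w)
        if (is.finite(fn) && fn <= f) {
          conv <- (f - fn) < 1e-9 * (1 + f)
          s <- sn; p <- pn; Q <- Qn; f <- fn
          lambda <- max(lambda / 5, 1e-10)
          accepted <- TRUE
          if (conv) accepted <- "converged"
          break
        }
      }
      lambda <- lambda * 10
    }
    hist <- c(hist, f)
    if (verbose) message("outer ", outer, ": objective ", signif(f, 8))
    if (identical(accepted, "converged") || isFALSE(accepted)) break
  }
  # restore exact inner-IK stationarity; the warm-started per-frame IK
  # only ever decreases the data term, hence the full objective
  ik <- init_poses(skel, s, p, traj, q_init = Q, grad_tol = 1e-10)
  Q <- ik$Q
  f <- map_objective(skel, prior, mo, s, p, Q, w)
  hist <- c(hist, f)
  rep <- marker_error_report(skel, s, p, Q, traj)
  structure(list(s = s, p = p, Q = Q, dt = 1 / traj$rate,
                 marker_rmse = rep$rmse, marker_max = rep$max,
                 stationarity_norm = max(ik$grad_norms),
                 objective = f, objective_init = f_init,
                 objective_history = hist, report = rep,
                 flagged = ik$flagged),
            class = "kinematic_fit")
}

#' @export
print.kinematic_fit <- function(x, ...) {
  cat("kinematic_fit:", nrow(x$Q), "frames | marker RMSE",
      signif(x$marker_rmse * 100, 3), "cm | max",
      signif(x$marker_max * 100, 3), "cm | stationarity",
      signif(x$stationarity_norm, 2), "\n")
  invisible(x)
}

#' Marker error report
#'
#' RMSE over all present marker-frames, the maximum per-marker-frame
#' distance, and a per-marker breakdown.
#'
#' @param skel a [skeleton()].
#' @param s,p,Q fitted scales, offsets and poses.
#' @param traj the observed [marker_trajectories()].
#' @return list with `rmse`, `max`, `per_marker` (data frame with label,
#'   rmse, max, n).
#' @export
marker_error_report <- function(skel, s, p, Q, traj) {
  mo <- traj_to_model_order(skel, traj)
  T <- nrow(Q)
  M <- length(skel$marker_labels)
  X <- cpp_markers_traj(skel$compiled, s, Q, p)
  sq <- matrix(NA_real_, T, M)
  for (i in seq_len(M)) {
    d2 <- (X[, 3 * i - 2] - mo$xobs[, i, 1])^2 +
      (X[, 3 * i - 1] - mo$xobs[, i, 2])^2 +
      (X[, 3 * i] - mo$xobs[, i, 3])^2
    d2[!mo$present[, i]] <- NA
    sq[, i] <- d2
  }
  all_sq <- sq[!is.na(sq)]
  per <- data.frame(
    label = skel$marker_labels,
    rmse = vapply(seq_len(M), function(i)
      sqrt(mean(sq[, i], na.rm = TRUE)), numeric(1)),
    max = vapply(seq_len(M), function(i) {
      v <- sq[, i][!is.na(sq[, i])]
      if (length(v)) sqrt(max(v)) else NA_real_
    }, numeric(1)),
    n = colSums(!is.na(sq)))
  list(rmse = sqrt(mean(all_sq)), max = sqrt(max(all_sq)),
       per_marker = per)
}
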