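#' @title Functional joint geometry from marker motion
#' @description
#' A joint's center of rotation (and, for hinge-like joints, its axis) can
#' be estimated from the relative motion of markers on the two adjacent
#' segments, before any model scaling is known. The center is
#' parameterized as a fixed point of the parent-segment frame -- built per
#' frame from the parent markers by rigid (Kabsch) registration -- and the
#' child markers are required to keep a constant distance (sphere fit) or
#' constant axial/radial offsets (axis fit) from it. The axis fit is the
#' strictly more demanding problem; when it succeeds its line constraint
#' is preferred over the point constraint when initializing segment
#' scales, because purely sagittal marker motion leaves the sphere-fit
#' center unidentifiable along the plane normal.
#' @name joint_geometry
NULL

# Rigid registration (Kabsch): returns R, d with  moving ~ R %*% fixed + d
kabsch <- function(fixed, moving) {
  cf <- colMeans(fixed); cm <- colMeans(moving)
  H <- t(sweep(fixed, 2, cf)) %*% sweep(moving, 2, cm)
  sv <- svd(H)
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  list(R = R, d = cm - R %*% cf)
}

# Parent-frame coordinates of child markers across frames.
# Returns per-frame parent pose (R_t, d_t) and child marker coords y.
parent_frame_coords <- function(traj, parent_markers, child_markers,
                                min_frames = 30) {
  ip <- match(parent_markers, traj$labels)
  ic <- match(child_markers, traj$labels)
  if (anyNA(ip) || anyNA(ic)) stop("marker group labels not in trajectory")
  if (length(ip) < 3) stop("need at least 3 parent markers")
  ok <- rowSums(!traj$present[, ip, drop = FALSE]) == 0
  frames <- which(ok)
  if (length(frames) < min_frames)
    stop("only ", length(frames), " frames with all parent markers ",
         "visible; need ", min_frames)
  ref <- traj$frames[frames[1], ip, , drop = TRUE]
  Rlist <- vector("list", length(frames))
  dlist <- matrix(0, length(frames), 3)
  y <- array(NA_real_, c(length(frames), length(ic), 3))
  for (k in seq_along(frames)) {
    t <- frames[k]
    kb <- kabsch(ref, traj$frames[t, ip, , drop = TRUE])
    Rlist[[k]] <- kb$R; dlist[k, ] <- kb$d
    for (j in seq_along(ic)) {
      if (traj$present[t, ic[j]]) {
        y[k, j, ] <- t(kb$R) %*% (traj$frames[t, ic[j], ] - kb$d)
      }
    }
  }
  list(frames = frames, R = Rlist, d = dlist, y = y,
       child_markers = child_markers)
}

#' Closed-form functional joint centers
#'
#' Deterministic linear least-squares center-of-rotation estimate: in the
#' parent-attached frame every child marker keeps a constant distance r_i
#' from the (fixed) center c, giving the linear system
#' `2 y' c + (r_i^2 - |c|^2) = |y|^2` in `c` and one scalar per marker.
#' Used purely as the initial guess for [sphere_fit()].
#'
#' @param traj a [marker_trajectories()].
#' @param parent_markers,child_markers labels of the markers on the two
#'   segments adjacent to the joint (>= 3 parent markers).
#' @param min_frames minimum number of co-visible frames (default 30).
#' @return list with `c_local` (center, parent frame), `centers` (T_used x
#'   3 world trajectory), `r` (per child marker), `frames` (frame indices
#'   used) and `cond` (conditioning of the normal equations).
#' @export
closed_form_centers <- function(traj, parent_markers, child_markers,
                                min_frames = 30) {
  pf <- parent_frame_coords(traj, parent_markers, child_markers, min_frames)
  nm <- length(child_markers)
  rows <- list(); rhs <- c()
  for (j in seq_len(nm)) {
    yj <- pf$y[, j, , drop = TRUE]
    vis <- !is.na(yj[, 1])
    yj <- yj[vis, , drop = FALSE]
    if (nrow(yj) < min_frames) next
    blk <- matrix(0, nrow(yj), 3 + nm)
    blk[, 1:3] <- 2 * yj
    blk[, 3 + j] <- 1
    rows[[length(rows) + 1]] <- blk
    rhs <- c(rhs, rowSums(yj^2))
  }
  if (!length(rows)) stop("no child marker with enough co-visible frames")
  A <- do.call(rbind, rows)
  keep <- c(rep(TRUE, 3), colSums(abs(A[, -(1:3), drop = FALSE])) > 0)
  A <- A[, keep, drop = FALSE]
  sv <- svd(A)
  cond <- sv$d[1] / sv$d[length(sv$d)]
  tiny <- sv$d < 1e-8 * sv$d[1]
  # one unconstrained direction is the hinge ambiguity (center can slide
  # along the axis): keep the minimum-norm solution and let the axis fit
  # resolve it; more than one dead direction means no usable motion
  if (sum(tiny) > 1 || !is.finite(cond))
    stop("rank-deficient center-of-rotation system ",
         "(markers static relative to the parent?)")
  keep_sv <- !tiny
  sol <- sv$v[, keep_sv, drop = FALSE] %*%
    ((t(sv$u[, keep_sv, drop = FALSE]) %*% rhs) / sv$d[keep_sv])
  c_local <- sol[1:3]
  k <- rep(NA_real_, nm)
  k[which(keep[-(1:3)])] <- sol[-(1:3)]
  r <- sqrt(pmax(k + sum(c_local^2), 0))
  centers <- t(vapply(seq_along(pf$frames), function(t)
    drop(pf$R[[t]] %*% c_local + pf$d[t, ]), numeric(3)))
  list(c_local = c_local, centers = centers, r = r, frames = pf$frames,
       cond = cond, pf = pf)
}

# Gauss-Newton/LM driver for small dense problems.
gn_lm <- function(x0, resid_fn, jac_fn, max_iter = 60, tol = 1e-12,
                  lambda0 = 1e-6) {
  x <- x0
  r <- resid_fn(x)
  f <- sum(r^2)
  lambda <- lambda0
  converged <- FALSE
  history <- f
  for (it in seq_len(max_iter)) {
    J <- jac_fn(x)
    g <- crossprod(J, r)
    H <- crossprod(J)
    improved <- FALSE
    for (k in 1:12) {
      step <- tryCatch(solve(H + lambda * diag(diag(H) + 1e-12), -g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        xn <- x + drop(step)
        rn <- resid_fn(xn)
        fn <- sum(rn^2)
        if (is.finite(fn) && fn <= f) {
          x <- xn; r <- rn
          improved <- TRUE
          conv <- (f - fn) < tol * (1 + f)
          f <- fn
          lambda <- max(lambda / 3, 1e-10)
          history <- c(history, f)
          if (conv) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!improved || converged) {
      converged <- converged || !improved
      break
    }
  }
  list(x = x, f = f, converged = converged, history = history,
       H = crossprod(jac_fn(x)))
}

#' Moving-sphere refinement of a functional joint center
#'
#' Nonlinear least squares on the residuals `|y_t(i) - c| - r_i` (parent
#' frame), initialized from [closed_form_centers()]. The fixed
#' parent-frame center maps to a per-frame world center trajectory.
#'
#' @inheritParams closed_form_centers
#' @param init result of [closed_form_centers()]; computed when `NULL`.
#' @return list with fields `c_local`, `centers`, `r`, `residual` (RMS of
#'   the per-term errors, m), `cond` (conditioning of the center block of
#'   the Gauss-Newton Hessian), `converged`, `history` (objective values,
#'   non-increasing), `frames`.
#' @export
sphere_fit <- function(traj, parent_markers, child_markers, init = NULL,
                       min_frames = 30) {
  if (is.null(init))
    init <- closed_form_centers(traj, parent_markers, child_markers,
                                min_frames)
  pf <- init$pf
  nm <- dim(pf$y)[2]
  obs <- list()
  for (j in seq_len(nm)) {
    yj <- pf$y[, j, , drop = TRUE]
    vis <- !is.na(yj[, 1])
    obs[[j]] <- yj[vis, , drop = FALSE]
  }
  nobs <- vapply(obs, nrow, integer(1))
  use <- which(nobs >= min_frames)
  r0 <- init$r[use]
  r0[!is.finite(r0)] <- 0.1
  x0 <- c(init$c_local, r0)
  resid <- function(x) {
    cc <- x[1:3]; r <- x[-(1:3)]
    unlist(lapply(seq_along(use), function(k) {
      d <- sqrt(rowSums(sweep(obs[[use[k]]], 2, cc)^2))
      d - r[k]
    }))
  }
  jac <- function(x) {
    cc <- x[1:3]
    do.call(rbind, lapply(seq_along(use), function(k) {
      dv <- sweep(obs[[use[k]]], 2, cc)
      d <- sqrt(rowSums(dv^2))
      J <- matrix(0, length(d), 3 + length(use))
      J[, 1:3] <- -dv / d
      J[, 3 + k] <- -1
      J
    }))
  }
  fit <- gn_lm(x0, resid, jac)
  # conditioning of the center after eliminating the radii (Schur
  # complement): a hinge leaves the center free along the axis because
  # the radii can compensate, which only the reduced Hessian exposes
  Hc <- fit$H[1:3, 1:3] -
    fit$H[1:3, -(1:3), drop = FALSE] %*%
    solve(fit$H[-(1:3), -(1:3), drop = FALSE],
          fit$H[-(1:3), 1:3, drop = FALSE])
  ev <- eigen(Hc, symmetric = TRUE, only.values = TRUE)$values
  cond <- ev[1] / max(ev[3], .Machine$double.eps)
  cc <- fit$x[1:3]
  centers <- t(vapply(seq_along(pf$frames), function(t)
    drop(pf$R[[t]] %*% cc + pf$d[t, ]), numeric(3)))
  rms <- sqrt(fit$f / length(resid(fit$x)))
  list(c_local = cc, centers = centers, r = fit$x[-(1:3)],
       residual = rms, cond = cond, converged = fit$converged,
       history = fit$history, frames = pf$frames, pf = pf, use = use)
}

sph_dir <- function(ang) {
  c(cos(ang[1]) * cos(ang[2]), cos(ang[1]) * sin(ang[2]), sin(ang[1]))
}

#' Joint axis fit
#'
#' Decomposes each child-marker offset from the center into components
#' parallel and perpendicular to a (parent-frame constant, hence
#' per-frame world) axis direction and requires both to be constant over
#' time: residuals `a'(y - c) - u_i` and `|(y - c) - a a'(y - c)| - v_i`,
#' with the axis constrained to unit norm via a spherical-angle
#' parameterization. Succeeds on hinge-like motion; genuinely spherical
#' motion leaves a clearly larger residual, which
#' [classify_joint_geometry()] uses to fall back to the sphere fit.
#'
#' @inheritParams sphere_fit
#' @param sphere result of [sphere_fit()]; computed when `NULL`.
#' @return list with `c_local`, `a_local`, `centers`, `axis` (T_used x 3
#'   unit world vectors, sign-canonicalized), `u`, `v`, `residual` (RMS,
#'   m), `converged`, `frames`.
#' @export
axis_fit <- function(traj, parent_markers, child_markers, sphere = NULL,
                     min_frames = 30) {
  if (is.null(sphere))
    sphere <- sphere_fit(traj, parent_markers, child_markers,
                         min_frames = min_frames)
  pf <- sphere$pf
  use <- sphere$use
  obs <- lapply(use, function(j) {
    yj <- pf$y[, j, , drop = TRUE]
    yj[!is.na(yj[, 1]), , drop = FALSE]
  })
  # axis init: pooled per-marker-centered covariance has least variance
  # along the hinge axis
  Cv <- matrix(0, 3, 3)
  for (o in obs) Cv <- Cv + crossprod(sweep(o, 2, colMeans(o)))
  a0 <- eigen(Cv, symmetric = TRUE)$vectors[, 3]
  ang0 <- c(asin(max(-1, min(1, a0[3]))), atan2(a0[2], a0[1]))
  cc0 <- sphere$c_local
  u0 <- vapply(obs, function(o) mean(sweep(o, 2, cc0) %*% a0), numeric(1))
  v0 <- vapply(seq_along(obs), function(k) {
    d <- sweep(obs[[k]], 2, cc0)
    par <- drop(d %*% a0)
    mean(sqrt(pmax(rowSums(d^2) - par^2, 0)))
  }, numeric(1))
  nmu <- length(use)
  x0 <- c(cc0, ang0, u0, v0)
  unpack <- function(x) list(cc = x[1:3], a = sph_dir(x[4:5]),
                             u = x[5 + seq_len(nmu)],
                             v = x[5 + nmu + seq_len(nmu)])
  resid <- function(x) {
    z <- unpack(x)
    unlist(lapply(seq_along(obs), function(k) {
      d <- sweep(obs[[k]], 2, z$cc)
      par <- drop(d %*% z$a)
      perp <- sqrt(pmax(rowSums(d^2) - par^2, 1e-30))
      c(par - z$u[k], perp - z$v[k])
    }))
  }
  jac <- function(x) {
    z <- unpack(x)
    phi <- x[4]; psi <- x[5]
    da_dphi <- c(-sin(phi) * cos(psi), -sin(phi) * sin(psi), cos(phi))
    da_dpsi <- c(-cos(phi) * sin(psi), cos(phi) * cos(psi), 0)
    do.call(rbind, lapply(seq_along(obs), function(k) {
      d <- sweep(obs[[k]], 2, z$cc)
      nr <- nrow(d)
      par <- drop(d %*% z$a)
      perp <- sqrt(pmax(rowSums(d^2) - par^2, 1e-30))
      J1 <- matrix(0, nr, length(x))
      J1[, 1:3] <- matrix(-z$a, nr, 3, byrow = TRUE)
      J1[, 4] <- d %*% da_dphi
      J1[, 5] <- d %*% da_dpsi
      J1[, 5 + k] <- -1
      J2 <- matrix(0, nr, length(x))
      # perp^2 = d'd - par^2  =>  d(perp)/dc = (-d + par a)/perp
      w <- (d - outer(par, z$a)) / perp
      J2[, 1:3] <- -w
      J2[, 4] <- -(par / perp) * drop(d %*% da_dphi)
      J2[, 5] <- -(par / perp) * drop(d %*% da_dpsi)
      J2[, 5 + nmu + k] <- -1
      rbind(J1, J2)
    }))
  }
  fit <- gn_lm(x0, resid, jac, max_iter = 80)
  z <- unpack(fit$x)
  centers <- t(vapply(seq_along(pf$frames), function(t)
    drop(pf$R[[t]] %*% z$cc + pf$d[t, ]), numeric(3)))
  axis <- t(vapply(seq_along(pf$frames), function(t)
    drop(pf$R[[t]] %*% z$a), numeric(3)))
  # canonical sign: keep positive continuity with the previous frame,
  # overall sign so the dominant component of frame 1 is positive
  if (axis[1, which.max(abs(axis[1, ]))] < 0) axis <- -axis
  rms <- sqrt(fit$f / length(resid(fit$x)))
  list(c_local = z$cc, a_local = z$a, centers = centers, axis = axis,
       u = z$u, v = z$v, residual = rms, converged = fit$converged,
       frames = pf$frames)
}

#' Estimate and classify the functional geometry of one joint
#'
#' Runs [closed_form_centers()], [sphere_fit()] and [axis_fit()] and
#' classifies the joint: `"axis"` when the axis fit succeeds (residual
#' within `max(tol_abs, tol_ratio x sphere residual)`), `"sphere"` when
#' only the sphere fit converged, `"none"` when the geometry is degenerate
#' (e.g. static markers or too little relative motion).
#'
#' @inheritParams sphere_fit
#' @param joint_name label carried into the report.
#' @param tol_abs absolute axis-success threshold on the RMS residual
#'   (default 1 mm).
#' @param tol_ratio relative threshold against the sphere residual
#'   (default 1.5).
#' @return object of class `joint_geometry_estimate`: fields `joint_name`,
#'   `mode`, `centers`, `axis`, `r`, `u`, `v`, `sphere_residual`,
#'   `axis_residual`, `frames`, `cond`.
#' @export
estimate_joint_geometry <- function(traj, joint_name, parent_markers,
                                    child_markers, min_frames = 30,
                                    tol_abs = 1e-3, tol_ratio = 1.5) {
  est <- list(joint_name = joint_name, mode = "none", centers = NULL,
              axis = NULL, r = NULL, u = NULL, v = NULL,
              sphere_residual = Inf, axis_residual = Inf, frames = NULL,
              cond = Inf)
  sph <- tryCatch(sphere_fit(traj, parent_markers, child_markers,
                             min_frames = min_frames),
                  error = function(e) e)
  if (inherits(sph, "error")) {
    est$error <- conditionMessage(sph)
    class(est) <- "joint_geometry_estimate"
    return(est)
  }
  est$centers <- sph$centers
  est$r <- sph$r
  est$sphere_residual <- sph$residual
  est$frames <- sph$frames
  est$cond <- sph$cond
  ax <- tryCatch(axis_fit(traj, parent_markers, child_markers, sphere = sph,
                          min_frames = min_frames),
                 error = function(e) NULL)
  if (!is.null(ax)) {
    est$axis_residual <- ax$residual
    if (ax$converged && ax$residual <= max(tol_abs,
                                           tol_ratio * sph$residual)) {
      est$mode <- "axis"
      est$centers <- ax$centers
      est$axis <- ax$axis
      est$u <- ax$u; est$v <- ax$v
    }
  }
  if (est$mode == "none" && sph$converged && is.finite(sph$cond) &&
      sph$cond < 1e6)
    est$mode <- "sphere"
  class(est) <- "joint_geometry_estimate"
  est
}

#' Classify an existing joint geometry estimate
#'
#' @param est a `joint_geometry_estimate`.
#' @param tol_abs,tol_ratio thresholds as in [estimate_joint_geometry()].
#' @return `"axis"`, `"sphere"` or `"none"`.
#' @export
classify_joint_geometry <- function(est, tol_abs = 1e-3, tol_ratio = 1.5) {
  if (!is.finite(est$sphere_residual)) return("none")
  if (is.finite(est$axis_residual) &&
      est$axis_residual <= max(tol_abs, tol_ratio * est$sphere_residual) &&
      !is.null(est$axis))
    return("axis")
  if (is.finite(est$cond) && est$cond < 1e6) return("sphere")
  "none"
}

#' @export
print.joint_geometry_estimate <- function(x, ...) {
  cat("joint", x$joint_name, "- mode:", x$mode,
      "| sphere RMS:", signif(x$sphere_residual, 3), "m",
      "| axis RMS:", signif(x$axis_residual, 3), "m\n")
  invisible(x)
}

#' Write joint geometry estimates to a JSON diagnostics report
#' @param ests list of `joint_geometry_estimate` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_joint_geometry_json <- function(ests, path) {
  doc <- lapply(ests, function(e) list(
    joint = e$joint_name, mode = e$mode,
    sphere_residual = e$sphere_residual,
    axis_residual = if (is.finite(e$axis_residual)) e$axis_residual else NULL,
    radii = e$r,
    centers = if (!is.null(e$centers)) apply(e$centers, 1, c,
                                             simplify = FALSE) else NULL,
    axis = if (!is.null(e$axis)) apply(e$axis, 1, c,
                                       simplify = FALSE) else NULL))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
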