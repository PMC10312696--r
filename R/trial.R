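#' Bundle marker, force-plate and subject data for one trial
#'
#' @param markers a [marker_trajectories()].
#' @param plates list of [force_plate()] records (may be empty for
#'   kinematics-only processing).
#' @param meta list with optional `height` (m), `weight` (kg), `sex`
#'   (`"male"`/`"female"`).
#' @return object of class `trial_data`.
#' @export
trial_data <- function(markers, plates = list(), meta = list()) {
  structure(list(markers = markers, plates = plates, meta = meta),
            class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  cat("trial_data:", dim(x$markers$frames)[1], "marker frames at",
      x$markers$rate, "Hz;", length(x$plates), "force plate(s)\n")
  invisible(x)
}

# ---- zero-phase Butterworth ----------------------------------------------

#' Butterworth low-pass coefficients
#'
#' Bilinear-transform design of an order-`n` digital Butterworth low-pass.
#'
#' @param n filter order.
#' @param cutoff_hz cutoff frequency, Hz.
#' @param rate_hz sampling rate, Hz.
#' @return list with numerator `b` and denominator `a`.
#' @export
butter_lowpass <- function(n, cutoff_hz, rate_hz) {
  stopifnot(cutoff_hz > 0, cutoff_hz < rate_hz / 2)
  fs2 <- 2 * rate_hz
  wc <- fs2 * tan(pi * cutoff_hz / rate_hz) # pre-warped analog cutoff
  k <- seq_len(n)
  poles_a <- wc * exp(1i * pi * (2 * k + n - 1) / (2 * n))
  poles_z <- (fs2 + poles_a) / (fs2 - poles_a)
  a <- Re(poly_from_roots(poles_z))
  b <- choose(n, 0:n) # (z + 1)^n
  b <- b * sum(a) / sum(b) # unit DC gain
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  p <- 1
  for (rk in r) p <- c(p, 0) - c(0, p * rk)
  p
}

iir_filter <- function(b, a, x) {
  # direct-form ARMA: a[1] y_t = sum b x - sum a[-1] y; the AR pass is
  # started at its steady state for x[1] so constants pass unchanged
  b <- b / a[1]; a <- a / a[1]
  u <- as.numeric(stats::filter(c(rep(x[1], length(b) - 1), x), b,
                                method = "convolution", sides = 1))
  u <- u[-seq_len(length(b) - 1)]
  if (length(a) > 1) {
    y_ss <- u[1] / (1 + sum(a[-1]))
    u <- as.numeric(stats::filter(u, -a[-1], method = "recursive",
                                  init = rep(y_ss, length(a) - 1)))
  }
  u
}

#' Zero-phase filtering (forward-backward)
#'
#' Applies the filter forward and backward with odd reflection padding, so
#' the pass is phase-free and edge transients are suppressed.
#'
#' @param b,a filter coefficients from [butter_lowpass()].
#' @param x signal vector.
#' @return filtered signal, same length.
#' @export
filtfilt_zero <- function(b, a, x) {
  np <- 3 * (max(length(a), length(b)) - 1)
  np <- min(np, length(x) - 1)
  pre <- 2 * x[1] - x[seq(np + 1, 2)]
  post <- 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - np)]
  xp <- c(pre, x, post)
  y <- iir_filter(b, a, xp)
  y <- rev(iir_filter(b, a, rev(y)))
  y[seq(np + 1, np + length(x))]
}

lin_resample <- function(t_in, y, t_out) {
  stats::approx(t_in, y, xout = t_out, rule = 2)$y
}

#' Synchronize force-plate streams onto the marker clock
#'
#' Force plates typically sample at 1000-2000 Hz while markers run at
#' 100-200 Hz. Each plate channel is low-pass filtered (zero-phase
#' Butterworth) and linearly resampled onto the marker timestamps; after
#' this step every stream in the trial shares the marker `dt`, which is
#' the integration step of all downstream dynamics fitting. When plate and
#' marker rates already match, the data pass through untouched.
#'
#' @param trial a [trial_data()].
#' @param cutoff_hz low-pass cutoff for force channels (default 15 Hz).
#' @param order Butterworth order (default 4).
#' @return a new [trial_data()] with plates resampled to the marker rate.
#' @export
synchronize <- function(trial, cutoff_hz = 15, order = 4) {
  mk <- trial$markers
  if (!length(trial$plates)) return(trial)
  t_out <- mk$time
  plates <- lapply(trial$plates, function(pl) {
    if (abs(pl$rate - mk$rate) < 1e-9) return(pl)
    if (pl$rate < mk$rate)
      stop("plate rate below marker rate; cannot synchronize")
    if (max(pl$time) < min(t_out) || min(pl$time) > max(t_out))
      stop("non-overlapping time ranges between plates and markers")
    co <- butter_lowpass(order, cutoff_hz, pl$rate)
    smooth_rs <- function(Y) {
      out <- sapply(seq_len(ncol(Y)), function(j)
        lin_resample(pl$time, filtfilt_zero(co$b, co$a, Y[, j]), t_out))
      matrix(out, length(t_out), ncol(Y))
    }
    # COP is resampled without filtering: it is a quotient of filtered
    # quantities and jumps at contact changes would smear across frames
    cop_rs <- sapply(1:3, function(j)
      lin_resample(pl$time, pl$cop[, j], t_out))
    force_plate(pl$plate_id, pl$corners, smooth_rs(pl$force),
                smooth_rs(pl$moment), matrix(cop_rs, length(t_out), 3),
                mk$rate, time = t_out)
  })
  trial_data(mk, plates, trial$meta)
}

point_in_polygon_xz <- function(pt, corners) {
  # ray casting in the horizontal (x, z) plane
  x <- pt[1]; z <- pt[3]
  xs <- corners[, 1]; zs <- corners[, 3]
  n <- length(xs)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((zs[i] > z) != (zs[j] > z) &&
        x < (xs[j] - xs[i]) * (z - zs[i]) / (zs[j] - zs[i]) + xs[i])
      inside <- !inside
    j <- i
  }
  inside
}

#' Assign plate loads to feet
#'
#' For every frame and plate whose force magnitude exceeds the threshold,
#' the plate wrench is assigned to the foot segment that is in ground
#' contact over that plate: the foot origin projects inside the plate
#' polygon (horizontal plane) and sits below `contact_height`. If no foot
#' projects inside, the nearest contacting foot takes the load. Two feet
#' over the same loaded plate violate the one-foot-per-plate assumption
#' and raise an error.
#'
#' @param trial synchronized [trial_data()].
#' @param skel a [skeleton()] whose `foot_segments` are named.
#' @param s scale vector.
#' @param Q T x nq pose trajectory (marker rate).
#' @param foot_segments character vector of foot segment names.
#' @param force_threshold minimum force magnitude (N) treated as contact.
#' @param contact_height maximum foot-origin height (m) treated as ground
#'   contact.
#' @return list with `wrenches` (per foot: T x 6 matrix of world force and
#'   moment about the world origin) and `assignment` (T x n_plates matrix
#'   of foot indices, 0 = unloaded).
#' @export
assign_forces_to_feet <- function(trial, skel, s, Q, foot_segments,
                                  force_threshold = 10,
                                  contact_height = 0.12) {
  feet <- match(foot_segments, skel$seg_names)
  if (anyNA(feet)) stop("unknown foot segment(s): ",
                        paste(foot_segments[is.na(feet)], collapse = ", "))
  T <- nrow(Q)
  np <- length(trial$plates)
  foot_pos <- array(0, c(T, length(feet), 3))
  for (t in seq_len(T)) {
    fk <- cpp_fk(skel$compiled, s, Q[t, ])
    foot_pos[t, , ] <- fk$o[feet, , drop = FALSE]
  }
  wrenches <- lapply(seq_along(feet), function(i) matrix(0, T, 6))
  assignment <- matrix(0L, T, np)
  for (k in seq_len(np)) {
    pl <- trial$plates[[k]]
    fn <- sqrt(rowSums(pl$force^2))
    for (t in seq_len(T)) {
      if (fn[t] <= force_threshold) next
      inside <- vapply(seq_along(feet), function(i) {
        pos <- foot_pos[t, i, ]
        pos[2] <= contact_height && point_in_polygon_xz(pos, pl$corners)
      }, logical(1))
      if (sum(inside) > 1)
        stop("two feet in contact with plate ", pl$plate_id,
             " at frame ", t,
             ": violates the one-foot-per-plate assumption")
      if (sum(inside) == 1) {
        foot <- which(inside)
      } else {
        # fallback: the load is applied where the plate measures it, so
        # take the foot horizontally nearest the centre of pressure
        d <- vapply(seq_along(feet), function(i)
          sum((foot_pos[t, i, c(1, 3)] - pl$cop[t, c(1, 3)])^2),
          numeric(1))
        foot <- which.min(d)
      }
      w <- wrench_at_point(pl$force[t, ], pl$cop[t, ], pl$moment[t, ])
      wrenches[[foot]][t, ] <- wrenches[[foot]][t, ] + w
      assignment[t, k] <- foot
    }
  }
  list(wrenches = wrenches, assignment = assignment,
       foot_segments = foot_segments)
}

# external-wrench cube (6 x ns x T) for the inverse-dynamics trajectory
ext_cube <- function(skel, foot_wrenches, foot_segments) {
  feet <- match(foot_segments, skel$seg_names)
  T <- nrow(foot_wrenches[[1]])
  ext <- array(0, c(6, n_segments(skel), T))
  for (i in seq_along(feet))
    ext[, feet[i], ] <- t(foot_wrenches[[i]])
  ext
}
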