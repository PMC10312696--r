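#' Marker trajectory container
#'
#' @param labels character vector of marker labels.
#' @param frames T x M x 3 array of world positions, metres.
#' @param present T x M logical mask; `FALSE` marks occluded marker-frames
#'   whose coordinates must never be read.
#' @param rate capture rate, Hz.
#' @param time optional explicit time stamps (seconds).
#' @return object of class `marker_trajectories`.
#' @export
marker_trajectories <- function(labels, frames, present = NULL, rate,
                                time = NULL) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[2] == length(labels),
            dim(frames)[3] == 3, rate > 0)
  T <- dim(frames)[1]
  if (is.null(present)) present <- !apply(is.na(frames), c(1, 2), any)
  stopifnot(dim(present) == c(T, length(labels)))
  frames[rep(!present, 3)] <- NA_real_
  if (is.null(time)) time <- (seq_len(T) - 1) / rate
  structure(list(labels = labels, frames = frames, present = present,
                 rate = rate, time = time),
            class = "marker_trajectories")
}

#' @export
print.marker_trajectories <- function(x, ...) {
  cat("marker_trajectories:", dim(x$frames)[1], "frames,",
      length(x$labels), "markers at", x$rate, "Hz;",
      round(100 * mean(!x$present), 1), "% occluded\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$frames)[1]

#' Read a TRC marker file
#'
#' Standard tab-delimited TRC: a 5-line header carrying `DataRate`,
#' `NumMarkers`, `Units` and the marker labels, then one row per frame of
#' `Frame#`, `Time` and X/Y/Z triples. Blank cells become masked
#' (occluded) marker-frames. Positions are converted to metres.
#'
#' @param path file path.
#' @return a [marker_trajectories()].
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6) stop("malformed TRC: too short")
  hd_keys <- strsplit(lines[2], "\t")[[1]]
  hd_vals <- strsplit(lines[3], "\t")[[1]]
  hd <- setNames(as.list(hd_vals), hd_keys)
  if (is.null(hd$DataRate) || is.null(hd$Units))
    stop("malformed TRC header: DataRate/Units missing")
  rate <- as.numeric(hd$DataRate)
  unit <- hd$Units
  scale <- switch(unit, mm = 1e-3, cm = 1e-2, m = 1,
                  stop("unknown TRC units: ", unit))
  lab_row <- strsplit(lines[4], "\t")[[1]]
  labels <- lab_row[seq(3, length(lab_row))]
  labels <- labels[labels != ""]
  M <- length(labels)
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[trimws(data_lines) != ""]
  T <- length(data_lines)
  frames <- array(NA_real_, c(T, M, 3))
  for (t in seq_len(T)) {
    cells <- strsplit(data_lines[t], "\t", fixed = TRUE)[[1]]
    need <- 2 + 3 * M
    if (length(cells) < need) cells <- c(cells, rep("", need - length(cells)))
    vals <- suppressWarnings(as.numeric(cells[3:need]))
    frames[t, , ] <- matrix(vals, M, 3, byrow = TRUE)
  }
  marker_trajectories(labels, frames * scale, rate = rate)
}

#' Write a TRC marker file
#'
#' Inverse of [read_trc()]; positions are written in the requested units
#' and masked marker-frames become blank cells, so a write/read round trip
#' is lossless for present values.
#'
#' @param traj a [marker_trajectories()].
#' @param path output path.
#' @param units `"mm"` or `"m"`.
#' @return `path`, invisibly.
#' @export
write_trc <- function(traj, path, units = "mm") {
  scale <- switch(units, mm = 1e3, cm = 1e2, m = 1,
                  stop("unknown TRC units: ", units))
  T <- n_frames(traj); M <- length(traj$labels)
  l1 <- paste("PathFileType", 4, "(X/Y/Z)", basename(path), sep = "\t")
  l2 <- paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
              "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames",
              sep = "\t")
  l3 <- paste(traj$rate, traj$rate, T, M, units, traj$rate, 1, T, sep = "\t")
  l4 <- paste(c("Frame#", "Time",
                as.vector(rbind(traj$labels, "", ""))), collapse = "\t")
  l5 <- paste(c("", "", paste0(rep(c("X", "Y", "Z"), M),
                               rep(seq_len(M), each = 3))), collapse = "\t")
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.8f", v))
  rows <- vapply(seq_len(T), function(t) {
    xyz <- t(traj$frames[t, , , drop = TRUE])
    if (M == 1) xyz <- matrix(traj$frames[t, 1, ], 3, 1)
    cells <- fmt(as.vector(xyz) * scale)
    paste(c(t, sprintf("%.6f", traj$time[t]), cells), collapse = "\t")
  }, character(1))
  writeLines(c(l1, l2, l3, l4, l5, rows), path)
  invisible(path)
}

# ---- MOT (tab-delimited, nRows/nColumns/endheader) -----------------------

read_mot_table <- function(path) {
  lines <- readLines(path)
  end <- which(trimws(lines) == "endheader")
  if (!length(end)) stop("malformed MOT: no endheader")
  hdr <- lines[seq_len(end[1] - 1)]
  in_deg <- any(grepl("^inDegrees\\s*=\\s*yes", hdr))
  cols <- strsplit(lines[end[1] + 1], "\t")[[1]]
  body <- lines[-seq_len(end[1] + 1)]
  body <- body[trimws(body) != ""]
  dat <- matrix(as.numeric(unlist(strsplit(body, "\t", fixed = TRUE))),
                nrow = length(body), byrow = TRUE)
  colnames(dat) <- cols
  list(data = dat, in_degrees = in_deg)
}

write_mot_table <- function(dat, path, name = "mocapfit",
                            in_degrees = FALSE) {
  hdr <- c(name,
           "version=1",
           paste0("nRows=", nrow(dat)),
           paste0("nColumns=", ncol(dat)),
           paste0("inDegrees=", if (in_degrees) "yes" else "no"),
           "endheader",
           paste(colnames(dat), collapse = "\t"))
  rows <- apply(dat, 1, function(r) paste(sprintf("%.10g", r),
                                          collapse = "\t"))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a coordinate (joint angle or torque) MOT file
#'
#' Rotational coordinates are written in degrees (`inDegrees=yes`), the
#' common convention for motion files; translational coordinates stay in
#' metres. Torque files are written as-is in N m / N.
#'
#' @param time time stamps, s.
#' @param Q T x n matrix of values.
#' @param names column names (DOF names).
#' @param rotational logical vector marking rotational columns.
#' @param path output path.
#' @param kind `"coordinates"` (angles, converted to degrees) or
#'   `"torques"` (written unconverted).
#' @return `path`, invisibly.
#' @export
write_mot_coords <- function(time, Q, names, rotational, path,
                             kind = c("coordinates", "torques")) {
  kind <- match.arg(kind)
  out <- Q
  in_deg <- FALSE
  if (kind == "coordinates") {
    out[, rotational] <- out[, rotational, drop = FALSE] * 180 / pi
    in_deg <- TRUE
  }
  dat <- cbind(time = time, out)
  colnames(dat) <- c("time", names)
  write_mot_table(dat, path, name = kind, in_degrees = in_deg)
}

#' Read a coordinate MOT file
#'
#' @param path file path.
#' @param rotational logical vector (per non-time column) marking
#'   rotational coordinates; when the file declares `inDegrees=yes` those
#'   columns are converted back to radians. Default: all columns whose name
#'   does not end in `_tx`/`_ty`/`_tz`.
#' @return list with `time` and `Q` (columns named).
#' @export
read_mot_coords <- function(path, rotational = NULL) {
  mt <- read_mot_table(path)
  dat <- mt$data
  tcol <- which(colnames(dat) == "time")[1]
  Q <- dat[, -tcol, drop = FALSE]
  if (is.null(rotational))
    rotational <- !grepl("_t[xyz]$", colnames(Q))
  if (mt$in_degrees)
    Q[, rotational] <- Q[, rotational, drop = FALSE] * pi / 180
  list(time = dat[, tcol], Q = Q)
}

logical_rotational_dofs <- function(skel) {
  rot <- rep(TRUE, skel$nq)
  for (i in seq_along(skel$jtype))
    if (skel$jtype[i] == 0L) rot[skel$dof0[i] + 1:3] <- FALSE
  rot
}

#' Rotational-DOF mask for a skeleton
#' @param skel a [skeleton()].
#' @return logical vector of length `skel$nq`, `TRUE` for rotational DOFs.
#' @export
rotational_dofs <- function(skel) logical_rotational_dofs(skel)

#' Force-plate record
#'
#' @param plate_id identifier.
#' @param corners 4 x 3 matrix of corner positions (m, lab frame); must be
#'   coplanar to within 1 mm.
#' @param force,moment,cop T_f x 3 matrices (N, N m, m). `moment` is the
#'   free moment (couple) reported by the plate; the point of application
#'   is `cop`.
#' @param rate sampling rate, Hz.
#' @param time optional time stamps.
#' @return object of class `force_plate`.
#' @export
force_plate <- function(plate_id, corners, force, moment, cop, rate,
                        time = NULL) {
  corners <- matrix(as.numeric(corners), 4, 3)
  # coplanarity: distance of 4th corner from plane of first three
  n <- cross3(corners[2, ] - corners[1, ], corners[3, ] - corners[1, ])
  n <- n / sqrt(sum(n^2))
  d <- abs(sum((corners[4, ] - corners[1, ]) * n))
  if (d > 1e-3) stop("plate corners not coplanar (", signif(d, 3), " m)")
  stopifnot(nrow(force) == nrow(moment), nrow(force) == nrow(cop), rate > 0)
  if (is.null(time)) time <- (seq_len(nrow(force)) - 1) / rate
  structure(list(plate_id = plate_id, corners = corners, force = force,
                 moment = moment, cop = cop, rate = rate, time = time),
            class = "force_plate")
}

#' Read a ground-reaction-force MOT file
#'
#' Expects a tab-delimited MOT table with a monotone `time` column and,
#' per plate, nine channels following the common ground-reaction naming
#' scheme: `<prefix>_v[xyz]` force, `<prefix>_p[xyz]` centre of pressure
#' and a matching torque triple (`<prefix>_m[xyz]` or the
#' `..._torque_[xyz]` variant). Units are normalised to N, N m and m using
#' the declarations in `plate_config`.
#'
#' @param path file path.
#' @param plate_config plate geometry configuration: a list (or path to a
#'   JSON file) with element `plates`, one entry per plate carrying `id`
#'   and `corners` (4 x 3), plus optional `cop_units` (`"m"`/`"mm"`),
#'   `force_units`, `torque_units`.
#' @return list of [force_plate()] records, in `plates` order.
#' @export
read_grf_mot <- function(path, plate_config) {
  cfg <- load_plate_config(plate_config)
  mt <- read_mot_table(path)
  dat <- mt$data
  cols <- colnames(dat)
  if (!"time" %in% cols) stop("GRF MOT missing time column")
  tv <- dat[, "time"]
  if (any(diff(tv) <= 0)) stop("non-monotone time column in GRF file")
  rate <- 1 / stats::median(diff(tv))
  prefixes <- sub("_vx$", "", grep("_vx$", cols, value = TRUE))
  if (length(prefixes) < length(cfg$plates))
    stop("GRF file has ", length(prefixes), " force channel groups but ",
         length(cfg$plates), " plates configured")
  cop_scale <- unit_scale(cfg$cop_units %||% "m", "length")
  f_scale <- unit_scale(cfg$force_units %||% "N", "force")
  t_scale <- unit_scale(cfg$torque_units %||% "Nm", "torque")
  lapply(seq_along(cfg$plates), function(k) {
    pre <- prefixes[k]
    grab <- function(nms) {
      miss <- setdiff(nms, cols)
      if (length(miss)) stop("missing GRF columns: ",
                             paste(miss, collapse = ", "))
      dat[, nms, drop = FALSE]
    }
    force <- grab(paste0(pre, "_v", c("x", "y", "z"))) * f_scale
    cop <- grab(paste0(pre, "_p", c("x", "y", "z"))) * cop_scale
    tor_pre <- if (all(paste0(pre, "_m", c("x", "y", "z")) %in% cols))
      paste0(pre, "_m", c("x", "y", "z"))
    else paste0(sub("force", "torque", pre), "_", c("x", "y", "z"))
    moment <- grab(tor_pre) * t_scale
    pl <- cfg$plates[[k]]
    force_plate(pl$id %||% k, pl$corners, force, moment, cop, rate,
                time = tv)
  })
}

#' Write a ground-reaction-force MOT file
#' @param plates list of [force_plate()] records sharing time stamps.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grf_mot <- function(plates, path) {
  tv <- plates[[1]]$time
  blocks <- lapply(seq_along(plates), function(k) {
    pl <- plates[[k]]
    d <- cbind(pl$force, pl$cop, pl$moment)
    colnames(d) <- c(paste0("ground_force_", k, "_v", c("x", "y", "z")),
                     paste0("ground_force_", k, "_p", c("x", "y", "z")),
                     paste0("ground_force_", k, "_m", c("x", "y", "z")))
    d
  })
  dat <- cbind(time = tv, do.call(cbind, blocks))
  write_mot_table(dat, path, name = "ground reaction forces")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unit_scale <- function(u, what) {
  tab <- list(length = c(m = 1, mm = 1e-3, cm = 1e-2),
              force = c(N = 1, kN = 1e3),
              torque = c(Nm = 1, Nmm = 1e-3, "N-m" = 1))
  sc <- tab[[what]][u]
  if (is.na(sc)) stop("unknown ", what, " unit: ", u)
  unname(sc)
}

#' Load (or pass through) a plate geometry configuration
#'
#' Plate geometry lives in a small JSON file: `{"plates": [{"id": 1,
#' "corners": [[x,y,z] x 4]}, ...], "cop_units": "m", ...}`.
#'
#' @param cfg a list or a JSON file path.
#' @return normalized list with `plates` entries holding 4 x 3 corner
#'   matrices.
#' @export
load_plate_config <- function(cfg) {
  if (is.character(cfg)) cfg <- jsonlite::fromJSON(cfg,
                                                   simplifyVector = FALSE)
  stopifnot(is.list(cfg), !is.null(cfg$plates))
  cfg$plates <- lapply(cfg$plates, function(p) {
    if (!is.matrix(p$corners))
      p$corners <- matrix(unlist(p$corners), 4, 3, byrow = TRUE)
    p
  })
  cfg
}

#' Write a plate geometry configuration to JSON
#' @param cfg configuration list as in [load_plate_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_plate_config <- function(cfg, path) {
  cfg$plates <- lapply(cfg$plates, function(p) {
    p$corners <- lapply(seq_len(nrow(p$corners)),
                        function(i) p$corners[i, ])
    p
  })
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
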