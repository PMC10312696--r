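#' Pipeline configuration
#'
#' Collects the inputs and every tunable constant of the sequential
#' pipeline in one validated list. Paths may be replaced by in-memory
#' objects (a [skeleton()] / [trial_data()]).
#'
#' @param skeleton skeleton JSON path, OpenSim path, or a [skeleton()].
#' @param trc TRC path or a [marker_trajectories()].
#' @param grf GRF MOT path or a list of [force_plate()]s (optional for
#'   kinematics-only runs).
#' @param plates plate geometry JSON path or config list (required with
#'   `grf` paths).
#' @param prior a [scaling_prior()], or `NULL` to use the synthetic one.
#' @param meta subject metadata list (`height`, `weight`, `sex`).
#' @param out_dir output directory (`NULL`: no files written).
#' @param foot_segments names of the foot segments.
#' @param skeleton_format `"native_json"` or `"osim_subset"`.
#' @param kinematics_only skip all dynamics stages.
#' @param force_threshold_n,cutoff_hz,contact_height force assignment and
#'   synchronization settings.
#' @param tracking_weight jerk-smoothing tracking weight.
#' @param sigma_force,sigma_torque residual penalty SDs (N, N m).
#' @param root_fit_tol,root_fit_max_iter root angular fit settings.
#' @param map_max_outer,final_max_outer outer iteration caps.
#' @param weights marker/offset noise model ([map_weights()]).
#' @param seed RNG seed for any stochastic component.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(skeleton, trc, grf = NULL, plates = NULL,
                            prior = NULL, meta = list(), out_dir = NULL,
                            foot_segments = c("foot_r", "foot_l"),
                            skeleton_format = "native_json",
                            kinematics_only = FALSE,
                            force_threshold_n = 10, cutoff_hz = 15,
                            contact_height = 0.12, tracking_weight = 1,
                            sigma_force = 1, sigma_torque = 1,
                            root_fit_tol = 1e-6, root_fit_max_iter = 100,
                            map_max_outer = 30, final_max_outer = 10,
                            weights = map_weights(), seed = 1) {
  cfg <- as.list(environment())
  if (!kinematics_only && is.null(grf))
    stop("dynamics requested but no GRF input given ",
         "(set kinematics_only = TRUE for marker-only processing)")
  if (is.character(grf) && is.null(plates))
    stop("GRF path given without plate geometry config")
  class(cfg) <- "pipeline_config"
  cfg
}

resolve_inputs <- function(config) {
  skel <- config$skeleton
  if (is.character(skel))
    skel <- load_skeleton(skel, config$skeleton_format)
  traj <- config$trc
  if (is.character(traj)) traj <- read_trc(traj)
  plates <- NULL
  if (!config$kinematics_only) {
    plates <- config$grf
    if (is.character(plates))
      plates <- read_grf_mot(plates, config$plates)
  }
  prior <- config$prior
  if (is.null(prior)) prior <- synthetic_scaling_prior(skel)
  list(skel = skel, traj = traj, plates = plates, prior = prior)
}

# marker groups (parent/child labels) for every joint with enough markers
joint_marker_groups <- function(skel, min_parent = 3, min_child = 1) {
  out <- list()
  for (i in seq_along(skel$joint_names)) {
    if (skel$parent[i] < 0) next
    pm <- skel$marker_labels[skel$marker_seg == skel$parent[i]]
    cm <- skel$marker_labels[skel$marker_seg == (i - 1L)]
    if (length(pm) >= min_parent && length(cm) >= min_child)
      out[[skel$joint_names[i]]] <- list(parent = pm, child = cm)
  }
  out
}

#' Run the scaling / registration / inverse-kinematics stage
#'
#' Executes, in order: functional joint-center and axis estimation from
#' the raw marker motion; scale initialization against the estimated
#' geometry; per-frame inverse kinematics; and the bilevel MAP fit of
#' scales, registrations and poses. When an output directory is
#' configured, writes the optimized skeleton JSON, the joint-angle MOT
#' file and a JSON report.
#'
#' @param config a [pipeline_config()].
#' @return list of class `kinematics_run`: the `fit` (a
#'   `kinematic_fit`), `skel`, `prior` (conditioned), `geometry`,
#'   `timing` (seconds per stage), `paths`.
#' @export
run_kinematics <- function(config) {
  set.seed(config$seed)
  inp <- resolve_inputs(config)
  skel <- inp$skel; traj <- inp$traj
  timing <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  prior <- condition_prior(inp$prior, height = config$meta$height,
                           weight = config$meta$weight,
                           sex = config$meta$sex)
  groups <- joint_marker_groups(skel)
  geometry <- lapply(names(groups), function(jn)
    estimate_joint_geometry(traj, jn, groups[[jn]]$parent,
                            groups[[jn]]$child))
  names(geometry) <- names(groups)
  timing["joint_geometry"] <- tic() - t0

  t0 <- tic()
  p0 <- init_marker_offsets(skel)
  sc <- init_scales(skel, geometry, traj, p0, prior)
  timing["init_scales"] <- tic() - t0

  t0 <- tic()
  ik <- init_poses(skel, sc$s, p0, traj)
  timing["init_poses"] <- tic() - t0

  t0 <- tic()
  fit <- bilevel_map_fit(skel, prior, traj, sc$s, p0, ik$Q,
                         weights = config$weights,
                         max_outer = config$map_max_outer)
  timing["bilevel_map"] <- tic() - t0

  paths <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      model = file.path(config$out_dir, "model_scaled.json"),
      angles = file.path(config$out_dir, "joint_angles.mot"),
      geometry = file.path(config$out_dir, "joint_geometry.json"),
      report = file.path(config$out_dir, "kinematics_report.json"))
    save_skeleton(skel, paths$model, s = fit$s, p = fit$p)
    write_mot_coords(traj$time, fit$Q, skel$dof_names,
                     rotational_dofs(skel), paths$angles)
    write_joint_geometry_json(geometry, paths$geometry)
    jsonlite::write_json(
      list(marker_rmse_m = fit$marker_rmse, marker_max_m = fit$marker_max,
           stationarity_norm = fit$stationarity_norm,
           objective = fit$objective, timing_s = as.list(timing)),
      paths$report, auto_unbox = TRUE, digits = NA)
  }
  structure(list(fit = fit, skel = skel, prior = prior,
                 geometry = geometry, traj = traj, timing = timing,
                 paths = paths, config = config),
            class = "kinematics_run")
}

#' Run the dynamics (residual reduction) stage
#'
#' Continues from a kinematics run: synchronizes the force plates onto
#' the marker clock, smooths the joint trajectories by minimum jerk,
#' assigns plate loads to feet, fits total mass and the COM trajectory
#' linearly, iterates the linearized root angular fit, and finishes with
#' the residual-minimizing optimization of masses, scales, registrations
#' and root kinematics. Writes joint torques, residual series and a
#' pass/fail summary when an output directory is configured.
#'
#' @param config a [pipeline_config()].
#' @param kin optional result of [run_kinematics()] (run inline when
#'   omitted).
#' @return list of class `dynamics_run`: `fit` (a `dynamics_fit`),
#'   `root_fit` (iterations/convergence), `com_fit`, `report`
#'   (residual pass/fail), `timing`, `paths`.
#' @export
run_dynamics <- function(config, kin = NULL) {
  if (config$kinematics_only)
    stop("config requests kinematics only")
  if (is.null(kin)) kin <- run_kinematics(config)
  skel <- kin$skel
  fit <- kin$fit
  timing <- kin$timing
  tic <- function() proc.time()[["elapsed"]]
  inp <- resolve_inputs(config)
  trial <- trial_data(kin$traj, inp$plates, config$meta)

  t0 <- tic()
  trial <- synchronize(trial, cutoff_hz = config$cutoff_hz)
  dt <- fit$dt
  Q <- smooth_min_jerk(fit$Q, dt, config$tracking_weight)
  asg <- assign_forces_to_feet(trial, skel, fit$s, Q,
                               config$foot_segments,
                               config$force_threshold_n,
                               config$contact_height)
  ext <- ext_cube(skel, asg$wrenches, config$foot_segments)
  timing["assign"] <- tic() - t0

  t0 <- tic()
  forces_tot <- t(apply(ext, 3, function(e) rowSums(matrix(e[1:3, ], 3))))
  sys <- build_com_system(forces_tot, dt, skel$gravity)
  Zhat <- com_trajectory(skel, fit$s, skel$mass0, Q)
  cf <- com_linear_fit(Zhat, sys$A, sys$b)
  masses <- skel$mass0 / sum(skel$mass0) * cf$mass
  Q <- apply_root_translation(Q, cf$Z, skel, fit$s, masses)
  timing["com_fit"] <- tic() - t0

  t0 <- tic()
  raf <- root_angular_fit(skel, fit$s, masses, Q, ext, dt,
                          mass = cf$mass, tol = config$root_fit_tol,
                          max_iter = config$root_fit_max_iter)
  timing["root_fit"] <- tic() - t0

  t0 <- tic()
  fin <- final_dynamics_map(skel, kin$prior, kin$traj, ext, fit$s, fit$p,
                            raf$Q, masses, m_target = cf$mass, dt = dt,
                            weights = config$weights,
                            sigma_force = config$sigma_force,
                            sigma_torque = config$sigma_torque,
                            max_outer = config$final_max_outer)
  timing["final_map"] <- tic() - t0
  rep <- residual_report(fin)

  paths <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      torques = file.path(config$out_dir, "joint_torques.mot"),
      angles = file.path(config$out_dir, "joint_angles_dynamics.mot"),
      residuals = file.path(config$out_dir, "residuals.json"),
      summary = file.path(config$out_dir, "residual_summary.txt"),
      model = file.path(config$out_dir, "model_dynamics.json"))
    write_mot_coords(kin$traj$time, fin$torques, skel$dof_names,
                     rotational_dofs(skel), paths$torques,
                     kind = "torques")
    write_mot_coords(kin$traj$time, fin$Q, skel$dof_names,
                     rotational_dofs(skel), paths$angles)
    save_skeleton(skel, paths$model, s = fin$s, p = fin$p,
                  masses = fin$masses)
    jsonlite::write_json(
      list(normalized_force_pct = fin$normalized_force_pct,
           normalized_torque_pct = fin$normalized_torque_pct,
           peak_grf_n = fin$peak_grf, com_height_m = fin$com_height,
           total_mass_kg = sum(fin$masses),
           marker_rmse_m = fin$marker_rmse,
           root_fit_iterations = raf$iterations,
           pass = rep$pass, timing_s = as.list(timing)),
      paths$residuals, auto_unbox = TRUE, digits = NA)
    writeLines(c(
      sprintf("residual force : %.4f %% of peak GRF (threshold %.1f %%) -> %s",
              rep$force_pct, rep$thresholds$force_pct,
              if (rep$force_pass) "PASS" else "FAIL"),
      sprintf("residual torque: %.4f %% of peak GRF x COM height (threshold %.1f %%) -> %s",
              rep$torque_pct, rep$thresholds$torque_pct,
              if (rep$torque_pass) "PASS" else "FAIL")),
      paths$summary)
  }
  structure(list(fit = fin, root_fit = raf, com_fit = cf, report = rep,
                 assignment = asg, kin = kin, timing = timing,
                 paths = paths),
            class = "dynamics_run")
}

#' Compare a solved trajectory against a reference
#'
#' Resamples both trajectories onto the overlapping time grid and reports
#' the RMSE per shared coordinate plus the overall mean (rotational
#' coordinates in degrees). For torque comparisons, values can be
#' normalized to percent of body weight times height.
#'
#' @param time,Q solved time stamps and T x n matrix (column names =
#'   coordinate names).
#' @param ref_time,ref_Q reference trajectory (same units; columns
#'   named).
#' @param rotational logical vector per solved column; rotational
#'   coordinates are reported in degrees.
#' @param normalize `NULL`, or `list(weight =, height =)` to report
#'   torque RMSE as % of BW x height.
#' @return list with `per_coordinate` (data frame), `mean_rmse`, and
#'   `units`.
#' @export
compare_to_reference <- function(time, Q, ref_time, ref_Q,
                                 rotational = NULL, normalize = NULL) {
  shared <- intersect(colnames(Q), colnames(ref_Q))
  if (!length(shared)) stop("no overlapping coordinates to compare")
  t0 <- max(min(time), min(ref_time))
  t1 <- min(max(time), max(ref_time))
  if (t1 <= t0) stop("no overlapping time range")
  grid <- time[time >= t0 & time <= t1]
  if (is.null(rotational))
    rotational <- setNames(!grepl("_t[xyz]$", colnames(Q)), colnames(Q))
  else rotational <- setNames(rotational, colnames(Q))
  rmse <- vapply(shared, function(nm) {
    a <- stats::approx(time, Q[, nm], grid)$y
    b <- stats::approx(ref_time, ref_Q[, nm], grid)$y
    e <- sqrt(mean((a - b)^2))
    if (!is.null(normalize))
      e <- 100 * e / (normalize$weight * 9.81 * normalize$height)
    else if (rotational[[nm]]) e <- e * 180 / pi
    e
  }, numeric(1))
  units <- if (!is.null(normalize)) "% BW x height"
  else "degrees (rotational) / m (translational)"
  list(per_coordinate = data.frame(coordinate = shared, rmse = rmse,
                                   row.names = NULL),
       mean_rmse = mean(rmse), units = units)
}
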