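# planar_dynamics: geometry, contact, ligaments, initialization, rollout.

#' Muscle-tendon geometry at a posture
#'
#' MTU lengths, lengthening velocities and moment arms at generalized
#' coordinates `q`.  Lengths are smooth (affine + quadratic) functions of
#' the spanned joint angles, and moment arms are derived analytically from
#' the same polynomials, so the tendon-excursion identity
#' `moment arm = -d(length)/d(angle)` holds exactly.
#'
#' @param model an `msk_model`.
#' @param q generalized coordinates (9): pelvis x, pelvis y, pelvis tilt,
#'   then hip/knee/ankle for the left and right leg (radians).
#' @param qdot generalized speeds (9), for MTU velocities.
#' @return list with named `length` (m), `velocity` (m/s) and an 18 x 9
#'   `moment_arm` matrix (m).
#' @export
muscle_geometry <- function(model, q, qdot = rep(0, 9)) {
  stopifnot(inherits(model, "msk_model"), length(q) == 9, length(qdot) == 9,
            all(is.finite(q)), all(is.finite(qdot)))
  out <- .gait_core_geometry(as_core_model(model), as.numeric(q), as.numeric(qdot))
  names(out$length) <- names(out$velocity) <- core_muscle_names()
  dimnames(out$moment_arm) <- list(core_muscle_names(), DOF_NAMES)
  out
}

#' Compliant sphere-ground contact force
#'
#' Hunt-Crossley normal force (Hertz elastic term scaled by
#' `1 + dissipation * depth_rate`, floored at zero) with Coulomb friction
#' smoothed across the stick/slip transition velocity by a `tanh` law, so
#' the tangential-to-normal force ratio approaches the dynamic friction
#' coefficient at high slip speed.
#'
#' @param depth penetration depth (m); non-positive depth gives zero force.
#' @param depth_rate penetration rate (m/s, positive = penetrating).
#' @param tangential_velocity slip velocity (m/s).
#' @param sphere a list or one-row data.frame with `radius`,
#'   `plane_strain_modulus`, `dissipation`, `mu_dynamic`,
#'   `transition_velocity` (as in `model$contact`).
#' @return named force vector `c(tangential, normal)` in N.
#' @export
contact_force <- function(depth, depth_rate, tangential_velocity, sphere) {
  f <- .contact_force_cpp(depth, depth_rate, tangential_velocity,
                          sphere$radius, sphere$plane_strain_modulus,
                          sphere$dissipation, sphere$mu_dynamic,
                          sphere$transition_velocity)
  c(tangential = f[1], normal = f[2])
}

#' Ligament limit torque
#'
#' Nonlinear rotational limit spring: zero torque strictly inside the
#' engagement limits, exponentially stiffening resisting torque beyond
#' them, continuous at the limit.
#'
#' @param angle joint angle (rad, vectorized).
#' @param lower,upper engagement limits (rad).
#' @param stiffness torque scale (N·m).
#' @param width exponential e-folding width (rad).
#' @return torque in N·m (sign resists the violation).
#' @export
ligament_torque <- function(angle, lower, upper, stiffness = 6,
                            width = 3 * pi / 180) {
  stopifnot(all(is.finite(angle)), lower < upper)
  vapply(angle, .ligament_torque_cpp, numeric(1), lo = lower, hi = upper,
         K = stiffness, w = width)
}

#' Initialize the skeletal and muscle state
#'
#' Builds the full simulation state from the 16 free initial-state
#' parameters: the pelvis horizontal position is fixed at 0 m, the 7 angles
#' and 9 velocities come from the parameters, and the pelvis height is
#' solved by a 1-D root find so the static vertical ground reaction force
#' equals half the model's body weight.  Muscle activations are set from
#' the controller's initial excitations and fiber lengths by fiber-tendon
#' equilibration.
#'
#' @param model an `msk_model`.
#' @param controller a `gait_controller`.
#' @param params controller parameter vector (74); default: the
#'   controller's initial values.
#' @param init16 the 16 free initial-state values; default: the
#'   controller file's `initial_state` values.
#' @return list with `state` (54), `pelvis_y`, `static_vgrf` (N).
#' @export
initialize_state <- function(model, controller, params = NULL, init16 = NULL) {
  stopifnot(inherits(model, "msk_model"), inherits(controller, "gait_controller"))
  if (is.null(params)) params <- controller_params(controller)
  if (is.null(init16)) init16 <- initial_state_values(controller)
  if (length(init16) != 16) {
    stop("argument error: expected 16 initial-state free parameters, got ",
         length(init16))
  }
  if (length(params) != 74) {
    stop("argument error: expected 74 controller parameters, got ", length(params))
  }
  .gait_core_initialize(as_core_model(model), as_core_controller(controller),
                        as.numeric(params), as.numeric(init16))
}

# trajectory channel names, matching the C++ record layout
trajectory_colnames <- function() {
  mn <- core_muscle_names()
  c("time", paste0("q_", DOF_NAMES), paste0("qd_", DOF_NAMES),
    paste0("act_", mn), paste0("lmn_", mn), paste0("u_", mn),
    paste0("fnorm_", mn), paste0("mom_", JOINT_DOFS), paste0("lig_", JOINT_DOFS),
    "grf_L_x", "grf_L_y", "grf_R_x", "grf_R_y",
    "headacc_x", "headacc_y", "edot", "com_x", "com_y",
    "phase_L", "phase_R")
}

#' Simulate a gait rollout
#'
#' Integrates the coupled skeletal, muscle and reflex-controller dynamics
#' with an adaptive embedded Runge-Kutta (Dormand-Prince 5(4)) scheme.
#' Integration stops at the desired simulation time `t_des` or as soon as
#' the whole-body center of mass drops below `fall_com_fraction` (default
#' 0.8) of its initial height, which defines a fall.  All channels (states,
#' excitations, normalized tendon forces, muscle joint moments, ligament
#' torques, per-foot ground reaction forces, head-point accelerations,
#' metabolic rate, center of mass, gait phases) are recorded and resampled
#' onto a uniform output grid.
#'
#' @param model an `msk_model`.
#' @param controller a `gait_controller`.
#' @param params controller parameter vector (74); default: initial values.
#' @param init either the 16 free initial-state values (the usual case) or
#'   a full 54-element state vector (for tests of mechanical subsystems).
#' @param t_des desired simulation time (s).
#' @param output_dt output sampling interval (s); `NA` returns the raw
#'   accepted integrator steps (useful for conservation audits).
#' @param rtol,atol integrator relative/absolute tolerances.
#' @param h_max maximum integrator step (s); kept below the shortest reflex
#'   delay so delayed signals always interpolate recorded history.
#' @param contact,muscles enable ground contact / muscle actuation.
#' @param locked_dofs integer indices (1..9) of coordinates to hold fixed
#'   (e.g. `1:3` pins the pelvis for passive-pendulum tests).
#' @param strict if `TRUE`, an integrator failure raises an error; if
#'   `FALSE` the partial trajectory is returned with
#'   `status = "integration_failure"` (used inside optimization).
#' @return a `gait_trajectory`: list with `time`, `data` (matrix of named
#'   channels), `status` (`"completed"`, `"fell"` or
#'   `"integration_failure"`), `t_end`, `t_fall`, `mass`, `output_dt`.
#' @export
simulate_gait <- function(model, controller, params = NULL, init = NULL,
                          t_des = 10, output_dt = 0.01, rtol = 1e-5,
                          atol = 1e-7, h_max = 0.004, contact = TRUE,
                          muscles = TRUE, locked_dofs = integer(0),
                          strict = TRUE) {
  stopifnot(inherits(model, "msk_model"), t_des > 0)
  if (is.null(params)) params <- controller_params(controller)
  if (is.null(init)) init <- initial_state_values(controller)
  opts <- list(t_des = as.numeric(t_des), rtol = rtol, atol = atol,
               h_max = h_max, muscles_on = muscles, contact_on = contact,
               locked_dofs = as.integer(locked_dofs))
  res <- .gait_core_rollout(as_core_model(model), as_core_controller(controller),
                            as.numeric(params), as.numeric(init), opts)
  if (res$status == "integration_failure" && strict) {
    stop("simulation error: integrator failed at t = ",
         signif(res$t_end, 6), " s (last valid state returned with strict = FALSE)")
  }
  rec <- res$records
  colnames(rec) <- trajectory_colnames()
  time <- rec[, "time"]
  if (!is.na(output_dt)) {
    grid <- seq(0, res$t_end, by = output_dt)
    if (grid[length(grid)] < res$t_end - 1e-12) grid <- c(grid, res$t_end)
    resampled <- matrix(NA_real_, nrow = length(grid), ncol = ncol(rec))
    colnames(resampled) <- colnames(rec)
    resampled[, "time"] <- grid
    const_cols <- c("phase_L", "phase_R")
    for (j in seq_len(ncol(rec))[-1]) {
      meth <- if (colnames(rec)[j] %in% const_cols) "constant" else "linear"
      resampled[, j] <- approx(time, rec[, j], xout = grid, method = meth,
                               rule = 2)$y
    }
    data <- resampled
  } else {
    data <- rec
  }
  out <- structure(list(
    time = data[, "time"], data = data, status = res$status,
    t_end = res$t_end, t_fall = res$t_fall,
    pelvis_y0 = res$pelvis_y, com0 = res$com0,
    mass = model$total_mass, gravity = model$gravity,
    basal_rate_W_kg = model$metabolics$basal_rate_W_kg %||% 1.2,
    output_dt = output_dt, t_des = t_des
  ), class = "gait_trajectory")
  attr(out, "model") <- model
  out
}

#' @export
print.gait_trajectory <- function(x, ...) {
  cat("Gait rollout:", x$status,
      sprintf("(t_end = %.3f s%s)\n", x$t_end,
              if (!is.na(x$t_fall)) sprintf(", fell at %.3f s", x$t_fall) else ""))
  cat(sprintf("  %d samples x %d channels, model mass %.2f kg\n",
              nrow(x$data), ncol(x$data), x$mass))
  d <- diff(range(x$data[, "com_x"]))
  cat(sprintf("  COM travel %.2f m, mean speed %.2f m/s\n", d,
              d / max(x$t_end, 1e-9)))
  invisible(x)
}

#' @export
plot.gait_trajectory <- function(x, channels = c("q_hip_L", "q_knee_L",
                                                 "q_ankle_L", "grf_L_y"), ...) {
  old <- par(mfrow = c(length(channels), 1), mar = c(2.5, 4, 1, 1))
  on.exit(par(old))
  for (ch in channels) {
    plot(x$time, x$data[, ch], type = "l", xlab = "", ylab = ch, ...)
  }
  invisible(x)
}

# --- motion-table (.sto dialect) I/O ----------------------------------------

#' Write a trajectory as a plain-text motion table
#'
#' OpenSim-style `.sto` dialect: a short header (`name`, `version`,
#' `nRows`, `nColumns`, `inDegrees`, `endheader`) followed by tab-separated
#' columns, time first.  Angles are written in degrees at the file
#' boundary; all internal computation is in radians.
#'
#' @param traj a `gait_trajectory` (or any matrix with a `time` column via
#'   the `data` argument).
#' @param path output file path.
#' @param name table name written in the header.
#' @return `path`, invisibly.
#' @export
write_sto <- function(traj, path, name = "reflexgait-trajectory") {
  data <- if (inherits(traj, "gait_trajectory")) traj$data else as.matrix(traj)
  out <- data
  ang <- grep("^(q|qd)_(pelvis_tilt|hip|knee|ankle)", colnames(out))
  out[, ang] <- out[, ang] * 180 / pi
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name, "version=1",
               sprintf("nRows=%d", nrow(out)),
               sprintf("nColumns=%d", ncol(out)),
               "inDegrees=yes", "endheader"), con)
  writeLines(paste(colnames(out), collapse = "\t"), con)
  writeLines(apply(out, 1, function(r) paste(sprintf("%.8g", r), collapse = "\t")),
             con)
  invisible(path)
}

#' Read a motion table written by [write_sto()]
#'
#' @param path file path.
#' @return a matrix with named columns (angles converted back to radians).
#' @export
read_sto <- function(path) {
  lines <- readLines(path)
  hend <- match("endheader", lines)
  if (is.na(hend)) stop("not a motion table: missing 'endheader' in ", path)
  indeg <- any(grepl("^inDegrees=yes", lines[1:hend]))
  header <- strsplit(lines[hend + 1], "\t", fixed = TRUE)[[1]]
  body <- lines[-seq_len(hend + 1)]
  body <- body[nzchar(body)]
  mat <- matrix(as.numeric(unlist(strsplit(body, "\t", fixed = TRUE))),
                nrow = length(body), byrow = TRUE)
  colnames(mat) <- header
  if (indeg) {
    ang <- grep("^(q|qd)_(pelvis_tilt|hip|knee|ankle)", colnames(mat))
    mat[, ang] <- mat[, ang] * pi / 180
  }
  mat
}

# --- small helpers shared by audits and metrics -----------------------------

#' Mass matrix at a posture (for energy audits)
#' @param model an `msk_model`.
#' @param q generalized coordinates (9).
#' @return the 9 x 9 joint-space mass matrix.
#' @export
mass_matrix <- function(model, q) {
  stopifnot(length(q) == 9)
  m <- .gait_core_mass_matrix(as_core_model(model), as.numeric(q))
  dimnames(m) <- list(DOF_NAMES, DOF_NAMES)
  m
}

#' Body, sphere and head-point kinematics at a state
#' @param model an `msk_model`.
#' @param q,qdot generalized coordinates and speeds (9 each).
#' @return list with `com`, `body_pos`, `body_vel`, `spheres` (world
#'   position and velocity per contact sphere), `head`.
#' @export
body_points <- function(model, q, qdot = rep(0, 9)) {
  stopifnot(length(q) == 9, length(qdot) == 9)
  .gait_core_body_points(as_core_model(model), as.numeric(q), as.numeric(qdot))
}

# trapezoidal quadrature on a possibly non-uniform grid
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2) return(0)
  sum((t[-1] - t[-n]) * (y[-1] + y[-n]) / 2)
}
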