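# Shared fixtures: cached default model/controller and synthetic builders.

.fixture_env <- new.env(parent = emptyenv())

test_model <- function() {
  if (is.null(.fixture_env$model)) .fixture_env$model <- gait_model()
  .fixture_env$model
}

test_controller <- function() {
  if (is.null(.fixture_env$controller)) .fixture_env$controller <- gait_controller()
  .fixture_env$controller
}

# minimal controller config with an arbitrary law list (full canonical
# thresholds / initial-state sections so the census machinery is exercised)
mini_controller <- function(laws, u_floor = 0) {
  pdef <- function(v) list(value = v, sd = 0.1, min = -10, max = 10)
  thresholds <- list(
    es_to_ms_dist_m = pdef(0), ps_to_s_grf_N = pdef(50),
    s_to_lp_dist_m = pdef(0.25), lp_to_es_grf_N = pdef(40))
  init_names <- c("pelvis_tilt_rad", "hip_L_rad", "knee_L_rad", "ankle_L_rad",
                  "hip_R_rad", "knee_R_rad", "ankle_R_rad", "pelvis_vx_m_s",
                  "pelvis_vy_m_s", "pelvis_tilt_vel_rad_s", "hip_L_vel_rad_s",
                  "knee_L_vel_rad_s", "ankle_L_vel_rad_s", "hip_R_vel_rad_s",
                  "knee_R_vel_rad_s", "ankle_R_vel_rad_s")
  initial_state <- setNames(lapply(init_names, function(n) pdef(0)), init_names)
  build_controller_from_config(list(
    name = "mini", u_floor = u_floor,
    initial_phase = list(left = "ES", right = "S"),
    laws = laws, thresholds = thresholds, initial_state = initial_state))
}

# neutral sensor set (all channels zero except where overridden)
mini_sensors <- function(lmn = 1, vmn = 0, fnorm = 0, theta = 0, thetadot = 0) {
  nm <- reflexgait:::core_muscle_names()
  list(lmn = setNames(rep(lmn, 18), nm), vmn = setNames(rep(vmn, 18), nm),
       fnorm = setNames(rep(fnorm, 18), nm), theta = theta, thetadot = thetadot)
}

# synthetic trajectory with caller-supplied channels; everything else zero
synth_traj <- function(time, channels = list(), mass = 75.16,
                       status = "completed", t_fall = NA_real_,
                       model = NULL) {
  cols <- reflexgait:::trajectory_colnames()
  data <- matrix(0, nrow = length(time), ncol = length(cols),
                 dimnames = list(NULL, cols))
  data[, "time"] <- time
  for (nm in names(channels)) data[, nm] <- channels[[nm]]
  out <- structure(list(
    time = time, data = data, status = status,
    t_end = max(time), t_fall = t_fall,
    mass = mass, gravity = 9.80665, basal_rate_W_kg = 1.2,
    output_dt = if (length(time) > 1) time[2] - time[1] else NA,
    t_des = max(time)), class = "gait_trajectory")
  if (!is.null(model)) attr(out, "model") <- model
  out
}

# alternating-feet square-wave GRF with strikes at known times
walking_grf <- function(time, period = 0.55, duty = 0.62, bw = 75.16 * 9.80665) {
  phase_L <- (time %% (2 * period)) / (2 * period)
  phase_R <- ((time + period) %% (2 * period)) / (2 * period)
  list(L = ifelse(phase_L < duty, 0.8 * bw, 0),
       R = ifelse(phase_R < duty, 0.8 * bw, 0))
}

# --- independent oracles (literal transcriptions, separate from R/ code) ----

# equilibrium residual, normalized by f_max
oracle_equilibrium_residual <- function(model, idx, lmn, mtu_length, activation) {
  mus <- model$muscles
  ord <- order(match(mus$side, c("L", "R")),
               match(mus$name, reflexgait:::MUSCLE_GROUPS))
  r <- mus[ord, ][idx, ]
  cv <- model$curves
  strain <- (mtu_length - lmn * r$l_opt - r$l_tendon_slack) / r$l_tendon_slack
  ft <- if (strain <= 0) 0 else {
    (exp(cv$tendon_shape_k * strain / r$tendon_strain_at_fmax) - 1) /
      (exp(cv$tendon_shape_k) - 1)
  }
  fl <- exp(log(0.05) * abs((lmn - 1) / cv$active_fl_width)^3)
  fp <- if (lmn <= 1) 0 else {
    r$passive_curve_scale * (exp(cv$passive_kpe * (lmn - 1) /
                                 cv$passive_strain_at_one) - 1) /
      (exp(cv$passive_kpe) - 1)
  }
  activation * fl + fp - ft
}

# Umberger-family metabolic rate (W), literal transcription
oracle_metabolic_rate <- function(a, u, lmn, v, fmax, lopt, vmax = 15,
                                  ft = 0.5, w_act = 0.45,
                                  sigma = 250000, rho = 1059.7) {
  mass <- fmax / sigma * rho * lopt
  A <- if (u > a) u else (u + a) / 2
  A_am <- A^0.6
  A_s <- A^2
  fl <- exp(log(0.05) * abs((lmn - 1) / w_act)^3)
  hb <- 128 * ft + 25
  h_am <- if (lmn > 1) hb * A_am * (0.4 + 0.6 * fl) else hb * A_am
  vmax_st <- vmax / 2.5
  a_st <- 100 / vmax_st; a_ft <- 153 / vmax; a_len <- 0.3 * a_st
  scale_l <- if (lmn > 1) fl else 1
  h_sl <- if (v <= 0) {
    -v * (a_st * (1 - ft) + a_ft * ft) * A_s * scale_l
  } else {
    v * a_len * A * scale_l
  }
  heat <- max(h_am + h_sl, 1.0)
  fv <- if (v / vmax <= 0) {
    if (v / vmax <= -1) 0 else (1 + v / vmax) / (1 - v / vmax / 0.25)
  } else {
    s <- (1 + 1 / 0.25) / (1.5 - 1)
    1.5 - 0.5 * exp(-s * v / vmax)
  }
  fce <- fmax * a * fl * fv
  w <- max(-fce * v * lopt / mass, 0)
  max(heat + w, 0) * mass
}

# Hunt-Crossley normal force, literal closed form
oracle_hunt_crossley <- function(depth, depth_rate, E, R, c) {
  if (depth <= 0) return(0)
  max((4 / 3) * E * sqrt(R) * depth^1.5 * (1 + c * depth_rate), 0)
}
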