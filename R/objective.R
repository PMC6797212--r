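# objective: J = w_cot*J_cot + w_spd*J_spd + w_inj*J_inj + w_head*J_head.

#' Range penalty
#'
#' Linear out-of-range penalty: zero inside `(phi_min, phi_max)`,
#' `phi_min - phi` below the range, `phi - phi_max` above it.
#'
#' @param phi value(s).
#' @param phi_min,phi_max range bounds (`phi_min < phi_max`).
#' @return the penalty (non-negative), vectorized over `phi`.
#' @examples
#' psi(1.25, 1.20, 1.30)  # 0
#' psi(1.10, 1.20, 1.30)  # 0.10
#' @export
psi <- function(phi, phi_min, phi_max) {
  stopifnot(phi_min < phi_max)
  ifelse(phi < phi_min, phi_min - phi, ifelse(phi > phi_max, phi - phi_max, 0))
}

#' Objective weights
#'
#' Default weights of the four-term rollout objective: cost of transport
#' (1 kg·m/J), step-speed penalty (10,000 1/s), ligament injury
#' (0.1 (N·m)^-2 s^-1) and head stability (0.25 s^3/m^2).
#' @return named list of weights.
#' @export
objective_weights <- function(cot = 1, spd = 10000, inj = 0.1, head = 0.25) {
  stopifnot(cot >= 0, spd >= 0, inj >= 0, head >= 0)
  list(cot = cot, spd = spd, inj = inj, head = head)
}

#' Step-speed specifications
#'
#' `prescribed_speed(v)` allows step speeds within ±0.05 m/s of the
#' prescribed speed; `self_selected()` imposes only a minimum of 0.75 m/s
#' with an unbounded maximum.
#'
#' @param v prescribed speed (m/s).
#' @param tol half-width of the allowed window (m/s).
#' @return list with `v_min`, `v_max`.
#' @export
prescribed_speed <- function(v, tol = 0.05) {
  stopifnot(v > 0, tol > 0)
  list(v_min = v - tol, v_max = v + tol, mode = "prescribed", v_target = v)
}

#' @rdname prescribed_speed
#' @param v_min minimum allowed speed (m/s).
#' @export
self_selected <- function(v_min = 0.75) {
  list(v_min = v_min, v_max = Inf, mode = "self_selected")
}

#' Head-acceleration bounds
#' @param g standard gravity (m/s^2).
#' @return list with `ax_min`, `ax_max`, `ay_min`, `ay_max` (m/s^2).
#' @export
head_accel_bounds <- function(g = STANDARD_GRAVITY) {
  list(ax_min = -0.25 * g, ax_max = 0.25 * g,
       ay_min = -0.50 * g, ay_max = 0.50 * g)
}

#' Step-speed objective term
#'
#' Penalizes rollouts that fall before the desired end time or take steps
#' outside the allowed speed window.  Each completed step earns a credit
#' factor `v_pen = max(0, 1 m/s - psi(v_s, v_min, v_max))` (1 m/s meaning
#' no penalty); a step in progress when the model falls earns nothing, and
#' time not covered by steps earns nothing.  Contributions are scaled by
#' step duration and normalized by the desired simulation time:
#' `J_spd = 1 - sum(t_s * v_pen) / (t_des * 1 m/s)`, clamped to `[0, 1]`.
#' A completed rollout whose in-range steps tile the rollout scores 0; an
#' immediate fall (no steps) scores 1; a rollout that walks in range for
#' part of the horizon and then falls scores in between, in proportion to
#' the stepping time it achieved.
#'
#' @param steps data.frame with columns `duration` (s) and `speed` (m/s)
#'   for the completed steps (contralateral contact to contact) of the
#'   rollout; zero rows for a rollout with no steps.
#' @param t_end actual end time of the rollout (s).
#' @param t_des desired simulation time (s).
#' @param t_fall time of the fall, or `NA` if the rollout completed.
#' @param spec a speed specification ([prescribed_speed()] or
#'   [self_selected()]).
#' @return `J_spd` in `[0, 1]`.
#' @export
j_spd <- function(steps, t_end, t_des, t_fall, spec) {
  stopifnot(t_des > 0)
  if (is.null(steps) || nrow(steps) == 0) return(1)
  keep <- if (!is.na(t_fall)) steps$t_end <= t_fall + 1e-9 else rep(TRUE, nrow(steps))
  if (is.null(steps$t_end)) keep <- rep(TRUE, nrow(steps))
  steps <- steps[keep, , drop = FALSE]
  if (nrow(steps) == 0) return(1)
  v_pen <- pmax(0, 1 - psi(steps$speed, spec$v_min, spec$v_max))
  val <- 1 - sum(steps$duration * v_pen) / (t_des * 1.0)
  min(max(val, 0), 1)
}

#' Gross cost of transport
#'
#' Time integral of the gross metabolic rate (including the basal term)
#' normalized by model mass and distance travelled, J/(kg·m).
#'
#' @param edot metabolic rate trace (W), aligned with `time`.
#' @param time time grid (s).
#' @param mass model mass (kg).
#' @param distance distance travelled (m); must be positive.
#' @return cost of transport in J/(kg·m).
#' @export
j_cot <- function(edot, time, mass, distance) {
  stopifnot(mass > 0, all(edot >= 0))
  if (!is.finite(distance) || distance <= 0) {
    stop("cost of transport is undefined for zero-displacement rollouts (distance = ",
         signif(distance, 4), " m)")
  }
  trapz(time, edot) / (mass * distance)
}

#' Ligament-injury objective term
#'
#' Integral over time of the sum of squared ligament torques,
#' in (N·m)^2·s.
#'
#' @param torques matrix of ligament torque traces (one column per joint,
#'   N·m) or a vector for a single joint.
#' @param time time grid (s).
#' @return the injury term.
#' @export
j_inj <- function(torques, time) {
  torques <- as.matrix(torques)
  stopifnot(nrow(torques) == length(time))
  trapz(time, rowSums(torques^2))
}

#' Head-stability objective term
#'
#' Integral of the squared out-of-bounds head-point accelerations,
#' `integral [psi(a_x)^2 + psi(a_y)^2] dt`, with bounds of ±0.25 g
#' horizontally and ±0.50 g vertically by default.
#'
#' @param ax,ay head-point acceleration traces (m/s^2).
#' @param time time grid (s).
#' @param bounds acceleration bounds, see [head_accel_bounds()].
#' @return the head term in m^2/s^3.
#' @export
j_head <- function(ax, ay, time, bounds = head_accel_bounds()) {
  stopifnot(length(ax) == length(time), length(ay) == length(time))
  px <- psi(ax, bounds$ax_min, bounds$ax_max)
  py <- psi(ay, bounds$ay_min, bounds$ay_max)
  trapz(time, px^2 + py^2)
}

#' Evaluate the full rollout objective
#'
#' Computes the four raw objective terms from a trajectory, applies the
#' weights, and returns the breakdown.  Steps are segmented from the
#' ground-reaction forces ([segment_steps()]); all steps count toward the
#' speed term (the exclusion of the first two steps applies to gait
#' analysis, not to the objective).  The distance travelled is the
#' center-of-mass fore-aft displacement, and the metabolic trace is the
#' summed per-muscle rate plus the whole-body basal rate.
#'
#' @param traj a `gait_trajectory`.
#' @param weights objective weights ([objective_weights()]).
#' @param speed speed specification ([prescribed_speed()] /
#'   [self_selected()]).
#' @param bounds head-acceleration bounds.
#' @param degenerate `"error"` raises on a zero-displacement rollout (the
#'   cost of transport is undefined); `"penalize"` floors the distance at
#'   1 cm so optimization remains total over the search box.
#' @return an `objective_breakdown`: list with `J`, `raw` and `weighted`
#'   four-term vectors, and the step table used.
#' @export
gait_objective <- function(traj, weights = objective_weights(),
                           speed = self_selected(),
                           bounds = head_accel_bounds(),
                           degenerate = c("error", "penalize")) {
  stopifnot(inherits(traj, "gait_trajectory"))
  degenerate <- match.arg(degenerate)
  d <- traj$data
  need <- c("edot", "com_x", "headacc_x", "headacc_y",
            paste0("lig_", JOINT_DOFS))
  missing <- setdiff(need, colnames(d))
  if (length(missing)) {
    stop("trajectory contract error: missing channel(s) ",
         paste(missing, collapse = ", "))
  }
  time <- traj$time
  fell <- identical(traj$status, "fell") || !is.na(traj$t_fall)
  # integration failures are scored as a fall at the last valid time
  t_fall <- if (fell) traj$t_fall else if (traj$status != "completed") traj$t_end else NA_real_

  events <- segment_steps(traj)
  steps <- attr(events, "steps")

  distance <- unname(abs(d[nrow(d), "com_x"] - d[1, "com_x"]))
  if (distance <= 0.01) {
    if (degenerate == "error") {
      stop("cost of transport is undefined for zero-displacement rollouts")
    }
    distance <- max(distance, 0.01)
  }
  edot_gross <- d[, "edot"] + traj$basal_rate_W_kg * traj$mass
  raw <- c(
    cot = j_cot(edot_gross, time, traj$mass, distance),
    spd = j_spd(steps, traj$t_end, traj$t_des, t_fall, speed),
    inj = j_inj(d[, paste0("lig_", JOINT_DOFS)], time),
    head = j_head(d[, "headacc_x"], d[, "headacc_y"], time, bounds))
  w <- c(cot = weights$cot, spd = weights$spd, inj = weights$inj,
         head = weights$head)
  weighted <- w * raw
  structure(list(J = sum(weighted), raw = raw, weighted = weighted,
                 weights = w, steps = steps, distance = distance,
                 t_end = traj$t_end, t_fall = t_fall),
            class = "objective_breakdown")
}

#' @export
print.objective_breakdown <- function(x, ...) {
  cat(sprintf("J = %.4f\n", x$J))
  tab <- rbind(raw = x$raw, weight = x$weights, weighted = x$weighted)
  print(signif(tab, 5))
  cat(sprintf("distance %.2f m over %.2f s", x$distance, x$t_end))
  if (!is.na(x$t_fall)) cat(sprintf(" (fell at %.2f s)", x$t_fall))
  cat(sprintf(", %d steps\n", if (is.null(x$steps)) 0L else nrow(x$steps)))
  invisible(x)
}
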