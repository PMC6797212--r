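# mtu: Hill-type muscle-tendon dynamics and metabolic energetics.

default_curves <- function() {
  list(active_fl_width = 0.45, passive_kpe = 4.0, passive_strain_at_one = 0.6,
       tendon_shape_k = 3.0, fv_curvature_K = 0.25, fv_eccentric_plateau_N = 1.5)
}

#' First-order activation dynamics
#'
#' Advances muscle activation `a` toward excitation `u` over a time step
#' `dt` under first-order dynamics `da/dt = (u - a)/tau`, with
#' `tau = tau_act` when `u > a` (activation) and `tau_deact` otherwise.
#' The update uses the exact exponential solution for constant excitation,
#' so sub-stepping and a single step agree to machine precision.
#'
#' @param a current activation in `[0, 1]` (vectorized).
#' @param u excitation in `[0, 1]` (vectorized).
#' @param dt time step in seconds (`> 0`).
#' @param tau_act,tau_deact activation / deactivation time constants (s).
#' @return new activation, clamped to `[0, 1]`.
#' @examples
#' activation_step(0, 1, dt = 0.010)  # ~ 1 - exp(-1) = 0.632
#' @export
activation_step <- function(a, u, dt, tau_act = 0.010, tau_deact = 0.040) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stop("argument error: dt must be a positive scalar")
  }
  stopifnot(all(a >= 0 & a <= 1), all(u >= 0 & u <= 1))
  tau <- ifelse(u > a, tau_act, tau_deact)
  out <- u + (a - u) * exp(-dt / tau)
  pmin(pmax(out, 0), 1)
}

#' Hill-curve force multipliers
#'
#' Evaluates the dimensionless active force-length, passive force-length and
#' force-velocity multipliers at a normalized fiber length (optimal fiber
#' lengths) and normalized fiber velocity (optimal fiber lengths per second,
#' shortening negative).  The curve family is a smooth exponential
#' parameterization: the active curve equals 1 at optimal length and decays
#' as `exp(ln(0.05) |(l-1)/w|^3)`; the passive curve is zero below optimal
#' length and exponentially stiffening above; the force-velocity curve is
#' the Hill hyperbola for shortening joined C1-continuously to an
#' exponential eccentric branch with plateau `N`, so that `fv(0) = 1` and
#' `fv(-v_max) = 0`.
#'
#' @param norm_fiber_length normalized fiber length(s).
#' @param norm_fiber_velocity normalized fiber velocity(ies), `l_opt/s`.
#' @param v_max maximum contraction velocity (`l_opt/s`), default 15.
#' @param curves curve shape coefficients (see `default_curves`); taken from
#'   a model's `curves` section when simulating.
#' @return list with `active_fl`, `passive_fl`, `fv`.
#' @export
force_multipliers <- function(norm_fiber_length, norm_fiber_velocity = 0,
                              v_max = 15, curves = default_curves()) {
  stopifnot(all(is.finite(norm_fiber_length)), all(is.finite(norm_fiber_velocity)))
  list(
    active_fl = .hill_active_fl(as.numeric(norm_fiber_length),
                                curves$active_fl_width),
    passive_fl = .hill_passive_fl(as.numeric(norm_fiber_length),
                                  curves$passive_kpe, curves$passive_strain_at_one),
    fv = .hill_fv(as.numeric(norm_fiber_velocity), v_max,
                  curves$fv_curvature_K, curves$fv_eccentric_plateau_N))
}

#' Tendon force from strain
#'
#' Series-elastic tendon force: zero for slack (non-positive strain),
#' strictly increasing exponential toe region for positive strain,
#' normalized so the force equals `f_max_iso` exactly at the reference
#' strain (`tendon_strain_at_fmax`; 4.9% for most muscles, 10% for the
#' plantarflexors).
#'
#' @param strain tendon strain (dimensionless, vectorized).
#' @param f_max_iso maximum isometric force (N).
#' @param tendon_strain_at_fmax strain at which force equals `f_max_iso`.
#' @param shape_k exponential shape constant.
#' @return tendon force in N.
#' @export
tendon_force <- function(strain, f_max_iso, tendon_strain_at_fmax = 0.049,
                         shape_k = 3.0) {
  stopifnot(f_max_iso > 0, tendon_strain_at_fmax > 0)
  f_max_iso * .tendon_force_norm(as.numeric(strain), tendon_strain_at_fmax, shape_k)
}

#' Fiber-tendon equilibrium
#'
#' Solves for the normalized fiber length at which the isometric fiber force
#' (active + passive, along the line of action; zero pennation) balances the
#' series tendon force at a given muscle-tendon length and activation.
#' Used to set initial muscle states, and mirrors the per-step implicit
#' fiber update inside the simulator.  A damped Newton iteration with a
#' 100-iteration cap is used.
#'
#' @param model an `msk_model`.
#' @param muscle muscle name (e.g. `"SOL"`) plus `side`, or an index 1..18
#'   in core (side-major) ordering.
#' @param mtu_length total muscle-tendon length (m).
#' @param activation activation in `[0, 1]`.
#' @param side `"L"` or `"R"` when `muscle` is a name.
#' @param tol convergence tolerance on the normalized force residual.
#' @return list with `norm_fiber_length`, `residual` (normalized by
#'   `f_max_iso`), `converged`.
#' @export
equilibrate_muscle <- function(model, muscle, mtu_length, activation,
                               side = "L", tol = 1e-6) {
  stopifnot(inherits(model, "msk_model"), mtu_length > 0,
            activation >= 0, activation <= 1)
  idx <- if (is.numeric(muscle)) as.integer(muscle) else mus_index(muscle, side)
  if (is.na(idx) || idx < 1 || idx > 18) stop("unknown muscle: ", muscle)
  res <- .gait_core_equilibrate(as_core_model(model), idx, mtu_length,
                                activation, tol)
  if (!isTRUE(res$converged)) {
    nm <- core_muscle_names()[idx]
    stop(sprintf(paste0("equilibrium solver error for muscle %s: residual ",
                        "%.3e at mtu_length %.4f m (infeasible geometry or ",
                        "non-convergence)"), nm, res$residual, mtu_length))
  }
  res
}

#' Muscle metabolic rate
#'
#' Energy expenditure rate of one muscle following the Umberger-family
#' model (activation/maintenance heat, shortening/lengthening heat, and
#' positive mechanical work of the contractile element), with a resting-heat
#' floor and a non-negativity clamp.  Muscle mass is derived from maximum
#' isometric force, optimal fiber length, specific tension and muscle
#' density.  The whole-body basal rate is added separately in the objective.
#'
#' @param activation activation in `[0, 1]`.
#' @param excitation excitation in `[0, 1]`.
#' @param norm_fiber_length normalized fiber length.
#' @param norm_fiber_velocity normalized fiber velocity (`l_opt/s`,
#'   shortening negative).
#' @param f_max_iso maximum isometric force (N).
#' @param l_opt optimal fiber length (m).
#' @param v_max maximum contraction velocity (`l_opt/s`).
#' @param fast_twitch_fraction fraction of fast-twitch fibers in `[0, 1]`.
#' @param curves curve coefficients (for the force-length dependence).
#' @param specific_tension muscle specific tension (N/m^2).
#' @param density muscle density (kg/m^3).
#' @return metabolic rate in W (never negative).
#' @export
metabolic_rate <- function(activation, excitation, norm_fiber_length,
                           norm_fiber_velocity, f_max_iso, l_opt,
                           v_max = 15, fast_twitch_fraction = 0.5,
                           curves = default_curves(),
                           specific_tension = 250000, density = 1059.7) {
  stopifnot(activation >= 0, activation <= 1, excitation >= 0, excitation <= 1)
  res <- .gait_core_metabolic(activation, excitation, norm_fiber_length,
                              norm_fiber_velocity, f_max_iso, l_opt, v_max,
                              fast_twitch_fraction, curves$active_fl_width,
                              specific_tension, density)
  res$rate
}
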