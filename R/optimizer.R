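# shooting_optimizer (2/2): gait fitting front end and protocols.

#' Optimization protocols
#'
#' `gait_protocol()` builds a protocol description; `protocol_presets()`
#' returns the named presets used for the full-scale experiments and
#' reduced desk-scale variants:
#'
#' * `prescribed_speed`: 10 s rollouts, 20 parallel runs, up to 3000
#'   generations, for prescribed speeds from 0.50 to 2.00 m/s at 0.25 m/s
#'   intervals (training starts at 1.25 m/s and seeds outward).
#' * `self_selected`: 30 s rollouts, 10 parallel runs, up to 1500
#'   generations, minimum speed 0.75 m/s.
#' * `deficit_chain`: the seeding order for impaired models: unimpaired
#'   seeds mild, mild seeds moderate, moderate seeds severe.
#' * `desk`: a reduced single-run protocol (5 s rollouts, lambda 8, 50
#'   generations) for desktop-scale experimentation and tests.
#' * `stress_one_hour`: a single 3600 s rollout of an already-optimized
#'   solution, for stability checking (no optimization).
#'
#' @param t_des desired rollout duration (s).
#' @param lambda,mu CMA-ES population and parent counts.
#' @param max_gen maximum generations per run.
#' @param n_parallel runs per restart set.
#' @param improvement_threshold restart stopping threshold (fraction).
#' @param rtol integrator relative tolerance used during optimization.
#' @return a `gait_protocol` list.
#' @export
gait_protocol <- function(t_des = 10, lambda = 16, mu = 8, max_gen = 3000,
                          n_parallel = 1, improvement_threshold = 0.05,
                          rtol = 1e-4) {
  stopifnot(mu <= lambda, t_des > 0, improvement_threshold > 0,
            improvement_threshold < 1)
  structure(list(t_des = t_des, lambda = lambda, mu = mu, max_gen = max_gen,
                 n_parallel = n_parallel,
                 improvement_threshold = improvement_threshold, rtol = rtol),
            class = "gait_protocol")
}

#' @rdname gait_protocol
#' @param name preset name; `NULL` lists available presets.
#' @export
protocol_presets <- function(name = NULL) {
  presets <- list(
    prescribed_speed = c(gait_protocol(t_des = 10, lambda = 16, mu = 8,
                                       max_gen = 3000, n_parallel = 20),
                         list(speeds = seq(0.5, 2.0, by = 0.25),
                              seed_order = c(1.25, 1.0, 1.5, 0.75, 1.75, 0.5, 2.0))),
    self_selected = c(gait_protocol(t_des = 30, lambda = 16, mu = 8,
                                    max_gen = 1500, n_parallel = 10),
                      list(v_min = 0.75)),
    deficit_chain = list(order = c("mild", "moderate", "severe"),
                         seed = "unimpaired",
                         base = gait_protocol(t_des = 30, lambda = 16, mu = 8,
                                              max_gen = 1500, n_parallel = 10)),
    desk = gait_protocol(t_des = 5, lambda = 8, mu = 4, max_gen = 50,
                         n_parallel = 1, rtol = 1e-3),
    stress_one_hour = c(gait_protocol(t_des = 3600, lambda = 1, mu = 1,
                                      max_gen = 1), list(optimize = FALSE)))
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  presets[[name]]
}

#' Fit a walking controller by CMA-ES single shooting
#'
#' The fitting entry point of the package.  Each candidate design vector
#' (70 reflex gains/offsets, 4 state-machine thresholds, 16 initial-state
#' values) is evaluated by a full forward rollout ([simulate_gait()])
#' scored with the four-term objective ([gait_objective()]); CMA-ES
#' ([cma_es()]) adapts the candidate distribution.  Rollouts that fall are
#' scored by the same objective (the speed term saturates at 1); rollouts
#' whose integration fails are scored as falls at the failure time.
#'
#' @param model an `msk_model` (possibly with deficits applied).
#' @param controller a `gait_controller`.
#' @param protocol a `gait_protocol` (see [protocol_presets()]).
#' @param speed speed specification ([prescribed_speed()] or
#'   [self_selected()]).
#' @param x0 initial design vector (named, length 90); default: the
#'   controller file's initial values.
#' @param seed RNG seed for the optimization (also recorded for replay).
#' @param restarts if `TRUE`, apply the parallel-set restart protocol with
#'   the protocol's `n_parallel` and improvement threshold; otherwise run a
#'   single optimization.
#' @param weights objective weights.
#' @return a `gait_fit` object with `print`, `summary`, `coef`, `plot` and
#'   `simulate` methods.
#' @export
optimize_gait <- function(model, controller,
                          protocol = protocol_presets("desk"),
                          speed = self_selected(), x0 = NULL, seed = 1,
                          restarts = FALSE, weights = objective_weights()) {
  stopifnot(inherits(model, "msk_model"), inherits(controller, "gait_controller"))
  bounds <- design_bounds(controller)
  sds <- design_sds(controller)
  if (is.null(x0)) x0 <- design_vector(controller)
  if (length(x0) != length(sds)) {
    stop("argument error: design vector must have length ", length(sds))
  }
  x0 <- pmin(pmax(x0, bounds$lower), bounds$upper)

  fn <- make_gait_objective_fn(model, controller, protocol, speed, weights)

  if (restarts && protocol$n_parallel > 1) {
    res <- restart_protocol(fn, x0, bounds$lower, bounds$upper, sds,
                            protocol, seed = seed)
    history <- NULL
    best_par <- res$best_par
    best_value <- res$best_value
    sets <- res$sets
  } else {
    res <- cma_es(x0, fn, lower = bounds$lower, upper = bounds$upper,
                  sigma = sds, lambda = protocol$lambda, mu = protocol$mu,
                  max_gen = protocol$max_gen, seed = seed)
    history <- res$history
    best_par <- res$best_par
    best_value <- res$best_value
    sets <- NULL
  }
  names(best_par) <- names(design_vector(controller))
  sp <- split_design(controller, best_par)
  best_traj <- simulate_gait(model, controller, params = sp$params,
                             init = sp$init, t_des = protocol$t_des,
                             rtol = protocol$rtol, strict = FALSE)
  best_breakdown <- gait_objective(best_traj, weights = weights,
                                   speed = speed, degenerate = "penalize")
  structure(list(
    call = match.call(), model = model, controller = controller,
    protocol = protocol, speed = speed, weights = weights,
    best = best_par, best_J = best_value,
    breakdown = best_breakdown, trajectory = best_traj,
    history = history, sets = sets, seed = seed, x0 = x0
  ), class = "gait_fit")
}

# objective closure over the design vector; total over the search box
make_gait_objective_fn <- function(model, controller, protocol, speed,
                                   weights) {
  force(model); force(controller); force(protocol); force(speed); force(weights)
  function(x) {
    sp <- split_design(controller, x)
    traj <- tryCatch(
      simulate_gait(model, controller, params = sp$params, init = sp$init,
                    t_des = protocol$t_des, rtol = protocol$rtol,
                    strict = FALSE),
      error = function(e) NULL)
    if (is.null(traj)) {
      # infeasible initial pose (muscle equilibrium or ground clearance):
      # scored as worse than an immediate fall so the search stays total
      return(2 * weights$spd)
    }
    br <- tryCatch(
      gait_objective(traj, weights = weights, speed = speed,
                     degenerate = "penalize"),
      error = function(e) NULL)
    if (is.null(br)) return(2 * weights$spd)
    br$J
  }
}

#' @export
print.gait_fit <- function(x, ...) {
  cat("Reflex-gait shooting fit\n")
  cat(sprintf("  design variables: %d, seed %s\n", length(x$best),
              format(x$seed)))
  cat(sprintf("  best J = %.4f (rollout %s, t_end %.2f s)\n", x$best_J,
              x$trajectory$status, x$trajectory$t_end))
  br <- x$breakdown
  cat(sprintf("  weighted terms: cot %.3f | spd %.3f | inj %.3f | head %.3f\n",
              br$weighted["cot"], br$weighted["spd"], br$weighted["inj"],
              br$weighted["head"]))
  invisible(x)
}

#' @export
summary.gait_fit <- function(object, ...) {
  out <- list(best_J = object$best_J, breakdown = object$breakdown,
              status = object$trajectory$status,
              t_end = object$trajectory$t_end,
              generations = if (!is.null(object$history)) nrow(object$history) else NA)
  st <- tryCatch(spatiotemporal_summary(object$trajectory),
                 error = function(e) NULL)
  out$gait <- st
  class(out) <- "summary.gait_fit"
  out
}

#' @export
print.summary.gait_fit <- function(x, ...) {
  cat(sprintf("Best J = %.4f after %s generations (rollout %s, %.2f s)\n",
              x$best_J, format(x$generations), x$status, x$t_end))
  print(x$breakdown)
  if (!is.null(x$gait)) print(x$gait)
  else cat("  (no analyzable steps; gait summary unavailable)\n")
  invisible(x)
}

#' @export
coef.gait_fit <- function(object, ...) object$best

#' @export
plot.gait_fit <- function(x, ...) {
  if (is.null(x$history)) {
    plot(x$sets$set, x$sets$best, type = "b", xlab = "restart set",
         ylab = "best J", ...)
    return(invisible(x))
  }
  gen <- seq_len(nrow(x$history))
  matplot(gen, cbind(x$history$best_ever, x$history$median), type = "l",
          lty = c(1, 2), col = c("black", "grey50"),
          xlab = "generation", ylab = "objective J", log = "y", ...)
  legend("topright", c("best ever", "generation median"), lty = c(1, 2),
         col = c("black", "grey50"), bty = "n")
  invisible(x)
}

#' Re-simulate a fitted gait
#'
#' Rolls out the fitted design vector, optionally for a different duration
#' (e.g. a long stability check of a solution trained on a shorter
#' horizon).
#'
#' @param object a `gait_fit`.
#' @param nsim number of rollouts (the dynamics are deterministic; values
#'   above 1 only make sense with `perturb > 0`).
#' @param seed RNG seed for perturbations.
#' @param t_des rollout duration; default: the protocol's.
#' @param perturb SD of a Gaussian perturbation applied to the 16
#'   initial-state values (0 = exact replay).
#' @param ... passed to [simulate_gait()].
#' @return a `gait_trajectory`, or a list of them when `nsim > 1`.
#' @export
simulate.gait_fit <- function(object, nsim = 1, seed = NULL, t_des = NULL,
                              perturb = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(t_des)) t_des <- object$protocol$t_des
  sp <- split_design(object$controller, object$best)
  one <- function() {
    init <- sp$init
    if (perturb > 0) init <- init + rnorm(length(init), 0, perturb)
    simulate_gait(object$model, object$controller, params = sp$params,
                  init = init, t_des = t_des, strict = FALSE, ...)
  }
  if (nsim == 1) one() else lapply(seq_len(nsim), function(i) one())
}

#' Random feasible design vector
#'
#' Uniform draw within the design box: a deliberately naive starting point
#' used to measure how much a short optimization improves the objective.
#'
#' @param controller a `gait_controller`.
#' @param seed RNG seed.
#' @return named design vector of length 90.
#' @export
random_design <- function(controller, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  b <- design_bounds(controller)
  lo <- b$lower; hi <- b$upper
  hi_eff <- pmin(hi, lo + 4 * design_sds(controller) * 5)  # finite draw box
  x <- lo + runif(length(lo)) * (hi_eff - lo)
  setNames(x, names(lo))
}
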