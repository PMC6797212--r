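# reflex_controller: 5-phase state machine + delayed reflex laws.

LAW_KINDS <- c("C", "L+", "V+", "F+", "F-", "PD")
THRESHOLD_NAMES <- c("es_to_ms_dist_m", "ps_to_s_grf_N",
                     "s_to_lp_dist_m", "lp_to_es_grf_N")
INIT_STATE_NAMES <- c("pelvis_tilt_rad", "hip_L_rad", "knee_L_rad",
                      "ankle_L_rad", "hip_R_rad", "knee_R_rad", "ankle_R_rad",
                      "pelvis_vx_m_s", "pelvis_vy_m_s", "pelvis_tilt_vel_rad_s",
                      "hip_L_vel_rad_s", "knee_L_vel_rad_s", "ankle_L_vel_rad_s",
                      "hip_R_vel_rad_s", "knee_R_vel_rad_s", "ankle_R_vel_rad_s")

# most proximal joint spanned by each muscle group (sets the reflex delay)
PROXIMAL_JOINT <- c(GMAX = "hip", HAMS = "hip", ILPSO = "hip", RF = "hip",
                    VAS = "knee", BFSH = "knee", GAS = "knee",
                    SOL = "ankle", TA = "ankle")

#' Load a reflex gait controller
#'
#' Reads a controller file: a declarative topology (which law, acting on
#' which muscle, active in which gait phases) plus the free parameters
#' (gains, offsets) with their initial values, CMA-ES initial standard
#' deviations and box bounds; the four state-machine transition thresholds;
#' and the 16 free initial-state values.  Laws are instantiated
#' bilaterally with shared parameters.  Reflex delays are derived from the
#' most proximal joint spanned by the target muscle (hip 5 ms, knee 10 ms,
#' ankle 20 ms; 40 ms for the SOL to TA inhibition), not stored per law.
#'
#' The shipped default topology exposes exactly 70 gain/offset parameters;
#' with the 4 thresholds and 16 initial-state values this yields the
#' 90-variable design vector used by [optimize_gait()].
#'
#' The shipped topology file carries a hand-designed initial guess; the
#' companion values file `default_controller_trained.csv` holds parameter
#' values pre-trained with the package's own shooting optimizer at desk
#' scale, and is applied on top of the default topology unless
#' `values = NA`.
#'
#' @param path controller YAML file; `NULL` loads the shipped default.
#' @param values optional CSV of named parameter values (columns `name`,
#'   `value`) applied over the file's initial values; defaults to the
#'   shipped pre-trained values when `path` is `NULL`; use `NA` to skip.
#' @return an object of class `gait_controller`.
#' @export
gait_controller <- function(path = NULL, values = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_controller.yaml", package = "reflexgait")
    if (is.null(values)) {
      trained <- system.file("extdata", "default_controller_trained.csv",
                             package = "reflexgait")
      if (nzchar(trained)) values <- trained
    }
  }
  if (!file.exists(path)) stop("controller file not found: ", path)
  cfg <- yaml::read_yaml(path)
  ctrl <- build_controller_from_config(cfg, source = path)
  if (!is.null(values) && !identical(values, NA)) {
    tab <- read.csv(values, stringsAsFactors = FALSE)
    ctrl <- set_design_values(ctrl, setNames(tab$value, tab$name))
  }
  ctrl
}

#' Overwrite named design values (gains/offsets, thresholds, initial state)
#' @param controller a `gait_controller`.
#' @param values named numeric vector; every name must be a design-vector
#'   entry.
#' @return the updated controller.
#' @export
set_design_values <- function(controller, values) {
  stopifnot(!is.null(names(values)))
  unknown <- setdiff(names(values),
                     c(controller$param_table$name, controller$init_table$name))
  if (length(unknown)) {
    stop("unknown design parameter(s): ", paste(unknown, collapse = ", "))
  }
  i <- match(controller$param_table$name, names(values))
  controller$param_table$value[!is.na(i)] <- values[i[!is.na(i)]]
  j <- match(controller$init_table$name, names(values))
  controller$init_table$value[!is.na(j)] <- values[j[!is.na(j)]]
  sync_controller_config(controller)
}

# keep the raw config in step with the parameter tables so that a written
# snapshot (save_run) carries the effective values
sync_controller_config <- function(controller) {
  p <- setNames(controller$param_table$value, controller$param_table$name)
  for (i in seq_along(controller$config$laws)) {
    l <- controller$config$laws[[i]]
    for (nm in names(l$params)) {
      controller$config$laws[[i]]$params[[nm]]$value <-
        unname(p[[paste0(l$id, ".", nm)]])
    }
  }
  for (nm in names(controller$config$thresholds)) {
    controller$config$thresholds[[nm]]$value <- unname(p[[nm]])
  }
  iv <- setNames(controller$init_table$value, controller$init_table$name)
  for (nm in names(controller$config$initial_state)) {
    controller$config$initial_state[[nm]]$value <- unname(iv[[nm]])
  }
  controller
}

#' @rdname gait_controller
#' @param cfg parsed controller configuration list.
#' @param source provenance string.
#' @export
build_controller_from_config <- function(cfg, source = "<config>") {
  if (is.null(cfg$laws) || is.null(cfg$thresholds) || is.null(cfg$initial_state)) {
    stop("controller configuration error: need laws, thresholds and initial_state sections")
  }
  delays <- cfg$delays_s %||% list(hip = 0.005, knee = 0.010, ankle = 0.020,
                                   sol_ta_inhibition = 0.040)
  laws <- lapply(cfg$laws, function(l) {
    kind <- l$kind
    if (!kind %in% LAW_KINDS) {
      stop("controller configuration error: unknown law kind '", kind,
           "' in law ", l$id)
    }
    target <- l$target
    if (!target %in% MUSCLE_GROUPS) {
      stop("controller configuration error: law ", l$id,
           " references unknown muscle '", target, "'")
    }
    source_mus <- l$source %||% target
    if (!source_mus %in% MUSCLE_GROUPS) {
      stop("controller configuration error: law ", l$id,
           " references unknown source muscle '", source_mus, "'")
    }
    if (kind == "PD" && !target %in% c("ILPSO", "GMAX", "HAMS")) {
      stop("controller configuration error: PD laws may only target the ",
           "hip-spanning muscles (ILPSO, GMAX, HAMS); law ", l$id)
    }
    if (kind != "PD" && source_mus != target && !(kind == "F-" &&
        source_mus == "SOL" && target == "TA")) {
      stop("controller configuration error: the only cross-muscle law is the ",
           "SOL to TA negative force feedback; law ", l$id)
    }
    if (!all(unlist(l$phases) %in% PHASE_NAMES)) {
      stop("controller configuration error: unknown phase in law ", l$id)
    }
    expected <- switch(kind, C = "K", `L+` = c("K", "l_o"), `V+` = "K",
                       `F+` = "K", `F-` = "K", PD = c("Kp", "Kv", "theta_o"))
    if (!identical(names(l$params), expected)) {
      stop("controller configuration error: law ", l$id, " of kind ", kind,
           " must define parameters ", paste(expected, collapse = ", "))
    }
    delay <- if (kind == "C") 0 else if (kind == "F-" && source_mus == "SOL" &&
                                         target == "TA") {
      delays$sol_ta_inhibition
    } else delays[[PROXIMAL_JOINT[[target]]]]
    list(id = l$id, kind = kind, target = target, source = source_mus,
         phases = unlist(l$phases), delay = delay, params = l$params)
  })
  ids <- vapply(laws, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("controller configuration error: duplicate law ids")

  param_table <- do.call(rbind, lapply(laws, function(l) {
    data.frame(name = paste0(l$id, ".", names(l$params)),
               value = vapply(l$params, function(p) p$value, numeric(1)),
               sd = vapply(l$params, function(p) p$sd, numeric(1)),
               lower = vapply(l$params, function(p) p$min, numeric(1)),
               upper = vapply(l$params, function(p) p$max, numeric(1)),
               role = "gain_offset", stringsAsFactors = FALSE)
  }))
  if (!identical(names(cfg$thresholds), THRESHOLD_NAMES)) {
    stop("controller configuration error: thresholds must be exactly ",
         paste(THRESHOLD_NAMES, collapse = ", "), " in that order")
  }
  thr <- do.call(rbind, lapply(THRESHOLD_NAMES, function(nm) {
    p <- cfg$thresholds[[nm]]
    data.frame(name = nm, value = p$value, sd = p$sd, lower = p$min,
               upper = p$max, role = "threshold", stringsAsFactors = FALSE)
  }))
  param_table <- rbind(param_table, thr)
  rownames(param_table) <- NULL

  if (!identical(names(cfg$initial_state), INIT_STATE_NAMES)) {
    stop("controller configuration error: initial_state must define exactly ",
         "the 16 free state values in canonical order (",
         paste(INIT_STATE_NAMES, collapse = ", "), ")")
  }
  init_table <- do.call(rbind, lapply(INIT_STATE_NAMES, function(nm) {
    p <- cfg$initial_state[[nm]]
    data.frame(name = nm, value = p$value, sd = p$sd, lower = p$min,
               upper = p$max, role = "initial_state", stringsAsFactors = FALSE)
  }))
  rownames(init_table) <- NULL

  ip <- cfg$initial_phase %||% list(left = "ES", right = "S")
  structure(list(
    name = cfg$name %||% "reflex-controller",
    source = source, config = cfg,
    laws = laws, delays = delays,
    param_table = param_table, init_table = init_table,
    u_floor = cfg$u_floor %||% 0.01,
    initial_phase = c(L = ip$left, R = ip$right)
  ), class = "gait_controller")
}

#' @export
print.gait_controller <- function(x, ...) {
  cen <- controller_census(x)
  cat("Reflex gait controller:", x$name, "\n")
  cat(sprintf("  %d laws (bilateral, shared parameters), 5-phase state machine\n",
              cen$n_laws))
  cat(sprintf("  free parameters: %d gains/offsets + %d thresholds + %d initial-state = %d design variables\n",
              cen$n_gain_offset, cen$n_thresholds, cen$n_initial_state,
              cen$n_design))
  invisible(x)
}

#' Controller parameter census
#'
#' Counts of the controller's free parameters: gains/offsets, state-machine
#' thresholds, initial-state values and the total design-vector length.
#' The `controller lint` CLI subcommand prints this census and verifies the
#' structural constraints.
#'
#' @param controller a `gait_controller`.
#' @return a list of counts.
#' @export
controller_census <- function(controller) {
  stopifnot(inherits(controller, "gait_controller"))
  ngo <- sum(controller$param_table$role == "gain_offset")
  nth <- sum(controller$param_table$role == "threshold")
  nin <- nrow(controller$init_table)
  list(n_laws = length(controller$laws), n_gain_offset = ngo,
       n_thresholds = nth, n_controller = ngo + nth, n_initial_state = nin,
       n_design = ngo + nth + nin)
}

#' Controller parameter vector (74 values)
#'
#' Named vector of the controller's free gains/offsets and thresholds, in
#' canonical (file) order.  Round-trips losslessly through
#' [set_controller_params()].
#'
#' @param controller a `gait_controller`.
#' @return named numeric vector.
#' @export
controller_params <- function(controller) {
  stopifnot(inherits(controller, "gait_controller"))
  setNames(controller$param_table$value, controller$param_table$name)
}

#' @rdname controller_params
#' @param values named or unnamed numeric vector of length 74; names, when
#'   present, are matched against the canonical parameter names.
#' @export
set_controller_params <- function(controller, values) {
  stopifnot(inherits(controller, "gait_controller"))
  if (length(values) != nrow(controller$param_table)) {
    stop("argument error: expected ", nrow(controller$param_table),
         " controller parameters, got ", length(values))
  }
  if (!is.null(names(values))) {
    idx <- match(controller$param_table$name, names(values))
    if (anyNA(idx)) stop("argument error: missing parameter names: ",
                         paste(setdiff(controller$param_table$name,
                                       names(values)), collapse = ", "))
    values <- values[idx]
  }
  controller$param_table$value <- as.numeric(values)
  sync_controller_config(controller)
}

#' Initial-state free values (16)
#' @param controller a `gait_controller`.
#' @return named numeric vector of the 16 free initial-state values.
#' @export
initial_state_values <- function(controller) {
  setNames(controller$init_table$value, controller$init_table$name)
}

#' Full design vector, bounds and initial standard deviations
#'
#' The 90-variable design vector of the shooting optimization: 70 reflex
#' gains/offsets + 4 transition thresholds + 16 initial-state values, each
#' name-addressable with per-entry box bounds and CMA-ES initial SDs.
#'
#' @param controller a `gait_controller`.
#' @return for `design_vector`, a named numeric vector; for
#'   `design_bounds`, a list with `lower` and `upper`; for `design_sds`,
#'   a named numeric vector of initial standard deviations.
#' @export
design_vector <- function(controller) {
  tab <- rbind(controller$param_table, controller$init_table)
  setNames(tab$value, tab$name)
}

#' @rdname design_vector
#' @export
design_bounds <- function(controller) {
  tab <- rbind(controller$param_table, controller$init_table)
  list(lower = setNames(tab$lower, tab$name),
       upper = setNames(tab$upper, tab$name))
}

#' @rdname design_vector
#' @export
design_sds <- function(controller) {
  tab <- rbind(controller$param_table, controller$init_table)
  setNames(tab$sd, tab$name)
}

# split a 90-vector into (74 controller, 16 initial-state)
split_design <- function(controller, x) {
  n <- nrow(controller$param_table)
  list(params = x[seq_len(n)], init = x[n + seq_len(nrow(controller$init_table))])
}

#' Advance the gait state machine by one update
#'
#' Applies the five transition rules, at most one transition per leg per
#' update: ES to MS when the ipsilateral foot-pelvis horizontal distance
#' drops below a threshold; MS to PS when the contralateral leg enters ES
#' (no threshold); PS to S when the ipsilateral ground-reaction-force
#' magnitude drops below a threshold; S to LP when the foot-pelvis distance
#' exceeds a threshold; LP to ES when the GRF magnitude exceeds a
#' threshold.
#'
#' @param phases character vector of length 2 (left, right), values in
#'   `ES`, `MS`, `PS`, `S`, `LP`.
#' @param foot_pelvis_dist numeric length 2: heel-sphere-to-pelvis
#'   horizontal distance, signed along +x (m).
#' @param grf_mag numeric length 2: GRF magnitude per foot (N).
#' @param thresholds named numeric with the four transition thresholds.
#' @return updated phases (character, length 2).
#' @export
update_phase <- function(phases, foot_pelvis_dist, grf_mag, thresholds) {
  stopifnot(length(phases) == 2, all(phases %in% PHASE_NAMES),
            all(is.finite(foot_pelvis_dist)), all(is.finite(grf_mag)))
  thr <- thresholds[THRESHOLD_NAMES]
  new <- phases
  for (leg in 1:2) {
    new[leg] <- switch(phases[leg],
      ES = if (foot_pelvis_dist[leg] < thr[["es_to_ms_dist_m"]]) "MS" else "ES",
      MS = "MS",
      PS = if (grf_mag[leg] < thr[["ps_to_s_grf_N"]]) "S" else "PS",
      S  = if (foot_pelvis_dist[leg] > thr[["s_to_lp_dist_m"]]) "LP" else "S",
      LP = if (grf_mag[leg] > thr[["lp_to_es_grf_N"]]) "ES" else "LP")
  }
  for (leg in 1:2) {
    other <- 3 - leg
    if (phases[leg] == "MS" && new[other] == "ES" && phases[other] != "ES") {
      new[leg] <- "PS"
    }
  }
  new
}

#' Interpolate a delayed sensor value from a history buffer
#'
#' Returns the channel value at `t - t_D` by linear interpolation on the
#' stored history.  Before the start of the buffer (start-up), the
#' pre-filled initial value is returned.
#'
#' @param history a list with `time` (increasing numeric) and `values`
#'   (matrix with named columns), optionally with attribute `capacity`
#'   giving the maximum representable delay (s).
#' @param channel column name or index.
#' @param t current time (s).
#' @param t_D delay (s, non-negative).
#' @return the delayed value.
#' @export
sense_delayed <- function(history, channel, t, t_D) {
  stopifnot(t_D >= 0)
  cap <- attr(history, "capacity")
  if (!is.null(cap) && t_D > cap) {
    stop("controller configuration error: requested delay ", t_D,
         " s exceeds the history buffer capacity ", cap, " s")
  }
  tq <- t - t_D
  tv <- history$time
  y <- history$values[, channel]
  if (tq <= tv[1]) return(y[[1]])
  approx(tv, y, xout = min(tq, tv[length(tv)]), rule = 2)$y
}

#' Compute muscle excitations from delayed sensors
#'
#' Reference implementation of the reflex law set: per muscle, the
#' contributions of all laws active in the leg's current phase are summed
#' and clamped to `[0, 1]` (with a small configurable excitation floor).
#' Law contributions: constant `u = K`; length feedback
#' `u = max(0, K (l - l_o))`; velocity feedback `u = max(0, K v)`; force
#' feedback `u = +/- K F`; pelvis-tilt PD `u = Kp (theta - theta_o) +
#' Kv thetadot`.  Sensors are normalized (fiber length in optimal fiber
#' lengths, velocity in optimal fiber lengths per second, force in units of
#' maximum isometric force).
#'
#' @param controller a `gait_controller`.
#' @param params controller parameter vector (74).
#' @param sensors list with `lmn`, `vmn`, `fnorm` (named 18-vectors in core
#'   ordering, already delayed per law as appropriate), `theta`,
#'   `thetadot`.
#' @param phases character length 2 (left, right).
#' @return named excitation vector (18) in `[0, 1]`.
#' @export
compute_excitations <- function(controller, params, sensors, phases) {
  stopifnot(inherits(controller, "gait_controller"),
            length(params) == nrow(controller$param_table),
            length(phases) == 2)
  p <- setNames(as.numeric(params), controller$param_table$name)
  u <- setNames(numeric(18), core_muscle_names())
  for (leg in 1:2) {
    side <- c("L", "R")[leg]
    for (l in controller$laws) {
      if (!phases[leg] %in% l$phases) next
      ti <- mus_index(l$target, side)
      si <- mus_index(l$source, side)
      pk <- function(suffix) p[[paste0(l$id, ".", suffix)]]
      contrib <- switch(l$kind,
        C = pk("K"),
        `L+` = max(0, pk("K") * (sensors$lmn[[si]] - pk("l_o"))),
        `V+` = max(0, pk("K") * sensors$vmn[[si]]),
        `F+` = pk("K") * sensors$fnorm[[si]],
        `F-` = -pk("K") * sensors$fnorm[[si]],
        PD = pk("Kp") * (sensors$theta - pk("theta_o")) +
             pk("Kv") * sensors$thetadot)
      u[ti] <- u[ti] + contrib
    }
  }
  pmin(pmax(u, controller$u_floor), 1)
}

#' Lint a controller file
#'
#' Verifies the structural constraints of the reflex topology (PD laws
#' only on hip-spanning muscles, SOL to TA as the only cross-muscle law,
#' canonical delays, phase names) and the parameter census
#' (70 gains/offsets + 4 thresholds + 16 initial-state values).
#'
#' @param controller a `gait_controller`.
#' @param expect_census expected counts; set to `NULL` to skip.
#' @return invisibly, the census; errors describe any violation.
#' @export
lint_controller <- function(controller,
                            expect_census = c(gain_offset = 70, thresholds = 4,
                                              initial_state = 16)) {
  cen <- controller_census(controller)
  if (!is.null(expect_census)) {
    if (cen$n_gain_offset != expect_census[["gain_offset"]]) {
      stop("controller lint: expected ", expect_census[["gain_offset"]],
           " gain/offset parameters, found ", cen$n_gain_offset)
    }
    if (cen$n_thresholds != expect_census[["thresholds"]]) {
      stop("controller lint: expected ", expect_census[["thresholds"]],
           " thresholds, found ", cen$n_thresholds)
    }
    if (cen$n_initial_state != expect_census[["initial_state"]]) {
      stop("controller lint: expected ", expect_census[["initial_state"]],
           " initial-state values, found ", cen$n_initial_state)
    }
  }
  # delay audit: by most-proximal spanned joint; 40 ms for SOL->TA
  for (l in controller$laws) {
    if (l$kind == "C") next
    want <- if (l$kind == "F-" && l$source == "SOL" && l$target == "TA") {
      controller$delays$sol_ta_inhibition
    } else controller$delays[[PROXIMAL_JOINT[[l$target]]]]
    if (!isTRUE(all.equal(l$delay, want))) {
      stop("controller lint: law ", l$id, " has delay ", l$delay,
           " s, expected ", want, " s")
    }
  }
  invisible(cen)
}

# --- internal: flatten to the C++ core layout -------------------------------

as_core_controller <- function(controller) {
  p <- controller$param_table
  pidx <- function(law_id, suffix) {
    match(paste0(law_id, ".", suffix), p$name) - 1L  # 0-based
  }
  rows <- list()
  delays <- numeric(0)
  for (leg in 0:1) {
    side <- c("L", "R")[leg + 1]
    for (l in controller$laws) {
      kind <- match(l$kind, LAW_KINDS) - 1L
      mask <- sum(bitwShiftL(1L, match(l$phases, PHASE_NAMES) - 1L))
      p1 <- p2 <- p3 <- -1L
      if (l$kind == "PD") {
        p1 <- pidx(l$id, "Kp"); p2 <- pidx(l$id, "Kv"); p3 <- pidx(l$id, "theta_o")
      } else if (l$kind == "L+") {
        p1 <- pidx(l$id, "K"); p2 <- pidx(l$id, "l_o")
      } else {
        p1 <- pidx(l$id, "K")
      }
      rows[[length(rows) + 1]] <- c(kind,
                                    mus_index(l$target, side) - 1L,
                                    mus_index(l$source, side) - 1L,
                                    leg, mask, p1, p2, p3)
      delays <- c(delays, l$delay)
    }
  }
  laws <- do.call(rbind, rows)
  storage.mode(laws) <- "integer"
  thr_idx <- vapply(THRESHOLD_NAMES, function(nm) match(nm, p$name) - 1L,
                    integer(1))
  list(laws = laws, delays = delays,
       thr_idx = as.integer(thr_idx),
       u_floor = controller$u_floor,
       init_phase = as.integer(match(controller$initial_phase, PHASE_NAMES) - 1L))
}
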