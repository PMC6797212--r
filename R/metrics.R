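# gait_metrics: step/cycle segmentation, spatiotemporal measures,
# cycle normalization, and comparison metrics against normative bands.

#' Segment a rollout into steps and gait cycles
#'
#' Detects foot contact and lift from the per-foot vertical ground reaction
#' force crossing a small threshold (default 1% of body weight) with an
#' n-sample hysteresis, and emits steps (contralateral foot contact to
#' contact) and gait cycles (ipsilateral contact to contact).  The first
#' two steps are flagged as excluded from analysis summaries.
#'
#' @param traj a `gait_trajectory`.
#' @param threshold_frac contact threshold as a fraction of body weight.
#' @param debounce_s hysteresis window in seconds: a contact-state change
#'   must persist this long to register (time-based, so segmentation does
#'   not depend on the output sampling interval).
#' @return a data.frame of events (`time`, `foot`, `type`) with attributes
#'   `steps` (data.frame: `t_start`, `t_end`, `duration`, `foot`, `length`,
#'   `speed`, `excluded`) and `cycles` (data.frame: `foot`, `t_start`,
#'   `t_end`, `duration`, `stance_duration`, `percent_stance`, `valid`).
#'   With no contacts detected, an empty event list with a warning status
#'   attribute is returned.
#' @export
segment_steps <- function(traj, threshold_frac = 0.01, debounce_s = 0.03) {
  stopifnot(inherits(traj, "gait_trajectory"))
  d <- traj$data
  if (!all(c("grf_L_y", "grf_R_y") %in% colnames(d))) {
    stop("trajectory contract error: missing GRF channels")
  }
  time <- traj$time
  thr <- threshold_frac * traj$mass * traj$gravity
  dt_med <- if (length(time) > 1) median(diff(time)) else 0.01
  hysteresis <- max(1L, as.integer(round(debounce_s / dt_med)))

  contact_series <- function(grf) {
    raw <- grf > thr
    state <- raw[1]
    out <- logical(length(raw))
    out[1] <- state
    run <- 0L
    for (i in 2:length(raw)) {
      if (raw[i] != state) {
        run <- run + 1L
        if (run >= hysteresis) { state <- raw[i]; run <- 0L }
      } else run <- 0L
      out[i] <- state
    }
    out
  }
  events <- data.frame(time = numeric(0), foot = character(0),
                       type = character(0), stringsAsFactors = FALSE)
  contact <- list()
  for (foot in c("L", "R")) {
    cs <- contact_series(d[, paste0("grf_", foot, "_y")])
    contact[[foot]] <- cs
    ix <- which(diff(cs) != 0) + 1L
    if (length(ix)) {
      ev <- data.frame(time = time[ix], foot = foot,
                       type = ifelse(cs[ix], "strike", "lift"),
                       stringsAsFactors = FALSE)
      events <- rbind(events, ev)
    }
  }
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL

  if (!any(contact$L) && !any(contact$R)) {
    attr(events, "status") <- "no_contact"
    attr(events, "steps") <- data.frame()
    attr(events, "cycles") <- data.frame()
    warning("no foot contacts detected")
    return(events)
  }

  # contact-point x: deepest contact sphere of the striking foot
  cm <- as_core_model_cached(traj, NULL)
  contact_x <- function(t_ev, foot) {
    i <- which.min(abs(time - t_ev))
    q <- d[i, paste0("q_", DOF_NAMES)]
    bp <- .gait_core_body_points(cm, as.numeric(q), rep(0, 9))
    rows <- if (foot == "L") 1:3 else 4:6
    sp <- bp$spheres[rows, , drop = FALSE]
    sp[which.min(sp[, 2]), 1]
  }

  strikes <- events[events$type == "strike", , drop = FALSE]
  steps <- data.frame()
  if (nrow(strikes) >= 2) {
    rows <- list()
    for (i in seq_len(nrow(strikes) - 1)) {
      a <- strikes[i, ]; b <- strikes[i + 1, ]
      if (a$foot == b$foot) next  # step is contralateral contact to contact
      dur <- b$time - a$time
      if (dur <= 0) next
      x0 <- if (!is.null(cm)) contact_x(a$time, a$foot) else NA_real_
      x1 <- if (!is.null(cm)) contact_x(b$time, b$foot) else NA_real_
      i0 <- which.min(abs(time - a$time)); i1 <- which.min(abs(time - b$time))
      rows[[length(rows) + 1]] <- data.frame(
        t_start = a$time, t_end = b$time, duration = dur,
        foot = b$foot, length = x1 - x0,
        speed = (d[i1, "com_x"] - d[i0, "com_x"]) / dur,
        stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      steps <- do.call(rbind, rows)
      steps$excluded <- seq_len(nrow(steps)) <= 2
    }
  }

  cycles <- data.frame()
  for (foot in c("L", "R")) {
    st <- events[events$type == "strike" & events$foot == foot, "time"]
    lf <- events[events$type == "lift" & events$foot == foot, "time"]
    if (length(st) < 2) next
    for (i in seq_len(length(st) - 1)) {
      t0 <- st[i]; t1 <- st[i + 1]
      lifts <- lf[lf > t0 & lf < t1]
      stance <- if (length(lifts)) lifts[1] - t0 else t1 - t0
      pct <- 100 * stance / (t1 - t0)
      cycles <- rbind(cycles, data.frame(
        foot = foot, t_start = t0, t_end = t1, duration = t1 - t0,
        stance_duration = stance, percent_stance = pct,
        valid = length(lifts) > 0 && pct > 0 && pct < 100,
        stringsAsFactors = FALSE))
    }
  }
  attr(events, "status") <- "ok"
  attr(events, "steps") <- steps
  attr(events, "cycles") <- cycles
  events
}

# trajectories carry enough model information for contact-point recovery;
# rebuild the core model list from the trajectory's source model if attached
as_core_model_cached <- function(traj, default) {
  m <- attr(traj, "model")
  if (is.null(m)) return(default)
  as_core_model(m)
}

#' Spatiotemporal and metabolic gait summary
#'
#' Per-step speed, step length and cadence, per-cycle percent stance, their
#' means, and the gross cost of transport over the analyzed interval.  The
#' first two steps of the rollout are excluded from all summaries.
#'
#' @param traj a `gait_trajectory`.
#' @param events segmentation from [segment_steps()]; computed if `NULL`.
#' @return a `gait_summary` list.
#' @export
spatiotemporal_summary <- function(traj, events = NULL) {
  stopifnot(inherits(traj, "gait_trajectory"))
  if (is.null(events)) events <- segment_steps(traj)
  steps <- attr(events, "steps")
  cycles <- attr(events, "cycles")
  if (is.null(steps) || nrow(steps) == 0 || all(steps$excluded)) {
    stop("gait summary error: no included steps (need at least three steps)")
  }
  inc <- steps[!steps$excluded, , drop = FALSE]
  t_ana0 <- inc$t_start[1]
  cyc <- if (nrow(cycles)) cycles[cycles$t_start >= t_ana0 - 1e-9, , drop = FALSE] else cycles
  d <- traj$data
  i0 <- which.min(abs(traj$time - t_ana0))
  n <- nrow(d)
  dist <- unname(d[n, "com_x"] - d[i0, "com_x"])
  dur <- traj$time[n] - traj$time[i0]
  edot_gross <- d[i0:n, "edot"] + traj$basal_rate_W_kg * traj$mass
  cot <- if (dist > 0.01) {
    trapz(traj$time[i0:n], edot_gross) / (traj$mass * dist)
  } else NA_real_
  structure(list(
    steps = inc, cycles = cyc,
    n_steps = nrow(inc),
    mean_speed = dist / max(dur, 1e-9),
    mean_step_length = mean(inc$length, na.rm = TRUE),
    mean_cadence = mean(60 / inc$duration),
    mean_percent_stance = if (nrow(cyc)) mean(cyc$percent_stance[cyc$valid]) else NA_real_,
    cost_of_transport = cot,
    excluded_steps = 2L
  ), class = "gait_summary")
}

#' @export
print.gait_summary <- function(x, ...) {
  cat("Gait summary (first two steps excluded):\n")
  cat(sprintf("  steps analyzed: %d\n", x$n_steps))
  cat(sprintf("  mean speed: %.3f m/s\n", x$mean_speed))
  cat(sprintf("  mean step length: %.3f m\n", x$mean_step_length))
  cat(sprintf("  mean cadence: %.1f steps/min\n", x$mean_cadence))
  cat(sprintf("  mean percent stance: %.1f %%\n", x$mean_percent_stance))
  cat(sprintf("  gross cost of transport: %.3f J/(kg*m)\n", x$cost_of_transport))
  invisible(x)
}

#' Normalize a channel to the gait cycle
#'
#' Linearly interpolates a channel onto 101 samples at 0-100% of the gait
#' cycle for each cycle, and averages across cycles.
#'
#' @param x channel trace.
#' @param time time grid aligned with `x`.
#' @param cycles data.frame with `t_start`, `t_end` (e.g. from
#'   [segment_steps()]), one row per cycle.
#' @param n_samples number of samples (default 101, i.e. every 1%).
#' @return a `cycle_trajectory`: list with `percent`, `mean`, `sd`,
#'   `cycles` (matrix, one row per cycle), `n_cycles`.
#' @export
normalize_cycle <- function(x, time, cycles, n_samples = 101) {
  if (is.null(cycles) || nrow(cycles) == 0) {
    stop("cycle normalization error: need at least one complete cycle")
  }
  pct <- seq(0, 100, length.out = n_samples)
  rows <- t(vapply(seq_len(nrow(cycles)), function(i) {
    tt <- seq(cycles$t_start[i], cycles$t_end[i], length.out = n_samples)
    approx(time, x, xout = tt, rule = 2)$y
  }, numeric(n_samples)))
  structure(list(percent = pct,
                 mean = colMeans(rows),
                 sd = apply(rows, 2, sd),
                 cycles = rows, n_cycles = nrow(cycles)),
            class = "cycle_trajectory")
}

#' Root-mean-squared error in standard-deviation units
#'
#' Z-scores the simulated mean trajectory against a reference mean and SD
#' at every cycle sample and returns the root of the mean squared Z-score.
#' (The root-mean-square form is used, matching the "RMSE (SD)" label and
#' the typical ~1 SD magnitudes of such comparisons.)
#'
#' @param sim simulated trajectory (vector, e.g. 101 samples), or a
#'   `cycle_trajectory` (its mean is used).
#' @param ref_mean,ref_sd reference band (same length; all `ref_sd > 0`).
#' @return RMSE in SD units.
#' @examples
#' rmse_sd(c(0, 1, 2), rep(0, 3), rep(1, 3))  # sqrt(5/3)
#' @export
rmse_sd <- function(sim, ref_mean, ref_sd) {
  if (inherits(sim, "cycle_trajectory")) sim <- sim$mean
  stopifnot(length(sim) == length(ref_mean), length(sim) == length(ref_sd))
  if (any(ref_sd <= 0)) {
    stop("rmse_sd error: reference SD must be positive at every sample")
  }
  z <- (sim - ref_mean) / ref_sd
  sqrt(mean(z^2))
}

#' Zero-lag normalized cross-correlation
#'
#' Pearson-form shape similarity of two aligned, cycle-normalized
#' trajectories: both are mean-centered and the zero-lag normalized
#' cross-correlation is returned (1 for identical shapes, -1 for opposite,
#' invariant to positive affine transforms).
#'
#' @param sim,ref trajectories of equal length (vectors or
#'   `cycle_trajectory` objects).
#' @return NCC in `[-1, 1]`.
#' @export
ncc <- function(sim, ref) {
  if (inherits(sim, "cycle_trajectory")) sim <- sim$mean
  if (inherits(ref, "cycle_trajectory")) ref <- ref$mean
  stopifnot(length(sim) == length(ref))
  a <- sim - mean(sim); b <- ref - mean(ref)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("ncc error: zero-variance input")
  }
  sum(a * b) / (na * nb)
}

#' Z-score panel of scalar gait measures
#'
#' Z-scores named scalar measures (gait speed, percent stance, peak
#' moments, etc.) against normative mean ± SD bands and flags deviations
#' strictly beyond 2 SD.
#'
#' @param values named numeric vector of measures.
#' @param bands data.frame with columns `measure`, `mean`, `sd`.
#' @param flag_sd flag threshold (strict inequality).
#' @return data.frame with `measure`, `value`, `mean`, `sd`, `z`, `flag`.
#' @export
zscore_panel <- function(values, bands, flag_sd = 2) {
  stopifnot(!is.null(names(values)), all(c("measure", "mean", "sd") %in% names(bands)))
  idx <- match(names(values), bands$measure)
  if (anyNA(idx)) {
    stop("zscore panel error: missing band for measure(s) ",
         paste(names(values)[is.na(idx)], collapse = ", "))
  }
  m <- bands$mean[idx]; s <- bands$sd[idx]
  if (any(s <= 0)) stop("zscore panel error: band SD must be positive")
  z <- (values - m) / s
  # strict inequality with a numerical guard so a value at exactly the
  # threshold is not flagged
  data.frame(measure = names(values), value = as.numeric(values),
             mean = m, sd = s, z = as.numeric(z),
             flag = (abs(z) - flag_sd) > 1e-9, stringsAsFactors = FALSE)
}

#' Synthetic normative gait bands
#'
#' Generates smooth, gait-like mean ± SD reference bands for
#' cycle-normalized channels (sinusoid mixtures with a stance/swing phase
#' structure) and scalar spatiotemporal measures.  This is a synthetic
#' stand-in for laboratory normative datasets, which are not redistributed
#' with the package; it reproduces their format and rough magnitudes, not
#' their subject data.  Deterministic for a given seed.
#'
#' @param seed RNG seed.
#' @param percent_stance stance fraction of the cycle used to place phase
#'   structure (percent).
#' @return list with `channels` (named list; each has `percent`, `mean`,
#'   `sd`) and `measures` (data.frame `measure`, `mean`, `sd`).
#' @export
normative_fixture <- function(seed = 1, percent_stance = 62) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pct <- seq(0, 100, by = 1)
  s <- pct / 100
  st <- percent_stance / 100
  mk <- function(amp, base, phase, wobble) {
    mean <- base + amp * cos(2 * pi * (s - phase)) +
      0.3 * amp * sin(4 * pi * (s - phase)) +
      wobble * exp(-((s - st)^2) / 0.01)
    sdv <- pmax(0.06 * (max(mean) - min(mean)), 1e-3) *
      (1 + 0.5 * abs(sin(2 * pi * s + runif(1, 0, pi))))
    list(percent = pct, mean = mean, sd = sdv)
  }
  channels <- list(
    hip_angle_deg = mk(20, 10, 0.05, 0),
    knee_angle_deg = mk(25, 25, 0.75, -8),
    ankle_angle_deg = mk(10, 2, 0.45, -12),
    hip_moment_Nm = mk(40, 0, 0.1, 10),
    knee_moment_Nm = mk(25, 5, 0.2, 8),
    ankle_moment_Nm = mk(50, -40, 0.48, -25),
    grf_x_N = mk(120, 0, 0.3, 40),
    grf_y_N = mk(180, 420, 0.5, 120))
  measures <- data.frame(
    measure = c("speed_m_s", "percent_stance", "cadence_steps_min",
                "step_length_m", "peak_plantarflexion_moment_Nm",
                "peak_grf_x_N", "peak_dorsiflexion_stance_deg",
                "stance_hip_flexion_deg", "stance_knee_flexion_deg"),
    mean = c(1.25, 62, 113, 0.66, 110, 170, 14, 25, 15),
    sd = c(0.15, 3, 9, 0.07, 20, 30, 4, 6, 6),
    stringsAsFactors = FALSE)
  list(channels = channels, measures = measures, seed = seed)
}

#' Write / read normative band CSV files
#'
#' One CSV per channel with columns `percent`, `mean`, `sd`.
#'
#' @param bands a fixture from [normative_fixture()] (or the same shape).
#' @param dir output directory (created if needed).
#' @return the directory (write) or a bands list (read).
#' @export
write_bands <- function(bands, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bands$channels)) {
    ch <- bands$channels[[nm]]
    write.csv(data.frame(percent = ch$percent, mean = ch$mean, sd = ch$sd),
              file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  write.csv(bands$measures, file.path(dir, "measures.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_bands
#' @export
read_bands <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  channels <- list()
  measures <- NULL
  for (f in files) {
    nm <- sub("\\.csv$", "", basename(f))
    tab <- read.csv(f)
    if (nm == "measures") measures <- tab
    else channels[[nm]] <- list(percent = tab$percent, mean = tab$mean, sd = tab$sd)
  }
  list(channels = channels, measures = measures)
}
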