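# msk_model: build, validate, and mutate the planar musculoskeletal model.

#' Load a planar musculoskeletal model
#'
#' Reads a structured YAML model description (segments, joints, muscles,
#' contact spheres, ligament limit springs, curve and metabolic constants)
#' and returns a validated `msk_model` object.  The package ships an
#' editable default describing an adult of about 1.8 m and 75.16 kg with 9
#' mobile degrees of freedom and 18 muscle-tendon units (9 sagittal muscle
#' groups per leg); its parameter values are documented approximations meant
#' to be edited in place.
#'
#' Base (unimpaired) values of maximum isometric force and optimal fiber
#' length are stored alongside the working values so that deficit
#' transforms ([apply_deficit()]) always scale from the unimpaired model and
#' severity chains do not compound.
#'
#' @param path path to a model YAML file; `NULL` loads the shipped default.
#' @return an object of class `msk_model`.
#' @seealso [apply_deficit()], [validate_model()], [simulate_gait()]
#' @examples
#' m <- gait_model()
#' m
#' @export
gait_model <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_model.yaml", package = "reflexgait")
  }
  if (!file.exists(path)) {
    stop("model file not found: ", path)
  }
  cfg <- yaml::read_yaml(path)
  model <- build_model_from_config(cfg, source = path)
  validate_model(model)
  model
}

#' @rdname gait_model
#' @param cfg a parsed model configuration list (as from `yaml::read_yaml`).
#' @param source provenance string stored on the object.
#' @export
build_model_from_config <- function(cfg, source = "<config>") {
  need <- c("segments", "joints", "muscles", "contact", "curves",
            "metabolics", "ligaments")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("model configuration error: missing section(s) ",
         paste(missing, collapse = ", "))
  }
  for (seg in c("trunk", "thigh", "shank", "foot")) {
    if (is.null(cfg$segments[[seg]])) {
      stop("model configuration error: missing segment entry '", seg, "'")
    }
  }
  for (mus in MUSCLE_GROUPS) {
    if (is.null(cfg$muscles[[mus]])) {
      stop("model configuration error: missing muscle entry '", mus, "'")
    }
  }

  seg <- cfg$segments
  segments <- data.frame(
    name = c("trunk", "thigh", "shank", "foot"),
    mass = c(seg$trunk$mass_kg, seg$thigh$mass_kg, seg$shank$mass_kg,
             seg$foot$mass_kg),
    moment_of_inertia = c(seg$trunk$inertia_kgm2, seg$thigh$inertia_kgm2,
                          seg$shank$inertia_kgm2, seg$foot$inertia_kgm2),
    length = c(seg$trunk$length_m, seg$thigh$length_m, seg$shank$length_m,
               seg$foot$length_m),
    com_offset = c(seg$trunk$com_offset_m, seg$thigh$com_offset_m,
                   seg$shank$com_offset_m, NA),
    stringsAsFactors = FALSE)
  if (any(segments$mass <= 0) || any(segments$length <= 0) ||
      any(segments$moment_of_inertia < 0)) {
    stop("model validation error: segment masses and lengths must be positive, inertias non-negative")
  }

  # bilateral muscle table; path coefficients per spanned joint
  one_side <- function(side) {
    rows <- lapply(MUSCLE_GROUPS, function(nm) {
      mu <- cfg$muscles[[nm]]
      p <- mu$path
      gp <- function(joint, field) {
        if (is.null(p[[joint]])) 0 else p[[joint]][[field]] %||% 0
      }
      data.frame(
        name = nm, side = side,
        f_max_iso = mu$f_max_iso_N,
        l_opt = mu$l_opt_m,
        l_tendon_slack = mu$l_tendon_slack_m,
        tendon_strain_at_fmax = mu$tendon_strain_at_fmax,
        v_max = mu$v_max_lopt_s %||% 15,
        tau_act = mu$tau_act_s %||% 0.010,
        tau_deact = mu$tau_deact_s %||% 0.040,
        passive_curve_scale = mu$passive_curve_scale %||% 1,
        fast_twitch_fraction = mu$fast_twitch_fraction %||% 0.5,
        hip_c1 = gp("hip", "c1_m_rad"), hip_c2 = gp("hip", "c2_m_rad2"),
        knee_c1 = gp("knee", "c1_m_rad"), knee_c2 = gp("knee", "c2_m_rad2"),
        ankle_c1 = gp("ankle", "c1_m_rad"), ankle_c2 = gp("ankle", "c2_m_rad2"),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  muscles <- rbind(one_side("L"), one_side("R"))
  muscles$base_f_max_iso <- muscles$f_max_iso
  muscles$base_l_opt <- muscles$l_opt
  if (any(muscles$f_max_iso <= 0) || any(muscles$l_opt <= 0)) {
    stop("model validation error: f_max_iso and l_opt must be positive")
  }

  sph <- cfg$contact$spheres
  if (is.null(sph$heel) || is.null(sph$toe_medial) || is.null(sph$toe_lateral)) {
    stop("model configuration error: each foot needs heel, toe_medial and toe_lateral spheres")
  }
  mk_sph <- function(leg) {
    data.frame(
      leg = leg,
      name = c("heel", "toe_medial", "toe_lateral"),
      offset_x = c(sph$heel$offset_x_m, sph$toe_medial$offset_x_m,
                   sph$toe_lateral$offset_x_m),
      offset_y = c(sph$heel$offset_y_m, sph$toe_medial$offset_y_m,
                   sph$toe_lateral$offset_y_m),
      radius = c(sph$heel$radius_m, sph$toe_medial$radius_m,
                 sph$toe_lateral$radius_m),
      plane_strain_modulus = cfg$contact$plane_strain_modulus_N_m2,
      dissipation = cfg$contact$dissipation_s_m,
      mu_static = cfg$contact$mu_static,
      mu_dynamic = cfg$contact$mu_dynamic,
      mu_viscous = cfg$contact$mu_viscous %||% 0,
      transition_velocity = cfg$contact$transition_velocity_m_s,
      stringsAsFactors = FALSE)
  }
  contact <- rbind(mk_sph("L"), mk_sph("R"))

  kp <- cfg$joints$knee$translation_poly_m %||% c(0, 0, 0)
  if (any(unlist(kp) != 0)) {
    stop("model configuration error: nonzero knee translation polynomials are ",
         "not supported by the dynamics core; set translation_poly_m to zeros")
  }

  lig_limits <- function(joint) {
    r <- cfg$joints[[joint]]$range_limit_deg
    c(lo = r[[1]] * pi / 180, hi = r[[2]] * pi / 180)
  }
  lims <- rbind(hip = lig_limits("hip"), knee = lig_limits("knee"),
                ankle = lig_limits("ankle"))
  ligaments <- data.frame(
    joint = JOINT_DOFS,
    lower = lims[c("hip", "knee", "ankle", "hip", "knee", "ankle"), "lo"],
    upper = lims[c("hip", "knee", "ankle", "hip", "knee", "ankle"), "hi"],
    stiffness = cfg$ligaments$stiffness_Nm,
    width = cfg$ligaments$width_deg * pi / 180,
    stringsAsFactors = FALSE)

  total_mass <- segments$mass[1] + 2 * sum(segments$mass[2:4])

  joints <- data.frame(
    name = c("pelvis_ground", "lumbar", "hip_L", "knee_L", "ankle_L",
             "hip_R", "knee_R", "ankle_R"),
    kind = c("planar-3dof", "locked", "pin-1dof", "coupled-knee-1dof",
             "pin-1dof", "pin-1dof", "coupled-knee-1dof", "pin-1dof"),
    dof = c(3, 0, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)

  structure(list(
    name = cfg$name %||% "planar-model",
    source = source,
    config = cfg,
    segments = segments,
    joints = joints,
    muscles = muscles,
    contact = contact,
    ligaments = ligaments,
    curves = cfg$curves,
    metabolics = cfg$metabolics,
    head_point_height = cfg$head_point_height_m %||% 0.7,
    lumbar_locked_deg = cfg$joints$lumbar$locked_angle_deg %||% 5,
    gravity = cfg$gravity_m_s2 %||% STANDARD_GRAVITY,
    fall_com_fraction = cfg$fall_com_fraction %||% 0.8,
    total_mass = total_mass,
    deficits = list()
  ), class = "msk_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate model invariants
#'
#' Checks the structural invariants of a planar walking model: 9 mobile
#' degrees of freedom with exactly one planar base joint and a locked lumbar
#' joint, 18 muscles (9 groups per leg), 6 contact spheres (one 5 cm heel
#' and two 2.5 cm toe spheres per foot), positive inertial and muscle
#' parameters, and left/right symmetry of the unimpaired model.  Called by
#' [gait_model()]; also useful after hand-editing a model file.
#'
#' @param model an `msk_model`.
#' @param bilateral_symmetry require left/right parameter equality (disable
#'   after unilateral edits).
#' @return invisibly, a census list (dof, muscle, sphere counts).
#' @export
validate_model <- function(model, bilateral_symmetry = length(model$deficits) == 0) {
  stopifnot(inherits(model, "msk_model"))
  ndof <- sum(model$joints$dof)
  if (ndof != 9) stop("model validation error: mobile DOF count is ", ndof, ", expected 9")
  if (sum(model$joints$kind == "planar-3dof") != 1) {
    stop("model validation error: exactly one planar-3dof base joint required")
  }
  if (nrow(model$muscles) != 18) {
    stop("model validation error: expected 18 muscles, found ", nrow(model$muscles))
  }
  if (nrow(model$contact) != 6) {
    stop("model validation error: expected 6 contact spheres, found ", nrow(model$contact))
  }
  heel <- model$contact[model$contact$name == "heel", ]
  toes <- model$contact[model$contact$name != "heel", ]
  if (!all(abs(heel$radius - 0.05) < 1e-12) || !all(abs(toes$radius - 0.025) < 1e-12)) {
    stop("model validation error: per foot, one heel sphere r = 0.05 m and two toe spheres r = 0.025 m are required")
  }
  if (bilateral_symmetry) {
    num <- vapply(model$muscles, is.numeric, logical(1))
    L <- model$muscles[model$muscles$side == "L", num]
    R <- model$muscles[model$muscles$side == "R", num]
    if (!isTRUE(all.equal(L, R, check.attributes = FALSE))) {
      stop("model validation error: unimpaired model must be bilaterally symmetric")
    }
  }
  expected_mass <- model$segments$mass[1] + 2 * sum(model$segments$mass[2:4])
  if (abs(model$total_mass - expected_mass) > 1e-9) {
    stop("model validation error: total_mass must equal the sum of segment masses")
  }
  invisible(list(n_dof = ndof, n_muscles = nrow(model$muscles),
                 n_spheres = nrow(model$contact),
                 total_mass = model$total_mass))
}

#' @export
print.msk_model <- function(x, ...) {
  cat("Planar musculoskeletal model:", x$name, "\n")
  cat(sprintf("  total mass %.2f kg, gravity %.5f m/s^2\n", x$total_mass, x$gravity))
  cat(sprintf("  9 mobile DOF (planar pelvis + hip/knee/ankle x 2), lumbar locked at %g deg\n",
              x$lumbar_locked_deg))
  cat(sprintf("  %d muscle-tendon units, %d contact spheres\n",
              nrow(x$muscles), nrow(x$contact)))
  if (length(x$deficits)) {
    cat("  applied deficits:\n")
    for (d in x$deficits) {
      cat(sprintf("    %s %s (%s)\n", d$severity, d$kind, d$target))
    }
  } else {
    cat("  unimpaired (no deficits applied)\n")
  }
  invisible(x)
}

# deficit severity scale factors (fractions of the base value retained)
WEAKNESS_SCALE <- c(mild = 0.25, moderate = 0.125, severe = 0.0625)
CONTRACTURE_SCALE <- c(mild = 0.85, moderate = 0.70, severe = 0.55)

#' Specify a plantarflexor deficit
#'
#' A deficit targets the soleus (`SOL`), gastrocnemius (`GAS`) or both
#' plantarflexors (`PF`), on both legs.  Weakness scales the muscle's
#' maximum isometric force to 25% (mild), 12.5% (moderate) or 6.25%
#' (severe) of its unimpaired value; contracture scales the optimal fiber
#' length to 85%, 70% or 55%.
#'
#' @param target `"SOL"`, `"GAS"` or `"PF"`.
#' @param kind `"weakness"` or `"contracture"`.
#' @param severity `"mild"`, `"moderate"` or `"severe"`.
#' @return a `deficit_spec` list.
#' @export
deficit_spec <- function(target = c("SOL", "GAS", "PF"),
                         kind = c("weakness", "contracture"),
                         severity = c("mild", "moderate", "severe")) {
  target <- match.arg(target)
  kind <- match.arg(kind)
  severity <- match.arg(severity)
  structure(list(target = target, kind = kind, severity = severity),
            class = "deficit_spec")
}

#' Apply a deficit transform to a model
#'
#' Returns a new model (the input is unchanged) in which only the targeted
#' parameters are scaled, bilaterally, from the stored unimpaired base
#' values.  Because scaling is always relative to the base, applying the
#' same deficit twice is idempotent, and weakness/contracture transforms
#' commute.
#'
#' @param model an `msk_model`.
#' @param deficit a [deficit_spec()] (or a list with `target`, `kind`,
#'   `severity`); may also be a list of several specs, applied in order.
#' @return the mutated `msk_model`.
#' @examples
#' m <- gait_model()
#' weak <- apply_deficit(m, deficit_spec("SOL", "weakness", "severe"))
#' weak$muscles$f_max_iso[weak$muscles$name == "SOL"] /
#'   m$muscles$f_max_iso[m$muscles$name == "SOL"]  # 0.0625
#' @export
apply_deficit <- function(model, deficit) {
  stopifnot(inherits(model, "msk_model"))
  if (is.null(deficit) || (is.list(deficit) && length(deficit) == 0)) {
    return(model)
  }
  if (!inherits(deficit, "deficit_spec") && is.list(deficit) &&
      is.null(deficit$target)) {
    for (d in deficit) model <- apply_deficit(model, d)
    return(model)
  }
  if (!all(c("target", "kind", "severity") %in% names(deficit))) {
    stop("deficit validation error: need target, kind and severity")
  }
  target <- as.character(deficit$target)
  kind <- as.character(deficit$kind)
  severity <- as.character(deficit$severity)
  if (!target %in% c("SOL", "GAS", "PF")) {
    stop("deficit validation error: unknown target '", target, "'")
  }
  if (!kind %in% c("weakness", "contracture")) {
    stop("deficit validation error: unknown kind '", kind, "'")
  }
  if (!severity %in% c("mild", "moderate", "severe")) {
    stop("deficit validation error: unknown severity '", severity, "'")
  }
  muscles <- if (target == "PF") c("SOL", "GAS") else target
  rows <- model$muscles$name %in% muscles   # both sides
  if (kind == "weakness") {
    s <- WEAKNESS_SCALE[[severity]]
    model$muscles$f_max_iso[rows] <- model$muscles$base_f_max_iso[rows] * s
  } else {
    s <- CONTRACTURE_SCALE[[severity]]
    model$muscles$l_opt[rows] <- model$muscles$base_l_opt[rows] * s
  }
  # mirror into the raw config so write_model() round-trips
  for (nm in muscles) {
    if (kind == "weakness") {
      model$config$muscles[[nm]]$f_max_iso_N <-
        model$muscles$f_max_iso[model$muscles$name == nm][1]
    } else {
      model$config$muscles[[nm]]$l_opt_m <-
        model$muscles$l_opt[model$muscles$name == nm][1]
    }
  }
  model$deficits <- c(
    Filter(function(d) !(d$target == target && d$kind == kind), model$deficits),
    list(list(target = target, kind = kind, severity = severity)))
  model
}

#' Enumerate all deficit cases
#'
#' All combinations of kind (weakness, contracture), severity (mild,
#' moderate, severe) and target (SOL, GAS, PF): 18 cases, ordered
#' mild to severe within each target so that each case can seed the
#' next more severe one in the optimization chain.
#'
#' @return a data.frame with columns `target`, `kind`, `severity`.
#' @export
deficit_cases <- function() {
  out <- expand.grid(severity = c("mild", "moderate", "severe"),
                     target = c("SOL", "GAS", "PF"),
                     kind = c("weakness", "contracture"),
                     stringsAsFactors = FALSE)
  out[, c("target", "kind", "severity")]
}

#' Write a model back to YAML
#'
#' @param model an `msk_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "msk_model"))
  yaml::write_yaml(model$config, path, precision = 15)
  invisible(path)
}

# --- internal: flatten to the C++ core layout -------------------------------

as_core_model <- function(model) {
  seg <- model$segments
  trunk <- seg[seg$name == "trunk", ]
  thigh <- seg[seg$name == "thigh", ]
  shank <- seg[seg$name == "shank", ]
  foot <- seg[seg$name == "foot", ]
  fc <- model$config$segments$foot
  segv <- c(trunk$mass, trunk$moment_of_inertia, trunk$com_offset,
            model$head_point_height,
            thigh$mass, thigh$moment_of_inertia, thigh$length, thigh$com_offset,
            shank$mass, shank$moment_of_inertia, shank$length, shank$com_offset,
            foot$mass, foot$moment_of_inertia,
            fc$com_offset_x_m, fc$com_offset_y_m,
            model$total_mass)
  cv <- model$curves
  curves <- c(cv$active_fl_width, cv$passive_kpe, cv$passive_strain_at_one,
              cv$tendon_shape_k, cv$fv_curvature_K, cv$fv_eccentric_plateau_N)
  mtb <- c(model$metabolics$specific_tension_N_m2,
           model$metabolics$muscle_density_kg_m3)
  mus <- model$muscles
  # rows must be ordered L (9 groups) then R
  ord <- order(match(mus$side, c("L", "R")), match(mus$name, MUSCLE_GROUPS))
  mus <- mus[ord, ]
  dof_of <- function(side, joint) {
    idx <- match(paste0(joint, "_", side), DOF_NAMES) - 1L  # 0-based
    idx
  }
  mrows <- t(vapply(seq_len(nrow(mus)), function(i) {
    r <- mus[i, ]
    joints <- c("hip", "knee", "ankle")
    c1 <- c(r$hip_c1, r$knee_c1, r$ankle_c1)
    c2 <- c(r$hip_c2, r$knee_c2, r$ankle_c2)
    used <- which(c1 != 0 | c2 != 0)
    if (length(used) > 2) stop("muscle '", r$name, "' spans more than two joints")
    j <- c(-1, -1); cc1 <- c(0, 0); cc2 <- c(0, 0)
    for (k in seq_along(used)) {
      j[k] <- dof_of(r$side, joints[used[k]])
      cc1[k] <- c1[used[k]]; cc2[k] <- c2[used[k]]
    }
    L0 <- r$l_opt + r$l_tendon_slack
    c(r$f_max_iso, r$l_opt, r$l_tendon_slack, r$tendon_strain_at_fmax,
      r$v_max, r$tau_act, r$tau_deact, r$passive_curve_scale,
      r$fast_twitch_fraction, L0, j[1], cc1[1], cc2[1], j[2], cc1[2], cc2[2])
  }, numeric(16)))
  ct <- model$contact
  ct <- ct[order(match(ct$leg, c("L", "R")), match(ct$name, c("heel", "toe_medial", "toe_lateral"))), ]
  crows <- cbind(ifelse(ct$leg == "L", 0, 1), ct$offset_x, ct$offset_y,
                 ct$radius, ct$plane_strain_modulus, ct$dissipation,
                 ct$mu_dynamic, ct$transition_velocity)
  lg <- model$ligaments
  lrows <- cbind(match(lg$joint, DOF_NAMES) - 1L, lg$lower, lg$upper,
                 lg$stiffness, lg$width)
  list(seg = segv, grav = model$gravity, fall_frac = model$fall_com_fraction,
       curves = curves, metab = mtb, mus = mrows, contact = crows, lig = lrows)
}

# ordered (side-major) muscle labels as used by the core and trajectories
core_muscle_names <- function() {
  c(paste0(MUSCLE_GROUPS, "_L"), paste0(MUSCLE_GROUPS, "_R"))
}

#' Locate a muscle row index in core ordering
#' @noRd
mus_index <- function(name, side) {
  match(paste0(name, "_", side), core_muscle_names())
}
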