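# workbench_io: run directories, manifests, reproduction, and the CLI.

#' Save an optimization run
#'
#' Writes a self-describing run directory: `manifest.json` (package
#' version, seed, protocol, objective weights, content hashes of the model
#' and controller files), copies of the model and controller files, the
#' per-generation history CSV, the best design vector, the best rollout as
#' a motion table, and a JSON metric report.  Replaying the snapshot with
#' the recorded seed reproduces the best objective value exactly.
#'
#' @param fit a `gait_fit`.
#' @param dir output directory (created).
#' @return the directory, invisibly.
#' @export
save_run <- function(fit, dir) {
  stopifnot(inherits(fit, "gait_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model_file <- file.path(dir, "model.yaml")
  ctrl_file <- file.path(dir, "controller.yaml")
  write_model(fit$model, model_file)
  yaml::write_yaml(fit$controller$config, ctrl_file, precision = 15)
  manifest <- list(
    package = "reflexgait",
    version = as.character(utils::packageVersion("reflexgait")),
    seed = fit$seed,
    protocol = unclass(fit$protocol),
    weights = fit$weights,
    speed = fit$speed,
    best_J = sprintf("%.17g", fit$best_J),  # lossless decimal round-trip
    hashes = list(model = unname(tools::md5sum(model_file)),
                  controller = unname(tools::md5sum(ctrl_file))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(fit$history)) {
    write.csv(cbind(generation = seq_len(nrow(fit$history)), fit$history),
              file.path(dir, "history.csv"), row.names = FALSE)
  }
  jsonlite::write_json(as.list(fit$best), file.path(dir, "best_solution.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_sto(fit$trajectory, file.path(dir, "best_trajectory.sto"))
  report <- list(J = fit$best_J,
                 raw = as.list(fit$breakdown$raw),
                 weighted = as.list(fit$breakdown$weighted),
                 status = fit$trajectory$status,
                 t_end = fit$trajectory$t_end)
  jsonlite::write_json(report, file.path(dir, "objective.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Reproduce a saved run
#'
#' Re-executes the optimization from a run directory's snapshot and seed
#' and compares the best objective value.  The manifest's content hashes
#' are verified first; a mismatch raises an integrity error.
#'
#' @param dir run directory written by [save_run()].
#' @return list with `pass` (logical), `best_J_original`,
#'   `best_J_replayed`, `difference`.
#' @export
reproduce_run <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  model_file <- file.path(dir, "model.yaml")
  ctrl_file <- file.path(dir, "controller.yaml")
  for (nm in c("model", "controller")) {
    f <- if (nm == "model") model_file else ctrl_file
    h <- unname(tools::md5sum(f))
    if (!identical(h, manifest$hashes[[nm]])) {
      stop("integrity error: ", nm, " file hash mismatch in ", dir)
    }
  }
  model <- gait_model(model_file)
  controller <- gait_controller(ctrl_file)
  protocol <- do.call(gait_protocol, manifest$protocol[
    c("t_des", "lambda", "mu", "max_gen", "n_parallel",
      "improvement_threshold", "rtol")])
  speed <- manifest$speed
  speed$v_min <- as.numeric(speed$v_min)   # "Inf" survives JSON as a string
  speed$v_max <- as.numeric(speed$v_max)
  fit <- optimize_gait(model, controller, protocol = protocol, speed = speed,
                       seed = manifest$seed,
                       weights = do.call(objective_weights, manifest$weights))
  best_orig <- as.numeric(manifest$best_J)
  diff <- abs(fit$best_J - best_orig)
  list(pass = diff == 0, best_J_original = best_orig,
       best_J_replayed = fit$best_J, difference = diff)
}

# --- command line interface -------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: gaitsim <subcommand> [options]",
    "",
    "subcommands:",
    "  validate        --model FILE            check model invariants, print census",
    "  controller-lint --controller FILE       verify the 70+4+16 parameter census",
    "  simulate        --model F --controller F [--tdes S] [--out FILE.sto]",
    "  optimize        --model F --controller F [--preset NAME] [--seed N] [--out DIR]",
    "  apply-deficit   --model F --target SOL|GAS|PF --kind weakness|contracture",
    "                  --severity mild|moderate|severe --out FILE.yaml",
    "  analyze         --sto FILE.sto --mass KG [--objective]",
    "  mtu-curves      [--out FILE.csv]        dump sampled Hill curves as CSV",
    "  fixtures        --out DIR [--seed N]    write synthetic normative bands",
    sep = "\n")
}

cli_args <- function(argv) {
  out <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i < length(argv) && !startsWith(argv[i + 1], "--")) {
        out[[key]] <- argv[i + 1]; i <- i + 2
      } else {
        out[[key]] <- TRUE; i <- i + 1
      }
    } else i <- i + 1
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the `gaitsim` subcommands (see `inst/cli/gaitsim.R` for the
#' executable wrapper).  Returns an exit status: 0 on success, 1 on a
#' contract or validation error, 2 on usage errors.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit status, invisibly.
#' @export
gait_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) { message(cli_usage()); return(invisible(2L)) }
  sub <- argv[1]
  opts <- cli_args(argv[-1])
  status <- tryCatch({
    switch(sub,
      validate = {
        model <- gait_model(opts$model)
        cen <- validate_model(model)
        cat(sprintf("OK: %d DOF, %d muscles, %d contact spheres, mass %.2f kg\n",
                    cen$n_dof, cen$n_muscles, cen$n_spheres, cen$total_mass))
        0L
      },
      `controller-lint` = {
        ctrl <- gait_controller(opts$controller)
        cen <- lint_controller(ctrl)
        cat(sprintf("OK: %d gains/offsets + %d thresholds + %d initial-state = %d design variables (%d laws)\n",
                    cen$n_gain_offset, cen$n_thresholds, cen$n_initial_state,
                    cen$n_design, cen$n_laws))
        0L
      },
      simulate = {
        model <- gait_model(opts$model)
        ctrl <- gait_controller(opts$controller)
        t_des <- as.numeric(opts$tdes %||% 2)
        traj <- simulate_gait(model, ctrl, t_des = t_des, strict = FALSE)
        print(traj)
        if (!is.null(opts$out)) {
          write_sto(traj, opts$out)
          cat("trajectory written to ", opts$out, "\n", sep = "")
        }
        0L
      },
      optimize = {
        model <- gait_model(opts$model)
        ctrl <- gait_controller(opts$controller)
        protocol <- if (!is.null(opts$preset)) protocol_presets(opts$preset)
                    else protocol_presets("desk")
        fit <- optimize_gait(model, ctrl, protocol = protocol,
                             seed = as.integer(opts$seed %||% 1))
        print(fit)
        if (!is.null(opts$out)) save_run(fit, opts$out)
        0L
      },
      `apply-deficit` = {
        model <- gait_model(opts$model)
        d <- deficit_spec(opts$target, opts$kind, opts$severity)
        out_model <- apply_deficit(model, d)
        if (is.null(opts$out)) stop("apply-deficit requires --out FILE.yaml")
        write_model(out_model, opts$out)
        cat("deficit model written to ", opts$out, "\n", sep = "")
        0L
      },
      analyze = {
        mat <- read_sto(opts$sto)
        mass <- as.numeric(opts$mass %||% 75.16)
        traj <- structure(list(time = mat[, "time"], data = mat,
                               status = "completed",
                               t_end = max(mat[, "time"]), t_fall = NA_real_,
                               mass = mass, gravity = STANDARD_GRAVITY,
                               basal_rate_W_kg = 1.2,
                               t_des = max(mat[, "time"]), output_dt = NA),
                          class = "gait_trajectory")
        if (isTRUE(opts$objective)) {
          br <- gait_objective(traj, degenerate = "penalize")
          cat(jsonlite::toJSON(list(J = br$J, raw = as.list(br$raw),
                                    weighted = as.list(br$weighted)),
                               auto_unbox = TRUE, digits = NA, pretty = TRUE),
              "\n")
        } else {
          print(spatiotemporal_summary(traj))
        }
        0L
      },
      `mtu-curves` = {
        lmn <- seq(0.4, 1.8, by = 0.01)
        v <- seq(-15, 15, by = 0.1)
        strain <- seq(-0.01, 0.12, by = 0.001)
        fm <- force_multipliers(lmn)
        tab1 <- data.frame(norm_fiber_length = lmn,
                           active_fl = fm$active_fl, passive_fl = fm$passive_fl)
        tab2 <- data.frame(norm_fiber_velocity = v,
                           fv = force_multipliers(1, v)$fv)
        tab3 <- data.frame(strain = strain,
                           tendon_fnorm_049 = .tendon_force_norm(strain, 0.049, 3),
                           tendon_fnorm_100 = .tendon_force_norm(strain, 0.10, 3))
        out <- opts$out %||% "mtu_curves.csv"
        n <- max(nrow(tab1), nrow(tab2), nrow(tab3))
        pad <- function(d) { d[seq_len(n), , drop = FALSE] }
        write.csv(cbind(pad(tab1), pad(tab2), pad(tab3)), out, row.names = FALSE)
        cat("curves written to ", out, "\n", sep = "")
        0L
      },
      fixtures = {
        bands <- normative_fixture(seed = as.integer(opts$seed %||% 1))
        if (is.null(opts$out)) stop("fixtures requires --out DIR")
        write_bands(bands, opts$out)
        cat("normative bands written to ", opts$out, "\n", sep = "")
        0L
      },
      {
        message("unknown subcommand: ", sub, "\n\n", cli_usage())
        2L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
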