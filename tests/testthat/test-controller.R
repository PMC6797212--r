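# Reflex controller: census, state machine, delays, excitation laws.

test_that("default controller exposes the canonical parameter census", {
  ctrl <- test_controller()
  cen <- controller_census(ctrl)
  expect_equal(cen$n_gain_offset, 70)
  expect_equal(cen$n_thresholds, 4)
  expect_equal(cen$n_controller, 74)
  expect_equal(cen$n_initial_state, 16)
  expect_equal(cen$n_design, 90)
  expect_silent(lint_controller(ctrl))
})

test_that("structural constraints are enforced at load time", {
  # PD on a non-hip muscle is rejected
  expect_error(mini_controller(list(
    list(id = "BAD", kind = "PD", target = "VAS", phases = list("ES"),
         params = list(Kp = list(value = 1, sd = 1, min = -5, max = 5),
                       Kv = list(value = 0, sd = 1, min = -5, max = 5),
                       theta_o = list(value = 0, sd = 1, min = -1, max = 1))))),
    "hip-spanning")
  # cross-muscle law other than SOL->TA is rejected
  expect_error(mini_controller(list(
    list(id = "BAD2", kind = "F+", target = "VAS", source = "GAS",
         phases = list("ES"),
         params = list(K = list(value = 1, sd = 1, min = 0, max = 5))))),
    "cross-muscle")
  # unknown muscle is a configuration error
  expect_error(mini_controller(list(
    list(id = "BAD3", kind = "C", target = "PSOAS", phases = list("ES"),
         params = list(K = list(value = 1, sd = 1, min = 0, max = 1))))),
    "unknown muscle")
})

test_that("reflex delays follow the most-proximal-joint rule", {
  ctrl <- test_controller()
  for (l in ctrl$laws) {
    if (l$kind == "C") next
    expected <- if (l$kind == "F-" && l$source == "SOL" && l$target == "TA") {
      0.040
    } else {
      switch(reflexgait:::PROXIMAL_JOINT[[l$target]],
             hip = 0.005, knee = 0.010, ankle = 0.020)
    }
    expect_equal(l$delay, expected, info = l$id)
  }
})

test_that("state-machine transitions follow the five rules", {
  thr <- c(es_to_ms_dist_m = 0, ps_to_s_grf_N = 50,
           s_to_lp_dist_m = 0.25, lp_to_es_grf_N = 40)
  # PS -> S when ipsilateral GRF drops below threshold
  expect_equal(update_phase(c("PS", "MS"), c(0.1, -0.1), c(30, 400), thr)[1], "S")
  # ES -> MS when the foot-pelvis distance drops below threshold
  expect_equal(update_phase(c("ES", "S"), c(-0.05, 0.1), c(400, 0), thr)[1], "MS")
  # S -> LP when the foot swings ahead of the distance threshold
  expect_equal(update_phase(c("MS", "S"), c(0, 0.3), c(400, 0), thr)[2], "LP")
  # LP -> ES on loading, and the contralateral MS leg then enters PS
  out <- update_phase(c("MS", "LP"), c(0, 0.3), c(400, 100), thr)
  expect_equal(out, c("PS", "ES"))
  # no threshold crossed: phases unchanged
  expect_equal(update_phase(c("MS", "S"), c(0.1, 0.1), c(400, 0), thr),
               c("MS", "S"))
})

test_that("phase sequence in rollouts never skips states", {
  m <- test_model()
  ctrl <- test_controller()
  tr <- simulate_gait(m, ctrl, t_des = 3, strict = FALSE)
  successor <- c(ES = "MS", MS = "PS", PS = "S", S = "LP", LP = "ES")
  for (col in c("phase_L", "phase_R")) {
    ph <- reflexgait:::PHASE_NAMES[tr$data[, col] + 1]
    ch <- which(diff(tr$data[, col]) != 0)
    for (i in ch) {
      expect_equal(ph[i + 1], unname(successor[ph[i]]))
    }
  }
})

test_that("delayed sensing interpolates history with startup pre-fill", {
  tt <- seq(0, 1, by = 0.01)
  hist <- list(time = tt, values = cbind(ramp = 2 * tt))
  # zero delay returns the current value
  expect_equal(sense_delayed(hist, "ramp", 0.5, 0), 1.0)
  # linear ramp: f(t - tD) = 2 (t - tD)
  expect_equal(sense_delayed(hist, "ramp", 0.5, 0.02), 2 * (0.5 - 0.02),
               tolerance = 1e-10)
  # before the buffer start: the pre-filled initial value
  expect_equal(sense_delayed(hist, "ramp", 0.005, 0.02), 0)
  # delay longer than capacity is a configuration error
  attr(hist, "capacity") <- 0.05
  expect_error(sense_delayed(hist, "ramp", 0.5, 0.1), "capacity")
})

test_that("excitation law arithmetic matches the reflex equations", {
  # single constant law
  c1 <- mini_controller(list(
    list(id = "VAS_C", kind = "C", target = "VAS", phases = list("ES"),
         params = list(K = list(value = 0.05, sd = 0.1, min = 0, max = 1)))))
  u <- compute_excitations(c1, controller_params(c1), mini_sensors(),
                           c("ES", "ES"))
  expect_equal(unname(u[["VAS_L"]]), 0.05)
  expect_equal(unname(u[["VAS_R"]]), 0.05)
  expect_equal(unname(u[["SOL_L"]]), 0)      # floor 0 in the mini controller

  # length feedback with the max(0, .) gate
  c2 <- mini_controller(list(
    list(id = "VAS_L1", kind = "L+", target = "VAS", phases = list("ES"),
         params = list(K = list(value = 2, sd = 0.1, min = 0, max = 5),
                       l_o = list(value = 1.0, sd = 0.1, min = 0.4, max = 1.6)))))
  u_hi <- compute_excitations(c2, controller_params(c2),
                              mini_sensors(lmn = 1.1), c("ES", "ES"))
  u_lo <- compute_excitations(c2, controller_params(c2),
                              mini_sensors(lmn = 0.9), c("ES", "ES"))
  expect_equal(unname(u_hi[["VAS_L"]]), 0.2, tolerance = 1e-12)
  expect_equal(unname(u_lo[["VAS_L"]]), 0)

  # signed force-feedback sum: TA gets F+ 0.5 and SOL->TA F- 0.3
  c3 <- mini_controller(list(
    list(id = "TA_F", kind = "F+", target = "TA", phases = list("ES"),
         params = list(K = list(value = 1.0, sd = 0.1, min = 0, max = 5))),
    list(id = "TA_FSOL", kind = "F-", target = "TA", source = "SOL",
         phases = list("ES"),
         params = list(K = list(value = 0.6, sd = 0.1, min = 0, max = 5)))))
  u3 <- compute_excitations(c3, controller_params(c3),
                            mini_sensors(fnorm = 0.5), c("ES", "ES"))
  expect_equal(unname(u3[["TA_L"]]), 1.0 * 0.5 - 0.6 * 0.5, tolerance = 1e-12)

  # PD law: Kp (theta - theta_o) + Kv thetadot
  c4 <- mini_controller(list(
    list(id = "GMAX_PD", kind = "PD", target = "GMAX", phases = list("ES"),
         params = list(Kp = list(value = 2, sd = 0.1, min = -5, max = 5),
                       Kv = list(value = 0.5, sd = 0.1, min = -5, max = 5),
                       theta_o = list(value = 0, sd = 0.1, min = -1, max = 1)))))
  u4 <- compute_excitations(c4, controller_params(c4),
                            mini_sensors(theta = 0.1, thetadot = -0.1),
                            c("ES", "ES"))
  expect_equal(unname(u4[["GMAX_L"]]), 2 * 0.1 + 0.5 * (-0.1), tolerance = 1e-12)
})

test_that("excitations stay in [0,1] and zeroed gains vanish exactly", {
  ctrl <- test_controller()
  p <- controller_params(ctrl)
  set.seed(33)
  for (i in 1:25) {
    sens <- mini_sensors(lmn = runif(1, 0.4, 1.8), vmn = runif(1, -10, 10),
                         fnorm = runif(1, 0, 1.5), theta = runif(1, -1, 1),
                         thetadot = runif(1, -3, 3))
    phases <- sample(reflexgait:::PHASE_NAMES, 2, replace = TRUE)
    u <- compute_excitations(ctrl, p, sens, phases)
    expect_true(all(u >= 0 & u <= 1))
  }
  # zeroing a law's gain equals removing the law from the topology
  sens <- mini_sensors(fnorm = 0.8, lmn = 1.1, theta = 0.1)
  p0 <- p; p0[["SOL_F_ES.K"]] <- 0
  u_zero <- compute_excitations(ctrl, p0, sens, c("ES", "ES"))
  ctrl_removed <- ctrl
  ctrl_removed$laws <- Filter(function(l) l$id != "SOL_F_ES", ctrl$laws)
  u_removed <- compute_excitations(ctrl_removed, p, sens, c("ES", "ES"))
  expect_equal(u_zero, u_removed, tolerance = 1e-15)
})

test_that("R and core excitation paths agree on random inputs", {
  ctrl <- test_controller()
  p <- controller_params(ctrl)
  core <- reflexgait:::as_core_controller(ctrl)
  set.seed(44)
  for (i in 1:20) {
    ch <- c(runif(18, 0.4, 1.8), runif(18, -10, 10), runif(18, 0, 1.5),
            runif(1, -1, 1), runif(1, -3, 3))
    ph <- sample.int(5, 2, replace = TRUE) - 1L
    u_cpp <- reflexgait:::.gait_core_excitations(core, p, ch, ph)
    sens <- list(lmn = ch[1:18], vmn = ch[19:36], fnorm = ch[37:54],
                 theta = ch[55], thetadot = ch[56])
    u_r <- compute_excitations(ctrl, p, sens,
                               reflexgait:::PHASE_NAMES[ph + 1])
    expect_equal(unname(u_r), u_cpp, tolerance = 1e-12)
  }
})

test_that("controller is deterministic and parameters round-trip by name", {
  ctrl <- test_controller()
  p <- controller_params(ctrl)
  sens <- mini_sensors(lmn = 1.2, fnorm = 0.4, theta = 0.05)
  u1 <- compute_excitations(ctrl, p, sens, c("MS", "S"))
  u2 <- compute_excitations(ctrl, p, sens, c("MS", "S"))
  expect_identical(u1, u2)
  # named round-trip, order-independent
  shuffled <- sample(p)
  ctrl2 <- set_controller_params(ctrl, shuffled)
  expect_identical(controller_params(ctrl2), p)
  expect_error(set_controller_params(ctrl, p[-1]), "74")
})
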