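# Planar dynamics: geometry, contact, ligaments, initialization, rollouts.

test_that("moment arms obey the tendon-excursion identity", {
  m <- test_model()
  set.seed(11)
  h <- 1e-6
  for (rep in 1:20) {
    q <- c(runif(2, -0.2, 0.2), runif(7, -0.6, 0.6))
    geo <- muscle_geometry(m, q)
    j <- sample(4:9, 1)                      # a joint coordinate
    qp <- q; qp[j] <- qp[j] + h
    dL <- (muscle_geometry(m, qp)$length - geo$length) / h
    expect_lt(max(abs(geo$moment_arm[, j] + dL)), 1e-6)
  }
})

test_that("uniarticular and biarticular spanning are respected", {
  m <- test_model()
  q0 <- rep(0, 9)
  qk <- q0; qk[5] <- 0.5                     # left knee
  qa <- q0; qa[6] <- 0.3                     # left ankle
  L0 <- muscle_geometry(m, q0)$length
  Lk <- muscle_geometry(m, qk)$length
  La <- muscle_geometry(m, qa)$length
  # TA spans only the ankle: knee variation leaves it unchanged
  expect_equal(Lk[["TA_L"]], L0[["TA_L"]])
  # GAS spans knee and ankle: responds to both
  expect_false(isTRUE(all.equal(Lk[["GAS_L"]], L0[["GAS_L"]])))
  expect_false(isTRUE(all.equal(La[["GAS_L"]], L0[["GAS_L"]])))
  # VAS spans only the knee
  expect_equal(La[["VAS_L"]], L0[["VAS_L"]])
})

test_that("contact force matches the Hunt-Crossley closed form", {
  m <- test_model()
  heel <- m$contact[m$contact$name == "heel" & m$contact$leg == "L", ]
  expect_equal(unname(contact_force(0, 0, 0, heel)), c(0, 0))
  expect_equal(unname(contact_force(-0.003, 0.1, 0.5, heel)), c(0, 0))
  # literal-formula oracle at 5 mm depth, zero rates
  f <- contact_force(0.005, 0, 0, heel)
  expect_equal(unname(f[["normal"]]),
               oracle_hunt_crossley(0.005, 0, 500000, 0.05, 1.0),
               tolerance = 1e-12)
  expect_equal(unname(f[["tangential"]]), 0)
  # dissipation scales the elastic term linearly
  f2 <- contact_force(0.005, 0.2, 0, heel)
  expect_equal(unname(f2[["normal"]]),
               oracle_hunt_crossley(0.005, 0.2, 500000, 0.05, 1.0))
  # strong withdrawal cannot produce adhesion
  f3 <- contact_force(0.005, -5, 0, heel)
  expect_equal(unname(f3[["normal"]]), 0)
})

test_that("friction ratio approaches the dynamic coefficient at high slip", {
  m <- test_model()
  heel <- m$contact[m$contact$name == "heel" & m$contact$leg == "L", ]
  f <- contact_force(0.005, 0, 1.0, heel)   # slip 1.0 m/s >> 0.1 m/s
  ratio <- abs(f[["tangential"]]) / f[["normal"]]
  expect_equal(unname(ratio), 0.8, tolerance = 0.01 * 0.8)
  expect_lt(unname(ratio), 0.8 + 1e-12)
  # friction opposes the slip direction
  expect_lt(unname(f[["tangential"]]), 0)
  fneg <- contact_force(0.005, 0, -1.0, heel)
  expect_gt(unname(fneg[["tangential"]]), 0)
})

test_that("ligament torques engage only beyond the limits", {
  # knee: 0 to 140 degrees
  expect_equal(ligament_torque(60 * pi / 180, 0, 140 * pi / 180), 0)
  # hyperextension at -5 degrees resists with flexion torque
  t_hx <- ligament_torque(-5 * pi / 180, 0, 140 * pi / 180)
  expect_gt(t_hx, 0)
  # ankle: engaged at 25 degrees dorsiflexion (limit 20)
  t_df <- ligament_torque(25 * pi / 180, -40 * pi / 180, 20 * pi / 180)
  expect_lt(t_df, 0)
  expect_gt(abs(t_df), 0)
  # continuity at the limit
  eps <- 1e-9
  expect_lt(abs(ligament_torque(20 * pi / 180 + eps, -40 * pi / 180,
                                20 * pi / 180)), 1e-6)
})

test_that("initialization meets the half-body-weight condition", {
  m <- test_model()
  ctrl <- test_controller()
  ini <- initialize_state(m, ctrl)
  expect_equal(ini$static_vgrf, 0.5 * 75.16 * 9.80665, tolerance = 0.1 / 368)
  st <- ini$state
  expect_equal(st[1], 0)                     # pelvis x at 0 m
  expect_error(initialize_state(m, ctrl, init16 = rep(0, 10)), "16")
})

test_that("passive pendulum conserves mechanical energy", {
  m <- test_model()
  ctrl <- test_controller()
  # pelvis pinned, muscles and contact off: legs swing as double pendulums
  y0 <- c(0, 1.2, 0, 0.5, 0.3, 0, -0.2, 0.1, 0,  # q
          rep(0, 9),                             # qdot
          rep(0.01, 18), rep(1, 18))             # quiescent muscles
  tr <- simulate_gait(m, ctrl, init = y0, t_des = 5, output_dt = NA,
                      rtol = 1e-8, atol = 1e-10, contact = FALSE,
                      muscles = FALSE, locked_dofs = 1:3)
  expect_identical(tr$status, "completed")
  energy <- vapply(seq_len(nrow(tr$data)), function(i) {
    q <- tr$data[i, paste0("q_", reflexgait:::DOF_NAMES)]
    qd <- tr$data[i, paste0("qd_", reflexgait:::DOF_NAMES)]
    M <- mass_matrix(m, q)
    bp <- body_points(m, q, qd)
    ke <- 0.5 * as.numeric(t(qd) %*% M %*% qd)
    pe <- sum(m$segments$mass[c(1, 2, 3, 4, 2, 3, 4)] * 9.80665 *
              bp$body_pos[, 2])
    ke + pe
  }, numeric(1))
  drift <- max(abs(energy - energy[1]))
  expect_lt(drift / abs(energy[1]), 0.001)   # < 0.1% over 5 s
})

test_that("ground reactions satisfy the impulse-momentum balance", {
  m <- test_model()
  ctrl <- test_controller()
  tr <- simulate_gait(m, ctrl, t_des = 1.0, output_dt = NA, rtol = 1e-5,
                      atol = 1e-7, strict = FALSE)
  d <- tr$data
  tt <- tr$time
  # whole-body momentum from COM velocity at the recorded states
  mom <- t(vapply(seq_len(nrow(d)), function(i) {
    q <- d[i, paste0("q_", reflexgait:::DOF_NAMES)]
    qd <- d[i, paste0("qd_", reflexgait:::DOF_NAMES)]
    bp <- body_points(m, q, qd)
    masses <- m$segments$mass[c(1, 2, 3, 4, 2, 3, 4)]
    colSums(masses * bp$body_vel)
  }, numeric(2)))
  fx <- d[, "grf_L_x"] + d[, "grf_R_x"]
  fy <- d[, "grf_L_y"] + d[, "grf_R_y"] - m$total_mass * 9.80665
  n <- nrow(d)
  win <- tt >= 0.05 & tt <= min(1.0, tt[n])  # a window inside the rollout
  i0 <- which(win)[1]; i1 <- rev(which(win))[1]
  imp_x <- reflexgait:::trapz(tt[i0:i1], fx[i0:i1])
  imp_y <- reflexgait:::trapz(tt[i0:i1], fy[i0:i1])
  scale <- m$total_mass * 9.80665 * (tt[i1] - tt[i0])
  expect_lt(abs((mom[i1, 1] - mom[i0, 1]) - imp_x) / scale, 0.01)
  expect_lt(abs((mom[i1, 2] - mom[i0, 2]) - imp_y) / scale, 0.01)
})

test_that("reported GRFs equal recomputed sphere contact forces", {
  m <- test_model()
  ctrl <- test_controller()
  tr <- simulate_gait(m, ctrl, t_des = 0.4, output_dt = NA, strict = FALSE)
  d <- tr$data
  heel <- m$contact[m$contact$name == "heel" & m$contact$leg == "L", ]
  for (i in seq(1, nrow(d), length.out = 25)) {
    q <- d[i, paste0("q_", reflexgait:::DOF_NAMES)]
    qd <- d[i, paste0("qd_", reflexgait:::DOF_NAMES)]
    bp <- body_points(m, q, qd)
    total <- c(0, 0)
    for (s in 1:3) {                         # left-foot spheres
      sp <- bp$spheres[s, ]
      r <- m$contact$radius[s]
      depth <- r - sp[2]
      if (depth > 0) {
        total <- total + contact_force(depth, -sp[4], sp[3], m$contact[s, ])
      }
    }
    expect_equal(unname(total),
                 unname(d[i, c("grf_L_x", "grf_L_y")]), tolerance = 1e-8)
  }
})

test_that("an unactuated model falls and termination is recorded", {
  m <- test_model()
  ctrl <- test_controller()
  params <- controller_params(ctrl)
  params[] <- 0                              # all laws silenced
  tr <- simulate_gait(m, ctrl, params = params, t_des = 5, strict = FALSE)
  expect_identical(tr$status, "fell")
  expect_false(is.na(tr$t_fall))
  expect_lte(tr$t_fall, 5)
  # fall criterion: COM below 0.8 x initial COM height at the fall sample
  expect_lt(tr$data[nrow(tr$data), "com_y"], 0.8 * tr$com0 + 1e-6)
})

test_that("a stable passive configuration completes the full duration", {
  m <- test_model()
  ctrl <- test_controller()
  # pelvis pinned, gravity acting on hanging legs: never meets the fall
  # criterion, so the rollout runs to t_des exactly
  y0 <- c(0, 1.2, 0, 0.2, 0.1, 0, -0.1, 0.2, 0, rep(0, 9),
          rep(0.01, 18), rep(1, 18))
  tr <- simulate_gait(m, ctrl, init = y0, t_des = 2, contact = FALSE,
                      muscles = FALSE, locked_dofs = 1:3)
  expect_identical(tr$status, "completed")
  expect_equal(tr$t_end, 2)
  expect_equal(max(tr$time), 2)
})

test_that("motion tables round-trip through the sto dialect", {
  m <- test_model()
  ctrl <- test_controller()
  tr <- simulate_gait(m, ctrl, t_des = 0.2, strict = FALSE)
  f1 <- tempfile(fileext = ".sto")
  write_sto(tr, f1)
  back <- read_sto(f1)
  expect_equal(dim(back), dim(tr$data))
  expect_equal(unname(back[, "q_hip_L"]), unname(tr$data[, "q_hip_L"]),
               tolerance = 1e-6)
  # canonical write -> read -> write is byte-identical
  tr2 <- tr; tr2$data <- back
  f2 <- tempfile(fileext = ".sto")
  write_sto(tr2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
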