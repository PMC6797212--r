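# Hill-type muscle-tendon dynamics and metabolic energetics.

test_that("activation dynamics match the closed-form exponential", {
  # fixed point
  expect_equal(activation_step(0.5, 0.5, 0.01), 0.5)
  # one activation time constant: 1 - exp(-1)
  expect_equal(activation_step(0, 1, dt = 0.010), 1 - exp(-1), tolerance = 1e-10)
  # one deactivation time constant: exp(-1)
  expect_equal(activation_step(1, 0, dt = 0.040), exp(-1), tolerance = 1e-10)
  expect_error(activation_step(0.5, 0.5, dt = 0), "dt")
  expect_error(activation_step(0.5, 0.5, dt = -0.01), "dt")
})

test_that("sub-stepping agrees with a single step for constant excitation", {
  for (case in list(c(a = 0.1, u = 0.9), c(a = 0.8, u = 0.2))) {
    a1 <- activation_step(case[["a"]], case[["u"]], dt = 0.05)
    a2 <- case[["a"]]
    for (i in 1:500) a2 <- activation_step(a2, case[["u"]], dt = 0.05 / 500)
    expect_lt(abs(a1 - a2), 1e-8)
  }
})

test_that("force multipliers satisfy the Hill-curve endpoints", {
  fm <- force_multipliers(1, 0)
  expect_equal(fm$active_fl, 1)
  expect_equal(fm$fv, 1)
  expect_equal(fm$passive_fl, 0)
  # maximum shortening velocity: no force
  expect_equal(force_multipliers(1, -15)$fv, 0, tolerance = 1e-12)
  # far below the active range
  expect_lt(force_multipliers(0.5, 0)$active_fl, 0.05)
  # eccentric plateau bounds fv above
  v <- seq(0, 60, by = 0.5)
  expect_true(all(force_multipliers(1, v)$fv <= 1.5 + 1e-12))
  # passive curve is non-decreasing
  l <- seq(0.5, 1.8, by = 0.001)
  expect_true(all(diff(force_multipliers(l)$passive_fl) >= 0))
})

test_that("all multipliers are continuous on a dense grid", {
  l <- seq(0.3, 2.0, length.out = 20001)
  v <- seq(-20, 20, length.out = 20001)
  fm_l <- force_multipliers(l)
  fm_v <- force_multipliers(1, v)$fv
  h_l <- diff(l)[1]; h_v <- diff(v)[1]
  # no jumps: finite differences scale with grid spacing x curve slope bound
  expect_lt(max(abs(diff(fm_l$active_fl))), 20 * h_l)
  expect_lt(max(abs(diff(fm_l$passive_fl))), 200 * h_l)
  expect_lt(max(abs(diff(fm_v))), 0.5 * h_v)
})

test_that("tendon force is zero when slack and f_max at the reference strain", {
  expect_equal(tendon_force(-0.01, 6000), 0)
  expect_equal(tendon_force(0, 6000), 0)
  # reference strain hits f_max within 0.1% for both tendon classes
  expect_equal(tendon_force(0.049, 6000, 0.049), 6000, tolerance = 1e-3)
  expect_equal(tendon_force(0.10, 4250, 0.10), 4250, tolerance = 1e-3)
  # strictly increasing for positive strain
  s <- seq(1e-4, 0.15, by = 1e-4)
  expect_true(all(diff(tendon_force(s, 1000, 0.049)) > 0))
})

test_that("equilibrium residual is tiny over 1000 random valid inputs", {
  m <- test_model()
  set.seed(101)
  mus <- m$muscles
  ord <- order(match(mus$side, c("L", "R")),
               match(mus$name, reflexgait:::MUSCLE_GROUPS))
  mus <- mus[ord, ]
  worst <- 0
  for (i in 1:1000) {
    idx <- sample.int(18, 1)
    r <- mus[idx, ]
    a <- runif(1)
    # lengths covering slack through stretched configurations
    L <- r$l_tendon_slack + r$l_opt * runif(1, 0.55, 1.6)
    res <- equilibrate_muscle(m, idx, L, a)
    # independent residual evaluation (literal transcription)
    ora <- oracle_equilibrium_residual(m, idx, res$norm_fiber_length, L, a)
    worst <- max(worst, abs(ora))
  }
  expect_lt(worst, 1e-6)  # in units of f_max_iso
})

test_that("equilibration balances passive force for a quiescent muscle", {
  m <- test_model()
  r <- m$muscles[m$muscles$name == "GMAX" & m$muscles$side == "L", ]
  L <- r$l_tendon_slack + 1.2 * r$l_opt
  res <- equilibrate_muscle(m, "GMAX", L, activation = 0, side = "L")
  lmn <- res$norm_fiber_length
  strain <- (L - lmn * r$l_opt - r$l_tendon_slack) / r$l_tendon_slack
  # stretched fiber with a slightly tensioned tendon
  expect_gt(lmn, 1)
  expect_gte(strain, 0)
  expect_lt(strain, 0.02)
})

test_that("infeasible geometry raises a solver error naming the muscle", {
  m <- test_model()
  r <- m$muscles[m$muscles$name == "SOL" & m$muscles$side == "L", ]
  expect_error(equilibrate_muscle(m, "SOL", 0.05 * r$l_tendon_slack, 0.5),
               "SOL")
})

test_that("metabolic rate is the resting heat for a quiescent muscle", {
  m <- test_model()
  rate <- metabolic_rate(0, 0, 1, 0, f_max_iso = 3000, l_opt = 0.1)
  mass <- 3000 / 250000 * 1059.7 * 0.1
  expect_equal(rate, 1.0 * mass)  # 1 W/kg resting floor
})

test_that("metabolic rate matches an independent Umberger transcription", {
  set.seed(202)
  for (i in 1:100) {
    a <- runif(1); u <- runif(1)
    lmn <- runif(1, 0.6, 1.5)
    v <- runif(1, -12, 12)
    fmax <- runif(1, 500, 6000); lopt <- runif(1, 0.05, 0.16)
    ft <- runif(1)
    got <- metabolic_rate(a, u, lmn, v, fmax, lopt,
                          fast_twitch_fraction = ft)
    want <- oracle_metabolic_rate(a, u, lmn, v, fmax, lopt, ft = ft)
    expect_equal(got, want, tolerance = 1e-10)
    expect_gte(got, 0)
  }
  # maximal isometric contraction at optimal length: pure
  # activation+maintenance heat
  got <- metabolic_rate(1, 1, 1, 0, 3000, 0.1, fast_twitch_fraction = 0.5)
  mass <- 3000 / 250000 * 1059.7 * 0.1
  expect_equal(got, (128 * 0.5 + 25) * mass, tolerance = 1e-10)
})

test_that("eccentric contractions never yield negative rates", {
  set.seed(203)
  for (i in 1:50) {
    rate <- metabolic_rate(runif(1), runif(1), runif(1, 1.0, 1.6),
                           runif(1, 0, 15), 2000, 0.08)
    expect_gte(rate, 0)
  }
})
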