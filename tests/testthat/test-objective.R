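# Four-term rollout objective.

test_that("psi applies the linear out-of-range penalty", {
  expect_equal(psi(1.25, 1.20, 1.30), 0)
  expect_equal(psi(1.10, 1.20, 1.30), 0.10)
  expect_equal(psi(1.45, 1.20, 1.30), 0.15)
  expect_equal(psi(c(-1, 0, 1), -0.5, 0.5), c(0.5, 0, 0.5))
})

test_that("speed term hits its boundary values", {
  spec <- prescribed_speed(1.25)
  expect_equal(spec$v_min, 1.20)
  expect_equal(spec$v_max, 1.30)
  # immediate fall, no steps
  expect_equal(j_spd(data.frame(), 0, 10, 0, spec), 1)
  expect_equal(j_spd(NULL, 0, 10, 0, spec), 1)
  # completed rollout whose in-range steps tile the horizon
  steps <- data.frame(duration = rep(0.5, 20), speed = rep(1.25, 20),
                      t_end = cumsum(rep(0.5, 20)))
  expect_equal(j_spd(steps, 10, 10, NA, spec), 0)
  # partial stepping: linear in the covered time
  steps2 <- data.frame(duration = rep(0.5, 10), speed = rep(1.25, 10),
                       t_end = cumsum(rep(0.5, 10)))
  expect_equal(j_spd(steps2, 10, 10, NA, spec), 0.5)
})

test_that("speed term penalizes out-of-range steps by duration", {
  spec <- self_selected(0.75)
  # two equal-duration steps, one in range, one with psi-penalty 0.5 m/s
  steps <- data.frame(duration = c(5, 5), speed = c(1.0, 0.25),
                      t_end = c(5, 10))
  val <- j_spd(steps, 10, 10, NA, spec)
  expect_equal(val, 1 - (5 * 1 + 5 * 0.5) / 10)   # 0.25
  expect_gt(val, 0); expect_lt(val, 1)
  # monotone: worsening a step's penalty never lowers J_spd
  worse <- steps; worse$speed[2] <- 0.10
  expect_gte(j_spd(worse, 10, 10, NA, spec), val)
})

test_that("steps completed before a fall keep their credit", {
  spec <- self_selected(0.75)
  steps <- data.frame(duration = c(1, 1, 1), speed = c(1, 1, 1),
                      t_end = c(1, 2, 3))
  # fall at 2.5 s: the first two steps count, the third does not
  expect_equal(j_spd(steps, 2.5, 5, 2.5, spec), 1 - 2 / 5)
  # completed: all three count
  expect_equal(j_spd(steps, 5, 5, NA, spec), 1 - 3 / 5)
  expect_true(all(vapply(seq(0, 3, by = 0.5), function(tf)
    j_spd(steps, tf, 5, tf, spec), numeric(1)) >= 0))
})

test_that("cost of transport follows its closed form", {
  tt <- seq(0, 10, by = 0.01)
  expect_equal(j_cot(rep(300, length(tt)), tt, 75.16, 12.5),
               300 * 10 / (75.16 * 12.5), tolerance = 1e-12)  # 3.193
  expect_equal(j_cot(rep(0, length(tt)), tt, 75.16, 12.5), 0)
  # doubling the distance halves the value
  expect_equal(j_cot(rep(300, length(tt)), tt, 75.16, 25),
               j_cot(rep(300, length(tt)), tt, 75.16, 12.5) / 2)
  expect_error(j_cot(rep(300, length(tt)), tt, 75.16, 0), "zero-displacement")
})

test_that("injury term integrates squared ligament torques", {
  tt <- seq(0, 2, by = 0.001)
  expect_equal(j_inj(matrix(0, length(tt), 6), tt), 0)
  one <- matrix(10, length(tt), 1)
  expect_equal(j_inj(one, tt), 200, tolerance = 1e-9)   # 10^2 * 2 s
  two <- matrix(10, length(tt), 2)
  expect_equal(j_inj(two, tt), 2 * j_inj(one, tt))
})

test_that("head term penalizes out-of-bound accelerations symmetrically", {
  g <- 9.80665
  tt <- seq(0, 1, by = 0.001)
  zero <- rep(0, length(tt))
  expect_equal(j_head(zero, zero, tt), 0)
  in_bounds <- rep(0.2 * g, length(tt))
  expect_equal(j_head(in_bounds, zero, tt), 0)
  # a_x = 0.35 g for 1 s: (0.10 g)^2 ~ 0.9617
  ax <- rep(0.35 * g, length(tt))
  expect_equal(j_head(ax, zero, tt), (0.10 * g)^2, tolerance = 1e-9)
  expect_equal(j_head(-ax, zero, tt), j_head(ax, zero, tt))
})

test_that("objective evaluation is a consistent pure function", {
  m <- test_model()
  ctrl <- test_controller()
  tr <- simulate_gait(m, ctrl, t_des = 2, strict = FALSE)
  b1 <- gait_objective(tr, degenerate = "penalize")
  b2 <- gait_objective(tr, degenerate = "penalize")
  expect_identical(b1, b2)
  expect_equal(b1$J, sum(b1$weighted))
  expect_identical(unname(b1$weighted), unname(b1$weights * b1$raw))
  expect_true(all(b1$raw >= 0))
  expect_gte(b1$raw[["spd"]], 0); expect_lte(b1$raw[["spd"]], 1)
  # default weights follow the framework defaults
  w <- objective_weights()
  expect_equal(unlist(w), c(cot = 1, spd = 10000, inj = 0.1, head = 0.25))
  # weighted-sum arithmetic at reference raw values
  expect_equal(sum(unlist(w) * c(1, 0.1, 2, 0.4)), 1001.3)
})

test_that("missing channels raise a contract error naming the channel", {
  m <- test_model()
  ctrl <- test_controller()
  tr <- simulate_gait(m, ctrl, t_des = 0.2, strict = FALSE)
  tr$data <- tr$data[, setdiff(colnames(tr$data), "edot")]
  expect_error(gait_objective(tr, degenerate = "penalize"), "edot")
})

test_that("a silenced controller is dominated by the speed penalty", {
  m <- test_model()
  ctrl <- test_controller()
  params <- controller_params(ctrl); params[] <- 0
  tr <- simulate_gait(m, ctrl, params = params, t_des = 5, strict = FALSE)
  expect_identical(tr$status, "fell")
  br <- gait_objective(tr, degenerate = "penalize")
  # near-saturated speed term (passive drift may register marginal steps)
  expect_gte(unname(br$weighted[["spd"]]), 0.95 * 10000)
  expect_gt(br$weighted[["spd"]] / br$J, 0.5)        # dominant term
})
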