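# CMA-ES optimizer and the parallel-set restart protocol.

test_that("CMA-ES solves the 10-D sphere to high precision", {
  res <- cma_es(rep(3, 10), function(x) sum(x^2), lower = -5, upper = 5,
                sigma = 1, lambda = 16, mu = 8, max_gen = 200, seed = 7)
  expect_lt(res$best_value, 1e-6)
  expect_lte(res$generations, 200)
  expect_lt(sum(res$best_par^2), 1e-6)
})

test_that("best-ever objective is non-increasing across generations", {
  res <- cma_es(rep(2, 6), function(x) sum((x - 1)^2) + 0.5, lower = -4,
                upper = 4, sigma = 0.5, lambda = 12, mu = 6, max_gen = 80,
                seed = 3)
  expect_true(all(diff(res$history$best_ever) <= 0))
  expect_equal(min(res$history$best_ever), res$best_value)
})

test_that("fixed seeds replay bit-identically and restore the global RNG", {
  set.seed(999)
  before <- runif(1)
  set.seed(999)
  r1 <- cma_es(rep(1, 5), function(x) sum(abs(x)), lower = -3, upper = 3,
               sigma = 0.4, lambda = 8, mu = 4, max_gen = 30, seed = 11)
  after <- runif(1)
  expect_identical(before, after)           # global RNG stream untouched
  r2 <- cma_es(rep(1, 5), function(x) sum(abs(x)), lower = -3, upper = 3,
               sigma = 0.4, lambda = 8, mu = 4, max_gen = 30, seed = 11)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best_par, r2$best_par)
})

test_that("candidates respect the box constraints", {
  seen <- new.env(); seen$bad <- 0
  fn <- function(x) {
    if (any(x < -1 | x > 1)) seen$bad <- seen$bad + 1
    sum(x^2)
  }
  cma_es(rep(0.9, 4), fn, lower = -1, upper = 1, sigma = 0.8, lambda = 10,
         mu = 5, max_gen = 40, seed = 5)
  expect_equal(seen$bad, 0)
})

test_that("an all-failing generation raises an optimization error", {
  expect_error(
    cma_es(rep(0, 3), function(x) NA_real_, lower = -1, upper = 1,
           sigma = 0.1, lambda = 6, mu = 3, max_gen = 5, seed = 1),
    "optimization error")
})

test_that("restart protocol stops on the 5% improvement rule", {
  # flat objective: the second set cannot improve -> exactly 2 sets
  flat <- function(x) 1
  res <- restart_protocol(flat, c(0, 0), lower = -1, upper = 1, sigma = 0.2,
                          protocol = list(lambda = 4, mu = 2, max_gen = 2,
                                          n_parallel = 1,
                                          improvement_threshold = 0.05),
                          seed = 2)
  expect_equal(nrow(res$sets), 2)
  expect_equal(res$best_value, 1)

  # scripted improvement sequence 100 -> 90 -> 87: stops after the third
  # set because (90 - 87)/90 = 3.3% < 5%
  env <- new.env(); env$calls <- 0
  evals_per_set <- 4 * 2                     # lambda x max_gen, n_parallel 1
  scripted <- function(x) {
    env$calls <- env$calls + 1
    set_idx <- ceiling(env$calls / evals_per_set)
    c(100, 90, 87, 86.9)[min(set_idx, 4)]
  }
  res2 <- restart_protocol(scripted, c(0, 0), lower = -1, upper = 1,
                           sigma = 0.2,
                           protocol = list(lambda = 4, mu = 2, max_gen = 2,
                                           n_parallel = 1,
                                           improvement_threshold = 0.05),
                           seed = 2)
  expect_equal(nrow(res2$sets), 3)
  expect_equal(res2$sets$best, c(100, 90, 87))
  expect_equal(res2$best_value, 87)
  # improvement column documents the rule
  expect_equal(res2$sets$improvement[2], 0.10, tolerance = 1e-12)
  expect_equal(res2$sets$improvement[3], 3 / 90, tolerance = 1e-12)
})

test_that("protocol presets encode the full-scale protocol settings", {
  ps <- protocol_presets("prescribed_speed")
  expect_equal(ps$t_des, 10)
  expect_equal(ps$n_parallel, 20)
  expect_equal(ps$max_gen, 3000)
  expect_equal(ps$lambda, 16); expect_equal(ps$mu, 8)
  expect_equal(ps$speeds, seq(0.5, 2.0, by = 0.25))
  expect_length(ps$speeds, 7)
  # seeding starts at the middle speed and works outward
  expect_equal(ps$seed_order[1], 1.25)

  ss <- protocol_presets("self_selected")
  expect_equal(ss$t_des, 30)
  expect_equal(ss$n_parallel, 10)
  expect_equal(ss$max_gen, 1500)
  expect_equal(ss$v_min, 0.75)

  dc <- protocol_presets("deficit_chain")
  expect_equal(dc$order, c("mild", "moderate", "severe"))
  expect_equal(dc$seed, "unimpaired")

  expect_error(protocol_presets("nope"), "available")
})

test_that("design vectors round-trip by name with bounds and SDs", {
  ctrl <- test_controller()
  x <- design_vector(ctrl)
  expect_length(x, 90)
  b <- design_bounds(ctrl)
  s <- design_sds(ctrl)
  expect_identical(names(b$lower), names(x))
  expect_identical(names(s), names(x))
  expect_true(all(x >= b$lower & x <= b$upper))
  expect_true(all(s > 0))
  sp <- reflexgait:::split_design(ctrl, x)
  expect_length(sp$params, 74)
  expect_length(sp$init, 16)
  expect_identical(c(sp$params, sp$init), x)
})
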