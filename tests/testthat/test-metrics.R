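# Gait analysis: segmentation, spatiotemporal measures, comparison metrics.

test_that("step events are recovered from synthetic square-wave GRFs", {
  dt <- 0.005
  tt <- seq(0, 5, by = dt)
  grf <- walking_grf(tt, period = 0.55, duty = 0.62)
  tr <- synth_traj(tt, list(grf_L_y = grf$L, grf_R_y = grf$R,
                            com_x = 1.2545 * tt))
  ev <- segment_steps(tr)
  expect_identical(attr(ev, "status"), "ok")
  strikes_R <- ev$time[ev$type == "strike" & ev$foot == "R"]
  # right-foot strikes occur at odd multiples of 0.55 s (known truth)
  truth <- seq(0.55, 4.8, by = 1.1)
  for (s in truth) {
    # events register within the 30 ms debounce window plus one sample
    expect_lte(min(abs(strikes_R - s)), 0.03 + dt + 1e-9)
  }
  steps <- attr(ev, "steps")
  expect_gt(nrow(steps), 4)
  expect_equal(steps$duration, rep(0.55, nrow(steps)), tolerance = 0.05)
  # first two steps flagged as excluded
  expect_identical(steps$excluded[1:2], c(TRUE, TRUE))
  expect_false(any(steps$excluded[-(1:2)]))
})

test_that("continuous double support yields no swing and flags invalid cycles", {
  tt <- seq(0, 3, by = 0.01)
  bw <- 75.16 * 9.80665
  tr <- synth_traj(tt, list(grf_L_y = rep(0.5 * bw, length(tt)),
                            grf_R_y = rep(0.5 * bw, length(tt))))
  ev <- segment_steps(tr)
  expect_equal(sum(ev$type == "lift"), 0)
  expect_equal(nrow(attr(ev, "steps")), 0)
})

test_that("no contacts yields an empty event list with a warning", {
  tt <- seq(0, 1, by = 0.01)
  tr <- synth_traj(tt)
  expect_warning(ev <- segment_steps(tr), "no foot contacts")
  expect_identical(attr(ev, "status"), "no_contact")
  expect_equal(nrow(ev), 0)
})

test_that("spatiotemporal measures follow their definitions", {
  dt <- 0.005
  tt <- seq(0, 6, by = dt)
  grf <- walking_grf(tt, period = 0.55, duty = 0.62)
  # pelvis advances 0.69 m per 0.55 s step; standing posture so the foot
  # contact points track the pelvis
  q_cols <- list(grf_L_y = grf$L, grf_R_y = grf$R,
                 com_x = (0.69 / 0.55) * tt, q_pelvis_x = (0.69 / 0.55) * tt,
                 q_pelvis_y = rep(0.94, length(tt)))
  tr <- synth_traj(tt, q_cols, model = test_model())
  summ <- spatiotemporal_summary(tr)
  expect_equal(summ$mean_cadence, 60 / 0.55, tolerance = 0.05)   # ~109
  expect_equal(summ$mean_speed, 0.69 / 0.55, tolerance = 0.01)   # ~1.25
  expect_equal(summ$mean_step_length, 0.69, tolerance = 0.05)
  expect_equal(summ$mean_percent_stance, 62, tolerance = 2)
  # stance + swing partition each cycle exactly
  cyc <- summ$cycles
  swing <- 100 * (cyc$duration - cyc$stance_duration) / cyc$duration
  expect_equal(cyc$percent_stance + swing, rep(100, nrow(cyc)))
})

test_that("cycle normalization resamples onto 101 points", {
  tt <- seq(0, 2, by = 0.001)
  cyc <- data.frame(t_start = c(0, 1), t_end = c(1, 2))
  # constant channel
  out <- normalize_cycle(rep(3, length(tt)), tt, cyc)
  expect_length(out$mean, 101)
  expect_equal(out$mean, rep(3, 101))
  expect_equal(out$percent, seq(0, 100, by = 1))
  # dense sine resampled within 1e-3 of the analytic values
  s <- tt %% 1
  out2 <- normalize_cycle(sin(2 * pi * s), tt, cyc)
  expect_lt(max(abs(out2$mean - sin(2 * pi * out2$percent / 100))), 1e-3)
  # two identical cycles: the mean equals either cycle
  expect_equal(out2$mean, out2$cycles[1, ], tolerance = 1e-9)
  expect_equal(out2$cycles[1, ], out2$cycles[2, ], tolerance = 1e-9)
  # single incomplete cycle errors
  expect_error(normalize_cycle(sin(tt), tt, data.frame()), "cycle")
})

test_that("cycle normalization is idempotent on a 101-sample cycle", {
  pct_time <- seq(0, 1, length.out = 101)
  x <- cos(2 * pi * pct_time) + 0.3 * pct_time
  out <- normalize_cycle(x, pct_time, data.frame(t_start = 0, t_end = 1))
  expect_equal(out$mean, x, tolerance = 1e-12)
})

test_that("rmse_sd matches hand arithmetic and brute force", {
  expect_equal(rmse_sd(rep(1, 101), rep(1, 101), rep(0.2, 101)), 0)
  expect_equal(rmse_sd(rep(1.3, 101), rep(1, 101), rep(0.3, 101)), 1,
               tolerance = 1e-12)
  # 3-sample toy with z = 0, 1, 2
  expect_equal(rmse_sd(c(0, 1, 2), rep(0, 3), rep(1, 3)), sqrt(5 / 3),
               tolerance = 1e-12)
  expect_error(rmse_sd(1:3, 1:3, c(1, 0, 1)), "positive")
  set.seed(55)
  for (i in 1:20) {
    sim <- rnorm(101); mu <- rnorm(101); sdv <- runif(101, 0.1, 2)
    brute <- sqrt(sum(((sim - mu) / sdv)^2) / 101)
    expect_equal(rmse_sd(sim, mu, sdv), brute, tolerance = 1e-12)
  }
})

test_that("ncc is the zero-lag Pearson correlation of shapes", {
  x <- sin(seq(0, 2 * pi, length.out = 101))
  expect_equal(ncc(x, x), 1, tolerance = 1e-12)
  expect_equal(ncc(x, -x), -1, tolerance = 1e-12)
  # affine invariance with positive slope
  expect_equal(ncc(2.5 * x + 7, x), 1, tolerance = 1e-12)
  expect_error(ncc(rep(1, 101), x), "zero-variance")
  set.seed(56)
  for (i in 1:20) {
    a <- rnorm(101); b <- rnorm(101)
    brute <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(ncc(a, b), brute, tolerance = 1e-12)
    expect_gte(ncc(a, b), -1); expect_lte(ncc(a, b), 1)
  }
})

test_that("z-score panel flags deviations strictly beyond 2 SD", {
  bands <- data.frame(measure = c("speed_m_s", "percent_stance"),
                      mean = c(1.25, 62), sd = c(0.15, 3))
  z0 <- zscore_panel(c(speed_m_s = 1.25), bands)
  expect_equal(z0$z, 0); expect_false(z0$flag)
  # exactly 2 SD sits on the boundary and is not flagged (strict >)
  z2 <- zscore_panel(c(speed_m_s = 1.25 + 2 * 0.15), bands)
  expect_equal(z2$z, 2); expect_false(z2$flag)
  # the severe-weakness-like slow speed is flagged
  zs <- zscore_panel(c(speed_m_s = 0.87), bands)
  expect_equal(zs$z, (0.87 - 1.25) / 0.15, tolerance = 1e-12)  # ~ -2.53
  expect_true(zs$flag)
  expect_error(zscore_panel(c(unknown = 1), bands), "unknown")
  # invariance to a consistent change of units
  z_m <- zscore_panel(c(speed_m_s = 0.87), bands)
  bands_cm <- bands; bands_cm$mean <- bands$mean * 100; bands_cm$sd <- bands$sd * 100
  z_cm <- zscore_panel(c(speed_m_s = 87), bands_cm)
  expect_equal(z_m$z, z_cm$z, tolerance = 1e-12)
})

test_that("synthetic normative bands are deterministic and well-formed", {
  b1 <- normative_fixture(seed = 5)
  b2 <- normative_fixture(seed = 5)
  expect_identical(b1$channels, b2$channels)
  b3 <- normative_fixture(seed = 6)
  expect_false(identical(b1$channels, b3$channels))
  for (ch in b1$channels) {
    expect_length(ch$mean, 101)
    expect_true(all(ch$sd > 0))
    expect_equal(rmse_sd(ch$mean, ch$mean, ch$sd), 0)
  }
  expect_true(all(b1$measures$sd > 0))
  # CSV round-trip
  dir <- tempfile()
  write_bands(b1, dir)
  back <- read_bands(dir)
  expect_equal(back$channels$hip_angle_deg$mean, b1$channels$hip_angle_deg$mean)
  expect_equal(back$measures$mean, b1$measures$mean)
})
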