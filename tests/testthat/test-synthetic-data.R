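test_that("planted configurations are deterministic and respect their invariants", {
  a <- make_planted_configuration(300, cluster_fraction = 0.4, seed = 11)
  b <- make_planted_configuration(300, cluster_fraction = 0.4, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- make_planted_configuration(300, cluster_fraction = 0.4, seed = 12)
  expect_false(identical(a$x, c$x))

  # labels partition the sites; counts follow the requested fraction
  expect_equal(nrow(a), 300)
  expect_equal(sum(is.na(a$truth)), 0)
  expect_equal(sum(a$truth != "free"), round(0.4 * 300))

  # all positions wrapped into the box
  box <- attr(a, "box_xy")
  expect_true(all(a$x >= 0 & a$x < box[1]))
  expect_true(all(a$y >= 0 & a$y < box[2]))
})

test_that("hard-disk sampling never places free sites closer than the minimum", {
  cfg <- make_planted_configuration(400, cluster_fraction = 0, seed = 21,
                                    box = c(20, 20), min_distance = 0.45)
  pos <- cbind(cfg$x, cfg$y)
  box <- attr(cfg, "box_xy")
  dx <- outer(pos[, 1], pos[, 1], "-"); dx <- dx - box[1] * round(dx / box[1])
  dy <- outer(pos[, 2], pos[, 2], "-"); dy <- dy - box[2] * round(dy / box[2])
  d2 <- dx^2 + dy^2; diag(d2) <- Inf
  expect_gte(sqrt(min(d2)), 0.45 - 1e-12)
})

test_that("cluster-fraction extremes give pure lattice or pure matrix truth", {
  full <- triangular_config()
  expect_setequal(as.character(unique(full$truth)), c("core", "edge"))
  none <- make_planted_configuration(100, cluster_fraction = 0, seed = 5,
                                     box = c(20, 20))
  expect_true(all(none$truth == "free"))
  # infeasible density errors out rather than looping forever
  expect_error(
    make_planted_configuration(500, cluster_fraction = 0, box = c(5, 5),
                               seed = 1, max_attempts = 50),
    class = "lipidorder_error_density"
  )
})

test_that("observable series reproduce their planted structure exactly at zero noise", {
  # equal slopes collapse the piecewise model to a straight line
  s <- make_observable_series("piecewise_linear",
    truth = list(breakpoint = 310, slope_below = 0.002, slope_above = 0.002),
    grid = seq(293, 333, 2), noise_sd = 0, seed = 1)
  fit <- lm(value ~ temperature, data = s)
  expect_lt(max(abs(resid(fit))), 1e-12)

  # a single gaussian peaks exactly at its mean
  g <- make_observable_series("gaussian_mixture",
    truth = list(means = 314, sigmas = 2, amplitudes = 1, baseline = c(0, 0)),
    grid = seq(293, 333, 0.5), noise_sd = 0, seed = 1)
  expect_equal(g$temperature[which.max(g$value)], 314)

  # zero-width sigmoid degenerates to a step at the inflection
  st <- make_observable_series("sigmoid",
    truth = list(t_inflection = 314, width = 0,
                 lower = c(1, 0), upper = c(0, 0)),
    grid = seq(293, 333, 1), noise_sd = 0, seed = 1)
  expect_true(all(st$value[st$temperature < 314] == 1))
  expect_true(all(st$value[st$temperature >= 314] == 0))

  # breakpoint outside the grid is a parameter error
  expect_error(
    make_observable_series("piecewise_linear", truth = list(breakpoint = 400),
                           grid = seq(293, 333, 2)),
    class = "lipidorder_error_parameter"
  )
})

test_that("series regeneration under one seed is bit-for-bit", {
  a <- make_observable_series("sigmoid", grid = seq(288, 338, 2),
                              noise_sd = 0.05, seed = 99)
  b <- make_observable_series("sigmoid", grid = seq(288, 338, 2),
                              noise_sd = 0.05, seed = 99)
  expect_identical(a$value, b$value)
})

test_that("toy trajectories plant what they claim", {
  # static centers at D = 0
  toy0 <- make_toy_trajectory(n_lipids = 6, n_frames = 4, d = 0, seed = 2)
  tr <- lipid_tracks(toy0$frames, species = "DPPC")
  drift <- tapply(tr$x, tr$id, function(v) diff(range(v)))
  expect_true(all(drift == 0))

  # perfectly ordered untilted rods: |S_CD| = 0.5 exactly
  toy <- make_toy_trajectory(n_lipids = 8, n_frames = 2, order_level = 0.5,
                             tilt = 0, seed = 3)
  prof <- deuterium_order(toy$frames)
  expect_equal(attr(prof, "mean_scd"), -0.5, tolerance = 1e-12)

  # MSD follows the analytic 4 D t law within sampling error
  w <- make_observable_series("brownian", truth = list(d = 2, n_walkers = 60),
                              grid = seq(0, 50, 0.5), seed = 4)
  dfit <- lateral_diffusion(w, dt = 0.5)
  msd_mid <- dfit$msd[which.min(abs(dfit$msd$time - 10)), ]
  expect_equal(msd_mid$msd, 4 * 2 * msd_mid$time, tolerance = 0.15)
})
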