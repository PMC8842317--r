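test_that("generalized polarization arithmetic, bounds and antisymmetry", {
  df <- data.frame(i_blue = c(1, 1, 1, 0), i_red = c(1, 0, 3, 0))
  expect_warning(out <- generalized_polarization(df),
                 class = "lipidorder_warning_undefined")
  expect_equal(out$gp, c(0, 1, -0.5, NA))
  ok <- !is.na(out$gp)
  expect_true(all(out$gp[ok] >= -1 & out$gp[ok] <= 1))

  # channel swap flips the sign
  swapped <- generalized_polarization(
    data.frame(i_blue = df$i_red[1:3], i_red = df$i_blue[1:3]))
  expect_equal(swapped$gp, -out$gp[1:3])

  expect_error(generalized_polarization(data.frame(i_blue = -1, i_red = 1)),
               class = "lipidorder_error_parameter")
})

test_that("steady-state anisotropy arithmetic and physical-range flags", {
  df <- data.frame(i_vv = c(2, 1, 5), i_vh = c(1, 1, 0))
  expect_warning(out <- steady_state_anisotropy(df, g = 1),
                 class = "lipidorder_warning_unphysical")
  expect_equal(out$r, c(0.25, 0, 1))
  expect_identical(out$r_unphysical, c(FALSE, FALSE, TRUE))

  # G factor as a column
  df$g <- 2
  out2 <- suppressWarnings(steady_state_anisotropy(df, g = "g"))
  expect_equal(out2$r[2], (1 - 2) / (1 + 4))

  expect_error(steady_state_anisotropy(data.frame(i_vv = 1, i_vh = 1), g = 0),
               class = "lipidorder_error_parameter")
})

test_that("noiseless sigmoids are recovered exactly; lines are flagged", {
  s <- make_observable_series("sigmoid",
    truth = list(t_inflection = 314, width = 2),
    grid = seq(288, 338, length.out = 15), noise_sd = 0, seed = 1)
  ft <- boltzmann_fit(s, n_boot = 0)
  expect_false(ft$no_inflection)
  expect_equal(ft$t_inflection, 314, tolerance = 1e-4)
  expect_equal(ft$width, 2, tolerance = 1e-3)

  lin <- data.frame(temperature = seq(290, 335, 3),
                    value = 0.5 - 0.002 * seq(290, 335, 3))
  expect_true(boltzmann_fit(lin, n_boot = 0)$no_inflection)

  expect_error(boltzmann_fit(s[1:5, ], n_boot = 0),
               class = "lipidorder_error_parameter")
})

test_that("the inflection is invariant under affine rescaling of the observable", {
  s <- make_observable_series("sigmoid", truth = list(t_inflection = 311),
                              grid = seq(288, 338, length.out = 18),
                              noise_sd = 0.005, seed = 2)
  f1 <- boltzmann_fit(s, n_boot = 0)
  s2 <- s
  s2$value <- -3 * s2$value + 10
  f2 <- boltzmann_fit(s2, n_boot = 0)
  expect_equal(f1$t_inflection, f2$t_inflection, tolerance = 1e-3)
})

test_that("flat-baseline fits reduce to the plain Boltzmann", {
  s <- make_observable_series("sigmoid",
    truth = list(t_inflection = 314, width = 2,
                 lower = c(0.4, 0), upper = c(-0.05, 0)),
    grid = seq(288, 338, length.out = 15), noise_sd = 0, seed = 1)
  ft <- boltzmann_fit(s, baseline = "flat", n_boot = 0)
  expect_equal(ft$t_inflection, 314, tolerance = 1e-4)
  expect_equal(ft$lower_slope, 0)
  expect_equal(ft$upper_slope, 0)
})

test_that("high-temperature exclusion masks points before fitting", {
  grid <- seq(288, 348, length.out = 21)
  s <- make_observable_series("sigmoid", truth = list(t_inflection = 314),
                              grid = grid, noise_sd = 0, seed = 1)
  # corrupt the hot tail as a wavelength-dependent artifact would
  s$value[s$temperature > 333] <- s$value[s$temperature > 333] + 0.4
  ft <- boltzmann_fit(s, exclude_above = 333, n_boot = 0)
  expect_equal(ft$t_inflection, 314, tolerance = 0.05)
  expect_lte(max(ft$data$temperature), 333)
})

test_that("DSC decomposition recovers planted components exactly at zero noise", {
  s <- make_observable_series("gaussian_mixture",
    truth = list(means = 318, sigmas = 2, amplitudes = 1,
                 baseline = c(0.05, 0.001)),
    grid = seq(293, 333, 0.5), noise_sd = 0, seed = 1)
  ft <- dsc_decompose(s)
  expect_equal(ft$n_components, 1L)
  expect_false(ft$featureless)
  expect_equal(ft$components$mean, 318, tolerance = 1e-6)
  expect_equal(ft$components$width, 2, tolerance = 1e-4)
  expect_equal(unname(ft$baseline), c(0.05, 0.001), tolerance = 1e-4)

  # components come back sorted by mean and with positive amplitudes
  s2 <- make_observable_series("gaussian_mixture",
    truth = list(means = c(320, 305), sigmas = c(1.5, 3),
                 amplitudes = c(0.7, 1)),
    grid = seq(293, 333, 0.5), noise_sd = 0.005, seed = 2)
  f2 <- dsc_decompose(s2, n_components = 2)
  expect_equal(f2$components$mean, sort(f2$components$mean))
  expect_true(all(f2$components$amplitude >= 0))
  expect_equal(f2$components$mean, c(305, 320), tolerance = 0.01)
})

test_that("featureless thermograms are flagged instead of over-fitted", {
  flat <- data.frame(temperature = seq(293, 333, 1), value = 0.05)
  ft <- dsc_decompose(flat)
  expect_true(ft$featureless)
  expect_equal(ft$n_components, 0L)

  expect_error(dsc_decompose(flat[1:5, ]), class = "lipidorder_error_parameter")
})

test_that("heating and cooling scans are decomposed independently", {
  heat <- make_observable_series("gaussian_mixture",
    truth = list(means = 316, sigmas = 2, amplitudes = 1),
    grid = seq(293, 333, 0.5), noise_sd = 0.005, seed = 3)
  cool <- make_observable_series("gaussian_mixture",
    truth = list(means = 312, sigmas = 2, amplitudes = 1),
    grid = seq(293, 333, 0.5), noise_sd = 0.005, seed = 4)
  both <- rbind(cbind(as.data.frame(heat), scan = "heating"),
                cbind(as.data.frame(cool), scan = "cooling"))
  fits <- dsc_decompose(both)
  expect_named(fits, c("cooling", "heating"))
  expect_equal(fits$heating$components$mean, 316, tolerance = 0.1)
  expect_equal(fits$cooling$components$mean, 312, tolerance = 0.1)
})
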