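test_that("segmented fits recover planted breakpoints and stay continuous", {
  s <- make_observable_series("piecewise_linear",
                              truth = list(breakpoint = 311.3),
                              grid = seq(293, 333, 2), noise_sd = 0, seed = 1)
  ft <- segmented_fit(s, n_boot = 0)
  expect_equal(ft$breakpoint, 311.3, tolerance = 1e-3)
  expect_false(ft$no_crossover)
  tr <- attr(s, "truth")
  expect_equal(ft$slope_below, tr$slope_below, tolerance = 1e-6)
  expect_equal(ft$slope_above, tr$slope_above, tolerance = 1e-6)

  # continuity at the breakpoint by construction
  eps <- 1e-9
  lo <- predict(ft, data.frame(temperature = ft$breakpoint - eps))
  hi <- predict(ft, data.frame(temperature = ft$breakpoint + eps))
  expect_equal(lo, hi, tolerance = 1e-6)

  # breakpoint strictly inside the range
  expect_gt(ft$breakpoint, min(s$temperature))
  expect_lt(ft$breakpoint, max(s$temperature))

  expect_error(segmented_fit(s[1:4, ], n_boot = 0),
               class = "lipidorder_error_parameter")
})

test_that("equal-slope series are flagged as having no crossover", {
  s <- make_observable_series("piecewise_linear",
    truth = list(breakpoint = 313, slope_below = 0.002, slope_above = 0.002),
    grid = seq(293, 333, 2), noise_sd = 0, seed = 1)
  ft <- segmented_fit(s, n_boot = 0)
  expect_true(ft$no_crossover)
})

test_that("breakpoints are invariant under affine rescaling of the observable", {
  s <- make_observable_series("piecewise_linear", truth = list(breakpoint = 308),
                              grid = seq(293, 333, 2), noise_sd = 0.001,
                              seed = 3)
  f1 <- segmented_fit(s, n_boot = 0)
  s2 <- s
  s2$value <- 40 * s2$value - 7
  f2 <- segmented_fit(s2, n_boot = 0)
  expect_equal(f1$breakpoint, f2$breakpoint, tolerance = 1e-6)
  expect_equal(f2$slope_below, 40 * f1$slope_below, tolerance = 1e-6)
})

test_that("bootstrap confidence intervals are seeded and shrink with noise", {
  mk <- function(noise, seed) {
    make_observable_series("piecewise_linear", truth = list(breakpoint = 308),
                           grid = seq(293, 333, 2), noise_sd = noise,
                           seed = seed)
  }
  f_lo <- segmented_fit(mk(0.0005, 4), n_boot = 200, seed = 9)
  f_hi <- segmented_fit(mk(0.004, 4), n_boot = 200, seed = 9)
  expect_lt(diff(f_lo$ci), diff(f_hi$ci))
  # same seed, same CI
  f_again <- segmented_fit(mk(0.0005, 4), n_boot = 200, seed = 9)
  expect_identical(f_lo$ci, f_again$ci)
})

test_that("expansion coefficients follow the closed form", {
  # A(T) = A0 (1 + c (T - T0)) exactly: alpha = c / (1 + c (T_mid - T0))
  a0 <- 0.6; cc <- 0.002; t0 <- 313
  grid <- seq(293, 333, 2)
  s <- data.frame(temperature = grid, value = a0 * (1 + cc * (grid - t0)))
  ft <- segmented_fit(s, n_boot = 0)
  ec <- expansion_coefficients(ft)
  t_mid <- ec$t_mid
  oracle <- (a0 * cc) / (a0 * (1 + cc * (t_mid - t0)))
  expect_equal(ec$alpha, oracle, tolerance = 1e-6)

  # flat segments have zero expansion
  flat <- data.frame(temperature = grid, value = 0.6)
  ft0 <- segmented_fit(flat, n_boot = 0)
  expect_equal(expansion_coefficients(ft0)$alpha, c(0, 0), tolerance = 1e-12)
})

test_that("crossover consensus pools breakpoints and honors flags", {
  mk_fit <- function(b, seed, equal = FALSE) {
    tr <- if (equal) {
      list(breakpoint = b, slope_below = 0.002, slope_above = 0.002)
    } else {
      list(breakpoint = b)
    }
    segmented_fit(
      make_observable_series("piecewise_linear", truth = tr,
                             grid = seq(293, 333, 2), noise_sd = 0,
                             seed = seed),
      n_boot = 0
    )
  }
  # identical breakpoints: consensus equals them with zero spread
  fits <- list(appl = mk_fit(309, 1), tilt = mk_fit(309, 2))
  cons <- crossover_consensus(fits)
  expect_equal(attr(cons, "t_co"), 309, tolerance = 1e-3)
  expect_equal(attr(cons, "spread"), 0, tolerance = 1e-3)

  # a no-crossover observable is excluded
  fits$flat <- mk_fit(309, 3, equal = TRUE)
  cons2 <- crossover_consensus(fits)
  expect_true(cons2$excluded[cons2$observable == "flat"])
  expect_equal(attr(cons2, "t_co"), 309, tolerance = 1e-3)

  # all flagged: empty consensus with a message
  expect_message(cons3 <- crossover_consensus(list(a = mk_fit(309, 4, TRUE))))
  expect_true(is.na(attr(cons3, "t_co")))
})

test_that("a planted common crossover is pooled within two kelvin", {
  fits <- lapply(1:4, function(i) {
    s <- make_observable_series("piecewise_linear",
      truth = list(breakpoint = 313, value_at_break = 1,
                   slope_below = 0.004, slope_above = 0.012),
      grid = seq(293, 333, 2), noise_sd = 0.01, seed = 40 + i)
    segmented_fit(s, n_boot = 100, seed = i)
  })
  names(fits) <- paste0("obs", 1:4)
  cons <- crossover_consensus(fits)
  expect_equal(attr(cons, "t_co"), 313, tolerance = 2 / 313)
})

test_that("temperature series files parse with named errors", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(data.frame(temperature = c(300, 310), value = c(1, 2)), tmp)
  df <- read_temperature_series(tmp)
  expect_named(df, c("temperature", "value"))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tb\n1\t2", bad)
  expect_error(read_temperature_series(bad), class = "lipidorder_error_format")
  expect_error(read_temperature_series("nope.tsv"),
               class = "lipidorder_error_format")
})
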