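#' Generate observable-vs-temperature (or time) series with planted truth
#'
#' Produces the tabular inputs of the curve-fitting stages with known
#' ground-truth parameters: piecewise-linear thermotropic series with a
#' planted slope break (area per phospholipid, tilt, order parameters),
#' sloped-baseline Boltzmann sigmoids (generalized polarization, DPH
#' anisotropy), Gaussian-mixture thermograms on a linear baseline (DSC),
#' stretched-exponential orientation autocorrelation decays, and 2D
#' Brownian walks for diffusion analysis.
#'
#' The truth parameters are stored in the `truth` attribute of the result
#' and regeneration with the same seed is bit-for-bit reproducible.
#'
#' @param kind One of `"piecewise_linear"`, `"sigmoid"`,
#'   `"gaussian_mixture"`, `"exponential_acf"`, `"brownian"`.
#' @param truth Named list of kind-specific ground-truth parameters, merged
#'   over sensible defaults:
#'   * piecewise_linear: `breakpoint` (K), `value_at_break`, `slope_below`,
#'     `slope_above` (units per K);
#'   * sigmoid: `t_inflection` (K), `width` (K; `<= 0` gives a step),
#'     `lower`, `upper` (each `c(level, slope)`: branch value at the
#'     inflection and baseline slope per K);
#'   * gaussian_mixture: `means` (K), `sigmas` (K), `amplitudes`,
#'     `baseline` (`c(intercept, slope)`);
#'   * exponential_acf: `tau` (time units of `grid`), `beta` in (0, 1];
#'   * brownian: `d` (nm^2 per time unit), `n_walkers`.
#' @param grid Strictly increasing temperature (K) or time grid.
#' @param noise_sd Standard deviation of iid Gaussian noise added to the
#'   clean curve (ignored for `"brownian"`).
#' @param seed Integer seed.
#'
#' @return A tibble of class `planted_series`: columns `temperature`,
#'   `value` for thermotropic kinds; `t`, `value` for `exponential_acf`;
#'   `t`, `id`, `x`, `y` for `brownian`. Attributes: `kind`, `truth`,
#'   `noise_sd`, `seed`.
#' @export
#' @examples
#' s <- make_observable_series("piecewise_linear",
#'   truth = list(breakpoint = 308), grid = seq(293, 333, 2), seed = 1)
#' attr(s, "truth")$breakpoint
make_observable_series <- function(kind = c("piecewise_linear", "sigmoid",
                                            "gaussian_mixture",
                                            "exponential_acf", "brownian"),
                                   truth = list(),
                                   grid,
                                   noise_sd = 0,
                                   seed = 1L) {
  kind <- match.arg(kind)
  grid <- as.numeric(grid)
  if (length(grid) < 2L || any(diff(grid) <= 0)) {
    abort("`grid` must be strictly increasing with >= 2 points.",
          class = "lipidorder_error_parameter")
  }
  if (noise_sd < 0) {
    abort("`noise_sd` must be >= 0.", class = "lipidorder_error_parameter")
  }

  defaults <- switch(kind,
    piecewise_linear = list(breakpoint = 308, value_at_break = 0.55,
                            slope_below = 0.0012, slope_above = 0.0028),
    sigmoid = list(t_inflection = 314, width = 2,
                   lower = c(level = 0.40, slope = -0.002),
                   upper = c(level = -0.05, slope = -0.003)),
    gaussian_mixture = list(means = c(308, 314), sigmas = c(3, 1),
                            amplitudes = c(1, 0.6), baseline = c(0.05, 0)),
    exponential_acf = list(tau = 10, beta = 1),
    brownian = list(d = 1, n_walkers = 50)
  )
  tr <- modifyList(defaults, truth)

  out <- with_seed(seed, {
    switch(kind,
      piecewise_linear = {
        if (tr$breakpoint <= min(grid) || tr$breakpoint >= max(grid)) {
          abort("Planted breakpoint must lie strictly inside the grid.",
                class = "lipidorder_error_parameter")
        }
        dT <- grid - tr$breakpoint
        clean <- tr$value_at_break +
          ifelse(dT < 0, tr$slope_below * dT, tr$slope_above * dT)
        tibble(temperature = grid, value = clean + rnorm(length(grid), sd = noise_sd))
      },
      sigmoid = {
        clean <- sigmoid_curve(grid, tr)
        tibble(temperature = grid, value = clean + rnorm(length(grid), sd = noise_sd))
      },
      gaussian_mixture = {
        clean <- tr$baseline[1] + tr$baseline[2] * grid
        for (k in seq_along(tr$means)) {
          clean <- clean + tr$amplitudes[k] *
            exp(-(grid - tr$means[k])^2 / (2 * tr$sigmas[k]^2))
        }
        tibble(temperature = grid, value = clean + rnorm(length(grid), sd = noise_sd))
      },
      exponential_acf = {
        clean <- exp(-(grid / tr$tau)^tr$beta)
        tibble(t = grid, value = clean + rnorm(length(grid), sd = noise_sd))
      },
      brownian = {
        dt <- diff(grid)
        nw <- tr$n_walkers
        walks <- map(seq_len(nw), function(i) {
          sds <- sqrt(2 * tr$d * dt)
          tibble(
            t = grid, id = i,
            x = cumsum(c(0, rnorm(length(dt), sd = sds))),
            y = cumsum(c(0, rnorm(length(dt), sd = sds)))
          )
        })
        list_rbind(walks)
      }
    )
  })

  attr(out, "kind") <- kind
  attr(out, "truth") <- tr
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- seed
  class(out) <- c("planted_series", class(out))
  out
}

# Sloped-baseline Boltzmann sigmoid, parameterized by branch values at the
# inflection plus baseline slopes; width <= 0 degenerates to a step.
sigmoid_curve <- function(temp, tr) {
  dT <- temp - tr$t_inflection
  low <- tr$lower[[1]] + tr$lower[[2]] * dT
  high <- tr$upper[[1]] + tr$upper[[2]] * dT
  if (tr$width <= 0) {
    ifelse(dT < 0, low, high)
  } else {
    high + (low - high) / (1 + exp(dT / tr$width))
  }
}

#' Write a planted series to a delimited text table
#'
#' @param series A `planted_series` (or any tibble).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  readr::write_tsv(series, path)
  invisible(path)
}
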