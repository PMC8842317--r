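# broom-style tidy()/glance() methods for the fit objects.

#' @describeIn segmented_fit Per-parameter tidy table.
#' @param x,object A fitted object.
#' @param ... Unused.
#' @export
tidy.segmented_fit <- function(x, ...) {
  tibble(
    term = c("breakpoint", "slope_below", "slope_above", "value_at_break"),
    estimate = c(x$breakpoint, x$slope_below, x$slope_above, x$value_at_break),
    conf.low = c(x$ci[1], NA, NA, NA),
    conf.high = c(x$ci[2], NA, NA, NA)
  )
}

#' @describeIn segmented_fit One-row model summary.
#' @export
glance.segmented_fit <- function(x, ...) {
  tibble(
    breakpoint = x$breakpoint,
    conf.low = x$ci[1], conf.high = x$ci[2],
    slope_below = x$slope_below, slope_above = x$slope_above,
    rss = x$rss, rss_single = x$rss_single,
    p.value = x$p_value, no_crossover = x$no_crossover,
    nobs = x$n
  )
}

#' @describeIn boltzmann_fit Per-parameter tidy table.
#' @param x,object A fitted object.
#' @param ... Unused.
#' @export
tidy.boltzmann_fit <- function(x, ...) {
  terms <- c("t_inflection", "width", "lower_intercept", "lower_slope",
             "upper_intercept", "upper_slope")
  est <- c(x$t_inflection, x$width, x$lower_intercept, x$lower_slope,
           x$upper_intercept, x$upper_slope)
  out <- tibble(term = terms, estimate = est,
                conf.low = NA_real_, conf.high = NA_real_)
  if (!is.null(x$ci)) {
    map_ci <- c(t_inflection = "t_i", width = "w", lower_intercept = "a1",
                lower_slope = "b1", upper_intercept = "a2", upper_slope = "b2")
    for (i in seq_len(nrow(out))) {
      nm <- map_ci[[out$term[i]]]
      if (nm %in% colnames(x$ci)) {
        out$conf.low[i] <- x$ci[1, nm]
        out$conf.high[i] <- x$ci[2, nm]
      }
    }
  }
  out
}

#' @describeIn boltzmann_fit One-row model summary.
#' @export
glance.boltzmann_fit <- function(x, ...) {
  tibble(
    t_inflection = x$t_inflection, width = x$width,
    rss = x$rss, rss_single = x$rss_single, p.value = x$p_value,
    no_inflection = x$no_inflection, converged = x$converged, nobs = x$n
  )
}

#' @describeIn dsc_decompose Per-component tidy table.
#' @param x,object A fitted object.
#' @param ... Unused.
#' @export
tidy.dsc_fit <- function(x, ...) {
  if (nrow(x$components) == 0) {
    return(tibble(component = integer(0), amplitude = numeric(0),
                  mean = numeric(0), width = numeric(0)))
  }
  mutate(x$components, component = dplyr::row_number(), .before = 1)
}

#' @describeIn dsc_decompose One-row model summary.
#' @export
glance.dsc_fit <- function(x, ...) {
  tibble(
    n_components = x$n_components, featureless = x$featureless,
    rss = x$rss, baseline_intercept = x$baseline[["intercept"]],
    baseline_slope = x$baseline[["slope"]], nobs = x$n
  )
}

#' @describeIn orientation_autocorrelation One-row KWW fit summary.
#' @param x A `correlation_result`.
#' @param ... Unused.
#' @export
glance.correlation_result <- function(x, ...) {
  tibble(tau = x$tau, beta = x$beta, tau_c = x$tau_c, converged = x$converged)
}

#' @describeIn lateral_diffusion One-row diffusion summary.
#' @param x A `diffusion_fit`.
#' @param ... Unused.
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble(d = x$d, se = x$se,
         window_lo = x$fit_window[1], window_hi = x$fit_window[2])
}
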