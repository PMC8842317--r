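# ggplot2 quick-look methods. Each returns a ggplot the caller can theme.

#' @describeIn segmented_fit Data with the two fitted segments and the
#'   breakpoint.
#' @export
autoplot.segmented_fit <- function(object, ...) {
  grid <- tibble(temperature = seq(min(object$data$temperature),
                                   max(object$data$temperature),
                                   length.out = 200))
  grid$value <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$temperature, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, color = "firebrick") +
    ggplot2::geom_vline(xintercept = object$breakpoint, linetype = "dotted") +
    ggplot2::labs(x = "Temperature (K)", y = "Observable",
                  subtitle = sprintf("breakpoint %.1f K%s", object$breakpoint,
                                     if (object$no_crossover) " (no crossover)" else ""))
}

#' @describeIn boltzmann_fit Data with the fitted sigmoid.
#' @export
autoplot.boltzmann_fit <- function(object, ...) {
  grid <- tibble(temperature = seq(min(object$data$temperature),
                                   max(object$data$temperature),
                                   length.out = 200))
  grid$value <- predict(object, grid)
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(.data$temperature, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Temperature (K)", y = "Observable")
  if (!object$no_inflection) {
    p <- p + ggplot2::geom_line(data = grid, color = "firebrick") +
      ggplot2::geom_vline(xintercept = object$t_inflection,
                          linetype = "dotted")
  }
  p
}

#' @describeIn dsc_decompose Thermogram with components and total fit.
#' @export
autoplot.dsc_fit <- function(object, ...) {
  tt <- seq(min(object$data$temperature), max(object$data$temperature),
            length.out = 400)
  total <- tibble(temperature = tt, value = predict(object,
                                                    tibble(temperature = tt)))
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(.data$temperature, .data$value)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = total, color = "firebrick") +
    ggplot2::labs(x = "Temperature (K)", y = "Specific heat (a.u.)")
  if (nrow(object$components) > 0) {
    comps <- imap(split(object$components,
                        seq_len(nrow(object$components))), function(cmp, i) {
      tibble(temperature = tt,
             value = object$baseline[["intercept"]] +
               object$baseline[["slope"]] * tt +
               cmp$amplitude * exp(-(tt - cmp$mean)^2 / (2 * cmp$width^2)),
             component = i)
    }) |> list_rbind()
    p <- p + ggplot2::geom_line(
      data = comps,
      ggplot2::aes(group = .data$component),
      linetype = "dashed", color = "steelblue"
    )
  }
  p
}

#' @describeIn hexatic_order Site map colored by S_hex.
#' @param object A fitted/derived object.
#' @param ... Unused.
#' @export
autoplot.hexatic_field <- function(object, ...) {
  sites <- attr(object, "site_set")
  if (is.null(sites)) {
    abort("Field carries no site_set; cannot plot.",
          class = "lipidorder_error_parameter")
  }
  df <- left_join(as_tibble(sites), as_tibble(object), by = "site")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, color = .data$s_hex)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_color_viridis_c(limits = c(0, 1), name = expression(S[hex])) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)")
}

#' @describeIn lateral_diffusion MSD curve with the fitted slope window.
#' @export
autoplot.diffusion_fit <- function(object, ...) {
  ggplot2::ggplot(object$msd, ggplot2::aes(.data$time, .data$msd)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 4 * object$d, intercept = 0,
                         linetype = "dashed", color = "firebrick") +
    ggplot2::annotate("rect", xmin = object$fit_window[1],
                      xmax = object$fit_window[2], ymin = -Inf, ymax = Inf,
                      alpha = 0.1) +
    ggplot2::labs(x = "Lag time (ns)", y = expression(MSD ~ (nm^2)))
}

#' @describeIn orientation_autocorrelation ACF with the KWW fit.
#' @export
autoplot.correlation_result <- function(object, ...) {
  p <- ggplot2::ggplot(object$acf, ggplot2::aes(.data$time, .data$acf)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Lag time", y = "C(t)")
  if (object$converged) {
    grid <- tibble(time = seq(0, max(object$acf$time), length.out = 300))
    grid$acf <- exp(-(grid$time / object$tau)^object$beta)
    p <- p + ggplot2::geom_line(data = grid, color = "firebrick")
  }
  p
}

#' Plot class fractions against temperature
#'
#' @param fractions Output of [class_fractions_vs_temperature()].
#' @return A ggplot.
#' @export
plot_class_fractions <- function(fractions) {
  ggplot2::ggplot(fractions,
                  ggplot2::aes(.data$temperature, .data$fraction,
                               color = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Temperature (K)", y = "Fraction", color = "Class")
}
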