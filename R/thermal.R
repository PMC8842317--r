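#' Continuous segmented two-slope fit with breakpoint detection
#'
#' Fits the continuous piecewise-linear model
#' `y = b0 + b1 (T - Tco) + (b2 - b1) max(T - Tco, 0)` by profiled least
#' squares: the breakpoint is scanned over the interior data temperatures
#' and refined by golden-section search, with the remaining parameters
#' solved linearly at each candidate. Continuity at the breakpoint is
#' enforced by construction (the crossover is a change of slope, not a
#' discontinuous transition). A single straight line is fitted alongside
#' and compared by a variance-ratio (F-style) statistic whose p-value is
#' Bonferroni-adjusted over the breakpoint grid, so that series with no
#' interior crossover are flagged rather than over-fitted. Breakpoint
#' confidence intervals come from a seeded nonparametric bootstrap over
#' residuals.
#'
#' @param data Data frame with the series (e.g. a `planted_series` or a
#'   table read by [read_temperature_series()]).
#' @param temperature,value Column names (tidy evaluation); defaults
#'   `temperature` and `value`.
#' @param n_boot Bootstrap resamples for the breakpoint CI (default 1000;
#'   0 skips the bootstrap).
#' @param conf_level Confidence level for the bootstrap CI.
#' @param p_threshold Variance-ratio p-value below which the two-segment
#'   model is preferred (default 0.05).
#' @param min_points_per_side Interior candidates keep at least this many
#'   points strictly on each side (default 2).
#' @param seed Seed for the bootstrap.
#' @return A `segmented_fit` object: breakpoint, slopes below/above,
#'   value at the breakpoint, CI, residual variances, adjusted p-value and
#'   `no_crossover` flag. Methods: [tidy()], [glance()], [autoplot()],
#'   `predict()`.
#' @export
#' @examples
#' s <- make_observable_series("piecewise_linear",
#'   truth = list(breakpoint = 308), grid = seq(293, 333, 2), seed = 1)
#' fit <- segmented_fit(s, n_boot = 0)
#' fit$breakpoint
segmented_fit <- function(data,
                          temperature = "temperature",
                          value = "value",
                          n_boot = 1000L,
                          conf_level = 0.95,
                          p_threshold = 0.05,
                          min_points_per_side = 2L,
                          seed = NULL) {
  tt <- data[[temperature]]
  yy <- data[[value]]
  ok <- complete.cases(tt, yy)
  tt <- tt[ok]; yy <- yy[ok]
  o <- order(tt); tt <- tt[o]; yy <- yy[o]
  n <- length(tt)
  if (n < 5L) {
    abort("Segmented fit needs >= 5 points.", class = "lipidorder_error_parameter")
  }

  # single-line reference fit
  lin <- lm(yy ~ tt)
  rss1 <- sum(resid(lin)^2)

  prof <- profile_breakpoint(tt, yy, min_points_per_side)
  b_hat <- prof$breakpoint
  fit2 <- segmented_solve(tt, yy, b_hat)
  rss2 <- fit2$rss

  scale2 <- mean(yy^2)
  p_adj <- if (rss1 <= 1e-12 * scale2) {
    # both models interpolate: prefer the line
    1
  } else {
    f_stat <- ((rss1 - rss2) / 2) / (rss2 / (n - 4))
    if (!is.finite(f_stat) || rss2 <= 0) 0
    else min(1, prof$n_candidates * pf(f_stat, 2, n - 4, lower.tail = FALSE))
  }
  at_boundary <- prof$at_boundary
  no_crossover <- at_boundary || p_adj >= p_threshold

  ci <- c(NA_real_, NA_real_)
  boot_b <- numeric(0)
  if (n_boot > 0) {
    res <- yy - fit2$fitted
    boot_b <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      yb <- fit2$fitted + sample(res, n, replace = TRUE)
      profile_breakpoint(tt, yb, min_points_per_side)$breakpoint
    }, numeric(1)))
    alpha <- (1 - conf_level) / 2
    ci <- unname(quantile(boot_b, c(alpha, 1 - alpha)))
  }

  structure(list(
    breakpoint = b_hat,
    ci = ci,
    conf_level = conf_level,
    slope_below = fit2$slope_below,
    slope_above = fit2$slope_above,
    value_at_break = fit2$value_at_break,
    rss = rss2,
    rss_single = rss1,
    single_slope = unname(coef(lin)[2]),
    single_intercept = unname(coef(lin)[1]),
    p_value = p_adj,
    p_threshold = p_threshold,
    no_crossover = no_crossover,
    at_boundary = at_boundary,
    n = n,
    boot = boot_b,
    data = tibble(temperature = tt, value = yy, fitted = fit2$fitted)
  ), class = "segmented_fit")
}

# Linear solve of the continuous two-segment model at a fixed breakpoint.
segmented_solve <- function(tt, yy, b) {
  x1 <- tt - b
  x2 <- pmax(tt - b, 0)
  X <- cbind(1, x1, x2)
  ft <- stats::lm.fit(X, yy)
  cf <- ft$coefficients
  cf[is.na(cf)] <- 0
  fitted <- drop(X %*% cf)
  list(
    rss = sum((yy - fitted)^2),
    value_at_break = unname(cf[1]),
    slope_below = unname(cf[2]),
    slope_above = unname(cf[2] + cf[3]),
    fitted = fitted
  )
}

# Grid scan over interior breakpoint candidates + golden-section
# refinement of the profiled RSS.
profile_breakpoint <- function(tt, yy, min_points_per_side) {
  n <- length(tt)
  k <- min_points_per_side
  lo_t <- tt[k + 1L]
  hi_t <- tt[n - k]
  cand <- unique(tt[tt >= lo_t & tt <= hi_t])
  rss <- vapply(cand, function(b) segmented_solve(tt, yy, b)$rss, numeric(1))
  i <- which.min(rss)
  bracket <- c(cand[max(1L, i - 1L)], cand[min(length(cand), i + 1L)])
  opt <- optimize(function(b) segmented_solve(tt, yy, b)$rss,
                  interval = bracket, tol = 1e-4)
  best <- if (opt$objective <= rss[i]) opt$minimum else cand[i]
  list(
    breakpoint = best,
    n_candidates = length(cand),
    at_boundary = i == 1L || i == length(cand)
  )
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf(
    "<segmented_fit> breakpoint %.2f K [%s], slopes %.4g / %.4g, p = %.3g%s\n",
    x$breakpoint,
    if (all(is.finite(x$ci))) sprintf("%.2f, %.2f", x$ci[1], x$ci[2]) else "no CI",
    x$slope_below, x$slope_above, x$p_value,
    if (x$no_crossover) " (no crossover)" else ""
  ))
  invisible(x)
}

#' @export
predict.segmented_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$data$temperature else newdata$temperature
  dT <- tt - object$breakpoint
  object$value_at_break +
    ifelse(dT < 0, object$slope_below * dT, object$slope_above * dT)
}

#' Thermal expansion coefficients from a segmented APPL fit
#'
#' The expansion coefficient of each segment is alpha = (1/A)(dA/dT)
#' evaluated at the segment midpoint, i.e. the fitted slope divided by the
#' fitted area at the midpoint of the segment's temperature range.
#'
#' @param fit A `segmented_fit` of an area-per-phospholipid series.
#' @return Tibble with columns `segment` (below/above), `t_mid` (K),
#'   `area_mid` (nm^2), `slope` (nm^2/K), `alpha` (1/K).
#' @export
expansion_coefficients <- function(fit) {
  if (!inherits(fit, "segmented_fit")) {
    abort("`fit` must be a segmented_fit.", class = "lipidorder_error_parameter")
  }
  rng <- range(fit$data$temperature)
  t_mid <- c(mean(c(rng[1], fit$breakpoint)), mean(c(fit$breakpoint, rng[2])))
  a_mid <- predict(fit, tibble(temperature = t_mid))
  if (any(a_mid == 0)) {
    abort("Fitted area is zero at a segment midpoint; alpha undefined.",
          class = "lipidorder_error_parameter")
  }
  slopes <- c(fit$slope_below, fit$slope_above)
  tibble(
    segment = c("below", "above"),
    t_mid = t_mid,
    area_mid = a_mid,
    slope = slopes,
    alpha = slopes / a_mid
  )
}

#' Consensus crossover temperature across observables
#'
#' Combines per-observable breakpoints into an inverse-variance weighted
#' mean crossover temperature; observables flagged as having no crossover
#' are excluded. Standard errors come from the bootstrap CIs; when absent,
#' observables enter with equal weight.
#'
#' @param fits List of `segmented_fit` objects, optionally named by
#'   observable.
#' @return A `crossover_consensus`: tibble of per-observable breakpoints
#'   with `excluded` flags; attributes `t_co` (weighted mean, K) and
#'   `spread` (weighted sd, K).
#' @export
crossover_consensus <- function(fits) {
  if (inherits(fits, "segmented_fit")) fits <- list(fits)
  if (length(fits) < 1L) {
    abort("Need >= 1 fit.", class = "lipidorder_error_parameter")
  }
  nms <- names(fits) %||% paste0("observable_", seq_along(fits))
  nms[nms == ""] <- paste0("observable_", which(nms == ""))

  tbl <- map2(fits, nms, function(f, nm) {
    se <- if (all(is.finite(f$ci))) (f$ci[2] - f$ci[1]) / (2 * 1.96) else NA_real_
    tibble(observable = nm, breakpoint = f$breakpoint, se = se,
           p_value = f$p_value, excluded = f$no_crossover)
  }) |> list_rbind()

  keep <- tbl[!tbl$excluded, ]
  if (nrow(keep) == 0) {
    inform("All observables flagged no-crossover; consensus is empty.")
    attr(tbl, "t_co") <- NA_real_
    attr(tbl, "spread") <- NA_real_
  } else {
    w <- 1 / keep$se^2
    if (any(!is.finite(w))) w <- rep(1, nrow(keep))
    t_co <- sum(w * keep$breakpoint) / sum(w)
    spread <- if (nrow(keep) > 1) {
      sqrt(sum(w * (keep$breakpoint - t_co)^2) / sum(w))
    } else {
      0
    }
    attr(tbl, "t_co") <- t_co
    attr(tbl, "spread") <- spread
  }
  class(tbl) <- c("crossover_consensus", class(tbl))
  tbl
}

#' @export
print.crossover_consensus <- function(x, ...) {
  cat(sprintf("<crossover_consensus> T_co = %.2f K (spread %.2f K)\n",
              attr(x, "t_co"), attr(x, "spread")))
  NextMethod()
}

#' Read a temperature series from delimited text
#'
#' Expects columns `temperature`, `value` and optionally `se` and `scan`;
#' any delimiter understood by [readr::read_delim()] works for
#' tab/comma/whitespace tables.
#'
#' @param path File path.
#' @return Tibble sorted by temperature.
#' @export
read_temperature_series <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Series file not found: %s", path),
          class = "lipidorder_error_format")
  }
  df <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) {
      abort(sprintf("Could not parse series file '%s': %s", path,
                    conditionMessage(e)),
            class = "lipidorder_error_format")
    }
  )
  if (nrow(df) == 0 || !all(c("temperature", "value") %in% names(df))) {
    abort(sprintf(
      "Series file '%s' must have `temperature` and `value` columns.", path
    ), class = "lipidorder_error_format")
  }
  arrange(df, .data$temperature)
}
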