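#' Generalized polarization from two-band emission intensities
#'
#' GP = (I_B - I_R) / (I_B + I_R), where I_B is the blue band (420 nm,
#' typical of gel and Lo phases) and I_R the red band (495 nm,
#' characteristic of Ld). High GP reports low carbonyl-region hydration
#' and mobility. GP is undefined (NA) where the total intensity is zero.
#'
#' @param data Data frame with the intensity columns.
#' @param i_blue,i_red Column names (defaults `"i_blue"`, `"i_red"`).
#' @return `data` with a `gp` column appended.
#' @export
#' @examples
#' generalized_polarization(data.frame(i_blue = 1, i_red = 3))$gp # -0.5
generalized_polarization <- function(data, i_blue = "i_blue", i_red = "i_red") {
  ib <- data[[i_blue]]; ir <- data[[i_red]]
  if (any(ib < 0 | ir < 0, na.rm = TRUE)) {
    abort("Intensities must be >= 0.", class = "lipidorder_error_parameter")
  }
  tot <- ib + ir
  out <- as_tibble(data)
  out$gp <- ifelse(tot > 0, (ib - ir) / tot, NA_real_)
  if (any(tot == 0, na.rm = TRUE)) {
    warn("GP undefined at zero total intensity; set to NA.",
         class = "lipidorder_warning_undefined")
  }
  out
}

#' Steady-state fluorescence anisotropy
#'
#' r = (I_VV - G I_VH) / (I_VV + 2 G I_VH) with the instrument correction
#' factor G. Values outside the physical range `[-0.2, 0.4]` are flagged.
#'
#' @param data Data frame with polarized intensity columns.
#' @param i_vv,i_vh Column names (defaults `"i_vv"`, `"i_vh"`).
#' @param g Instrument G factor (scalar or column name).
#' @return `data` with `r` and `r_unphysical` columns appended.
#' @export
#' @examples
#' steady_state_anisotropy(data.frame(i_vv = 2, i_vh = 1))$r # 0.25
steady_state_anisotropy <- function(data, i_vv = "i_vv", i_vh = "i_vh", g = 1) {
  ivv <- data[[i_vv]]; ivh <- data[[i_vh]]
  gg <- if (is.character(g)) data[[g]] else g
  if (any(ivv < 0 | ivh < 0, na.rm = TRUE) || any(gg <= 0, na.rm = TRUE)) {
    abort("Intensities must be >= 0 and G > 0.",
          class = "lipidorder_error_parameter")
  }
  den <- ivv + 2 * gg * ivh
  out <- as_tibble(data)
  out$r <- ifelse(den != 0, (ivv - gg * ivh) / den, NA_real_)
  out$r_unphysical <- !is.na(out$r) & (out$r < -0.2 | out$r > 0.4)
  if (any(out$r_unphysical)) {
    warn("Anisotropy outside the physical range [-0.2, 0.4]; flagged.",
         class = "lipidorder_warning_unphysical")
  }
  out
}

# Sloped-baseline Boltzmann model used for GP and anisotropy melting
# curves; `flat` pins both baseline slopes to zero.
boltzmann_model <- function(temp, a1, b1, a2, b2, t_i, w) {
  low <- a1 + b1 * temp
  high <- a2 + b2 * temp
  high + (low - high) / (1 + exp((temp - t_i) / w))
}

#' Modified Boltzmann sigmoid fit for melting curves
#'
#' Fits f(T) = (a2 + b2 T) + [(a1 + b1 T) - (a2 + b2 T)] /
#' (1 + exp((T - T_i)/w)): a Boltzmann sigmoid between two sloped
#' baselines, suited to generalized-polarization and anisotropy series
#' that drift approximately linearly away from the transition. The
#' inflection T_i houses the melting temperature for main-transition
#' curves. Initialization is multi-start (T_i seeded at the
#' maximum-|slope| temperature and at the median; w at 1/10 and 1/20 of
#' the range) and the best converged least-squares solution is kept.
#' A single sloped line is fitted alongside; when it explains the data as
#' well (variance-ratio p above `p_threshold`), or the fitted inflection
#' leaves the data range, the series is flagged `no_inflection`
#' (monotone featureless curves, e.g. POPC). Parameter CIs come from a
#' seeded residual bootstrap.
#'
#' @param data Data frame with the series.
#' @param temperature,value Column names (defaults `temperature`,
#'   `value`; use `value = "gp"` or `"r"` after the derivation helpers).
#' @param baseline `"sloped"` (default) or `"flat"` (plain Boltzmann).
#' @param exclude_above Mask points above this temperature (K) before
#'   fitting (e.g. 333 K for DPH curves that become unreliable when hot);
#'   `NULL` keeps everything.
#' @param n_boot Bootstrap resamples for CIs (default 200; 0 skips).
#' @param p_threshold Model-comparison threshold (default 0.05).
#' @param seed Bootstrap seed.
#' @return A `boltzmann_fit`: `t_inflection`, `width`, baselines, CIs,
#'   `no_inflection`/`converged` flags and the data. Methods: [tidy()],
#'   [glance()], [autoplot()], `predict()`.
#' @export
boltzmann_fit <- function(data,
                          temperature = "temperature",
                          value = "value",
                          baseline = c("sloped", "flat"),
                          exclude_above = NULL,
                          n_boot = 200L,
                          p_threshold = 0.05,
                          seed = NULL) {
  baseline <- match.arg(baseline)
  tt <- data[[temperature]]
  yy <- data[[value]]
  ok <- complete.cases(tt, yy)
  if (!is.null(exclude_above)) ok <- ok & tt <= exclude_above
  tt <- tt[ok]; yy <- yy[ok]
  o <- order(tt); tt <- tt[o]; yy <- yy[o]
  n <- length(tt)
  if (n < 6L) {
    abort("Boltzmann fit needs >= 6 points.", class = "lipidorder_error_parameter")
  }

  lin <- lm(yy ~ tt)
  rss1 <- sum(resid(lin)^2)
  rng <- diff(range(tt))

  if (rss1 <= 1e-12 * max(mean(yy^2), 1e-300)) {
    return(new_boltzmann_fit(tt, yy, NULL, rss1, lin, TRUE, baseline,
                             p_value = 1, n_boot = 0, seed = seed))
  }

  fit <- fit_boltzmann_nls(tt, yy, baseline)
  if (is.null(fit)) {
    warn("Boltzmann fit did not converge; returning raw data.",
         class = "lipidorder_warning_fit")
    return(new_boltzmann_fit(tt, yy, NULL, rss1, lin, TRUE, baseline,
                             p_value = NA_real_, n_boot = 0, seed = seed,
                             converged = FALSE))
  }

  rss2 <- sum(resid(fit)^2)
  k2 <- length(coef(fit))
  df1 <- k2 - 2
  f_stat <- ((rss1 - rss2) / df1) / (rss2 / (n - k2))
  p_value <- if (!is.finite(f_stat) || rss2 <= 0) 0 else {
    pf(f_stat, df1, n - k2, lower.tail = FALSE)
  }
  cf <- coef(fit)
  inside <- cf[["t_i"]] > min(tt) && cf[["t_i"]] < max(tt) &&
    cf[["w"]] > 0 && cf[["w"]] < rng
  no_inflection <- p_value >= p_threshold || !inside

  new_boltzmann_fit(tt, yy, fit, rss1, lin, no_inflection, baseline,
                    p_value = p_value, n_boot = n_boot, seed = seed)
}

fit_boltzmann_nls <- function(tt, yy, baseline) {
  n <- length(tt)
  rng <- diff(range(tt))
  # initialization from the thirds of the series and the steepest slope
  lo_third <- tt <= quantile(tt, 1 / 3)
  hi_third <- tt >= quantile(tt, 2 / 3)
  lo_fit <- lm(yy[lo_third] ~ tt[lo_third])
  hi_fit <- lm(yy[hi_third] ~ tt[hi_third])
  slopes <- diff(yy) / diff(tt)
  t_steep <- tt[which.max(abs(slopes))] + 0.5 * diff(tt)[which.max(abs(slopes))]

  starts <- list()
  for (t0 in unique(c(t_steep, median(tt)))) {
    for (w0 in c(rng / 10, rng / 20)) {
      starts[[length(starts) + 1L]] <- list(
        a1 = unname(coef(lo_fit)[1]), b1 = unname(coef(lo_fit)[2]),
        a2 = unname(coef(hi_fit)[1]), b2 = unname(coef(hi_fit)[2]),
        t_i = t0, w = w0
      )
    }
  }

  dat <- tibble(tt = tt, yy = yy)
  best <- NULL
  for (st in starts) {
    if (baseline == "flat") {
      st$b1 <- NULL; st$b2 <- NULL
      st$a1 <- mean(yy[lo_third]); st$a2 <- mean(yy[hi_third])
      form <- yy ~ boltzmann_model(tt, a1, 0, a2, 0, t_i, w)
      lower <- c(a1 = -Inf, a2 = -Inf, t_i = min(tt) - rng, w = 1e-6)
      upper <- c(a1 = Inf, a2 = Inf, t_i = max(tt) + rng, w = 10 * rng)
    } else {
      form <- yy ~ boltzmann_model(tt, a1, b1, a2, b2, t_i, w)
      lower <- c(a1 = -Inf, b1 = -Inf, a2 = -Inf, b2 = -Inf,
                 t_i = min(tt) - rng, w = 1e-6)
      upper <- c(a1 = Inf, b1 = Inf, a2 = Inf, b2 = Inf,
                 t_i = max(tt) + rng, w = 10 * rng)
    }
    ft <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = st,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL
    )
    if (!is.null(ft) &&
        (is.null(best) || sum(resid(ft)^2) < sum(resid(best)^2))) {
      best <- ft
    }
  }
  best
}

new_boltzmann_fit <- function(tt, yy, fit, rss1, lin, no_inflection, baseline,
                              p_value, n_boot, seed, converged = TRUE) {
  cf <- if (!is.null(fit)) as.list(coef(fit)) else NULL
  obj <- list(
    t_inflection = cf$t_i %||% NA_real_,
    width = cf$w %||% NA_real_,
    lower_intercept = cf$a1 %||% NA_real_,
    lower_slope = if (is.null(cf)) NA_real_ else cf$b1 %||% 0,
    upper_intercept = cf$a2 %||% NA_real_,
    upper_slope = if (is.null(cf)) NA_real_ else cf$b2 %||% 0,
    ci = NULL,
    rss = if (!is.null(fit)) sum(resid(fit)^2) else NA_real_,
    rss_single = rss1,
    p_value = p_value,
    baseline = baseline,
    no_inflection = no_inflection,
    converged = converged,
    n = length(tt),
    data = tibble(temperature = tt, value = yy,
                  fitted = if (!is.null(fit)) fitted(fit) else
                    fitted(lin))
  )
  if (!is.null(fit) && n_boot > 0 && !no_inflection) {
    res <- yy - fitted(fit)
    fv <- fitted(fit)
    boot <- with_seed(seed, {
      map(seq_len(n_boot), function(b) {
        yb <- fv + sample(res, length(res), replace = TRUE)
        fb <- fit_boltzmann_nls(tt, yb, baseline)
        if (is.null(fb)) return(NULL)
        coef(fb)
      })
    })
    boot <- boot[!vapply(boot, is.null, logical(1))]
    if (length(boot) >= 20) {
      bm <- do.call(rbind, boot)
      obj$ci <- apply(bm, 2L, quantile, probs = c(0.025, 0.975))
    }
  }
  structure(obj, class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  if (x$no_inflection) {
    cat("<boltzmann_fit> no inflection (featureless or linear series)\n")
  } else {
    cat(sprintf("<boltzmann_fit> T_i = %.2f K, width = %.2f K (p = %.3g)\n",
                x$t_inflection, x$width, x$p_value))
  }
  invisible(x)
}

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$data$temperature else newdata$temperature
  boltzmann_model(tt, object$lower_intercept, object$lower_slope,
                  object$upper_intercept, object$upper_slope,
                  object$t_inflection, object$width)
}

#' Gaussian decomposition of a DSC thermogram
#'
#' Fits the specific-heat profile as a linear baseline plus one to three
#' Gaussian components by nonlinear least squares with multi-start
#' initialization (component means seeded at the largest local maxima of
#' the detrended, lightly smoothed curve). In auto mode the number of
#' components is chosen by BIC among a baseline-only model and 1-3
#' components; a baseline-only winner (or vanishing amplitudes) flags the
#' thermogram as featureless. Components with negligible fitted amplitude
#' are dropped and the model refitted. Components are reported sorted by
#' mean; peak maxima equal the component means. When a `scan` column with
#' several values is present, heating and cooling scans are fitted
#' independently and a named list is returned.
#'
#' @param data Data frame with the thermogram.
#' @param temperature,heat_capacity Column names (defaults `temperature`,
#'   `value`).
#' @param n_components Fixed component count 1-3, or `NULL` for auto.
#' @param scan Optional scan-direction column name (default `"scan"` when
#'   present).
#' @return A `dsc_fit` (or named list of them, one per scan): `components`
#'   tibble (`amplitude`, `mean`, `width`), `baseline`, `n_components`,
#'   `featureless` flag, BIC table. Methods: [tidy()], [glance()],
#'   [autoplot()], `predict()`.
#' @export
dsc_decompose <- function(data,
                          temperature = "temperature",
                          heat_capacity = "value",
                          n_components = NULL,
                          scan = if ("scan" %in% names(data)) "scan" else NULL) {
  if (!is.null(scan) && length(unique(data[[scan]])) > 1L) {
    groups <- split(as_tibble(data), data[[scan]])
    return(map(groups, dsc_decompose, temperature = temperature,
               heat_capacity = heat_capacity, n_components = n_components,
               scan = NULL))
  }
  tt <- data[[temperature]]
  yy <- data[[heat_capacity]]
  ok <- complete.cases(tt, yy)
  tt <- tt[ok]; yy <- yy[ok]
  o <- order(tt); tt <- tt[o]; yy <- yy[o]
  n <- length(tt)
  if (n < 10L) {
    abort("DSC decomposition needs >= 10 points.",
          class = "lipidorder_error_parameter")
  }

  base_fit <- lm(yy ~ tt)
  rss0 <- sum(resid(base_fit)^2)
  models <- list(`0` = list(rss = rss0, k = 2L, fit = NULL))

  ns <- if (is.null(n_components)) 1:3 else as.integer(n_components)
  if (any(ns < 1L | ns > 3L)) {
    abort("`n_components` must be between 1 and 3.",
          class = "lipidorder_error_parameter")
  }
  for (nc in ns) {
    ft <- fit_dsc_nls(tt, yy, nc)
    if (!is.null(ft)) {
      models[[as.character(nc)]] <- list(rss = sum(resid(ft)^2),
                                         k = 2L + 3L * nc, fit = ft)
    }
  }

  bic_tbl <- imap(models, function(m, nm) {
    tibble(n_components = as.integer(nm),
           rss = m$rss,
           bic = n * log(m$rss / n) + m$k * log(n))
  }) |> list_rbind()

  pick_from <- if (is.null(n_components)) bic_tbl else {
    bic_tbl[bic_tbl$n_components %in% ns, , drop = FALSE]
  }
  best_n <- pick_from$n_components[which.min(pick_from$bic)]

  featureless <- FALSE
  if (is.null(n_components)) {
    best0 <- bic_tbl$bic[bic_tbl$n_components == 0]
    if (length(best0) == 1 && best0 <= min(pick_from$bic[pick_from$n_components > 0],
                                           Inf)) {
      featureless <- TRUE
      best_n <- 0L
    }
  }

  comps <- tibble(amplitude = numeric(0), mean = numeric(0), width = numeric(0))
  baseline <- coef(base_fit)
  fit <- NULL
  if (best_n > 0) {
    fit <- models[[as.character(best_n)]]$fit
    cf <- coef(fit)
    amp <- cf[grep("^a[0-9]$", names(cf))]
    mu <- cf[grep("^m[0-9]$", names(cf))]
    sig <- cf[grep("^s[0-9]$", names(cf))]
    # drop negligible components and refit
    keep <- amp > max(amp) * 1e-3 & amp > 1e-9
    if (!all(keep) && sum(keep) >= 1) {
      refit <- fit_dsc_nls(tt, yy, sum(keep),
                           init = list(amp = amp[keep], mu = mu[keep],
                                       sig = sig[keep]))
      if (!is.null(refit)) {
        fit <- refit
        cf <- coef(fit)
        amp <- cf[grep("^a[0-9]$", names(cf))]
        mu <- cf[grep("^m[0-9]$", names(cf))]
        sig <- cf[grep("^s[0-9]$", names(cf))]
        best_n <- length(amp)
      }
    }
    ord <- order(mu)
    comps <- tibble(amplitude = unname(amp[ord]), mean = unname(mu[ord]),
                    width = unname(sig[ord]))
    baseline <- c(cf[["c0"]], cf[["c1"]])
    # amplitudes indistinguishable from noise -> featureless
    noise <- sd(diff(yy)) / sqrt(2)
    if (all(comps$amplitude < 2 * noise)) featureless <- TRUE
  }

  structure(list(
    components = comps,
    baseline = setNames(as.numeric(baseline), c("intercept", "slope")),
    n_components = as.integer(best_n),
    featureless = featureless,
    bic = bic_tbl,
    rss = if (!is.null(fit)) sum(resid(fit)^2) else rss0,
    n = n,
    data = tibble(temperature = tt, value = yy)
  ), class = "dsc_fit")
}

# Multi-start Gaussian-mixture-on-baseline least squares for one scan.
fit_dsc_nls <- function(tt, yy, nc, init = NULL) {
  n <- length(tt)
  rng <- diff(range(tt))
  base_fit <- lm(yy ~ tt)
  detr <- resid(base_fit)
  sm <- stats::filter(detr, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- detr[is.na(sm)]
  sm <- as.numeric(sm)

  starts <- list()
  if (!is.null(init)) {
    starts[[1]] <- list(mu = init$mu, amp = init$amp, sig = init$sig)
  } else {
    amp_floor <- max(max(detr) * 0.2, 1e-6)
    # (a) largest local maxima of the lightly smoothed detrended curve
    is_max <- c(FALSE, diff(sign(diff(sm))) < 0, FALSE)
    peaks <- order(sm * is_max, decreasing = TRUE)
    peaks <- peaks[is_max[peaks]][seq_len(min(nc, sum(is_max)))]
    if (length(peaks) < nc) {
      extra <- round(seq(n * 0.25, n * 0.75, length.out = nc - length(peaks)))
      peaks <- unique(c(peaks, extra))[seq_len(nc)]
    }
    starts[[1]] <- list(mu = tt[peaks],
                        amp = pmax(sm[peaks], amp_floor),
                        sig = rep(rng / 15, nc))
    # (b) means spread evenly over the central range
    starts[[2]] <- list(mu = quantile(tt, seq(0.25, 0.75, length.out = nc),
                                      names = FALSE),
                        amp = rep(max(detr), nc),
                        sig = rep(rng / 10, nc))
    if (nc > 1) {
      # (c) split the dominant peak: narrow + broad components nearby
      mmax <- tt[which.max(sm)]
      starts[[3]] <- list(mu = mmax + seq(-rng / 12, rng / 12,
                                          length.out = nc),
                          amp = rep(max(detr), nc),
                          sig = rng / 15 * seq(0.5, 1.5, length.out = nc))
    }
  }

  nm_a <- paste0("a", seq_len(nc))
  nm_m <- paste0("m", seq_len(nc))
  nm_s <- paste0("s", seq_len(nc))
  terms <- paste(
    sprintf("%s * exp(-(tt - %s)^2 / (2 * %s^2))", nm_a, nm_m, nm_s),
    collapse = " + "
  )
  form <- stats::as.formula(paste("yy ~ c0 + c1 * tt +", terms))
  lower <- c(c0 = -Inf, c1 = -Inf,
             setNames(rep(0, nc), nm_a),
             setNames(rep(min(tt), nc), nm_m),
             setNames(rep(rng / 200, nc), nm_s))
  upper <- c(c0 = Inf, c1 = Inf,
             setNames(rep(Inf, nc), nm_a),
             setNames(rep(max(tt), nc), nm_m),
             setNames(rep(rng, nc), nm_s))
  dat <- tibble(tt = tt, yy = yy)

  best <- NULL
  for (st in starts) {
    start <- c(list(c0 = unname(coef(base_fit)[1]),
                    c1 = unname(coef(base_fit)[2])),
               setNames(as.list(pmax(st$amp, 1e-6)), nm_a),
               setNames(as.list(pmin(pmax(st$mu, min(tt)), max(tt))), nm_m),
               setNames(as.list(pmax(st$sig, rng / 100)), nm_s))
    ft <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = start, lower = lower,
                        upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL
    )
    if (!is.null(ft) &&
        (is.null(best) || sum(resid(ft)^2) < sum(resid(best)^2))) {
      best <- ft
    }
  }
  best
}

#' @export
print.dsc_fit <- function(x, ...) {
  if (x$featureless) {
    cat("<dsc_fit> featureless thermogram (baseline only)\n")
  } else {
    cat(sprintf("<dsc_fit> %d component(s), peak means: %s K\n",
                x$n_components,
                paste(sprintf("%.2f", x$components$mean), collapse = ", ")))
  }
  invisible(x)
}

#' @export
predict.dsc_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$data$temperature else newdata$temperature
  yy <- object$baseline[["intercept"]] + object$baseline[["slope"]] * tt
  if (nrow(object$components) > 0) {
    for (i in seq_len(nrow(object$components))) {
      yy <- yy + object$components$amplitude[i] *
        exp(-(tt - object$components$mean[i])^2 /
              (2 * object$components$width[i]^2))
    }
  }
  yy
}
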