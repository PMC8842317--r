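#' Glycerol backbone orientation vectors
#'
#' Extracts the unit vector from glycerol C1 to C3 per lipid per frame, the
#' default definition of "the orientation of the glycerol backbone" used by
#' the rotational-dynamics analysis.
#'
#' @param frames A [bilayer_frames] tibble.
#' @param from,to Glycerol carbon indices defining the vector (default 1
#'   and 3).
#' @return Tibble with columns `frame`, `time`, `id`, `ux`, `uy`, `uz`.
#' @export
glycerol_orientation <- function(frames, from = 1L, to = 3L) {
  frames <- as_tibble(as.data.frame(frames))
  g <- frames[frames$role == "glycerol" & frames$carbon %in% c(from, to), ]
  if (nrow(g) == 0) {
    abort("No glycerol atoms present.", class = "lipidorder_error_parameter")
  }
  g |>
    group_by(.data$frame, .data$time, id = .data$lipid_id) |>
    summarise(
      ux = .data$x[.data$carbon == to] - .data$x[.data$carbon == from],
      uy = .data$y[.data$carbon == to] - .data$y[.data$carbon == from],
      uz = .data$z[.data$carbon == to] - .data$z[.data$carbon == from],
      .groups = "drop"
    ) |>
    mutate(
      norm = sqrt(.data$ux^2 + .data$uy^2 + .data$uz^2),
      ux = .data$ux / .data$norm, uy = .data$uy / .data$norm,
      uz = .data$uz / .data$norm
    ) |>
    select(-"norm")
}

#' Orientation autocorrelation with stretched-exponential fit
#'
#' Computes C(t) = <u(s) . u(s+t)> averaged over time origins and
#' molecules, then fits the Kohlrausch-Williams-Watts form
#' C(t) = exp(-(t/tau)^beta) with beta free in (0.3, 1]. The correlation
#' time is the analytic integral of the fit,
#' tau_c = (tau/beta) * Gamma(1/beta), which reduces to tau for beta = 1.
#' tau is initialized from the lag where the ACF crosses 1/e.
#'
#' @param vectors Tibble with columns `id`, `ux`, `uy`, `uz` and either
#'   `time` or `frame` (rows sorted or sortable by time within id), e.g.
#'   from [glycerol_orientation()].
#' @param dt Time per frame (any unit; tau and tau_c inherit it). When a
#'   `time` column is present, `dt` defaults to its spacing.
#' @param max_lag Maximum lag in frames (default: half the series).
#' @param fit Fit the KWW form (default TRUE).
#' @return A `correlation_result`: list with `acf` (tibble `lag`, `time`,
#'   `acf`), `tau`, `beta`, `tau_c`, `converged`.
#' @export
orientation_autocorrelation <- function(vectors, dt = NULL, max_lag = NULL,
                                        fit = TRUE) {
  v <- as_tibble(vectors)
  if (!"time" %in% names(v)) {
    if ("t" %in% names(v)) {
      v$time <- v$t
    } else if ("frame" %in% names(v)) {
      v$time <- v$frame
    } else {
      abort("`vectors` needs a `time`, `t` or `frame` column.",
            class = "lipidorder_error_parameter")
    }
  }
  times <- sort(unique(v$time))
  nt <- length(times)
  if (nt < 10L) {
    abort("Need >= 10 time points for the autocorrelation.",
          class = "lipidorder_error_parameter")
  }
  if (is.null(dt)) dt <- if (nt > 1) times[2] - times[1] else 1
  ids <- sort(unique(v$id))
  v <- v[order(v$id, v$time), ]
  nn <- length(ids)
  ux <- matrix(v$ux, nt, nn); uy <- matrix(v$uy, nt, nn)
  uz <- matrix(v$uz, nt, nn)

  max_lag <- min(max_lag %||% floor(nt / 2), nt - 1L)
  lags <- 0:max_lag
  acf_vals <- vapply(lags, function(l) {
    s <- seq_len(nt - l)
    mean(ux[s, , drop = FALSE] * ux[s + l, , drop = FALSE] +
           uy[s, , drop = FALSE] * uy[s + l, , drop = FALSE] +
           uz[s, , drop = FALSE] * uz[s + l, , drop = FALSE])
  }, numeric(1))

  acf_tbl <- tibble(lag = lags, time = lags * dt, acf = acf_vals)
  res <- list(acf = acf_tbl, tau = NA_real_, beta = NA_real_,
              tau_c = NA_real_, converged = FALSE)

  if (fit) {
    pos <- acf_tbl[acf_tbl$lag > 0, ]
    below <- which(pos$acf < exp(-1))
    tau0 <- if (length(below) > 0) pos$time[below[1]] else max(pos$time)
    fit_obj <- tryCatch(
      minpack.lm::nlsLM(
        acf ~ exp(-(time / tau)^beta),
        data = acf_tbl,
        start = list(tau = max(tau0, dt / 2), beta = 0.9),
        lower = c(tau = 1e-9, beta = 0.3),
        upper = c(tau = Inf, beta = 1),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit_obj)) {
      cf <- coef(fit_obj)
      res$tau <- unname(cf["tau"])
      res$beta <- unname(cf["beta"])
      res$tau_c <- kww_correlation_time(res$tau, res$beta)
      res$converged <- TRUE
    } else {
      warn("KWW fit did not converge; returning the ACF only.",
           class = "lipidorder_warning_fit")
    }
  }
  class(res) <- "correlation_result"
  res
}

#' Analytic KWW correlation time
#'
#' @param tau KWW time constant.
#' @param beta Stretching exponent in (0, 1].
#' @return `(tau / beta) * Gamma(1 / beta)`.
#' @export
kww_correlation_time <- function(tau, beta) {
  (tau / beta) * gamma(1 / beta)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "<correlation_result> tau = %.4g, beta = %.3f, tau_c = %.4g (%s)\n",
    x$tau, x$beta, x$tau_c,
    if (x$converged) "converged" else "fit failed"
  ))
  invisible(x)
}

#' Extract lipid center-of-mass in-plane tracks
#'
#' Uses the phosphorus position (or the chain-carbon centroid when no
#' phosphorus is present) as the per-lipid in-plane reference.
#'
#' @param frames A [bilayer_frames] tibble.
#' @param species Restrict to one species (default all).
#' @return Tibble with columns `frame`, `time`, `id`, `x`, `y` (wrapped).
#' @export
lipid_tracks <- function(frames, species = NULL) {
  df <- as_tibble(as.data.frame(frames))
  if (!is.null(species)) df <- df[df$species %in% species, ]
  p <- df[df$role == "phosphorus", ]
  if (nrow(p) == 0) p <- df[df$role == "chain", ]
  if (nrow(p) == 0) {
    abort("No reference atoms for tracks.", class = "lipidorder_error_parameter")
  }
  p |>
    group_by(.data$frame, .data$time, id = .data$lipid_id) |>
    summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop")
}

#' Lateral diffusion coefficient from the mean squared displacement
#'
#' Trajectories are unwrapped by minimum-imaging consecutive displacements
#' and accumulating them (exact when the frame spacing is much shorter than
#' the box-crossing time), then the time-and-ensemble averaged MSD is
#' computed and D = slope/4 is fitted by least squares over a lag window.
#'
#' @param tracks Tibble with columns `id`, `x`, `y` and `frame` or `time`.
#' @param dt Time per frame (ns). When a `time` column is present its
#'   spacing is used.
#' @param box Length-2 periodic box (nm) for unwrapping; `NULL` means the
#'   tracks are already unwrapped.
#' @param fit_window Lag window for the linear fit as fractions of the
#'   maximum lag (default `c(0.1, 0.5)`).
#' @param min_frames Minimum frames required (default 50).
#' @return A `diffusion_fit`: list with `msd` (tibble `lag`, `time`,
#'   `msd`), `d` (nm^2/ns), `se`, `fit_window` (ns).
#' @export
lateral_diffusion <- function(tracks, dt = NULL, box = NULL,
                              fit_window = c(0.1, 0.5), min_frames = 50L) {
  v <- as_tibble(tracks)
  if (!"time" %in% names(v)) {
    if ("t" %in% names(v)) {
      v$time <- v$t
    } else if ("frame" %in% names(v)) {
      v$time <- v$frame
    } else {
      abort("`tracks` needs a `time`, `t` or `frame` column.",
            class = "lipidorder_error_parameter")
    }
  }
  times <- sort(unique(v$time))
  nt <- length(times)
  if (nt < min_frames) {
    abort(sprintf("Need >= %d frames for a diffusion fit.", min_frames),
          class = "lipidorder_error_parameter")
  }
  ids <- unique(v$id)
  if (length(ids) < 2L) {
    abort("Need >= 2 lipids.", class = "lipidorder_error_parameter")
  }
  if (is.null(dt)) dt <- times[2] - times[1]

  v <- v[order(v$id, v$time), ]
  x <- matrix(v$x, nt, length(ids))
  y <- matrix(v$y, nt, length(ids))
  if (!is.null(box)) {
    x <- apply(x, 2L, function(col) cumsum(c(col[1], min_image(diff(col), box[1]))))
    y <- apply(y, 2L, function(col) cumsum(c(col[1], min_image(diff(col), box[2]))))
  }

  max_lag <- floor(nt / 2)
  lags <- unique(round(seq(0, max_lag, length.out = min(max_lag + 1L, 101L))))
  msd <- vapply(lags, function(l) {
    if (l == 0) return(0)
    s <- seq_len(nt - l)
    mean((x[s + l, , drop = FALSE] - x[s, , drop = FALSE])^2 +
           (y[s + l, , drop = FALSE] - y[s, , drop = FALSE])^2)
  }, numeric(1))
  msd_tbl <- tibble(lag = lags, time = lags * dt, msd = msd)

  lo <- fit_window[1] * max_lag * dt
  hi <- fit_window[2] * max_lag * dt
  sel <- msd_tbl$time >= lo & msd_tbl$time <= hi
  if (sum(sel) < 2L) {
    abort("Fit window contains fewer than 2 MSD points.",
          class = "lipidorder_error_parameter")
  }
  fit <- lm(msd ~ time, data = msd_tbl[sel, ])
  slope <- unname(coef(fit)[2])
  se <- tryCatch(summary(fit)$coefficients[2, 2], error = function(e) NA_real_)

  structure(list(
    msd = msd_tbl,
    d = max(slope / 4, 0),
    se = se / 4,
    fit_window = c(lo, hi)
  ), class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.4g nm^2/ns (window %.3g-%.3g)\n",
              x$d, x$fit_window[1], x$fit_window[2]))
  invisible(x)
}
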