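#' Deuterium order parameter profile
#'
#' S_CD per carbon is the ensemble average of (3 cos^2 theta - 1)/2 over
#' C-H bond vectors, with theta the angle between the C-H vector and the
#' bilayer normal (the z axis; frames are assumed pre-oriented). When the
#' frames carry no hydrogen records, hydrogens are reconstructed from the
#' heavy-atom geometry with ideal tetrahedral angles (common practice for
#' united-atom inputs) and the result is flagged.
#'
#' The mean order parameter is reported over `carbons` (default 8:16, the
#' chain middle onward), intersected with the carbons actually present.
#'
#' @param frames A [bilayer_frames] tibble.
#' @param chain `"sn2"` (default), `"sn1"`, or `"both"`.
#' @param carbons Carbon range for the mean |S_CD| aggregate.
#' @param species Restrict to one species (default `"DPPC"`; `NULL` keeps
#'   all phospholipids).
#' @return A `chain_order_profile` tibble: columns `carbon`, `s_cd`,
#'   `n_obs`; attributes `mean_scd` (signed), `mean_abs_scd`, `carbons`,
#'   `reconstructed`.
#' @export
deuterium_order <- function(frames, chain = c("sn2", "sn1", "both"),
                            carbons = 8:16, species = "DPPC") {
  chain <- match.arg(chain)
  frames <- as_tibble(as.data.frame(frames))
  ch_sel <- if (chain == "both") c("sn1", "sn2") else chain
  df <- frames[frames$chain %in% ch_sel, ]
  if (!is.null(species)) df <- df[df$species %in% species, ]
  cpos <- df[df$role == "chain", ]
  hpos <- df[df$role == "hydrogen", ]
  if (nrow(cpos) < 2L) {
    abort("Need at least 2 chain carbons.", class = "lipidorder_error_parameter")
  }

  reconstructed <- nrow(hpos) == 0
  if (!reconstructed) {
    key <- c("frame", "lipid_id", "chain", "carbon")
    vec <- dplyr::inner_join(
      hpos[, c(key, "x", "y", "z")],
      cpos[, c(key, "x", "y", "z")],
      by = key, suffix = c("_h", "_c"),
      relationship = "many-to-many"
    )
    vx <- vec$x_h - vec$x_c; vy <- vec$y_h - vec$y_c; vz <- vec$z_h - vec$z_c
    obs <- tibble(carbon = vec$carbon,
                  cos2 = (vz^2) / (vx^2 + vy^2 + vz^2))
  } else {
    obs <- reconstruct_ch_cos2(cpos)
  }

  prof <- obs |>
    group_by(.data$carbon) |>
    summarise(s_cd = mean((3 * .data$cos2 - 1) / 2), n_obs = dplyr::n(),
              .groups = "drop") |>
    arrange(.data$carbon)

  use <- prof$carbon %in% carbons
  attr(prof, "mean_scd") <- mean(prof$s_cd[use])
  attr(prof, "mean_abs_scd") <- abs(mean(prof$s_cd[use]))
  attr(prof, "carbons") <- carbons
  attr(prof, "chain") <- chain
  attr(prof, "reconstructed") <- reconstructed
  class(prof) <- c("chain_order_profile", class(prof))
  prof
}

# Ideal-tetrahedral hydrogen reconstruction from heavy atoms: for each
# carbon the two H directions lie in the plane perpendicular to the local
# chain bisector; collinear (all-trans) neighborhoods degenerate to the
# plane perpendicular to the chain, handled explicitly.
reconstruct_ch_cos2 <- function(cpos) {
  half <- 54.735 * pi / 180 # half the tetrahedral H-C-H angle
  out <- cpos |>
    group_by(.data$frame, .data$lipid_id, .data$chain) |>
    arrange(.data$carbon, .by_group = TRUE) |>
    dplyr::group_map(function(g, key) {
      nc <- nrow(g)
      if (nc < 2) return(NULL)
      p <- as.matrix(g[, c("x", "y", "z")])
      cos2 <- numeric(0); carb <- integer(0)
      for (i in seq_len(nc)) {
        prev <- if (i > 1) p[i - 1, ] - p[i, ] else p[i, ] - p[i + 1, ]
        nxt <- if (i < nc) p[i + 1, ] - p[i, ] else p[i, ] - p[i - 1, ]
        u1 <- prev / sqrt(sum(prev^2)); u2 <- nxt / sqrt(sum(nxt^2))
        s <- u1 + u2
        cr <- c(u1[2] * u2[3] - u1[3] * u2[2],
                u1[3] * u2[1] - u1[1] * u2[3],
                u1[1] * u2[2] - u1[2] * u2[1])
        if (sqrt(sum(s^2)) < 1e-8 || sqrt(sum(cr^2)) < 1e-8) {
          # collinear: any perpendicular pair; build one deterministically
          ref <- if (abs(u2[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
          e1 <- ref - sum(ref * u2) * u2
          e1 <- e1 / sqrt(sum(e1^2))
          e2 <- c(u2[2] * e1[3] - u2[3] * e1[2],
                  u2[3] * e1[1] - u2[1] * e1[3],
                  u2[1] * e1[2] - u2[2] * e1[1])
          h <- rbind(e1, e2)
        } else {
          b <- -s / sqrt(sum(s^2))
          e2 <- cr / sqrt(sum(cr^2))
          h <- rbind(cos(half) * b + sin(half) * e2,
                     cos(half) * b - sin(half) * e2)
        }
        cos2 <- c(cos2, h[, 3]^2 / rowSums(h^2))
        carb <- c(carb, rep(g$carbon[i], 2L))
      }
      tibble(carbon = carb, cos2 = cos2)
    }) |> list_rbind()
  out
}

#' Acyl chain tilt angles
#'
#' The tilt of a chain is the angle between the vector from its first to
#' its last carbon and the bilayer normal (z axis), folded into
#' `[0, 90]` degrees.
#'
#' @param frames A [bilayer_frames] tibble.
#' @param species Restrict to one species (default `"DPPC"`).
#' @return Tibble with columns `frame`, `lipid_id`, `chain`, `tilt`
#'   (degrees); zero-length chain vectors give `NA`.
#' @export
chain_tilt <- function(frames, species = "DPPC") {
  frames <- as_tibble(as.data.frame(frames))
  cpos <- frames[frames$role == "chain", ]
  if (!is.null(species)) cpos <- cpos[cpos$species %in% species, ]
  if (nrow(cpos) < 2L) {
    abort("Need at least 2 chain carbons.", class = "lipidorder_error_parameter")
  }
  cpos |>
    group_by(.data$frame, .data$lipid_id, .data$chain) |>
    summarise(
      vx = .data$x[which.max(.data$carbon)] - .data$x[which.min(.data$carbon)],
      vy = .data$y[which.max(.data$carbon)] - .data$y[which.min(.data$carbon)],
      vz = .data$z[which.max(.data$carbon)] - .data$z[which.min(.data$carbon)],
      .groups = "drop"
    ) |>
    mutate(
      norm = sqrt(.data$vx^2 + .data$vy^2 + .data$vz^2),
      tilt = ifelse(.data$norm > 0,
                    acos(pmin(1, abs(.data$vz) / .data$norm)) * 180 / pi,
                    NA_real_)
    ) |>
    select("frame", "lipid_id", "chain", "tilt")
}

#' Cholesterol depth relative to the phosphate plane
#'
#' Mean z-offset of the CHOL hydroxyl oxygen relative to the phosphorus
#' plane of its leaflet, signed positive toward the headgroups (away from
#' the bilayer core).
#'
#' @param frames A [bilayer_frames] tibble with leaflets assigned.
#' @return Tibble with columns `frame`, `time`, `leaflet`, `n_chol`,
#'   `depth` (nm).
#' @export
chol_depth <- function(frames) {
  frames <- as_tibble(as.data.frame(frames))
  oh <- frames[frames$role == "hydroxyl" & frames$species == "CHOL", ]
  ph <- frames[frames$role == "phosphorus", ]
  if (nrow(oh) == 0 || nrow(ph) == 0) {
    abort("Need both CHOL hydroxyl and phosphorus atoms.",
          class = "lipidorder_error_parameter")
  }
  plane <- ph |>
    group_by(.data$frame, .data$leaflet) |>
    summarise(z_p = mean(.data$z), .groups = "drop")
  oh |>
    left_join(plane, by = c("frame", "leaflet")) |>
    mutate(d = ifelse(.data$leaflet == "lower",
                      .data$z_p - .data$z, .data$z - .data$z_p)) |>
    group_by(.data$frame, .data$time, .data$leaflet) |>
    summarise(n_chol = dplyr::n(), depth = mean(.data$d), .groups = "drop")
}
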