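#' Generate a toy bilayer trajectory with planted dynamics and order
#'
#' Builds a minimal two-leaflet bilayer whose per-lipid geometry and
#' dynamics are planted rather than simulated: lipid centers follow
#' independent 2D Brownian motion with a prescribed lateral diffusion
#' coefficient, acyl chains are stiff rods at a prescribed tilt from the
#' bilayer normal, carbon-hydrogen directions are drawn so the mean
#' deuterium order parameter equals a prescribed value in expectation, and
#' the glycerol backbone vector reorients by rotational diffusion with a
#' prescribed correlation time. An optional cholesterol fraction adds CHOL
#' molecules (hydroxyl oxygen plus ring atoms) at a prescribed depth.
#'
#' The C-H draw mixes two exactly solvable orientations relative to the
#' bilayer normal: perpendicular (order parameter -1/2) with probability
#' `2 * order_level` and magic-angle (order parameter 0) otherwise, giving
#' mean S_CD = -`order_level`. `order_level = 0.5` with `tilt = 0` yields
#' perfectly ordered rods with S_CD exactly -0.5.
#'
#' @param n_lipids Total lipids (split evenly between leaflets).
#' @param n_frames Number of frames.
#' @param dt Frame spacing (ns).
#' @param d Planted lateral diffusion coefficient (nm^2/ns).
#' @param order_level Planted mean |S_CD|, in (0, 0.5].
#' @param tilt Planted chain tilt from the bilayer normal (degrees).
#' @param tau_rot Planted glycerol orientation correlation time (ns).
#' @param chol_fraction Fraction of lipids that are cholesterol.
#' @param chol_depth Planted z-offset of the CHOL hydroxyl oxygen relative
#'   to the phosphate plane, positive toward the headgroups (nm).
#' @param n_carbons Carbons per acyl chain.
#' @param appl Area per phospholipid used to size the box (nm^2).
#' @param seed Integer seed.
#'
#' @return List of class `toy_trajectory`: `frames` (a [bilayer_frames]
#'   tibble) and `truth` (the planted parameters).
#' @export
#' @examples
#' toy <- make_toy_trajectory(n_lipids = 8, n_frames = 5, seed = 1)
#' toy$truth$d
make_toy_trajectory <- function(n_lipids = 64,
                                n_frames = 50,
                                dt = 0.1,
                                d = 1,
                                order_level = 0.35,
                                tilt = 15,
                                tau_rot = 0.5,
                                chol_fraction = 0,
                                chol_depth = -0.5,
                                n_carbons = 16,
                                appl = 0.64,
                                seed = 1L) {
  check_positive(n_lipids, "n_lipids")
  check_positive(n_frames, "n_frames")
  check_positive(dt, "dt")
  check_positive(tau_rot, "tau_rot")
  if (d < 0) abort("`d` must be >= 0.", class = "lipidorder_error_parameter")
  if (order_level <= 0 || order_level > 0.5) {
    abort("`order_level` must lie in (0, 0.5].", class = "lipidorder_error_parameter")
  }
  if (tilt < 0 || tilt >= 90) {
    abort("`tilt` must lie in [0, 90).", class = "lipidorder_error_parameter")
  }
  if (chol_fraction < 0 || chol_fraction >= 1) {
    abort("`chol_fraction` must lie in [0, 1).", class = "lipidorder_error_parameter")
  }

  nl <- as.integer(n_lipids)
  nf <- as.integer(n_frames)
  nc <- as.integer(n_carbons)
  n_upper <- as.integer(ceiling(nl / 2))
  leaflet_of <- rep(c("upper", "lower"), c(n_upper, nl - n_upper))
  sgn_of <- ifelse(leaflet_of == "upper", 1, -1)
  n_chol <- as.integer(round(chol_fraction * nl))
  species_of <- rep("DPPC", nl)
  if (n_chol > 0) {
    species_of[round(seq(1, nl, length.out = n_chol))] <- "CHOL"
  }
  dppc <- which(species_of == "DPPC")
  chol <- which(species_of == "CHOL")
  nd <- length(dppc)

  side <- sqrt(max(n_upper, nl - n_upper) * appl)
  box <- c(side, side, 6)
  d_rot <- 1 / (2 * tau_rot)
  tilt_rad <- tilt * pi / 180
  bond <- 0.127   # carbon-carbon rise along the rod (nm)
  ch_len <- 0.109 # C-H bond length (nm)

  with_seed(seed, {
    # Brownian centers, wrapped in xy
    cx <- matrix(0, nf, nl); cy <- matrix(0, nf, nl)
    cx[1, ] <- runif(nl, 0, box[1]); cy[1, ] <- runif(nl, 0, box[2])
    if (nf > 1) {
      step_sd <- sqrt(2 * d * dt)
      cx[-1, ] <- matrix(rnorm((nf - 1) * nl, sd = step_sd), nf - 1, nl)
      cy[-1, ] <- matrix(rnorm((nf - 1) * nl, sd = step_sd), nf - 1, nl)
      cx <- apply(cx, 2L, cumsum)
      cy <- apply(cy, 2L, cumsum)
    }
    cx <- wrap_coord(cx, box[1]); cy <- wrap_coord(cy, box[2])

    # glycerol orientation: rotational diffusion on the sphere
    gx <- matrix(0, nf, nl); gy <- matrix(0, nf, nl); gz <- matrix(0, nf, nl)
    u0 <- matrix(rnorm(3 * nl), nl, 3)
    u0 <- u0 / sqrt(rowSums(u0^2))
    gx[1, ] <- u0[, 1]; gy[1, ] <- u0[, 2]; gz[1, ] <- u0[, 3]
    if (nf > 1) {
      rot_sd <- sqrt(2 * d_rot * dt)
      for (f in 2:nf) {
        ux <- gx[f - 1, ] + rnorm(nl, sd = rot_sd)
        uy <- gy[f - 1, ] + rnorm(nl, sd = rot_sd)
        uz <- gz[f - 1, ] + rnorm(nl, sd = rot_sd)
        nn <- sqrt(ux^2 + uy^2 + uz^2)
        gx[f, ] <- ux / nn; gy[f, ] <- uy / nn; gz[f, ] <- uz / nn
      }
    }

    azimuth <- runif(nl, 0, 2 * pi)
    dir_x <- sin(tilt_rad) * cos(azimuth)
    dir_y <- sin(tilt_rad) * sin(azimuth)
    dir_z <- -sgn_of * cos(tilt_rad)

    times <- (seq_len(nf) - 1) * dt * 1000 # ps

    # helper: flatten an [nf, subset] matrix, frame index fastest
    flat <- function(m, idx) as.vector(m[, idx, drop = FALSE])
    f_rep <- function(k) rep(seq_len(nf), times = k)

    # phosphorus rows (one per DPPC per frame)
    p_tbl <- tibble(
      frame = f_rep(nd),
      lipid_id = rep(dppc, each = nf),
      species = "DPPC",
      leaflet = rep(leaflet_of[dppc], each = nf),
      role = "phosphorus", chain = NA_character_, carbon = NA_integer_,
      x = flat(cx, dppc), y = flat(cy, dppc),
      z = rep(sgn_of[dppc] * 2.2, each = nf)
    )

    # glycerol rows: C1/C2/C3 at coefficients -0.125, 0, +0.125 along u
    gly_coef <- c(-0.125, 0, 0.125)
    g_tbl <- map(1:3, function(ci) {
      tibble(
        frame = f_rep(nd),
        lipid_id = rep(dppc, each = nf),
        species = "DPPC",
        leaflet = rep(leaflet_of[dppc], each = nf),
        role = "glycerol", chain = NA_character_,
        carbon = as.integer(ci),
        x = flat(cx, dppc) + gly_coef[ci] * flat(gx, dppc),
        y = flat(cy, dppc) + gly_coef[ci] * flat(gy, dppc),
        z = rep(sgn_of[dppc] * 1.9, each = nf) + gly_coef[ci] * flat(gz, dppc)
      )
    }) |> list_rbind()

    # chain carbons: dims ordered (frame, lipid, chain, carbon)
    n_fl <- nf * nd
    chain_off <- c(-0.12, 0.12)
    base_x <- rep(flat(cx, dppc), times = 2 * nc)
    base_y <- rep(flat(cy, dppc), times = 2 * nc)
    sgn_big <- rep(rep(sgn_of[dppc], each = nf), times = 2 * nc)
    dirx_big <- rep(rep(dir_x[dppc], each = nf), times = 2 * nc)
    diry_big <- rep(rep(dir_y[dppc], each = nf), times = 2 * nc)
    dirz_big <- rep(rep(dir_z[dppc], each = nf), times = 2 * nc)
    off_big <- rep(rep(chain_off, each = n_fl), times = nc)
    k_big <- rep((seq_len(nc) - 1) * bond, each = n_fl * 2)

    c_x <- base_x + off_big + k_big * dirx_big
    c_y <- base_y + k_big * diry_big
    c_z <- sgn_big * 1.7 + k_big * dirz_big

    meta <- tibble(
      frame = rep(seq_len(nf), times = nd * 2 * nc),
      lipid_id = rep(rep(dppc, each = nf), times = 2 * nc),
      species = "DPPC",
      leaflet = rep(rep(leaflet_of[dppc], each = nf), times = 2 * nc),
      chain = rep(rep(c("sn1", "sn2"), each = n_fl), times = nc),
      carbon = rep(seq_len(nc), each = n_fl * 2)
    )
    c_tbl <- mutate(meta, role = "chain", x = c_x, y = c_y, z = c_z,
                    .after = "leaflet")

    # planted C-H directions relative to the +z normal
    n_ch <- length(c_x)
    perp <- runif(n_ch) < 2 * order_level
    phi <- runif(n_ch, 0, 2 * pi)
    cos_t <- ifelse(perp, 0, 1 / sqrt(3))
    sin_t <- sqrt(1 - cos_t^2)
    h_tbl <- mutate(meta, role = "hydrogen",
                    x = c_x + ch_len * sin_t * cos(phi),
                    y = c_y + ch_len * sin_t * sin(phi),
                    z = c_z + ch_len * cos_t,
                    .after = "leaflet")

    # cholesterol: hydroxyl + three ring pseudo-atoms below it
    chol_tbl <- NULL
    if (length(chol) > 0) {
      ring_off <- c(0, 0.4, 0.8, 1.2)
      roles <- c("hydroxyl", "ring", "ring", "ring")
      chol_tbl <- map(seq_along(ring_off), function(ri) {
        tibble(
          frame = f_rep(length(chol)),
          lipid_id = rep(chol, each = nf),
          species = "CHOL",
          leaflet = rep(leaflet_of[chol], each = nf),
          role = roles[ri], chain = NA_character_, carbon = NA_integer_,
          x = flat(cx, chol), y = flat(cy, chol),
          z = rep(sgn_of[chol] * (2.2 + chol_depth), each = nf) -
            rep(sgn_of[chol], each = nf) * ring_off[ri]
        )
      }) |> list_rbind()
    }

    atoms <- bind_rows(p_tbl, g_tbl, c_tbl, h_tbl, chol_tbl) |>
      mutate(time = times[.data$frame], .after = "frame") |>
      arrange(.data$frame, .data$lipid_id)

    box_tbl <- tibble(frame = seq_len(nf), time = times,
                      box_x = box[1], box_y = box[2], box_z = box[3])
    frames <- new_bilayer_frames(atoms, box_tbl)

    structure(list(
      frames = frames,
      truth = list(d = d, order_level = order_level, tilt = tilt,
                   tau_rot = tau_rot, chol_depth = chol_depth,
                   dt = dt, seed = seed)
    ), class = "toy_trajectory")
  })
}
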