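#' Project acyl-chain reference sites into the membrane plane
#'
#' For every acyl chain, the in-plane (xy) centroid of a mid-chain carbon
#' range is taken as the chain's packing site. Mid-chain atoms carry the
#' hexagonal packing signal without headgroup noise; the range is
#' configurable. Cholesterol is excluded by default; when included, its
#' ring-system centroid is used as the site.
#'
#' @param frames A [bilayer_frames] tibble with leaflets assigned.
#' @param carbons Carbon index range defining the reference site
#'   (default 4:14).
#' @param include_chol Also emit one site per CHOL molecule (ring centroid).
#' @return Tibble of class `chain_sites` with columns `frame`, `leaflet`,
#'   `chain_id`, `lipid_id`, `species`, `chain`, `x`, `y` (wrapped into the
#'   box). Use [split_sites()] to obtain per-frame per-leaflet `site_set`s.
#' @export
project_chain_sites <- function(frames, carbons = 4:14, include_chol = FALSE) {
  box <- frame_box(frames)
  frames <- as_tibble(as.data.frame(frames))
  ch <- frames[frames$role == "chain", ]
  if (any(is.na(ch$leaflet))) {
    abort("Leaflets are not assigned; call assign_leaflets() first.",
          class = "lipidorder_error_parameter")
  }

  avail <- ch[ch$carbon %in% carbons, ]
  # chains shorter than the requested range fall back to what they have
  got <- dplyr::count(ch, .data$frame, .data$lipid_id, .data$chain)
  used <- dplyr::count(avail, .data$frame, .data$lipid_id, .data$chain)
  short <- nrow(got) > nrow(used)
  if (short) {
    warn("Some chains lack the requested carbon range; using available carbons.",
         class = "lipidorder_warning_short_chain")
    key_used <- paste(used$frame, used$lipid_id, used$chain)
    key_got <- paste(got$frame, got$lipid_id, got$chain)
    extra <- ch[paste(ch$frame, ch$lipid_id, ch$chain) %in%
                  setdiff(key_got, key_used), ]
    avail <- bind_rows(avail, extra)
  }

  sites <- avail |>
    group_by(.data$frame, .data$leaflet, .data$lipid_id,
             .data$species, .data$chain) |>
    summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop")

  if (include_chol) {
    ring <- frames[frames$role == "ring", ]
    if (nrow(ring) > 0) {
      chol_sites <- ring |>
        group_by(.data$frame, .data$leaflet, .data$lipid_id, .data$species) |>
        summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop") |>
        mutate(chain = "chol")
      sites <- bind_rows(sites, chol_sites)
    }
  }

  sites <- sites |>
    left_join(box[, c("frame", "box_x", "box_y")], by = "frame") |>
    mutate(x = wrap_coord(.data$x, .data$box_x),
           y = wrap_coord(.data$y, .data$box_y),
           chain_id = paste0(.data$lipid_id, ":", .data$chain)) |>
    select("frame", "leaflet", "chain_id", "lipid_id", "species",
           "chain", "x", "y") |>
    arrange(.data$frame, .data$leaflet, .data$lipid_id, .data$chain)

  attr(sites, "box") <- box
  attr(sites, "carbons") <- carbons
  class(sites) <- c("chain_sites", class(sites))
  sites
}

#' Split projected chain sites into per-frame, per-leaflet site sets
#'
#' @param sites Result of [project_chain_sites()].
#' @return Named list (`"<frame>/<leaflet>"`) of `site_set` tibbles.
#' @export
split_sites <- function(sites) {
  box <- attr(sites, "box")
  keys <- distinct(as_tibble(sites)[, c("frame", "leaflet")])
  out <- map(seq_len(nrow(keys)), function(i) {
    f <- keys$frame[i]; lf <- keys$leaflet[i]
    df <- as_tibble(sites)[sites$frame == f & sites$leaflet == lf, ]
    df$site <- seq_len(nrow(df))
    b <- box[box$frame == f, ]
    new_site_set(df[, c("site", "chain_id", "lipid_id", "species",
                        "chain", "x", "y")],
                 box_xy = c(b$box_x[1], b$box_y[1]), leaflet = lf)
  })
  names(out) <- paste0(keys$frame, "/", keys$leaflet)
  out
}

#' Area per phospholipid
#'
#' APPL is the in-plane box area divided by the number of phospholipids in
#' the leaflet; cholesterol does not count toward the denominator. A
#' `leaflet = "mean"` row carries the leaflet average per frame.
#'
#' @param frames A [bilayer_frames] tibble with leaflets assigned.
#' @return Tibble with columns `frame`, `time`, `leaflet`,
#'   `n_phospholipid`, `appl` (nm^2).
#' @export
area_per_phospholipid <- function(frames) {
  box <- frame_box(frames)
  frames <- as_tibble(as.data.frame(frames))
  ph <- frames[frames$species %in% phospholipid_species(), ] |>
    distinct(.data$frame, .data$lipid_id, .data$leaflet)
  if (nrow(ph) == 0) {
    abort("No phospholipids in any leaflet; APPL undefined.",
          class = "lipidorder_error_parameter")
  }
  per <- ph |>
    count(.data$frame, .data$leaflet, name = "n_phospholipid") |>
    left_join(box, by = "frame") |>
    mutate(appl = .data$box_x * .data$box_y / .data$n_phospholipid) |>
    select("frame", "time", "leaflet", "n_phospholipid", "appl")
  means <- per |>
    group_by(.data$frame, .data$time) |>
    summarise(leaflet = "mean", n_phospholipid = sum(.data$n_phospholipid),
              appl = mean(.data$appl), .groups = "drop")
  bind_rows(per, means) |> arrange(.data$frame, .data$leaflet)
}
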