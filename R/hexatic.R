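#' Per-site hexatic order parameter
#'
#' The hexatic order parameter of site j is the magnitude of the mean
#' six-fold bond-orientational phase factor over its neighbors,
#' S_hex(j) = | (1/n_j) * sum_k exp(i 6 theta_jk) |, where theta_jk is the
#' in-plane bond angle to neighbor k. It is 1 for an interior site of a
#' perfect triangular lattice and 0 for an interior site of a perfect
#' square lattice. Sites with fewer than 2 neighbors are flagged undefined
#' and excluded from aggregates.
#'
#' @param graph A `neighbor_graph` from [build_neighbor_graph()].
#' @return A `hexatic_field`: tibble with columns `site`, `n_neighbors`,
#'   `s_hex`, `defined`; the graph is carried in the `graph` attribute.
#' @export
#' @examples
#' cfg <- make_planted_configuration(100, cluster_fraction = 1, jitter_sd = 0,
#'                                   box = c(12, 12), seed = 1)
#' f <- hexatic_order(build_neighbor_graph(cfg))
#' max(f$s_hex, na.rm = TRUE)
hexatic_order <- function(graph) {
  n <- attr(graph, "n_sites")
  if (is.null(n)) {
    abort("`graph` must be a neighbor_graph.", class = "lipidorder_error_parameter")
  }
  if (nrow(graph) == 0) {
    out <- tibble(site = integer(0), n_neighbors = integer(0),
                  s_hex = numeric(0), defined = logical(0))
  } else {
    agg <- as_tibble(graph) |>
      group_by(.data$site) |>
      summarise(
        n_neighbors = dplyr::n(),
        s_hex = sqrt(mean(cos(6 * .data$theta))^2 +
                       mean(sin(6 * .data$theta))^2),
        .groups = "drop"
      )
    out <- tibble(site = seq_len(n)) |>
      left_join(agg, by = "site") |>
      mutate(
        n_neighbors = dplyr::coalesce(.data$n_neighbors, 0L),
        defined = .data$n_neighbors >= 2L,
        s_hex = ifelse(.data$defined, .data$s_hex, NA_real_)
      )
  }
  attr(out, "graph") <- graph
  attr(out, "site_set") <- attr(graph, "site_set")
  class(out) <- c("hexatic_field", class(out))
  out
}

# Raw one-frame classification: a core chain is fully surrounded by
# hexagonally packed chains (a complete six-neighbor shell, all packed);
# contact sites on either side of the packed boundary are edge; the rest
# (and undefined-S_hex sites) are free.
classify_field <- function(field, hex_threshold, edge_side = "packed",
                           min_packed_neighbors = 3L) {
  graph <- attr(field, "graph")
  packed <- field$defined & !is.na(field$s_hex) & field$s_hex >= hex_threshold &
    field$n_neighbors >= min_packed_neighbors
  nbr_list <- split(graph$nbr, graph$site)
  idx <- as.integer(names(nbr_list))
  all_nb_packed <- rep(NA, nrow(field))
  any_nb_packed <- rep(FALSE, nrow(field))
  all_nb_packed[idx] <- vapply(nbr_list, function(nb) all(packed[nb]), logical(1))
  any_nb_packed[idx] <- vapply(nbr_list, function(nb) any(packed[nb]), logical(1))

  full_shell <- field$n_neighbors >= 6L
  label <- rep("free", nrow(field))
  label[packed & full_shell & all_nb_packed %in% TRUE] <- "core"
  label[packed & !(full_shell & all_nb_packed %in% TRUE)] <- "edge"
  if (edge_side == "both") label[!packed & any_nb_packed] <- "edge"
  label[!field$defined] <- "free"
  tibble(site = field$site, s_hex = field$s_hex, defined = field$defined,
         label = label)
}

#' Classify chains into core/edge/free cluster populations
#'
#' A site is "packed" when its hexatic order parameter reaches
#' `hex_threshold` and it has at least `min_packed_neighbors` bonds. A
#' packed site with a complete, fully packed six-neighbor shell is
#' `"core"` (a core chain is surrounded by hexagonally packed chains);
#' any other packed site is `"edge"`; everything else is `"free"`. With
#' `edge_side = "both"`, unpacked sites touching a packed site are also
#' counted as edges. Sites with undefined S_hex inherit `"free"` and are
#' flagged via `defined`. Over a frame sequence, a new label must persist
#' for at least `persistence` consecutive frames, otherwise the previous
#' stable label is kept.
#'
#' @param fields A `hexatic_field` or a list of them (one per frame, same
#'   site order).
#' @param hex_threshold Packing threshold on S_hex in (0, 1); default 0.8
#'   separates the lattice and fluid modes of the planted generator.
#' @param persistence Minimum run length (frames) for a label change to
#'   take effect; default 2. Ignored for single-frame input.
#' @param edge_side Which side of the packed boundary carries the `"edge"`
#'   label: `"packed"` (default; only packed non-core sites are edges) or
#'   `"both"` (unpacked sites touching a packed site are also edges).
#' @param min_packed_neighbors Minimum neighbor count for a site to count
#'   as packed (default 3): S_hex estimated from very few bonds is
#'   unreliable, and a hexagonally packed chain necessarily has a
#'   substantial shell.
#' @return A `chain_class_series` tibble: columns `frame`, `site`, `s_hex`,
#'   `defined`, `label` (factor core/edge/free).
#' @export
classify_chains <- function(fields, hex_threshold = 0.8, persistence = 2L,
                            edge_side = c("packed", "both"),
                            min_packed_neighbors = 3L) {
  edge_side <- match.arg(edge_side)
  if (hex_threshold <= 0 || hex_threshold >= 1) {
    abort("`hex_threshold` must lie in (0, 1).", class = "lipidorder_error_parameter")
  }
  if (persistence < 1) {
    abort("`persistence` must be >= 1.", class = "lipidorder_error_parameter")
  }
  if (inherits(fields, "hexatic_field")) fields <- list(fields)

  raw <- map2(fields, seq_along(fields), function(f, i) {
    mutate(classify_field(f, hex_threshold, edge_side, min_packed_neighbors),
           frame = as.integer(i), .before = 1)
  }) |> list_rbind()

  if (length(fields) > 1L && persistence > 1L) {
    raw <- raw |>
      group_by(.data$site) |>
      arrange(.data$frame, .by_group = TRUE) |>
      mutate(label = stabilize_labels(.data$label, as.integer(persistence))) |>
      ungroup() |>
      arrange(.data$frame, .data$site)
  }
  raw$label <- factor(raw$label, levels = c("core", "edge", "free"))
  attr(raw, "hex_threshold") <- hex_threshold
  attr(raw, "persistence") <- persistence
  class(raw) <- c("chain_class_series", class(raw))
  raw
}

# Persistence filter on one site's label sequence: runs shorter than
# `persistence` revert to the preceding stable label (or the next stable
# one at the start of the series).
stabilize_labels <- function(labels, persistence) {
  r <- rle(as.character(labels))
  stable <- r$lengths >= persistence
  if (!any(stable)) return(labels)
  vals <- r$values
  last_stable <- NA_character_
  for (i in seq_along(vals)) {
    if (stable[i]) {
      last_stable <- vals[i]
    } else if (!is.na(last_stable)) {
      vals[i] <- last_stable
    }
  }
  # leading unstable runs inherit the first stable label
  first_stable <- vals[which(stable)[1]]
  if (!is.na(first_stable)) {
    for (i in seq_along(vals)) {
      if (stable[i]) break
      vals[i] <- first_stable
    }
  }
  inverse.rle(list(lengths = r$lengths, values = vals))
}

#' Per-frame class fractions
#'
#' @param series A `chain_class_series` from [classify_chains()].
#' @return Tibble with columns `frame`, `f_core`, `f_edge`, `f_free`
#'   (summing to 1 per frame).
#' @export
class_fractions <- function(series) {
  as_tibble(series) |>
    group_by(.data$frame) |>
    summarise(
      f_core = mean(.data$label == "core"),
      f_edge = mean(.data$label == "edge"),
      f_free = mean(.data$label == "free"),
      .groups = "drop"
    )
}

#' Class fractions as a function of temperature
#'
#' Frame-averaged core/edge/free fractions with standard errors over
#' frames, ordered by temperature.
#'
#' @param series_by_temperature Named list of `chain_class_series`, one per
#'   temperature; names (or `temperatures`) give the temperature in K.
#' @param temperatures Optional numeric vector overriding the names.
#' @return Tibble with columns `temperature`, `class`, `fraction`, `se`,
#'   `n_frames`.
#' @export
class_fractions_vs_temperature <- function(series_by_temperature,
                                           temperatures = NULL) {
  if (length(series_by_temperature) < 2L) {
    abort("Need series at >= 2 temperatures.", class = "lipidorder_error_parameter")
  }
  temps <- temperatures %||% as.numeric(names(series_by_temperature))
  if (any(is.na(temps))) {
    abort("Temperatures must be supplied as names or via `temperatures`.",
          class = "lipidorder_error_parameter")
  }
  out <- map2(series_by_temperature, temps, function(s, tt) {
    fr <- class_fractions(s)
    long <- tidyr::pivot_longer(fr, -"frame", names_to = "class",
                                values_to = "fraction")
    long$class <- sub("^f_", "", long$class)
    long |>
      group_by(.data$class) |>
      summarise(
        temperature = tt,
        n_frames = dplyr::n(),
        se = if (dplyr::n() > 1) sd(.data$fraction) / sqrt(dplyr::n()) else NA_real_,
        fraction = mean(.data$fraction),
        .groups = "drop"
      )
  }) |> list_rbind()
  out |>
    select("temperature", "class", "fraction", "se", "n_frames") |>
    arrange(.data$temperature, .data$class)
}

#' Chain exchange rate between clusters and the free population
#'
#' Counts transitions between the in-cluster state (core or edge) and the
#' free state per chain per unit time. Apply the persistence filter
#' ([classify_chains()]) before calling.
#'
#' @param series A `chain_class_series` spanning >= 2 frames.
#' @param dt Frame spacing (ns).
#' @return Tibble with one row per chain: `site`, `n_transitions`, `rate`
#'   (1/ns); the mean rate is carried in the `overall_rate` attribute.
#' @export
exchange_rate <- function(series, dt) {
  check_positive(dt, "dt")
  nf <- length(unique(series$frame))
  if (nf < 2L) {
    abort("Exchange rate is undefined for a single frame.",
          class = "lipidorder_error_parameter")
  }
  out <- as_tibble(series) |>
    group_by(.data$site) |>
    arrange(.data$frame, .by_group = TRUE) |>
    summarise(
      n_transitions = sum(diff(.data$label != "free") != 0),
      .groups = "drop"
    ) |>
    mutate(rate = .data$n_transitions / ((nf - 1L) * dt))
  attr(out, "overall_rate") <- mean(out$rate)
  out
}

#' Per-class mean distance from chain sites to the nearest cholesterol
#'
#' For every chain site, the minimum-image in-plane distance to the nearest
#' CHOL reference position (ring-system centroid by default) in the same
#' leaflet, averaged within each class.
#'
#' @param frame A [bilayer_frames] tibble restricted to (or containing) the
#'   frame of interest.
#' @param labels Tibble with columns `site` and `label` for the sites in
#'   `site_set` (e.g. one frame of a `chain_class_series`).
#' @param site_set The `site_set` the labels refer to.
#' @param chol_reference `"ring"` (centroid, default) or `"hydroxyl"`.
#' @return Tibble with columns `label`, `mean_distance` (nm), `n`.
#' @export
class_distance_to_chol <- function(frame, labels, site_set,
                                   chol_reference = c("ring", "hydroxyl")) {
  chol_reference <- match.arg(chol_reference)
  box <- site_box(site_set)
  leaflet <- attr(site_set, "leaflet")
  role <- if (chol_reference == "ring") "ring" else "hydroxyl"

  chol <- frame[frame$species == "CHOL" & frame$role == role, ]
  if (!is.na(leaflet) && !is.null(frame$leaflet)) {
    chol <- chol[is.na(chol$leaflet) | chol$leaflet == leaflet, ]
  }
  if (nrow(chol) == 0) {
    abort("No CHOL reference atoms in the leaflet; distances undefined.",
          class = "lipidorder_error_parameter")
  }
  ref <- chol |>
    group_by(.data$lipid_id) |>
    summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop")

  dmin <- vapply(seq_len(nrow(site_set)), function(i) {
    dx <- min_image(ref$x - site_set$x[i], box[1])
    dy <- min_image(ref$y - site_set$y[i], box[2])
    sqrt(min(dx^2 + dy^2))
  }, numeric(1))

  tibble(site = site_set$site, distance = dmin) |>
    left_join(as_tibble(labels)[, c("site", "label")], by = "site") |>
    group_by(.data$label) |>
    summarise(mean_distance = mean(.data$distance), n = dplyr::n(),
              .groups = "drop")
}
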