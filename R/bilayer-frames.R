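# bilayer_frames: long-format atom records for a sequence of bilayer
# frames. One row per atom per frame, with the role of each atom in the
# lipid (phosphorus, glycerol, chain carbon, chain hydrogen, cholesterol
# hydroxyl/ring) made explicit so observables can be computed by plain
# grouped operations. Box dimensions per frame live in the `box` attribute.

new_bilayer_frames <- function(atoms, box) {
  need <- c("frame", "time", "lipid_id", "species", "leaflet",
            "role", "chain", "carbon", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  out <- as_tibble(atoms)
  attr(out, "box") <- as_tibble(box)
  class(out) <- c("bilayer_frames", class(out))
  out
}

#' Per-frame box dimensions of a frame set
#'
#' @param frames A `bilayer_frames` object.
#' @return Tibble with columns `frame`, `time`, `box_x`, `box_y`, `box_z` (nm).
#' @export
frame_box <- function(frames) {
  box <- attr(frames, "box")
  if (is.null(box)) {
    abort("`frames` carries no box attribute.", class = "lipidorder_error_parameter")
  }
  box
}

# Subset frames while keeping the box attribute in sync.
filter_frames <- function(frames, keep) {
  box <- frame_box(frames)
  out <- frames[frames$frame %in% keep, ]
  new_bilayer_frames(out, box[box$frame %in% keep, ])
}

#' @export
print.bilayer_frames <- function(x, ...) {
  box <- attr(x, "box")
  cat(sprintf("<bilayer_frames> %d frames, %d lipids, %d atom records\n",
              nrow(box), length(unique(x$lipid_id)), nrow(x)))
  NextMethod()
}

# Species sets used throughout: cholesterol is never a "phospholipid".
phospholipid_species <- function() c("DPPC", "DOPC", "POPC", "other")
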