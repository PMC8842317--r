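# site_set: per-leaflet 2D projected positions of acyl-chain reference
# sites, with the periodic in-plane box carried as attributes.

new_site_set <- function(data, box_xy, leaflet = NA_character_, periodic = TRUE) {
  stopifnot(all(c("site", "x", "y") %in% names(data)))
  out <- as_tibble(data)
  attr(out, "box_xy") <- as.numeric(box_xy)
  attr(out, "leaflet") <- leaflet
  attr(out, "periodic") <- periodic
  class(out) <- c("site_set", class(out))
  out
}

#' Coerce a data frame of 2D positions to a site set
#'
#' @param data Data frame with columns `x` and `y` (nm); a `site` id column
#'   is added when absent.
#' @param box_xy Length-2 periodic box (nm).
#' @param leaflet Optional leaflet label.
#' @return A `site_set` tibble; positions are wrapped into the primary box.
#' @export
as_site_set <- function(data, box_xy, leaflet = NA_character_) {
  data <- as_tibble(data)
  if (!all(c("x", "y") %in% names(data))) {
    abort("`data` needs `x` and `y` columns.", class = "lipidorder_error_parameter")
  }
  if (!"site" %in% names(data)) data$site <- seq_len(nrow(data))
  data$x <- wrap_coord(data$x, box_xy[1])
  data$y <- wrap_coord(data$y, box_xy[2])
  new_site_set(data[, union(c("site", "x", "y"), names(data))], box_xy, leaflet)
}

site_box <- function(sites) {
  box <- attr(sites, "box_xy")
  if (is.null(box)) {
    abort("Site set has no `box_xy` attribute.", class = "lipidorder_error_parameter")
  }
  box
}

#' @export
print.site_set <- function(x, ...) {
  box <- attr(x, "box_xy")
  cat(sprintf("<site_set> %d sites, box %.2f x %.2f nm, leaflet %s\n",
              nrow(x), box[1], box[2], attr(x, "leaflet") %||% "?"))
  NextMethod()
}
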