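# Internal geometry and RNG helpers. All coordinates are in nm; boxes are
# orthorhombic with in-plane (xy) periodicity; z is non-periodic.

#' Wrap coordinates into the primary periodic cell
#'
#' @param x Numeric vector of coordinates (nm).
#' @param box Periodic box length along this axis (nm).
#' @return Coordinates folded into `[0, box)`.
#' @keywords internal
#' @noRd
wrap_coord <- function(x, box) {
  x - box * floor(x / box)
}

# Minimum-image convention for displacements in a periodic box.
min_image <- function(d, box) {
  d - box * round(d / box)
}

# Minimum-image displacement matrix for 2D positions (n x 2) against a
# reference point; `box` is length-2.
min_image2 <- function(d, box) {
  cbind(min_image(d[, 1], box[1]), min_image(d[, 2], box[2]))
}

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# global stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Positive scalar check used by generator preconditions.
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name),
          class = "lipidorder_error_parameter")
  }
  invisible(x)
}
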