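#' Build a periodic neighbor graph over 2D chain sites
#'
#' Two methods are available. `"voronoi_capped"` computes the periodic
#' Voronoi (Delaunay) adjacency and removes edges longer than `cutoff`;
#' adjacency is decided by the exact empty-circumcircle criterion: sites j
#' and k share a Voronoi facet of positive length if and only if some point
#' on their perpendicular bisector is strictly closer to j and k than to
#' every other site. The test is evaluated per candidate pair (pairs within
#' `cutoff` under minimum image) by intersecting the half-line constraints
#' each third site imposes on the bisector, so four-point degeneracies
#' (e.g. the diagonals of a square lattice) are correctly rejected.
#' `"k_nearest"` connects each site to its `k` nearest neighbors under
#' minimum image and symmetrizes the result.
#'
#' Bond angles are measured from the +x axis using minimum-image
#' displacements.
#'
#' @param sites A `site_set` (see [as_site_set()],
#'   [make_planted_configuration()], [split_sites()]).
#' @param method `"voronoi_capped"` (default) or `"k_nearest"`.
#' @param cutoff Maximum edge length for the capped Voronoi graph (nm).
#'   The default 0.9 nm is about 1.5 times the chain-chain spacing.
#' @param k Number of neighbors for `"k_nearest"`.
#' @return A `neighbor_graph`: tibble of directed edges with columns
#'   `site`, `nbr`, `dist`, `theta` (radians); attributes `method`,
#'   `cutoff`, `n_sites`, `box_xy`.
#' @export
#' @examples
#' cfg <- make_planted_configuration(100, cluster_fraction = 1, jitter_sd = 0,
#'                                   box = c(12, 12), seed = 1)
#' g <- build_neighbor_graph(cfg)
#' table(table(g$site)) # interior sites have 6 neighbors
build_neighbor_graph <- function(sites,
                                 method = c("voronoi_capped", "k_nearest"),
                                 cutoff = 0.9,
                                 k = 6L) {
  method <- match.arg(method)
  check_positive(cutoff, "cutoff")
  pos <- cbind(sites$x, sites$y)
  n <- nrow(pos)
  if (n < 3) {
    abort("Need at least 3 sites to build a neighbor graph.",
          class = "lipidorder_error_parameter")
  }
  box <- site_box(sites)

  # collinearity guard: Voronoi adjacency is degenerate on a line
  if (method == "voronoi_capped") {
    ctr <- sweep(pos, 2L, colMeans(pos))
    sv <- svd(ctr, nu = 0, nv = 0)$d
    if (sv[2] < 1e-9 * max(sv[1], 1)) {
      warn("Collinear configuration; falling back to k_nearest.",
           class = "lipidorder_warning_collinear")
      method <- "k_nearest"
    }
  }

  dx <- min_image(outer(pos[, 1], pos[, 1], "-"), box[1])
  dy <- min_image(outer(pos[, 2], pos[, 2], "-"), box[2])
  d2 <- dx^2 + dy^2

  if (method == "voronoi_capped") {
    cand <- which(upper.tri(d2) & d2 <= cutoff^2, arr.ind = TRUE)
    keep <- vapply(seq_len(nrow(cand)), function(r) {
      voronoi_pair_adjacent(cand[r, 1], cand[r, 2], pos, box)
    }, logical(1))
    ed <- cand[keep, , drop = FALSE]
  } else {
    diag(d2) <- Inf
    k <- min(as.integer(k), n - 1L)
    nb <- t(apply(d2, 1L, function(row) order(row)[seq_len(k)]))
    ed <- cbind(rep(seq_len(n), each = k), as.vector(t(nb)))
    # symmetrize (union) and deduplicate as i < j
    ed <- unique(cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2])))
  }

  i <- c(ed[, 1], ed[, 2])
  j <- c(ed[, 2], ed[, 1])
  ddx <- dx[cbind(j, i)] # displacement from site i to its neighbor j
  ddy <- dy[cbind(j, i)]
  out <- tibble(
    site = i, nbr = j,
    dist = sqrt(ddx^2 + ddy^2),
    theta = atan2(ddy, ddx)
  ) |> arrange(.data$site, .data$nbr)

  attr(out, "method") <- method
  attr(out, "cutoff") <- cutoff
  attr(out, "n_sites") <- n
  attr(out, "box_xy") <- box
  attr(out, "site_set") <- sites
  class(out) <- c("neighbor_graph", class(out))
  out
}

# Exact empty-circumcircle test for one candidate pair under periodic
# minimum image. Centers on the bisector are c(t) = M + t*u with M the pair
# midpoint and u the unit perpendicular; each third site m forbids the ray
# a*t < b with a = -2 u.r_m, b = |d|^2/4 - |r_m|^2 (r_m relative to M).
# The pair is adjacent iff a point with both j,k strictly nearest survives.
voronoi_pair_adjacent <- function(i, j, pos, box, eps = 1e-7) {
  d <- c(min_image(pos[j, 1] - pos[i, 1], box[1]),
         min_image(pos[j, 2] - pos[i, 2], box[2]))
  dl2 <- sum(d^2)
  m <- pos[i, ] + d / 2
  u <- c(-d[2], d[1]) / sqrt(dl2)

  r <- cbind(min_image(pos[, 1] - m[1], box[1]),
             min_image(pos[, 2] - m[2], box[2]))
  r <- r[-c(i, j), , drop = FALSE]
  if (nrow(r) == 0) return(TRUE)

  a <- -2 * (r[, 1] * u[1] + r[, 2] * u[2])
  b <- dl2 / 4 - (r[, 1]^2 + r[, 2]^2)

  flat <- abs(a) < 1e-12
  if (any(flat & b > eps^2)) return(FALSE)
  lo <- if (any(a > 0)) max(b[a > 0] / a[a > 0]) else -Inf
  hi <- if (any(a < 0)) min(b[a < 0] / a[a < 0]) else Inf
  hi - lo > eps
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %s, %d sites, %d undirected edges, cutoff %.2f nm\n",
              attr(x, "method"), attr(x, "n_sites"), nrow(x) / 2,
              attr(x, "cutoff")))
  NextMethod()
}
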