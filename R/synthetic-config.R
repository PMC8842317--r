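#' Generate a 2D site configuration with planted hexagonally packed clusters
#'
#' Builds a synthetic per-leaflet chain-site configuration emulating the
#' in-plane structure of a liquid-ordered membrane: one or more compact
#' patches of a jittered triangular (hexagonal) lattice embedded in a
#' disordered matrix of hard-disk random sites. The ground-truth label of
#' every site is stored alongside the coordinates, so cluster-classification
#' code can be scored against a known answer.
#'
#' Cluster patches are grown as hexagonal coronas (ring by ring) around
#' randomly placed seed cells of a single randomly oriented global lattice;
#' patches that touch merge naturally because they share that lattice. The
#' grown patch set is recentred so it does not straddle the periodic
#' boundary. Truth labels follow the lattice topology: a lattice site whose
#' six lattice neighbors are all part of the patch is `"core"`, a lattice
#' site with at least one missing neighbor is `"edge"`, and every
#' disordered-matrix site is `"free"`.
#'
#' @param n_sites Total number of sites.
#' @param cluster_fraction Fraction of sites placed on the lattice, in
#'   `[0, 1]`.
#' @param lattice_spacing Triangular lattice constant (nm). The default,
#'   0.6 nm, is a typical chain-chain spacing in tightly packed acyl-chain
#'   regions.
#' @param jitter_sd Isotropic Gaussian jitter applied to lattice sites (nm).
#' @param box Length-2 numeric, periodic box edges (nm).
#' @param seed Integer seed; the same seed reproduces the configuration
#'   exactly.
#' @param n_patches Number of lattice patches to grow (default 1).
#' @param min_distance Minimum distance enforced between a random matrix
#'   site and every other site (nm). Default 0.45 nm, about chain-chain
#'   contact.
#' @param max_attempts Rejection-sampling attempts per matrix site before
#'   the configuration is declared infeasibly dense.
#'
#' @return A `site_set` tibble with columns `site`, `x`, `y` and `truth`
#'   (factor core/edge/free), and attributes `box_xy`, `leaflet`,
#'   `periodic`, `lattice_spacing`, `jitter_sd`, `cluster_fraction`,
#'   `seed`. Also carries class `planted_config`.
#' @export
#' @examples
#' cfg <- make_planted_configuration(200, cluster_fraction = 0.5, seed = 1)
#' table(cfg$truth)
make_planted_configuration <- function(n_sites,
                                       cluster_fraction,
                                       lattice_spacing = 0.6,
                                       jitter_sd = 0.02,
                                       box = c(32, 32),
                                       seed = 1L,
                                       n_patches = 1L,
                                       min_distance = 0.45,
                                       max_attempts = 200L) {
  check_positive(n_sites, "n_sites")
  check_positive(lattice_spacing, "lattice_spacing")
  if (!is.numeric(cluster_fraction) || cluster_fraction < 0 || cluster_fraction > 1) {
    abort("`cluster_fraction` must lie in [0, 1].",
          class = "lipidorder_error_parameter")
  }
  if (jitter_sd < 0) {
    abort("`jitter_sd` must be >= 0.", class = "lipidorder_error_parameter")
  }
  box <- as.numeric(box)
  if (length(box) != 2L || any(box <= 0)) {
    abort("`box` must be two positive lengths (nm).",
          class = "lipidorder_error_parameter")
  }

  n_sites <- as.integer(n_sites)
  n_lattice <- as.integer(round(cluster_fraction * n_sites))
  n_free <- n_sites - n_lattice

  with_seed(seed, {
    lattice <- if (n_lattice > 0) {
      grow_lattice_patches(n_lattice, n_patches, lattice_spacing, box)
    } else {
      list(xy = matrix(numeric(0), 0, 2), truth = character(0))
    }

    xy <- lattice$xy
    if (n_lattice > 0 && jitter_sd > 0) {
      xy <- xy + matrix(rnorm(2L * n_lattice, sd = jitter_sd), ncol = 2L)
    }
    if (n_lattice > 0) {
      xy[, 1] <- wrap_coord(xy[, 1], box[1])
      xy[, 2] <- wrap_coord(xy[, 2], box[2])
    }

    free_xy <- sample_hard_disk(n_free, existing = xy, box = box,
                                min_distance = min_distance,
                                max_attempts = max_attempts)

    pos <- rbind(xy, free_xy)
    truth <- c(lattice$truth, rep("free", n_free))

    out <- new_site_set(
      tibble(
        site = seq_len(n_sites),
        x = pos[, 1],
        y = pos[, 2],
        truth = factor(truth, levels = c("core", "edge", "free"))
      ),
      box_xy = box, leaflet = "upper"
    )
    attr(out, "lattice_spacing") <- lattice_spacing
    attr(out, "jitter_sd") <- jitter_sd
    attr(out, "cluster_fraction") <- cluster_fraction
    attr(out, "seed") <- seed
    class(out) <- c("planted_config", class(out))
    out
  })
}

# Grow `n_patches` corona patches totalling `n_cells` cells on a single
# randomly oriented triangular lattice, then recentre so no patch wraps.
grow_lattice_patches <- function(n_cells, n_patches, a, box) {
  n_patches <- max(1L, as.integer(n_patches))
  # ring-ordered axial offsets around a seed cell, enough for the worst case
  max_ring <- ceiling(sqrt(n_cells / 3)) + 2L
  rings <- axial_rings(max_ring)

  # seed cells spread over axial space; patches share the lattice so
  # overlapping coronas merge by deduplication
  span <- ceiling(sqrt(n_cells)) * 2L
  seeds <- cbind(sample.int(span, n_patches, replace = TRUE),
                 sample.int(span, n_patches, replace = TRUE))

  chosen <- matrix(integer(0), 0, 2)
  ring_idx <- rep(1L, n_patches)
  while (nrow(chosen) < n_cells) {
    progressed <- FALSE
    for (p in seq_len(n_patches)) {
      if (nrow(chosen) >= n_cells) break
      if (ring_idx[p] > length(rings)) next
      cells <- sweep(rings[[ring_idx[p]]], 2L, seeds[p, ], "+")
      ring_idx[p] <- ring_idx[p] + 1L
      progressed <- TRUE
      key_new <- paste(cells[, 1], cells[, 2])
      key_old <- paste(chosen[, 1], chosen[, 2])
      cells <- cells[!key_new %in% key_old, , drop = FALSE]
      need <- n_cells - nrow(chosen)
      if (nrow(cells) > need) cells <- cells[seq_len(need), , drop = FALSE]
      chosen <- rbind(chosen, cells)
    }
    if (!progressed) {
      abort("Lattice patch growth exhausted; increase box or lower n_sites.",
            class = "lipidorder_error_density")
    }
  }

  # truth labels from lattice topology
  key <- paste(chosen[, 1], chosen[, 2])
  nbr_offsets <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, -1), c(-1, 1))
  full_shell <- vapply(seq_len(nrow(chosen)), function(i) {
    nb <- sweep(nbr_offsets, 2L, chosen[i, ], "+")
    all(paste(nb[, 1], nb[, 2]) %in% key)
  }, logical(1))
  truth <- ifelse(full_shell, "core", "edge")

  # axial -> cartesian with random global orientation, then recentre
  theta <- runif(1, 0, pi / 3)
  q <- chosen[, 1]; r <- chosen[, 2]
  xy0 <- cbind(a * (q + r / 2), a * r * sqrt(3) / 2)
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  xy0 <- xy0 %*% t(rot)

  ext <- apply(xy0, 2L, range)
  widths <- ext[2, ] - ext[1, ]
  if (any(widths >= box - 2 * a)) {
    abort("Planted lattice does not fit in the box; enlarge `box`.",
          class = "lipidorder_error_density")
  }
  # random placement of the patch bounding box fully inside the cell
  shift <- vapply(1:2, function(k) {
    runif(1, a - ext[1, k], box[k] - a - ext[2, k])
  }, numeric(1))
  xy0 <- sweep(xy0, 2L, shift, "+")

  list(xy = xy0, truth = truth)
}

# Axial-coordinate rings (corona shells) of a triangular lattice:
# rings[[1]] is the seed cell, rings[[k+1]] the k-th hexagonal ring.
axial_rings <- function(max_ring) {
  rings <- vector("list", max_ring + 1L)
  rings[[1]] <- matrix(c(0L, 0L), 1, 2)
  dirs <- rbind(c(-1, 1), c(-1, 0), c(0, -1), c(1, -1), c(1, 0), c(0, 1))
  for (k in seq_len(max_ring)) {
    cell <- c(k, 0L)
    ring <- matrix(integer(0), 0, 2)
    for (d in seq_len(6)) {
      for (s in seq_len(k)) {
        ring <- rbind(ring, cell)
        cell <- cell + dirs[d, ]
      }
    }
    rings[[k + 1L]] <- ring
  }
  rings
}

# Uniform hard-disk rejection sampling in a periodic box.
sample_hard_disk <- function(n, existing, box, min_distance, max_attempts) {
  if (n <= 0) return(matrix(numeric(0), 0, 2))
  pos <- matrix(NA_real_, n, 2)
  placed <- existing
  for (i in seq_len(n)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      cand <- c(runif(1, 0, box[1]), runif(1, 0, box[2]))
      if (nrow(placed) == 0) {
        ok <- TRUE
      } else {
        d <- min_image2(cbind(placed[, 1] - cand[1], placed[, 2] - cand[2]), box)
        ok <- min(rowSums(d^2)) >= min_distance^2
      }
      if (ok) break
    }
    if (!ok) {
      abort(sprintf(
        "Could not place free site %d after %d attempts; density too high.",
        i, max_attempts
      ), class = "lipidorder_error_density")
    }
    pos[i, ] <- cand
    placed <- rbind(placed, cand)
  }
  pos
}
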