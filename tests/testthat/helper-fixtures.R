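# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Complete hexagonal patch: 1 + 3k(k+1) sites for k full rings.
hex_patch_sizes <- function(k) 1 + 3 * k * (k + 1)

triangular_config <- function() {
  fixture("triangular", function() {
    make_planted_configuration(hex_patch_sizes(7), cluster_fraction = 1,
                               jitter_sd = 0, box = c(12, 12), seed = 3)
  })
}

square_site_set <- function() {
  fixture("square", function() {
    grid <- expand.grid(x = (0:9) + 0.5, y = (0:9) + 0.5)
    as_site_set(grid, box_xy = c(10, 10))
  })
}

toy_small <- function() {
  fixture("toy_small", function() {
    make_toy_trajectory(n_lipids = 8, n_frames = 3, chol_fraction = 0.25,
                        seed = 6)
  })
}

# Independent brute-force hexatic sum for one site given explicit
# neighbor displacements (oracle for hexatic_order).
hexatic_brute <- function(dx, dy) {
  th <- atan2(dy, dx)
  sqrt(mean(cos(6 * th))^2 + mean(sin(6 * th))^2)
}
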