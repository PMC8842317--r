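test_that("periodic Voronoi adjacency matches lattice ground truth", {
  # triangular lattice: interior coordination 6
  tri <- triangular_config()
  g <- build_neighbor_graph(tri, cutoff = 0.9)
  deg <- table(factor(g$site, levels = tri$site))
  inner <- tri$truth == "core"
  expect_true(all(deg[inner] == 6))

  # square lattice: exactly 4 neighbors everywhere, diagonals rejected
  # (four-point cocircular degeneracy)
  sq <- square_site_set()
  gs <- build_neighbor_graph(sq, cutoff = 1.45)
  expect_true(all(table(gs$site) == 4))

  # edges are symmetric and never self-referencing
  key <- paste(g$site, g$nbr)
  rev <- paste(g$nbr, g$site)
  expect_setequal(key, rev)
  expect_false(any(g$site == g$nbr))
  expect_true(all(g$dist <= 0.9 + 1e-12))
})

test_that("minimum image connects pairs across the periodic boundary", {
  pts <- data.frame(x = c(0.1, 9.9, 5, 5.3, 4.7), y = c(5, 5, 5, 4, 6))
  ss <- as_site_set(pts, box_xy = c(10, 10))
  g <- build_neighbor_graph(ss, cutoff = 1)
  expect_true(any(g$site == 1 & g$nbr == 2)) # 0.2 nm apart through the wall
  d12 <- g$dist[g$site == 1 & g$nbr == 2]
  expect_equal(d12, 0.2, tolerance = 1e-9)
})

test_that("collinear configurations fall back to k-nearest with a warning", {
  line <- data.frame(x = seq(1, 9, 1), y = 5)
  ss <- as_site_set(line, box_xy = c(10, 10))
  expect_warning(g <- build_neighbor_graph(ss, cutoff = 2),
                 class = "lipidorder_warning_collinear")
  expect_identical(attr(g, "method"), "k_nearest")
})

test_that("hexatic order hits its exact lattice identities", {
  tri <- triangular_config()
  f <- hexatic_order(build_neighbor_graph(tri, cutoff = 0.9))
  expect_true(all(f$s_hex[f$n_neighbors == 6] > 1 - 1e-9))

  sq <- square_site_set()
  fs <- hexatic_order(build_neighbor_graph(sq, cutoff = 1.45))
  # hand oracle: angles 0/90/180/270 give alternating +1/-1 phase factors
  expect_equal(hexatic_brute(c(1, 0, -1, 0), c(0, 1, 0, -1)), 0)
  expect_lt(max(fs$s_hex), 1e-9)

  expect_true(all(f$s_hex >= 0 & f$s_hex <= 1))
})

test_that("hexatic order agrees with a brute-force sum on irregular sites", {
  set.seed(42)
  pts <- data.frame(x = runif(40, 0, 20), y = runif(40, 0, 20))
  ss <- as_site_set(pts, box_xy = c(20, 20))
  g <- build_neighbor_graph(ss, cutoff = 3)
  f <- hexatic_order(g)
  for (s in c(1, 7, 20)) {
    nb <- g[g$site == s, ]
    if (nrow(nb) >= 2) {
      expect_equal(f$s_hex[f$site == s],
                   hexatic_brute(cos(nb$theta), sin(nb$theta)),
                   tolerance = 1e-12)
    }
  }
})

test_that("hexatic magnitudes are invariant under global rotation", {
  cfg <- make_planted_configuration(150, cluster_fraction = 0.6,
                                    jitter_sd = 0.03, box = c(40, 40), seed = 7)
  # keep the cloud far from the walls so rotation does not change wrapping
  pos <- cbind(cfg$x, cfg$y)
  ctr <- colMeans(pos)
  th <- 0.31
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pos2 <- sweep(sweep(pos, 2, ctr) %*% t(rot), 2, ctr, "+")
  s1 <- hexatic_order(build_neighbor_graph(cfg, cutoff = 0.9))
  ss2 <- as_site_set(data.frame(x = pos2[, 1], y = pos2[, 2]),
                     box_xy = c(40, 40))
  s2 <- hexatic_order(build_neighbor_graph(ss2, cutoff = 0.9))
  expect_equal(s1$s_hex, s2$s_hex, tolerance = 1e-8)
})

test_that("mean hexatic order decreases monotonically with lattice jitter", {
  jitters <- c(0, 0.03, 0.06, 0.1)
  means <- vapply(jitters, function(j) {
    mean(vapply(1:5, function(s) {
      cfg <- make_planted_configuration(hex_patch_sizes(6), cluster_fraction = 1,
                                        jitter_sd = j, box = c(12, 12),
                                        seed = s)
      f <- hexatic_order(build_neighbor_graph(cfg, cutoff = 0.9))
      mean(f$s_hex, na.rm = TRUE)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("classification recovers planted truth at the extremes", {
  tri <- triangular_config()
  lab <- classify_chains(hexatic_order(build_neighbor_graph(tri)))
  expect_identical(as.character(lab$label), as.character(tri$truth))

  none <- make_planted_configuration(200, cluster_fraction = 0, seed = 5,
                                     box = c(25, 25))
  lab0 <- classify_chains(hexatic_order(build_neighbor_graph(none)))
  expect_true(all(lab0$label == "free"))

  # fractions always partition to one
  fr <- class_fractions(lab)
  expect_equal(fr$f_core + fr$f_edge + fr$f_free, 1)
})

test_that("the persistence filter suppresses short-lived label flips", {
  labs <- c("free", "free", "core", "free", "free")
  expect_identical(
    lipidorder:::stabilize_labels(labs, 2L),
    c("free", "free", "free", "free", "free")
  )
  # persistent change survives
  labs2 <- c("free", "free", "core", "core", "core")
  expect_identical(lipidorder:::stabilize_labels(labs2, 2L), labs2)
  # persistence 1 is the identity
  expect_identical(lipidorder:::stabilize_labels(labs, 1L), labs)
})

test_that("class fractions vs temperature track a planted sweep", {
  fracs <- c(0.7, 0.5, 0.3)
  series <- lapply(seq_along(fracs), function(i) {
    cfg <- make_planted_configuration(500, cluster_fraction = fracs[i],
                                      jitter_sd = 0.02, box = c(25, 25),
                                      seed = 100 + i)
    classify_chains(hexatic_order(build_neighbor_graph(cfg)))
  })
  names(series) <- c(298, 308, 318)
  out <- class_fractions_vs_temperature(series)
  in_cluster <- tapply(out$fraction[out$class != "free"],
                       out$temperature[out$class != "free"], sum)
  expect_true(all(diff(in_cluster) < 0)) # clusters melt as T rises
  sums <- tapply(out$fraction, out$temperature, sum)
  expect_equal(as.numeric(sums), rep(1, 3))
})

test_that("exchange rates count cluster entry/exit transitions per time", {
  # constant labels: rate 0
  const <- data.frame(frame = rep(1:5, each = 2), site = rep(1:2, 5),
                      label = "core")
  expect_true(all(exchange_rate(const, dt = 1)$rate == 0))

  # alternating core/free each frame, dt 1 ns: one transition per frame
  alt <- data.frame(frame = rep(1:6, each = 1), site = 1,
                    label = rep(c("core", "free"), 3))
  expect_equal(exchange_rate(alt, dt = 1)$rate, 1)

  # edge <-> core moves stay in-cluster and do not count
  ec <- data.frame(frame = 1:6, site = 1,
                   label = rep(c("core", "edge"), 3))
  expect_equal(exchange_rate(ec, dt = 1)$rate, 0)

  expect_error(exchange_rate(const[const$frame == 1, ], dt = 1),
               class = "lipidorder_error_parameter")
})

test_that("planted telegraph switching is recovered within ten percent", {
  set.seed(31)
  p_switch <- 0.2; nf <- 4000; nchain <- 20; dt <- 1
  labs <- lapply(1:nchain, function(i) {
    state <- cumsum(c(sample(0:1, 1), rbinom(nf - 1, 1, p_switch))) %% 2
    ifelse(state == 1, "core", "free")
  })
  df <- data.frame(
    frame = rep(1:nf, nchain),
    site = rep(1:nchain, each = nf),
    label = unlist(labs)
  )
  rate <- attr(exchange_rate(df, dt = dt), "overall_rate")
  expect_equal(rate, p_switch / dt, tolerance = 0.1)
})

test_that("per-class CHOL distances order core farthest, free closest", {
  # construct a frame whose CHOL sit exclusively among the free sites
  cfg <- make_planted_configuration(400, cluster_fraction = 0.5,
                                    jitter_sd = 0.01, box = c(20, 20),
                                    seed = 13)
  free_idx <- which(cfg$truth == "free")[1:20]
  chol <- data.frame(
    frame = 1, time = 0, lipid_id = 1000 + seq_along(free_idx),
    species = "CHOL", leaflet = "upper", role = "ring",
    chain = NA_character_, carbon = NA_integer_,
    x = cfg$x[free_idx], y = cfg$y[free_idx], z = 1
  )
  frame <- new_bilayer_frames(
    chol, box = data.frame(frame = 1, time = 0, box_x = 20, box_y = 20,
                           box_z = 6))
  labels <- data.frame(site = cfg$site, label = cfg$truth)
  res <- class_distance_to_chol(frame, labels, cfg)
  expect_lt(res$mean_distance[res$label == "free"],
            res$mean_distance[res$label == "core"])
  expect_gt(res$mean_distance[res$label == "core"],
            res$mean_distance[res$label == "edge"])

  # rigid translation leaves distances unchanged (minimum image)
  shift <- frame
  shift$x <- (shift$x + 7) %% 20
  cfg2 <- cfg
  cfg2$x <- (cfg2$x + 7) %% 20
  res2 <- class_distance_to_chol(shift, labels, cfg2)
  expect_equal(res$mean_distance, res2$mean_distance, tolerance = 1e-9)

  no_chol <- frame[0, ]
  expect_error(class_distance_to_chol(no_chol, labels, cfg),
               class = "lipidorder_error_parameter")
})
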