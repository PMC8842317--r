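test_that("toy trajectories survive a write/read round trip", {
  toy <- toy_small()
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_frames(toy$frames, tmp)
  fr <- load_frames(tmp)

  expect_equal(nrow(frame_box(fr)), 3)
  expect_true(all(diff(frame_box(fr)$time) > 0))
  expect_equal(sum(fr$frame == 1), sum(toy$frames$frame == 1))

  orig <- toy$frames[toy$frames$frame == 1, ]
  orig <- orig[order(orig$lipid_id, orig$role, orig$chain, orig$carbon), ]
  got <- fr[fr$frame == 1, ]
  got <- got[order(got$lipid_id, got$role, got$chain, got$carbon), ]
  bx <- frame_box(toy$frames)$box_x[1]
  dx <- abs(orig$x - got$x)
  dx <- pmin(dx, abs(dx - bx)) # whole-molecule rewrapping shifts by one box
  # PDB stores 3 decimals in Angstrom -> 1e-4 nm precision
  expect_lt(max(dx), 2e-4)
  expect_lt(max(abs(orig$z - got$z)), 2e-4)
  expect_identical(orig$species, got$species)
})

test_that("frame stride subsamples frames in time order", {
  toy <- make_toy_trajectory(n_lipids = 4, n_frames = 4, seed = 8)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_frames(toy$frames, tmp)
  fr <- load_frames(tmp, frame_stride = 2)
  box <- frame_box(fr)
  expect_equal(nrow(box), 2)
  expect_equal(box$time, frame_box(toy$frames)$time[c(1, 3)])
})

test_that("unknown residue names are a named error, not a silent drop", {
  toy <- make_toy_trajectory(n_lipids = 4, n_frames = 1, seed = 8)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_frames(toy$frames, tmp)
  txt <- readLines(tmp)
  txt <- sub("DPPC", "XXXX", txt, fixed = TRUE)
  tmp2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(txt, tmp2)
  expect_error(load_frames(tmp2), regexp = "XXXX",
               class = "lipidorder_error_species")
  # a mapping loaded from text fixes it
  mapfile <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# test map", "XXXX DPPC", "DPPC DPPC", "CHOL CHOL"), mapfile)
  expect_silent(load_frames(tmp2, species_map = read_species_map(mapfile)))
  expect_error(load_frames("does/not/exist.pdb"),
               class = "lipidorder_error_format")
})

test_that("leaflet assignment splits by the phosphorus median and handles CHOL", {
  toy <- toy_small()
  fr <- assign_leaflets(toy$frames)
  ph <- fr[fr$role == "phosphorus", ]
  expect_true(all(ph$leaflet[ph$z > 0] == "upper"))
  expect_true(all(ph$leaflet[ph$z < 0] == "lower"))
  # CHOL assigned by hydroxyl-oxygen side of the midplane
  oh <- fr[fr$role == "hydroxyl", ]
  expect_true(all(oh$leaflet == ifelse(oh$z >= 0, "upper", "lower")))

  # rigid z-translation leaves the assignment unchanged
  shifted <- toy$frames
  shifted$z <- shifted$z + 3.7
  fr2 <- assign_leaflets(new_bilayer_frames(shifted, frame_box(toy$frames)))
  expect_identical(fr$leaflet, fr2$leaflet)
})

test_that("monolayer input warns and collapses to a single leaflet", {
  toy <- make_toy_trajectory(n_lipids = 6, n_frames = 1, seed = 9)
  mono <- toy$frames[toy$frames$z > 0, ]
  mono <- new_bilayer_frames(mono, frame_box(toy$frames))
  expect_warning(out <- assign_leaflets(mono),
                 class = "lipidorder_warning_monolayer")
  expect_true(all(out$leaflet == "upper"))
})

test_that("chain sites project to mid-chain centroids, wrapped into the box", {
  toy <- make_toy_trajectory(n_lipids = 64, n_frames = 1, tilt = 0, seed = 10)
  fr <- assign_leaflets(toy$frames)
  sites <- project_chain_sites(fr)
  # one site per acyl chain: 64 DPPC x 2 chains
  expect_equal(nrow(sites), 64 * 2)
  box <- frame_box(fr)
  expect_true(all(sites$x >= 0 & sites$x < box$box_x[1]))

  # untilted chains: site centroid sits at the carbon x within rounding
  ch <- fr[fr$role == "chain" & fr$lipid_id == 1 & fr$chain == "sn1", ]
  s1 <- sites[sites$lipid_id == 1 & sites$chain == "sn1", ]
  expect_equal(s1$x, mean(ch$x[ch$carbon %in% 4:14]) %% box$box_x[1],
               tolerance = 1e-10)

  # chains shorter than the carbon range fall back with a warning
  short <- fr[!(fr$role %in% c("chain", "hydrogen")) | fr$carbon <= 3, ]
  short <- new_bilayer_frames(short, frame_box(fr))
  expect_warning(s2 <- project_chain_sites(short),
                 class = "lipidorder_warning_short_chain")
  expect_equal(nrow(s2), 64 * 2)
})

test_that("area per phospholipid follows box area and excludes cholesterol", {
  toy <- toy_small() # 8 lipids, 2 CHOL
  fr <- assign_leaflets(toy$frames)
  ap <- area_per_phospholipid(fr)
  box <- frame_box(fr)
  up <- ap[ap$frame == 1 & ap$leaflet == "upper", ]
  n_up <- length(unique(fr$lipid_id[fr$leaflet == "upper" &
                                      fr$species == "DPPC"]))
  expect_equal(up$n_phospholipid, n_up)
  expect_equal(up$appl, box$box_x[1] * box$box_y[1] / n_up)

  # doubling the box area doubles APPL at fixed composition
  box2 <- frame_box(fr)
  box2$box_x <- box2$box_x * 2
  fr2 <- new_bilayer_frames(fr, box2)
  ap2 <- area_per_phospholipid(fr2)
  expect_equal(ap2$appl, ap$appl * 2)

  # per-leaflet values are reported alongside their mean
  expect_setequal(unique(ap$leaflet), c("upper", "lower", "mean"))
  m <- ap[ap$frame == 1, ]
  expect_equal(m$appl[m$leaflet == "mean"],
               mean(m$appl[m$leaflet != "mean"]))
})
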