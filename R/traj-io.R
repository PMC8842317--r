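# Trajectory I/O. Reading goes through bio3d's PDB parser; the supported
# pair is a (multi-model) PDB topology + trajectory, which may be the same
# file. Coordinates are stored in nm internally (PDB is in Angstrom).

#' Default residue-name to species mapping
#'
#' Editable key-value mapping used by [load_frames()] to translate residue
#' names into lipid species. Residue names not present in the mapping are
#' an error, never silently dropped.
#'
#' @return Named character vector (names = residue names, values = species).
#' @export
default_species_map <- function() {
  c(DPPC = "DPPC", DPP = "DPPC", DOPC = "DOPC", DOP = "DOPC",
    POPC = "POPC", POP = "POPC", CHOL = "CHOL", CHL = "CHOL",
    CHL1 = "CHOL")
}

#' Read a species mapping from a key-value text file
#'
#' Two whitespace- or tab-separated columns: residue name, species.
#' Lines starting with `#` are comments.
#'
#' @param path File path.
#' @return Named character vector usable as `species_map`.
#' @export
read_species_map <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t]+")
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    abort(sprintf("Malformed species-map line: '%s'", lines[which(bad)[1]]),
          class = "lipidorder_error_format")
  }
  setNames(vapply(parts, `[[`, "", 2L), vapply(parts, `[[`, "", 1L))
}

# Atom-name conventions understood by the role parser (CHARMM-like):
# P = phosphorus; C1/C2/C3 = glycerol; C2<k>/C3<k> = sn-2/sn-1 chain carbon
# k; H2<k>/H3<k> = hydrogen on that carbon; CHOL: O3 = hydroxyl oxygen,
# other C* = ring atoms.
parse_atom_roles <- function(elety, species) {
  n <- length(elety)
  role <- rep("other", n)
  chain <- rep(NA_character_, n)
  carbon <- rep(NA_integer_, n)

  is_chol <- species == "CHOL"
  role[!is_chol & elety == "P"] <- "phosphorus"
  gly <- !is_chol & grepl("^C[123]$", elety)
  role[gly] <- "glycerol"
  carbon[gly] <- as.integer(sub("^C", "", elety[gly]))

  sn2 <- !is_chol & grepl("^C2[0-9]+$", elety)
  sn1 <- !is_chol & grepl("^C3[0-9]+$", elety)
  role[sn2 | sn1] <- "chain"
  chain[sn2] <- "sn2"; chain[sn1] <- "sn1"
  carbon[sn2] <- as.integer(sub("^C2", "", elety[sn2]))
  carbon[sn1] <- as.integer(sub("^C3", "", elety[sn1]))

  h2 <- !is_chol & grepl("^H2[0-9]+$", elety)
  h1 <- !is_chol & grepl("^H3[0-9]+$", elety)
  role[h2 | h1] <- "hydrogen"
  chain[h2] <- "sn2"; chain[h1] <- "sn1"
  carbon[h2] <- as.integer(sub("^H2", "", elety[h2]))
  carbon[h1] <- as.integer(sub("^H3", "", elety[h1]))

  role[is_chol & elety == "O3"] <- "hydroxyl"
  role[is_chol & grepl("^C[0-9]+$", elety)] <- "ring"

  list(role = role, chain = chain, carbon = carbon)
}

#' Load bilayer frames from a topology/trajectory pair
#'
#' Reads coordinates through bio3d's PDB reader. The trajectory is a
#' multi-model PDB; the topology (atom names, residues) may be the same
#' file or a single-frame PDB with identical atom order. Box dimensions are
#' taken from the `CRYST1` record and frame times from `REMARK TIME <ps>`
#' lines when present. In-plane coordinates are wrapped into the primary
#' box; z is left unwrapped (leaflet logic is non-periodic in z).
#'
#' @param topology_path Path to the topology PDB.
#' @param trajectory_path Path to the trajectory PDB (defaults to the
#'   topology).
#' @param frame_stride Keep every `frame_stride`-th frame (>= 1).
#' @param species_map Named character vector mapping residue names to
#'   species (see [default_species_map()], [read_species_map()]).
#' @return A [bilayer_frames] tibble (leaflet column unset; see
#'   [assign_leaflets()]).
#' @export
load_frames <- function(topology_path,
                        trajectory_path = topology_path,
                        frame_stride = 1L,
                        species_map = default_species_map()) {
  if (!file.exists(topology_path)) {
    abort(sprintf("Topology file not found: %s", topology_path),
          class = "lipidorder_error_format")
  }
  if (!file.exists(trajectory_path)) {
    abort(sprintf("Trajectory file not found: %s", trajectory_path),
          class = "lipidorder_error_format")
  }
  if (frame_stride < 1) {
    abort("`frame_stride` must be >= 1.", class = "lipidorder_error_parameter")
  }

  top <- tryCatch(
    suppressWarnings(bio3d::read.pdb(topology_path, multi = FALSE)),
    error = function(e) {
      abort(sprintf("Could not parse '%s' as PDB: %s", topology_path,
                    conditionMessage(e)),
            class = "lipidorder_error_format")
    }
  )
  trj <- if (identical(topology_path, trajectory_path)) {
    suppressWarnings(bio3d::read.pdb(trajectory_path, multi = TRUE))
  } else {
    tryCatch(
      suppressWarnings(bio3d::read.pdb(trajectory_path, multi = TRUE)),
      error = function(e) {
        abort(sprintf("Could not parse '%s' as PDB: %s", trajectory_path,
                      conditionMessage(e)),
              class = "lipidorder_error_format")
      }
    )
  }

  resid <- top$atom$resid
  unknown <- setdiff(unique(resid), names(species_map))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown species for residue name(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "lipidorder_error_species")
  }
  species <- unname(species_map[resid])

  # raw text pass for box and times (bio3d does not expose CRYST1/REMARK)
  raw <- readLines(trajectory_path)
  cryst <- grep("^CRYST1", raw, value = TRUE)
  if (length(cryst) == 0) {
    abort("Trajectory has no CRYST1 record; box dimensions required.",
          class = "lipidorder_error_format")
  }
  box_a <- as.numeric(substring(cryst[1], c(7, 16, 25), c(15, 24, 33))) / 10
  times <- grep("^REMARK +TIME", raw, value = TRUE)
  times <- as.numeric(sub("^REMARK +TIME +", "", times))

  xyz <- trj$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames_all <- nrow(xyz)
  keep <- seq(1L, n_frames_all, by = as.integer(frame_stride))
  if (length(times) != n_frames_all) times <- (seq_len(n_frames_all) - 1)

  natom <- nrow(top$atom)
  if (ncol(xyz) != 3L * natom) {
    abort("Topology and trajectory atom counts differ.",
          class = "lipidorder_error_format")
  }
  roles <- parse_atom_roles(top$atom$elety, species)
  lipid_id <- as.integer(top$atom$resno)

  frames_list <- map(seq_along(keep), function(j) {
    f <- keep[j]
    m <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE) / 10 # Angstrom -> nm
    # wrap molecules whole: shift each lipid by its reference-atom image
    first <- match(unique(lipid_id), lipid_id)
    ref_x <- m[first, 1][match(lipid_id, lipid_id[first])]
    ref_y <- m[first, 2][match(lipid_id, lipid_id[first])]
    tibble(
      frame = j, time = times[f],
      lipid_id = lipid_id, species = species,
      leaflet = NA_character_,
      role = roles$role, chain = roles$chain, carbon = roles$carbon,
      x = m[, 1] + (wrap_coord(ref_x, box_a[1]) - ref_x),
      y = m[, 2] + (wrap_coord(ref_y, box_a[2]) - ref_y),
      z = m[, 3]
    )
  })

  box_tbl <- tibble(frame = seq_along(keep), time = times[keep],
                    box_x = box_a[1], box_y = box_a[2], box_z = box_a[3])
  new_bilayer_frames(list_rbind(frames_list), box_tbl)
}

#' Write bilayer frames as a multi-model PDB
#'
#' Emits GROMACS-style PDB with a `CRYST1` box record and one
#' `REMARK TIME <ps>` line per model, readable by [load_frames()] and by
#' standard MD tooling. Atom names follow the conventions understood by the
#' reader (`P`, `C1`-`C3`, `C2<k>`/`C3<k>`, `H2<k>`/`H3<k>`, `O3`).
#'
#' @param frames A [bilayer_frames] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  box <- frame_box(frames)
  con <- file(path, "w")
  on.exit(close(con))

  atom_name <- function(df) {
    dplyr::case_when(
      df$role == "phosphorus" ~ "P",
      df$role == "glycerol" ~ paste0("C", df$carbon),
      df$role == "chain" & df$chain == "sn2" ~ paste0("C2", df$carbon),
      df$role == "chain" & df$chain == "sn1" ~ paste0("C3", df$carbon),
      df$role == "hydrogen" & df$chain == "sn2" ~ paste0("H2", df$carbon),
      df$role == "hydrogen" & df$chain == "sn1" ~ paste0("H3", df$carbon),
      df$role == "hydroxyl" ~ "O3",
      df$role == "ring" ~ paste0("C", 10 + seq_len(nrow(df)) %% 90),
      TRUE ~ "X"
    )
  }

  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
    box$box_x[1] * 10, box$box_y[1] * 10, box$box_z[1] * 10
  ), con)

  frame_ids <- sort(unique(frames$frame))
  for (fi in seq_along(frame_ids)) {
    f <- frame_ids[fi]
    df <- frames[frames$frame == f, ]
    df <- df[order(df$lipid_id, df$role, df$chain, df$carbon), ]
    nm <- atom_name(df)
    writeLines(sprintf("REMARK TIME %.3f", box$time[box$frame == f][1]), con)
    writeLines(sprintf("MODEL     %4d", fi), con)
    serial <- seq_len(nrow(df)) %% 100000L
    # ring atoms get generated names per CHOL; recompute within lipid
    writeLines(sprintf(
      "ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00",
      serial, nm, df$species,
      df$lipid_id %% 10000L, df$x * 10, df$y * 10, df$z * 10
    ), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Assign leaflets from headgroup positions
#'
#' Phospholipids above the median phosphorus z are labelled `"upper"`,
#' those below `"lower"`. Cholesterol is assigned per frame by the z of its
#' hydroxyl oxygen relative to the bilayer midplane (mean phosphorus z), so
#' flip-flopping CHOL is re-assigned frame by frame. If the two putative
#' leaflets are not separated by at least `min_separation`, the input is
#' treated as a monolayer: a warning is raised and all lipids are labelled
#' `"upper"`.
#'
#' @param frames A [bilayer_frames] tibble.
#' @param min_separation Minimum distance between mean phosphorus z of the
#'   two leaflets (nm) below which a monolayer warning fires.
#' @return `frames` with the `leaflet` column filled in.
#' @export
assign_leaflets <- function(frames, min_separation = 1) {
  box <- frame_box(frames)
  ref <- frames[frames$role %in% c("phosphorus", "hydroxyl"), ]
  if (nrow(ref) == 0) {
    abort("No phosphorus or hydroxyl reference atoms present.",
          class = "lipidorder_error_parameter")
  }

  out <- frames
  for (f in unique(frames$frame)) {
    sel <- frames$frame == f
    ph <- frames[sel & frames$role == "phosphorus", ]
    if (nrow(ph) == 0) ph <- frames[sel & frames$role == "hydroxyl", ]
    # split at the midpoint of the largest gap in sorted phosphorus z;
    # identical to the median split for balanced leaflets, robust to odd
    # or asymmetric counts
    zs <- sort(ph$z)
    gaps <- diff(zs)
    if (length(gaps) == 0 || max(gaps) < min_separation) {
      warn("Lipids appear to form a single leaflet; labelling all 'upper'.",
           class = "lipidorder_warning_monolayer")
      out$leaflet[sel] <- "upper"
      next
    }
    j <- which.max(gaps)
    thr <- (zs[j] + zs[j + 1]) / 2
    lip_leaf <- ifelse(ph$z >= thr, "upper", "lower")
    names(lip_leaf) <- as.character(ph$lipid_id)

    midplane <- thr
    lf <- rep(NA_character_, sum(sel))
    df <- frames[sel, ]
    is_chol <- df$species == "CHOL"
    lf[!is_chol] <- unname(lip_leaf[as.character(df$lipid_id[!is_chol])])
    if (any(is_chol)) {
      oz <- df[df$role == "hydroxyl", c("lipid_id", "z")]
      chol_leaf <- ifelse(oz$z >= midplane, "upper", "lower")
      names(chol_leaf) <- as.character(oz$lipid_id)
      lf[is_chol] <- unname(chol_leaf[as.character(df$lipid_id[is_chol])])
    }
    out$leaflet[sel] <- lf
  }
  new_bilayer_frames(out, box)
}
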