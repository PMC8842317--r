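# Pipeline layer: a file-describable configuration, a synthetic fixture
# bundle generator, and the three analysis drivers. Every run writes a
# machine-readable manifest (config hash, seed, package version) next to
# its outputs, and refuses to overwrite an existing output directory
# unless told to.

#' Default pipeline configuration
#'
#' Every analysis parameter of the pipeline with its package default;
#' override via `...` (nested lists are merged) or load from YAML with
#' [read_config()].
#'
#' @param ... Named overrides, e.g. `packing = list(hex_threshold = 0.75)`.
#' @return Nested list of class `lo_config`.
#' @export
lo_config <- function(...) {
  cfg <- list(
    seed = 1L,
    paths = list(topology = NULL, trajectory = NULL, out_dir = "lo-output"),
    sites = list(carbons = 4:14, include_chol = FALSE),
    packing = list(method = "voronoi_capped", cutoff = 0.9,
                   hex_threshold = 0.8, persistence = 2L),
    order = list(chain = "sn2", carbons = 8:16),
    thermal = list(n_boot = 1000L, p_threshold = 0.05),
    expfit = list(baseline = "sloped", exclude_above = 333,
                  n_boot = 200L, dsc_components = NULL),
    simulate = list(n_sites = 400L, cluster_fraction = 0.5,
                    lattice_spacing = 0.6, jitter_sd = 0.02,
                    box = c(16, 16),
                    n_lipids = 32L, n_frames = 20L, dt = 0.1,
                    d = 1, order_level = 0.35, tilt = 15, tau_rot = 0.5,
                    chol_fraction = 0.25)
  )
  over <- list(...)
  structure(modifyList(cfg, over), class = "lo_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror [lo_config()].
#' @return `lo_config` list with defaults filled in.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "lipidorder_error_format")
  }
  do.call(lo_config, yaml::read_yaml(path))
}

prepare_out_dir <- function(out_dir, overwrite) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite) {
    abort(sprintf("Output directory '%s' is not empty; pass overwrite = TRUE.",
                  out_dir),
          class = "lipidorder_error_output")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out_dir
}

write_manifest <- function(out_dir, config, extra = list()) {
  manifest <- c(list(
    package = "lipidorder",
    version = as.character(utils::packageVersion("lipidorder")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config_hash = rlang::hash(config),
    config = config
  ), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(manifest)
}

#' Generate a full synthetic fixture bundle
#'
#' Writes everything the analysis subcommands consume into one directory:
#' a toy trajectory (multi-model PDB), a planted site configuration with
#' truth labels, and planted observable tables (piecewise-linear APPL
#' series, GP sigmoid, anisotropy sigmoid, DSC thermogram), plus a
#' manifest recording every planted truth.
#'
#' @param config An [lo_config()].
#' @param out_dir Output directory (default from the config).
#' @param overwrite Allow writing into a non-empty directory.
#' @return The manifest, invisibly.
#' @export
simulate_bundle <- function(config = lo_config(), out_dir = NULL,
                            overwrite = FALSE) {
  out_dir <- prepare_out_dir(out_dir %||% config$paths$out_dir, overwrite)
  sim <- config$simulate
  seed <- config$seed

  toy <- make_toy_trajectory(
    n_lipids = sim$n_lipids, n_frames = sim$n_frames, dt = sim$dt,
    d = sim$d, order_level = sim$order_level, tilt = sim$tilt,
    tau_rot = sim$tau_rot, chol_fraction = sim$chol_fraction, seed = seed
  )
  write_frames(toy$frames, file.path(out_dir, "trajectory.pdb"))

  cfg2d <- make_planted_configuration(
    n_sites = sim$n_sites, cluster_fraction = sim$cluster_fraction,
    lattice_spacing = sim$lattice_spacing, jitter_sd = sim$jitter_sd,
    box = sim$box, seed = seed
  )
  readr::write_tsv(as_tibble(cfg2d), file.path(out_dir, "planted_sites.tsv"))

  appl <- make_observable_series(
    "piecewise_linear", truth = list(breakpoint = 308),
    grid = seq(293, 333, 2), noise_sd = 0.0015, seed = seed
  )
  write_series(appl, file.path(out_dir, "appl_series.tsv"))

  gp <- make_observable_series(
    "sigmoid", truth = list(t_inflection = 314, width = 2),
    grid = seq(288, 338, length.out = 15), noise_sd = 0.02, seed = seed + 1L
  )
  write_series(gp, file.path(out_dir, "gp_series.tsv"))

  dsc <- make_observable_series(
    "gaussian_mixture", truth = list(means = c(308, 314), sigmas = c(3, 1),
                                     amplitudes = c(1, 0.6)),
    grid = seq(293, 333, 0.5), noise_sd = 0.01, seed = seed + 2L
  )
  names(dsc)[names(dsc) == "value"] <- "value"
  write_series(dsc, file.path(out_dir, "dsc_thermogram.tsv"))

  write_manifest(out_dir, config, extra = list(
    truths = list(
      toy_trajectory = toy$truth,
      planted_sites = list(
        cluster_fraction = sim$cluster_fraction,
        lattice_spacing = sim$lattice_spacing,
        jitter_sd = sim$jitter_sd
      ),
      appl = attr(appl, "truth"),
      gp = attr(gp, "truth"),
      dsc = attr(dsc, "truth")
    ),
    files = c("trajectory.pdb", "planted_sites.tsv", "appl_series.tsv",
              "gp_series.tsv", "dsc_thermogram.tsv")
  ))
}

#' Run the packing analysis over a trajectory
#'
#' Loads the trajectory, assigns leaflets, projects chain sites, computes
#' hexatic fields per frame and leaflet, classifies chains, and writes the
#' per-site order parameters, labels, class fractions, exchange rates and
#' chain-CHOL distances together with a run manifest.
#'
#' @param config An [lo_config()] with `paths$topology`/`paths$trajectory`
#'   set (trajectory defaults to topology).
#' @param out_dir Output directory (default `paths$out_dir`).
#' @param overwrite Allow writing into a non-empty directory.
#' @return Named list of the output tibbles, invisibly.
#' @export
run_packing <- function(config, out_dir = NULL, overwrite = FALSE) {
  topo <- config$paths$topology %||% config$paths$trajectory
  if (is.null(topo)) {
    abort("run_packing: config field `paths$topology` is not set.",
          class = "lipidorder_error_parameter")
  }
  traj <- config$paths$trajectory %||% topo
  out_dir <- prepare_out_dir(out_dir %||% config$paths$out_dir, overwrite)

  frames <- load_frames(topo, traj) |> assign_leaflets()
  sites <- project_chain_sites(frames, carbons = config$sites$carbons,
                               include_chol = config$sites$include_chol)
  splits <- split_sites(sites)

  fields <- map(splits, function(s) {
    hexatic_order(build_neighbor_graph(s, method = config$packing$method,
                                       cutoff = config$packing$cutoff))
  })

  # classification runs per leaflet across frames
  leaflets <- unique(sub("^[0-9]+/", "", names(splits)))
  series_by_leaflet <- map(leaflets, function(lf) {
    fl <- fields[grepl(paste0("/", lf, "$"), names(fields))]
    classify_chains(fl, hex_threshold = config$packing$hex_threshold,
                    persistence = config$packing$persistence)
  })
  names(series_by_leaflet) <- leaflets

  shex_tbl <- imap(fields, function(f, nm) {
    mutate(as_tibble(f), key = nm, .before = 1)
  }) |> list_rbind()

  labels_tbl <- imap(series_by_leaflet, function(s, lf) {
    mutate(as_tibble(s), leaflet = lf, .before = 1)
  }) |> list_rbind()

  fractions_tbl <- imap(series_by_leaflet, function(s, lf) {
    mutate(class_fractions(s), leaflet = lf, .before = 1)
  }) |> list_rbind()

  dt <- {
    box <- frame_box(frames)
    if (nrow(box) > 1) (box$time[2] - box$time[1]) / 1000 else 1
  }
  exchange_tbl <- imap(series_by_leaflet, function(s, lf) {
    if (length(unique(s$frame)) < 2) return(NULL)
    mutate(exchange_rate(s, dt = dt), leaflet = lf, .before = 1)
  }) |> list_rbind()

  has_chol <- any(frames$species == "CHOL")
  distance_tbl <- if (has_chol) {
    imap(splits, function(s, nm) {
      f <- as.integer(sub("/.*$", "", nm))
      lf <- sub("^[0-9]+/", "", nm)
      labs <- series_by_leaflet[[lf]]
      labs <- labs[labs$frame == f, c("site", "label")]
      res <- tryCatch(
        class_distance_to_chol(frames[frames$frame == f, ], labs, s),
        error = function(e) NULL
      )
      if (is.null(res)) NULL else mutate(res, frame = f, leaflet = lf, .before = 1)
    }) |> list_rbind()
  } else {
    tibble(frame = integer(0), leaflet = character(0),
           label = character(0), mean_distance = numeric(0), n = integer(0))
  }

  outputs <- list(
    s_hex = shex_tbl, labels = labels_tbl, fractions = fractions_tbl,
    exchange_rates = exchange_tbl, chol_distances = distance_tbl
  )
  for (nm in names(outputs)) {
    readr::write_tsv(outputs[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  write_manifest(out_dir, config,
                 extra = list(stage = "packing",
                              files = paste0(names(outputs), ".tsv")))
  invisible(outputs)
}

#' Fit thermotropic crossovers over a set of series files
#'
#' @param config An [lo_config()].
#' @param series_files Character vector of series tables (see
#'   [read_temperature_series()]); names become observable labels.
#' @param out_dir Output directory.
#' @param overwrite Allow writing into a non-empty directory.
#' @return List with `fits` and `consensus`, invisibly.
#' @export
run_thermal <- function(config, series_files, out_dir = NULL,
                        overwrite = FALSE) {
  if (length(series_files) < 1L) {
    abort("run_thermal needs >= 1 series file.",
          class = "lipidorder_error_parameter")
  }
  out_dir <- prepare_out_dir(out_dir %||% config$paths$out_dir, overwrite)
  nms <- names(series_files) %||%
    tools::file_path_sans_ext(basename(series_files))
  fits <- map(series_files, function(p) {
    segmented_fit(read_temperature_series(p),
                  n_boot = config$thermal$n_boot,
                  p_threshold = config$thermal$p_threshold,
                  seed = config$seed)
  })
  names(fits) <- nms
  fit_tbl <- imap(fits, function(f, nm) {
    mutate(glance(f), observable = nm, .before = 1)
  }) |> list_rbind()
  consensus <- crossover_consensus(fits)
  cons_tbl <- mutate(as_tibble(consensus),
                     t_co_consensus = attr(consensus, "t_co"),
                     spread = attr(consensus, "spread"))
  readr::write_tsv(fit_tbl, file.path(out_dir, "segmented_fits.tsv"))
  readr::write_tsv(cons_tbl, file.path(out_dir, "crossover_consensus.tsv"))
  write_manifest(out_dir, config,
                 extra = list(stage = "thermal",
                              files = c("segmented_fits.tsv",
                                        "crossover_consensus.tsv")))
  invisible(list(fits = fits, consensus = consensus))
}

# Infer the kind of an experimental table from its header.
infer_expfit_kind <- function(df, path) {
  nm <- names(df)
  if (all(c("temperature", "i_blue", "i_red") %in% nm)) return("gp")
  if (all(c("temperature", "i_vv", "i_vh") %in% nm)) return("anisotropy")
  if (all(c("temperature", "heat_capacity") %in% nm)) return("dsc")
  if (all(c("temperature", "value") %in% nm)) return("dsc")
  abort(sprintf(
    paste0("Cannot infer data kind of '%s'. Accepted headers: ",
           "(temperature, i_blue, i_red); (temperature, i_vv, i_vh[, g]); ",
           "(temperature, heat_capacity|value[, scan])."), path
  ), class = "lipidorder_error_format")
}

#' Run the experimental-arm fits over data files
#'
#' File kinds are inferred from headers: two-channel fluorescence tables
#' become GP sigmoid fits, polarized-intensity tables become anisotropy
#' sigmoid fits, thermograms become DSC decompositions. Outputs mirror
#' per-sample parameter tables.
#'
#' @param config An [lo_config()].
#' @param data_files Character vector of input tables.
#' @param out_dir Output directory.
#' @param overwrite Allow writing into a non-empty directory.
#' @return List of fit objects keyed by file, invisibly.
#' @export
run_expfit <- function(config, data_files, out_dir = NULL, overwrite = FALSE) {
  if (length(data_files) < 1L) {
    abort("run_expfit needs >= 1 data file.",
          class = "lipidorder_error_parameter")
  }
  out_dir <- prepare_out_dir(out_dir %||% config$paths$out_dir, overwrite)

  results <- list()
  sigmoid_rows <- list()
  dsc_rows <- list()
  for (p in data_files) {
    df <- read_temperature_series_any(p)
    kind <- infer_expfit_kind(df, p)
    nm <- tools::file_path_sans_ext(basename(p))
    if (kind == "gp") {
      df <- generalized_polarization(df)
      ft <- boltzmann_fit(df, value = "gp",
                          baseline = config$expfit$baseline,
                          n_boot = config$expfit$n_boot, seed = config$seed)
      sigmoid_rows[[nm]] <- mutate(glance(ft), sample = nm, kind = "gp",
                                   .before = 1)
    } else if (kind == "anisotropy") {
      g <- if ("g" %in% names(df)) "g" else 1
      df <- steady_state_anisotropy(df, g = g)
      ft <- boltzmann_fit(df, value = "r",
                          baseline = config$expfit$baseline,
                          exclude_above = config$expfit$exclude_above,
                          n_boot = config$expfit$n_boot, seed = config$seed)
      sigmoid_rows[[nm]] <- mutate(glance(ft), sample = nm,
                                   kind = "anisotropy", .before = 1)
    } else {
      val_col <- if ("heat_capacity" %in% names(df)) "heat_capacity" else "value"
      ft <- dsc_decompose(df, heat_capacity = val_col,
                          n_components = config$expfit$dsc_components)
      fts <- if (inherits(ft, "dsc_fit")) list(all = ft) else ft
      dsc_rows[[nm]] <- imap(fts, function(f, sc) {
        mutate(tidy(f), sample = nm, scan = sc, .before = 1)
      }) |> list_rbind()
    }
    results[[nm]] <- ft
  }

  if (length(sigmoid_rows) > 0) {
    readr::write_tsv(list_rbind(sigmoid_rows),
                     file.path(out_dir, "sigmoid_fits.tsv"))
  }
  if (length(dsc_rows) > 0) {
    readr::write_tsv(list_rbind(dsc_rows),
                     file.path(out_dir, "dsc_components.tsv"))
  }
  write_manifest(out_dir, config, extra = list(stage = "expfit"))
  invisible(results)
}

# Tolerant reader for experimental tables (tab-separated, header row).
read_temperature_series_any <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Data file not found: %s", path),
          class = "lipidorder_error_format")
  }
  df <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) {
      abort(sprintf("Could not parse '%s': %s", path, conditionMessage(e)),
            class = "lipidorder_error_format")
    }
  )
  if (nrow(df) == 0) {
    abort(sprintf("Data file '%s' is empty.", path),
          class = "lipidorder_error_format")
  }
  df
}
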