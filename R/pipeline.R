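.RUN_CONFIG_KEYS <- c(
  "structures_dir", "qm_sites", "qm_molecules", "measurements", "out_dir",
  "algorithm", "seed", "mode", "augment", "holdout_arenes",
  "sphere_radius", "grid_spacing", "shell", "angle_resolution",
  "bv_radius_scale", "sterimol_radius_scale", "statistical_factors"
)

.RUN_CONFIG_DEFAULTS <- list(
  algorithm = "extra_trees", seed = 1L, mode = "pair", augment = TRUE,
  holdout_arenes = NULL, sphere_radius = 3.5, grid_spacing = 0.1,
  shell = 2, angle_resolution = 0.1, bv_radius_scale = 1.17,
  sterimol_radius_scale = 1.0, statistical_factors = TRUE
)

#' Assemble and validate a pipeline run configuration
#'
#' A single configuration drives every pipeline stage. Unknown keys are
#' rejected. `read_run_config()` loads YAML or JSON (by file extension).
#'
#' @param ... Configuration keys: `structures_dir`, `qm_sites`,
#'   `qm_molecules`, `measurements`, `out_dir` (paths); `algorithm`, `seed`,
#'   `mode`, `augment`, `holdout_arenes` (modeling); `sphere_radius`,
#'   `grid_spacing`, `shell`, `angle_resolution`, `bv_radius_scale`,
#'   `sterimol_radius_scale`, `statistical_factors` (descriptors).
#' @return A `run_config` list with defaults filled in.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) == 1 && is.list(cfg[[1]]) && is.null(names(cfg))) {
    cfg <- cfg[[1]]
  }
  unknown <- setdiff(names(cfg), .RUN_CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(.RUN_CONFIG_DEFAULTS)) {
    if (is.null(cfg[[k]])) cfg[k] <- list(.RUN_CONFIG_DEFAULTS[[k]])
  }
  need <- c("structures_dir", "qm_sites", "qm_molecules", "measurements",
            "out_dir")
  miss <- need[!vapply(need, function(k) !is.null(cfg[[k]]), logical(1))]
  if (length(miss) > 0) {
    stop("run config is missing required key(s): ", paste(miss, collapse = ", "))
  }
  if (!cfg$algorithm %in% names(model_registry())) {
    stop("unknown algorithm in run config: ", cfg$algorithm)
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML (`.yaml`/`.yml`) or JSON (`.json`) configuration file.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config format '.", ext, "' (use YAML or JSON)"))
  run_config(cfg)
}

.read_structure_dir <- function(dir) {
  if (!dir.exists(dir)) stop("structure directory not found: ", dir)
  files <- sort(list.files(dir, pattern = "\\.(xyz|sdf|mol)$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no XYZ/SDF structures in ", dir)
  mols <- lapply(files, function(f) {
    if (grepl("\\.xyz$", f)) read_xyz(f) else read_sdf(f)
  })
  mols <- unlist(lapply(mols, function(m) {
    if (inherits(m, "molecule3d")) list(m) else m
  }), recursive = FALSE)
  stats::setNames(mols, vapply(mols, `[[`, "", "id"))
}

#' Cross-validate pipeline inputs
#'
#' Checks that every measured arene has a structure, that measured symmetry
#' classes exist for that structure, that every aromatic C-H site carries a
#' QM descriptor row, and that every arene has a molecule-level redox entry.
#'
#' @param structures Named list of [molecule3d()] objects, or a directory of
#'   XYZ/SDF files.
#' @param qm Result of [load_qm_table()].
#' @param measurements Measurements tibble (`arene_id`, `symmetry_class`,
#'   `fraction`, `temperature_K`, optional `multiplicity`).
#' @return A tibble of violations (`type`, `arene_id`, `detail`); zero rows
#'   means the bundle is consistent.
#' @export
validate_inputs <- function(structures, qm, measurements) {
  if (is.character(structures)) structures <- .read_structure_dir(structures)
  v <- list()
  bad <- function(type, arene, detail) {
    v[[length(v) + 1L]] <<- tibble::tibble(type = type, arene_id = arene,
                                           detail = detail)
  }
  site_cache <- list()
  sites_of <- function(arene) {
    if (is.null(site_cache[[arene]])) {
      site_cache[[arene]] <<- suppressWarnings(
        enumerate_sites(structures[[arene]]))
    }
    site_cache[[arene]]
  }
  for (arene in unique(measurements$arene_id)) {
    if (!arene %in% names(structures)) {
      bad("missing_structure", arene, "no structure for measured arene")
      next
    }
    st <- sites_of(arene)
    meas_cls <- measurements$symmetry_class[measurements$arene_id == arene]
    unknown <- setdiff(meas_cls, st$symmetry_class)
    if (length(unknown) > 0) {
      bad("unknown_class", arene,
          paste("measured class(es) not among sites:",
                paste(unknown, collapse = ", ")))
    }
    qrows <- qm$sites[qm$sites$arene_id == arene, ]
    missing_atoms <- setdiff(st$atom_index, qrows$atom_index)
    if (length(missing_atoms) > 0) {
      bad("missing_qm_site", arene,
          paste("no QM descriptors for site atom(s):",
                paste(missing_atoms, collapse = ", ")))
    }
    if (!is.null(qm$molecules) &&
        !arene %in% qm$molecules$arene_id) {
      bad("missing_redox", arene, "no molecule-level redox potential")
    }
  }
  if (length(v) == 0) {
    tibble::tibble(type = character(), arene_id = character(),
                   detail = character())
  } else {
    dplyr::bind_rows(v)
  }
}

.assemble_site_table <- function(structures, qm, measurements, cfg,
                                 schema = descriptor_schema()) {
  bv_radii <- radii_set("bondi", cfg$bv_radius_scale)
  st_radii <- radii_set("bondi", cfg$sterimol_radius_scale)
  arenes <- intersect(unique(measurements$arene_id), names(structures))
  purrr::map_dfr(arenes, function(arene) {
    mol <- structures[[arene]]
    sites <- enumerate_sites(mol)
    steric <- site_steric_descriptors(
      mol, sites, sphere_radius = cfg$sphere_radius,
      grid_spacing = cfg$grid_spacing, bv_radii = bv_radii,
      sterimol_radii = st_radii, shell = cfg$shell,
      angle_resolution = cfg$angle_resolution)
    qrows <- qm$sites[qm$sites$arene_id == arene, ]
    elec <- qrows[match(steric$atom_index, qrows$atom_index), , drop = FALSE]
    out <- dplyr::bind_cols(
      tibble::tibble(arene_id = arene),
      steric,
      elec[, setdiff(names(elec), c("arene_id", "atom_index")), drop = FALSE])
    # absent extension slots are zero-filled to the schema width
    for (aux in setdiff(schema$per_site, names(out))) out[[aux]] <- 0
    out
  })
}

#' Run the full selectivity-prediction pipeline
#'
#' Featurize -> train/evaluate -> predict -> report: reads structures and
#' ingested QM tables, validates them, computes steric descriptors, builds
#' the pairwise encoding, converts measured isomer fractions to pairwise
#' free-energy targets, evaluates the configured algorithm by leave-one-out,
#' optionally evaluates held-out arenes out-of-sample, aggregates
#' leave-one-out pair predictions to per-site probabilities, and writes JSON
#' and CSV artifacts (stamped with the seed and config hash) to `out_dir`.
#' Re-running the same configuration reproduces identical artifacts.
#'
#' @param config A [run_config()] (or plain named list).
#' @return The report list, invisibly. Artifacts: `report.json`,
#'   `pair_predictions.csv`, `site_probabilities.json` under `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  structures <- .read_structure_dir(cfg$structures_dir)
  qm <- load_qm_table(cfg$qm_sites, cfg$qm_molecules)
  measurements <- readr::read_csv(cfg$measurements, show_col_types = FALSE)
  violations <- validate_inputs(structures, qm, measurements)
  if (nrow(violations) > 0) {
    stop("input validation failed with ", nrow(violations), " violation(s):\n",
         paste(utils::capture.output(print.data.frame(violations)),
               collapse = "\n"))
  }
  schema <- descriptor_schema()
  site_tbl <- .assemble_site_table(structures, qm, measurements, cfg, schema)
  # multiplicities come from site enumeration, not from the measurement file
  measurements <- measurements |>
    dplyr::select(-dplyr::any_of("multiplicity")) |>
    dplyr::left_join(
      dplyr::select(site_tbl, "arene_id", "symmetry_class", "multiplicity"),
      by = c("arene_id", "symmetry_class"))
  temp_tbl <- measurements |>
    dplyr::distinct(.data$arene_id, .data$temperature_K)
  pairs <- featurize_pairs(site_tbl, qm$molecules, temperature = temp_tbl,
                           schema = schema)
  targets <- measurements_to_targets(
    measurements, statistical_factors = cfg$statistical_factors)
  data <- dplyr::inner_join(pairs, targets,
                            by = c("arene_id", "site_a", "site_b"))
  if (nrow(data) == 0) stop("no measured competing-site pairs after joining")
  report <- loo_evaluate(data, cfg$algorithm, seed = cfg$seed,
                         mode = cfg$mode, augment = cfg$augment)
  oos <- NULL
  if (!is.null(cfg$holdout_arenes) && length(cfg$holdout_arenes) > 0) {
    oos <- oos_evaluate(data, cfg$holdout_arenes, cfg$algorithm,
                        seed = cfg$seed, augment = cfg$augment)
  }
  # aggregate held-out pair predictions to per-site probabilities
  pred_pairs <- dplyr::bind_cols(
    data[, c("arene_id", "site_a", "site_b")],
    ddg = report$predictions$predicted)
  site_probs <- pred_pairs |>
    dplyr::group_by(.data$arene_id) |>
    dplyr::group_map(function(g, key) {
      sc <- aggregate_site_scores(g)
      mult <- site_tbl$multiplicity[match(
        paste(key$arene_id, sc$site),
        paste(site_tbl$arene_id, site_tbl$symmetry_class))]
      tk <- temp_tbl$temperature_K[temp_tbl$arene_id == key$arene_id][1]
      p <- site_probabilities(stats::setNames(sc$score, sc$site),
                              multiplicities = mult, temperature = tk)
      dplyr::bind_cols(tibble::tibble(arene_id = key$arene_id), p)
    }) |>
    dplyr::bind_rows()

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  run_hash <- rlang::hash(list(cfg[sort(names(cfg))], schema))
  out_report <- list(
    seed = cfg$seed, algorithm = cfg$algorithm, mode = cfg$mode,
    config_hash = run_hash, n_pairs = report$n,
    encoding_width = schema_width(schema),
    pearson_r = report$pearson_r, mae = report$mae)
  if (!is.null(oos)) {
    out_report$oos <- list(holdout = cfg$holdout_arenes, n_pairs = oos$n,
                           pearson_r = oos$pearson_r, mae = oos$mae)
  }
  jsonlite::write_json(out_report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(tidy(report), file.path(cfg$out_dir,
                                           "pair_predictions.csv"))
  jsonlite::write_json(site_probs, file.path(cfg$out_dir,
                                             "site_probabilities.json"),
                       digits = NA, pretty = TRUE)
  invisible(c(out_report, list(report = report, oos = oos,
                               site_probabilities = site_probs)))
}

#' Write a structure-grounded synthetic input bundle
#'
#' Builds fixture arenes (named heteroarene templates plus randomly
#' substituted benzenes), samples their electronic site descriptors and redox
#' potentials, derives exact isomer fractions from a known electronic ground
#' truth, and writes the bundle in exactly the formats [run_pipeline()]
#' reads: an XYZ structure directory, per-site and per-molecule QM CSV tables
#' (0-based atom indices) and a measurements CSV.
#'
#' @param dir Output directory.
#' @param n_arenes Number of arenes (>= 2; the first few are the named
#'   fixture templates).
#' @param temperature Reaction temperature, K.
#' @param seed Integer seed fixing all sampling.
#' @return Invisibly, a list with the file paths and the ground-truth site
#'   table (`arene_id`, `symmetry_class`, `g_true`).
#' @export
write_synthetic_bundle <- function(dir, n_arenes = 6, temperature = 333.15,
                                   seed = 1) {
  set.seed(seed)
  templates <- c("anisole", "o-xylene", "naphthalene", "thiophene", "furan")
  mols <- list()
  k <- 0L
  while (length(mols) < n_arenes) {
    k <- k + 1L
    mol <- if (k <= length(templates)) {
      make_ring_fixture(templates[k])
    } else {
      pat <- rep("H", 6)
      npos <- sample(1:2, 1)
      pat[sample(6, npos)] <- sample(c("Me", "OMe", "F", "Cl", "OH", "CN"),
                                     npos, replace = TRUE)
      make_ring_fixture(pat, id = sprintf("sub_benzene_%02d", k))
    }
    sites <- suppressWarnings(enumerate_sites(mol))
    if (length(unique(sites$symmetry_class)) < 2) next
    mols[[mol$id]] <- mol
  }
  elec_w <- c(fukui_minus = 40, fukui_plus = 8, ch_bde = -0.08,
              partial_charge = -3)
  site_rows <- list()
  mol_rows <- list()
  truth <- list()
  meas <- list()
  for (id in names(mols)) {
    sites <- enumerate_sites(mols[[id]])
    cls <- site_classes(sites)
    elec <- tibble::tibble(
      fukui_plus = pmax(stats::rnorm(nrow(cls), 0.06, 0.02), 0),
      fukui_minus = pmax(stats::rnorm(nrow(cls), 0.08, 0.03), 0),
      fukui_zero = pmax(stats::rnorm(nrow(cls), 0.07, 0.02), 0),
      partial_charge = stats::rnorm(nrow(cls), -0.05, 0.05),
      ch_bde = stats::rnorm(nrow(cls), 112, 3))
    g_true <- drop(as.matrix(elec[, names(elec_w)]) %*% elec_w)
    # symmetry-equivalent atoms share the class descriptor values
    per_atom <- dplyr::left_join(
      sites,
      dplyr::bind_cols(cls[, "symmetry_class"], elec),
      by = "symmetry_class")
    site_rows[[id]] <- dplyr::bind_cols(
      tibble::tibble(arene_id = id, atom_index = per_atom$atom_index - 1L),
      per_atom[, names(elec)])
    mol_rows[[id]] <- tibble::tibble(
      arene_id = id, redox_potential = stats::rnorm(1, 1.8, 0.3))
    truth[[id]] <- tibble::tibble(arene_id = id,
                                  symmetry_class = cls$symmetry_class,
                                  multiplicity = cls$multiplicity,
                                  g_true = g_true)
    meas[[id]] <- simulate_measurements(truth[[id]],
                                        temperature = temperature)
  }
  dir.create(file.path(dir, "structures"), recursive = TRUE,
             showWarnings = FALSE)
  for (id in names(mols)) {
    write_xyz(mols[[id]], file.path(dir, "structures", paste0(id, ".xyz")))
  }
  paths <- list(structures_dir = file.path(dir, "structures"),
                qm_sites = file.path(dir, "qm_sites.csv"),
                qm_molecules = file.path(dir, "qm_molecules.csv"),
                measurements = file.path(dir, "measurements.csv"))
  readr::write_csv(dplyr::bind_rows(site_rows), paths$qm_sites)
  readr::write_csv(dplyr::bind_rows(mol_rows), paths$qm_molecules)
  readr::write_csv(dplyr::bind_rows(meas), paths$measurements)
  invisible(c(paths, list(truth = dplyr::bind_rows(truth))))
}
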