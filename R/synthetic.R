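# Deterministic idealized fixture geometries and the synthetic benchmark
# generator with a known ground-truth selectivity mechanism.

.SUBSTITUENTS <- c("H", "Me", "Et", "OMe", "OH", "F", "Cl", "CN")

# directions at `angle` degrees from +axis, rotated about it at angles `phis`
.cone_dirs <- function(axis, perp1, perp2, angle, phis) {
  a <- angle * pi / 180
  lapply(phis * pi / 180, function(phi) {
    cos(a) * axis + sin(a) * (cos(phi) * perp1 + sin(phi) * perp2)
  })
}

.unit <- function(v) v / sqrt(sum(v^2))

# append substituent atoms for a ring position; c_pos = ring carbon position,
# u = outward radial unit vector, p = in-plane tangential unit, z = (0,0,1)
.substituent_atoms <- function(token, c_pos, u, p, z = c(0, 0, 1)) {
  at <- function(el, pos) list(element = el, pos = pos)
  switch(token,
    H  = list(at("H", c_pos + 1.09 * u)),
    F  = list(at("F", c_pos + 1.35 * u)),
    Cl = list(at("Cl", c_pos + 1.74 * u)),
    CN = list(at("C", c_pos + 1.43 * u), at("N", c_pos + 2.59 * u)),
    OH = {
      o <- c_pos + 1.36 * u
      hdir <- cos(70.5 * pi / 180) * u + sin(70.5 * pi / 180) * p
      list(at("O", o), at("H", o + 0.96 * hdir))
    },
    Me = {
      cme <- c_pos + 1.50 * u
      dirs <- .cone_dirs(u, p, z, 70.53, c(0, 120, 240))
      c(list(at("C", cme)),
        lapply(dirs, function(d) at("H", cme + 1.09 * d)))
    },
    Et = {
      c1 <- c_pos + 1.50 * u
      d2 <- .cone_dirs(u, p, z, 70.53, 0)[[1]]
      c2 <- c1 + 1.53 * d2
      h1 <- .cone_dirs(u, p, z, 70.53, c(120, 240))
      w <- .unit(c2 - c1)
      e1 <- .unit(z - sum(z * w) * w)
      e2 <- c(w[2] * e1[3] - w[3] * e1[2], w[3] * e1[1] - w[1] * e1[3],
              w[1] * e1[2] - w[2] * e1[1])
      h2 <- .cone_dirs(w, e1, e2, 70.53, c(60, 180, 300))
      c(list(at("C", c1), at("C", c2)),
        lapply(h1, function(d) at("H", c1 + 1.09 * d)),
        lapply(h2, function(d) at("H", c2 + 1.09 * d)))
    },
    OMe = {
      o <- c_pos + 1.36 * u
      d <- cos(62.5 * pi / 180) * u + sin(62.5 * pi / 180) * p
      cme <- o + 1.43 * d
      w <- .unit(cme - o)
      e1 <- .unit(z - sum(z * w) * w)
      e2 <- c(w[2] * e1[3] - w[3] * e1[2], w[3] * e1[1] - w[1] * e1[3],
              w[1] * e1[2] - w[2] * e1[1])
      hd <- .cone_dirs(w, e1, e2, 70.53, c(0, 120, 240))
      c(list(at("O", o), at("C", cme)),
        lapply(hd, function(dd) at("H", cme + 1.09 * dd)))
    },
    stop("unknown substituent token '", token, "'; vocabulary: ",
         paste(.SUBSTITUENTS, collapse = ", "))
  )
}

.benzene_pattern <- function(pattern, id) {
  stopifnot(length(pattern) == 6)
  ang <- (seq_len(6) - 1) * pi / 3
  centers <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  atoms <- lapply(seq_len(6), function(k) {
    list(element = "C", pos = centers[k, ])
  })
  for (k in seq_len(6)) {
    u <- c(cos(ang[k]), sin(ang[k]), 0)
    p <- c(-sin(ang[k]), cos(ang[k]), 0)
    atoms <- c(atoms, .substituent_atoms(pattern[k], centers[k, ], u, p))
  }
  .atoms_to_mol(atoms, id)
}

.atoms_to_mol <- function(atoms, id) {
  molecule3d(tibble::tibble(
    element = vapply(atoms, `[[`, "", "element"),
    x = vapply(atoms, function(a) a$pos[1], numeric(1)),
    y = vapply(atoms, function(a) a$pos[2], numeric(1)),
    z = vapply(atoms, function(a) a$pos[3], numeric(1))
  ), id = id)
}

# turtle-walk planar 5-ring: bond lengths and interior angles in order,
# starting at the heteroatom
.penta_ring <- function(elements, lengths_, interior, id) {
  pos <- matrix(0, 5, 3)
  heading <- 0
  for (k in 2:5) {
    pos[k, ] <- pos[k - 1, ] +
      lengths_[k - 1] * c(cos(heading), sin(heading), 0)
    if (k < 5) heading <- heading + (180 - interior[k]) * pi / 180
  }
  ctr <- colMeans(pos)
  pos <- sweep(pos, 2, ctr)
  atoms <- lapply(seq_len(5), function(k) {
    list(element = elements[k], pos = pos[k, ])
  })
  # H on each carbon along the external angle bisector
  for (k in seq_len(5)) {
    if (elements[k] != "C") next
    prv <- if (k == 1) 5 else k - 1
    nxt <- if (k == 5) 1 else k + 1
    bis <- -.unit(.unit(pos[prv, ] - pos[k, ]) + .unit(pos[nxt, ] - pos[k, ]))
    atoms <- c(atoms, list(list(element = "H", pos = pos[k, ] + 1.08 * bis)))
  }
  .atoms_to_mol(atoms, id)
}

.naphthalene <- function(id) {
  ang <- (30 + 60 * (0:5)) * pi / 180
  ring1 <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  ring2 <- ring1
  ring2[, 1] <- 2 * 1.39 * cos(30 * pi / 180) - ring2[, 1]
  allc <- rbind(ring1, ring2)
  keep <- !duplicated(round(allc, 6))
  allc <- allc[keep, , drop = FALSE]
  centers <- rbind(c(0, 0, 0), c(2 * 1.39 * cos(30 * pi / 180), 0, 0))
  atoms <- lapply(seq_len(nrow(allc)), function(k) {
    list(element = "C", pos = allc[k, ])
  })
  # hydrogens on non-fusion carbons, pointing away from the nearer ring center
  fusion <- abs(allc[, 1] - 1.39 * cos(30 * pi / 180)) < 1e-6
  for (k in seq_len(nrow(allc))) {
    if (fusion[k]) next
    ctr <- centers[which.min(c(sum((allc[k, ] - centers[1, ])^2),
                               sum((allc[k, ] - centers[2, ])^2))), ]
    atoms <- c(atoms, list(list(element = "H",
                                pos = allc[k, ] + 1.09 * .unit(allc[k, ] - ctr))))
  }
  .atoms_to_mol(atoms, id)
}

#' Build an idealized ring fixture molecule
#'
#' Deterministic, idealized planar geometries (aromatic C-C 1.39 Angstrom,
#' C-H 1.09 Angstrom) for testing the geometric pipeline: either a named
#' template (`"benzene"`, `"anisole"`, `"o-xylene"`, `"naphthalene"`,
#' `"thiophene"`, `"furan"`) or a 6-vector substituent pattern over a benzene
#' ring drawn from the vocabulary H, Me, Et, OMe, OH, F, Cl, CN.
#'
#' @param pattern Template name, or character vector of length 6.
#' @param id Optional identifier (defaults to the template name or a
#'   pattern-derived label).
#' @return A [molecule3d()] with inferred bonds.
#' @examples
#' make_ring_fixture("anisole")
#' make_ring_fixture(c("Me", "Me", "H", "H", "H", "H"), id = "o-xylene")
#' @export
make_ring_fixture <- function(pattern = "benzene", id = NULL) {
  if (length(pattern) == 1L) {
    tpl <- pattern
    id <- id %||% tpl
    return(switch(tpl,
      benzene = .benzene_pattern(rep("H", 6), id),
      anisole = .benzene_pattern(c("OMe", rep("H", 5)), id),
      "o-xylene" = .benzene_pattern(c("Me", "Me", rep("H", 4)), id),
      naphthalene = .naphthalene(id),
      thiophene = .penta_ring(c("S", "C", "C", "C", "C"),
                              c(1.714, 1.370, 1.423, 1.370, 1.714),
                              c(92.2, 111.5, 112.5, 112.5, 111.5), id),
      furan = .penta_ring(c("O", "C", "C", "C", "C"),
                          c(1.362, 1.361, 1.431, 1.361, 1.362),
                          c(106.5, 110.7, 106.0, 106.0, 110.7), id),
      stop("unknown template '", tpl, "'")))
  }
  id <- id %||% paste0("ring_", paste(pattern, collapse = ""))
  .benzene_pattern(pattern, id)
}

#' Configuration of the synthetic selectivity benchmark
#'
#' Declares the study conditions of the synthetic benchmark: how many arenes
#' (or competing-site pairs), the per-site descriptor sampling distributions,
#' the ground-truth weight vector that maps descriptors to per-site free
#' energies, the Gaussian target noise, and the reaction temperature. Defaults
#' are loosely physical (e.g. percent buried volume ~ N(35, 8) truncated to
#' \[0, 100\]) with the reacting site's Fukui electrophilicity descriptor as
#' the dominant ground-truth driver, and noise of 0.25 kcal/mol on pair
#' targets at 333.15 K.
#'
#' @param n_arenes Number of synthetic arenes (each contributes all pairs of
#'   its 2-4 symmetry classes, about 3.3 pairs on average).
#' @param n_pairs Optional exact dataset size; arenes are generated until the
#'   pair count is reached and the list is truncated.
#' @param classes_per_arene Integer vector sampled from for the number of
#'   symmetry classes per arene.
#' @param weights Named ground-truth weights over per-site descriptors
#'   (kcal/mol per descriptor unit).
#' @param molecule_weights,temperature_weight Ground-truth weights on the
#'   molecule-level block and temperature. Both default to 0 so pair targets
#'   are exactly antisymmetric under site exchange; the features are still
#'   emitted (as distractors).
#' @param noise_sd Gaussian noise added to pair targets, kcal/mol.
#' @param temperature Reaction temperature, K.
#' @param nonlinear Add tree-friendly threshold terms to the ground truth.
#' @param seed Integer seed fixing all randomness.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_arenes = 45, n_pairs = NULL,
                             classes_per_arene = 2:4,
                             weights = default_truth_weights(),
                             molecule_weights = c(redox_potential = 0),
                             temperature_weight = 0,
                             noise_sd = 0.25, temperature = 333.15,
                             nonlinear = FALSE, seed = 1) {
  stopifnot(noise_sd >= 0, temperature > 0, all(is.finite(weights)))
  structure(list(n_arenes = n_arenes, n_pairs = n_pairs,
                 classes_per_arene = classes_per_arene, weights = weights,
                 molecule_weights = molecule_weights,
                 temperature_weight = temperature_weight,
                 noise_sd = noise_sd, temperature = temperature,
                 nonlinear = isTRUE(nonlinear), seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @return `default_truth_weights()`: the default named weight vector
#'   (dominated by `fukui_minus`, the reacting site's Fukui descriptor).
#' @export
default_truth_weights <- function() {
  c(fukui_minus = 40, fukui_plus = 8, pct_buried_volume = -0.04,
    ch_bde = -0.08, sterimol_B1 = -0.5, partial_charge = -3)
}

.DESCRIPTOR_DISTS <- tibble::tibble(
  name  = c("pct_buried_volume", "sterimol_L", "sterimol_B1", "sterimol_B5",
            "fukui_plus", "fukui_minus", "fukui_zero", "partial_charge",
            "ch_bde", "aux_1", "aux_2", "aux_3"),
  mean  = c(35, 4.0, 1.7, 3.0, 0.06, 0.08, 0.07, -0.05, 112, 0, 0, 0),
  sd    = c(8, 1.0, 0.3, 0.8, 0.02, 0.03, 0.02, 0.05, 3, 1, 1, 1),
  lower = c(0, 1.0, 0.3, 0.5, 0, 0, 0, -1, 90, -Inf, -Inf, -Inf),
  upper = c(100, Inf, Inf, Inf, 1, 1, 1, 1, 140, Inf, Inf, Inf)
)

.sample_site_descriptors <- function(n) {
  d <- .DESCRIPTOR_DISTS
  out <- purrr::map(seq_len(nrow(d)), function(k) {
    pmin(pmax(stats::rnorm(n, d$mean[k], d$sd[k]), d$lower[k]), d$upper[k])
  })
  names(out) <- d$name
  out <- tibble::as_tibble(out)
  # enforce B1 <= B5 and derive the dual descriptor
  b1 <- pmin(out$sterimol_B1, out$sterimol_B5)
  b5 <- pmax(out$sterimol_B1, out$sterimol_B5)
  out$sterimol_B1 <- b1
  out$sterimol_B5 <- b5
  out$dual_descriptor <- out$fukui_plus - out$fukui_minus
  out
}

.true_site_energy <- function(desc, config) {
  w <- config$weights
  g <- rep(0, nrow(desc))
  for (nm in names(w)) {
    if (!nm %in% names(desc)) stop("truth weight on unknown descriptor: ", nm)
    g <- g + w[[nm]] * desc[[nm]]
  }
  if (config$nonlinear) {
    g <- 0.25 * g +
      1.2 * (desc$fukui_minus > 0.08) -
      0.8 * (desc$pct_buried_volume > 35) +
      0.6 * (desc$fukui_minus > 0.10 & desc$partial_charge < -0.05)
  }
  g
}

#' Generate a synthetic competing-site benchmark dataset
#'
#' Samples per-site descriptors from the declared distributions, computes the
#' true per-site free energy `g = w' d` (plus optional threshold terms),
#' forms all canonical class pairs per arene with target
#' `g_A - g_B + molecule terms + N(0, noise_sd)`, and returns the generating
#' truth alongside the dataset for recovery tests. With the default zero
#' molecule/temperature weights, swapped pairs have exactly negated targets
#' at zero noise.
#'
#' @param config A [synthetic_config()].
#' @return A list: `data` (pair-dataset tibble, 28 feature columns under the
#'   default schema), `sites` (per-class descriptors with `g_true`),
#'   `molecules` (redox potentials), `weights`, `config`.
#' @export
generate_synthetic_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  target_pairs <- config$n_pairs
  n_arenes <- if (is.null(target_pairs)) config$n_arenes else
    ceiling(target_pairs) + 5L  # upper bound; trimmed below
  n_cls <- sample(config$classes_per_arene, n_arenes, replace = TRUE)
  if (!is.null(target_pairs)) {
    cum <- cumsum(choose(n_cls, 2))
    n_arenes <- which(cum >= target_pairs)[1]
    if (is.na(n_arenes)) n_arenes <- length(n_cls)
    n_cls <- n_cls[seq_len(n_arenes)]
  }
  arene_ids <- sprintf("arene_%03d", seq_len(n_arenes))
  sites <- tibble::tibble(
    arene_id = rep(arene_ids, n_cls),
    symmetry_class = unlist(lapply(n_cls, function(k) letters[seq_len(k)])),
    multiplicity = sample(c(1L, 2L), sum(n_cls), replace = TRUE,
                          prob = c(0.4, 0.6))
  )
  desc <- .sample_site_descriptors(nrow(sites))
  sites <- dplyr::bind_cols(sites, desc)
  sites$g_true <- .true_site_energy(desc, config)
  molecules <- tibble::tibble(
    arene_id = arene_ids,
    redox_potential = stats::rnorm(n_arenes, 1.8, 0.3))
  data <- featurize_pairs(sites, molecules, temperature = config$temperature)
  g <- stats::setNames(sites$g_true,
                       paste(sites$arene_id, sites$symmetry_class))
  truth <- g[paste(data$arene_id, data$site_a)] -
    g[paste(data$arene_id, data$site_b)]
  mw <- config$molecule_weights
  for (nm in names(mw)) {
    if (mw[[nm]] != 0) {
      truth <- truth + mw[[nm]] * data[[paste0("mol_", nm)]]
    }
  }
  if (config$temperature_weight != 0) {
    truth <- truth + config$temperature_weight * data$temperature_K
  }
  data$target <- unname(truth) +
    stats::rnorm(nrow(data), 0, config$noise_sd)
  if (!is.null(target_pairs)) {
    data <- data[seq_len(min(target_pairs, nrow(data))), , drop = FALSE]
  }
  list(data = data, sites = sites, molecules = molecules,
       weights = config$weights, config = config)
}

#' Simulate selectivity measurements from ground-truth site energies
#'
#' Converts true per-site free energies to isomer fractions through the
#' Boltzmann site probabilities (statistical factors included), optionally
#' adding multinomial counting noise. At zero noise the measurements
#' round-trip through [measurements_to_targets()] to the exact pairwise
#' energy differences.
#'
#' @param sites Tibble with `arene_id`, `symmetry_class`, `multiplicity`,
#'   `g_true` (e.g. from [generate_synthetic_dataset()]).
#' @param temperature Temperature in Kelvin.
#' @param counts Optional number of simulated product counts per arene;
#'   `NULL` (default) gives exact fractions.
#' @param seed Seed for the multinomial noise (only used when `counts` is
#'   given).
#' @return A measurements tibble: `arene_id`, `symmetry_class`, `fraction`,
#'   `multiplicity`, `temperature_K`.
#' @export
simulate_measurements <- function(sites, temperature = 333.15, counts = NULL,
                                  seed = 1) {
  stopifnot(all(c("arene_id", "symmetry_class", "multiplicity", "g_true")
                %in% names(sites)))
  if (!is.null(counts)) set.seed(seed)
  sites |>
    dplyr::group_by(.data$arene_id) |>
    dplyr::group_map(function(g, key) {
      p <- site_probabilities(
        stats::setNames(g$g_true, g$symmetry_class),
        multiplicities = g$multiplicity, temperature = temperature)
      frac <- p$probability
      if (!is.null(counts)) {
        frac <- as.numeric(stats::rmultinom(1, counts, frac)) / counts
      }
      tibble::tibble(arene_id = key$arene_id, symmetry_class = g$symmetry_class,
                     fraction = frac, multiplicity = g$multiplicity,
                     temperature_K = temperature)
    }) |>
    dplyr::bind_rows()
}
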