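#' Weisfeiler-Lehman atom equivalence classes
#'
#' Partitions atoms by iterative neighborhood refinement on the bond graph:
#' atoms start colored by element, and each round re-colors every atom by its
#' own color plus the sorted multiset of neighbor colors, until the partition
#' stabilizes. Topology-only (no 3D information), so conformational noise
#' cannot split classes.
#'
#' @param mol A [molecule3d()] with bonds.
#' @return Integer vector of class ids (1-based, arbitrary but deterministic).
#' @export
wl_atom_classes <- function(mol) {
  stopifnot(inherits(mol, "molecule3d"))
  n <- n_atoms(mol)
  adj <- neighbors(mol)
  colors <- match(mol$atoms$element, sort(unique(mol$atoms$element)))
  for (iter in seq_len(n)) {
    keys <- vapply(seq_len(n), function(i) {
      paste(colors[i], paste(sort(colors[adj[[i]]]), collapse = ","), sep = "|")
    }, character(1))
    new_colors <- match(keys, sort(unique(keys)))
    if (identical(split(seq_len(n), new_colors), split(seq_len(n), colors))) break
    colors <- new_colors
  }
  colors
}

# all simple cycles of length min_size..max_size; each returned once, sorted
.find_rings <- function(adj, min_size = 5L, max_size = 6L) {
  found <- list()
  n <- length(adj)
  for (start in seq_len(n)) {
    # DFS over paths whose interior vertices all exceed `start`
    stack <- list(c(start))
    while (length(stack) > 0) {
      path <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      last <- path[length(path)]
      for (nb in adj[[last]]) {
        if (nb == start && length(path) >= min_size) {
          found[[length(found) + 1L]] <- sort(path)
        } else if (nb > start && !(nb %in% path) &&
                   length(path) < max_size) {
          stack[[length(stack) + 1L]] <- c(path, nb)
        }
      }
    }
  }
  unique(found)
}

.aromatic_rings <- function(mol) {
  if (nrow(mol$bonds) == 0L) return(list())
  cyc <- .find_rings(neighbors(mol), 5L, 6L)
  deg <- lengths(neighbors(mol))
  el <- mol$atoms$element
  keep <- list()
  for (ring in cyc) {
    if (!all(el[ring] %in% c("C", "N", "O", "S"))) next
    carbons <- ring[el[ring] == "C"]
    if (length(carbons) == 0L) next
    if (any(deg[carbons] > 3L)) next   # sp3-like carbon disqualifies the ring
    keep[[length(keep) + 1L]] <- sort(ring)
  }
  unique(keep)
}

#' Enumerate symmetry-distinct aromatic C-H sites
#'
#' Every aromatic carbon bearing a hydrogen is a candidate site. Aromaticity
#' is approximated by ring perception on the (inferred) bond graph: 5- and
#' 6-membered rings of C/N/O/S atoms whose carbons are all sp2-like (graph
#' degree at most 3). Sites are grouped into symmetry classes by
#' Weisfeiler-Lehman canonical ranking ([wl_atom_classes()]); the class
#' multiplicity is the statistical factor used to correct observed isomer
#' fractions. Classes are labelled `"a"`, `"b"`, ... in order of their lowest
#' atom index, so the output is deterministic.
#'
#' @param mol A [molecule3d()] with bonds.
#' @return A tibble with one row per site: `atom_index` (the carbon),
#'   `h_index` (its hydrogen), `symmetry_class` (label) and `multiplicity`
#'   (class size). Zero rows, with a warning, when the molecule has no
#'   aromatic C-H.
#' @examples
#' enumerate_sites(make_ring_fixture("benzene"))    # one class, multiplicity 6
#' enumerate_sites(make_ring_fixture("anisole"))    # classes 2 + 2 + 1
#' @export
enumerate_sites <- function(mol) {
  stopifnot(inherits(mol, "molecule3d"))
  rings <- .aromatic_rings(mol)
  el <- mol$atoms$element
  adj <- neighbors(mol)
  arom_c <- intersect(unique(unlist(rings)), which(el == "C"))
  site_c <- arom_c[vapply(arom_c, function(i) any(el[adj[[i]]] == "H"),
                          logical(1))]
  if (length(site_c) == 0L) {
    warning("molecule '", mol$id, "' has no aromatic C-H site")
    return(tibble::tibble(atom_index = integer(), h_index = integer(),
                          symmetry_class = character(),
                          multiplicity = integer()))
  }
  cls <- wl_atom_classes(mol)[site_c]
  # label classes a, b, c, ... by lowest member atom index
  lowest <- vapply(unique(cls), function(cc) min(site_c[cls == cc]), integer(1))
  labels_by_class <- letters[rank(lowest)]
  names(labels_by_class) <- as.character(unique(cls))
  lab <- labels_by_class[as.character(cls)]
  out <- tibble::tibble(atom_index = as.integer(site_c),
                        h_index = vapply(site_c, function(i) {
                          as.integer(adj[[i]][el[adj[[i]]] == "H"][1L])
                        }, integer(1)),
                        symmetry_class = unname(lab))
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$symmetry_class),
    multiplicity = dplyr::n()
  )
  dplyr::arrange(dplyr::ungroup(out), .data$symmetry_class, .data$atom_index)
}

#' Per-class site summary
#'
#' Collapses [enumerate_sites()] output to one row per symmetry class,
#' keeping the representative (lowest-index) site atom.
#'
#' @param sites Output of [enumerate_sites()].
#' @return A tibble: `symmetry_class`, `atom_index` (representative),
#'   `multiplicity`.
#' @export
site_classes <- function(sites) {
  sites |>
    dplyr::group_by(.data$symmetry_class) |>
    dplyr::summarise(atom_index = min(.data$atom_index),
                     multiplicity = dplyr::first(.data$multiplicity),
                     .groups = "drop") |>
    dplyr::arrange(.data$symmetry_class)
}

#' Steric descriptors for each symmetry-distinct site
#'
#' Computes percent buried volume at the representative carbon of each
#' symmetry class and Sterimol L/B1/B5 along the C->H axis ([site_sterimol()]).
#'
#' @param mol A [molecule3d()].
#' @param sites Optional [enumerate_sites()] output (recomputed when `NULL`).
#' @param sphere_radius,grid_spacing Buried-volume settings.
#' @param bv_radii Radii set for buried volume (Bondi x 1.17 by default).
#' @param sterimol_radii Radii set for Sterimol (unscaled Bondi by default).
#' @param shell Neighbor shell for the Sterimol substituent.
#' @param angle_resolution B1 scan resolution in degrees.
#' @return One row per symmetry class: `symmetry_class`, `atom_index`,
#'   `multiplicity`, `pct_buried_volume`, `sterimol_L`, `sterimol_B1`,
#'   `sterimol_B5`.
#' @export
site_steric_descriptors <- function(mol, sites = NULL,
                                    sphere_radius = 3.5, grid_spacing = 0.05,
                                    bv_radii = radii_set("bondi", 1.17),
                                    sterimol_radii = radii_set("bondi", 1.0),
                                    shell = 2, angle_resolution = 0.1) {
  if (is.null(sites)) sites <- enumerate_sites(mol)
  cls <- site_classes(sites)
  steric <- purrr::map_dfr(cls$atom_index, function(i) {
    bv <- compute_buried_volume(mol, i, sphere_radius = sphere_radius,
                                radii = bv_radii, grid_spacing = grid_spacing)
    st <- site_sterimol(mol, i, shell = shell, radii = sterimol_radii,
                        angle_resolution = angle_resolution)
    dplyr::bind_cols(tibble::tibble(pct_buried_volume = bv), st)
  })
  dplyr::bind_cols(cls, steric)
}
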