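#' Percent buried volume of a site
#'
#' Fraction (as a percentage) of a probe sphere centered on `center_atom`
#' that is occupied by the scaled van der Waals spheres of the surrounding
#' atoms. Computed by regular-grid point counting: a cubic grid of pitch
#' `grid_spacing` is laid over the probe sphere and each in-sphere grid point
#' is tested against every occupying atom. Deterministic for a fixed grid.
#'
#' Defaults follow the common buried-volume convention: 3.5 Angstrom probe
#' sphere, Bondi radii scaled by 1.17, hydrogens included, and the center
#' atom itself excluded from the occupancy.
#'
#' @param mol A [molecule3d()].
#' @param center_atom 1-based index of the probe-sphere center atom.
#' @param sphere_radius Probe sphere radius in Angstrom.
#' @param radii A [radii_set()]; default Bondi scaled by 1.17.
#' @param grid_spacing Grid pitch in Angstrom; must lie in
#'   `(0, sphere_radius / 5]`.
#' @param exclude_atoms Indices excluded from the occupancy (default: the
#'   center atom itself).
#' @param include_hydrogens Count hydrogen atoms as occupying (default TRUE).
#' @return Percent buried volume, a scalar in `[0, 100]`.
#' @examples
#' m <- make_ring_fixture("benzene")
#' compute_buried_volume(m, center_atom = 1)
#' @export
compute_buried_volume <- function(mol, center_atom,
                                  sphere_radius = 3.5,
                                  radii = radii_set("bondi", scale = 1.17),
                                  grid_spacing = 0.05,
                                  exclude_atoms = center_atom,
                                  include_hydrogens = TRUE) {
  stopifnot(inherits(mol, "molecule3d"), inherits(radii, "radii_set"))
  n <- n_atoms(mol)
  center_atom <- as.integer(center_atom)
  if (length(center_atom) != 1L || is.na(center_atom) ||
      center_atom < 1L || center_atom > n) {
    stop("center_atom index out of range")
  }
  stopifnot(sphere_radius > 0,
            grid_spacing > 0, grid_spacing <= sphere_radius / 5)
  xyz <- coords(mol)
  ctr <- xyz[center_atom, ]
  keep <- setdiff(seq_len(n), as.integer(exclude_atoms))
  if (!include_hydrogens) keep <- keep[mol$atoms$element[keep] != "H"]
  if (length(keep) == 0L) {
    warning("no occupying atoms besides the excluded set; buried volume is 0")
    return(0)
  }
  r_at <- vdw_radius(radii, mol$atoms$element[keep])
  pos <- sweep(xyz[keep, , drop = FALSE], 2, ctr)
  # cull atoms whose sphere cannot intersect the probe sphere
  d_ctr <- sqrt(rowSums(pos^2))
  near <- d_ctr <= sphere_radius + r_at
  pos <- pos[near, , drop = FALSE]
  r_at <- r_at[near]
  if (nrow(pos) == 0L) return(0)

  g <- seq(-sphere_radius, sphere_radius, by = grid_spacing)
  ng <- length(g)
  gx <- rep(g, times = ng * ng)
  gy <- rep(rep(g, each = ng), times = ng)
  gz <- rep(g, each = ng * ng)
  inside <- (gx * gx + gy * gy + gz * gz) <= sphere_radius^2
  gx <- gx[inside]; gy <- gy[inside]; gz <- gz[inside]
  total <- length(gx)
  occupied <- logical(total)
  for (k in seq_len(nrow(pos))) {
    free <- which(!occupied)
    if (length(free) == 0L) break
    dx <- gx[free] - pos[k, 1]
    dy <- gy[free] - pos[k, 2]
    dz <- gz[free] - pos[k, 3]
    occupied[free[dx * dx + dy * dy + dz * dz <= r_at[k]^2]] <- TRUE
  }
  100 * sum(occupied) / total
}

#' Sterimol steric parameters L, B1 and B5
#'
#' Verloop steric parameters of a substituent measured along the
#' `base_atom -> attached_atom` axis: `L` is the substituent length along the
#' axis measured from the base atom (maximal axial projection plus van der
#' Waals radius); `B5` the maximal perpendicular half-width; `B1` the minimal
#' perpendicular half-width, found by scanning in-plane directions at
#' `angle_resolution` degrees, 0.1 by default (for each direction the width is the maximum
#' over atoms of the signed projection plus radius).
#'
#' @param mol A [molecule3d()].
#' @param base_atom 1-based index of the attachment-point atom (axis origin).
#' @param attached_atom 1-based index of the first substituent atom defining
#'   the axis; must be bonded to, or within 2.0 Angstrom of, `base_atom`.
#' @param substituent_atoms Indices of the substituent atoms (must contain
#'   `attached_atom`; must not contain `base_atom`).
#' @param radii A [radii_set()]; classic Verloop values use unscaled Bondi.
#' @param angle_resolution Scan resolution for B1, in degrees.
#' @return A one-row tibble with columns `sterimol_L`, `sterimol_B1`,
#'   `sterimol_B5` (Angstrom).
#' @examples
#' m <- make_ring_fixture("benzene")
#' h <- neighbors(m)[[1]][m$atoms$element[neighbors(m)[[1]]] == "H"]
#' compute_sterimol(m, base_atom = 1, attached_atom = h, substituent_atoms = h)
#' @export
compute_sterimol <- function(mol, base_atom, attached_atom, substituent_atoms,
                             radii = radii_set("bondi", scale = 1.0),
                             angle_resolution = 0.1) {
  stopifnot(inherits(mol, "molecule3d"), inherits(radii, "radii_set"),
            angle_resolution > 0)
  n <- n_atoms(mol)
  idx <- c(base_atom, attached_atom, substituent_atoms)
  if (any(idx < 1L | idx > n)) stop("atom index out of range")
  if (length(substituent_atoms) == 0L) stop("substituent_atoms must be nonempty")
  if (!(attached_atom %in% substituent_atoms)) {
    stop("substituent_atoms must contain attached_atom")
  }
  if (base_atom %in% substituent_atoms) {
    stop("substituent_atoms must not contain base_atom")
  }
  xyz <- coords(mol)
  v <- xyz[attached_atom, ] - xyz[base_atom, ]
  len <- sqrt(sum(v^2))
  if (len < 1e-6) stop("degenerate axis: base and attached atoms coincide")
  bonded <- any((mol$bonds$i == base_atom & mol$bonds$j == attached_atom) |
                (mol$bonds$j == base_atom & mol$bonds$i == attached_atom))
  if (!bonded && len > 2.0) {
    stop("base and attached atoms are neither bonded nor within 2.0 Angstrom")
  }
  u <- v / len
  # deterministic orthonormal in-plane basis
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])

  sub <- as.integer(unique(substituent_atoms))
  r_at <- vdw_radius(radii, mol$atoms$element[sub])
  d <- sweep(xyz[sub, , drop = FALSE], 2, xyz[base_atom, ])
  axial <- drop(d %*% u)
  L <- max(axial + r_at)
  p1 <- drop(d %*% e1)
  p2 <- drop(d %*% e2)
  B5 <- max(sqrt(p1^2 + p2^2) + r_at)
  theta <- seq(0, 360 - angle_resolution, by = angle_resolution) * pi / 180
  W <- outer(cos(theta), p1) + outer(sin(theta), p2)
  W <- sweep(W, 2, r_at, "+")
  B1 <- min(apply(W, 1, max))
  tibble::tibble(sterimol_L = L, sterimol_B1 = B1, sterimol_B5 = B5)
}

#' Atoms within a graph radius of a start atom
#'
#' Breadth-first shell on the bond graph; the start atom itself is excluded.
#'
#' @param mol A [molecule3d()].
#' @param start 1-based start atom index.
#' @param depth Maximum graph distance (number of bonds).
#' @return Sorted integer vector of atom indices.
#' @export
graph_shell <- function(mol, start, depth) {
  adj <- neighbors(mol)
  seen <- as.integer(start)
  frontier <- as.integer(start)
  for (d in seq_len(depth)) {
    frontier <- setdiff(unique(unlist(adj[frontier])), seen)
    if (length(frontier) == 0L) break
    seen <- c(seen, frontier)
  }
  sort(setdiff(seen, as.integer(start)))
}

#' Sterimol parameters of an aromatic C-H site
#'
#' Convenience wrapper for ring C-H sites: the axis runs from the site carbon
#' to its hydrogen, and the substituent is the hydrogen plus every atom within
#' `shell` bonds of the site carbon (excluding the carbon itself). `shell = 0`
#' measures the bare hydrogen; the default of 2 captures the flanking ring
#' environment that differentiates ortho-, meta- and para-like sites.
#'
#' @param mol A [molecule3d()].
#' @param site_carbon 1-based index of the aromatic carbon.
#' @param shell Graph radius (bonds) of neighbors included in the substituent.
#' @inheritParams compute_sterimol
#' @return A one-row tibble (`sterimol_L`, `sterimol_B1`, `sterimol_B5`).
#' @export
site_sterimol <- function(mol, site_carbon, shell = 2,
                          radii = radii_set("bondi", scale = 1.0),
                          angle_resolution = 0.1) {
  adj <- neighbors(mol)[[site_carbon]]
  hs <- adj[mol$atoms$element[adj] == "H"]
  if (length(hs) == 0L) stop("atom ", site_carbon, " bears no hydrogen")
  h <- hs[1L]
  sub <- unique(c(h, graph_shell(mol, site_carbon, shell)))
  sub <- setdiff(sub, site_carbon)
  compute_sterimol(mol, base_atom = site_carbon, attached_atom = h,
                   substituent_atoms = sub, radii = radii,
                   angle_resolution = angle_resolution)
}
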