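# Independent oracles used to pin the package's numerical routines.
# These deliberately re-derive each quantity by a different method than the
# implementation (Monte-Carlo integration, fine brute-force scans, graph
# automorphisms) and must stay independent of the code under test.

# Monte-Carlo buried volume: uniform points in the probe sphere.
mc_buried_volume <- function(mol, center, sphere_radius = 3.5,
                             radii = radii_set("bondi", 1.17),
                             n = 1e6, exclude = center, seed = 1) {
  set.seed(seed)
  xyz <- coords(mol)
  ctr <- xyz[center, ]
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- sphere_radius * stats::runif(n)^(1 / 3)
  pts <- sweep(u * r, 2, ctr, "+")
  keep <- setdiff(seq_len(n_atoms(mol)), exclude)
  rads <- vdw_radius(radii, mol$atoms$element[keep])
  occ <- rep(FALSE, n)
  for (k in seq_along(keep)) {
    i <- keep[k]
    occ <- occ | ((pts[, 1] - xyz[i, 1])^2 + (pts[, 2] - xyz[i, 2])^2 +
                    (pts[, 3] - xyz[i, 3])^2 <= rads[k]^2)
  }
  100 * mean(occ)
}

# Brute-force Sterimol with a fine angle scan and an independently chosen
# perpendicular basis (seeded random Gram-Schmidt).
scan_sterimol <- function(mol, base, attached, sub,
                          radii = radii_set("bondi", 1.0),
                          step_deg = 0.1, seed = 7) {
  xyz <- coords(mol)
  u <- xyz[attached, ] - xyz[base, ]
  u <- u / sqrt(sum(u^2))
  set.seed(seed)
  repeat {
    v <- stats::rnorm(3)
    v <- v - sum(v * u) * u
    if (sqrt(sum(v^2)) > 0.1) break
  }
  e1 <- v / sqrt(sum(v^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  sub <- unique(as.integer(sub))
  rads <- vdw_radius(radii, mol$atoms$element[sub])
  d <- sweep(xyz[sub, , drop = FALSE], 2, xyz[base, ])
  ax <- drop(d %*% u)
  p1 <- drop(d %*% e1)
  p2 <- drop(d %*% e2)
  th <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  widths <- vapply(th, function(t) max(p1 * cos(t) + p2 * sin(t) + rads),
                   numeric(1))
  list(L = max(ax + rads), B1 = min(widths),
       B5 = max(sqrt(p1^2 + p2^2) + rads))
}

# Element-colored graph-automorphism orbits via igraph (BLISS), reduced to
# orbit ids with a union-find closure over the group generators.
automorphism_orbits <- function(mol) {
  n <- n_atoms(mol)
  g <- igraph::graph_from_data_frame(
    mol$bonds, directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(n))))
  colors <- as.integer(factor(mol$atoms$element))
  gens <- igraph::automorphism_group(g, colors = colors)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (gen in gens) {
    perm <- as.integer(gen)
    for (v in seq_len(n)) {
      rv <- find(v); rp <- find(perm[v])
      if (rv != rp) parent[rv] <- rp
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Tiny fixtures used across tests.
methane_fixture <- function() {
  d <- 1.09 / sqrt(3)
  molecule3d(data.frame(
    element = c("C", "H", "H", "H", "H"),
    x = c(0, d, -d, d, -d), y = c(0, d, -d, -d, d),
    z = c(0, d, d, -d, -d)), id = "methane")
}

water_fixture <- function() {
  # equilibrium geometry: O-H 0.96 A, H-O-H 104.5 deg
  a <- 104.5 / 2 * pi / 180
  molecule3d(data.frame(
    element = c("O", "H", "H"),
    x = c(0, 0.96 * sin(a), -0.96 * sin(a)),
    y = c(0, 0.96 * cos(a), 0.96 * cos(a)), z = 0), id = "water")
}

# Deterministic rigid rotation + translation.
rigid_transform <- function(mol, seed = 1) {
  set.seed(seed)
  th <- stats::runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0),
              c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
  xyz <- coords(mol) %*% (Rx %*% Rz) + matrix(stats::rnorm(3, 0, 2),
                                              n_atoms(mol), 3, byrow = TRUE)
  molecule3d(tibble::tibble(element = mol$atoms$element,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
             id = mol$id)
}

# Random atom-order permutation with bonds remapped.
permute_atoms <- function(mol, seed = 1) {
  set.seed(seed)
  n <- n_atoms(mol)
  perm <- sample(n)                 # new position of old atom i is match(i, perm)
  inv <- order(perm)
  molecule3d(mol$atoms[perm, ],
             bonds = tibble::tibble(i = inv[mol$bonds$i], j = inv[mol$bonds$j]),
             id = mol$id)
}
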