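test_that("XYZ write/read round-trips coordinates and identifier", {
  m <- make_ring_fixture("anisole")
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(m, path)
  m2 <- read_xyz(path)
  expect_s3_class(m2, "molecule3d")
  expect_identical(m2$id, "anisole")
  expect_equal(coords(m2), coords(m), tolerance = 1e-7)
  expect_identical(m2$atoms$element, m$atoms$element)
})

test_that("SDF V2000 records parse atoms and bonds", {
  sdf <- c(
    "water", "  test", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 O   0  0",
    "    0.7586    0.5927    0.0000 H   0  0",
    "   -0.7586    0.5927    0.0000 H   0  0",
    "  1  2  1  0", "  1  3  1  0", "M  END", "$$$$")
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(sdf, path)
  m <- read_sdf(path)
  expect_identical(m$id, "water")
  expect_identical(m$atoms$element, c("O", "H", "H"))
  expect_equal(nrow(m$bonds), 2)
})

test_that("molecule construction enforces geometric and element invariants", {
  expect_error(molecule3d(data.frame(element = "Xx", x = 0, y = 0, z = 0)),
               "unknown element")
  expect_error(
    molecule3d(data.frame(element = c("C", "C"), x = c(0, 0.2), y = 0, z = 0)),
    "closer than 0.5")
  expect_error(
    molecule3d(data.frame(element = c("C", "C"), x = c(0, 2), y = 0, z = 0),
               bonds = data.frame(i = 1, j = 5)),
    "out of range")
})

test_that("bond inference follows covalent-radius cutoffs", {
  far <- molecule3d(data.frame(element = c("H", "H"), x = c(0, 10), y = 0,
                               z = 0))
  expect_equal(nrow(far$bonds), 0)

  benzene <- make_ring_fixture("benzene")
  el <- benzene$atoms$element
  kinds <- paste0(el[benzene$bonds$i], el[benzene$bonds$j])
  expect_equal(sum(kinds == "CC"), 6)
  expect_equal(sum(kinds %in% c("CH", "HC")), 6)

  expect_equal(nrow(water_fixture()$bonds), 2)
  expect_error(infer_bonds(benzene, tolerance = 0.9), "tolerance")
})

test_that("buried volume handles empty and saturated occupancy", {
  lone <- molecule3d(data.frame(element = "C", x = 0, y = 0, z = 0))
  expect_warning(bv <- compute_buried_volume(lone, 1, grid_spacing = 0.25,
                                             sphere_radius = 2),
                 "no occupying atoms")
  expect_equal(bv, 0)

  # a large S sphere 0.6 A away fully covers a 1.4 A probe sphere
  full <- molecule3d(data.frame(element = c("C", "S"), x = c(0, 0.6),
                                y = 0, z = 0))
  bv <- compute_buried_volume(full, 1, sphere_radius = 1.4,
                              grid_spacing = 0.25)
  expect_equal(bv, 100, tolerance = 0.5)

  expect_error(compute_buried_volume(full, 7), "out of range")
  expect_error(compute_buried_volume(full, 1, grid_spacing = 2),
               "grid_spacing")
})

test_that("grid buried volume matches the Monte-Carlo oracle", {
  mol <- molecule3d(data.frame(element = c("C", "C"), x = c(0, 2), y = 0,
                               z = 0), id = "single-neighbor")
  grid <- compute_buried_volume(mol, 1, sphere_radius = 3.5,
                                grid_spacing = 0.05)
  mc <- mc_buried_volume(mol, 1, sphere_radius = 3.5, n = 1e6)
  expect_lt(abs(grid - mc), 0.5)
})

test_that("buried volume is monotone in occupancy and sphere radius", {
  one <- molecule3d(data.frame(element = c("C", "C"), x = c(0, 1.8), y = 0,
                               z = 0))
  two <- molecule3d(data.frame(element = c("C", "C", "N"),
                               x = c(0, 1.8, -1.8), y = 0, z = 0))
  bv1 <- compute_buried_volume(one, 1, grid_spacing = 0.1)
  bv2 <- compute_buried_volume(two, 1, grid_spacing = 0.1)
  expect_gte(bv2, bv1)
  expect_gte(bv1, 0)
  expect_lte(bv2, 100)
  # with a single close atom, growing the probe sphere dilutes the occupancy
  wide <- compute_buried_volume(one, 1, sphere_radius = 5, grid_spacing = 0.1)
  expect_lte(wide, bv1)
})

test_that("Sterimol closed form holds for a lone hydrogen substituent", {
  m <- make_ring_fixture("benzene")
  h <- enumerate_sites(m)$h_index[1]
  st <- compute_sterimol(m, 1, h, h)
  expect_equal(st$sterimol_L, 1.09 + 1.20, tolerance = 1e-9)
  expect_equal(st$sterimol_B1, 1.20, tolerance = 1e-9)
  expect_equal(st$sterimol_B5, 1.20, tolerance = 1e-9)
})

test_that("axially symmetric substituents give B1 equal to B5", {
  # nitrile carbon and nitrogen collinear with the attachment axis
  m <- make_ring_fixture(c("CN", rep("H", 5)))
  cn_c <- 7L   # substituents are appended right after the six ring carbons
  cn_n <- 8L
  expect_identical(m$atoms$element[c(cn_c, cn_n)], c("C", "N"))
  st <- compute_sterimol(m, 1, cn_c, c(cn_c, cn_n))
  expect_equal(st$sterimol_B1, st$sterimol_B5, tolerance = 1e-9)
})

test_that("Sterimol agrees with the fine brute-force angle scan for methyl", {
  m <- make_ring_fixture(c("Me", rep("H", 5)))
  me_c <- 7L   # first appended substituent atom after the six ring carbons
  sub <- c(me_c, neighbors(m)[[me_c]][m$atoms$element[neighbors(m)[[me_c]]] == "H"])
  st <- compute_sterimol(m, 1, me_c, sub, angle_resolution = 0.5)
  oracle <- scan_sterimol(m, 1, me_c, sub, step_deg = 0.1)
  expect_equal(st$sterimol_L, oracle$L, tolerance = 1e-9)
  expect_lt(abs(st$sterimol_B5 - oracle$B5), 1e-9)
  expect_lt(abs(st$sterimol_B1 - oracle$B1), 0.01)
})

test_that("steric descriptors are invariant under rigid motion and atom order", {
  m <- make_ring_fixture("anisole")
  mt <- rigid_transform(m, seed = 3)
  bv <- compute_buried_volume(m, 2, grid_spacing = 0.1)
  bvt <- compute_buried_volume(mt, 2, grid_spacing = 0.1)
  expect_lt(abs(bv - bvt), 0.3)   # grid re-registration tolerance

  st <- site_sterimol(m, 2, shell = 2)
  stt <- site_sterimol(mt, 2, shell = 2)
  expect_equal(st$sterimol_L, stt$sterimol_L, tolerance = 1e-9)
  expect_equal(st$sterimol_B5, stt$sterimol_B5, tolerance = 1e-9)
  expect_equal(st$sterimol_B1, stt$sterimol_B1, tolerance = 2e-3)

  mp <- permute_atoms(m, seed = 5)
  new_pos <- order(withr::with_seed(5, sample(n_atoms(m))))[2]
  stp <- site_sterimol(mp, new_pos, shell = 2)
  expect_equal(stp$sterimol_L, st$sterimol_L, tolerance = 1e-9)
  expect_equal(stp$sterimol_B5, st$sterimol_B5, tolerance = 1e-9)
})

test_that("halving the B1 angle resolution never increases B1", {
  m <- make_ring_fixture(c("OMe", rep("H", 5)))
  s2 <- site_sterimol(m, 2, shell = 2, angle_resolution = 2)$sterimol_B1
  s1 <- site_sterimol(m, 2, shell = 2, angle_resolution = 1)$sterimol_B1
  s05 <- site_sterimol(m, 2, shell = 2, angle_resolution = 0.5)$sterimol_B1
  expect_lte(s1, s2 + 1e-12)
  expect_lte(s05, s1 + 1e-12)
})

test_that("degenerate Sterimol axes are rejected", {
  m <- make_ring_fixture("benzene")
  expect_error(compute_sterimol(m, 1, 1, 1), "substituent_atoms must not")
  expect_error(compute_sterimol(m, 1, 4, 4), "neither bonded nor within")
})
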