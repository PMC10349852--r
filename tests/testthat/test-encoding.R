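fake_site <- function(arene = "a1", class = "a", seed = 1) {
  set.seed(seed)
  vals <- as.list(stats::rnorm(13))
  names(vals) <- descriptor_schema()$per_site
  c(list(arene_id = arene, symmetry_class = class), vals)
}

test_that("the default pair encoding is 28-dimensional with block layout", {
  schema <- descriptor_schema()
  expect_equal(schema_width(schema), 28)
  expect_equal(length(schema_feature_names(schema)), 28)
  expect_false(anyDuplicated(schema_feature_names(schema)) > 0)

  a <- fake_site(class = "a", seed = 1)
  b <- fake_site(class = "b", seed = 2)
  v <- build_pair_vector(a, b, mol = list(redox_potential = 1.8),
                         temperature = 333.15)
  expect_equal(ncol(v), 28)
  expect_identical(names(v), schema_feature_names(schema))
  expect_equal(v$temperature_K, 333.15)
  expect_equal(v$mol_redox_potential, 1.8)

  # swapping the sites exchanges the blocks and leaves the rest unchanged
  w <- build_pair_vector(b, a, mol = list(redox_potential = 1.8),
                         temperature = 333.15)
  expect_equal(unlist(w[paste0("a_", schema$per_site)], use.names = FALSE),
               unlist(v[paste0("b_", schema$per_site)], use.names = FALSE))
  expect_equal(unlist(w[paste0("b_", schema$per_site)], use.names = FALSE),
               unlist(v[paste0("a_", schema$per_site)], use.names = FALSE))
  expect_equal(w$mol_redox_potential, v$mol_redox_potential)
  expect_equal(w$temperature_K, v$temperature_K)
})

test_that("schema width follows the declared arithmetic", {
  s27 <- descriptor_schema(include_temperature = FALSE)
  expect_equal(schema_width(s27), 27)
  expect_equal(schema_width(descriptor_schema(encoding = "delta")), 15)
  s_small <- descriptor_schema(per_site = c("fukui_minus", "ch_bde"),
                               molecule = character(0))
  expect_equal(schema_width(s_small), 5)
})

test_that("pair vectors validate arene identity, classes and coverage", {
  a <- fake_site(arene = "a1", class = "a")
  b <- fake_site(arene = "a2", class = "b")
  expect_error(build_pair_vector(a, b, list(redox_potential = 1), 300),
               "different arenes")
  b$arene_id <- "a1"; b$symmetry_class <- "a"
  expect_error(build_pair_vector(a, b, list(redox_potential = 1), 300),
               "different symmetry classes")
  b$symmetry_class <- "b"
  b$fukui_plus <- NULL
  expect_error(build_pair_vector(a, b, list(redox_potential = 1), 300),
               "missing site-B descriptor")
  a2 <- fake_site(class = "b")
  expect_error(build_pair_vector(a, a2, list(redox_potential = 1), NULL),
               "temperature")
})

test_that("canonical pair order is deterministic, signed and idempotent", {
  expect_identical(canonical_pair_order("b", "a"),
                   list(first = "a", second = "b", sign = -1))
  expect_identical(canonical_pair_order("a", "b"),
                   list(first = "a", second = "b", sign = +1))
  once <- canonical_pair_order("c", "a")
  twice <- canonical_pair_order(once$first, once$second)
  expect_identical(twice$sign, +1)
  expect_identical(c(twice$first, twice$second), c(once$first, once$second))
  expect_error(canonical_pair_order("a", "a"), "itself")
})

test_that("QM tables load, derive the dual descriptor and keep extensions", {
  sp <- withr::local_tempfile(fileext = ".csv")
  mp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "arene_id,atom_index,fukui_plus,fukui_minus,fukui_zero,partial_charge,ch_bde,nmr_shift",
    "m1,0,0.05,0.08,0.06,-0.04,112.1,7.2",
    "m1,1,0.03,0.02,0.04,-0.02,113.0,7.4"), sp)
  writeLines(c("arene_id,redox_potential", "m1,1.85"), mp)
  qm <- load_qm_table(sp, mp)
  expect_equal(nrow(qm$sites), 2)
  expect_equal(qm$sites$atom_index, c(1L, 2L))   # 0-based input converted
  expect_true("nmr_shift" %in% names(qm$sites))
  expect_equal(qm$sites$dual_descriptor, c(-0.03, 0.01), tolerance = 1e-12)
  expect_equal(qm$molecules$redox_potential, 1.85)

  writeLines(c("arene_id,atom_index,fukui_minus,fukui_zero,partial_charge,ch_bde",
               "m1,0,0.08,0.06,-0.04,112.1"), sp)
  expect_error(load_qm_table(sp), "missing column.*fukui_plus")

  writeLines(c(
    "arene_id,atom_index,fukui_plus,fukui_minus,fukui_zero,partial_charge,ch_bde",
    "m1,0,0.05,0.08,0.06,-0.04,112.1",
    "m1,0,0.04,0.07,0.05,-0.03,112.5"), sp)
  expect_error(load_qm_table(sp), "duplicate")
})

test_that("featurize_pairs expands arenes into canonical class pairs", {
  sites <- dplyr::bind_rows(
    tibble::as_tibble(fake_site("m1", "a", seed = 1)),
    tibble::as_tibble(fake_site("m1", "b", seed = 2)),
    tibble::as_tibble(fake_site("m1", "c", seed = 3)),
    tibble::as_tibble(fake_site("m2", "a", seed = 4)),
    tibble::as_tibble(fake_site("m2", "b", seed = 5)))
  mols <- tibble::tibble(arene_id = c("m1", "m2"),
                         redox_potential = c(1.7, 1.9))
  pairs <- featurize_pairs(sites, mols, temperature = 333.15)
  expect_equal(nrow(pairs), choose(3, 2) + choose(2, 2))
  expect_true(all(pairs$site_a < pairs$site_b))
  expect_equal(length(pair_feature_names(pairs)), 28)
})
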