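test_that("Boltzmann inversion reproduces closed-form selectivity values", {
  # equal per-site fractions: no preference at any temperature
  expect_equal(ratio_to_ddg(0.5, 0.5, temperature = 300), 0)
  expect_equal(ratio_to_ddg(0.4, 0.2, 2, 1, temperature = 350), 0)

  # a 17:1 isomer ratio at 333.15 K corresponds to ~1.876 kcal/mol
  f <- parse_ratio("17:1")[[1]]
  ddg <- ratio_to_ddg(f[1], f[2], temperature = 333.15)
  expect_equal(ddg, 1.9872e-3 * 333.15 * log(17), tolerance = 1e-12)
  expect_equal(ddg, 1.876, tolerance = 1e-3)

  back <- ddg_to_ratio(1.876, temperature = 333.15)
  expect_equal(back$fraction_a / back$fraction_b, 17, tolerance = 1e-2)
})

test_that("ratio <-> free energy round trip is numerically exact", {
  set.seed(4)
  for (k in 1:20) {
    fa <- stats::runif(1, 0.01, 0.99)
    ma <- sample(1:3, 1); mb <- sample(1:3, 1)
    tk <- stats::runif(1, 250, 400)
    ddg <- ratio_to_ddg(fa, 1 - fa, ma, mb, tk)
    rt <- ddg_to_ratio(ddg, ma, mb, tk)
    expect_equal(rt$fraction_a, fa, tolerance = 1e-10)
  }
})

test_that("free-energy targets are antisymmetric and statistically corrected", {
  expect_equal(ratio_to_ddg(0.7, 0.3, 2, 1, 333.15),
               -ratio_to_ddg(0.3, 0.7, 1, 2, 333.15))
  # zero preference with multiplicities 2:1 gives fractions 2/3 and 1/3
  r <- ddg_to_ratio(0, 2, 1, 333.15)
  expect_equal(c(r$fraction_a, r$fraction_b), c(2 / 3, 1 / 3))
  # large preferences saturate monotonically toward 1
  f1 <- ddg_to_ratio(5, temperature = 333.15)$fraction_a
  f2 <- ddg_to_ratio(10, temperature = 333.15)$fraction_a
  expect_gt(f2, f1)
  expect_lt(f2, 1)
})

test_that("favored fractions shrink as temperature rises", {
  fr <- sapply(c(280, 320, 360, 400),
               function(tk) ddg_to_ratio(1.5, temperature = tk)$fraction_a)
  expect_true(all(diff(fr) < 0))
})

test_that("zero fractions error unless an epsilon clamp is requested", {
  expect_error(ratio_to_ddg(0, 1, temperature = 300), "positive")
  expect_true(is.finite(ratio_to_ddg(0, 1, temperature = 300,
                                     epsilon = 1e-6)))
  expect_error(ddg_to_ratio(1, temperature = -5), "positive")
})

test_that("site potentials solve the pairwise least-squares problem", {
  one <- aggregate_site_scores(tibble::tibble(site_a = "A", site_b = "B",
                                              ddg = 1))
  expect_equal(one$score[one$site == "A"], 0.5)
  expect_equal(one$score[one$site == "B"], -0.5)

  tri <- aggregate_site_scores(tibble::tibble(
    site_a = c("A", "B", "A"), site_b = c("B", "C", "C"), ddg = c(1, 1, 2)))
  expect_equal(tri$score, c(1, 0, -1), tolerance = 1e-10)

  # inconsistent triangle: compare residual with a brute-force minimizer
  pairs <- tibble::tibble(site_a = c("A", "B", "A"),
                          site_b = c("B", "C", "C"), ddg = c(1, 1, 1))
  fit <- aggregate_site_scores(pairs)
  resid_fit <- sum((fit$score[match(pairs$site_a, fit$site)] -
                      fit$score[match(pairs$site_b, fit$site)] - pairs$ddg)^2)
  oracle <- stats::optim(c(0, 0), function(th) {
    g <- c(th, -sum(th))
    sum((g[match(pairs$site_a, c("A", "B", "C"))] -
           g[match(pairs$site_b, c("A", "B", "C"))] - pairs$ddg)^2)
  }, method = "BFGS")
  expect_equal(resid_fit, oracle$value, tolerance = 1e-8)
  expect_equal(sum(fit$score), 0, tolerance = 1e-12)
})

test_that("spanning-tree pair sets are reproduced exactly", {
  set.seed(9)
  sites <- LETTERS[1:6]
  g_true <- stats::rnorm(6)
  g_true <- g_true - mean(g_true)
  tree <- tibble::tibble(site_a = sites[1:5], site_b = sites[2:6])
  tree$ddg <- g_true[1:5] - g_true[2:6]
  fit <- aggregate_site_scores(tree)
  expect_equal(fit$score[match(sites, fit$site)], g_true, tolerance = 1e-10)
})

test_that("disconnected comparison graphs are rejected with components named", {
  pairs <- tibble::tibble(site_a = c("A", "C"), site_b = c("B", "D"),
                          ddg = c(1, 1))
  expect_error(aggregate_site_scores(pairs), "disconnected.*A.*B.*C.*D")
})

test_that("site probabilities follow the Boltzmann weighting", {
  u <- site_probabilities(c(a = 1, b = 1, c = 1), temperature = 300)
  expect_equal(u$probability, rep(1 / 3, 3))
  p <- site_probabilities(c(a = 1.876, b = 0), temperature = 333.15)
  expect_equal(p$probability, c(0.944, 0.056), tolerance = 1e-2)
  m <- site_probabilities(c(a = 0, b = 0), multiplicities = c(2, 1),
                          temperature = 300)
  expect_equal(m$probability, c(2 / 3, 1 / 3))
  expect_equal(sum(p$probability), 1, tolerance = 1e-12)
})

test_that("measurements convert to targets and back to fractions exactly", {
  meas <- tibble::tibble(
    arene_id = "m1", symmetry_class = c("a", "b", "c"),
    fraction = c(0.6, 0.3, 0.1), multiplicity = c(2, 2, 1),
    temperature_K = 333.15)
  tg <- measurements_to_targets(meas)
  expect_equal(nrow(tg), 3)
  expect_true(all(tg$site_a < tg$site_b))
  # perfect predictor: aggregate the targets and regenerate the fractions
  sc <- aggregate_site_scores(dplyr::rename(tg, ddg = "target"))
  p <- site_probabilities(stats::setNames(sc$score, sc$site),
                          multiplicities = c(2, 2, 1), temperature = 333.15)
  expect_equal(p$probability, meas$fraction, tolerance = 1e-6)
})
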