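# Gas constant in kcal / (mol K)
.R_KCAL <- 1.9872e-3

#' Parse an isomer-ratio string
#'
#' Converts strings such as `"17:1"` or `"2:1:0.5"` to normalized fractions.
#'
#' @param ratio Character vector of colon-separated ratio strings.
#' @return A list of numeric fraction vectors (each summing to 1).
#' @examples
#' parse_ratio("17:1")
#' @export
parse_ratio <- function(ratio) {
  lapply(strsplit(as.character(ratio), ":"), function(p) {
    v <- as.numeric(p)
    if (anyNA(v) || any(v < 0) || sum(v) <= 0) {
      stop("malformed ratio string: ", paste(p, collapse = ":"))
    }
    v / sum(v)
  })
}

#' Isomer fractions to an apparent free-energy difference
#'
#' Boltzmann inversion of an observed product distribution with statistical
#' factors removed:
#' `ddG = R T ln[(f_a / m_a) / (f_b / m_b)]`, with R = 1.9872e-3
#' kcal/(mol K). Positive values mean site A is favored on a per-site basis.
#' Exactly antisymmetric under exchange of the two sites.
#'
#' @param fraction_a,fraction_b Observed product fractions (> 0).
#' @param mult_a,mult_b Site multiplicities (statistical factors, >= 1).
#' @param temperature Temperature in Kelvin (> 0).
#' @param epsilon Optional clamp: zero fractions are replaced by `epsilon`
#'   instead of raising an error.
#' @return Apparent free-energy preference of A over B, kcal/mol. Vectorized.
#' @examples
#' ratio_to_ddg(17 / 18, 1 / 18, temperature = 333.15)  # ~1.876 kcal/mol
#' @export
ratio_to_ddg <- function(fraction_a, fraction_b, mult_a = 1, mult_b = 1,
                         temperature = 333.15, epsilon = NULL) {
  if (any(temperature <= 0)) stop("temperature must be positive (Kelvin)")
  if (any(mult_a < 1) || any(mult_b < 1)) stop("multiplicities must be >= 1")
  if (!is.null(epsilon)) {
    fraction_a <- pmax(fraction_a, epsilon)
    fraction_b <- pmax(fraction_b, epsilon)
  }
  if (any(fraction_a <= 0) || any(fraction_b <= 0)) {
    stop("fractions must be positive (or provide `epsilon` to clamp zeros)")
  }
  .R_KCAL * temperature * log((fraction_a / mult_a) / (fraction_b / mult_b))
}

#' Apparent free-energy difference to isomer fractions
#'
#' Exact inverse of [ratio_to_ddg()]: per-site Boltzmann weights are
#' multiplied back by the statistical factors and normalized over the pair.
#'
#' @param ddg Apparent free-energy preference of A over B, kcal/mol.
#' @param mult_a,mult_b Site multiplicities.
#' @param temperature Temperature in Kelvin (> 0).
#' @return A tibble with columns `fraction_a`, `fraction_b` (summing to 1).
#' @export
ddg_to_ratio <- function(ddg, mult_a = 1, mult_b = 1, temperature = 333.15) {
  if (any(temperature <= 0)) stop("temperature must be positive (Kelvin)")
  wa <- mult_a * exp(ddg / (.R_KCAL * temperature))
  wb <- mult_b
  tibble::tibble(fraction_a = wa / (wa + wb), fraction_b = wb / (wa + wb))
}

#' Pairwise free-energy targets from selectivity measurements
#'
#' Expands each arene's measured class fractions into all canonical class
#' pairs and computes the statistical-factor-corrected pairwise target.
#' Fractions are renormalized over the measured classes (unmeasured minor
#' isomers are dropped).
#'
#' @param measurements Tibble with columns `arene_id`, `symmetry_class`,
#'   `fraction` (or `ratio` strings per arene), `multiplicity`,
#'   `temperature_K`.
#' @param statistical_factors Apply multiplicity correction (default TRUE)?
#' @param epsilon Passed to [ratio_to_ddg()].
#' @return A tibble `arene_id`, `site_a`, `site_b`, `target` (kcal/mol) in
#'   canonical pair order.
#' @export
measurements_to_targets <- function(measurements, statistical_factors = TRUE,
                                    epsilon = NULL) {
  stopifnot(all(c("arene_id", "symmetry_class", "fraction", "multiplicity",
                  "temperature_K") %in% names(measurements)))
  measurements |>
    dplyr::group_by(.data$arene_id) |>
    dplyr::group_map(function(g, key) {
      if (nrow(g) < 2) return(NULL)
      g <- g[order(g$symmetry_class), ]
      g$fraction <- g$fraction / sum(g$fraction)
      m <- if (statistical_factors) g$multiplicity else rep(1, nrow(g))
      pairs <- utils::combn(seq_len(nrow(g)), 2, simplify = FALSE)
      purrr::map_dfr(pairs, function(ij) {
        a <- ij[1]; b <- ij[2]
        tibble::tibble(
          arene_id = key$arene_id,
          site_a = g$symmetry_class[a], site_b = g$symmetry_class[b],
          target = ratio_to_ddg(g$fraction[a], g$fraction[b], m[a], m[b],
                                g$temperature_K[1], epsilon = epsilon))
      })
    }) |>
    dplyr::bind_rows()
}

#' Least-squares site potentials from pairwise predictions
#'
#' Reduces pairwise free-energy predictions to one score per site: the
#' potentials `g_i` minimizing `sum (g_a - g_b - ddG_ab)^2`, gauge-fixed by
#' `sum g_i = 0`. Unique on connected comparison graphs; on a spanning tree
#' of consistent pairs every input is reproduced exactly.
#'
#' @param pairs Tibble with columns `site_a`, `site_b`, `ddg` (kcal/mol).
#' @return A tibble `site`, `score` (zero-sum, kcal/mol).
#' @export
aggregate_site_scores <- function(pairs) {
  stopifnot(all(c("site_a", "site_b", "ddg") %in% names(pairs)))
  sites <- sort(unique(c(pairs$site_a, pairs$site_b)))
  ns <- length(sites)
  if (ns < 2) stop("need at least two distinct sites")
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs$site_a, to = pairs$site_b),
    directed = FALSE, vertices = data.frame(name = sites))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    parts <- split(sites, comp$membership)
    stop("comparison graph is disconnected; components: ",
         paste(vapply(parts, paste, "", collapse = "+"), collapse = " | "))
  }
  A <- matrix(0, nrow(pairs), ns)
  ia <- match(pairs$site_a, sites)
  ib <- match(pairs$site_b, sites)
  A[cbind(seq_len(nrow(pairs)), ia)] <- 1
  A[cbind(seq_len(nrow(pairs)), ib)] <- A[cbind(seq_len(nrow(pairs)), ib)] - 1
  # drop the last potential (fix g_ns = 0), solve, then shift to zero sum
  fit <- stats::lm.fit(A[, -ns, drop = FALSE], pairs$ddg)
  scores <- c(fit$coefficients, 0)
  scores[is.na(scores)] <- 0
  scores <- scores - mean(scores)
  tibble::tibble(site = sites, score = unname(scores))
}

#' Boltzmann site probabilities from scores
#'
#' `p_i` proportional to `mult_i * exp(g_i / (R T))`, normalized. Higher
#' scores mean more reactive sites (consistent with the sign convention of
#' [ratio_to_ddg()]).
#'
#' @param scores Numeric vector of site scores (kcal/mol), or the tibble
#'   returned by [aggregate_site_scores()].
#' @param multiplicities Statistical factors (recycled).
#' @param temperature Temperature in Kelvin.
#' @return A tibble `site`, `score`, `multiplicity`, `probability`
#'   (summing to 1).
#' @export
site_probabilities <- function(scores, multiplicities = 1,
                               temperature = 333.15) {
  if (temperature <= 0) stop("temperature must be positive (Kelvin)")
  if (is.data.frame(scores)) {
    site <- scores$site
    s <- scores$score
  } else {
    s <- as.numeric(scores)
    site <- names(scores) %||% as.character(seq_along(s))
  }
  stopifnot(all(is.finite(s)))
  m <- rep_len(multiplicities, length(s))
  w <- m * exp((s - max(s)) / (.R_KCAL * temperature))
  tibble::tibble(site = site, score = s, multiplicity = m,
                 probability = w / sum(w))
}
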