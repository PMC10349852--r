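.DEFAULT_PER_SITE <- c(
  # steric block (geometry-derived)
  "pct_buried_volume", "sterimol_L", "sterimol_B1", "sterimol_B5",
  # electronic block (ingested QM)
  "fukui_plus", "fukui_minus", "fukui_zero", "dual_descriptor",
  "partial_charge", "ch_bde",
  # named extension slots, filled from extra QM-table columns
  "aux_1", "aux_2", "aux_3"
)

#' Descriptor schema for the pairwise competing-site encoding
#'
#' Declares which per-site and molecule-level descriptors enter the pair
#' feature vector and in what order. With the default 13 per-site descriptors
#' (4 steric + 6 electronic + 3 extension slots), one molecule-level
#' descriptor (redox potential) and the reaction temperature, the pair
#' encoding has width `2 * 13 + 1 + 1 = 28`.
#'
#' Two encodings are supported: `"blocks"` lays out
#' `[site A | site B | molecule | temperature]`; `"delta"` replaces the two
#' site blocks by their difference `A - B` (width `13 + 1 + 1 = 15` by
#' default).
#'
#' @param per_site Ordered character vector of per-site descriptor names.
#' @param molecule Ordered character vector of molecule-level descriptor
#'   names (default `"redox_potential"`).
#' @param include_temperature Append the reaction temperature (K)?
#' @param encoding `"blocks"` (default) or `"delta"`.
#' @return An object of class `descriptor_schema`.
#' @examples
#' schema_width(descriptor_schema())  # 28
#' @export
descriptor_schema <- function(per_site = .DEFAULT_PER_SITE,
                              molecule = "redox_potential",
                              include_temperature = TRUE,
                              encoding = c("blocks", "delta")) {
  encoding <- match.arg(encoding)
  stopifnot(length(per_site) > 0, !anyDuplicated(per_site),
            !anyDuplicated(molecule))
  structure(list(per_site = as.character(per_site),
                 molecule = as.character(molecule),
                 include_temperature = isTRUE(include_temperature),
                 encoding = encoding),
            class = "descriptor_schema")
}

#' @rdname descriptor_schema
#' @param schema A `descriptor_schema`.
#' @return `schema_width()`: total feature-vector length.
#' @export
schema_width <- function(schema) {
  stopifnot(inherits(schema, "descriptor_schema"))
  site_part <- if (schema$encoding == "blocks") 2L else 1L
  site_part * length(schema$per_site) + length(schema$molecule) +
    as.integer(schema$include_temperature)
}

#' @rdname descriptor_schema
#' @return `schema_feature_names()`: the ordered feature names of the pair
#'   vector.
#' @export
schema_feature_names <- function(schema) {
  stopifnot(inherits(schema, "descriptor_schema"))
  nm <- if (schema$encoding == "blocks") {
    c(paste0("a_", schema$per_site), paste0("b_", schema$per_site))
  } else {
    paste0("d_", schema$per_site)
  }
  nm <- c(nm, if (length(schema$molecule)) paste0("mol_", schema$molecule))
  if (schema$include_temperature) nm <- c(nm, "temperature_K")
  nm
}

#' @export
print.descriptor_schema <- function(x, ...) {
  cat("<descriptor_schema> ", x$encoding, " encoding, width ",
      schema_width(x), "\n  per-site (", length(x$per_site), "): ",
      paste(x$per_site, collapse = ", "), "\n  molecule: ",
      paste(x$molecule, collapse = ", "),
      if (x$include_temperature) "\n  + temperature_K" else "", "\n", sep = "")
  invisible(x)
}

#' Canonical ordering of a competing-site pair
#'
#' Orders two symmetry classes of one arene deterministically: lexicographic
#' on the class label, ties broken by the lower atom index. The sign is -1
#' when the inputs had to be swapped (pair targets are multiplied by the
#' sign), +1 otherwise. Applying the function to an already-canonical pair is
#' the identity, so it is idempotent.
#'
#' @param class_a,class_b Symmetry-class labels (distinct).
#' @param index_a,index_b Optional representative atom indices for
#'   tie-breaking.
#' @return A list with `first`, `second` (the labels in canonical order) and
#'   `sign` (+1 or -1).
#' @export
canonical_pair_order <- function(class_a, class_b,
                                 index_a = NA_integer_, index_b = NA_integer_) {
  if (identical(class_a, class_b)) {
    stop("cannot pair a symmetry class with itself: ", class_a)
  }
  swap <- (class_a > class_b) ||
    (class_a == class_b && !is.na(index_a) && !is.na(index_b) &&
       index_a > index_b)
  if (swap) {
    list(first = class_b, second = class_a, sign = -1)
  } else {
    list(first = class_a, second = class_b, sign = +1)
  }
}

#' Build one pairwise competing-site feature vector
#'
#' Assembles the encoding for a pair of regioisomeric competing sites:
#' `[site A block | site B block | molecule block | temperature]` under the
#' default blocks encoding (28 features with the default schema), or
#' `[A - B | molecule | temperature]` under the delta encoding.
#'
#' @param a,b Named lists / one-row data frames holding the per-site
#'   descriptors of the two sites; may carry `arene_id` and `symmetry_class`
#'   for validation.
#' @param mol Named list / one-row data frame of molecule-level descriptors.
#' @param temperature Reaction temperature in Kelvin.
#' @param schema A [descriptor_schema()].
#' @return A one-row tibble whose columns are [schema_feature_names()].
#' @export
build_pair_vector <- function(a, b, mol = NULL, temperature = NULL,
                              schema = descriptor_schema()) {
  stopifnot(inherits(schema, "descriptor_schema"))
  a <- as.list(a); b <- as.list(b); mol <- as.list(mol)
  if (!is.null(a$arene_id) && !is.null(b$arene_id) &&
      !identical(a$arene_id, b$arene_id)) {
    stop("sites belong to different arenes: '", a$arene_id, "' vs '",
         b$arene_id, "'")
  }
  if (!is.null(a$symmetry_class) && !is.null(b$symmetry_class) &&
      identical(a$symmetry_class, b$symmetry_class)) {
    stop("sites must come from different symmetry classes")
  }
  need <- function(src, keys, what) {
    miss <- keys[!vapply(keys, function(k) {
      !is.null(src[[k]]) && is.finite(as.numeric(src[[k]]))
    }, logical(1))]
    if (length(miss) > 0) {
      stop("missing ", what, " descriptor(s): ", paste(miss, collapse = ", "))
    }
    vapply(keys, function(k) as.numeric(src[[k]]), numeric(1))
  }
  va <- need(a, schema$per_site, "site-A")
  vb <- need(b, schema$per_site, "site-B")
  vals <- if (schema$encoding == "blocks") c(va, vb) else va - vb
  if (length(schema$molecule) > 0) {
    vals <- c(vals, need(mol, schema$molecule, "molecule-level"))
  }
  if (schema$include_temperature) {
    if (is.null(temperature) || !is.finite(temperature) || temperature <= 0) {
      stop("a positive reaction temperature (K) is required by the schema")
    }
    vals <- c(vals, as.numeric(temperature))
  }
  names(vals) <- schema_feature_names(schema)
  tibble::as_tibble(as.list(vals))
}

#' Featurize all competing-site pairs of a set of arenes
#'
#' Expands every arene's symmetry classes into all unordered class pairs in
#' canonical order ([canonical_pair_order()]) and builds the pair feature
#' vector for each.
#'
#' @param site_descriptors Tibble with one row per (arene, symmetry class):
#'   columns `arene_id`, `symmetry_class`, `multiplicity`, plus every
#'   per-site descriptor named in the schema.
#' @param molecule_descriptors Tibble with `arene_id` plus the molecule-level
#'   descriptors, or `NULL` when the schema has none.
#' @param temperature Reaction temperature in Kelvin (scalar, or a tibble
#'   `arene_id`, `temperature_K`).
#' @param schema A [descriptor_schema()].
#' @return A pair-dataset tibble: `arene_id`, `site_a`, `site_b`,
#'   `multiplicity_a`, `multiplicity_b`, then the feature columns.
#' @export
featurize_pairs <- function(site_descriptors, molecule_descriptors = NULL,
                            temperature = 333.15,
                            schema = descriptor_schema()) {
  stopifnot(all(c("arene_id", "symmetry_class") %in% names(site_descriptors)))
  if (!"multiplicity" %in% names(site_descriptors)) {
    site_descriptors$multiplicity <- 1L
  }
  temp_tbl <- if (is.data.frame(temperature)) {
    temperature
  } else {
    tibble::tibble(arene_id = unique(site_descriptors$arene_id),
                   temperature_K = temperature)
  }
  rows <- site_descriptors |>
    dplyr::group_by(.data$arene_id) |>
    dplyr::group_map(function(g, key) {
      if (nrow(g) < 2) return(NULL)
      arene <- key$arene_id
      mol <- NULL
      if (!is.null(molecule_descriptors)) {
        mol <- molecule_descriptors[molecule_descriptors$arene_id == arene, ]
        if (nrow(mol) != 1 && length(schema$molecule) > 0) {
          stop("molecule descriptors missing for arene '", arene, "'")
        }
      }
      tk <- temp_tbl$temperature_K[temp_tbl$arene_id == arene][1]
      g <- g[order(g$symmetry_class), ]
      pairs <- utils::combn(seq_len(nrow(g)), 2, simplify = FALSE)
      purrr::map_dfr(pairs, function(ij) {
        a <- g[ij[1], ]; b <- g[ij[2], ]
        ord <- canonical_pair_order(a$symmetry_class, b$symmetry_class)
        if (ord$sign < 0) { tmp <- a; a <- b; b <- tmp }
        fv <- build_pair_vector(a, b, mol, tk, schema)
        dplyr::bind_cols(
          tibble::tibble(arene_id = arene,
                         site_a = a$symmetry_class, site_b = b$symmetry_class,
                         multiplicity_a = a$multiplicity,
                         multiplicity_b = b$multiplicity),
          fv)
      })
    }) |>
    dplyr::bind_rows()
  rows
}
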