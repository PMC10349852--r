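#' Construct a 3D molecule
#'
#' The basic geometric container: element symbols with Cartesian coordinates
#' in Angstrom, plus an optional bond list (derivable from covalent-radius
#' distance cutoffs via [infer_bonds()]). Atom indices are 1-based throughout
#' the package.
#'
#' @param atoms A data frame with columns `element` (character) and `x`, `y`,
#'   `z` (numeric, Angstrom).
#' @param bonds Optional data frame with integer columns `i`, `j` (1-based
#'   atom indices, `i < j`). If `NULL`, bonds are inferred from covalent radii.
#' @param id Text identifier for the molecule.
#' @return An object of class `molecule3d`: a list with `id`, an `atoms`
#'   tibble and a `bonds` tibble.
#' @examples
#' h2 <- molecule3d(
#'   data.frame(element = c("H", "H"), x = c(0, 0.74), y = 0, z = 0),
#'   id = "dihydrogen"
#' )
#' n_atoms(h2)
#' @export
molecule3d <- function(atoms, bonds = NULL, id = "molecule") {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  atoms <- atoms[, c("element", "x", "y", "z")]
  atoms$element <- as.character(atoms$element)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("atom positions must be finite")
  unknown <- setdiff(unique(atoms$element), names(.BONDI_VDW))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  n <- nrow(atoms)
  if (n >= 2) {
    dmin <- min(stats::dist(coords))
    if (dmin < 0.5) {
      stop(sprintf("atoms closer than 0.5 Angstrom (min distance %.3f)", dmin))
    }
  }
  mol <- structure(list(id = as.character(id), atoms = atoms,
                        bonds = .empty_bonds()),
                   class = "molecule3d")
  if (is.null(bonds)) {
    mol$bonds <- if (n >= 2) infer_bonds(mol) else .empty_bonds()
  } else {
    bonds <- tibble::as_tibble(bonds)
    stopifnot(all(c("i", "j") %in% names(bonds)))
    bonds <- tibble::tibble(i = as.integer(pmin(bonds$i, bonds$j)),
                            j = as.integer(pmax(bonds$i, bonds$j)))
    if (nrow(bonds) > 0) {
      if (any(bonds$i < 1L) || any(bonds$j > n)) stop("bond index out of range")
      if (any(bonds$i == bonds$j)) stop("self-bonds are not allowed")
      bonds <- dplyr::distinct(bonds)
    }
    mol$bonds <- dplyr::arrange(bonds, .data$i, .data$j)
  }
  mol
}

.empty_bonds <- function() tibble::tibble(i = integer(), j = integer())

#' @rdname molecule3d
#' @param mol A `molecule3d`.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Atom coordinate matrix
#' @param mol A `molecule3d`.
#' @return Numeric matrix (n x 3) of Cartesian coordinates in Angstrom.
#' @export
coords <- function(mol) {
  m <- as.matrix(mol$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' @export
print.molecule3d <- function(x, ...) {
  cat("<molecule3d> ", x$id, ": ", n_atoms(x), " atoms, ",
      nrow(x$bonds), " bonds (",
      paste(unique(x$atoms$element), collapse = ""), ")\n", sep = "")
  invisible(x)
}

#' Infer bonds from covalent radii
#'
#' Two atoms are bonded when their distance does not exceed
#' `tolerance * (r_cov_i + r_cov_j)`. The bond list is symmetric and free of
#' self-bonds; each bond is stored once with `i < j`.
#'
#' @param mol A [molecule3d()].
#' @param tolerance Dimensionless cutoff multiplier in `[1.0, 1.5]`.
#' @return A tibble with integer columns `i`, `j`.
#' @export
infer_bonds <- function(mol, tolerance = 1.2) {
  stopifnot(inherits(mol, "molecule3d"),
            is.numeric(tolerance), length(tolerance) == 1L,
            tolerance >= 1.0, tolerance <= 1.5)
  n <- n_atoms(mol)
  if (n < 2) return(.empty_bonds())
  xyz <- coords(mol)
  rc <- covalent_radius(mol$atoms$element)
  d <- as.matrix(stats::dist(xyz))
  cut <- tolerance * outer(rc, rc, `+`)
  hit <- which(d <= cut & upper.tri(d), arr.ind = TRUE)
  tibble::tibble(i = as.integer(hit[, 1]), j = as.integer(hit[, 2])) |>
    dplyr::arrange(.data$i, .data$j)
}

#' Adjacency list from the bond table
#' @param mol A `molecule3d`.
#' @return List of integer vectors; element `k` holds the neighbors of atom `k`.
#' @export
neighbors <- function(mol) {
  n <- n_atoms(mol)
  adj <- rep(list(integer()), n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
  }
  lapply(adj, sort)
}

#' Read molecules from an XYZ file
#'
#' Plain XYZ: an atom-count line, a comment line (used as the identifier when
#' non-empty), then `element x y z` rows in Angstrom. Multi-frame files return
#' a list of molecules.
#'
#' @param path Path to an `.xyz` file.
#' @param id Identifier override; defaults to the comment line, falling back
#'   to the file name.
#' @return A `molecule3d`, or a list of them for multi-frame files.
#' @export
read_xyz <- function(path, id = NULL) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  out <- list()
  pos <- 1L
  while (pos <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat < 1) stop("malformed XYZ atom-count line at line ", pos)
    if (pos + 1L + nat > length(lines)) stop("truncated XYZ block at line ", pos)
    comment <- trimws(lines[pos + 1L])
    rows <- lines[(pos + 2L):(pos + 1L + nat)]
    parts <- strsplit(trimws(rows), "\\s+")
    if (any(lengths(parts) < 4)) stop("malformed XYZ atom line")
    atoms <- tibble::tibble(
      element = vapply(parts, `[[`, "", 1L),
      x = as.numeric(vapply(parts, `[[`, "", 2L)),
      y = as.numeric(vapply(parts, `[[`, "", 3L)),
      z = as.numeric(vapply(parts, `[[`, "", 4L))
    )
    mol_id <- id %||% (if (nzchar(comment)) comment else
      tools::file_path_sans_ext(basename(path)))
    out[[length(out) + 1L]] <- molecule3d(atoms, id = mol_id)
    pos <- pos + 2L + nat
  }
  if (length(out) == 1L) out[[1L]] else out
}

#' Write a molecule to an XYZ file
#'
#' @param mol A `molecule3d`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(mol, path) {
  stopifnot(inherits(mol, "molecule3d"))
  a <- mol$atoms
  lines <- c(
    as.character(nrow(a)),
    mol$id,
    sprintf("%-2s %14.8f %14.8f %14.8f", a$element, a$x, a$y, a$z)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read molecules from an SDF/MOL V2000 file
#'
#' Parses the atom block (coordinates, element) and bond block of MOL V2000
#' records; multi-record SDF files (separated by `$$$$`) return a list.
#'
#' @param path Path to a `.mol` or `.sdf` file.
#' @return A `molecule3d`, or a list of them for multi-record files.
#' @export
read_sdf <- function(path) {
  lines <- readLines(path)
  recs <- split(lines, cumsum(c(0L, utils::head(grepl("^\\$\\$\\$\\$", lines), -1))))
  out <- list()
  for (rec in recs) {
    rec <- rec[!grepl("^\\$\\$\\$\\$", rec)]
    if (!any(nzchar(trimws(rec)))) next
    if (length(rec) < 4) stop("truncated MOL record")
    counts <- rec[4]
    if (!grepl("V2000", counts)) stop("only MOL V2000 records are supported")
    nat <- as.integer(substr(counts, 1, 3))
    nbd <- as.integer(substr(counts, 4, 6))
    if (is.na(nat) || nat < 1) stop("malformed V2000 counts line")
    ablk <- rec[5:(4 + nat)]
    atoms <- tibble::tibble(
      element = trimws(substr(ablk, 32, 34)),
      x = as.numeric(substr(ablk, 1, 10)),
      y = as.numeric(substr(ablk, 11, 20)),
      z = as.numeric(substr(ablk, 21, 30))
    )
    bonds <- NULL
    if (nbd > 0) {
      bblk <- rec[(5 + nat):(4 + nat + nbd)]
      bonds <- tibble::tibble(
        i = as.integer(substr(bblk, 1, 3)),
        j = as.integer(substr(bblk, 4, 6))
      )
    }
    name <- trimws(rec[1])
    out[[length(out) + 1L]] <- molecule3d(
      atoms, bonds = bonds,
      id = if (nzchar(name)) name else tools::file_path_sans_ext(basename(path))
    )
  }
  if (length(out) == 1L) out[[1L]] else out
}
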