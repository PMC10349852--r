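.QM_SITE_REQUIRED <- c("arene_id", "atom_index", "fukui_plus", "fukui_minus",
                       "fukui_zero", "partial_charge", "ch_bde")

#' Load ingested QM descriptor tables
#'
#' Reads the per-site electronic descriptor table (Fukui functions, atomic
#' partial charge, C-H bond dissociation energy) and the per-molecule table
#' (computed oxidation potential). These quantities come from external
#' quantum-chemical calculations; the package ingests them, never computes
#' them. The dual descriptor `f(+) - f(-)` is derived when absent. Unknown
#' columns are preserved as extension descriptors.
#'
#' @param sites_path CSV with header columns `arene_id`, `atom_index`,
#'   `fukui_plus`, `fukui_minus`, `fukui_zero`, `partial_charge`, `ch_bde`
#'   plus any extensions. Comma-separated, UTF-8.
#' @param molecules_path CSV with header columns `arene_id`,
#'   `redox_potential` (V).
#' @param index_base Base of `atom_index` in the file (0 by default, the
#'   fixed CSV dialect; pass 1 for 1-based tables). Indices are converted to
#'   the package's internal 1-based convention.
#' @return A list with tibbles `sites` (1-based `atom_index`) and `molecules`.
#' @export
load_qm_table <- function(sites_path, molecules_path = NULL, index_base = 0) {
  stopifnot(index_base %in% c(0, 1))
  sites <- readr::read_csv(sites_path, show_col_types = FALSE)
  missing_cols <- setdiff(.QM_SITE_REQUIRED, names(sites))
  if (length(missing_cols) > 0) {
    stop("QM site table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  sites$atom_index <- as.integer(sites$atom_index) + (1L - as.integer(index_base))
  dup <- duplicated(sites[, c("arene_id", "atom_index")])
  if (any(dup)) {
    d <- sites[dup, c("arene_id", "atom_index")][1, ]
    stop(sprintf("duplicate QM site row for (arene '%s', atom %d)",
                 d$arene_id, d$atom_index))
  }
  if (!"dual_descriptor" %in% names(sites)) {
    sites$dual_descriptor <- sites$fukui_plus - sites$fukui_minus
  }
  molecules <- NULL
  if (!is.null(molecules_path)) {
    molecules <- readr::read_csv(molecules_path, show_col_types = FALSE)
    miss <- setdiff(c("arene_id", "redox_potential"), names(molecules))
    if (length(miss) > 0) {
      stop("QM molecule table is missing column(s): ",
           paste(miss, collapse = ", "))
    }
    if (anyDuplicated(molecules$arene_id)) {
      stop("duplicate arene_id in QM molecule table")
    }
  }
  list(sites = tibble::as_tibble(sites),
       molecules = if (is.null(molecules)) NULL else tibble::as_tibble(molecules))
}
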