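#' Pair interaction energy from PIEDA components
#'
#' In fragment molecular orbital analysis the ligand-residue pair
#' interaction energy decomposes as
#' `PIE = E_es + E_ct+mix + E_di + E_ex + G_sol`:
#' electrostatics, charge transfer (plus mixing), dispersion, exchange
#' repulsion and the continuum solvation term. This is plain summation;
#' component sign conventions are ingested as supplied.
#'
#' @param e_es,e_ct_mix,e_di,e_ex,g_sol component energies, kcal/mol
#'   (vectorized).
#' @return total PIE, kcal/mol.
#' @export
#' @examples
#' pie_total(-10, -5, -3, 6, -1)  # -13
pie_total <- function(e_es, e_ct_mix, e_di, e_ex, g_sol) {
  vals <- cbind(e_es, e_ct_mix, e_di, e_ex, g_sol)
  if (!all(is.finite(vals))) stop("numeric error: non-finite PIEDA component")
  rowSums(vals)
}

#' Read a PIEDA component table
#'
#' CSV with columns `ligand, residue, e_es, e_ct_mix, e_di, e_ex, g_sol`
#' (one row per ligand-residue fragment pair).
#'
#' @param path CSV path.
#' @return data.frame with an appended `pie` total column.
#' @export
read_pieda_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cl in c("e_es", "e_ct_mix", "e_di", "e_ex", "g_sol")) {
    tab[[cl]] <- normalize_minus(tab[[cl]])
  }
  if (anyDuplicated(tab[c("ligand", "residue")])) {
    stop("PIEDA table: duplicate (ligand, residue) rows")
  }
  tab$pie <- pie_total(tab$e_es, tab$e_ct_mix, tab$e_di, tab$e_ex, tab$g_sol)
  tab
}

#' Per-residue interaction fingerprint
#'
#' @param pieda PIEDA data.frame (see [read_pieda_table()]).
#' @param ligand ligand code to extract.
#' @return named numeric vector: residue -> PIE (kcal/mol).
#' @export
pie_fingerprint <- function(pieda, ligand) {
  rows <- pieda[pieda$ligand == ligand, , drop = FALSE]
  stats::setNames(rows$pie, rows$residue)
}

#' Delta-PIE fingerprint between an analog and a reference
#'
#' `delta(res) = PIE_analog(res) - PIE_ref(res)` per residue. Fragmentation
#' lists differ between ligands, so a residue present in only one
#' fingerprint is treated as zero on the missing side and flagged
#' (`one_sided` = `"analog_only"` / `"ref_only"`) rather than raising an
#' error.
#'
#' @param fp_analog,fp_ref named numeric vectors (residue -> PIE).
#' @return data.frame with columns `residue`, `delta`, `one_sided`.
#' @export
delta_fingerprint <- function(fp_analog, fp_ref) {
  residues <- union(names(fp_analog), names(fp_ref))
  a <- fp_analog[residues]
  r <- fp_ref[residues]
  a[is.na(a)] <- 0
  r[is.na(r)] <- 0
  side <- ifelse(!residues %in% names(fp_analog), "ref_only",
          ifelse(!residues %in% names(fp_ref), "analog_only", "both"))
  data.frame(residue = residues, delta = unname(a - r), one_sided = side,
             stringsAsFactors = FALSE)
}

#' Consensus interacting residues
#'
#' Given a boolean interaction matrix (rows = analogs, columns = residues),
#' returns the residues that interact in at least `fraction` of the analogs.
#'
#' @param m logical/0-1 matrix with residue column names.
#' @param fraction consensus fraction in (0, 1].
#' @return character vector of residue labels (empty for an empty matrix).
#' @export
consensus_residues <- function(m, fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  if (is.null(dim(m)) || nrow(m) == 0 || ncol(m) == 0) return(character(0))
  frac <- colMeans(m != 0)
  colnames(m)[frac >= fraction]
}

#' Read / write boolean interaction matrices
#'
#' CSV layout: first column `code` (analog), remaining columns one residue
#' each with 0/1 cells.
#'
#' @param path CSV path.
#' @return numeric 0/1 matrix with analog row names and residue column
#'   names.
#' @export
read_interaction_matrix <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' @rdname read_interaction_matrix
#' @param m interaction matrix.
#' @export
write_interaction_matrix <- function(m, path) {
  tab <- data.frame(code = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
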