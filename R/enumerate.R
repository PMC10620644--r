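#' Analog codes
#'
#' An analog is identified by a code `"R1-R2"` where `R1` is the substituent
#' id at the para position, `R2` the id at the ortho position, and `0` means
#' unsubstituted. `"0-0"` denotes the parent 2-PAM scaffold. Positions are
#' taken relative to the aldoxime-bearing ring carbon (see
#' [build_smiles()]).
#'
#' @param r1,r2 substituent ids (0 = none).
#' @return `analog_code()` returns the code string; `parse_analog_code()`
#'   returns a list with integer elements `r1` and `r2`.
#' @export
#' @examples
#' analog_code(3, 1)
#' parse_analog_code("3-1")
analog_code <- function(r1, r2) {
  stopifnot(r1 >= 0, r2 >= 0)
  sprintf("%d-%d", as.integer(r1), as.integer(r2))
}

#' @rdname analog_code
#' @param code analog code string such as `"3-1"`.
#' @export
parse_analog_code <- function(code) {
  parts <- strsplit(code, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2 || anyNA(suppressWarnings(as.integer(parts)))) {
    stop(sprintf("malformed analog code: '%s'", code))
  }
  list(r1 = as.integer(parts[1]), r2 = as.integer(parts[2]))
}

#' Enumerate EDG-substituted analogs
#'
#' Enumerates substituted analogs of the 2-PAM scaffold. In `"single"` mode
#' one analog is produced per (position, id): `r1_ids` give `R1-0` analogs
#' and `r2_ids` give `0-R2` analogs. In `"combined"` mode the Cartesian
#' product `r1_ids x r2_ids` of doubly substituted `R1-R2` analogs is
#' produced. The output is sorted by code and free of duplicates.
#'
#' @param r1_ids integer vector of substituent ids for the para position
#'   (may be empty).
#' @param r2_ids integer vector of substituent ids for the ortho position.
#' @param mode `"single"` or `"combined"`.
#' @param registry substituent registry, see [default_registry()].
#' @return data.frame with columns `code`, `r1`, `r2`.
#' @export
#' @examples
#' nrow(enumerate_analogs(1:9, 1:9, mode = "single"))    # 18
#' nrow(enumerate_analogs(c(2, 3, 4, 5, 9), c(1:6, 8, 9),
#'                        mode = "combined"))            # 40
enumerate_analogs <- function(r1_ids, r2_ids, mode = c("single", "combined"),
                              registry = default_registry()) {
  mode <- match.arg(mode)
  r1_ids <- unique(as.integer(r1_ids))
  r2_ids <- unique(as.integer(r2_ids))
  for (id in c(r1_ids, r2_ids)) lookup_substituent(id, registry)
  if (mode == "single") {
    out <- rbind(
      if (length(r1_ids)) data.frame(r1 = r1_ids, r2 = 0L),
      if (length(r2_ids)) data.frame(r1 = 0L, r2 = r2_ids)
    )
  } else {
    out <- expand.grid(r2 = r2_ids, r1 = r1_ids)[, c("r1", "r2")]
  }
  if (is.null(out) || nrow(out) == 0) {
    return(data.frame(code = character(0), r1 = integer(0), r2 = integer(0),
                      stringsAsFactors = FALSE))
  }
  out$code <- analog_code(out$r1, out$r2)
  out <- unique(out[order(out$code), c("code", "r1", "r2")])
  rownames(out) <- NULL
  out
}

# scaffold: 1-methylpyridinium-2-aldoxime. Substitution sites are the ring
# carbons ortho (<R2>) and para (<R1>) to the aldoxime-bearing carbon.
pam_scaffold_template <- function() "C[n+]1c(/C=N/O)c(<R2>)cc(<R1>)c1"

#' SMILES for 2-PAM and its substituted analogs
#'
#' Grafts registry fragments onto the 1-methylpyridinium-2-aldoxime scaffold
#' at the ring carbons ortho (`R2`) and para (`R1`) to the aldoxime carbon.
#' The construction is a deterministic string graft; set
#' `canonical = TRUE` to canonicalize through the RDKit bridge (requires a
#' python interpreter with rdkit on the PATH, see [rdkit_available()]).
#'
#' @param analog an analog code string (e.g. `"3-1"`) or a list/row with
#'   elements `r1`, `r2`.
#' @param registry substituent registry.
#' @param canonical canonicalize the result with RDKit.
#' @return a single SMILES string.
#' @export
#' @examples
#' build_smiles("0-0")  # parent 2-PAM
#' build_smiles("3-1")  # phenyl at para, methyl at ortho
build_smiles <- function(analog, registry = default_registry(),
                         canonical = FALSE) {
  if (is.character(analog)) analog <- parse_analog_code(analog)
  r1 <- as.integer(analog$r1)
  r2 <- as.integer(analog$r2)
  graft <- function(id) {
    if (id == 0L) return("")
    frag <- lookup_substituent(id, registry)$fragment
    if (!nzchar(frag)) stop("structure error: empty fragment")
    frag
  }
  smi <- pam_scaffold_template()
  smi <- sub("<R1>", graft(r1), smi, fixed = TRUE)
  smi <- sub("<R2>", graft(r2), smi, fixed = TRUE)
  # drop empty branch parens left by unsubstituted sites
  smi <- gsub("()", "", smi, fixed = TRUE)
  if (canonical) smi <- canonical_smiles(smi)
  smi
}

#' Build an analog table with SMILES
#'
#' Convenience wrapper: enumerate analogs and attach grafted SMILES.
#'
#' @inheritParams enumerate_analogs
#' @param canonical canonicalize SMILES through the RDKit bridge.
#' @return data.frame with columns `code`, `r1`, `r2`, `smiles`.
#' @export
analog_table <- function(r1_ids, r2_ids, mode = c("single", "combined"),
                         registry = default_registry(), canonical = FALSE) {
  tab <- enumerate_analogs(r1_ids, r2_ids, mode, registry)
  tab$smiles <- vapply(seq_len(nrow(tab)), function(i) {
    build_smiles(list(r1 = tab$r1[i], r2 = tab$r2[i]), registry,
                 canonical = canonical)
  }, character(1))
  tab
}
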