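## RDKit subprocess bridge ----------------------------------------------------

the <- new.env(parent = emptyenv())

find_python <- function() {
  if (!is.null(the$python)) return(the$python)
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) {
      the$python <- unname(p)
      return(the$python)
    }
  }
  stop("no python interpreter found on PATH (needed for the RDKit bridge)")
}

rdkit_call <- function(lines, mode) {
  script <- system.file("python", "rdkit_bridge.py", package = "oximescreen")
  if (!nzchar(script)) stop("rdkit_bridge.py not found in installed package")
  out <- suppressWarnings(
    system2(find_python(), args = c(shQuote(script), mode),
            input = lines, stdout = TRUE, stderr = FALSE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("RDKit bridge failed (is rdkit importable from python?)")
  }
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyDataFrame = TRUE)
}

#' Is the RDKit python bridge available?
#'
#' Descriptor computation and SMILES canonicalization are delegated to RDKit
#' through a python subprocess. This probes that the bridge works.
#'
#' @return logical scalar.
#' @export
rdkit_available <- function() {
  if (!is.null(the$rdkit_ok)) return(the$rdkit_ok)
  ok <- tryCatch({
    res <- rdkit_call("C", "canonical")
    identical(res$canonical, "C")
  }, error = function(e) FALSE)
  the$rdkit_ok <- ok
  ok
}

#' Canonicalize SMILES through RDKit
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  res <- rdkit_call(smiles, "canonical")
  if (!is.null(res$error) && any(!is.na(res$error))) {
    bad <- res$smiles[!is.na(res$error)]
    stop("parse error: unparseable SMILES: ", paste(bad, collapse = ", "))
  }
  res$canonical[match(smiles, res$smiles)]
}

#' Substructure match through RDKit
#'
#' @param smiles SMILES of the molecule.
#' @param smarts SMARTS (or SMILES) pattern.
#' @return logical scalar.
#' @export
has_substructure <- function(smiles, smarts) {
  res <- rdkit_call(paste(smiles, smarts, sep = "\t"), "substruct")
  if (!is.null(res$error) && any(!is.na(res$error))) {
    stop("parse error in substructure query")
  }
  isTRUE(res$match[1])
}

## Descriptor profiles --------------------------------------------------------

#' Default blood-brain-barrier permeation surrogate
#'
#' A deterministic threshold stand-in for empirical BBB classifiers: a
#' molecule is called permeant when `psa <= 79` (angstrom squared) and
#' `0.4 <= clogp <= 6`. Intended as a documented, reproducible rule; ingested
#' experimental/external BBB calls override it.
#'
#' @param profile data.frame with columns `psa` and `clogp`.
#' @return logical vector.
#' @export
bbb_surrogate <- function(profile) {
  profile$psa <= 79 & profile$clogp >= 0.4 & profile$clogp <= 6
}

#' Compute physicochemical descriptor profiles
#'
#' Delegates molecular-weight, H-bond donor/acceptor counts, rotatable bonds,
#' Crippen logP, topological polar surface area and heavy-atom count to RDKit
#' through the python bridge. The `bbb_permeant` column is filled by the
#' surrogate rule in [bbb_surrogate()] (override by supplying your own
#' `bbb_rule`, or by ingesting an external descriptor table with
#' [read_descriptor_table()]).
#'
#' @param smiles character vector of SMILES.
#' @param bbb_rule function mapping the descriptor data.frame to a logical
#'   vector.
#' @return data.frame with columns `smiles`, `mw`, `hbd`, `hba`,
#'   `rotatable_bonds`, `clogp`, `psa`, `heavy_atoms`, `bbb_permeant`.
#' @export
#' @examples
#' \dontrun{compute_descriptors("c1ccccc1")}
compute_descriptors <- function(smiles, bbb_rule = bbb_surrogate) {
  res <- rdkit_call(smiles, "descriptors")
  if (!is.null(res$error) && any(!is.na(res$error))) {
    bad <- res$smiles[!is.na(res$error)]
    stop("parse error: unparseable SMILES: ", paste(bad, collapse = ", "))
  }
  res <- res[match(smiles, res$smiles),
             c("smiles", "mw", "hbd", "hba", "rotatable_bonds", "clogp",
               "psa", "heavy_atoms")]
  res$bbb_permeant <- bbb_rule(res)
  rownames(res) <- NULL
  res
}

## CNS drug-likeness filter ---------------------------------------------------

#' CNS drug-likeness criteria
#'
#' Threshold set for orally active, CNS-penetrant reactivator candidates:
#' molecular weight at most 450 Da, at most 7 H-bond donors and 3 acceptors,
#' cLogP at most 5, polar surface area at most 70 (the permissive end of the
#' quoted 60--70 range), heavy-atom count between 12 and 30, and BBB
#' permeation. All bounds are inclusive and individually configurable. Note
#' the donor/acceptor bounds are deliberately kept as printed in the source
#' screening protocol (7 donors / 3 acceptors), not the conventional CNS
#' 3/7 swap.
#'
#' @param mw_max,hbd_max,hba_max,clogp_max,psa_max numeric upper bounds.
#' @param heavy_min,heavy_max heavy-atom count range.
#' @param require_bbb require the BBB-permeant flag.
#' @return list of class `cns_criteria`.
#' @export
cns_criteria <- function(mw_max = 450, hbd_max = 7, hba_max = 3,
                         clogp_max = 5, psa_max = 70,
                         heavy_min = 12, heavy_max = 30,
                         require_bbb = TRUE) {
  stopifnot(heavy_min <= heavy_max)
  structure(list(mw_max = mw_max, hbd_max = hbd_max, hba_max = hba_max,
                 clogp_max = clogp_max, psa_max = psa_max,
                 heavy_min = heavy_min, heavy_max = heavy_max,
                 require_bbb = require_bbb),
            class = "cns_criteria")
}

# fixed reporting order of criterion names
cns_criterion_names <- function() {
  c("mw_max", "hbd_max", "hba_max", "clogp_max", "psa_max",
    "heavy_min", "heavy_max", "bbb")
}

#' Apply the CNS drug-likeness filter
#'
#' A profile passes iff every criterion holds, with inclusive bounds
#' (\code{<=} for maxima, \code{>=} for minima). Violations are listed in a
#' fixed criterion order. Verdicts do not depend on the order of the input
#' rows.
#'
#' @param profiles data.frame of descriptor profiles; a `code` column is
#'   carried through if present (otherwise row numbers are used).
#' @param criteria a [cns_criteria()] object.
#' @return data.frame with columns `code`, `passed` and `violations`
#'   (list column of character vectors; `passed` is `TRUE` iff the
#'   corresponding violation set is empty).
#' @export
apply_cns_filter <- function(profiles, criteria = cns_criteria()) {
  stopifnot(inherits(criteria, "cns_criteria"))
  code <- if ("code" %in% names(profiles)) as.character(profiles$code)
          else as.character(seq_len(nrow(profiles)))
  checks <- cbind(
    mw_max    = profiles$mw    <= criteria$mw_max,
    hbd_max   = profiles$hbd   <= criteria$hbd_max,
    hba_max   = profiles$hba   <= criteria$hba_max,
    clogp_max = profiles$clogp <= criteria$clogp_max,
    psa_max   = profiles$psa   <= criteria$psa_max,
    heavy_min = profiles$heavy_atoms >= criteria$heavy_min,
    heavy_max = profiles$heavy_atoms <= criteria$heavy_max,
    bbb       = if (criteria$require_bbb) as.logical(profiles$bbb_permeant)
                else rep(TRUE, nrow(profiles))
  )
  violations <- lapply(seq_len(nrow(profiles)), function(i) {
    cns_criterion_names()[!checks[i, ]]
  })
  out <- data.frame(code = code, passed = lengths(violations) == 0,
                    stringsAsFactors = FALSE)
  out$violations <- violations
  out
}

#' Read an ingested descriptor table
#'
#' Reads a CSV mirroring the layout of an external descriptor export:
#' columns `code`, `mw`, `hbd`, `hba`, `rotatable_bonds`, `clogp`, `psa`,
#' `heavy_atoms` and `bbb_permeant` (0/1 or logical). Unicode minus signs
#' are normalized to ASCII.
#'
#' @param path CSV path.
#' @return descriptor data.frame.
#' @export
read_descriptor_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- setdiff(names(tab), c("code", "bbb_permeant"))
  for (cl in num) tab[[cl]] <- normalize_minus(tab[[cl]])
  tab$bbb_permeant <- as.logical(tab$bbb_permeant)
  tab
}

# normalize Unicode minus / en-dash to ASCII and coerce numeric
normalize_minus <- function(x) {
  if (is.numeric(x)) return(x)
  as.numeric(gsub("−|–", "-", trimws(x)))
}

#' Write filter verdicts to CSV
#'
#' @param verdicts output of [apply_cns_filter()].
#' @param path CSV path.
#' @export
write_verdicts <- function(verdicts, path) {
  flat <- data.frame(
    code = verdicts$code, passed = verdicts$passed,
    violations = vapply(verdicts$violations, paste, character(1),
                        collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}
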