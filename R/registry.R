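#' Substituent registry for EDG-substituted pyridinium-aldoxime analogs
#'
#' The screening design decorates the 1-methylpyridinium-2-aldoxime (2-PAM)
#' scaffold with electron-donating groups (EDGs) at two ring positions. The
#' registry holds nine EDGs partitioned into three donor-strength classes:
#' three weak, two moderate and four strong. Identities 1--3 (methyl,
#' 2-methyl-2-butene, phenyl) are the weak donors named explicitly in the
#' design; ids 4--9 are clearly flagged placeholder common EDGs
#' (`authoritative = FALSE`) because their identities live in supplementary
#' material that is not distributed with the package. All enumeration and
#' counting logic is independent of fragment identity.
#'
#' Fragment SMILES must use ring-closure digits 2--9 only; digit 1 is
#' reserved for the scaffold ring.
#'
#' @return A `data.frame` with columns `id` (integer 1--9), `label`,
#'   `strength` (`"weak"`, `"moderate"`, `"strong"`), `fragment` (SMILES
#'   fragment grafted at a ring carbon) and `authoritative` (logical).
#' @export
#' @examples
#' reg <- default_registry()
#' table(reg$strength)
default_registry <- function() {
  reg <- data.frame(
    id = 1:9,
    label = c("methyl", "2-methyl-2-butene", "phenyl",
              "acetamido", "acetoxy",
              "hydroxy", "methoxy", "amino", "dimethylamino"),
    strength = c("weak", "weak", "weak",
                 "moderate", "moderate",
                 "strong", "strong", "strong", "strong"),
    fragment = c("C", "C(C)=C(C)C", "c2ccccc2",
                 "NC(C)=O", "OC(C)=O",
                 "O", "OC", "N", "N(C)C"),
    authoritative = c(TRUE, TRUE, TRUE, rep(FALSE, 6)),
    stringsAsFactors = FALSE
  )
  validate_registry(reg)
  reg
}

#' Validate a substituent registry
#'
#' @param reg data.frame with columns id, label, strength, fragment,
#'   authoritative.
#' @return The registry, invisibly, after validation.
#' @export
validate_registry <- function(reg) {
  required <- c("id", "label", "strength", "fragment", "authoritative")
  if (!all(required %in% names(reg))) {
    stop("registry error: missing columns: ",
         paste(setdiff(required, names(reg)), collapse = ", "))
  }
  if (anyDuplicated(reg$id)) {
    stop("registry error: substituent ids must be unique")
  }
  if (!all(reg$strength %in% c("weak", "moderate", "strong"))) {
    stop("registry error: strength must be weak, moderate or strong")
  }
  # digit 1 is reserved for the scaffold ring closure
  if (any(grepl("1", reg$fragment, fixed = TRUE))) {
    stop("registry error: fragment SMILES may not use ring-closure digit 1")
  }
  invisible(reg)
}

#' Read / write a substituent registry as YAML
#'
#' The on-disk format is a YAML sequence of mappings with keys `id`, `label`,
#' `strength`, `fragment` and `authoritative`.
#'
#' @param path file path.
#' @return `read_registry()` returns a validated registry data.frame.
#' @export
read_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  reg <- do.call(rbind, lapply(raw, function(x) {
    data.frame(id = as.integer(x$id), label = as.character(x$label),
               strength = as.character(x$strength),
               fragment = as.character(x$fragment),
               authoritative = isTRUE(x$authoritative),
               stringsAsFactors = FALSE)
  }))
  validate_registry(reg)
  reg
}

#' @rdname read_registry
#' @param reg registry data.frame.
#' @export
write_registry <- function(reg, path) {
  validate_registry(reg)
  yaml::write_yaml(
    lapply(seq_len(nrow(reg)), function(i) {
      list(id = reg$id[i], label = reg$label[i], strength = reg$strength[i],
           fragment = reg$fragment[i], authoritative = reg$authoritative[i])
    }),
    path)
  invisible(path)
}

lookup_substituent <- function(id, registry) {
  i <- match(id, registry$id)
  if (is.na(i)) {
    stop(sprintf("registry error: unknown substituent id %s", id))
  }
  registry[i, , drop = FALSE]
}
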