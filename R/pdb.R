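# Minimal fixed-width PDB coordinate I/O.
#
# Only ATOM/HETATM coordinate records and MODEL/ENDMDL framing are handled;
# this is deliberate -- the pose screen needs coordinates and names, nothing
# else, and no PDB-parsing package ships with the supported tool stack.
# Column layout follows the PDB v3.3 fixed-width convention. Alternate
# locations beyond the first (' ' or 'A') are dropped.

#' Read ATOM/HETATM records from a PDB file
#'
#' @param path PDB file path.
#' @return data.frame with columns `model` (NA when the file has no MODEL
#'   records), `serial`, `name`, `altloc`, `resname`, `chain`, `resseq`,
#'   `x`, `y`, `z`.
#' @export
read_pdb_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_id <- NA_integer_
  out <- vector("list", length(lines))
  n <- 0L
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (startsWith(r, "MODEL")) {
      model_id <- suppressWarnings(as.integer(substr(lines[i], 11, 14)))
    } else if (startsWith(r, "ENDMDL")) {
      model_id <- NA_integer_
    } else if (r == "ATOM  " || r == "HETATM") {
      ln <- lines[i]
      altloc <- substr(ln, 17, 17)
      if (!altloc %in% c(" ", "", "A")) next
      n <- n + 1L
      out[[n]] <- data.frame(
        model = model_id,
        serial = suppressWarnings(as.integer(substr(ln, 7, 11))),
        name = trimws(substr(ln, 13, 16)),
        altloc = altloc,
        resname = trimws(substr(ln, 18, 20)),
        chain = substr(ln, 22, 22),
        resseq = suppressWarnings(as.integer(substr(ln, 23, 26))),
        x = as.numeric(substr(ln, 31, 38)),
        y = as.numeric(substr(ln, 39, 46)),
        z = as.numeric(substr(ln, 47, 54)),
        stringsAsFactors = FALSE)
    }
  }
  if (n == 0L) {
    stop(sprintf("no ATOM/HETATM records found in '%s'", path))
  }
  atoms <- do.call(rbind, out[seq_len(n)])
  # models that ended before any MODEL record keep NA; if the file mixes
  # both, assign the pre-MODEL atoms to model NA as read.
  atoms
}

pdb_atom_line <- function(serial, name, resname, chain, resseq, xyz,
                          hetatm = TRUE) {
  sprintf("%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          if (hetatm) "HETATM" else "ATOM", serial,
          substr(name, 1, 4), substr(resname, 1, 3), chain, resseq,
          xyz[1], xyz[2], xyz[3])
}

#' Write a multi-MODEL PDB of attack-triplet poses
#'
#' Each pose becomes one MODEL holding three HETATM records named to match
#' the default [atom_selector()]: the ligand oxime oxygen (`LIG`/`O1`), the
#' adduct phosphorus (`POX`/`P`) and the serine hydroxyl oxygen
#' (`SER`/`OG`). Coordinates are written at PDB precision (1e-3 angstrom).
#'
#' @param triplets list of poses; each pose is a list with length-3 numeric
#'   elements `o_oxime`, `p_paraoxon`, `o_serine`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pose_pdb <- function(triplets, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(triplets)) {
    tp <- triplets[[i]]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(pdb_atom_line(1L, "O1", "LIG", "A", 1L, tp$o_oxime), con)
    writeLines(pdb_atom_line(2L, "P", "POX", "A", 2L, tp$p_paraoxon), con)
    writeLines(pdb_atom_line(3L, "OG", "SER", "A", 3L, tp$o_serine), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
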