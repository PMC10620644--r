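#' Apical (near-attack) conformation criteria
#'
#' A reactivator pose is "apical" when its oxime oxygen sits within `d_max`
#' of the adduct phosphorus (strict bound, as in the screening protocol) and
#' the attack angle theta_OPO lies in `(theta_min, theta_max]`. The upper
#' bound is inclusive so that the ideal in-line geometry of exactly 180
#' degrees counts as apical; that boundary is only attainable as a limit and
#' excluding it would be unintended.
#'
#' @param d_max maximum oxime-O to P distance, angstrom (strict `<`).
#' @param theta_min,theta_max attack-angle zone in degrees
#'   (`theta_min < theta <= theta_max`).
#' @return list of class `apical_criteria`.
#' @export
apical_criteria <- function(d_max = 8, theta_min = 120, theta_max = 180) {
  stopifnot(d_max > 0, theta_min < theta_max)
  structure(list(d_max = d_max, theta_min = theta_min,
                 theta_max = theta_max),
            class = "apical_criteria")
}

#' Near-attack geometry of an attack triplet
#'
#' Given coordinates of the oxime oxygen, the adduct phosphorus and the
#' catalytic-serine hydroxyl oxygen, computes the approach distance `d_op`
#' (Euclidean O...P distance, angstrom) and the attack angle `theta_opo`
#' (angle at the phosphorus vertex between the rays towards the two oxygens,
#' degrees in \[0, 180\]).
#'
#' @param o_oxime,p_paraoxon,o_serine numeric length-3 coordinate vectors
#'   (angstrom).
#' @return list with elements `d_op` and `theta_opo`.
#' @export
#' @examples
#' compute_geometry(c(0, 0, 0), c(3, 4, 0), c(6, 8, 0))  # d 5, theta 180
compute_geometry <- function(o_oxime, p_paraoxon, o_serine) {
  stopifnot(length(o_oxime) == 3, length(p_paraoxon) == 3,
            length(o_serine) == 3)
  u <- o_oxime - p_paraoxon
  v <- o_serine - p_paraoxon
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu < 1e-9 || nv < 1e-9 || sqrt(sum((o_oxime - o_serine)^2)) < 1e-9) {
    stop("degenerate geometry: coincident points in attack triplet")
  }
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  list(d_op = nu, theta_opo = acos(cosang) * 180 / pi)
}

#' Classify a pose geometry as apical
#'
#' @param d_op approach distance, angstrom.
#' @param theta_opo attack angle, degrees.
#' @param criteria an [apical_criteria()] object.
#' @return logical vector: `d_op < d_max & theta_min < theta_opo <= theta_max`.
#' @export
classify_apical <- function(d_op, theta_opo, criteria = apical_criteria()) {
  stopifnot(inherits(criteria, "apical_criteria"))
  d_op < criteria$d_max &
    theta_opo > criteria$theta_min &
    theta_opo <= criteria$theta_max
}

#' Default atom selector for the attack triplet
#'
#' Atom selection is by (residue name, atom name) pairs, one per role.
#' Defaults match the pose files written by [make_pose_set()]; covalent
#' adduct naming varies across preparation pipelines, so override as needed.
#' A selector entry with `resname = NA` matches on atom name alone.
#'
#' @param o_oxime,p_paraoxon,o_serine lists with elements `resname`, `name`.
#' @return list of class `atom_selector`.
#' @export
atom_selector <- function(
    o_oxime    = list(resname = "LIG", name = "O1"),
    p_paraoxon = list(resname = "POX", name = "P"),
    o_serine   = list(resname = "SER", name = "OG")) {
  structure(list(o_oxime = o_oxime, p_paraoxon = p_paraoxon,
                 o_serine = o_serine),
            class = "atom_selector")
}

select_atom <- function(atoms, sel, role) {
  hit <- atoms$name == sel$name
  if (!is.null(sel$resname) && !is.na(sel$resname)) {
    hit <- hit & atoms$resname == sel$resname
  }
  n <- sum(hit)
  if (n == 0) stop(sprintf("selection error: no atom matches role '%s'", role))
  if (n > 1) {
    stop(sprintf("selection error: ambiguous match (%d atoms) for role '%s'",
                 n, role))
  }
  unlist(atoms[hit, c("x", "y", "z")], use.names = FALSE)
}

#' Screen pose files for apical conformations
#'
#' Reads each PDB file, enumerates poses (one per MODEL record, or the whole
#' file when no MODEL records are present), extracts the attack triplet with
#' the selector, and classifies each pose. With `on_error = "keep"`
#' (default) poses whose atom selection fails are reported as rows with `NA`
#' geometry and the failure message in `status` rather than silently
#' dropped; with `on_error = "stop"` the first failure raises the selection
#' error.
#'
#' @param pdb_paths character vector of PDB file paths.
#' @param selector an [atom_selector()].
#' @param criteria an [apical_criteria()].
#' @param on_error `"keep"` or `"stop"`.
#' @return data.frame with columns `pose_id`, `d_op`, `theta_opo`, `apical`,
#'   `status` (`"ok"` or the selection error message).
#' @export
screen_poses <- function(pdb_paths, selector = atom_selector(),
                         criteria = apical_criteria(),
                         on_error = c("keep", "stop")) {
  on_error <- match.arg(on_error)
  rows <- list()
  for (path in pdb_paths) {
    atoms <- read_pdb_atoms(path)
    models <- if (all(is.na(atoms$model))) list(`1` = atoms)
              else split(atoms, atoms$model)
    multi <- length(models) > 1
    for (mod in names(models)) {
      pose_id <- if (multi) paste0(basename(path), "#", mod)
                 else basename(path)
      res <- tryCatch({
        g <- compute_geometry(
          select_atom(models[[mod]], selector$o_oxime, "o_oxime"),
          select_atom(models[[mod]], selector$p_paraoxon, "p_paraoxon"),
          select_atom(models[[mod]], selector$o_serine, "o_serine"))
        data.frame(pose_id = pose_id, d_op = g$d_op,
                   theta_opo = g$theta_opo,
                   apical = classify_apical(g$d_op, g$theta_opo, criteria),
                   status = "ok", stringsAsFactors = FALSE)
      }, error = function(e) {
        if (on_error == "stop") stop(e)
        data.frame(pose_id = pose_id, d_op = NA_real_,
                   theta_opo = NA_real_, apical = NA,
                   status = conditionMessage(e), stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows)) {
    return(data.frame(pose_id = character(0), d_op = numeric(0),
                      theta_opo = numeric(0), apical = logical(0),
                      status = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
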