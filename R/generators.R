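## Synthetic fixtures with known ground truth.
##
## Every generator here is deterministic given its seed and returns (or
## writes alongside its output) a machine-readable record of the ground
## truth it embedded, so consuming modules can be tested against
## by-construction answers. These tables are synthetic stand-ins; none of
## their values are measurements.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate an energy table with known pass counts
#'
#' Builds a Table-1-shaped energy table (`code, e_oniom2, d_b3lyp, d_mp2,
#' d_op` plus a reference row with exact zero deltas) in which exactly
#' `n_negative_mp2` analogs have `d_mp2 < 0` and exactly `n_below_b3lyp_cut`
#' analogs have `d_b3lyp <= b3lyp_cut`.
#'
#' @param n number of analog rows (reference excluded).
#' @param n_negative_mp2 analogs with strictly negative MP2-level delta.
#' @param n_below_b3lyp_cut analogs at or below `b3lyp_cut` at the B3LYP
#'   level.
#' @param seed RNG seed.
#' @param b3lyp_cut threshold for the B3LYP count (kcal/mol).
#' @param ref_code reference row code.
#' @return data.frame with attribute `"truth"` recording the requested
#'   counts.
#' @export
make_energy_table <- function(n, n_negative_mp2, n_below_b3lyp_cut, seed,
                              b3lyp_cut = -15, ref_code = "2-PAM") {
  if (n_negative_mp2 > n || n_below_b3lyp_cut > n ||
      n_negative_mp2 < 0 || n_below_b3lyp_cut < 0) {
    stop("generation error: infeasible count constraints")
  }
  with_seed(seed, {
    codes <- sprintf("syn-%02d", seq_len(n))
    d_mp2 <- c(stats::runif(n_negative_mp2, -45, -0.5),
               stats::runif(n - n_negative_mp2, 0.5, 25))
    d_b3lyp <- c(stats::runif(n_below_b3lyp_cut, b3lyp_cut - 20, b3lyp_cut),
                 stats::runif(n - n_below_b3lyp_cut, b3lyp_cut + 0.5, 25))
    perm <- sample.int(n)
    tab <- data.frame(
      code = codes,
      e_oniom2 = round(stats::runif(n, -4800, -4300), 2),
      d_b3lyp = round(d_b3lyp[perm], 2),
      d_mp2 = round(d_mp2[perm], 2),
      d_op = round(stats::runif(n, 2.9, 3.8), 2),
      stringsAsFactors = FALSE)
    # rounding must not move values across the count thresholds
    tab$d_mp2[tab$d_mp2 == 0] <- 0.5
    tab <- rbind(tab, data.frame(code = ref_code, e_oniom2 = -4292.53,
                                 d_b3lyp = 0, d_mp2 = 0, d_op = 4.42))
    stopifnot(count_below(tab, "d_mp2", 0, TRUE, ref_code) == n_negative_mp2,
              count_below(tab, "d_b3lyp", b3lyp_cut, FALSE, ref_code) ==
                n_below_b3lyp_cut)
    attr(tab, "truth") <- list(n = n, n_negative_mp2 = n_negative_mp2,
                               n_below_b3lyp_cut = n_below_b3lyp_cut,
                               b3lyp_cut = b3lyp_cut)
    tab
  })
}

# one attack triplet with prescribed (d, theta): random rigid placement
random_triplet <- function(d, theta) {
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  w <- stats::rnorm(3); w <- w - sum(w * u) * u; w <- w / sqrt(sum(w^2))
  p <- stats::runif(3, 5, 25)
  th <- theta * pi / 180
  list(o_oxime = p + d * (cos(th) * u + sin(th) * w),
       p_paraoxon = p,
       o_serine = p + 1.6 * u)
}

#' Generate a pose set with a known apical fraction
#'
#' Writes a multi-MODEL PDB of attack triplets, exactly `n_apical` of which
#' satisfy the apical criteria, and records the ground truth. Apical poses
#' are sampled with a safety margin inside the zone (and non-apical poses
#' outside it) so that PDB coordinate rounding (1e-3 angstrom) cannot flip a
#' classification; non-apical poses violate the distance bound, the angle
#' zone, or both. The boundary `d = d_max` itself is non-apical (strict
#' distance bound) and can only arise in the non-apical stratum.
#'
#' @param n total poses.
#' @param n_apical apical poses (`<= n`).
#' @param criteria an [apical_criteria()].
#' @param seed RNG seed.
#' @param path output PDB path.
#' @return list with `pdb` (the path) and `truth` (data.frame: `pose_id`,
#'   `d`, `theta`, `apical`).
#' @export
make_pose_set <- function(n, n_apical, criteria = apical_criteria(), seed,
                          path = tempfile(fileext = ".pdb")) {
  stopifnot(n_apical <= n, n >= 0)
  with_seed(seed, {
    apical <- sample(c(rep(TRUE, n_apical), rep(FALSE, n - n_apical)))
    margin_t <- 0.02 * (criteria$theta_max - criteria$theta_min)
    geoms <- lapply(apical, function(a) {
      if (a) {
        c(d = stats::runif(1, 2.5, criteria$d_max - 0.5),
          theta = stats::runif(1, criteria$theta_min + margin_t,
                               criteria$theta_max - margin_t))
      } else {
        kind <- sample(c("far", "side", "both"), 1)
        d <- if (kind == "side") stats::runif(1, 2.5, criteria$d_max - 0.5)
             else stats::runif(1, criteria$d_max, criteria$d_max + 4)
        theta <- if (kind == "far")
          stats::runif(1, criteria$theta_min + margin_t,
                       criteria$theta_max - margin_t)
        else stats::runif(1, 10, criteria$theta_min - margin_t)
        c(d = d, theta = theta)
      }
    })
    triplets <- lapply(geoms, function(g) random_triplet(g["d"], g["theta"]))
    write_pose_pdb(triplets, path)
    truth <- data.frame(
      pose_id = paste0(basename(path), "#", seq_len(n)),
      d = vapply(geoms, `[[`, numeric(1), "d"),
      theta = vapply(geoms, `[[`, numeric(1), "theta"),
      apical = apical, stringsAsFactors = FALSE)
    list(pdb = path, truth = truth)
  })
}

#' Generate an interaction matrix with a known consensus set
#'
#' Builds a 0/1 analog-by-residue matrix in which the residues of
#' `consensus_set` are present in at least `fraction` of the rows and every
#' other residue strictly below that fraction, so that
#' [consensus_residues()] recovers exactly `consensus_set`.
#'
#' @param analogs character vector of analog codes (rows).
#' @param residues character vector of residue labels (columns).
#' @param consensus_set subset of `residues` to plant as the consensus.
#' @param fraction consensus fraction in (0, 1].
#' @param seed RNG seed.
#' @return 0/1 matrix with dimnames.
#' @export
make_interaction_matrix <- function(analogs, residues, consensus_set,
                                    fraction = 0.5, seed = 1) {
  stopifnot(all(consensus_set %in% residues), fraction > 0, fraction <= 1)
  n <- length(analogs)
  if (n == 0) stop("generation error: no analog rows")
  lo <- ceiling(fraction * n)            # minimum count to reach consensus
  hi_non <- ceiling(fraction * n) - 1    # maximum strictly-below count
  if (length(setdiff(residues, consensus_set)) > 0 && hi_non < 0) {
    stop("generation error: non-consensus residues cannot stay below ",
         "the consensus fraction with ", n, " rows")
  }
  resample <- function(x) x[sample.int(length(x), 1)]  # scalar-safe sample
  with_seed(seed, {
    m <- matrix(0L, n, length(residues),
                dimnames = list(analogs, residues))
    for (r in residues) {
      cnt <- if (r %in% consensus_set) resample(lo:n)
             else resample(0:hi_non)
      if (cnt > 0) m[sample.int(n, cnt), r] <- 1L
    }
    stopifnot(setequal(consensus_residues(m, fraction), consensus_set))
    m
  })
}

#' Generate a synthetic descriptor table with a known pass count
#'
#' Stand-in for an external descriptor export: builds descriptor profiles
#' for the given analog codes in which exactly the `pass_codes` satisfy
#' every CNS criterion (inclusive bounds) and every other row violates at
#' least one randomly chosen criterion. Values are drawn uniformly within
#' (or beyond) the criterion bounds. All values are synthetic; none are
#' measurements of real analogs.
#'
#' @param codes character vector of analog codes.
#' @param pass_codes subset of `codes` that must pass the filter.
#' @param criteria a [cns_criteria()].
#' @param seed RNG seed.
#' @return descriptor data.frame with a `code` column.
#' @export
make_descriptor_table <- function(codes, pass_codes,
                                  criteria = cns_criteria(), seed = 1) {
  stopifnot(all(pass_codes %in% codes))
  with_seed(seed, {
    n <- length(codes)
    tab <- data.frame(
      code = codes,
      mw = round(stats::runif(n, 137, criteria$mw_max), 2),
      hbd = sample(0:criteria$hbd_max, n, replace = TRUE),
      hba = sample(1:criteria$hba_max, n, replace = TRUE),
      rotatable_bonds = sample(0:6, n, replace = TRUE),
      clogp = round(stats::runif(n, 0.5, criteria$clogp_max), 2),
      psa = round(stats::runif(n, 20, criteria$psa_max), 2),
      heavy_atoms = sample(criteria$heavy_min:criteria$heavy_max, n,
                           replace = TRUE),
      bbb_permeant = TRUE,
      stringsAsFactors = FALSE)
    fail <- !(codes %in% pass_codes)
    breaker <- sample(c("mw", "hbd", "hba", "clogp", "psa", "heavy", "bbb"),
                      sum(fail), replace = TRUE)
    k <- which(fail)
    for (j in seq_along(k)) {
      i <- k[j]
      switch(breaker[j],
             mw = { tab$mw[i] <- criteria$mw_max + round(stats::runif(1, 1, 150), 2) },
             hbd = { tab$hbd[i] <- criteria$hbd_max + sample(1:3, 1) },
             hba = { tab$hba[i] <- criteria$hba_max + sample(1:4, 1) },
             clogp = { tab$clogp[i] <- criteria$clogp_max + round(stats::runif(1, 0.5, 3), 2) },
             psa = { tab$psa[i] <- criteria$psa_max + round(stats::runif(1, 1, 40), 2) },
             heavy = { tab$heavy_atoms[i] <- criteria$heavy_max + sample(1:8, 1) },
             bbb = { tab$bbb_permeant[i] <- FALSE })
    }
    verdict <- apply_cns_filter(tab, criteria)
    stopifnot(setequal(verdict$code[verdict$passed], pass_codes))
    tab
  })
}
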