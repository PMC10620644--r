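#' Two-layer subtractive (ONIOM2) energy combination
#'
#' The target high-level energy of the full (real) system is extrapolated
#' from three tractable calculations:
#' `E_high(real) ~ E_high(model) + E_low(real) - E_low(model)`,
#' where "model" is the chemically interesting inner layer and "low" the
#' cheap method applied to everything.
#'
#' @param e_high_model,e_low_real,e_low_model energies in kcal/mol
#'   (vectorized).
#' @return extrapolated energy in kcal/mol.
#' @export
#' @examples
#' oniom2_energy(-10, -100, -5)  # -105
oniom2_energy <- function(e_high_model, e_low_real, e_low_model) {
  vals <- c(e_high_model, e_low_real, e_low_model)
  if (!all(is.finite(vals))) {
    stop("numeric error: non-finite ONIOM2 component")
  }
  e_high_model + e_low_real - e_low_model
}

#' Read an energy table (Table-1 layout)
#'
#' CSV with header `code, e_oniom2, d_b3lyp, d_mp2, d_op`. Unicode minus
#' signs are normalized to ASCII on ingestion. The packaged fixture
#' `system.file("extdata", "table1.csv", package = "oximescreen")`
#' transcribes the published screening table: ONIOM2
#' (B3LYP/6-31G*:UFF) binding energies, single-point PCM-ONIOM2 energy
#' differences vs the 2-PAM reference at the B3LYP/6-31G*:PM7 and
#' MP2/6-31G*:PM7 levels, and the approach distance d_OP.
#'
#' @param path CSV path; default is the packaged fixture.
#' @return data.frame.
#' @export
read_energy_table <- function(path = system.file("extdata", "table1.csv",
                                                 package = "oximescreen")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cl in setdiff(names(tab), "code")) {
    tab[[cl]] <- normalize_minus(tab[[cl]])
  }
  if (anyDuplicated(tab$code)) stop("energy table: duplicate analog codes")
  tab
}

#' Energy differences against a reference row
#'
#' Adds one `delta_<col>` column per requested energy column, with
#' `delta(analog) = E(analog) - E(reference)`; the reference row gets an
#' exact zero.
#'
#' @param table energy data.frame with a `code` column.
#' @param ref_code code of the reference row.
#' @param cols columns to difference.
#' @return the table with delta columns appended.
#' @export
delta_vs_reference <- function(table, ref_code = "2-PAM",
                               cols = "e_oniom2") {
  i <- match(ref_code, table$code)
  if (is.na(i)) stop(sprintf("lookup error: reference '%s' not in table",
                             ref_code))
  missing <- setdiff(cols, names(table))
  if (length(missing)) {
    stop("schema error: unknown column(s): ", paste(missing, collapse = ", "))
  }
  for (cl in cols) {
    d <- table[[cl]] - table[[cl]][i]
    d[i] <- 0
    table[[paste0("delta_", cl)]] <- d
  }
  table
}

#' Count analogs below an energy threshold
#'
#' Counts rows, excluding the reference row, whose `column` value is below
#' `threshold` -- strictly (`<`) or inclusively (`<=`).
#'
#' @param table energy data.frame.
#' @param column column name.
#' @param threshold numeric threshold.
#' @param strict strict (`<`) or inclusive (`<=`) comparison.
#' @param ref_code reference code excluded from the count (set `NULL` to
#'   count all rows).
#' @return integer count.
#' @export
#' @examples
#' tab <- read_energy_table()
#' count_below(tab, "d_mp2", 0)              # 13 analogs better than 2-PAM
#' count_below(tab, "d_mp2", -15, strict = FALSE)  # 8
count_below <- function(table, column, threshold, strict = TRUE,
                        ref_code = "2-PAM") {
  if (!column %in% names(table)) {
    stop(sprintf("schema error: unknown column '%s'", column))
  }
  rows <- table
  if (!is.null(ref_code)) rows <- rows[rows$code != ref_code, , drop = FALSE]
  v <- rows[[column]]
  if (strict) sum(v < threshold) else sum(v <= threshold)
}

#' Quartile-based candidate selection on docking scores
#'
#' Scores are ranked by affinity ascending (most negative = most favorable =
#' rank 1) with ties broken by code for determinism. Ranks are split into
#' empirical quartiles at n/4, n/2 and 3n/4; members whose rank exceeds
#' 3n/4 fall in Q4 (least favorable) and are dropped -- unless tied with the
#' Q3/Q4 boundary value, in which case they are kept (only scores strictly
#' worse than the boundary are dropped). With all scores equal, everything
#' is kept.
#'
#' @param scores data.frame with columns `code` and `affinity` (kcal/mol,
#'   more negative = more favorable). At least 4 scores are required.
#' @return list with elements `kept` (character codes), `dropped`, and
#'   `table` (the scored table with `rank` and `quartile` columns).
#' @export
quartile_select <- function(scores) {
  n <- nrow(scores)
  if (n < 4) stop("size error: quartile selection needs at least 4 scores")
  ord <- order(scores$affinity, scores$code)
  tab <- scores[ord, , drop = FALSE]
  tab$rank <- seq_len(n)
  tab$quartile <- cut(tab$rank, breaks = c(0, n / 4, n / 2, 3 * n / 4, n),
                      labels = c("Q1", "Q2", "Q3", "Q4"))
  boundary_rank <- max(tab$rank[tab$rank <= 3 * n / 4])
  boundary_value <- tab$affinity[boundary_rank]
  drop <- tab$rank > 3 * n / 4 & tab$affinity > boundary_value
  rownames(tab) <- NULL
  list(kept = tab$code[!drop], dropped = tab$code[drop], table = tab)
}

#' Rank analogs and report energy/geometry extremes
#'
#' Ranks the analog rows (reference excluded) by the MP2-level energy
#' difference ascending, ties broken by code, and reports the minimum /
#' maximum of the ONIOM2 energy and of the approach distance over analogs.
#'
#' @param table energy data.frame (Table-1 layout).
#' @param ref_code reference code to exclude from ranking and extremes.
#' @param rank_col column to rank by (ascending).
#' @return list with `ranking` (data.frame) and `extremes` (named list with
#'   `e_oniom2_min`, `e_oniom2_max`, `d_op_min`, `d_op_max`).
#' @export
rank_and_extremes <- function(table, ref_code = "2-PAM",
                              rank_col = "d_mp2") {
  if (!nrow(table)) stop("empty table")
  analogs <- if (!is.null(ref_code) && ref_code %in% table$code) {
    table[table$code != ref_code, , drop = FALSE]
  } else table
  ord <- order(analogs[[rank_col]], analogs$code)
  ranking <- analogs[ord, , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  list(
    ranking = ranking,
    extremes = list(
      e_oniom2_min = min(analogs$e_oniom2),
      e_oniom2_max = max(analogs$e_oniom2),
      d_op_min = min(analogs$d_op),
      d_op_max = max(analogs$d_op)
    )
  )
}

#' HOMO-LUMO gap difference
#'
#' Difference between a reference frontier-orbital gap and an analog's gap
#' (kcal/mol); positive when the analog's gap is narrower, i.e. the analog
#' is the softer nucleophile.
#'
#' @param ref_gap,analog_gap positive gaps in kcal/mol.
#' @return `ref_gap - analog_gap` (sign preserved).
#' @export
#' @examples
#' gap_difference(246.74, 220.57)  # 26.17
gap_difference <- function(ref_gap, analog_gap) {
  stopifnot(ref_gap > 0, analog_gap > 0)
  ref_gap - analog_gap
}
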