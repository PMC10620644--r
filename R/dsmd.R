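#' DS-MD configuration
#'
#' Distance-based selection MD runs a fixed number of fixed-length cycles;
#' each cycle restarts from the frame of the previous cycle with the
#' smallest ligand-target distance. Defaults mirror the published protocol:
#' 100 cycles of 100 frames (the toy analog of 100 ps at 1 frame/ps), three
#' independent replicates, and a 30-cycle burn-in excluded from downstream
#' model building.
#'
#' @param n_cycles cycles per replicate.
#' @param steps_per_cycle propagation steps (frames beyond frame 0) per
#'   cycle.
#' @param n_replicates independent replicates.
#' @param burn_in_cycles cycles discarded before MSM estimation
#'   (`burn_in_cycles < n_cycles`).
#' @param master_seed integer master seed; every per-cycle seed is derived
#'   from it deterministically.
#' @return list of class `dsmd_config`.
#' @export
dsmd_config <- function(n_cycles = 100, steps_per_cycle = 100,
                        n_replicates = 3, burn_in_cycles = 30,
                        master_seed = 1) {
  stopifnot(n_cycles >= 1, steps_per_cycle >= 1, n_replicates >= 1,
            burn_in_cycles >= 0, burn_in_cycles < n_cycles)
  structure(list(n_cycles = as.integer(n_cycles),
                 steps_per_cycle = as.integer(steps_per_cycle),
                 n_replicates = as.integer(n_replicates),
                 burn_in_cycles = as.integer(burn_in_cycles),
                 master_seed = as.integer(master_seed)),
            class = "dsmd_config")
}

#' Select the restart frame of a segment
#'
#' Returns the earliest frame attaining the minimum of the selection metric
#' (the ligand-target distance `d` by default). Frames are numbered from 0,
#' frame 0 being the segment's input state.
#'
#' @param segment propagator output (list with `states` and `obs`) or a
#'   bare observable matrix.
#' @param metric column name in `obs` (default `"d"`), or a function mapping
#'   the observable matrix to a numeric vector.
#' @return list with `frame` (0-based index) and `metric` (its value).
#' @export
#' @examples
#' seg <- list(obs = cbind(d = c(5, 4, 4, 6), theta = 0))
#' select_restart(seg)  # frame 1, metric 4
select_restart <- function(segment, metric = "d") {
  obs <- if (is.list(segment)) segment$obs else segment
  if (is.null(obs) || nrow(obs) == 0) {
    stop("size error: empty segment")
  }
  v <- if (is.function(metric)) metric(obs) else obs[, metric]
  i <- unname(which.min(v))  # which.min returns the earliest minimum
  list(frame = i - 1L, metric = unname(v[i]))
}

# deterministic per-(replicate, cycle) seed table derived from the master
# seed; values stay below 2^31.
dsmd_seed_table <- function(config) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$master_seed)
  matrix(sample.int(.Machine$integer.max - 1L,
                    config$n_replicates * config$n_cycles),
         nrow = config$n_replicates)
}

#' Run distance-based selection MD
#'
#' For each replicate, runs `n_cycles` propagation segments of
#' `steps_per_cycle` steps. The restart state of cycle `c + 1` is the state
#' of the earliest frame of cycle `c` with the smallest selection metric;
#' positions are inherited while stochastic degrees of freedom are re-drawn
#' under the new cycle seed (restarting with identical noise would merely
#' replay the segment). Because frame 0 of every segment reproduces the
#' restart state's observables, the per-cycle selected metric is
#' non-increasing within each replicate.
#'
#' @param propagator a propagator closure, e.g. [langevin_propagator()];
#'   contract: `propagator(state, n_steps, seed)` returns `states` and
#'   `obs` matrices of `n_steps + 1` rows with frame 0 equal to the input
#'   state.
#' @param initial_state starting state (shared by all replicates).
#' @param config a [dsmd_config()].
#' @param metric selection metric passed to [select_restart()].
#' @return object of class `dsmd_result`: list with `config`, `records`
#'   (data.frame: replicate, cycle, selected_frame, selected_metric, seed)
#'   and `series` (data.frame: replicate, cycle, frame, d, theta).
#' @export
run_dsmd <- function(propagator, initial_state, config = dsmd_config(),
                     metric = "d") {
  seeds <- dsmd_seed_table(config)
  records <- list()
  series <- list()
  for (rep_i in seq_len(config$n_replicates)) {
    state <- initial_state
    for (cyc in seq_len(config$n_cycles)) {
      seg <- tryCatch(
        propagator(state, config$steps_per_cycle, seeds[rep_i, cyc]),
        error = function(e) {
          stop(sprintf("propagation error in replicate %d, cycle %d: %s",
                       rep_i, cyc, conditionMessage(e)))
        })
      sel <- select_restart(seg, metric)
      state <- seg$states[sel$frame + 1L, ]
      records[[length(records) + 1L]] <- data.frame(
        replicate = rep_i, cycle = cyc, selected_frame = sel$frame,
        selected_metric = sel$metric, seed = seeds[rep_i, cyc])
      series[[length(series) + 1L]] <- data.frame(
        replicate = rep_i, cycle = cyc,
        frame = seq_len(nrow(seg$obs)) - 1L,
        d = seg$obs[, "d"], theta = seg$obs[, "theta"])
    }
  }
  structure(list(config = config,
                 records = do.call(rbind, records),
                 series = do.call(rbind, series)),
            class = "dsmd_result")
}

#' @export
print.dsmd_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "DS-MD result: %d replicate(s) x %d cycles x %d steps (seed %d)\n",
    cfg$n_replicates, cfg$n_cycles, cfg$steps_per_cycle, cfg$master_seed))
  fin <- tapply(x$records$selected_metric, x$records$replicate,
                function(v) v[length(v)])
  cat("final selected metric per replicate:",
      paste(sprintf("%.3f", fin), collapse = ", "), "\n")
  invisible(x)
}

#' Run a plain (un-selected) trajectory
#'
#' Baseline against which the selection scheme is assessed: one
#' uninterrupted segment of `total_steps` steps.
#'
#' @inheritParams run_dsmd
#' @param total_steps number of propagation steps.
#' @param seed RNG seed.
#' @return data.frame with columns `frame` (0-based), `d`, `theta`.
#' @export
run_plain <- function(propagator, initial_state, total_steps, seed) {
  stopifnot(total_steps > 0)
  seg <- propagator(initial_state, total_steps, seed)
  data.frame(frame = seq_len(nrow(seg$obs)) - 1L,
             d = seg$obs[, "d"], theta = seg$obs[, "theta"])
}

#' First passage into the apical zone
#'
#' Index (0-based, over the concatenated frame series) of the first frame
#' classified apical; `Inf` when the trajectory never reaches the zone.
#'
#' @param d,theta observable series.
#' @param criteria an [apical_criteria()].
#' @return numeric scalar (frame index or `Inf`).
#' @export
first_passage <- function(d, theta, criteria = apical_criteria()) {
  hit <- which(classify_apical(d, theta, criteria))
  if (!length(hit)) Inf else hit[1] - 1
}

#' Extract production segments from a DS-MD result
#'
#' Splits the observable series into contiguous per-cycle segments, dropping
#' burn-in cycles. Segment boundaries matter downstream: transition counting
#' must never bridge a selection restart.
#'
#' @param result a [run_dsmd()] result.
#' @param burn_in_cycles cycles to drop (default: from the result's config).
#' @return list of data.frames (one per retained cycle) with columns
#'   `d`, `theta`.
#' @export
dsmd_segments <- function(result, burn_in_cycles = NULL) {
  if (is.null(burn_in_cycles)) burn_in_cycles <- result$config$burn_in_cycles
  keep <- result$series[result$series$cycle > burn_in_cycles, , drop = FALSE]
  unname(split(keep[, c("d", "theta")],
               interaction(keep$replicate, keep$cycle, drop = TRUE)))
}

#' Write a DS-MD observable series to CSV
#'
#' @param result a [run_dsmd()] result.
#' @param path CSV path.
#' @export
write_dsmd_series <- function(result, path) {
  utils::write.csv(result$series, path, row.names = FALSE)
  invisible(path)
}
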