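#' Regular 2D grid over the (d, theta) plane
#'
#' Discretization grid for Markov-state-model estimation. Bins are
#' half-open `[lo, hi)` with the final bin closed, so a value at the exact
#' lower range edge falls in bin 1 and a value at the upper edge in the last
#' bin. Out-of-range values are clipped to the edge bins (with a count
#' warning at discretization time).
#'
#' @param d_range,theta_range coordinate ranges (angstrom, degrees).
#' @param n_d,n_theta bin counts (at least 2).
#' @return list of class `grid_spec`.
#' @export
grid_spec <- function(d_range = c(2, 10), theta_range = c(0, 180),
                      n_d = 30, n_theta = 30) {
  stopifnot(d_range[1] < d_range[2], theta_range[1] < theta_range[2],
            n_d >= 2, n_theta >= 2)
  structure(list(d_range = as.numeric(d_range),
                 theta_range = as.numeric(theta_range),
                 n_d = as.integer(n_d), n_theta = as.integer(n_theta)),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @param grid a `grid_spec`.
#' @return `n_states()`: total number of grid bins.
#' @export
n_states <- function(grid) grid$n_d * grid$n_theta

bin_1d <- function(x, range, n) {
  w <- (range[2] - range[1]) / n
  i <- floor((x - range[1]) / w) + 1
  i[x >= range[2]] <- n   # closed final bin
  clipped <- sum(i < 1 | i > n)
  i <- pmin(pmax(i, 1L), n)
  list(i = as.integer(i), clipped = clipped)
}

#' Discretize an observable series onto a grid
#'
#' @param d,theta observable series (equal length).
#' @param grid a [grid_spec()].
#' @return integer state-index series in `1..n_states(grid)` (column-major:
#'   `state = (i_theta - 1) * n_d + i_d`). Warns when out-of-range frames
#'   were clipped to edge bins.
#' @export
discretize <- function(d, theta, grid) {
  stopifnot(length(d) == length(theta), all(is.finite(d)),
            all(is.finite(theta)))
  bd <- bin_1d(d, grid$d_range, grid$n_d)
  bt <- bin_1d(theta, grid$theta_range, grid$n_theta)
  nclip <- bd$clipped + bt$clipped
  if (nclip > 0) {
    warning(sprintf("%d out-of-range frame coordinate(s) clipped to edge bins",
                    nclip))
  }
  (bt$i - 1L) * grid$n_d + bd$i
}

#' Bin indices and centers of grid states
#'
#' @param state integer state indices.
#' @param grid a [grid_spec()].
#' @return data.frame with `state`, `bin_d`, `bin_theta`, `d_center`,
#'   `theta_center`.
#' @export
state_bins <- function(state, grid) {
  bin_d <- ((state - 1L) %% grid$n_d) + 1L
  bin_theta <- ((state - 1L) %/% grid$n_d) + 1L
  wd <- diff(grid$d_range) / grid$n_d
  wt <- diff(grid$theta_range) / grid$n_theta
  data.frame(state = state, bin_d = bin_d, bin_theta = bin_theta,
             d_center = grid$d_range[1] + (bin_d - 0.5) * wd,
             theta_center = grid$theta_range[1] + (bin_theta - 0.5) * wt)
}

#' Count lagged transitions within contiguous segments
#'
#' Sliding-window counts of pairs `(x_t, x_{t+lag})`, taken within each
#' contiguous segment only: transitions never bridge a cycle restart or a
#' replicate boundary, because a selection jump is not dynamics. Segments
#' shorter than `lag + 1` contribute nothing (with a warning).
#'
#' @param segments list of integer state-index series (or a single vector).
#' @param lag lag time in frames (>= 1).
#' @param n integer: total number of states (rows/columns of the count
#'   matrix).
#' @return `n x n` count matrix.
#' @export
#' @examples
#' count_transitions(list(c(1, 1, 2, 2)), lag = 1, n = 2)
count_transitions <- function(segments, lag, n) {
  stopifnot(lag >= 1)
  if (!is.list(segments)) segments <- list(segments)
  counts <- matrix(0, n, n)
  short <- 0L
  for (s in segments) {
    s <- as.integer(s)
    len <- length(s)
    if (len <= lag) {
      short <- short + 1L
      next
    }
    from <- s[seq_len(len - lag)]
    to <- s[seq_len(len - lag) + lag]
    tt <- table(factor(from, levels = seq_len(n)),
                factor(to, levels = seq_len(n)))
    counts <- counts + unclass(tt)
  }
  if (short > 0) {
    warning(sprintf("%d segment(s) shorter than lag + 1 ignored", short))
  }
  dimnames(counts) <- NULL
  counts
}

#' Estimate a Markov state model from transition counts
#'
#' The count graph is restricted to its largest strongly-connected component
#' (most states; ties broken by total counts, then lowest state index),
#' which guarantees a unique stationary distribution. Rows of the restricted
#' count matrix are normalized into a transition matrix (non-reversible
#' maximum-likelihood estimate; exactly reproducible, unlike iterative
#' reversible estimators). The stationary distribution is obtained by power
#' iteration and verified as a fixed point. A detailed-balance diagnostic
#' (the largest absolute flux asymmetry `|pi_i T_ij - pi_j T_ji|`) is
#' reported since row normalization does not enforce reversibility.
#'
#' @param counts square count matrix.
#' @return object of class `msm_model`: `states` (active state indices into
#'   the original grid), `transition` (row-stochastic matrix over active
#'   states), `pi` (stationary distribution), `counts` (restricted counts),
#'   `db_asymmetry` (detailed-balance diagnostic).
#' @export
build_msm <- function(counts) {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts))
  if (sum(counts) == 0) stop("degeneracy error: empty count matrix")
  seen <- which(rowSums(counts) + colSums(counts) > 0)
  edges <- which(counts > 0, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[, 1]),
               to = as.character(edges[, 2])),
    directed = TRUE,
    vertices = data.frame(name = as.character(seen)))
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  members <- lapply(seq_along(sizes), function(k) {
    as.integer(igraph::V(g)$name[comp$membership == k])
  })
  if (max(sizes) < 2) {
    stop("degeneracy error: no strongly-connected component with >= 2 states")
  }
  # largest component; ties: most counts, then lowest state index
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    tot <- vapply(members[best],
                  function(st) sum(counts[st, st]), numeric(1))
    best <- best[order(-tot, vapply(members[best], min, integer(1)))]
  }
  active <- sort(members[[best[1]]])
  sub <- counts[active, active, drop = FALSE]
  tmat <- sub / rowSums(sub)
  pi <- stationary_distribution(tmat)
  flux <- pi * tmat
  structure(list(states = active, transition = tmat, pi = pi,
                 counts = sub,
                 db_asymmetry = max(abs(flux - t(flux)))),
            class = "msm_model")
}

#' Stationary distribution by power iteration
#'
#' Iterates `x <- x %*% T` from the uniform distribution until the L1
#' change drops below `tol`. Errors if the fixed-point residual of the
#' result exceeds 1e-8.
#'
#' @param tmat row-stochastic matrix.
#' @param tol convergence tolerance (L1).
#' @param max_iter iteration cap.
#' @return stationary probability vector.
#' @export
stationary_distribution <- function(tmat, tol = 1e-13, max_iter = 100000) {
  n <- nrow(tmat)
  x <- rep(1 / n, n)
  for (i in seq_len(max_iter)) {
    xn <- as.numeric(x %*% tmat)
    xn <- xn / sum(xn)
    if (sum(abs(xn - x)) < tol) {
      x <- xn
      break
    }
    x <- xn
  }
  if (max(abs(as.numeric(x %*% tmat) - x)) > 1e-8) {
    stop("stationary distribution did not converge (residual > 1e-8)")
  }
  x
}

#' @export
print.msm_model <- function(x, ...) {
  cat(sprintf("MSM: %d active states, %d counts, DB asymmetry %.2e\n",
              length(x$states), sum(x$counts), x$db_asymmetry))
  invisible(x)
}

#' Free-energy landscape from an MSM
#'
#' Bin free energies in units of k_B T: `F_i = -ln(pi_i / max(pi))`, so the
#' global-minimum bin sits at exactly 0 and every active bin is finite and
#' non-negative. Bins outside the model's active set are undefined (`NA`).
#'
#' @param model an [build_msm()] result.
#' @param grid the [grid_spec()] used for discretization.
#' @return object of class `fel2d`: `grid`, `table` (data.frame with bin
#'   indices, centers and `F_kbt`) and `matrix` (`n_d x n_theta`, `NA` for
#'   inactive bins).
#' @export
fel_from_msm <- function(model, grid) {
  f <- -log(model$pi / max(model$pi))
  tab <- state_bins(model$states, grid)
  tab$F_kbt <- f
  m <- matrix(NA_real_, grid$n_d, grid$n_theta)
  m[cbind(tab$bin_d, tab$bin_theta)] <- f
  structure(list(grid = grid, table = tab, matrix = m), class = "fel2d")
}

#' @export
print.fel2d <- function(x, ...) {
  cat(sprintf("2D FEL: %d active of %d bins, F range [0, %.2f] k_BT\n",
              nrow(x$table), n_states(x$grid), max(x$table$F_kbt)))
  invisible(x)
}

#' Write a FEL to CSV
#'
#' @param fel a [fel_from_msm()] result.
#' @param path CSV path.
#' @export
write_fel <- function(fel, path) {
  utils::write.csv(
    fel$table[, c("bin_d", "bin_theta", "d_center", "theta_center",
                  "F_kbt")],
    path, row.names = FALSE)
  invisible(path)
}

#' MSM and FEL straight from a DS-MD result
#'
#' Convenience pipeline: drop burn-in cycles, discretize each per-cycle
#' segment, count transitions at the given lag within segments only, build
#' the MSM and convert to a free-energy landscape.
#'
#' @param result a [run_dsmd()] result.
#' @param grid a [grid_spec()].
#' @param lag lag time in frames.
#' @param burn_in_cycles cycles to discard (default from the result config).
#' @return list with `msm` and `fel`.
#' @export
msm_from_dsmd <- function(result, grid = grid_spec(), lag = 25,
                          burn_in_cycles = NULL) {
  segs <- dsmd_segments(result, burn_in_cycles)
  states <- lapply(segs, function(s) discretize(s$d, s$theta, grid))
  counts <- count_transitions(states, lag, n_states(grid))
  msm <- build_msm(counts)
  list(msm = msm, fel = fel_from_msm(msm, grid))
}
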