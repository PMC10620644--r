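# Shared test utilities and a cache for the expensive DS-MD artifacts so
# that module tests and acceptance tests reuse the same simulations.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) {
    assign(name, force(expr), envir = .cache)
  }
  get(name, envir = .cache)
}

two_basin_system <- function() {
  cached("ts2", toy_system("two_basin_side_GM", barrier_kbt = 5))
}

single_basin_system <- function() {
  cached("ts1", toy_system("single_basin_apical", barrier_kbt = 5))
}

# the canonical production run: 3 replicates x 100 cycles x 100 steps,
# started from the apical pose (the screening protocol's optimized start)
dsmd_two_basin <- function() {
  cached("res2", {
    sys <- two_basin_system()
    run_dsmd(sys$propagator, sys$state_apical, dsmd_config(master_seed = 42))
  })
}

dsmd_single_basin <- function() {
  cached("res1", {
    sys <- single_basin_system()
    run_dsmd(sys$propagator, sys$state_apical, dsmd_config(master_seed = 42))
  })
}

# uniformly random 3D rotation matrix (QR of a Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# brute-force minimax path height: enumerate every simple 8-connected path
brute_minimax <- function(m, from, to) {
  nr <- nrow(m); nc <- ncol(m)
  best <- Inf
  visit <- function(i, j, seen, height) {
    height <- max(height, m[i, j])
    if (height >= best) return()
    if (i == to[1] && j == to[2]) {
      best <<- height
      return()
    }
    nb <- expand.grid(di = -1:1, dj = -1:1)
    for (k in seq_len(nrow(nb))) {
      if (nb$di[k] == 0 && nb$dj[k] == 0) next
      ni <- i + nb$di[k]; nj <- j + nb$dj[k]
      if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
      if (is.na(m[ni, nj]) || seen[ni, nj]) next
      seen[ni, nj] <- TRUE
      visit(ni, nj, seen, height)
      seen[ni, nj] <- FALSE
    }
  }
  seen <- matrix(FALSE, nr, nc)
  seen[from[1], from[2]] <- TRUE
  if (!is.na(m[from[1], from[2]]) && !is.na(m[to[1], to[2]])) {
    visit(from[1], from[2], seen, -Inf)
  }
  best
}

# brute-force lagged pair counting over a single series
brute_counts <- function(s, lag, n) {
  counts <- matrix(0, n, n)
  if (length(s) > lag) {
    for (t in seq_len(length(s) - lag)) {
      counts[s[t], s[t + lag]] <- counts[s[t], s[t + lag]] + 1
    }
  }
  counts
}

# descriptor profile sitting exactly on every CNS threshold
boundary_profile <- function(criteria = cns_criteria()) {
  data.frame(code = "boundary", mw = criteria$mw_max, hbd = criteria$hbd_max,
             hba = criteria$hba_max, clogp = criteria$clogp_max,
             psa = criteria$psa_max, heavy_atoms = criteria$heavy_max,
             bbb_permeant = TRUE, stringsAsFactors = FALSE)
}
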