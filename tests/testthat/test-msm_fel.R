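test_that("discretization follows the half-open/closed-end convention", {
  grid <- grid_spec(d_range = c(2, 10), theta_range = c(0, 180),
                    n_d = 4, n_theta = 3)
  # exact lower edges fall in the first bin
  expect_equal(discretize(2, 0, grid), 1L)
  # exact upper edges fall in the final (closed) bin
  expect_equal(discretize(10, 180, grid), n_states(grid))
  # bin centers re-discretize to their own bin
  cb <- state_bins(seq_len(n_states(grid)), grid)
  expect_equal(discretize(cb$d_center, cb$theta_center, grid), cb$state)
  # out-of-range values clip to edge bins with a warning
  expect_warning(s <- discretize(c(1, 11), c(90, 90), grid), "clipped")
  expect_equal(((s - 1L) %% grid$n_d) + 1L, c(1L, 4L))
})

test_that("transition counting enumerates lagged pairs within segments", {
  counts <- count_transitions(list(c(1, 1, 2, 2)), lag = 1, n = 2)
  expect_equal(counts, matrix(c(1, 0, 1, 1), 2))
  # lag >= series length contributes nothing
  expect_warning(empty <- count_transitions(list(c(1, 2)), lag = 5, n = 2),
                 "shorter than lag")
  expect_equal(sum(empty), 0)
  # segments never bridge: two segments vs their concatenation differ
  segs <- list(c(1, 1, 1), c(2, 2, 2))
  c2 <- count_transitions(segs, lag = 1, n = 2)
  expect_equal(c2[1, 2], 0)
  c1 <- count_transitions(list(unlist(segs)), lag = 1, n = 2)
  expect_equal(c1[1, 2], 1)
})

test_that("transition counts match the brute-force pair oracle", {
  set.seed(89)
  for (i in 1:10) {
    n <- 6
    s <- sample.int(n, 200, replace = TRUE)
    lag <- sample(1:30, 1)
    expect_equal(count_transitions(list(s), lag, n), brute_counts(s, lag, n))
  }
  # and across multiple segments: sum of per-segment oracles
  s1 <- sample.int(4, 60, replace = TRUE)
  s2 <- sample.int(4, 45, replace = TRUE)
  expect_equal(count_transitions(list(s1, s2), 3, 4),
               brute_counts(s1, 3, 4) + brute_counts(s2, 3, 4))
})

test_that("MSM estimation restricts, normalizes and solves correctly", {
  m <- build_msm(matrix(c(9, 1, 1, 9), 2, byrow = TRUE))
  expect_equal(m$transition, matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
  expect_equal(m$pi, c(0.5, 0.5))
  # analytic stationary solution of an asymmetric chain
  m2 <- build_msm(matrix(c(8, 2, 4, 6), 2, byrow = TRUE))
  expect_equal(m2$pi, c(2 / 3, 1 / 3), tolerance = 1e-9)
  # a disconnected flowless state is excluded from the active set
  c3 <- matrix(0, 3, 3)
  c3[1:2, 1:2] <- c(8, 4, 2, 6)
  c3[3, 3] <- 5
  m3 <- build_msm(c3)
  expect_equal(m3$states, 1:2)
  expect_error(build_msm(matrix(0, 2, 2)), "degeneracy")
  expect_error(build_msm(matrix(c(5, 0, 0, 0), 2)), "degeneracy")
})

test_that("MSM rows are stochastic and pi is a fixed point", {
  set.seed(97)
  counts <- matrix(rpois(100, 3), 10)
  m <- build_msm(counts)
  expect_equal(rowSums(m$transition), rep(1, nrow(m$transition)),
               tolerance = 1e-10)
  expect_lt(max(abs(as.numeric(m$pi %*% m$transition) - m$pi)), 1e-8)
  expect_equal(sum(m$pi), 1, tolerance = 1e-10)
})

test_that("power iteration agrees with a direct eigen-solve", {
  set.seed(101)
  for (n in c(5, 20, 50)) {
    counts <- matrix(rpois(n * n, 2) + 1e-3, n)  # strictly connected
    tmat <- counts / rowSums(counts)
    pi_power <- stationary_distribution(tmat)
    e <- eigen(t(tmat))
    k <- which.min(abs(e$values - 1))
    pi_eigen <- Re(e$vectors[, k])
    pi_eigen <- pi_eigen / sum(pi_eigen)
    expect_equal(pi_power, pi_eigen, tolerance = 1e-8)
  }
})

test_that("FEL conversion pins the global minimum at zero", {
  grid <- grid_spec(n_d = 2, n_theta = 2)
  m2 <- build_msm(matrix(c(8, 2, 4, 6), 2, byrow = TRUE))
  fel <- fel_from_msm(m2, grid)
  expect_equal(fel$table$F_kbt, c(0, log(2)), tolerance = 1e-9)
  # uniform stationary distribution gives an identically-zero landscape
  mu <- build_msm(matrix(5, 3, 3))
  grid3 <- grid_spec(n_d = 3, n_theta = 2)
  felu <- fel_from_msm(mu, grid3)
  expect_true(all(abs(felu$table$F_kbt) < 1e-12))
  # one dominant state is the GM
  md <- build_msm(matrix(c(90, 1, 9, 1), 2, byrow = TRUE))
  feld <- fel_from_msm(md, grid)
  expect_equal(which.min(feld$table$F_kbt), 1L)
})

test_that("minima and barriers follow the definitions", {
  # 1D-like landscape [0, 3, 1]: GM at bin 1, LM at bin 3, barrier 2
  grid <- grid_spec(d_range = c(0, 3), theta_range = c(0, 180),
                    n_d = 3, n_theta = 2)
  fel <- structure(list(
    grid = grid,
    matrix = matrix(c(0, 3, 1, NA, NA, NA), nrow = 3),
    table = NULL), class = "fel2d")
  rep <- find_minima_and_barrier(fel, min_prominence = 0)
  expect_equal(c(rep$gm$bin_d, rep$gm$bin_theta), c(1, 1))
  expect_equal(nrow(rep$lm), 1)
  expect_equal(rep$lm$bin_d, 3)
  expect_equal(rep$lm$barrier_kbt, 2)
  # a single-basin bowl has a GM and no local minima
  bowl <- outer((1:7 - 4)^2, (1:7 - 4)^2, "+") / 8
  fel2 <- structure(list(
    grid = grid_spec(n_d = 7, n_theta = 7), matrix = bowl, table = NULL),
    class = "fel2d")
  rep2 <- find_minima_and_barrier(fel2, min_prominence = 0)
  expect_equal(nrow(rep2$lm), 0)
  expect_equal(c(rep2$gm$bin_d, rep2$gm$bin_theta), c(4, 4))
})

test_that("minimax path height equals exhaustive enumeration on small grids", {
  set.seed(103)
  for (i in 1:12) {
    nr <- sample(2:4, 1); nc <- sample(2:4, 1)
    m <- matrix(runif(nr * nc, 0, 5), nr, nc)
    if (i %% 3 == 0) m[sample(length(m), 2)] <- NA  # inactive holes
    from <- c(sample(nr, 1), sample(nc, 1))
    to <- c(sample(nr, 1), sample(nc, 1))
    expect_equal(minimax_path_height(m, from, to), brute_minimax(m, from, to))
  }
})

test_that("a known analytic two-basin surface yields a 5 kBT barrier", {
  pot <- make_potential("two_basin_side_GM", barrier_kbt = 5)
  grid <- grid_spec(n_d = 60, n_theta = 60)
  cb <- state_bins(seq_len(n_states(grid)), grid)
  u <- toy_u(pot, cb$d_center, cb$theta_center)
  f <- matrix(u - min(u), grid$n_d, grid$n_theta)
  fel <- structure(list(grid = grid, matrix = f, table = NULL),
                   class = "fel2d")
  rep <- find_minima_and_barrier(fel)
  expect_false(rep$gm$apical)
  expect_equal(nrow(rep$lm), 1)
  expect_true(rep$lm$apical)
  # grid-center discretization keeps the barrier within ~0.1 kBT
  expect_equal(rep$lm$barrier_kbt, 5, tolerance = 0.12 / 5)
})

test_that("iid samples from a Boltzmann density recover -ln p", {
  set.seed(3)
  n <- 60000
  comp <- sample(1:2, n, replace = TRUE, prob = c(0.7, 0.3))
  d <- ifelse(comp == 1, rnorm(n, 4.4, 0.35), rnorm(n, 3.5, 0.35))
  th <- ifelse(comp == 1, rnorm(n, 90, 12), rnorm(n, 160, 12))
  d <- pmin(pmax(d, 2), 10); th <- pmin(pmax(th, 0), 180)
  grid <- grid_spec(n_d = 12, n_theta = 12)
  s <- discretize(d, th, grid)
  msm <- build_msm(count_transitions(list(s), 1, n_states(grid)))
  fel <- fel_from_msm(msm, grid)
  h <- tabulate(s, n_states(grid))
  idx <- intersect(which(h >= 200), fel$table$state)
  f_emp <- fel$table$F_kbt[match(idx, fel$table$state)]
  f_true <- -log(h[idx] / max(h))
  shift <- mean(f_emp - f_true)
  expect_lt(mean(abs(f_emp - shift - f_true)), 0.3)
})

test_that("doubling trajectory length leaves well-sampled bins stable", {
  sys <- single_basin_system()
  grid <- grid_spec()
  f_of <- function(n_frames, seed) {
    tr <- run_plain(sys$propagator, sys$state_apical, n_frames, seed)
    st <- discretize(tr$d, tr$theta, grid)
    msm <- build_msm(count_transitions(list(st), 25, n_states(grid)))
    list(fel = fel_from_msm(msm, grid), h = tabulate(st, n_states(grid)))
  }
  a <- f_of(10000, seed = 301)
  b <- f_of(20000, seed = 302)
  common <- intersect(a$fel$table$state, b$fel$table$state)
  well <- common[a$h[common] >= 200 & b$h[common] >= 200]
  fa <- a$fel$table$F_kbt[match(well, a$fel$table$state)]
  fb <- b$fel$table$F_kbt[match(well, b$fel$table$state)]
  expect_gt(length(well), 5)
  expect_lt(mean(abs(fa - fb)), 0.2)
})
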