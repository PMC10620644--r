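test_that("two-basin calibration hits the requested barrier", {
  pot <- make_potential("two_basin_side_GM", barrier_kbt = 5)
  # independent dense-grid mountain-pass oracle: every apical-to-side path
  # crosses each intermediate theta slice, so the saddle height equals the
  # highest slice-minimum between the basin centers
  dg <- seq(2, 10, length.out = 2000)
  tg <- seq(90, 160, length.out = 2000)
  u <- outer(dg, tg, function(d, th) toy_u(pot, d, th))
  saddle <- max(apply(u, 2, min))
  ap <- min(u[, tg > 125])
  expect_equal(saddle - ap, 5, tolerance = 0.05 / 5)
  # side basin is the deeper (global) minimum
  expect_lt(min(u[, tg < 120]), ap)
  expect_error(make_potential("two_basin_side_GM", barrier_kbt = 0),
               "calibration error")
})

test_that("single-basin scenario has exactly one local minimum", {
  pot <- make_potential("single_basin_apical", barrier_kbt = 5)
  nd <- 200; nt <- 200
  dg <- seq(2.02, 9.98, length.out = nd)
  tg <- seq(0.5, 179.5, length.out = nt)
  u <- outer(seq_len(nd), seq_len(nt),
             function(i, j) toy_u(pot, dg[i], tg[j]))
  # interior strict local minima
  core <- u[2:(nd - 1), 2:(nt - 1)]
  is_min <- core < u[1:(nd - 2), 2:(nt - 1)] &
    core < u[3:nd, 2:(nt - 1)] &
    core < u[2:(nd - 1), 1:(nt - 2)] &
    core < u[2:(nd - 1), 3:nt] &
    core < u[1:(nd - 2), 1:(nt - 2)] & core < u[3:nd, 3:nt] &
    core < u[1:(nd - 2), 3:nt] & core < u[3:nd, 1:(nt - 2)]
  # the flat far field is numerically degenerate; count minima with depth
  expect_equal(sum(is_min & core < -0.5), 1)
})

test_that("analytic gradient matches finite differences", {
  pot <- make_potential("two_basin_side_GM", 5)
  set.seed(67)
  for (i in 1:10) {
    d <- runif(1, 2.5, 9); th <- runif(1, 10, 170)
    g <- toy_grad(pot, d, th)
    eps <- 1e-6
    fd_d <- (toy_u(pot, d + eps, th) - toy_u(pot, d - eps, th)) / (2 * eps)
    fd_t <- (toy_u(pot, d, th + eps) - toy_u(pot, d, th - eps)) / (2 * eps)
    expect_equal(unname(g[1, "dU_dd"]), fd_d, tolerance = 1e-5)
    expect_equal(unname(g[1, "dU_dtheta"]), fd_t, tolerance = 1e-5)
  }
})

test_that("zero-temperature propagation descends monotonically", {
  pot <- make_potential("single_basin_apical", 5)
  params <- langevin_params(dt = 5e-4, gamma = c(1, 0.05), kT = 0,
                            substeps = 100L)
  # start inside the basin's capture range (the far plateau is nearly flat)
  tr <- run_plain(langevin_propagator(pot, params), c(3.8, 145), 200,
                  seed = 1)
  u <- toy_u(pot, tr$d, tr$theta)
  expect_true(all(diff(u) <= 1e-9))
  # converges to the apical minimum
  expect_equal(tail(tr$d, 1), 3.5, tolerance = 1e-3)
  expect_equal(tail(tr$theta, 1), 160, tolerance = 1e-3)
})

test_that("deep-well sampling matches the Boltzmann variance", {
  pot <- toy_potential(list(basin_spec(c(3.5, 90), 50, c(0.35, 8))),
                       d_walls = c(3, 4))
  params <- langevin_params(dt = 1e-4, gamma = c(1, 0.05), substeps = 200L)
  tr <- run_plain(langevin_propagator(pot, params), c(3.5, 90), 30000,
                  seed = 11)
  # exact Boltzmann oracle by numeric integration over the well
  f <- function(x) exp(50 * exp(-x^2 / (2 * 0.35^2)))
  z <- stats::integrate(f, -0.5, 0.5)$value
  exact <- stats::integrate(function(x) x^2 * f(x), -0.5, 0.5)$value / z
  expect_equal(var(tr$d), exact, tolerance = 0.1)
  # and the quadratic-expansion (harmonic) value is itself within 10%
  expect_equal(var(tr$d), 0.35^2 / 50, tolerance = 0.1)
})

test_that("free sampling reproduces the Boltzmann weight of the surface", {
  pot <- make_potential("single_basin_apical", 5)
  params <- langevin_params(dt = 8e-4, gamma = c(1, 0.05), substeps = 1250L)
  tr <- run_plain(langevin_propagator(pot, params), c(3.5, 160), 20000,
                  seed = 7)
  grid <- grid_spec()
  st <- discretize(tr$d, tr$theta, grid)
  h <- tabulate(st, n_states(grid))
  cb <- state_bins(seq_len(n_states(grid)), grid)
  f_true <- -log(exp(-toy_u(pot, cb$d_center, cb$theta_center)))
  keep <- h >= 200
  f_emp <- -log(h[keep] / sum(h))
  f_ref <- f_true[keep]
  shift <- mean(f_emp - f_ref)   # match up to an additive constant
  expect_lt(mean(abs(f_emp - shift - f_ref)), 0.3)
})

test_that("energy-table generator embeds the requested counts", {
  tab <- make_energy_table(18, 13, 3, seed = 71)
  expect_equal(nrow(tab), 19)
  expect_equal(count_below(tab, "d_mp2", 0, strict = TRUE), 13)
  expect_equal(count_below(tab, "d_b3lyp", -15, strict = FALSE), 3)
  ref <- tab[tab$code == "2-PAM", ]
  expect_equal(ref$d_b3lyp, 0)
  expect_equal(ref$d_mp2, 0)
  none <- make_energy_table(10, 0, 2, seed = 71)
  expect_true(all(none$d_mp2[none$code != "2-PAM"] >= 0))
  expect_error(make_energy_table(5, 6, 0, seed = 1), "generation error")
  # determinism
  expect_identical(make_energy_table(18, 13, 3, seed = 71), tab)
})

test_that("pose-set generator embeds the apical fraction", {
  ps <- make_pose_set(12, 5, seed = 73,
                      path = withr::local_tempfile(fileext = ".pdb"))
  out <- screen_poses(ps$pdb)
  expect_equal(sum(out$apical), 5)
  expect_identical(out$apical, ps$truth$apical)
  # a pose at exactly d = 8 is non-apical under the strict bound
  g <- compute_geometry(c(8, 0, 0), c(0, 0, 0), c(-1.6, 0, 0))
  expect_false(classify_apical(g$d_op, g$theta_opo))
})

test_that("interaction-matrix generator plants the consensus exactly", {
  residues <- paste0("r", 1:9)
  m <- make_interaction_matrix(letters[1:10], residues, paste0("r", 1:4),
                               fraction = 0.5, seed = 79)
  expect_setequal(consensus_residues(m, 0.5), paste0("r", 1:4))
  m1 <- make_interaction_matrix(letters[1:10], residues, residues,
                                fraction = 1.0, seed = 79)
  expect_true(all(colSums(m1) == 10))
  m0 <- make_interaction_matrix(letters[1:10], residues, character(0),
                                fraction = 0.5, seed = 79)
  expect_length(consensus_residues(m0, 0.5), 0)
})

test_that("descriptor-table generator embeds the pass set", {
  codes <- sprintf("c%02d", 1:30)
  pass <- codes[c(2, 5, 9, 20)]
  tab <- make_descriptor_table(codes, pass, seed = 83)
  v <- apply_cns_filter(tab)
  expect_setequal(v$code[v$passed], pass)
})
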