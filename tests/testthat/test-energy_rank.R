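test_that("ONIOM2 combination is the three-term extrapolation", {
  expect_equal(oniom2_energy(0, 0, 0), 0)
  expect_equal(oniom2_energy(-10, -100, -5), -105)
  # cancellation: equal high/low model energies leave the low real energy
  for (x in c(-3, 0, 42.5)) {
    expect_equal(oniom2_energy(x, -77.7, x), -77.7)
  }
  # independent summation oracle on random inputs
  set.seed(31)
  for (i in 1:50) {
    comp <- rnorm(3, sd = 1000)
    expect_equal(oniom2_energy(comp[1], comp[2], comp[3]),
                 sum(comp * c(1, 1, -1)))
  }
  expect_error(oniom2_energy(NA, 1, 2), "non-finite")
})

test_that("packaged energy table matches its printed reference row", {
  tab <- read_energy_table()
  expect_equal(nrow(tab), 19)
  ref <- tab[tab$code == "2-PAM", ]
  expect_equal(ref$e_oniom2, -4292.53)
  expect_equal(ref$d_b3lyp, 0)
  expect_equal(ref$d_mp2, 0)
  expect_equal(ref$d_op, 4.42)
})

test_that("delta_vs_reference zeroes the reference and round-trips", {
  tab <- read_energy_table()
  d <- delta_vs_reference(tab, "2-PAM", cols = "e_oniom2")
  i <- which(d$code == "2-PAM")
  expect_identical(d$delta_e_oniom2[i], 0)
  # adding the reference energy back recovers the original column
  expect_equal(d$delta_e_oniom2 + tab$e_oniom2[i], tab$e_oniom2)
  # identical energies give all-zero deltas
  same <- data.frame(code = c("a", "b", "r"), e_oniom2 = -5)
  expect_equal(delta_vs_reference(same, "r")$delta_e_oniom2, c(0, 0, 0))
  expect_error(delta_vs_reference(tab, "X"), "lookup error")
})

test_that("count_below reproduces the printed screening counts", {
  tab <- read_energy_table()
  expect_equal(count_below(tab, "d_mp2", 0, strict = TRUE), 13)
  expect_equal(count_below(tab, "d_b3lyp", -15, strict = FALSE), 3)
  expect_equal(count_below(tab, "d_mp2", -15, strict = FALSE), 8)
  expect_equal(count_below(tab[tab$code == "2-PAM", ], "d_mp2", 0), 0)
  expect_error(count_below(tab, "nope", 0), "schema error")
})

test_that("count_below is monotone in threshold and permutation-invariant", {
  tab <- read_energy_table()
  thresholds <- seq(-50, 20, by = 5)
  counts <- vapply(thresholds,
                   function(t) count_below(tab, "d_mp2", t), numeric(1))
  expect_true(all(diff(counts) >= 0))
  set.seed(13)
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(count_below(perm, "d_mp2", -15, strict = FALSE), 8)
})

test_that("quartile selection drops Q4 and keeps boundary ties", {
  # 24 candidate analogs plus the reference: reference and six analogs in Q4
  set.seed(17)
  scores <- data.frame(
    code = c(sprintf("a%02d", 1:24), "2-PAM"),
    affinity = c(runif(18, -8, -6.2),            # Q1-Q3 analogs
                 runif(6, -5.2, -4.0),           # Q4 analogs
                 -5.3))                          # reference, also Q4
  sel <- quartile_select(scores)
  expect_equal(length(sel$kept), 18)
  expect_true("2-PAM" %in% sel$dropped)
  expect_equal(sum(sel$dropped != "2-PAM"), 6)
  expect_false(any(sprintf("a%02d", 1:18) %in% sel$dropped))
  # brute-force check on 4 distinct values: exactly the best 3 kept
  s4 <- data.frame(code = letters[1:4], affinity = c(-4, -9, -6, -2))
  sel4 <- quartile_select(s4)
  expect_setequal(sel4$kept, c("b", "c", "a"))
  expect_equal(sel4$dropped, "d")
  # all-equal scores: no score strictly worse than the boundary
  se <- data.frame(code = letters[1:8], affinity = -5)
  expect_length(quartile_select(se)$kept, 8)
  expect_error(quartile_select(s4[1:3, ]), "size error")
})

test_that("quartile selection partitions and orders correctly", {
  set.seed(19)
  for (i in 1:10) {
    n <- sample(4:40, 1)
    scores <- data.frame(code = sprintf("c%02d", 1:n),
                         affinity = round(runif(n, -9, -3), 2))
    sel <- quartile_select(scores)
    expect_equal(length(sel$kept) + length(sel$dropped), n)
    if (length(sel$dropped)) {
      worst_kept <- max(scores$affinity[scores$code %in% sel$kept])
      expect_true(all(scores$affinity[scores$code %in% sel$dropped] >=
                        worst_kept))
    }
  }
})

test_that("ranking and extremes match the printed table", {
  tab <- read_energy_table()
  re <- rank_and_extremes(tab)
  expect_equal(re$extremes$e_oniom2_min, -4752.88)
  expect_equal(tab$code[tab$e_oniom2 == re$extremes$e_oniom2_min], "5-3")
  expect_equal(re$extremes$e_oniom2_max, -4331.56)
  expect_equal(re$extremes$d_op_max, 3.76)
  expect_equal(re$extremes$d_op_min, 2.90)
  expect_equal(re$ranking$code[1], "3-1")
  expect_equal(re$ranking$d_op[1], 3.54)
  one <- rank_and_extremes(tab[tab$code == "3-1", ], ref_code = NULL)
  expect_equal(one$ranking$rank, 1)
  expect_equal(one$extremes$e_oniom2_min, one$extremes$e_oniom2_max)
})

test_that("gap_difference preserves sign and rounds as reported", {
  expect_equal(gap_difference(246.74, 220.57), 26.17)
  expect_equal(round(gap_difference(246.74, 220.57)), 26)
  expect_equal(gap_difference(5, 5), 0)
  expect_equal(gap_difference(200, 300), -100)
})

test_that("unicode minus signs are normalized on ingestion", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("code,e_oniom2,d_b3lyp,d_mp2,d_op",
               "x,−4300.5,−15,2,3.1",
               "2-PAM,-4292.53,0,0,4.42"), path)
  tab <- read_energy_table(path)
  expect_equal(tab$e_oniom2[1], -4300.5)
  expect_equal(tab$d_b3lyp[1], -15)
})
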