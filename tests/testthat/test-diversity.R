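test_that("window pi matches the pairwise-enumeration oracle", {
  # hand example: one site, n = 4 alleles, a = 2, 10-bp window
  hap <- matrix(c(1L, 1L, 0L, 0L), 1, 4)
  p <- toy_panel(matrix(c(2L, 0L), 1, 2), pos = 5, hap = hap,
                 contig_len = 10)
  pm <- population_map(stats::setNames(rep("A", 2), p$samples))
  g <- make_windows(p, 10, 10)
  out <- window_pi(p, pm, "A", g)
  expect_equal(out$value[1], (2 * 2 * 2 / 12) / 10)
  expect_equal(out$value[1], oracle_pi(p, 1:4, 0, 10))

  # random tiny panels against the oracle
  for (seed in 1:5) {
    sim <- simulate_bn_panel(n_sites = 18, pops = c(A = 3), fst = 0.1,
                             spacing = 7, seed = seed)
    pmA <- sim_popmap(sim)
    gg <- make_windows(sim, 140, 140)
    got <- window_pi(sim, pmA, "A", gg)$value[1]
    expect_equal(got, oracle_pi(sim, 1:6, 0, gg$end[1]),
                 tolerance = 1e-12)
  }
})

test_that("monomorphic windows have pi = 0 and stay valid", {
  p <- toy_panel(matrix(0L, 3, 4))
  pm <- population_map(stats::setNames(rep("A", 4), p$samples))
  g <- make_windows(p, 40, 40)
  out <- window_pi(p, pm, "A", g)
  expect_equal(out$value, 0)
  expect_true(all(out$valid))
})

test_that("Tajima's D matches an independent implementation", {
  # every variant a singleton: n = 8, S = 5 -> negative D
  g <- matrix(0L, 5, 4)
  g[cbind(1:5, c(1, 2, 3, 4, 1))] <- 1L
  p <- toy_panel(g, pos = 1:5 * 10, contig_len = 60)
  pm <- population_map(stats::setNames(rep("A", 4), p$samples))
  grid <- make_windows(p, 60, 60)
  got <- window_tajima_d(p, pm, "A", grid)$value[1]
  n <- 8; S <- 5
  k <- sum(2 * 1 * 7 / (8 * 7))  * 5
  expect_lt(got, 0)
  expect_equal(got, oracle_tajima_d(n, S, k), tolerance = 1e-9)

  # one site at frequency 1/2 with n = 4
  p2 <- toy_panel(matrix(c(2L, 0L), 1, 2), pos = 5, contig_len = 10)
  pm2 <- population_map(stats::setNames(rep("A", 2), p2$samples))
  got2 <- window_tajima_d(p2, pm2, "A", make_windows(p2, 10, 10))$value[1]
  expect_equal(got2, oracle_tajima_d(4, 1, 2 * 2 * 2 / 12),
               tolerance = 1e-9)

  # no segregating site -> NA
  p3 <- toy_panel(matrix(2L, 2, 3))
  pm3 <- population_map(stats::setNames(rep("A", 3), p3$samples))
  expect_true(is.na(window_tajima_d(p3, pm3, "A",
                                    make_windows(p3, 40, 40))$value[1]))
})

test_that("FST is 1 for fixed differences and ~0 under identical frequencies", {
  g <- cbind(matrix(0L, 10, 6), matrix(2L, 10, 6))
  p <- toy_panel(g)
  pm <- population_map(stats::setNames(rep(c("A", "B"), each = 6),
                                       p$samples))
  expect_equal(global_fst(p, pm, "A", "B"), 1)
  w <- window_fst(p, pm, "A", "B", make_windows(p, 200, 200))
  expect_equal(w$value[1], 1)

  null <- simulate_bn_panel(n_sites = 10000, pops = c(A = 25, B = 25),
                            fst = 0, seed = 5)
  pmn <- sim_popmap(null)
  expect_lt(abs(global_fst(null, pmn, "A", "B")), 0.02)
})

test_that("FST recovers the Balding-Nichols target", {
  p <- simulate_bn_panel(n_sites = 20000, pops = c(A = 25, B = 25),
                         fst = 0.2, seed = 11)
  pm <- sim_popmap(p)
  est <- global_fst(p, pm, "A", "B")
  expect_gt(est, 0.18)
  expect_lt(est, 0.22)
})

test_that("dXY matches hand values and the cross-pair oracle", {
  # one fixed difference in a 10-bp window
  p <- toy_panel(matrix(c(0L, 2L), 1, 2), pos = 5, contig_len = 10,
                 hap = matrix(c(0L, 0L, 1L, 1L), 1, 4))
  pm <- population_map(stats::setNames(c("A", "B"), p$samples))
  g <- make_windows(p, 10, 10)
  expect_equal(window_dxy(p, pm, "A", "B", g)$value[1], 0.1)
  # identical fixed states -> 0
  p2 <- toy_panel(matrix(c(2L, 2L), 1, 2), pos = 5, contig_len = 10)
  expect_equal(window_dxy(p2, pm, "A", "B", g)$value[1], 0)
  # random panels vs enumeration
  for (seed in 6:9) {
    sim <- simulate_bn_panel(n_sites = 20, pops = c(A = 3, B = 3),
                             fst = 0.3, spacing = 5, seed = seed)
    pms <- sim_popmap(sim)
    gg <- make_windows(sim, 105, 105)
    got <- window_dxy(sim, pms, "A", "B", gg)$value[1]
    expect_equal(got, oracle_dxy(sim, 1:6, 7:12, 0, 105),
                 tolerance = 1e-12)
  }
})

test_that("dXY of a population against itself matches 2p(1-p) summation", {
  sim <- simulate_bn_panel(n_sites = 50, pops = c(A = 4), fst = 0.2,
                           spacing = 10, seed = 13)
  pm <- sim_popmap(sim)
  g <- make_windows(sim, 510, 510)
  ac <- rowSums(sim$geno) / (2 * 4)
  expect_equal(window_dxy(sim, pm, "A", "A", g)$value[1],
               sum(2 * ac * (1 - ac)) / 510)
})

test_that("inbreeding coefficient follows F = 1 - Ho/He", {
  # Ho = 0 with He > 0 -> F = 1
  g <- cbind(rep(0L, 4), rep(2L, 4), rep(0L, 4), rep(2L, 4))
  p <- toy_panel(g)
  pm <- population_map(stats::setNames(rep("A", 4), p$samples))
  out <- inbreeding_f(p, pm)$population
  expect_equal(out$f, 1)
  # Ho = He at a single 50/50 het-structured site
  g2 <- matrix(c(0L, 1L, 1L, 2L), 1, 4)
  p2 <- toy_panel(g2)
  out2 <- inbreeding_f(p2, pm)$population
  expect_equal(out2$ho, 0.5)
  expect_equal(out2$he, 0.5)
  expect_equal(out2$f, 0)
  # arithmetic: Ho = 0.1, He = 0.2 -> F = 0.5
  expect_equal(1 - 0.1 / 0.2, 0.5)
  # monomorphic -> warning + NA
  p3 <- toy_panel(matrix(0L, 2, 4))
  expect_warning(out3 <- inbreeding_f(p3, pm), "He = 0")
  expect_true(is.na(out3$population$f))
})

test_that("pi ratio log2 table and genome-wide scalar behave", {
  p <- simulate_bn_panel(n_sites = 2000, pops = c(A = 10, B = 10),
                         fst = 0.1, seed = 3)
  pm <- sim_popmap(p)
  g <- make_windows(p, 20000, 10000)
  piA <- window_pi(p, pm, "A", g)
  lr <- pi_ratio(piA, piA)
  expect_equal(lr$value[!is.na(lr$value)],
               rep(0, sum(!is.na(lr$value))))
  expect_equal(attr(lr, "ratio_of_sums"), 1)
  # quadrupling pi gives log-ratio 2
  piB <- piA
  piB$value <- piA$value * 4
  lr2 <- pi_ratio(piA, piB)
  expect_equal(unique(lr2$value[!is.na(lr2$value)]), 2)
  expect_equal(attr(lr2, "ratio_of_sums"), 4)
  expect_error(pi_ratio(piA, piA[1:3, ]), "grids differ")
})

test_that("windowed statistics agree with brute force on tiny panels", {
  sim <- simulate_bn_panel(n_sites = 20, pops = c(A = 3, B = 3),
                           fst = 0.25, spacing = 5, seed = 17)
  pm <- sim_popmap(sim)
  g <- make_windows(sim, 105, 105)
  expect_equal(window_pi(sim, pm, "A", g)$value[1],
               oracle_pi(sim, 1:6, 0, 105), tolerance = 1e-12)
  expect_equal(window_pi(sim, pm, "B", g)$value[1],
               oracle_pi(sim, 7:12, 0, 105), tolerance = 1e-12)
  expect_equal(window_dxy(sim, pm, "A", "B", g)$value[1],
               oracle_dxy(sim, 1:6, 7:12, 0, 105), tolerance = 1e-12)
})
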