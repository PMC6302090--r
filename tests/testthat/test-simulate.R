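test_that("generators are bit-identical under the same seed", {
  a <- simulate_bn_panel(n_sites = 300, pops = c(A = 6, B = 6),
                         fst = 0.2, seed = 141)
  b <- simulate_bn_panel(n_sites = 300, pops = c(A = 6, B = 6),
                         fst = 0.2, seed = 141)
  expect_identical(a, b)
  c1 <- simulate_tree_panel(n_sites = 300, seed = 143)
  c2 <- simulate_tree_panel(n_sites = 300, seed = 143)
  expect_identical(c1, c2)
  w1 <- simulate_wf_haplotypes(pops = c(P1 = 4, P2 = 4, P3 = 4, O = 4),
                               n_e = 40, chrom_length = 1e5, mu = 2e-6,
                               recomb = 2e-6,
                               split_gens = c(t12 = 10, t123 = 20,
                                              t_o = 30),
                               burn_in = 40, seed = 149)
  w2 <- simulate_wf_haplotypes(pops = c(P1 = 4, P2 = 4, P3 = 4, O = 4),
                               n_e = 40, chrom_length = 1e5, mu = 2e-6,
                               recomb = 2e-6,
                               split_gens = c(t12 = 10, t123 = 20,
                                              t_o = 30),
                               burn_in = 40, seed = 149)
  expect_identical(w1, w2)
  m1 <- simulate_cn_matrix(seed = 151)
  m2 <- simulate_cn_matrix(seed = 151)
  expect_identical(m1, m2)
  # different seeds diverge
  expect_false(identical(a$geno,
                         simulate_bn_panel(n_sites = 300,
                                           pops = c(A = 6, B = 6),
                                           fst = 0.2, seed = 142)$geno))
})

test_that("Balding-Nichols panels obey the F limit and variance relation", {
  # F -> 0: populations share the ancestral frequency exactly
  p0 <- simulate_bn_panel(n_sites = 4000, pops = c(A = 20, B = 20),
                          fst = 0, seed = 153)
  pm <- sim_popmap(p0)
  expect_lt(abs(global_fst(p0, pm, "A", "B")), 0.02)
  expect_equal(p0$truth$pop_freq[, "A"], p0$truth$pop_freq[, "B"])
  # var(freq) across populations matches F p (1 - p) in expectation
  p <- simulate_bn_panel(n_sites = 12000, pops = c(A = 5, B = 5),
                         fst = 0.2, seed = 157)
  tr <- p$truth
  realized <- rowMeans((tr$pop_freq - tr$ancestral_freq)^2)
  expected <- 0.2 * tr$ancestral_freq * (1 - tr$ancestral_freq)
  expect_lt(abs(mean(realized) / mean(expected) - 1), 0.1)
})

test_that("haplotypes are consistent with genotypes in all generators", {
  p <- simulate_tree_panel(n_sites = 200, seed = 163)
  expect_silent(validate_panel(p))
  w <- simulate_wf_haplotypes(pops = c(P1 = 5), n_e = 30,
                              chrom_length = 1e5, mu = 2e-6,
                              recomb = 2e-6,
                              split_gens = c(t12 = 0, t123 = 0, t_o = 0),
                              burn_in = 30, seed = 167)
  expect_silent(validate_panel(w))
  expect_true(all(diff(w$sites$pos) > 0))
})

test_that("a mutation-free run adds no new alleles after the founders", {
  base <- list(pops = c(P1 = 5), n_e = 30, chrom_length = 1e5,
               recomb = 2e-6,
               split_gens = c(t12 = 0, t123 = 0, t_o = 0))
  w0 <- do.call(simulate_wf_haplotypes,
                c(base, list(mu = 0, burn_in = 30, seed = 173)))
  # mu = 0 leaves the founder panel empty of segregating sites
  expect_equal(n_sites(w0), 0)
})

test_that("the neutral Wright-Fisher run sits near mutation-drift equilibrium", {
  w <- simulate_wf_haplotypes(pops = c(P1 = 12), n_e = 100,
                              chrom_length = 1e6, mu = 1e-6,
                              recomb = 1e-6,
                              split_gens = c(t12 = 0, t123 = 0, t_o = 0),
                              burn_in = 150, seed = 179)
  pm <- sim_popmap(w)
  g <- make_windows(w, 10000, 5000)
  td <- window_tajima_d(w, pm, "P1", g)
  expect_gte(sum(!is.na(td$value)), 150)
  expect_lt(abs(mean(td$value, na.rm = TRUE)), 0.5)
})

test_that("a migration pulse leaves the stated ancestry fraction", {
  # a very recent pulse: ancestry drift sd after t generations is about
  # sqrt(f (1 - f) t / 2N) per locus, so t must be small for the
  # realized genome-wide fraction to sit within 0.05 of the target
  w <- simulate_wf_haplotypes(pops = c(P1 = 8, P2 = 8, P3 = 8, O = 4),
                              n_e = 150, chrom_length = 5e5, mu = 1e-6,
                              recomb = 1e-6,
                              split_gens = c(t12 = 30, t123 = 60,
                                             t_o = 120),
                              burn_in = 120,
                              pulse = list(donor = "P3",
                                           recipient = "P2",
                                           time = 1, fraction = 0.3),
                              seed = 181)
  tr <- w$truth$pulse
  expect_equal(tr$donor, "P3")
  expect_lt(abs(tr$realized_fraction - 0.3), 0.05)
  expect_true(all(tr$marker$donor_freq >= 0 & tr$marker$donor_freq <= 1))
})

test_that("plant_sweep fixes haplotypes at the stated frequency", {
  p <- simulate_bn_panel(n_sites = 5000, pops = c(A = 15, B = 15),
                         fst = 0.05, spacing = 100, seed = 191)
  pm <- sim_popmap(p)
  reg <- list(contig = "chr1", start = 2e5, end = 3e5)
  # final_freq = 1 leaves the region monomorphic in the population
  p1 <- plant_sweep(p, pm, "A", reg, final_freq = 1, seed = 193)
  g <- make_windows(p1, 100000, 100000)
  piA <- window_pi(p1, pm, "A", g)
  expect_equal(piA$value[piA$start == 2e5], 0)
  # final_freq = q leaves about (1 - q^2) of the original diversity
  # (pairs with both haplotypes from the swept lineage are identical),
  # i.e. a ~2.8x reduction at q = 0.8
  p8 <- plant_sweep(p, pm, "A", reg, final_freq = 0.8, seed = 197)
  pi8 <- window_pi(p8, pm, "A", g)
  inreg <- pi8$value[pi8$start == 2e5]
  flank <- mean(pi8$value[pi8$start != 2e5 & pi8$n_snps > 0])
  expect_gt(flank / inreg, 2.3)
  expect_lt(flank / inreg, 3.5)
  expect_equal(p8$truth$sweeps$final_freq, 0.8)
  # final_freq = 0 is the identity
  expect_identical(plant_sweep(p, pm, "A", reg, 0), p)
})

test_that("plant_introgression records carriers and realized fraction", {
  p <- simulate_tree_panel(n_sites = 2000, seed = 199)
  pm <- sim_popmap(p)
  tr <- data.frame(contig = "chr1", start = 5e4, end = 1e5)
  p2 <- plant_introgression(p, pm, "P3", "P2", tr, fraction = 0.25,
                            seed = 211)
  rec <- p2$truth$tracts
  expect_equal(rec$realized_fraction, 0.25)
  expect_equal(length(rec$carriers), 10)  # 0.25 * 40 haplotypes
  # inside the tract, carrier haplotypes now match donor frequencies:
  # dXY(P2, P3) there drops relative to the unplanted panel
  g <- make_windows(p2, 50000, 50000)
  d0 <- window_dxy(p, pm, "P2", "P3", g)
  d1 <- window_dxy(p2, pm, "P2", "P3", g)
  w <- which(g$start == 5e4)
  expect_lt(d1$value[w], d0$value[w])
  expect_equal(d1$value[-w], d0$value[-w])
})
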