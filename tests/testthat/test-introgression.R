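make_role_panel <- function(geno, pos = NULL, contig_len = NULL) {
  # one sample per role, columns P1, P2, P3, O
  p <- toy_panel(geno, pos = pos, contig_len = contig_len)
  pm <- population_map(
    stats::setNames(c("P1", "P2", "P3", "O"), p$samples),
    roles = c(P1 = "P1", P2 = "P2", P3 = "P3", O = "O"))
  list(panel = p, pm = pm)
}

test_that("ABBA/BABA weights follow the frequency definition", {
  # pure ABBA site: p = (0, 1, 1, 0); pure BABA: p = (1, 0, 1, 0)
  x <- make_role_panel(rbind(c(0L, 2L, 2L, 0L), c(2L, 0L, 2L, 0L),
                             c(1L, 1L, 2L, 0L)))
  parts <- compute_d_parts(x$panel, x$pm)
  expect_equal(parts$abba, c(1, 0, 0.25))
  expect_equal(parts$baba, c(0, 1, 0.25))
  # p1 == p2 gives symmetric weights at every site
  expect_equal(parts$abba[3], parts$baba[3])
  # spreadsheet-style oracle on a random table
  sim <- simulate_tree_panel(n_sites = 20, seed = 41)
  pm <- sim_popmap(sim)
  pr <- compute_d_parts(sim, pm)
  expect_equal(patterson_d(pr),
               oracle_d(pr$p1, pr$p2, pr$p3, pr$p4), tolerance = 1e-12)
})

test_that("Patterson's D has the right value and range", {
  x <- make_role_panel(rbind(c(0L, 2L, 2L, 0L), c(0L, 2L, 2L, 0L)))
  expect_equal(patterson_d(compute_d_parts(x$panel, x$pm)), 1)
  # arithmetic: sums 3.2 and 1.6 -> D = 1/3
  parts <- data.frame(abba = c(2, 1.2), baba = c(1.2, 0.4))
  expect_equal(patterson_d(parts), 1 / 3)
  # unpolarized panels are rejected
  y <- toy_panel(matrix(0L, 2, 4), anc = "unknown")
  pm <- population_map(stats::setNames(c("P1", "P2", "P3", "O"),
                                       y$samples),
                       roles = c(P1 = "P1", P2 = "P2", P3 = "P3",
                                 O = "O"))
  expect_error(compute_d_parts(y, pm), "no usable sites")
})

test_that("swapping P1 and P2 negates D exactly", {
  sim <- simulate_tree_panel(n_sites = 2000, seed = 43)
  pm <- sim_popmap(sim)
  d1 <- patterson_d(compute_d_parts(sim, pm))
  pm_swap <- population_map(pm$assignments,
                            roles = c(P1 = "P2", P2 = "P1", P3 = "P3",
                                      O = "O"))
  d2 <- patterson_d(compute_d_parts(sim, pm_swap))
  expect_equal(d1, -d2, tolerance = 1e-12)
})

test_that("genome-wide D equals the aggregate of window sums", {
  sim <- simulate_tree_panel(n_sites = 3000, seed = 47)
  pm <- sim_popmap(sim)
  parts <- compute_d_parts(sim, pm)
  g <- make_windows(sim, 20000, 20000)   # non-overlapping
  fdw <- window_fd(parts, g, min_snps = 1)
  ws <- popgenscan:::window_sums(parts[, c("contig", "pos")], g,
                                 cbind(parts$abba, parts$baba))
  expect_equal(sum(ws$sums[, 1] - ws$sums[, 2]) /
                 sum(ws$sums[, 1] + ws$sums[, 2]),
               patterson_d(parts), tolerance = 1e-12)
})

test_that("block jackknife matches the two-block closed form", {
  # two equal-weight blocks engineered so that D = 0.2 and the
  # delete-one estimates are 0.3 and 0.1
  parts <- data.frame(
    contig = "c", pos = c(1e6, 6e6),
    abba = c(0.65, 0.55), baba = c(0.35, 0.45))
  parts$p1 <- parts$p2 <- parts$p3 <- parts$p4 <- 0
  j <- block_jackknife(parts, block_bp = 5e6)
  expect_equal(j$estimate, 0.2)
  expect_equal(j$n_blocks, 2)
  # delete block 1 -> 0.1/1 = 0.1; delete block 2 -> 0.3
  # weighted jackknife with equal weights: SE = sqrt(mean((loo - D)^2))
  expect_equal(j$se, 0.1, tolerance = 1e-12)
  expect_equal(j$z, 2, tolerance = 1e-12)
  # degenerate: identical blocks give SE 0 and infinite Z with warning
  parts2 <- parts
  parts2$abba <- c(0.6, 0.6); parts2$baba <- c(0.4, 0.4)
  expect_warning(j2 <- block_jackknife(parts2, block_bp = 5e6), "SE = 0")
  expect_equal(j2$se, 0)
  expect_true(is.infinite(j2$z))
  expect_error(block_jackknife(parts[1, ], block_bp = 5e6),
               "decrease block_bp")
})

test_that("f_d is 1 when P2 and P3 coincide and obeys the window filters", {
  # identical P2/P3 frequency columns -> numerator == denominator
  sim <- simulate_tree_panel(n_sites = 500, seed = 53)
  pm <- sim_popmap(sim)
  idx2 <- popgenscan:::sample_idx(sim, pm, "P2")
  idx3 <- popgenscan:::sample_idx(sim, pm, "P3")
  sim$geno[, idx2] <- sim$geno[, idx3]
  sim$hap[, popgenscan:::hap_cols(idx2)] <-
    sim$hap[, popgenscan:::hap_cols(idx3)]
  parts <- compute_d_parts(sim, pm)
  g <- make_windows(sim, 20000, 20000)
  # floating-point ties can push f_d to 1 + eps; the clip warning is the
  # documented behaviour
  fdw <- suppressWarnings(window_fd(parts, g, min_snps = 1))
  pos_d <- fdw$valid
  expect_true(any(pos_d))
  expect_equal(fdw$fd[pos_d], rep(1, sum(pos_d)))
  # windows below the SNP floor are invalid
  fdw30 <- window_fd(parts, g, min_snps = 1e6)
  expect_false(any(fdw30$valid))
})

test_that("top-5% introgression caller keeps quantile ties and merges", {
  fdw <- data.frame(contig = "c", start = (0:99) * 100,
                    end = (0:99) * 100 + 100, n_snps = 50,
                    d = 0.5, fd = seq(0.005, 0.5, by = 0.005),
                    valid = TRUE)
  seg <- call_introgression(fdw, top_fraction = 0.05)
  # 5 windows qualify and they are adjacent -> one merged segment
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start, 9500)
  expect_equal(seg$score, 0.5)
  expect_error(call_introgression(fdw[1:10, ]), "valid windows")
})

test_that("dxy contrast flags planted introgression and rejects bad input", {
  p <- simulate_tree_panel(n_sites = 20000, spacing = 100, seed = 59)
  pm <- sim_popmap(p)
  tr <- data.frame(contig = "chr1", start = c(3e5, 9e5, 15e5),
                   end = c(3e5, 9e5, 15e5) + 8e4)
  p2 <- plant_introgression(p, pm, "P3", "P2", tr, fraction = 0.5,
                            seed = 61)
  g <- make_windows(p2, 20000, 10000)
  seg <- segment_set(tr$contig, tr$start, tr$end, provenance = "truth")
  out <- dxy_contrast(p2, pm, "P2", "P3", seg, g)
  med <- out$summary$median
  expect_lt(med[out$summary$group == "segment"],
            med[out$summary$group == "background"])
  expect_lt(out$p_value, 0.05)
  expect_error(dxy_contrast(p2, pm, "P2", "P3",
                            segment_set(provenance = "x"), g), "empty")
  whole <- segment_set("chr1", 0, p2$contigs$length, provenance = "x")
  expect_error(dxy_contrast(p2, pm, "P2", "P3", whole, g),
               "no background")
})
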