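#' Windowed nucleotide diversity (theta-pi)
#'
#' Per window, pi is the sum over SNPs of `2 a (n - a) / (n (n - 1))`
#' (with `a` the alt-allele count and `n` the non-missing allele count at
#' the site) divided by the window length in bp — the average number of
#' pairwise differences per site between two randomly drawn sequences.
#' Monomorphic windows (0 SNPs) get pi = 0 and are valid.
#'
#' @param panel a `VariantPanel`.
#' @param popmap a `PopulationMap`.
#' @param pop population label or role (needs >= 2 samples).
#' @param grid a `WindowGrid` from [make_windows()].
#' @return A `WindowStatTable` with per-bp pi values.
#' @export
window_pi <- function(panel, popmap, pop, grid) {
  idx <- sample_idx(panel, popmap, pop)
  if (length(idx) < 2L) stop("window_pi needs >= 2 samples in ", pop)
  ac <- allele_counts(panel, idx)
  site_pi <- ifelse(ac$n >= 2,
                    2 * ac$a * (ac$n - ac$a) / (ac$n * (ac$n - 1)), 0)
  ws <- window_sums(panel$sites, grid, cbind(site_pi))
  new_stat_table(grid, ws$n, ws$sums[, 1L] / (grid$end - grid$start),
                 valid = rep(TRUE, nrow(grid)), statistic = "pi")
}

# Tajima (1989) constants for sample size n (haploid sequences)
tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' Standard Tajima (1989) D per window from the segregating-site count S
#' and the mean pairwise difference sum, with the a1..e2 constants
#' evaluated at `n = 2 x (samples of the population with any non-missing
#' call in the window)`. Sites with more than 50% missing genotypes in the
#' population are skipped; windows with S = 0 are NA.
#'
#' @inheritParams window_pi
#' @param max_missing per-site maximum fraction of missing genotypes
#'   within the population (default 0.5).
#' @return A `WindowStatTable`.
#' @export
window_tajima_d <- function(panel, popmap, pop, grid, max_missing = 0.5) {
  idx <- sample_idx(panel, popmap, pop)
  if (length(idx) < 2L) stop("window_tajima_d needs >= 2 samples in ", pop)
  g <- panel$geno[, idx, drop = FALSE]
  nonmiss <- rowSums(!is.na(g))
  usable <- nonmiss >= length(idx) * (1 - max_missing) & nonmiss >= 2
  a <- rowSums(g, na.rm = TRUE)
  n_site <- 2 * nonmiss
  seg <- usable & a > 0 & a < n_site
  site_pi <- ifelse(usable & n_site >= 2,
                    2 * a * (n_site - a) / (n_site * (n_site - 1)), 0)
  site_pi[!usable] <- 0

  value <- rep(NA_real_, nrow(grid))
  nsnp <- integer(nrow(grid))
  # per-window sample count needs "any non-missing call in window" per sample
  for (w in seq_len(nrow(grid))) {
    si <- sites_in_window(panel$sites, grid$contig[w], grid$start[w],
                          grid$end[w])
    nsnp[w] <- length(si)
    if (length(si) == 0L) next
    su <- si[usable[si]]
    S <- sum(seg[si])
    if (S == 0L) next
    nsamp <- sum(colSums(!is.na(g[su, , drop = FALSE])) > 0)
    n <- 2L * nsamp
    if (n < 4L) next
    k <- sum(site_pi[si])
    cst <- tajima_constants(n)
    denom <- sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
    if (denom > 0) value[w] <- (k - S / cst$a1) / denom
  }
  new_stat_table(grid, nsnp, value, statistic = "tajima_d")
}

# Weir & Cockerham (1984) per-site variance components for two populations.
# Returns matrix with columns a (among), b (between individuals within),
# c (within individuals); theta = a / (a + b + c).
wc_components <- function(panel, idxA, idxB) {
  comp_pop <- function(idx) {
    g <- panel$geno[, idx, drop = FALSE]
    n <- rowSums(!is.na(g))              # diploid individuals with data
    a <- rowSums(g, na.rm = TRUE)
    p <- ifelse(n > 0, a / (2 * n), NA_real_)
    h <- ifelse(n > 0, rowSums(g == 1L, na.rm = TRUE) / n, NA_real_)
    list(n = n, p = p, h = h)
  }
  A <- comp_pop(idxA); B <- comp_pop(idxB)
  n1 <- A$n; n2 <- B$n
  ok <- n1 > 0 & n2 > 0 & (n1 + n2) > 2
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * A$p + n2 * B$p) / (2 * nbar)
  s2 <- (n1 * (A$p - pbar)^2 + n2 * (B$p - pbar)^2) / nbar
  hbar <- (n1 * A$h + n2 * B$h) / (2 * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; c_[!ok] <- NA_real_
  cbind(a = a, b = b, c = c_)
}

#' Windowed Weir-Cockerham F_ST
#'
#' Weir & Cockerham (1984) theta for two populations, windowed as a ratio
#' of sums: the per-site variance components are summed over the window and
#' the window value is `sum(a) / sum(a + b + c)`. Windows without any
#' polymorphic site are NA; negative estimates are preserved.
#'
#' @param panel a `VariantPanel`.
#' @param popmap a `PopulationMap`.
#' @param popA,popB population labels or roles (each >= 2 samples).
#' @param grid a `WindowGrid`.
#' @return A `WindowStatTable`.
#' @export
window_fst <- function(panel, popmap, popA, popB, grid) {
  idxA <- sample_idx(panel, popmap, popA)
  idxB <- sample_idx(panel, popmap, popB)
  if (length(idxA) < 2L || length(idxB) < 2L)
    stop("window_fst needs >= 2 samples per population")
  comp <- wc_components(panel, idxA, idxB)
  poly <- !is.na(comp[, 1L]) & (comp[, 1L] + comp[, 2L] + comp[, 3L]) != 0
  X <- cbind(ifelse(poly, comp[, 1L], 0),
             ifelse(poly, comp[, 1L] + comp[, 2L] + comp[, 3L], 0),
             as.numeric(poly))
  ws <- window_sums(panel$sites, grid, X)
  value <- ifelse(ws$sums[, 3L] > 0 & ws$sums[, 2L] != 0,
                  ws$sums[, 1L] / ws$sums[, 2L], NA_real_)
  new_stat_table(grid, ws$n, value, statistic = "fst")
}

#' Genome-wide Weir-Cockerham F_ST
#'
#' Ratio-of-sums estimate over all sites (equivalent to a single window
#' spanning the genome).
#'
#' @inheritParams window_fst
#' @return scalar estimate.
#' @export
global_fst <- function(panel, popmap, popA, popB) {
  comp <- wc_components(panel, sample_idx(panel, popmap, popA),
                        sample_idx(panel, popmap, popB))
  keep <- !is.na(comp[, 1L])
  sum(comp[keep, 1L]) / sum(comp[keep, ])
}

#' Windowed absolute sequence divergence dXY
#'
#' Per window, `dXY = sum_sites [pA (1 - pB) + (1 - pA) pB] / window length`
#' with pA, pB the alt-allele frequencies over non-missing alleles;
#' invariant sites contribute 0, so the value is per-bp.
#'
#' @param panel a `VariantPanel`.
#' @param popmap a `PopulationMap`.
#' @param popA,popB population labels or roles (each >= 1 sample).
#' @param grid a `WindowGrid`.
#' @return A `WindowStatTable` with per-bp dXY.
#' @export
window_dxy <- function(panel, popmap, popA, popB, grid) {
  acA <- allele_counts(panel, sample_idx(panel, popmap, popA))
  acB <- allele_counts(panel, sample_idx(panel, popmap, popB))
  pA <- ifelse(acA$n > 0, acA$a / acA$n, NA_real_)
  pB <- ifelse(acB$n > 0, acB$a / acB$n, NA_real_)
  d <- pA * (1 - pB) + (1 - pA) * pB
  d[is.na(d)] <- 0
  ws <- window_sums(panel$sites, grid, cbind(d))
  new_stat_table(grid, ws$n, ws$sums[, 1L] / (grid$end - grid$start),
                 valid = rep(TRUE, nrow(grid)), statistic = "dxy")
}

#' Observed/expected heterozygosity and inbreeding coefficient
#'
#' Per population: `Ho` is the mean fraction of heterozygous genotypes
#' across sites and samples, `He` the mean over sites of `2 p (1 - p)`
#' with `p` the population alt-allele frequency, and `F = 1 - Ho / He`
#' (no small-sample correction). Also returns per-sample heterozygosity.
#'
#' @param panel a `VariantPanel`.
#' @param popmap a `PopulationMap`.
#' @return list with `population` (pop, n_samples, ho, he, f) and
#'   `sample` (sample, pop, n_called, n_het, het_rate) data.frames.
#' @export
inbreeding_f <- function(panel, popmap) {
  pops <- unique(popmap$assignments)
  pop_rows <- lapply(pops, function(pp) {
    idx <- sample_idx(panel, popmap, pp)
    g <- panel$geno[, idx, drop = FALSE]
    ho <- mean(g == 1L, na.rm = TRUE)
    ac <- allele_counts(panel, idx)
    p <- ifelse(ac$n > 0, ac$a / ac$n, NA_real_)
    he <- mean(2 * p * (1 - p), na.rm = TRUE)
    f <- if (is.na(he) || he == 0) {
      warning("He = 0 in population ", pp, "; F undefined")
      NA_real_
    } else 1 - ho / he
    data.frame(pop = pp, n_samples = length(idx), ho = ho, he = he, f = f,
               stringsAsFactors = FALSE)
  })
  n_called <- colSums(!is.na(panel$geno))
  n_het <- colSums(panel$geno == 1L, na.rm = TRUE)
  samp <- data.frame(sample = panel$samples,
                     pop = popmap$assignments[panel$samples],
                     n_called = n_called, n_het = n_het,
                     het_rate = ifelse(n_called > 0, n_het / n_called,
                                       NA_real_),
                     stringsAsFactors = FALSE, row.names = NULL)
  list(population = do.call(rbind, pop_rows), sample = samp)
}

#' Windowed log2 diversity ratio and genome-wide ratio
#'
#' Per window, `log2(piB / piA)`; NA when either pi is 0 or NA. The
#' genome-wide scalar is the ratio of summed diversities
#' `sum(piB) / sum(piA)` over windows valid in both tables (the mean of
#' per-window ratios is also reported as an attribute).
#'
#' @param piA,piB `WindowStatTable`s from [window_pi()] on the same grid.
#' @return A `WindowStatTable` of log2 ratios with attributes
#'   `ratio_of_sums` and `mean_of_ratios`.
#' @export
pi_ratio <- function(piA, piB) {
  if (!same_grid(piA, piB)) stop("pi_ratio: window grids differ")
  both <- piA$valid & piB$valid & !is.na(piA$value) & !is.na(piB$value)
  lr <- rep(NA_real_, nrow(piA))
  ok <- both & piA$value > 0 & piB$value > 0
  lr[ok] <- log2(piB$value[ok] / piA$value[ok])
  out <- new_stat_table(piA[, c("contig", "start", "end")],
                        pmin(piA$n_snps, piB$n_snps), lr,
                        statistic = "log2_pi_ratio")
  attr(out, "size") <- attr(piA, "size")
  attr(out, "step") <- attr(piA, "step")
  attr(out, "ratio_of_sums") <-
    sum(piB$value[both]) / sum(piA$value[both])
  attr(out, "mean_of_ratios") <- mean(piB$value[ok] / piA$value[ok])
  out
}
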