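# Synthetic multi-population genotype generators.
#
# Two complementary generators: a frequency-level Balding-Nichols model
# (fast, F_ST-calibrated, sites independent -- no linkage) for tests of
# frequency-based statistics, and a forward Wright-Fisher simulator with
# recombination and mutation (slow, produces the linkage, haplotype and
# homozygosity structure the EHH/ROH/LD scans require). Planting helpers
# transplant introgression tracts, partial sweeps and homozygous tracts
# with exact truth records.

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Balding-Nichols drift kernel: population frequency ~
# Beta(p (1 - F) / F, (1 - p) (1 - F) / F); F = 0 returns p exactly.
bn_drift <- function(p, f) {
  if (f <= 0) return(p)
  out <- p
  seg <- p > 0 & p < 1
  out[seg] <- stats::rbeta(sum(seg), p[seg] * (1 - f) / f,
                           (1 - p[seg]) * (1 - f) / f)
  out
}

freqs_to_panel <- function(freq, pops, spacing, contig, truth) {
  n_sites <- nrow(freq)
  total <- sum(pops)
  hap <- matrix(0L, n_sites, 2L * total)
  col0 <- 0L
  for (k in seq_along(pops)) {
    nh <- 2L * pops[[k]]
    hap[, col0 + seq_len(nh)] <-
      matrix(stats::rbinom(n_sites * nh, 1L, rep(freq[, k], nh)),
             n_sites, nh)
    col0 <- col0 + nh
  }
  samples <- unlist(lapply(names(pops), function(nm)
    paste0(nm, "_", seq_len(pops[[nm]]))))
  geno <- hap[, seq(1L, ncol(hap), by = 2L), drop = FALSE] +
    hap[, seq(2L, ncol(hap), by = 2L), drop = FALSE]
  pos <- as.numeric(spacing) * seq_len(n_sites)
  contigs <- data.frame(name = contig,
                        length = as.numeric(spacing) * (n_sites + 1L))
  sites <- data.frame(contig = contig, pos = pos, ref = "A", alt = "T",
                      ancestral = "ref", stringsAsFactors = FALSE)
  panel <- variant_panel(contigs, sites, geno, samples, hap = hap,
                         truth = truth)
  panel
}

#' Simulate a Balding-Nichols frequency panel
#'
#' Per site, an ancestral frequency is drawn uniformly on `p_range`; each
#' population's frequency is Beta-distributed around it with the
#' population's target F_ST; genotypes are binomial(2, freq) and
#' haplotypes Bernoulli draws (sites are independent, so the panel has no
#' linkage structure). The reference allele is the ancestral allele by
#' construction and sites are pre-polarized. Suitable for pi / F_ST /
#' dXY / D / f_d / V_ST-style tests, not for EHH, ROH or LD.
#'
#' @param n_sites number of sites.
#' @param pops named integer vector of diploid sample counts per
#'   population.
#' @param fst target F_ST, a scalar or one value per population.
#' @param spacing bp between adjacent sites (default 100).
#' @param p_range range of the ancestral allele frequency distribution.
#' @param contig contig name.
#' @param seed integer seed; identical seeds give identical panels.
#' @return A phased `VariantPanel`; `$truth` holds `ancestral_freq` and
#'   the realized `pop_freq` matrix.
#' @export
simulate_bn_panel <- function(n_sites = 1000L, pops = c(A = 25L, B = 25L),
                              fst = 0.2, spacing = 100L,
                              p_range = c(0.05, 0.95), contig = "chr1",
                              seed = NULL) {
  if (length(fst) == 1L) fst <- rep(fst, length(pops))
  with_seed_maybe(seed, {
    p0 <- stats::runif(n_sites, p_range[1L], p_range[2L])
    freq <- vapply(seq_along(pops), function(k) bn_drift(p0, fst[k]),
                   numeric(n_sites))
    colnames(freq) <- names(pops)
    freqs_to_panel(freq, pops, spacing, contig,
                   truth = list(ancestral_freq = p0, pop_freq = freq))
  })
}

#' Simulate a four-population tree-structured frequency panel
#'
#' Frequencies drift along the topology `(((P1, P2), P3), O)` with a
#' Balding-Nichols kernel per branch: the root frequency drifts to the
#' outgroup and to the internal P1P2P3 ancestor, then onward to P3 and to
#' the P1P2 ancestor, and finally to P1 and P2. With `F_P1 = F_P2` the
#' four-taxon D statistic has expectation 0 (no gene flow), making this
#' the null generator for ABBA-BABA calibration; introgression is planted
#' afterwards with [plant_introgression()].
#'
#' @param n_sites number of sites.
#' @param pops named diploid sample counts, names `P1`, `P2`, `P3`, `O`.
#' @param branch_fst named drift amounts per branch: `n123` (root to
#'   inner ancestor), `n12`, `P1`, `P2`, `P3`, `O`.
#' @param spacing,p_range,contig,seed as in [simulate_bn_panel()].
#' @return A phased, pre-polarized `VariantPanel` with role-ready
#'   population labels and truth frequencies.
#' @export
simulate_tree_panel <- function(n_sites = 5000L,
                                pops = c(P1 = 20L, P2 = 20L, P3 = 20L,
                                         O = 10L),
                                branch_fst = c(n123 = 0.1, n12 = 0.05,
                                               P1 = 0.03, P2 = 0.03,
                                               P3 = 0.15, O = 0.4),
                                spacing = 100L, p_range = c(0.02, 0.4),
                                contig = "chr1", seed = NULL) {
  stopifnot(all(c("P1", "P2", "P3", "O") %in% names(pops)))
  with_seed_maybe(seed, {
    p0 <- stats::runif(n_sites, p_range[1L], p_range[2L])
    p_o <- bn_drift(p0, branch_fst[["O"]])
    p_123 <- bn_drift(p0, branch_fst[["n123"]])
    p_3 <- bn_drift(p_123, branch_fst[["P3"]])
    p_12 <- bn_drift(p_123, branch_fst[["n12"]])
    p_1 <- bn_drift(p_12, branch_fst[["P1"]])
    p_2 <- bn_drift(p_12, branch_fst[["P2"]])
    freq <- cbind(P1 = p_1, P2 = p_2, P3 = p_3, O = p_o)
    freq <- freq[, names(pops), drop = FALSE]
    freqs_to_panel(freq, pops, spacing, contig,
                   truth = list(ancestral_freq = p0, pop_freq = freq))
  })
}

#' Default population map for a simulated panel
#'
#' Samples are named `<pop>_<i>` by the simulators; this rebuilds the
#' population map (with four-taxon roles when P1..O are present).
#'
#' @param panel a simulated `VariantPanel`.
#' @return A `PopulationMap`.
#' @export
sim_popmap <- function(panel) {
  pop <- sub("_[0-9]+$", "", panel$samples)
  a <- pop
  names(a) <- panel$samples
  roles <- NULL
  if (all(c("P1", "P2", "P3", "O") %in% pop))
    roles <- c(P1 = "P1", P2 = "P2", P3 = "P3", O = "O")
  population_map(a, roles = roles)
}

# one gamete from diploid `parent` (1-based): crossover count ~
# Poisson(r_bp * L), breakpoints uniform; returns a 0/1 vector over sites
gamete <- function(H, pos, parent, r_bp, L) {
  c1 <- 2L * parent - 1L
  nx <- stats::rpois(1L, r_bp * L)
  phase <- stats::runif(1L) < 0.5
  if (nx == 0L) return(H[, c1 + as.integer(phase)])
  br <- sort(stats::runif(nx, 0, L))
  sel <- (findInterval(pos, br) + as.integer(phase)) %% 2L
  h <- H[, c1]
  swap <- sel == 1L
  h[swap] <- H[swap, c1 + 1L]
  h
}

# advance one population state by `gens` generations
wf_evolve <- function(st, gens, n_dip, mu_bp, r_bp, L, selfing = 0) {
  for (g in seq_len(gens)) {
    S <- length(st$pos)
    n_hap <- 2L * n_dip
    Hn <- matrix(0L, S, n_hap)
    par1 <- sample.int(ncol(st$H) / 2L, n_dip, replace = TRUE)
    self <- stats::runif(n_dip) < selfing
    par2 <- ifelse(self, par1,
                   sample.int(ncol(st$H) / 2L, n_dip, replace = TRUE))
    for (i in seq_len(n_dip)) {
      Hn[, 2L * i - 1L] <- gamete(st$H, st$pos, par1[i], r_bp, L)
      Hn[, 2L * i] <- gamete(st$H, st$pos, par2[i], r_bp, L)
    }
    n_mut <- stats::rpois(1L, n_hap * mu_bp * L)
    if (n_mut > 0L) {
      mpos <- stats::runif(n_mut, 0, L)
      mpos <- mpos[!(mpos %in% st$pos)]
      if (length(mpos) > 0L) {
        block <- matrix(0L, length(mpos), n_hap)
        block[cbind(seq_along(mpos),
                    sample.int(n_hap, length(mpos), replace = TRUE))] <- 1L
        Hn <- rbind(Hn, block)
        st$pos <- c(st$pos, mpos)
        st$marker <- c(st$marker, rep(FALSE, length(mpos)))
      }
    }
    f <- rowSums(Hn)
    lost <- f == 0L & !st$marker
    fixed <- f == ncol(Hn) & !st$marker
    st$fixed <- c(st$fixed, st$pos[fixed])
    keep <- !lost & !fixed
    st$H <- Hn[keep, , drop = FALSE]
    st$pos <- st$pos[keep]
    st$marker <- st$marker[keep]
  }
  st
}

# founder population at mutation-drift equilibrium: segregating-site count
# theta_L * H_{2N-1} with frequencies ~ 1/i (the neutral SFS), carriers
# assigned independently per site (linkage equilibrium; the burn-in builds
# the LD).
wf_founders <- function(n_dip, mu_bp, L) {
  n_hap <- 2L * n_dip
  theta <- 2 * n_hap * mu_bp * L   # 4 N mu L
  i <- seq_len(n_hap - 1L)
  s <- stats::rpois(1L, theta * sum(1 / i))
  counts <- sample(i, s, replace = TRUE, prob = 1 / i)
  pos <- stats::runif(s, 0, L)
  H <- matrix(0L, s, n_hap)
  for (k in seq_len(s))
    H[k, sample.int(n_hap, counts[k])] <- 1L
  list(H = H, pos = pos, marker = rep(FALSE, s), fixed = numeric())
}

# align a donor state onto the recipient's site registry (union of
# positions, honouring each side's fixed lists); returns the donor
# haplotype matrix over the recipient's new registry and the updated
# recipient state
wf_align <- function(rec, don) {
  upos <- sort(unique(c(rec$pos, don$pos, rec$fixed, don$fixed)))
  expand <- function(st) {
    M <- matrix(0L, length(upos), ncol(st$H))
    hit <- match(st$pos, upos)
    M[hit, ] <- st$H
    fx <- match(setdiff(st$fixed, st$pos), upos)
    M[fx, ] <- 1L
    M
  }
  Mr <- expand(rec)
  Md <- expand(don)
  marker <- rep(FALSE, length(upos))
  marker[match(rec$pos[rec$marker], upos)] <- TRUE
  list(rec = list(H = Mr, pos = upos, marker = marker, fixed = numeric()),
       donor_H = Md)
}

#' Forward Wright-Fisher simulation of four phased populations
#'
#' Simulates diploid populations of size `n_e` on the topology
#' `(((P1, P2), P3), O)` by discrete-generation random mating with
#' per-generation crossover (Poisson, uniform breakpoints) and
#' infinite-sites mutation at continuous positions (discretized to bp at
#' emission). Founders are drawn from the neutral site-frequency
#' spectrum at linkage equilibrium and a burn-in builds the linkage
#' structure, so a neutral run stays near mutation-drift equilibrium.
#' An optional single-generation migration pulse implants donor
#' haplotypes into the recipient; donor ancestry is tracked by neutral
#' marker loci that recombine with the real sites, giving realized
#' ancestry fractions and tract records.
#'
#' Population sizes are desk-scale (`n_e <= 2000`, chromosome <= 5 Mb);
#' mutation and recombination rates are meant to be scaled up
#' accordingly so that theta = 4 N mu matches the diversity of the
#' system being emulated.
#'
#' @param pops named diploid sample counts to emit (names P1, P2, P3, O;
#'   any subset, but splits follow the fixed topology).
#' @param n_e diploid population size during the simulation.
#' @param chrom_length chromosome length in bp.
#' @param mu mutation rate per bp per generation.
#' @param recomb recombination rate per bp per generation.
#' @param split_gens generations ago of the splits: `t12` (P1/P2),
#'   `t123` (P3), `t_o` (outgroup); `t12 <= t123 <= t_o`.
#' @param burn_in generations of pre-split burn-in.
#' @param pulse optional list(donor, recipient, time, fraction) for a
#'   one-generation migration pulse `time` generations ago between
#'   present-day lineages (time < t12).
#' @param selfing per-individual selfing probability.
#' @param marker_bp spacing of ancestry marker loci (pulse only).
#' @param contig contig name.
#' @param seed integer seed.
#' @return A phased `VariantPanel`; `$truth` records the realized pulse
#'   ancestry (fraction, per-marker frequencies) when a pulse was run.
#' @export
simulate_wf_haplotypes <- function(pops = c(P1 = 10L, P2 = 10L,
                                            P3 = 10L, O = 10L),
                                   n_e = 100L, chrom_length = 1e6,
                                   mu = 5e-7, recomb = 1e-6,
                                   split_gens = c(t12 = 40L, t123 = 80L,
                                                  t_o = 160L),
                                   burn_in = 200L, pulse = NULL,
                                   selfing = 0, marker_bp = 5000,
                                   contig = "chr1", seed = NULL) {
  if (n_e > 2000L || chrom_length > 5e6)
    stop("desk-scale guard: n_e <= 2000 and chrom_length <= 5e6; ",
         "rescale mu and recomb to preserve theta = 4 N mu")
  t12 <- split_gens[["t12"]]; t123 <- split_gens[["t123"]]
  t_o <- split_gens[["t_o"]]
  stopifnot(t12 <= t123, t123 <= t_o)
  L <- chrom_length
  with_seed_maybe(seed, {
    ev <- function(st, gens) wf_evolve(st, gens, n_e, mu, recomb, L,
                                       selfing)
    root <- ev(wf_founders(n_e, mu, L), burn_in)
    pulse_truth <- NULL
    t_pulse <- if (is.null(pulse)) 0L else pulse$time
    if (!is.null(pulse)) stopifnot(t_pulse <= t12)
    # evolve every present-day lineage down to the pulse time (the
    # present when there is no pulse), inject, then finish
    n123 <- ev(root, t_o - t123)
    n12 <- ev(n123, t123 - t12)
    states <- list(P1 = ev(n12, t12 - t_pulse),
                   P2 = ev(n12, t12 - t_pulse),
                   P3 = ev(n123, t123 - t_pulse),
                   O = ev(root, t_o - t_pulse))
    if (!is.null(pulse)) {
      rec <- states[[pulse$recipient]]
      don <- states[[pulse$donor]]
      al <- wf_align(rec, don)
      rec <- al$rec
      # ancestry markers: offset positions so they never collide with sites
      mk_pos <- seq(marker_bp / 2, L, by = marker_bp) + 0.25
      mk <- matrix(0L, length(mk_pos), ncol(rec$H))
      n_mig <- max(1L, round(pulse$fraction * ncol(rec$H)))
      mig_cols <- sample.int(ncol(rec$H), n_mig)
      rec$H[, mig_cols] <- al$donor_H[, sample.int(ncol(al$donor_H),
                                                   n_mig, replace = TRUE)]
      mk[, mig_cols] <- 1L
      rec$H <- rbind(rec$H, mk)
      rec$pos <- c(rec$pos, mk_pos)
      rec$marker <- c(rec$marker, rep(TRUE, length(mk_pos)))
      states[[pulse$recipient]] <- rec
      for (nm in names(states))
        states[[nm]] <- ev(states[[nm]], t_pulse)
      # realized ancestry from the marker rows
      rec <- states[[pulse$recipient]]
      mrows <- which(rec$marker)
      ord <- order(rec$pos[mrows])
      mrows <- mrows[ord]
      mfreq <- rowMeans(rec$H[mrows, , drop = FALSE])
      pulse_truth <- list(
        donor = pulse$donor, recipient = pulse$recipient,
        fraction = pulse$fraction, time = t_pulse,
        realized_fraction = mean(mfreq),
        marker = data.frame(pos = rec$pos[mrows] - 0.25,
                            donor_freq = mfreq))
    }

    # sample and emit
    take <- names(pops)
    hap_list <- list()
    samples <- character()
    all_pos <- sort(unique(unlist(lapply(states[take], function(st)
      c(st$pos[!st$marker], st$fixed)))))
    for (nm in take) {
      st <- states[[nm]]
      ids <- sample.int(n_e, pops[[nm]])
      cols <- as.vector(rbind(2L * ids - 1L, 2L * ids))
      M <- matrix(0L, length(all_pos), length(cols))
      hit <- match(st$pos[!st$marker], all_pos)
      M[hit, ] <- st$H[!st$marker, cols, drop = FALSE]
      fx <- match(setdiff(st$fixed, st$pos[!st$marker]), all_pos)
      M[fx, ] <- 1L
      hap_list[[nm]] <- M
      samples <- c(samples, paste0(nm, "_", seq_len(pops[[nm]])))
    }
    hap <- do.call(cbind, hap_list)
    # keep sites segregating in the combined sample; discretize positions
    f <- rowSums(hap)
    keep <- f > 0L & f < ncol(hap)
    hap <- hap[keep, , drop = FALSE]
    pos <- ceiling(all_pos[keep])
    dup <- duplicated(pos)
    hap <- hap[!dup, , drop = FALSE]
    pos <- pos[!dup]
    geno <- hap[, seq(1L, ncol(hap), by = 2L), drop = FALSE] +
      hap[, seq(2L, ncol(hap), by = 2L), drop = FALSE]
    contigs <- data.frame(name = contig, length = L)
    sites <- data.frame(contig = rep(contig, length(pos)), pos = pos,
                        ref = rep("A", length(pos)),
                        alt = rep("T", length(pos)),
                        ancestral = rep("ref", length(pos)),
                        stringsAsFactors = FALSE)
    variant_panel(contigs, sites, geno, samples, hap = hap,
                  truth = list(pulse = pulse_truth))
  })
}

sites_in_region <- function(panel, contig, start, end) {
  which(panel$sites$contig == contig & panel$sites$pos > start &
          panel$sites$pos <= end)
}

recompute_geno <- function(panel) {
  panel$geno <- panel$hap[, seq(1L, ncol(panel$hap), by = 2L),
                          drop = FALSE] +
    panel$hap[, seq(2L, ncol(panel$hap), by = 2L), drop = FALSE]
  colnames(panel$geno) <- panel$samples
  panel
}

#' Transplant introgression tracts into a panel
#'
#' Within each tract, a fixed random subset (`fraction`) of the recipient
#' population's haplotypes is overwritten with haplotypes sampled from
#' the donor population, giving sharp truth boundaries for caller
#' recall/precision tests. Genotypes are recomputed from the haplotypes.
#'
#' @param panel a phased `VariantPanel`.
#' @param popmap a `PopulationMap`.
#' @param donor,recipient population labels or roles.
#' @param tracts data.frame with columns contig, start, end (0-based
#'   half-open).
#' @param fraction admixture fraction of recipient haplotypes replaced.
#' @param seed integer seed.
#' @return The modified panel; `$truth$tracts` records tracts, carrier
#'   haplotypes and the realized fraction.
#' @export
plant_introgression <- function(panel, popmap, donor, recipient, tracts,
                                fraction = 0.3, seed = NULL) {
  if (is.null(panel$hap)) stop("plant_introgression needs a phased panel")
  with_seed_maybe(seed, {
    don_cols <- hap_cols(sample_idx(panel, popmap, donor))
    rec_cols <- hap_cols(sample_idx(panel, popmap, recipient))
    n_carry <- max(1L, round(fraction * length(rec_cols)))
    carriers <- sample(rec_cols, n_carry)
    src <- sample(don_cols, n_carry, replace = TRUE)
    for (t in seq_len(nrow(tracts))) {
      rows <- sites_in_region(panel, tracts$contig[t], tracts$start[t],
                              tracts$end[t])
      if (length(rows) == 0L) next
      panel$hap[rows, carriers] <- panel$hap[rows, src, drop = FALSE]
    }
    panel <- recompute_geno(panel)
    panel$truth$tracts <- list(
      tracts = tracts, carriers = carriers,
      realized_fraction = n_carry / length(rec_cols),
      donor = donor, recipient = recipient)
    panel
  })
}

#' Plant a hard partial sweep
#'
#' Within the region, one randomly chosen haplotype of the population is
#' copied over `final_freq` of the population's haplotypes, reducing
#' diversity and extending haplotype homozygosity as an idealized
#' recent sweep would.
#'
#' @param panel a phased `VariantPanel`.
#' @param popmap a `PopulationMap`.
#' @param pop swept population label or role.
#' @param region list or data.frame row with contig, start, end.
#' @param final_freq frequency of the beneficial haplotype after the
#'   sweep (1 = fixed).
#' @param seed integer seed.
#' @return The modified panel with `$truth$sweeps` appended.
#' @export
plant_sweep <- function(panel, popmap, pop, region, final_freq = 0.8,
                        seed = NULL) {
  if (is.null(panel$hap)) stop("plant_sweep needs a phased panel")
  if (final_freq <= 0) return(panel)
  with_seed_maybe(seed, {
    cols <- hap_cols(sample_idx(panel, popmap, pop))
    rows <- sites_in_region(panel, region$contig, region$start,
                            region$end)
    if (length(rows) == 0L) stop("region contains no sites")
    src <- sample(cols, 1L)
    n_carry <- round(final_freq * length(cols))
    carriers <- if (final_freq >= 1) cols else
      c(src, sample(setdiff(cols, src), max(0L, n_carry - 1L)))
    panel$hap[rows, carriers] <- panel$hap[rows, src]
    panel <- recompute_geno(panel)
    panel$truth$sweeps <- rbind(
      panel$truth$sweeps,
      data.frame(contig = region$contig, start = region$start,
                 end = region$end, pop = pop, final_freq = final_freq,
                 stringsAsFactors = FALSE))
    panel
  })
}

#' Plant a homozygous (ROH) tract in one sample
#'
#' Copies the sample's first haplotype over its second within the region,
#' making every genotype there homozygous.
#'
#' @param panel a phased `VariantPanel`.
#' @param sample sample identifier.
#' @param region list or data.frame row with contig, start, end.
#' @return The modified panel with `$truth$roh` appended.
#' @export
plant_roh <- function(panel, sample, region) {
  if (is.null(panel$hap)) stop("plant_roh needs a phased panel")
  i <- match(sample, panel$samples)
  if (is.na(i)) stop("sample not in panel")
  rows <- sites_in_region(panel, region$contig, region$start, region$end)
  panel$hap[rows, 2L * i] <- panel$hap[rows, 2L * i - 1L]
  panel <- recompute_geno(panel)
  panel$truth$roh <- rbind(
    panel$truth$roh,
    data.frame(contig = region$contig, start = region$start,
               end = region$end, sample = sample, stringsAsFactors = FALSE))
  panel
}

#' Simulate a copy-number depth-ratio matrix
#'
#' Neutral regions have depth ratio Normal(1, `noise_sd`) in every
#' sample; differentiated regions give population B a mean copy number of
#' `2 + delta_copy` (ratio `(2 + delta_copy) / 2`) while population A
#' stays diploid. Ratios are floored at 0.
#'
#' @param n_regions total regions.
#' @param pops named diploid sample counts (two populations).
#' @param n_diff number of population-differentiated regions.
#' @param delta_copy copy-number difference planted in population B.
#' @param noise_sd depth-ratio noise standard deviation.
#' @param region_bp region span in bp (regions are laid end to end with
#'   a gap of the same size).
#' @param contig contig name.
#' @param seed integer seed.
#' @return list: `matrix` (a `CopyNumberMatrix`), `popmap`, and `truth`
#'   (data.frame of differentiated regions).
#' @export
simulate_cn_matrix <- function(n_regions = 200L,
                               pops = c(A = 10L, B = 10L), n_diff = 10L,
                               delta_copy = 1, noise_sd = 0.05,
                               region_bp = 1000, contig = "chr1",
                               seed = NULL) {
  stopifnot(length(pops) == 2L, n_diff <= n_regions)
  with_seed_maybe(seed, {
    start <- (seq_len(n_regions) - 1L) * 2 * region_bp
    regions <- data.frame(contig = contig, start = start,
                          end = start + region_bp,
                          stringsAsFactors = FALSE)
    samples <- unlist(lapply(names(pops), function(nm)
      paste0(nm, "_", seq_len(pops[[nm]]))))
    n_tot <- sum(pops)
    mean_ratio <- matrix(1, n_regions, n_tot)
    diff_idx <- sort(sample.int(n_regions, n_diff))
    b_cols <- sum(pops[1L]) + seq_len(pops[2L])
    mean_ratio[diff_idx, b_cols] <- (2 + delta_copy) / 2
    ratios <- mean_ratio +
      matrix(stats::rnorm(n_regions * n_tot, 0, noise_sd), n_regions)
    ratios <- pmax(ratios, 0)
    colnames(ratios) <- samples
    pm <- population_map(stats::setNames(rep(names(pops), pops), samples))
    list(matrix = cn_matrix(regions, ratios), popmap = pm,
         truth = data.frame(regions[diff_idx, , drop = FALSE],
                            delta_copy = delta_copy,
                            row.names = NULL))
  })
}
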