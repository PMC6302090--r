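# Independent brute-force oracles used to validate the vectorized
# implementations on tiny panels. These deliberately enumerate haplotype
# pairs / site patterns one by one and share no code with R/.

# mean pairwise difference per bp among the haplotypes of `cols`
oracle_pi <- function(panel, cols, start, end) {
  rows <- which(panel$sites$pos > start & panel$sites$pos <= end)
  H <- panel$hap[rows, cols, drop = FALSE]
  k <- length(cols)
  tot <- 0
  npair <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      tot <- tot + sum(H[, i] != H[, j])
      npair <- npair + 1
    }
  }
  tot / npair / (end - start)
}

# mean pairwise difference per bp across two haplotype sets
oracle_dxy <- function(panel, colsA, colsB, start, end) {
  rows <- which(panel$sites$pos > start & panel$sites$pos <= end)
  tot <- 0
  for (i in colsA)
    for (j in colsB)
      tot <- tot + sum(panel$hap[rows, i] != panel$hap[rows, j])
  tot / (length(colsA) * length(colsB)) / (end - start)
}

# per-pair IBS: fraction of alleles shared, averaged over sites
oracle_ibs_pair <- function(ga, gb) {
  ok <- !is.na(ga) & !is.na(gb)
  shared <- numeric(0)
  for (s in which(ok)) {
    # alleles of each genotype as multisets
    aa <- c(rep(0, 2 - ga[s]), rep(1, ga[s]))
    bb <- c(rep(0, 2 - gb[s]), rep(1, gb[s]))
    shared <- c(shared, (min(sum(aa == 0), sum(bb == 0)) +
                           min(sum(aa == 1), sum(bb == 1))) / 2)
  }
  mean(shared)
}

# EHH at each downstream site by grouping full haplotype prefixes
oracle_ehh_right <- function(H, pos, focal, core_cols) {
  K <- length(core_cols)
  out <- data.frame(dist = 0, ehh = 1)
  if (focal >= nrow(H)) return(out)
  for (j in (focal + 1):nrow(H)) {
    keys <- apply(H[(focal + 1):j, core_cols, drop = FALSE], 2,
                  paste, collapse = ",")
    cnt <- table(keys)
    out <- rbind(out, data.frame(
      dist = pos[j] - pos[focal],
      ehh = sum(choose(cnt, 2)) / choose(K, 2)))
  }
  out
}

# Patterson's D from per-population derived-allele frequencies
oracle_d <- function(p1, p2, p3, p4) {
  num <- den <- 0
  for (s in seq_along(p1)) {
    abba <- (1 - p1[s]) * p2[s] * p3[s] * (1 - p4[s])
    baba <- p1[s] * (1 - p2[s]) * p3[s] * (1 - p4[s])
    num <- num + (abba - baba)
    den <- den + (abba + baba)
  }
  num / den
}

# V_ST from the raw per-sample values of two populations
oracle_vst <- function(va, vb) {
  vt <- stats::var(c(va, vb))
  vs <- (length(va) * stats::var(va) + length(vb) * stats::var(vb)) /
    (length(va) + length(vb))
  (vt - vs) / vt
}

# Tajima's D for one window: n haploid sequences, S segregating sites,
# k mean pairwise differences (independent re-derivation of the 1989
# constants)
oracle_tajima_d <- function(n, S, k) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# small fully-specified panel builder for hand examples
toy_panel <- function(geno, pos = NULL, hap = NULL, contig_len = NULL,
                      anc = "ref") {
  geno <- as.matrix(geno)
  S <- nrow(geno)
  if (is.null(pos)) pos <- seq_len(S) * 10
  if (is.null(contig_len)) contig_len <- max(pos) + 10
  samples <- paste0("s", seq_len(ncol(geno)))
  variant_panel(
    contigs = data.frame(name = "chr1", length = contig_len),
    sites = data.frame(contig = "chr1", pos = pos, ref = "A", alt = "T",
                       ancestral = anc, stringsAsFactors = FALSE),
    geno = geno, samples = samples, hap = hap)
}
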