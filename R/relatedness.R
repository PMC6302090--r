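#' Identity score between reference-support ratios
#'
#' `IS = 1 - |Ra - Rb|`, where Ra and Rb are the fractions of evidence
#' supporting the reference allele in samples a and b at a site. The
#' absolute value keeps the score symmetric and within [0, 1].
#'
#' @param ra,rb numeric vectors in [0, 1].
#' @return numeric vector of identity scores.
#' @export
identity_score <- function(ra, rb) {
  stopifnot(all(ra >= 0 & ra <= 1, na.rm = TRUE),
            all(rb >= 0 & rb <= 1, na.rm = TRUE))
  1 - abs(ra - rb)
}

#' Pairwise identity-score matrix for a panel
#'
#' With genotype data only, the reference-support ratio is approximated by
#' the reference-allele dosage `(2 - g) / 2`. Per pair, IS is averaged
#' over sites non-missing in both samples.
#'
#' @param panel a `VariantPanel`.
#' @return symmetric samples x samples matrix (diagonal 1).
#' @export
identity_score_matrix <- function(panel) {
  pairwise_site_mean(panel, function(ga, gb) 1 - abs(ga - gb) / 2)
}

#' Pairwise identity-by-state similarity matrix
#'
#' Per pair, the mean over shared non-missing sites of
#' `(2 - |g_a - g_b|) / 2` — the fraction of alleles shared identical by
#' state.
#'
#' @param panel a `VariantPanel` (>= 2 samples).
#' @return symmetric samples x samples matrix.
#' @export
pairwise_ibs <- function(panel) {
  if (n_samples(panel) < 2L) stop("pairwise_ibs needs >= 2 samples")
  pairwise_site_mean(panel, function(ga, gb) (2 - abs(ga - gb)) / 2)
}

pairwise_site_mean <- function(panel, f) {
  g <- panel$geno
  ns <- ncol(g)
  out <- matrix(NA_real_, ns, ns, dimnames = list(panel$samples,
                                                  panel$samples))
  for (i in seq_len(ns)) {
    out[i, i] <- 1
    for (j in seq_len(ns)[-seq_len(i)]) {
      ok <- !is.na(g[, i]) & !is.na(g[, j])
      out[i, j] <- out[j, i] <-
        if (any(ok)) mean(f(g[ok, i], g[ok, j])) else NA_real_
    }
  }
  out
}

#' ROH detection configuration
#'
#' Defaults mirror the common sliding-window heuristic: 50-SNP windows
#' allowing 2 missing calls and no heterozygote, with final runs required
#' to contain >= 50 SNPs, span >= 50 kb and average at most 50 kb per SNP.
#'
#' @param window_snps SNPs per sliding window.
#' @param max_missing_per_window allowed missing calls per window.
#' @param max_het_per_window allowed heterozygotes per window.
#' @param min_snps minimum SNPs in a final ROH.
#' @param min_length_bp minimum ROH span in bp.
#' @param density_kb_per_snp maximum kb per SNP inside a ROH.
#' @param hit_fraction minimum fraction of passing windows covering a SNP
#'   for it to be ROH-eligible.
#' @return list of class `ROHConfig`.
#' @export
roh_config <- function(window_snps = 50L, max_missing_per_window = 2L,
                       max_het_per_window = 0L, min_snps = 50L,
                       min_length_bp = 50000, density_kb_per_snp = 50,
                       hit_fraction = 0.05) {
  structure(list(window_snps = window_snps,
                 max_missing_per_window = max_missing_per_window,
                 max_het_per_window = max_het_per_window,
                 min_snps = min_snps, min_length_bp = min_length_bp,
                 density_kb_per_snp = density_kb_per_snp,
                 hit_fraction = hit_fraction),
            class = "ROHConfig")
}

#' Detect runs of homozygosity for one sample
#'
#' Slides a window of `window_snps` consecutive SNPs along each contig; a
#' window passes when it contains at most `max_het_per_window`
#' heterozygotes and `max_missing_per_window` missing calls. Each SNP's
#' hit rate is the fraction of windows containing it that pass; SNPs with
#' hit rate >= `hit_fraction` are ROH-eligible, and maximal runs of
#' eligible SNPs are reported as ROH when they contain >= `min_snps`
#' SNPs, span >= `min_length_bp` and average at most
#' `density_kb_per_snp` kb per SNP.
#'
#' @param panel a `VariantPanel`.
#' @param sample sample identifier.
#' @param cfg a `ROHConfig`.
#' @return A `SegmentSet` (0-based half-open; score = SNP count,
#'   label = sample).
#' @export
detect_roh <- function(panel, sample, cfg = roh_config()) {
  si <- match(sample, panel$samples)
  if (is.na(si)) stop("sample '", sample, "' not in panel")
  w <- cfg$window_snps
  segs <- list()
  for (ctg in unique(panel$sites$contig)) {
    rows <- which(panel$sites$contig == ctg)
    g <- panel$geno[rows, si]
    S <- length(g)
    if (S < w) {
      warning("contig ", ctg, " has fewer than ", w, " SNPs; skipped")
      next
    }
    pos <- panel$sites$pos[rows]
    het <- cumsum(c(0L, as.integer(!is.na(g) & g == 1L)))
    mis <- cumsum(c(0L, as.integer(is.na(g))))
    nw <- S - w + 1L
    ks <- seq_len(nw)
    pass <- (het[ks + w] - het[ks]) <= cfg$max_het_per_window &
      (mis[ks + w] - mis[ks]) <= cfg$max_missing_per_window
    cpass <- cumsum(c(0L, as.integer(pass)))
    # windows containing SNP i: k in [max(1, i - w + 1), min(nw, i)]
    i <- seq_len(S)
    lo <- pmax(1L, i - w + 1L)
    hi <- pmin(nw, i)
    hits <- cpass[hi + 1L] - cpass[lo]
    rate <- hits / (hi - lo + 1L)
    eligible <- rate >= cfg$hit_fraction
    r <- rle(eligible)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (q in which(r$values)) {
      i1 <- starts[q]; i2 <- ends[q]
      n <- i2 - i1 + 1L
      span <- pos[i2] - pos[i1] + 1
      if (n < cfg$min_snps) next
      if (span < cfg$min_length_bp) next
      if (span / 1000 / n > cfg$density_kb_per_snp) next
      segs[[length(segs) + 1L]] <-
        data.frame(contig = ctg, start = pos[i1] - 1, end = pos[i2],
                   score = n, stringsAsFactors = FALSE)
    }
  }
  if (length(segs) == 0L)
    return(segment_set(provenance = "roh", label = character()))
  df <- do.call(rbind, segs)
  segment_set(df$contig, df$start, df$end, df$score, label = sample,
              provenance = "roh")
}

#' LD decay curve with sample-size-balanced resampling
#'
#' Repeatedly draws `k_samples` samples without replacement from the
#' population, computes r^2 between all SNP pairs within `max_dist` bp
#' (squared genotype-dosage correlation, or squared haplotype correlation
#' when the panel is phased and `use_haplotypes = TRUE`), averages r^2
#' within `bin_bp` distance bins, and reports the across-resample mean
#' and SD per bin. Sites monomorphic within a draw are skipped.
#'
#' @param panel a `VariantPanel`.
#' @param popmap a `PopulationMap`.
#' @param pop population label or role (>= `k_samples` samples).
#' @param max_dist maximum pair distance in bp (default 500000).
#' @param bin_bp distance bin width in bp (default 100).
#' @param k_samples samples per draw (default 5).
#' @param n_resample number of draws (default 100).
#' @param use_haplotypes compute haplotype r^2 when phase is available.
#' @param seed integer seed; identical seeds give identical output.
#' @return data.frame: bin_start (bp), mean_r2, sd_r2, n_pairs (mean
#'   pairs per resample contributing to the bin).
#' @export
ld_decay <- function(panel, popmap, pop, max_dist = 500000, bin_bp = 100,
                     k_samples = 5L, n_resample = 100L,
                     use_haplotypes = !is.null(panel$hap), seed = NULL) {
  idx <- sample_idx(panel, popmap, pop)
  if (length(idx) < k_samples)
    stop("population has fewer than k_samples samples")
  run <- function() {
    nb <- ceiling(max_dist / bin_bp)
    acc_sum <- matrix(0, n_resample, nb)
    acc_n <- matrix(0, n_resample, nb)
    for (r in seq_len(n_resample)) {
      draw <- sort(sample(idx, k_samples))
      M <- if (use_haplotypes) panel$hap[, hap_cols(draw), drop = FALSE]
      else panel$geno[, draw, drop = FALSE]
      for (ctg in unique(panel$sites$contig)) {
        rows <- which(panel$sites$contig == ctg)
        X <- M[rows, , drop = FALSE]
        v <- apply(X, 1L, stats::var, na.rm = TRUE)
        keep <- !is.na(v) & v > 0
        if (sum(keep) < 2L) next
        X <- t(X[keep, , drop = FALSE])
        pos <- panel$sites$pos[rows][keep]
        r2 <- suppressWarnings(
          stats::cor(X, use = "pairwise.complete.obs"))^2
        dm <- abs(outer(pos, pos, "-"))
        ut <- upper.tri(dm)
        sel <- ut & dm <= max_dist & !is.na(r2)
        if (!any(sel)) next
        b <- pmin(nb, floor(dm[sel] / bin_bp) + 1L)
        acc_sum[r, ] <- acc_sum[r, ] + tapply_fill(r2[sel], b, nb)
        acc_n[r, ] <- acc_n[r, ] + tapply_fill(rep(1, sum(sel)), b, nb)
      }
    }
    per <- acc_sum / ifelse(acc_n > 0, acc_n, NA)
    data.frame(bin_start = (seq_len(nb) - 1L) * bin_bp,
               mean_r2 = colMeans(per, na.rm = TRUE),
               sd_r2 = apply(per, 2L, stats::sd, na.rm = TRUE),
               n_pairs = colMeans(acc_n))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

tapply_fill <- function(x, bin, nb) {
  out <- numeric(nb)
  s <- rowsum(x, bin)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}
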