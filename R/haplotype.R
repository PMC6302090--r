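#' Extended haplotype homozygosity from a focal site
#'
#' Starting from the core haplotypes (those carrying the core allele at
#' the focal site), haplotypes are extended site by site away from the
#' focus; at distance d,
#' `EHH(d) = sum_g C(k_g, 2) / C(K, 2)` over the groups of identical
#' extended haplotypes, with K the number of core haplotypes. EHH(0) = 1
#' and EHH is non-increasing with distance.
#'
#' @param hap sites x haplotypes 0/1 matrix (one contig, positions sorted).
#' @param pos 1-based positions aligned with the rows of `hap`.
#' @param focal row index of the focal site.
#' @param core_cols haplotype column indices forming the core set
#'   (>= 2 required).
#' @param cutoff stop extending once EHH drops below this value (NULL =
#'   extend to the contig edge).
#' @return list of class `EHHCurve`: `left` and `right` data.frames
#'   (`dist` bp, `ehh`), each starting at (0, 1), plus `K`.
#' @export
ehh_curve <- function(hap, pos, focal, core_cols, cutoff = NULL) {
  K <- length(core_cols)
  if (K < 2L) stop("need >= 2 core haplotypes")
  pairs_total <- K * (K - 1) / 2
  walk <- function(idx_seq) {
    d <- 0
    e <- 1
    grp <- rep(1L, K)
    for (j in idx_seq) {
      al <- hap[j, core_cols]
      if (anyNA(al)) next
      key <- grp * 2L + al
      grp <- match(key, unique(key))
      tab <- tabulate(grp)
      val <- sum(tab * (tab - 1) / 2) / pairs_total
      d <- c(d, abs(pos[j] - pos[focal]))
      e <- c(e, val)
      if (!is.null(cutoff) && val < cutoff) break
      if (val == 0) break
    }
    data.frame(dist = d, ehh = e)
  }
  S <- nrow(hap)
  right <- if (focal < S) walk((focal + 1L):S) else
    data.frame(dist = 0, ehh = 1)
  left <- if (focal > 1L) walk((focal - 1L):1L) else
    data.frame(dist = 0, ehh = 1)
  structure(list(left = left, right = right, K = K), class = "EHHCurve")
}

# integrate one side of an EHH curve: trapezoids over physical distance,
# truncated at the last point with EHH >= cutoff. Contributes nothing once
# the starting EHH is <= cutoff. Returns list(area, decayed) where
# `decayed` says the curve fell below cutoff before the data ran out.
ihh_side <- function(side, cutoff) {
  d <- side$dist; e <- side$ehh
  area <- 0
  decayed <- FALSE
  m <- length(d)
  if (m >= 1L && e[1L] <= cutoff) return(list(area = 0, decayed = TRUE))
  for (i in seq_len(m - 1L)) {
    if (e[i] <= cutoff) { decayed <- TRUE; break }
    if (e[i + 1L] < cutoff) { decayed <- TRUE; break }
    area <- area + (e[i] + e[i + 1L]) / 2 * (d[i + 1L] - d[i])
  }
  if (!decayed && m >= 1L && e[m] < cutoff) decayed <- TRUE
  list(area = area, decayed = decayed)
}

#' Integrated haplotype homozygosity (iHH)
#'
#' Trapezoidal integral of the EHH curve over physical distance (bp),
#' left plus right, truncated at the last point with EHH at or above
#' `cutoff` (default 0.05). Curves that never decay below the cutoff
#' before the contig edge are flagged, because their integral is
#' censored.
#'
#' @param curve an `EHHCurve` from [ehh_curve()].
#' @param cutoff EHH truncation threshold.
#' @return list: `ihh` (bp), `decayed` (logical, TRUE when both sides
#'   fell below the cutoff within the data).
#' @export
ihh <- function(curve, cutoff = 0.05) {
  l <- ihh_side(curve$left, cutoff)
  r <- ihh_side(curve$right, cutoff)
  list(ihh = l$area + r$area, decayed = l$decayed && r$decayed)
}

# haplotype matrix restricted to one population, per contig
pop_hap <- function(panel, popmap, pop) {
  if (is.null(panel$hap)) stop("panel is not phased")
  panel$hap[, hap_cols(sample_idx(panel, popmap, pop)), drop = FALSE]
}

#' iHS scan (within-population integrated haplotype score)
#'
#' For each site with known ancestral state and derived-allele frequency
#' in `[maf, 1 - maf]` within the population, the raw score is
#' `ln(iHH_ancestral / iHH_derived)`; sites whose EHH curves do not decay
#' below the cutoff before the contig edge, or whose iHH is zero, are NA.
#' Raw scores are standardized to mean 0, sd 1 within derived-frequency
#' bins of width `bin_width` (large positive and negative values then
#' indicate unusually long ancestral and derived haplotypes respectively).
#'
#' @param panel a phased, polarized `VariantPanel`.
#' @param popmap a `PopulationMap`.
#' @param pop population label or role.
#' @param maf frequency bound for scored sites (default 0.05).
#' @param cutoff EHH truncation threshold (default 0.05).
#' @param bin_width derived-frequency bin width for standardization.
#' @return data.frame of class `ScoreTrack`: contig, pos, freq, raw,
#'   score, bin.
#' @export
ihs_scan <- function(panel, popmap, pop, maf = 0.05, cutoff = 0.05,
                     bin_width = 0.05) {
  idx <- sample_idx(panel, popmap, pop)
  cols <- hap_cols(idx)
  anc <- panel$sites$ancestral
  raw <- rep(NA_real_, n_sites(panel))
  freq <- rep(NA_real_, n_sites(panel))
  for (ctg in unique(panel$sites$contig)) {
    si <- which(panel$sites$contig == ctg)
    H <- panel$hap[si, cols, drop = FALSE]
    # derived coding: flip columns where the alt allele is ancestral
    flip <- anc[si] == "alt"
    Hd <- H
    Hd[flip, ] <- 1L - Hd[flip, , drop = FALSE]
    pos <- panel$sites$pos[si]
    p <- rowMeans(Hd)
    for (k in seq_along(si)) {
      if (anc[si[k]] == "unknown") next
      if (is.na(p[k]) || p[k] < maf || p[k] > 1 - maf) next
      freq[si[k]] <- p[k]
      der <- which(Hd[k, ] == 1L)
      ancc <- which(Hd[k, ] == 0L)
      if (length(der) < 2L || length(ancc) < 2L) next
      id <- ihh(ehh_curve(H, pos, k, der, cutoff = cutoff), cutoff)
      ia <- ihh(ehh_curve(H, pos, k, ancc, cutoff = cutoff), cutoff)
      if (!id$decayed || !ia$decayed) next
      if (id$ihh <= 0 || ia$ihh <= 0) next
      raw[si[k]] <- log(ia$ihh / id$ihh)
    }
  }
  bin <- floor(pmin(freq, 1 - 1e-9) / bin_width)
  score <- standardize_by_bin(raw, bin)
  out <- data.frame(contig = panel$sites$contig, pos = panel$sites$pos,
                    freq = freq, raw = raw, score = score, bin = bin,
                    stringsAsFactors = FALSE)
  class(out) <- c("ScoreTrack", "data.frame")
  out
}

standardize_by_bin <- function(raw, bin) {
  score <- rep(NA_real_, length(raw))
  for (b in unique(bin[!is.na(raw) & !is.na(bin)])) {
    i <- which(bin == b & !is.na(raw))
    if (length(i) < 2L) next
    m <- mean(raw[i])
    s <- stats::sd(raw[i])
    # bins whose spread is at rounding-error scale are effectively ties;
    # their z-scores would be cancellation noise
    if (s <= 1e-12 * (abs(m) + 1)) next
    score[i] <- (raw[i] - m) / s
  }
  score
}

#' XP-EHH scan (cross-population extended haplotype homozygosity)
#'
#' For each site, population-wise EHH curves are computed with all of the
#' population's haplotypes as the core set; the raw score is
#' `ln(iHH_A / iHH_B)` and the track is standardized genome-wide to mean
#' 0, sd 1. Large positive values indicate unusually long haplotypes
#' (ongoing or recent sweeps) in population A relative to B.
#'
#' @param panel a phased `VariantPanel`.
#' @param popmap a `PopulationMap`.
#' @param popA,popB population labels or roles (>= 4 haplotypes each).
#' @param cutoff EHH truncation threshold (default 0.05).
#' @return A `ScoreTrack` data.frame: contig, pos, raw, score.
#' @export
xpehh_scan <- function(panel, popmap, popA, popB, cutoff = 0.05) {
  colsA <- hap_cols(sample_idx(panel, popmap, popA))
  colsB <- hap_cols(sample_idx(panel, popmap, popB))
  if (length(colsA) < 4L || length(colsB) < 4L)
    stop("xpehh needs >= 4 haplotypes per population")
  raw <- rep(NA_real_, n_sites(panel))
  for (ctg in unique(panel$sites$contig)) {
    si <- which(panel$sites$contig == ctg)
    HA <- panel$hap[si, colsA, drop = FALSE]
    HB <- panel$hap[si, colsB, drop = FALSE]
    pos <- panel$sites$pos[si]
    pall <- rowMeans(cbind(HA, HB))
    for (k in seq_along(si)) {
      if (is.na(pall[k]) || pall[k] <= 0 || pall[k] >= 1) next
      ia <- ihh(ehh_curve(HA, pos, k, seq_len(ncol(HA)), cutoff = cutoff),
                cutoff)
      ib <- ihh(ehh_curve(HB, pos, k, seq_len(ncol(HB)), cutoff = cutoff),
                cutoff)
      if (!ia$decayed || !ib$decayed) next
      if (ia$ihh <= 0 || ib$ihh <= 0) next
      raw[si[k]] <- log(ia$ihh / ib$ihh)
    }
  }
  ok <- !is.na(raw)
  score <- rep(NA_real_, length(raw))
  if (sum(ok) >= 2L && stats::sd(raw[ok]) > 0)
    score[ok] <- (raw[ok] - mean(raw[ok])) / stats::sd(raw[ok])
  out <- data.frame(contig = panel$sites$contig, pos = panel$sites$pos,
                    raw = raw, score = score, stringsAsFactors = FALSE)
  class(out) <- c("ScoreTrack", "data.frame")
  out
}

#' Extreme-score-ratio window selection
#'
#' Per window, the ratio of scored sites with `|standardized score| >=
#' threshold` (default 2) to all scored sites; windows in the top
#' `top_fraction` (default 1%) of ratios, requiring a positive ratio, are
#' merged into candidate segments scored by the maximum ratio.
#'
#' @param track a `ScoreTrack` from [ihs_scan()] or [xpehh_scan()].
#' @param grid a `WindowGrid`.
#' @param threshold absolute standardized score called extreme.
#' @param top_fraction upper tail fraction of windows to keep.
#' @param min_windows minimum number of windows with >= 1 scored site.
#' @return A `SegmentSet` (provenance `"extreme_ratio"`).
#' @export
extreme_ratio_windows <- function(track, grid, threshold = 2,
                                  top_fraction = 0.01, min_windows = 100L) {
  scored <- !is.na(track$score)
  X <- cbind(as.numeric(scored),
             as.numeric(scored & abs(track$score) >= threshold))
  ws <- window_sums(data.frame(contig = track$contig, pos = track$pos),
                    grid, X)
  has <- ws$sums[, 1L] > 0
  if (sum(has) < min_windows)
    stop("only ", sum(has), " windows with scored sites; need >= ",
         min_windows)
  ratio <- ifelse(has, ws$sums[, 2L] / ws$sums[, 1L], NA_real_)
  thr <- stats::quantile(ratio[has], 1 - top_fraction, names = FALSE)
  sel <- which(has & ratio >= thr & ratio > 0)
  if (length(sel) == 0L)
    return(segment_set(provenance = "extreme_ratio"))
  seg <- segment_set(grid$contig[sel], grid$start[sel], grid$end[sel],
                     ratio[sel], provenance = "extreme_ratio")
  merge_segments(seg)
}
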