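#' Per-site ABBA/BABA weights for the four-taxon D statistic
#'
#' For roles (((P1, P2), P3), O) with per-population derived-allele
#' frequencies p1..p4, each usable site contributes
#' `ABBA = (1 - p1) p2 p3 (1 - p4)` and `BABA = p1 (1 - p2) p3 (1 - p4)`
#' (population-frequency formulation). Usable sites have a known ancestral
#' state and at least one non-missing allele in every role population.
#'
#' @param panel a polarized `VariantPanel` (see [polarize()]).
#' @param popmap a `PopulationMap` whose `roles` include P1, P2, P3, O.
#' @return data.frame of class `DParts` with columns contig, pos,
#'   p1, p2, p3, p4, abba, baba.
#' @export
compute_d_parts <- function(panel, popmap) {
  roles <- c("P1", "P2", "P3", "O")
  if (is.null(popmap$roles) || !all(roles %in% names(popmap$roles)))
    stop("popmap must assign roles P1, P2, P3 and O")
  p <- sapply(roles, function(r) derived_freq(panel, popmap, r))
  usable <- rowSums(is.na(p)) == 0L
  if (!any(usable)) stop("no usable sites (polarized, all roles called)")
  p <- p[usable, , drop = FALSE]
  out <- data.frame(contig = panel$sites$contig[usable],
                    pos = panel$sites$pos[usable],
                    p1 = p[, 1L], p2 = p[, 2L], p3 = p[, 3L], p4 = p[, 4L],
                    stringsAsFactors = FALSE)
  out$abba <- (1 - out$p1) * out$p2 * out$p3 * (1 - out$p4)
  out$baba <- out$p1 * (1 - out$p2) * out$p3 * (1 - out$p4)
  class(out) <- c("DParts", "data.frame")
  out
}

#' Patterson's D from site weights
#'
#' `D = sum(ABBA - BABA) / sum(ABBA + BABA)`, in [-1, 1]. A positive D
#' indicates an excess of derived-allele sharing between P2 and P3.
#'
#' @param parts a `DParts` table from [compute_d_parts()].
#' @return scalar D (NA when the denominator is zero).
#' @export
patterson_d <- function(parts) {
  denom <- sum(parts$abba + parts$baba)
  if (denom == 0) return(NA_real_)
  sum(parts$abba - parts$baba) / denom
}

#' Block-jackknife standard error and Z score for D
#'
#' Splits sites into consecutive genomic blocks (default 5 Mb), computes
#' delete-one-block estimates and the weighted delete-one jackknife
#' variance of Busing et al. (1999) with block weights equal to site
#' counts. `Z = D / SE`.
#'
#' @param parts a `DParts` table.
#' @param block_bp block size in bp (default 5e6).
#' @return list of class `jackknife_estimate` with fields `estimate`,
#'   `se`, `z`, `n_blocks`, `block_bp`.
#' @export
block_jackknife <- function(parts, block_bp = 5e6) {
  block <- paste0(parts$contig, ":", floor(parts$pos / block_bp))
  blocks <- unique(block)
  g <- length(blocks)
  if (g < 2L)
    stop("fewer than 2 non-empty blocks; decrease block_bp")
  num <- sum(parts$abba - parts$baba)
  den <- sum(parts$abba + parts$baba)
  D <- num / den
  m <- as.numeric(table(block)[blocks])
  n <- sum(m)
  loo <- vapply(blocks, function(b) {
    keep <- block != b
    sum(parts$abba[keep] - parts$baba[keep]) /
      sum(parts$abba[keep] + parts$baba[keep])
  }, numeric(1))
  h <- n / m
  theta_j <- g * D - sum((1 - m / n) * loo)
  pseudo <- h * D - (h - 1) * loo
  var_j <- mean((pseudo - theta_j)^2 / (h - 1))
  se <- sqrt(var_j)
  z <- if (se == 0) {
    warning("identical block estimates; SE = 0, Z reported as Inf")
    sign(D) * Inf
  } else D / se
  structure(list(estimate = D, se = se, z = z, n_blocks = g,
                 block_bp = block_bp),
            class = "jackknife_estimate")
}

#' @export
print.jackknife_estimate <- function(x, ...) {
  cat(sprintf("D = %.4f  SE = %.4f  Z = %.2f  (%d blocks of %g bp)\n",
              x$estimate, x$se, x$z, x$n_blocks, x$block_bp))
  invisible(x)
}

#' Windowed f_d admixture-proportion scan
#'
#' Per window: the window D from summed ABBA/BABA weights, and
#' `f_d = S(P1, P2, P3, O) / S(P1, P_D, P_D, O)` where
#' `S = sum(ABBA - BABA)` and, per site, `P_D` is whichever of P2/P3 has
#' the higher derived-allele frequency (Martin et al. 2015). Windows with
#' fewer than `min_snps` usable sites (default 30) or non-positive window
#' D are flagged invalid; f_d values above 1 are clipped to 1 with a
#' warning.
#'
#' @param parts a `DParts` table.
#' @param grid a `WindowGrid`.
#' @param min_snps minimum usable sites per window.
#' @return data.frame of class `FdWindowTable`: contig, start, end,
#'   n_snps, d, fd, valid.
#' @export
window_fd <- function(parts, grid, min_snps = 30L) {
  pd <- pmax(parts$p2, parts$p3)
  abba_d <- (1 - parts$p1) * pd * pd * (1 - parts$p4)
  baba_d <- parts$p1 * (1 - pd) * pd * (1 - parts$p4)
  X <- cbind(parts$abba, parts$baba, abba_d - baba_d)
  ws <- window_sums(parts[, c("contig", "pos")], grid, X)
  num <- ws$sums[, 1L] - ws$sums[, 2L]
  den <- ws$sums[, 1L] + ws$sums[, 2L]
  d <- ifelse(den > 0, num / den, NA_real_)
  s_den <- ws$sums[, 3L]
  fd <- ifelse(s_den > 0, num / s_den, NA_real_)
  valid <- ws$n >= min_snps & !is.na(d) & d > 0 & !is.na(fd)
  over <- valid & fd > 1
  if (any(over)) {
    warning(sum(over), " window(s) with f_d > 1 clipped to 1")
    fd[over] <- 1
  }
  out <- data.frame(contig = grid$contig, start = grid$start,
                    end = grid$end, n_snps = ws$n, d = d, fd = fd,
                    valid = valid, stringsAsFactors = FALSE)
  class(out) <- c("FdWindowTable", "data.frame")
  out
}

#' Call candidate introgression segments from an f_d scan
#'
#' Windows in the top `top_fraction` (default 5%) of f_d values among
#' valid windows are selected (ties at the threshold included) and merged
#' when overlapping or book-ended; segment score is the maximum f_d.
#'
#' @param fd_windows an `FdWindowTable` from [window_fd()].
#' @param top_fraction upper tail fraction.
#' @param min_windows minimum number of valid windows required.
#' @return A `SegmentSet` (provenance `"fd_scan"`).
#' @export
call_introgression <- function(fd_windows, top_fraction = 0.05,
                               min_windows = 20L) {
  v <- fd_windows[fd_windows$valid, , drop = FALSE]
  if (nrow(v) < min_windows)
    stop("only ", nrow(v), " valid windows; need >= ", min_windows)
  thr <- stats::quantile(v$fd, 1 - top_fraction, names = FALSE)
  sel <- v[v$fd >= thr, , drop = FALSE]
  seg <- segment_set(sel$contig, sel$start, sel$end, sel$fd,
                     provenance = "fd_scan")
  merge_segments(seg)
}

#' Contrast dXY inside candidate segments against the genome background
#'
#' Computes windowed dXY between two populations, splits windows into
#' segment-overlapping versus background, and reports medians, quartiles
#' and a one-sided Mann-Whitney U test of the hypothesis that segment
#' dXY is lower than background (recent introgression reduces absolute
#' divergence relative to ancestral structure).
#'
#' @param panel a `VariantPanel`.
#' @param popmap a `PopulationMap`.
#' @param popA,popB populations for dXY (typically recipient and donor).
#' @param segments a `SegmentSet` of candidate introgression regions.
#' @param grid a `WindowGrid`.
#' @return list with `summary` (group, n, q25, median, q75), `p_value`,
#'   and the window table with a `segment` indicator column.
#' @export
dxy_contrast <- function(panel, popmap, popA, popB, segments, grid) {
  if (nrow(segments) == 0L) stop("empty segment set")
  dxy <- window_dxy(panel, popmap, popA, popB, grid)
  inseg <- overlaps_segments(dxy, segments)
  seg_v <- dxy$value[inseg & dxy$valid]
  bg_v <- dxy$value[!inseg & dxy$valid]
  if (length(bg_v) == 0L) stop("no background windows outside segments")
  if (length(seg_v) == 0L) stop("no windows overlap the segments")
  q <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  qs <- q(seg_v); qb <- q(bg_v)
  p <- stats::wilcox.test(seg_v, bg_v, alternative = "less",
                          exact = FALSE)$p.value
  dxy$segment <- inseg
  list(summary = data.frame(group = c("segment", "background"),
                            n = c(length(seg_v), length(bg_v)),
                            q25 = c(qs[1L], qb[1L]),
                            median = c(qs[2L], qb[2L]),
                            q75 = c(qs[3L], qb[3L])),
       p_value = p, windows = dxy)
}
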