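#' Sweep-caller configuration
#'
#' @param fst_top_fraction upper tail of Z-transformed F_ST (default 0.05).
#' @param ratio_tail_fraction tail of the log2 pi-ratio (default 0.05).
#' @param min_snps minimum SNPs per window (default 10).
#' @param merge_gap bp gap across which selected windows are merged.
#' @return list of class `SweepConfig`.
#' @export
sweep_config <- function(fst_top_fraction = 0.05,
                         ratio_tail_fraction = 0.05,
                         min_snps = 10L, merge_gap = 0L) {
  stopifnot(fst_top_fraction > 0, fst_top_fraction <= 0.5,
            ratio_tail_fraction > 0, ratio_tail_fraction <= 0.5)
  structure(list(fst_top_fraction = fst_top_fraction,
                 ratio_tail_fraction = ratio_tail_fraction,
                 min_snps = min_snps, merge_gap = merge_gap),
            class = "SweepConfig")
}

#' Combined F_ST / pi-ratio sweep caller
#'
#' Windows with fewer than `min_snps` SNPs or missing values are dropped;
#' F_ST is Z-transformed over the remaining windows
#' (`(x - mean) / sd`); candidate sweep windows are simultaneously in the
#' top `fst_top_fraction` of Z(F_ST) and in the selected tail of the
#' log2 pi-ratio, then merged into regions scored by Z(F_ST).
#'
#' A sweep in the focal population reduces its diversity, so with the
#' ratio oriented as `log2(pi_other / pi_focal)` the sweep tail is the
#' *upper* tail (`tail = "high"`, the default). `tail = "low"` selects the
#' bottom tail instead, for ratios oriented the other way around.
#'
#' @param fst a `WindowStatTable` from [window_fst()].
#' @param piratio a log2-ratio `WindowStatTable` from [pi_ratio()],
#'   on the same grid.
#' @param cfg a `SweepConfig`.
#' @param tail `"high"` or `"low"` tail of the pi-ratio.
#' @param min_windows minimum usable windows (default 20).
#' @return A `SegmentSet` (provenance `"fst_piratio"`) with a
#'   `selected_windows` attribute holding the pre-merge window indices.
#' @export
combine_fst_piratio <- function(fst, piratio, cfg = sweep_config(),
                                tail = c("high", "low"),
                                min_windows = 20L) {
  tail <- match.arg(tail)
  if (!same_grid(fst, piratio)) stop("window grids differ")
  usable <- fst$valid & piratio$valid & !is.na(fst$value) &
    !is.na(piratio$value) & fst$n_snps >= cfg$min_snps
  if (sum(usable) < min_windows)
    stop("only ", sum(usable), " usable windows; need >= ", min_windows)
  z <- rep(NA_real_, nrow(fst))
  z[usable] <- (fst$value[usable] - mean(fst$value[usable])) /
    stats::sd(fst$value[usable])
  zthr <- stats::quantile(z[usable], 1 - cfg$fst_top_fraction,
                          names = FALSE)
  lr <- piratio$value
  if (tail == "high") {
    lthr <- stats::quantile(lr[usable], 1 - cfg$ratio_tail_fraction,
                            names = FALSE)
    in_tail <- usable & lr >= lthr
  } else {
    lthr <- stats::quantile(lr[usable], cfg$ratio_tail_fraction,
                            names = FALSE)
    in_tail <- usable & lr <= lthr
  }
  sel <- which(usable & z >= zthr & in_tail)
  if (length(sel) == 0L) {
    out <- segment_set(provenance = "fst_piratio")
  } else {
    out <- merge_segments(segment_set(fst$contig[sel], fst$start[sel],
                                      fst$end[sel], z[sel],
                                      provenance = "fst_piratio"),
                          gap = cfg$merge_gap)
  }
  attr(out, "selected_windows") <- sel
  attr(out, "z_fst") <- z
  out
}

#' Merge candidate regions from several scans
#'
#' Takes the union of the interval sets (e.g. the F_ST/pi-ratio caller,
#' the XP-EHH and iHS extreme-ratio windows), merging intervals within
#' `merge_gap` bp; provenance labels of merged constituents are
#' concatenated.
#'
#' @param sets list of `SegmentSet`s on the same genome.
#' @param merge_gap bp gap across which to merge (default 0).
#' @return A `SegmentSet` (provenance `"combined"`).
#' @export
merge_regions <- function(sets, merge_gap = 0L) {
  sets <- sets[vapply(sets, nrow, integer(1)) > 0L]
  if (length(sets) == 0L) return(segment_set(provenance = "combined"))
  all <- do.call(rbind, lapply(sets, function(s) {
    s$label <- rep(attr(s, "provenance"), nrow(s))
    as.data.frame(s)
  }))
  seg <- segment_set(all$contig, all$start, all$end, all$score, all$label,
                     provenance = "combined")
  merge_segments(seg, gap = merge_gap)
}
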