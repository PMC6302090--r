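#' Construct a variant panel
#'
#' A `VariantPanel` is the central in-memory container: a sites x samples
#' diploid genotype matrix with per-site metadata and, when the data are
#' phased, a sites x (2 * samples) binary haplotype matrix.
#'
#' Genotypes are coded 0 (hom-ref), 1 (het), 2 (hom-alt) with `NA` for
#' missing; haplotype codes are 0 (ref allele) and 1 (alt allele). All sites
#' are biallelic SNPs. Positions are 1-based (VCF convention); windows and
#' BED-style intervals elsewhere in the package are 0-based half-open.
#'
#' @param contigs data.frame with columns `name`, `length` (bp).
#' @param sites data.frame with columns `contig`, `pos` (1-based),
#'   `ref`, `alt`, and `ancestral` (one of `"ref"`, `"alt"`, `"unknown"`).
#' @param geno integer matrix, sites x samples, entries in `c(0, 1, 2, NA)`.
#' @param samples character vector of sample identifiers (column order of
#'   `geno`).
#' @param hap optional integer matrix, sites x (2 * samples), entries 0/1;
#'   columns `2i - 1` and `2i` are the two haplotypes of sample `i`.
#' @param truth optional list of truth records attached by the simulators
#'   (planted tracts, sweeps, ancestral states and the like).
#' @param validate check invariants (default TRUE).
#' @return An object of class `VariantPanel`.
#' @export
variant_panel <- function(contigs, sites, geno, samples, hap = NULL,
                          truth = NULL, validate = TRUE) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  colnames(geno) <- samples
  if (!is.null(hap)) {
    hap <- as.matrix(hap)
    storage.mode(hap) <- "integer"
  }
  if (is.null(sites$ancestral)) sites$ancestral <- "unknown"
  sites$contig <- as.character(sites$contig)
  panel <- structure(
    list(contigs = data.frame(name = as.character(contigs$name),
                              length = as.numeric(contigs$length),
                              stringsAsFactors = FALSE),
         sites = sites, geno = geno, hap = hap,
         samples = as.character(samples), truth = truth),
    class = "VariantPanel")
  if (validate) validate_panel(panel)
  panel
}

#' Validate a VariantPanel's invariants
#'
#' Checks strictly increasing positions within contigs, genotype coding,
#' haplotype/genotype consistency and dimensions. Called by constructors;
#' exported for use after manual surgery on a panel.
#'
#' @param panel a `VariantPanel`.
#' @return `panel`, invisibly; errors on violation.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "VariantPanel"))
  s <- panel$sites
  if (nrow(s) != nrow(panel$geno))
    stop("sites and genotype matrix disagree on site count")
  if (length(panel$samples) != ncol(panel$geno))
    stop("samples and genotype matrix disagree on sample count")
  for (ctg in unique(s$contig)) {
    p <- s$pos[s$contig == ctg]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on contig ", ctg)
  }
  bad <- !(panel$geno %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype codes outside {0,1,2,NA}")
  if (!all(s$ancestral %in% c("ref", "alt", "unknown")))
    stop("ancestral must be 'ref', 'alt' or 'unknown'")
  if (!is.null(panel$hap)) {
    if (ncol(panel$hap) != 2L * ncol(panel$geno))
      stop("haplotype matrix must have 2 columns per sample")
    if (!all(panel$hap %in% c(0L, 1L, NA)))
      stop("haplotype codes outside {0,1,NA}")
    gsum <- panel$hap[, seq(1L, ncol(panel$hap), by = 2L), drop = FALSE] +
      panel$hap[, seq(2L, ncol(panel$hap), by = 2L), drop = FALSE]
    ok <- is.na(panel$geno) | is.na(gsum) | gsum == panel$geno
    if (!all(ok)) stop("haplotypes inconsistent with genotypes")
  }
  invisible(panel)
}

#' @export
print.VariantPanel <- function(x, ...) {
  cat("VariantPanel:", nrow(x$sites), "sites x", length(x$samples),
      "samples on", nrow(x$contigs), "contig(s);",
      if (is.null(x$hap)) "unphased" else "phased", "\n")
  invisible(x)
}

#' Number of sites / samples in a panel
#' @param panel a `VariantPanel`.
#' @return integer count.
#' @export
n_sites <- function(panel) nrow(panel$sites)

#' @rdname n_sites
#' @export
n_samples <- function(panel) length(panel$samples)

#' Construct a population map
#'
#' Assigns each sample to a population and optionally names the roles used
#' by four-taxon tests (`P1`, `P2`, `P3`, `O`) or two-population contrasts
#' (`A`, `B`).
#'
#' @param assignments named character vector (names = sample ids, values =
#'   population labels) or a two-column data.frame (sample, population).
#' @param roles optional named character vector mapping role names to
#'   population labels, e.g. `c(P1 = "per", P2 = "kan", P3 = "mira", O = "dul")`.
#' @return An object of class `PopulationMap`.
#' @export
population_map <- function(assignments, roles = NULL) {
  if (is.data.frame(assignments)) {
    a <- as.character(assignments[[2L]])
    names(a) <- as.character(assignments[[1L]])
    assignments <- a
  }
  pm <- structure(list(assignments = assignments, roles = roles),
                  class = "PopulationMap")
  if (!is.null(roles)) {
    for (r in names(roles)) {
      if (!any(assignments == roles[[r]]))
        stop("role ", r, " maps to population '", roles[[r]],
             "' which has no samples")
    }
  }
  pm
}

#' Read a population map from a headerless two-column TSV
#' @param path file with columns sample, population.
#' @param roles optional role mapping passed to [population_map()].
#' @return A `PopulationMap`.
#' @export
read_popmap <- function(path, roles = NULL) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("sample", "population"))
  population_map(df, roles = roles)
}

#' Samples belonging to a population
#' @param popmap a `PopulationMap`.
#' @param pop population label, or a role name present in `popmap$roles`.
#' @return character vector of sample ids.
#' @export
samples_of <- function(popmap, pop) {
  label <- resolve_pop(popmap, pop)
  names(popmap$assignments)[popmap$assignments == label]
}

resolve_pop <- function(popmap, pop) {
  if (!is.null(popmap$roles) && pop %in% names(popmap$roles))
    pop <- popmap$roles[[pop]]
  if (!any(popmap$assignments == pop))
    stop("population '", pop, "' not present in the population map")
  pop
}

sample_idx <- function(panel, popmap, pop) {
  ids <- samples_of(popmap, pop)
  idx <- match(ids, panel$samples)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L)
    stop("no samples of population '", pop, "' found in the panel")
  idx
}

# haplotype columns for a set of sample indices
hap_cols <- function(idx) as.vector(rbind(2L * idx - 1L, 2L * idx))

#' Build a sliding-window grid over contigs
#'
#' Windows are 0-based half-open `[k * step, min(k * step + size, L))` for
#' `k = 0, 1, ...` while `k * step < L`, matching the 20-kb / 10-kb sliding
#' windows used throughout the scans.
#'
#' @param contigs data.frame with columns `name`, `length`, or a
#'   `VariantPanel` (its contig table is used).
#' @param size window size in bp (default 20000).
#' @param step step in bp (default 10000); must satisfy `0 < step <= size`.
#' @return A data.frame of class `WindowGrid` with columns `contig`,
#'   `start`, `end` and attributes `size`, `step`.
#' @export
make_windows <- function(contigs, size = 20000L, step = 10000L) {
  if (inherits(contigs, "VariantPanel")) contigs <- contigs$contigs
  if (size <= 0 || step <= 0) stop("size and step must be positive")
  if (step > size) stop("step must not exceed size")
  out <- lapply(seq_len(nrow(contigs)), function(i) {
    L <- contigs$length[i]
    k <- 0:max(0L, ceiling(L / step) - 1L)
    start <- k * step
    start <- start[start < L]
    data.frame(contig = contigs$name[i], start = start,
               end = pmin(start + size, L), stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, out)
  attr(grid, "size") <- size
  attr(grid, "step") <- step
  class(grid) <- c("WindowGrid", "data.frame")
  grid
}

same_grid <- function(a, b) {
  nrow(a) == nrow(b) && all(a$contig == b$contig) &&
    all(a$start == b$start) && all(a$end == b$end)
}

# Per-window sums of per-site values via cumulative sums.
# `values` is a numeric matrix (sites x k) aligned with panel site order;
# returns list(n = site counts, sums = nwin x k matrix). A site at 1-based
# position p falls in window [start, end) iff start < p <= end.
window_sums <- function(sites, grid, values) {
  values <- as.matrix(values)
  nw <- nrow(grid)
  sums <- matrix(0, nw, ncol(values))
  n <- integer(nw)
  for (ctg in unique(grid$contig)) {
    wi <- which(grid$contig == ctg)
    si <- which(sites$contig == ctg)
    if (length(si) == 0L) next
    pos <- sites$pos[si]
    cum <- rbind(0, apply(values[si, , drop = FALSE], 2L,
                          function(v) cumsum(ifelse(is.na(v), 0, v))))
    lo <- findInterval(grid$start[wi], pos) + 1L
    hi <- findInterval(grid$end[wi], pos)
    n[wi] <- pmax(0L, hi - lo + 1L)
    keep <- hi >= lo
    sums[wi[keep], ] <- cum[hi[keep] + 1L, , drop = FALSE] -
      cum[lo[keep], , drop = FALSE]
  }
  list(n = n, sums = sums)
}

# indices of panel sites inside one window (used by per-window loops)
sites_in_window <- function(sites, contig, start, end) {
  si <- which(sites$contig == contig)
  pos <- sites$pos[si]
  si[pos > start & pos <= end]
}

new_stat_table <- function(grid, n_snps, value, valid = !is.na(value),
                           statistic = NULL) {
  out <- data.frame(contig = grid$contig, start = grid$start, end = grid$end,
                    n_snps = n_snps, value = value, valid = valid,
                    stringsAsFactors = FALSE)
  attr(out, "size") <- attr(grid, "size")
  attr(out, "step") <- attr(grid, "step")
  attr(out, "statistic") <- statistic
  class(out) <- c("WindowStatTable", "data.frame")
  out
}

#' Construct a segment set
#'
#' Scored genomic intervals (introgressed segments, sweep candidates, ROH,
#' high-V_ST regions). Coordinates are 0-based half-open.
#'
#' @param contig,start,end,score,label parallel vectors (label defaults to
#'   the provenance string).
#' @param provenance which scan produced the segments.
#' @return data.frame of class `SegmentSet` with columns contig, start,
#'   end, score, label.
#' @export
segment_set <- function(contig = character(), start = numeric(),
                        end = numeric(), score = numeric(),
                        label = NULL, provenance = "manual") {
  if (is.null(label)) label <- rep(provenance, length(contig))
  if (length(score) == 0L && length(contig) > 0L)
    score <- rep(NA_real_, length(contig))
  stopifnot(length(start) == length(end))
  if (any(start >= end)) stop("segments require start < end")
  out <- data.frame(contig = as.character(contig), start = start, end = end,
                    score = score, label = as.character(label),
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- provenance
  class(out) <- c("SegmentSet", "data.frame")
  out
}

seg_to_gr <- function(seg) {
  GenomicRanges::GRanges(seg$contig,
                         IRanges::IRanges(start = seg$start + 1L,
                                          end = pmax(seg$end, seg$start + 1L)))
}

#' Merge a segment set
#'
#' Collapses overlapping or book-ended intervals (or intervals within
#' `gap` bp of one another); the merged score is the maximum of the
#' constituent scores and labels are concatenated.
#'
#' @param seg a `SegmentSet`.
#' @param gap maximum gap (bp) across which to merge (default 0 merges
#'   overlapping and book-ended intervals only).
#' @return A merged `SegmentSet`.
#' @export
merge_segments <- function(seg, gap = 0L) {
  if (nrow(seg) == 0L) return(seg)
  gr <- seg_to_gr(seg)
  red <- GenomicRanges::reduce(gr, min.gapwidth = gap + 1L)
  ov <- GenomicRanges::findOverlaps(red, gr)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  score <- vapply(seq_along(red), function(i) {
    s <- seg$score[sh[qh == i]]
    if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE)
  }, numeric(1))
  label <- vapply(seq_along(red), function(i)
    paste(unique(seg$label[sh[qh == i]]), collapse = ","), character(1))
  segment_set(as.character(GenomicRanges::seqnames(red)),
              GenomicRanges::start(red) - 1L, GenomicRanges::end(red),
              score, label, provenance = attr(seg, "provenance"))
}

#' Which intervals overlap a segment set
#'
#' @param a data.frame with `contig`, `start`, `end` columns (0-based
#'   half-open), e.g. a `WindowGrid`, `WindowStatTable` or `SegmentSet`.
#' @param seg a `SegmentSet`.
#' @return logical vector, one entry per row of `a`.
#' @export
overlaps_segments <- function(a, seg) {
  if (nrow(seg) == 0L) return(rep(FALSE, nrow(a)))
  gr_a <- GenomicRanges::GRanges(a$contig,
                                 IRanges::IRanges(a$start + 1L, a$end))
  IRanges::overlapsAny(gr_a, seg_to_gr(seg))
}

#' Write a segment set as BED
#'
#' BED5 (`chrom`, `start`, `end`, `name`, `score`), 0-based half-open,
#' sorted by contig then start.
#'
#' @param seg a `SegmentSet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(seg, path) {
  seg <- seg[order(seg$contig, seg$start), , drop = FALSE]
  df <- data.frame(seg$contig, format(seg$start, scientific = FALSE,
                                      trim = TRUE),
                   format(seg$end, scientific = FALSE, trim = TRUE),
                   seg$label, seg$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file written by [write_bed()]
#' @param path BED file (3-5 columns).
#' @param provenance provenance string for the resulting set.
#' @return A `SegmentSet`.
#' @export
read_bed <- function(path, provenance = "bed") {
  if (file.size(path) == 0)
    return(segment_set(provenance = provenance))
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  segment_set(df[[1L]], df[[2L]], df[[3L]],
              score = if (ncol(df) >= 5L) df[[5L]] else NA_real_,
              label = if (ncol(df) >= 4L) df[[4L]] else NULL,
              provenance = provenance)
}
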