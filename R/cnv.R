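#' Construct a copy-number matrix
#'
#' Region x sample mean depth ratios, with 1.0 the diploid baseline; the
#' implied integer copy number is `round(2 * ratio)`.
#'
#' @param regions data.frame with columns `contig`, `start`, `end`
#'   (0-based half-open, sorted, non-overlapping).
#' @param ratios numeric matrix, regions x samples, with sample names as
#'   column names; all values >= 0.
#' @return An object of class `CopyNumberMatrix`.
#' @export
cn_matrix <- function(regions, ratios) {
  ratios <- as.matrix(ratios)
  if (nrow(regions) != nrow(ratios))
    stop("regions and ratio matrix disagree on region count")
  if (any(ratios < 0, na.rm = TRUE)) stop("depth ratios must be >= 0")
  if (any(regions$start >= regions$end)) stop("regions need start < end")
  o <- order(regions$contig, regions$start)
  regions <- regions[o, , drop = FALSE]
  ratios <- ratios[o, , drop = FALSE]
  rownames(regions) <- NULL
  structure(list(regions = regions, ratios = ratios,
                 samples = colnames(ratios)),
            class = "CopyNumberMatrix")
}

#' Read a copy-number matrix from TSV
#'
#' Expects a header line with `contig`, `start`, `end` followed by one
#' column per sample.
#'
#' @param path TSV file.
#' @return A `CopyNumberMatrix`.
#' @export
read_cn_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  cn_matrix(df[, c("contig", "start", "end")],
            as.matrix(df[, -(1:3), drop = FALSE]))
}

#' Write a copy-number matrix as TSV
#' @param mat a `CopyNumberMatrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cn_matrix <- function(mat, path) {
  df <- cbind(mat$regions, as.data.frame(mat$ratios))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Call deletions and duplications from depth ratios
#'
#' A region x sample cell is a deletion when its mean depth ratio is
#' below `low` (default 0.5), a duplication when above `high` (default
#' 1.5), copy-neutral otherwise.
#'
#' @param mat a `CopyNumberMatrix`.
#' @param low,high depth-ratio thresholds.
#' @return data.frame of non-neutral calls: contig, start, end, sample,
#'   ratio, copy_number, call.
#' @export
cn_call <- function(mat, low = 0.5, high = 1.5) {
  calls <- lapply(seq_along(mat$samples), function(j) {
    r <- mat$ratios[, j]
    state <- ifelse(r < low, "deletion",
                    ifelse(r > high, "duplication", "neutral"))
    keep <- which(state != "neutral")
    if (length(keep) == 0L) return(NULL)
    data.frame(mat$regions[keep, , drop = FALSE],
               sample = mat$samples[j], ratio = r[keep],
               copy_number = round(2 * r[keep]), call = state[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  if (is.null(out))
    out <- data.frame(contig = character(), start = numeric(),
                      end = numeric(), sample = character(),
                      ratio = numeric(), copy_number = numeric(),
                      call = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-region V_ST copy-number differentiation
#'
#' `V_ST = (V_T - V_S) / V_T`, where V_T is the variance of the values
#' across all samples of both populations and V_S is the size-weighted
#' average of the within-population variances
#' `(n_A V_A + n_B V_B) / (n_A + n_B)`. Values are log2 depth ratios by
#' default (ratios floored at 0.01 before the log); sample (n - 1)
#' variances are used throughout. Regions with V_T = 0 are NA. Negative
#' estimates (possible with sample variances) are reported unclamped.
#'
#' @param mat a `CopyNumberMatrix`.
#' @param popmap a `PopulationMap`.
#' @param popA,popB population labels (>= 2 samples each).
#' @param scale `"log2"` (default) or `"linear"`.
#' @return data.frame: contig, start, end, v_t, v_s, vst.
#' @export
vst <- function(mat, popmap, popA, popB, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  sa <- intersect(samples_of(popmap, popA), mat$samples)
  sb <- intersect(samples_of(popmap, popB), mat$samples)
  if (length(sa) < 2L || length(sb) < 2L)
    stop("vst needs >= 2 samples per population")
  X <- mat$ratios[, c(sa, sb), drop = FALSE]
  if (scale == "log2") X <- log2(pmax(X, 0.01))
  ia <- seq_along(sa)
  ib <- length(sa) + seq_along(sb)
  v_t <- apply(X, 1L, stats::var)
  v_a <- apply(X[, ia, drop = FALSE], 1L, stats::var)
  v_b <- apply(X[, ib, drop = FALSE], 1L, stats::var)
  v_s <- (length(sa) * v_a + length(sb) * v_b) /
    (length(sa) + length(sb))
  v <- ifelse(!is.na(v_t) & v_t > 0, (v_t - v_s) / v_t, NA_real_)
  data.frame(mat$regions, v_t = v_t, v_s = v_s, vst = v,
             stringsAsFactors = FALSE)
}

#' Extract high-V_ST candidate regions
#'
#' Regions with V_ST at or above the `1 - top_fraction` quantile of valid
#' regions (ties included), merged when book-ended or overlapping; the
#' segment score is the maximum V_ST.
#'
#' @param vst_table output of [vst()].
#' @param top_fraction upper tail fraction (default 0.05).
#' @param min_regions minimum number of valid regions required.
#' @return A `SegmentSet` (provenance `"vst"`).
#' @export
high_vst_regions <- function(vst_table, top_fraction = 0.05,
                             min_regions = 20L) {
  v <- vst_table[!is.na(vst_table$vst), , drop = FALSE]
  if (nrow(v) < min_regions)
    stop("only ", nrow(v), " valid regions; need >= ", min_regions)
  thr <- stats::quantile(v$vst, 1 - top_fraction, names = FALSE)
  sel <- v[v$vst >= thr, , drop = FALSE]
  merge_segments(segment_set(sel$contig, sel$start, sel$end, sel$vst,
                             provenance = "vst"))
}
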