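#' Read a multi-sample VCF into a VariantPanel
#'
#' Parses a VCF 4.x file (via vcfR), keeping biallelic SNP records only;
#' multi-allelic and non-SNP records are dropped with a message giving the
#' count. Phased genotypes (`0|1`) populate the haplotype matrix; any
#' unphased retained genotype leaves the panel unphased. `./.` becomes
#' missing. An `AA=` INFO field, when present and equal to the REF or ALT
#' base, sets the ancestral state.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param require_phased error if any retained genotype is unphased.
#' @param contigs optional data.frame (`name`, `length`) overriding the
#'   `##contig` header lines; required if the header lacks lengths.
#' @return A `VariantPanel`.
#' @export
read_vcf <- function(path, require_phased = FALSE, contigs = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_in <- nrow(fix)
  is_snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  is_snp[is.na(is_snp)] <- FALSE
  if (sum(!is_snp) > 0L)
    message("read_vcf: dropped ", sum(!is_snp),
            " multi-allelic or non-SNP record(s)")
  keep <- which(is_snp)
  fix <- fix[keep, , drop = FALSE]
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(keep))
  samples <- colnames(v@gt)[-1L]

  a1 <- substr(gt, 1L, 1L)
  sep <- substr(gt, 2L, 2L)
  a2 <- substr(gt, 3L, 3L)
  ok <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  geno <- matrix(NA_integer_, nrow(gt), ncol(gt))
  geno[ok] <- as.integer(a1[ok]) + as.integer(a2[ok])
  phased <- sep == "|"
  if (require_phased && any(ok & !phased)) {
    first <- which(ok & !phased)[1L]
    rc <- arrayInd(first, dim(gt))
    stop("unphased genotype at ", fix$CHROM[rc[1L]], ":", fix$POS[rc[1L]],
         " sample ", samples[rc[2L]])
  }
  hap <- NULL
  if (nrow(gt) > 0L && all(phased[ok])) {
    hap <- matrix(NA_integer_, nrow(gt), 2L * ncol(gt))
    h1 <- matrix(NA_integer_, nrow(gt), ncol(gt))
    h2 <- h1
    h1[ok] <- as.integer(a1[ok]); h2[ok] <- as.integer(a2[ok])
    hap[, seq(1L, ncol(hap), by = 2L)] <- h1
    hap[, seq(2L, ncol(hap), by = 2L)] <- h2
  }

  anc <- rep("unknown", nrow(fix))
  if (!is.null(fix$INFO)) {
    has <- grepl("AA=[ACGTacgt]", fix$INFO)
    aa <- toupper(substr(regmatches(fix$INFO,
                                    regexpr("AA=[ACGTacgt]", fix$INFO)), 4L, 4L))
    anc[has][aa == fix$REF[has]] <- "ref"
    anc[has][aa == fix$ALT[has]] <- "alt"
  }

  if (is.null(contigs)) {
    meta <- v@meta
    cl <- meta[grepl("^##contig=", meta)]
    nm <- sub(".*ID=([^,>]+).*", "\\1", cl)
    ln <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", cl)))
    present <- unique(fix$CHROM)
    if (length(cl) > 0L && !any(is.na(ln))) {
      contigs <- data.frame(name = nm, length = ln, stringsAsFactors = FALSE)
      contigs <- contigs[contigs$name %in% present, , drop = FALSE]
    } else {
      message("read_vcf: no contig lengths in header; using max position")
      contigs <- data.frame(
        name = present,
        length = vapply(present, function(ctg)
          max(as.numeric(fix$POS[fix$CHROM == ctg])), numeric(1)),
        stringsAsFactors = FALSE)
    }
  }

  sites <- data.frame(contig = fix$CHROM, pos = as.numeric(fix$POS),
                      ref = fix$REF, alt = fix$ALT, ancestral = anc,
                      stringsAsFactors = FALSE)
  variant_panel(contigs, sites, geno, samples, hap = hap)
}

#' Write a VariantPanel as VCF 4.2
#'
#' Emits phased `a|b` genotypes when the panel carries haplotypes, else
#' unphased `0/0` / `0/1` / `1/1`; missing genotypes become `./.`. Known
#' ancestral states are recorded as `AA=` INFO entries so that
#' `read_vcf(write_vcf(panel))` round-trips genotypes, positions and
#' polarization.
#'
#' @param panel a `VariantPanel`.
#' @param path output file (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", panel$contigs$name,
                       as.integer(panel$contigs$length)),
               '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$samples), collapse = "\t")),
             con)
  S <- n_sites(panel)
  if (S == 0L) return(invisible(path))
  info <- rep(".", S)
  aa_ref <- panel$sites$ancestral == "ref"
  aa_alt <- panel$sites$ancestral == "alt"
  info[aa_ref] <- paste0("AA=", panel$sites$ref[aa_ref])
  info[aa_alt] <- paste0("AA=", panel$sites$alt[aa_alt])
  if (!is.null(panel$hap)) {
    h1 <- panel$hap[, seq(1L, ncol(panel$hap), by = 2L), drop = FALSE]
    h2 <- panel$hap[, seq(2L, ncol(panel$hap), by = 2L), drop = FALSE]
    gtmat <- matrix(paste0(h1, "|", h2), nrow = S)
    gtmat[is.na(h1) | is.na(h2)] <- ".|."
  } else {
    gtmat <- matrix(c("0/0", "0/1", "1/1")[panel$geno + 1L], nrow = S)
    gtmat[is.na(panel$geno)] <- "./."
  }
  lines <- paste(panel$sites$contig,
                 format(panel$sites$pos, scientific = FALSE, trim = TRUE),
                 ".", panel$sites$ref, panel$sites$alt, ".", "PASS",
                 info, "GT",
                 apply(gtmat, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Filter sites by minor-allele frequency and call rate
#'
#' Retains sites whose minor-allele frequency (computed over non-missing
#' alleles) is at least `maf_min` and whose fraction of non-missing
#' genotypes is at least `call_rate_min`; site order is preserved. The
#' standard panel-level screen is `maf_min = 0.05`, `call_rate_min = 0.9`.
#'
#' @param panel a `VariantPanel`.
#' @param maf_min minimum minor-allele frequency in `[0, 0.5)`.
#' @param call_rate_min minimum call rate in `(0, 1]`.
#' @return The filtered `VariantPanel`.
#' @export
filter_variants <- function(panel, maf_min = 0.05, call_rate_min = 0.9) {
  stopifnot(maf_min >= 0, maf_min < 0.5, call_rate_min > 0,
            call_rate_min <= 1)
  g <- panel$geno
  nonmiss <- rowSums(!is.na(g))
  n <- 2 * nonmiss
  a <- rowSums(g, na.rm = TRUE)
  p <- ifelse(n > 0, a / n, NA_real_)
  maf <- pmin(p, 1 - p)
  call_rate <- nonmiss / ncol(g)
  keep <- !is.na(maf) & maf >= maf_min & call_rate >= call_rate_min
  if (sum(keep) == 0L) message("filter_variants: no sites retained")
  subset_sites(panel, which(keep))
}

subset_sites <- function(panel, idx) {
  panel$sites <- panel$sites[idx, , drop = FALSE]
  rownames(panel$sites) <- NULL
  panel$geno <- panel$geno[idx, , drop = FALSE]
  if (!is.null(panel$hap)) panel$hap <- panel$hap[idx, , drop = FALSE]
  panel
}

#' Polarize a panel against an outgroup
#'
#' Sets each site's ancestral state to the outgroup's major allele when the
#' outgroup is non-missing and its major-allele frequency reaches
#' `threshold` (default 0.9); otherwise the ancestral state is `unknown`.
#' Downstream four-taxon and iHS scans use only sites with a known
#' ancestral state; all other scans keep every site.
#'
#' @param panel a `VariantPanel`.
#' @param popmap a `PopulationMap`.
#' @param outgroup outgroup population label (or the role `"O"`).
#' @param threshold outgroup major-allele frequency needed to call the
#'   ancestral state.
#' @return The panel with updated `sites$ancestral`.
#' @export
polarize <- function(panel, popmap, outgroup = "O", threshold = 0.9) {
  idx <- sample_idx(panel, popmap, outgroup)
  g <- panel$geno[, idx, drop = FALSE]
  n <- 2 * rowSums(!is.na(g))
  a <- rowSums(g, na.rm = TRUE)
  p_alt <- ifelse(n > 0, a / n, NA_real_)
  anc <- rep("unknown", n_sites(panel))
  anc[!is.na(p_alt) & p_alt >= threshold] <- "alt"
  anc[!is.na(p_alt) & (1 - p_alt) >= threshold] <- "ref"
  panel$sites$ancestral <- anc
  panel
}

# allele counts within a set of sample indices:
# a = alt allele count, n = non-missing allele count (haploid units)
allele_counts <- function(panel, idx) {
  g <- panel$geno[, idx, drop = FALSE]
  list(a = rowSums(g, na.rm = TRUE), n = 2 * rowSums(!is.na(g)))
}

#' Per-site derived-allele frequency within a population
#'
#' The derived allele is the non-ancestral allele; sites with unknown
#' ancestral state get `NA`.
#'
#' @param panel a polarized `VariantPanel`.
#' @param popmap a `PopulationMap`.
#' @param pop population label or role.
#' @return numeric vector, one frequency per site.
#' @export
derived_freq <- function(panel, popmap, pop) {
  ac <- allele_counts(panel, sample_idx(panel, popmap, pop))
  p_alt <- ifelse(ac$n > 0, ac$a / ac$n, NA_real_)
  out <- rep(NA_real_, n_sites(panel))
  anc <- panel$sites$ancestral
  out[anc == "ref"] <- p_alt[anc == "ref"]
  out[anc == "alt"] <- 1 - p_alt[anc == "alt"]
  out
}
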