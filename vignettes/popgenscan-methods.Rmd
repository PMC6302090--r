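---
title: "Methods: windowed population-genomic scans in popgenscan"
author: "popgenscan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed population-genomic scans in popgenscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenscan)
```

popgenscan re-implements, as one tested pipeline, the window-based scan
statistics that whole-genome resequencing studies of structured plant and
animal populations routinely combine: diversity and differentiation
(θ~π~, Tajima's D, Weir–Cockerham F~ST~, d~XY~), four-taxon introgression
tests (Patterson's D with block-jackknife errors, windowed f~d~ with
segment calling and a d~XY~ contrast), haplotype-homozygosity selection
statistics (EHH, iHS, XP-EHH with extreme-score window selection), runs
of homozygosity, inbreeding and LD summaries, and the V~ST~ statistic for
population-differentiated copy number. Because the raw sequence data such
studies use are far beyond desk scale, the package ships two synthetic
genotype generators whose planted truth makes every scan testable end to
end. This vignette records the models, the parameter choices and their
rationale, the numerical decisions, and what the synthetic tests do and
do not demonstrate about real data.

## Data model and conventions

A `VariantPanel` holds biallelic SNPs only: a sites × samples genotype
matrix coded 0/1/2 with `NA` for missing, plus an optional sites ×
2·samples binary haplotype matrix when genotypes are phased. VCF
positions are 1-based; windows, BED output and all interval arithmetic
are 0-based half-open — the standard interop choice. Multi-allelic and
non-SNP records are dropped on input rather than split, because every
statistic below is defined for two alleles. Minor-allele frequency is
computed over non-missing alleles only, and the panel-level screen
(`filter_variants()`) defaults to call rate ≥ 0.9 and MAF ≥ 0.05, the
usual thresholds for population-structure work.

Windows come from `make_windows()`: half-open `[k·step, k·step + size)`
sliding windows, 20 kb with a 10-kb step by default, truncated at contig
ends. Per-window values of every sum-decomposable statistic are
assembled from per-site terms by cumulative sums, so a scan costs
O(sites + windows).

### Ancestral-allele polarization

The four-taxon and iHS statistics need derived-allele frequencies. The
paper-style pipeline infers them from an outgroup: `polarize()` calls
the ancestral state as the outgroup's major allele when its frequency in
the outgroup reaches 0.9, and `unknown` otherwise. The 0.9 threshold is
a conservative default for a deliberately under-specified step: sites
with `unknown` ancestral state are excluded from D, f~d~ and iHS but
retained everywhere else. The simulators additionally record the true
ancestral allele, which lets the tests measure polarization accuracy
(typically > 90% of called sites with a deeply diverged outgroup;
errors are symmetric between ABBA and BABA and so do not bias D's null).

## Diversity and differentiation

Per site with alt count *a* among *n* non-missing alleles, nucleotide
diversity contributes 2a(n−a)/(n(n−1)); window θ~π~ divides the sum by
the window length in bp (monomorphic windows are 0, not NA — absence of
variation is information). d~XY~ uses p~A~(1−p~B~) + (1−p~A~)p~B~ per
site, again per bp. Tajima's D follows the 1989 constants with *n* taken
as twice the number of population samples with any non-missing call in
the window, and sites with > 50% missingness skipped; windows without a
segregating site are NA. F~ST~ is the Weir & Cockerham (1984) θ
with per-site variance components summed over the window before the
ratio is taken ("ratio of sums", as VCFtools computes it); negative
estimates are reported unclamped, and per-site sample sizes account for
missingness. The inbreeding coefficient is the plain F = 1 − H~o~/H~e~
with H~e~ = mean 2p(1−p), no small-sample correction — matching the bare
formula the statistic is usually quoted with.

`pi_ratio()` reports per-window log~2~(π~B~/π~A~) and two genome-wide
scalars: the ratio of summed diversities (default headline number) and
the mean of per-window ratios. Both are exposed because published
"θ~π~-ratio" values rarely state the averaging order.

## Introgression

`compute_d_parts()` uses the population-frequency formulation:
ABBA = (1−p̂₁)p̂₂p̂₃(1−p̂₄), BABA = p̂₁(1−p̂₂)p̂₃(1−p̂₄) per usable site, and
D = Σ(ABBA−BABA)/Σ(ABBA+BABA). Significance comes from a weighted
delete-one block jackknife (Busing et al. 1999) over 5-Mb blocks by
default, with block weights equal to usable-site counts; identical
block estimates yield SE = 0 and an infinite Z with a warning rather
than a silent division.

The windowed f~d~ follows Martin et al. (2015): the numerator is the
windowed D numerator and the denominator replaces P2 and P3 by
whichever of the two has the higher derived frequency at each site —
the value a complete-admixture donor would produce, making f~d~ an
estimate of the local admixture proportion. Windows with fewer than 30
usable SNPs or non-positive window D are invalid; f~d~ > 1 (floating
ties) is clipped to 1 with a warning. The top-5% caller includes values
tied with the quantile threshold and merges book-ended windows.
`dxy_contrast()` then compares windowed d~XY~ inside candidate segments
against the background with a one-sided Mann–Whitney U test: recent
introgression lowers absolute divergence, ancestral structure does not.
The null calibration in the test-suite uses non-overlapping windows,
because sliding windows share sites and would mildly inflate the
rejection rate of a rank test that assumes independent observations.

## Haplotype scans

EHH from a focal site is the probability that two randomly drawn core
haplotypes are identical over the interval extending to distance *d*,
computed by exact pair counting (Σ C(k~g~,2)/C(K,2)) with group
refinement outward from the core. iHH integrates the curve
trapezoidally over physical distance — no genetic map is assumed — and
truncates at the last point with EHH ≥ 0.05 (the Voight et al.
convention); curves still above the cutoff at the contig edge are
flagged censored and excluded from scores by default. iHS is
ln(iHH~ancestral~/iHH~derived~) at sites with derived frequency in
[0.05, 0.95], standardized to mean 0, sd 1 within derived-frequency
bins of width 0.05; XP-EHH is ln(iHH~A~/iHH~B~) with each population's
full haplotype set as core, standardized genome-wide. Bins whose raw
scores are numerically tied (spread at rounding-error scale) are left
unscored instead of amplifying cancellation noise.

"Normalization with a 20-kb window" is implemented as window
*summarization* of standardized scores — the per-window fraction of
sites with |score| ≥ 2, with the top 1% of windows kept — not as
per-window re-standardization, which would destroy comparability across
windows. Windows with an all-zero extreme ratio are never selected, so
a signal-free genome returns an empty segment set.

## Sweep calling and region merging

The combined caller drops windows with fewer than 10 SNPs, Z-transforms
F~ST~ across the remaining windows, and intersects the top 5% of
Z(F~ST~) with the diversity-reduction tail of the log~2~ π-ratio. A
sweep in the focal population depresses its own π, so with the ratio
oriented log~2~(π~other~/π~focal~) the sweep tail is the upper tail;
that orientation is the default, and `tail = "low"` reproduces the
literal bottom-tail reading for ratios oriented the other way (the
published wording is ambiguous about which population sits in the
numerator). `merge_regions()` unions candidate sets from different
scans, concatenating provenance labels.

## Relatedness, ROH and LD

The identity score uses IS = 1 − |R~a~ − R~b~|; the absolute value keeps
the score symmetric and in [0, 1] (the formula is sometimes printed
without it, which is asymmetric and can exceed 1). With genotypes only,
R is approximated by the reference-allele dosage/2. IBS is the mean
fraction of alleles shared identical by state. ROH detection follows
the PLINK-style heuristic with the stated flags: 50-SNP windows, ≤ 2
missing, 0 heterozygotes, per-SNP hit fraction 0.05 (the referenced
tool's default, which the flags list omits), and final runs required to
have ≥ 50 SNPs, ≥ 50 kb span and ≤ 50 kb per SNP ("SNP density of 50"
read in the tool's kb-per-SNP unit). LD decay resamples 5 accessions
100 times to remove sample-size bias, computes r² for SNP pairs within
500 kb (haplotype correlation when phased, genotype-dosage correlation
otherwise), bins by 100 bp and reports across-resample means and SDs;
the resampling is fully seeded.

## Copy-number differentiation

V~ST~ = (V~T~ − V~S~)/V~T~ per region, where V~T~ is the variance of
log~2~ depth ratios across all samples and V~S~ the sample-size-weighted
mean of within-population variances; sample (n−1) variances are used
throughout (the estimator is not specified in the usual verbal
definition), ratios are floored at 0.01 before the log, and a linear
scale is available. Regions with V~T~ = 0 are NA; negative values
(possible with sample variances) are reported unclamped. Deletion and
duplication calls use the 0.5/1.5 mean-depth-ratio thresholds, with
copy number approximated as round(2·ratio) — a stated stand-in for
model-based CNV genotyping, which consumes read data this package does
not.

## Synthetic data: what it emulates and what it does not

Two generators cover complementary needs:

* **Frequency-level (Balding–Nichols).** Ancestral frequencies are
  uniform (star model) or drawn from a low-frequency-skewed range on a
  fixed topology (((P1,P2),P3),O) with a Beta drift kernel per branch
  (`simulate_tree_panel()`). Sites are independent — ideal for π, F~ST~,
  d~XY~, D, f~d~ and V~ST~ tests, useless for EHH/ROH/LD. The tree
  defaults (branch F of 0.03–0.15 within the ingroup, 0.4 to the
  outgroup, root derived frequencies on [0.02, 0.4]) emulate
  species-level divergence with mutation-derived alleles; with equal
  drift on the two sister branches the four-taxon D has expectation 0,
  which is what makes this the D/f~d~ null generator.
* **Haplotype-level (forward Wright–Fisher).** Diploid populations of
  size N~e~ ≤ 2000 evolve by discrete-generation random mating with
  Poisson crossovers and infinite-sites mutation at continuous positions
  (discretized at emission). Founders are drawn from the neutral site
  frequency spectrum at linkage equilibrium; a burn-in (default 2N~e~
  generations) builds the linkage and haplotype-sharing structure while
  the frequency spectrum stays near equilibrium — a neutral run keeps
  mean windowed Tajima's D within ±0.5. This replaces the ~4N~e~
  generations a cold start would need. Default rates (μ = 5×10⁻⁷,
  r = 10⁻⁶ per bp per generation at N~e~ = 100) are scaled-down
  settings chosen so that θ = 4N~e~μ ≈ 2×10⁻⁴/bp matches a diverse
  plant genome while simulations finish in seconds; users emulating a
  specific system should preserve θ and ρ rather than the raw rates.
  A one-generation migration pulse implants whole donor haplotypes;
  donor ancestry is tracked by neutral marker loci that recombine with
  real sites, so realized admixture fractions and tract records come
  from the simulation itself. The realized genome-wide fraction drifts
  around the pulse fraction with sd ≈ √(f(1−f)t/2N~e~), which is why
  tight recovery checks use very recent pulses.

Planting helpers transplant donor haplotypes into tracts
(`plant_introgression()`, sharp truth boundaries for recall/precision),
copy one haplotype over a stated fraction of a population in a region
(`plant_sweep()`; the expected diversity reduction is a factor
1/(1−q²) ≈ 2.8 at q = 0.8, and iHS power peaks for sweeps near 50%
frequency, where both allelic cores remain large), force a sample
homozygous in a region (`plant_roh()`), and build depth-ratio matrices
with population-differentiated regions (`simulate_cn_matrix()`).

Passing tests on these generators show that the estimators compute
their definitions correctly, recover planted parameters, and are
calibrated under their own nulls. They do not show robustness to
sequencing error, genotype-likelihood uncertainty, reference bias,
variable recombination and mutation rate along the genome, gene
conversion, or realistic demographic complexity — none of which the
generators emulate.

## Numerical choices and degenerate inputs

* Quantile thresholds (top-5% f~d~ and V~ST~, top-1% extreme-ratio)
  use R's default quantile type; values tied with the threshold are
  included.
* Zero denominators return NA (D with no informative sites, V~ST~ with
  V~T~ = 0, log-ratios with a zero π) rather than infinities; the one
  exception is the jackknife Z with SE = 0, reported as signed Inf with
  a warning because "identical in every block" is evidence of a
  degenerate configuration, not of no signal.
* All simulators and the LD resampler take integer seeds and are
  bit-reproducible; nothing depends on hash ordering or parallel
  scheduling.
* Problem sizes in the test-suite (2–10 Mb genomes, 8–50 diploids,
  N~e~ = 40–150, 20–200 replicates for calibration rates) were chosen
  as the smallest sizes at which the checked quantities are stable,
  and are stated in each test.

## Known limitations

Genotypes are hard calls; there is no genotype-likelihood or imputation
support. EHH-family scans require phased input and use physical
distance only. The combined sweep caller inherits the arbitrariness of
tail thresholds; its null false-positive rate is the product of the two
tail fractions only approximately, since the F~ST~ and π-ratio tails
are positively correlated through shared drift. f~d~ is a conservative
estimator of the admixture proportion (its max-based denominator is
biased upward under noise), which the planted-tract recovery band
reflects. V~ST~ with few samples is noisy and its permutation null,
not an analytic distribution, is the intended reference.
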