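# popgenscan

Windowed population-genomic scans for introgression, selection and
copy-number differentiation, with fully seeded synthetic-data generators
that make the whole pipeline testable offline.

Whole-genome resequencing studies of structured populations — crop and
fruit-tree domestication panels, livestock breeds, natural hybrid zones —
lean on a recurring toolkit of window statistics: nucleotide diversity
(θπ), Tajima's D, Weir–Cockerham F<sub>ST</sub> and d<sub>XY</sub> in
20-kb sliding windows; Patterson's D (ABBA-BABA) with block-jackknife
standard errors and a windowed f<sub>d</sub> scan to localize
introgressed segments, discriminated from ancestral structure by lower
d<sub>XY</sub>; selective-sweep candidates from the intersection of
top-tail Z(F<sub>ST</sub>) and log2 π-ratio windows, complemented by
iHS and XP-EHH extreme-score windows; runs of homozygosity, inbreeding
coefficients (F = 1 − H<sub>o</sub>/H<sub>e</sub>), identity scores, IBS
and LD decay with resampling; and V<sub>ST</sub> =
(V<sub>T</sub> − V<sub>S</sub>)/V<sub>T</sub> for population-differentiated
copy number. popgenscan implements that toolkit as one coherent,
tested R package for researchers who need the scans reproducible and
verifiable rather than scattered across single-purpose binaries.

The core statistics, in the field's standard notation:

- θπ per window: Σ<sub>sites</sub> 2a(n−a)/(n(n−1)) / L, with a the
  alt-allele count among n non-missing alleles;
- D = Σ(ABBA − BABA)/Σ(ABBA + BABA), ABBA = (1−p̂₁)p̂₂p̂₃(1−p̂₄),
  BABA = p̂₁(1−p̂₂)p̂₃(1−p̂₄), Z from a weighted 5-Mb block jackknife;
- f<sub>d</sub> = S(P1,P2,P3,O)/S(P1,P<sub>D</sub>,P<sub>D</sub>,O),
  windows with < 30 SNPs or D ≤ 0 excluded, top 5% called;
- iHS = ln(iHH<sub>A</sub>/iHH<sub>D</sub>) standardized in
  derived-frequency bins; XP-EHH = ln(iHH<sub>A</sub>/iHH<sub>B</sub>)
  standardized genome-wide; top 1% of windows by the fraction of
  |score| ≥ 2 sites;
- V<sub>ST</sub> = (V<sub>T</sub> − V<sub>S</sub>)/V<sub>T</sub> on log2
  depth ratios, V<sub>S</sub> weighted by population size.

Inputs are standard formats: multi-sample VCF 4.x (phased or not), a
two-column sample→population TSV, BED for interval output, and a
region × sample depth-ratio TSV for the copy-number module. Two
generators — a Balding–Nichols frequency model (star or four-taxon tree)
and a forward Wright–Fisher simulator with recombination, mutation and an
optional migration pulse — plant introgression tracts, sweeps, ROH tracts
and differentiated copy-number regions with exact truth records.

## Worked example: an introgression scan end to end

Simulate a four-population panel (((P1,P2),P3),O), transplant donor
haplotypes from P3 into 30% of P2 in two tracts, and run the D / f_d /
d<sub>XY</sub> pipeline:

```r
library(popgenscan)

panel <- simulate_tree_panel(n_sites = 20000, spacing = 100, seed = 42)
popmap <- sim_popmap(panel)
panel <- plant_introgression(panel, popmap, donor = "P3",
  recipient = "P2",
  tracts = data.frame(contig = "chr1", start = c(5e5, 1.2e6),
                      end = c(5.6e5, 1.26e6)),
  fraction = 0.3, seed = 43)

parts <- compute_d_parts(panel, popmap)
block_jackknife(parts, block_bp = 1e5)
#> D = 0.0114  SE = 0.0059  Z = 1.93  (21 blocks of 1e+05 bp)

grid <- make_windows(panel, size = 20000, step = 10000)
fdw <- window_fd(parts, grid, min_snps = 30)
segments <- call_introgression(fdw, top_fraction = 0.05)
segments
#>   contig   start     end     score   label
#> 1   chr1  500000  560000 0.3383096 fd_scan
#> 2   chr1  910000  930000 0.2969127 fd_scan
#> 3   chr1 1230000 1250000 0.2271491 fd_scan

contrast <- dxy_contrast(panel, popmap, "P2", "P3", segments, grid)
contrast$summary
#>        group   n     q25  median     q75
#> 1    segment  13 0.00264 0.00265 0.00271
#> 2 background 188 0.00267 0.00275 0.00286
contrast$p_value
#> [1] 0.0068
```

Reading the output: the genome-wide D is small and non-significant
(Z = 1.93 < 3) because only ~3% of the genome is introgressed, yet the
windowed f<sub>d</sub> caller recovers both planted tracts
([500–560 kb] and [1.23–1.25 Mb] overlap the truth; the 910–930 kb
window is a false positive), the segment scores approximate the planted
admixture fraction 0.3, and d<sub>XY</sub>(P2, P3) inside the called
segments is significantly lower than the genome background (one-sided
Mann–Whitney p = 0.0068) — the signature that separates recent
introgression from shared ancestral polymorphism.

The same pattern applies to the other scans: `window_pi()`,
`window_tajima_d()`, `window_fst()` feed `pi_ratio()` and
`combine_fst_piratio()` for sweep calling; `ihs_scan()`, `xpehh_scan()`
and `extreme_ratio_windows()` cover the haplotype statistics;
`detect_roh()`, `inbreeding_f()`, `pairwise_ibs()` and `ld_decay()`
summarize homozygosity and linkage; `vst()` and `high_vst_regions()`
scan copy-number matrices. `write_bed()` / `write_vcf()` export any
result.

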