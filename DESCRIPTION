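Package: popgenscan
Title: Windowed Population-Genomic Scans for Introgression, Selection and
    Copy-Number Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sliding-window population-genetic statistics (nucleotide
    diversity, Tajima's D, Weir-Cockerham FST, dXY), ABBA-BABA D-statistics
    with block-jackknife standard errors and windowed f_d introgression
    scans, haplotype-homozygosity selection statistics (EHH, iHS, XP-EHH)
    with extreme-score window selection, runs of homozygosity, inbreeding
    and linkage-disequilibrium decay summaries, and the V_ST copy-number
    differentiation statistic, together with Balding-Nichols and forward
    Wright-Fisher genotype simulators that plant introgression tracts,
    sweeps, homozygous tracts and differentiated copy-number regions with
    full truth records for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
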