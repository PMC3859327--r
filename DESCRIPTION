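Package: meditile
Title: MeDIP Tiling-Array Methylation Profiling with Windowed KS Peak Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of MeDIP-chip (methylated DNA immunoprecipitation on
    tiling microarrays) promoter methylation profiles. Computes per-probe
    enrichment P-scores with a sliding-window one-sided Kolmogorov-Smirnov
    test on log2(IP/input) ratios, calls methylation peaks by rule-based
    merging of above-cutoff probes, maps peaks to genomic features (TSS,
    primary transcript, CpG island, tiled region) with a strand-aware
    distance window and priority order, flags strain-differential
    hypo/hypermethylated features, and derives profile-level statistics:
    inter-tissue Pearson correlations, promoter distance-class tabulations,
    high-peak censuses, methylation-expression association with rank-sum
    tests, and EASE-score category enrichment with Benjamini-Hochberg
    correction. Includes a synthetic methylome generator emulating a
    two-strain, three-tissue promoter-array study design for end-to-end
    validation with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    withr,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
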