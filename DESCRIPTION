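Package: postgwas
Title: Post-GWAS Locus Mapping, Gene Prioritization, Enrichment and Drug
    Connectivity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing of genome-wide association study (GWAS) summary
    statistics as used in large case-control mega-analyses of common disease:
    effective sample sizes, genomic inflation (lambda, lambda1000),
    LD-aware chi-square outlier filtering, Cochran's Q heterogeneity
    filtering and sample-size-weighted fixed-effects meta-analysis;
    definition of genome-wide significant loci from LD with the lead
    variant and locus-to-gene mapping by position and promoter chromatin
    interactions; multi-criteria biological gene prioritization; gene-set
    enrichment by central hypergeometric and gene-length-bias-corrected
    Wallenius noncentral hypergeometric tests; observed-to-liability-scale
    heritability conversion; and connectivity-map drug repurposing with
    cosine signature reversal scores, permutation null thresholds and
    drug-set enrichment statistics. A synthetic-data generator with planted
    signals makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
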