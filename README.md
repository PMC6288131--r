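# postgwas

Post-processing toolkit for case-control GWAS summary statistics, built
for the downstream arm of large epilepsy-style mega-analyses: from a
table of per-variant z-scores to risk loci, candidate genes, enrichment
statistics, liability-scale heritability and drug-repurposing
candidates. It is aimed at statistical geneticists who have association
summary statistics (their own or public) plus standard annotation
tables, and who want the bespoke downstream computations of such studies
as tested, reusable functions rather than one-off scripts.

## What it computes

* **Summary-statistic QC** — effective sample size
  `Neff = 4/(1/Ncases + 1/Nctrls)`; genomic inflation λ and λ1000;
  an LD-aware χ² outlier filter that flags variant pairs in high LD
  (r² > 0.4) with `|χ²₁ − χ²₂| > 3·sqrt((χ²₁+χ²₂)/2)/(r²)²`; Cochran's
  Q heterogeneity filtering (P_het < 1e-8); sample-size-weighted
  fixed-effects meta-analysis `z = Σ zᵢ√Nᵢ / sqrt(Σ Nᵢ)`.
* **Loci and genes** — genome-wide significant loci (lead p < 5e-8,
  members p < 1e-4 with r² > 0.2 to the lead, overlapping loci merged);
  positional gene mapping within ±250 kb of the locus and
  chromatin-interaction mapping at promoter-interaction FDR < 1e-6.
* **Gene prioritization** — six boolean evidence criteria (TWAS, eQTL,
  brain-preferential expression, missense, protein-interaction network,
  knockout-mouse phenotype), score = criteria met, top scorer(s) per
  locus with a minimum score of 2.
* **Enrichment** — sample odds ratio and exact hypergeometric tails for
  gene-set overlaps, plus a gene-length-bias-corrected Wallenius
  noncentral hypergeometric test (biased urn with odds = ratio of mean
  gene lengths), computed by an exact sequential-draw recursion.
* **Heritability** — observed-to-liability-scale conversion
  `h²_L = h²_o · K²(1−K)² / (p(1−p)Z²)` with prevalence sensitivity.
* **Drug connectivity** — disease signature = top 10% of genes by |z|;
  cosine reversal scores against perturbagen profiles; per-drug
  condition collapse by maximal |cos|; permutation null threshold at
  α = 0.05; drug-set overlap and median-rank permutation p-values.
* **Synthetic data** — a seeded generator planting causal loci through
  block LD, size-inflated target gene sets, top-scoring genes and
  signature-reversing drugs, so the whole pipeline is testable offline.

## Worked example

The enrichment worked example of the epilepsy mega-analysis: 146 genes
mapped to genome-wide significant loci, of which 6 are among the 102
known monogenic epilepsy genes, in a universe of 19,180 protein-coding
genes — first the central test, then the gene-size-corrected test at
sampling odds 2.42:

```r
library(postgwas)
tab <- enrichment_counts(universe_n = 19180, target_k = 102,
                         drawn_n = 146, overlap_a = 6)
test_enrichment(tab)
#> Hypergeometric enrichment (N=19180, K=102, n=146, a=6)
#>   OR = 8.454, P(X>a) = 1.29e-05, P(X>=a) = 0.00013
test_enrichment(tab, weight = 2.42)
#> Wallenius enrichment (N=19180, K=102, n=146, a=6, w=2.42)
#>   OR = 8.454, P(X>a) = 0.0025, P(X>=a) = 0.0105
```

The odds ratio 8.45 and strict tail 1.3e-5 are the published values for
this table. After the length-bias correction the enrichment weakens by
two orders of magnitude but survives: long genes are simply easier to
hit by positional mapping, and the corrected tail (~1e-2) is the honest
residual signal.

Converting an observed-scale heritability of 0.25 to the liability scale
at a prevalence of 0.002 with 34% cases in the sample, bracketed by
half/double prevalence:

```r
liability_transform(0.25, prevalence = 0.002, case_proportion = 0.34)
#> [1] 0.1104163
prevalence_sensitivity(0.25, 0.002, 0.34)
#>    factor prevalence h2_liability
#> 1:    0.5      0.001   0.09807056
#> 2:    1.0      0.002   0.11041631
#> 3:    2.0      0.004   0.12598961
```

An end-to-end synthetic run — plant five risk loci, define loci from the
summary statistics and LD, map genes and prioritize:

```r
cfg <- sim_config(seed = 42, n_snps = 4000, n_loci = 5, n_genes = 400)
sim <- simulate_sumstats(cfg)
loci <- define_loci(sim$sumstats, sim$ld)
loci[, c("locus_id", "lead_variant", "lead_p", "n_members")]
#>               locus_id lead_variant       lead_p n_members
#> 1:       1:5000-100000     rs000010 1.397213e-19        20
#> 2:   1:1405000-1500000     rs000290 2.563077e-16        20
#> 3:   1:4905000-5000000     rs000990 1.038857e-13        20
#> 4: 1:12605000-12700000     rs002530 1.429108e-13        20
#> 5: 1:18205000-18300000     rs003650 9.051370e-14        20

gs <- simulate_genes_and_sets(cfg, sim$truth)
prioritize_genes(score_genes(gs$criteria), map_genes(loci, gs$genes))
#> $`1:12605000-12700000`
#> [1] "GENE00004"
#> ...
```

All five planted loci are recovered with their full 20-variant LD blocks
as members, and the planted top-scoring gene is prioritized in each.
`run_pipeline(pipeline_config(...), out_dir)` chains all stages on files
and writes tab-separated outputs plus a JSON report embedding the
configuration.

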