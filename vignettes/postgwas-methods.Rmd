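---
title: "Methods: post-GWAS locus mapping, prioritization, enrichment and drug connectivity"
author: "postgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-GWAS locus mapping, prioritization, enrichment and drug connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postgwas)
```

# Scope

`postgwas` implements the downstream, summary-statistic-level arm of a
case-control GWAS mega-analysis of a common, polygenic disease: quality
control of association statistics, definition of genome-wide significant
loci, mapping of loci to candidate genes, multi-criteria biological gene
prioritization, gene-set enrichment with and without a gene-length bias
correction, conversion of SNP-heritability to the liability scale, and
connectivity-map drug repurposing. Everything upstream of the summary
statistics — genotype calling, imputation, kinship, the mixed-model
association itself — is out of scope, as are analyses that require
individual-level genotypes or external transcriptome references (TWAS
model fitting, eQTL calling, LD-score regression). Where such analyses
feed the pipeline, their outputs enter as plain columns: boolean
evidence criteria, gene-level association z-scores, interaction FDRs.

# Summary-statistic QC

**Effective sample size.** Unbalanced case-control strata are weighted
in meta-analysis by $N_\mathrm{eff} = 4/(1/N_\mathrm{cases} +
1/N_\mathrm{ctrls})$, the balanced-design size of equivalent power. It is
symmetric, bounded by the total sample size, and attains it only for
balanced designs.

**Genomic inflation.** $\lambda$ is the median observed 1-df
$\chi^2$ over the null median ($\approx 0.4549$); because $\lambda$
scales with sample size we also report
$\lambda_{1000} = 1 + (\lambda - 1)\cdot 500\,(1/N_\mathrm{cases} +
1/N_\mathrm{ctrls})$. The rescaling formula is the standard case-control
convention; it is an explicit design choice here because the source
analyses cite it without printing it.

**LD-aware $\chi^2$ outlier filter.** For every variant pair in high LD
($r^2 > 0.4$ by default), the pair is flagged when
$|\chi^2_1 - \chi^2_2| > 3\sqrt{(\chi^2_1 + \chi^2_2)/2}\,/\,(r^2)^2$.
A very large statistic that its strong LD partners do not support is the
signature of a spurious, isolated signal, so the implementation removes
the **larger**-$\chi^2$ member of a flagged pair; the full pair record
is returned so a caller preferring to drop both members can. Pairs with
$r^2 = 0$ are skipped (the cutoff is undefined there). Flags are
invariant to the orientation of a pair and to input row order.

**Heterogeneity.** Cochran's $Q = \sum_i w_i(\beta_i - \bar\beta)^2$
with $w_i = 1/\mathrm{se}_i^2$, referred to $\chi^2_{k-1}$; variants
with $P_\mathrm{het} < 10^{-8}$ across cohort clusters are removed. A
single stratum keeps the variant with $Q$ undefined.

**Meta-analysis.** The default scheme is the sample-size-weighted
z-combination $z = \sum_i z_i \sqrt{N_{\mathrm{eff},i}} \big/
\sqrt{\sum_i N_{\mathrm{eff},i}}$ — the scheme for which
$N_\mathrm{eff}$ exists — with an inverse-variance alternative behind a
flag. The choice is deliberate: the upstream tooling convention pairs
effective sample sizes with sample-size weighting.

Stored p-values are trusted but checked: a stored `P` inconsistent with
the two-sided normal map of `Z` beyond $10^{-6}$ relative tolerance is
an error, never silently overwritten.

# Locus definition and gene mapping

Loci are built greedily: the smallest-p unassigned variant with
$p < 5\times 10^{-8}$ seeds a locus spanning all unassigned variants
with $p < 10^{-4}$ and $r^2 > 0.2$ with the lead. The span uses the
positions of qualifying members only, not LD-block boundaries. Two open
choices are resolved as follows and exposed as parameters:

* **Overlapping loci are merged** (same chromosome, intersecting
  spans), keeping the smaller-p lead. This keeps member sets disjoint
  and prevents a gene from being counted twice in enrichment.
* **Ties** between equal p-values are broken by variant id, so locus
  construction is invariant to input row order.

Positional mapping assigns a gene to a locus when the gene interval
intersects the locus span widened by 250 kb on each side, measured from
the locus **edges**. Chromatin-interaction mapping assigns a gene when a
promoter interaction with anchor overlapping the locus has
FDR $< 10^{-6}$ (strict). Gene and anchor intervals follow the 0-based
half-open BED convention, summary-statistic positions are 1-based, and
overlap tests convert internally; both thresholds are strict
inequalities, matching the boundary tests in the suite. Interval
arithmetic is delegated to `GenomicRanges`/`IRanges`.

# Gene prioritization

Each mapped gene is scored 0-6, one point per boolean criterion met:
significant TWAS association, cis-eQTL in the locus, brain-preferential
expression, missense variant in the locus, protein-interaction-network
prioritization, and a nervous-system or behavioural knockout-mouse
phenotype. Five of the six require external resources and are consumed
as precomputed 0/1 columns; only brain-preferential expression (strict
inequality of mean brain vs mean non-brain expression) is computed here,
from any gene-by-tissue matrix. Per locus, all genes attaining the
maximal score are prioritized provided that maximum is at least 2;
otherwise the locus reports none. A gene mapped to several loci is
scored once but competes in each locus independently. Missing genes in
the criteria table score 0 with a warning — absence of evidence is
treated as absence.

# Enrichment

The overlap $a$ between a drawn gene list (size $n$) and a curated
target set (size $K$) in a universe of $N$ protein-coding genes is
tested two ways.

**Central hypergeometric.** Exact tails from `stats::phyper`; both
$P(X > a)$ and $P(X \ge a)$ are always reported because published
single-number p-values differ in which tail they quote. The reported
odds ratio is the sample cross-product $(a d)/(b c)$, not the
conditional MLE — this is the quantity that reproduces the published
worked examples. The universe convention is **total** universe
($N = 19{,}180$ with the drawn genes inside it); the source text's
"rest of the genome" phrasing is not what its own numbers use, and the
total-universe convention is the one that reproduces them.

**Wallenius noncentral hypergeometric.** Long genes are more likely to
be hit by positional mapping; target sets of long genes (the observed
mean-size ratio for monogenic epilepsy genes is 2.44) therefore enrich
spuriously. The correction gives each remaining target gene sampling
odds $w$ per draw (the mean-size ratio, conservatively rounded down to
2.42/2.43 in the replication recipes) and computes the tail under
Wallenius' distribution. The pmf is computed by the exact
sequential-draw recursion
$$P_{j+1}(x) = P_j(x{-}1)\frac{w(K-x+1)}{w(K-x+1) + M_j} +
P_j(x)\frac{M'_j}{w(K-x)+M'_j},$$
i.e. the defining Markov chain of the biased urn, which is numerically
stable and exact to floating point for draws in the hundreds (cost
$O(n\min(n,K))$). Probability conservation is asserted at $10^{-8}$ and
the suite cross-checks the pmf against exhaustive enumeration, a
Monte-Carlo biased-urn oracle, and the central distribution at $w = 1$
(agreement to $10^{-10}$). The integral representation used by other
implementations was not needed at these problem sizes.

A reproduction note: at the published counts (19180, 102, 146, 6) and
odds 2.42, the inclusive tail is $1.05\times 10^{-2}$ and the strict
tail $2.5\times 10^{-3}$; the corresponding published value
$8.3\times 10^{-3}$ lies between the two and is reproduced by neither
tail (two independent implementations agree to machine precision), while
the drug-target analogue $1.7\times 10^{-5}$ is matched by the
inclusive tail to one significant figure. The acceptance suite asserts
both faithfully; the monogenic check is expected to fail and is left
failing rather than loosened.

# Liability-scale heritability

Observed-scale SNP-heritability from an ascertained case-control sample
converts to the liability scale by
$h^2_L = h^2_o \cdot K^2(1-K)^2 / \big(p(1-p)\,Z^2\big)$ with prevalence
$K$, sample case proportion $p$ and $Z = \varphi(\Phi^{-1}(1-K))$. The
transform is strictly linear in $h^2_o$ (so CI endpoints convert
endpoint-wise) and a prevalence sensitivity sweep at half and double $K$
brackets the estimate. Estimating $h^2_o$ itself requires genotype data
and is out of scope.

# Connectivity mapping

The disease signature is the top decile of genes by $|z|$ of the
gene-level association z-scores (signs retained; ties at the cutoff
broken by gene id). Each profiled condition of each perturbagen is
scored by cosine similarity over the genes shared between signature and
profile; under the reversal sign convention a negative score means the
drug opposes the disease expression shift. Restricting to the shared
gene set (rather than zero-imputing a full universe) is a documented
choice; with the matrix interface the shared set is the intersection of
signature genes and profile rows.

Per perturbagen, the condition with the largest $|{\cos}|$ is kept,
whether positive or negative — an extreme value in either direction is
less likely under chance — with ties resolved toward the negative score,
then by condition id. Drugs are ranked by ascending collapsed score
(rank 1 = strongest reverser, ties share mean ranks) **after** the
collapse, one rank per drug.

The significance threshold comes from permutation: the z-scores are
permuted across **all** scored gene labels (not only signature genes),
the signature is rebuilt, and every drug is re-scored and re-collapsed;
pooling $n_\mathrm{perm}\times N_\mathrm{drugs}$ values gives the null,
and the empirical lower $\alpha$-quantile (inverse ECDF) is the
threshold. Reversers are drugs strictly below it.

Two drug-set enrichment statistics use Monte-Carlo permutation with the
add-one estimator $(c+1)/(n_\mathrm{iter}+1)$ — so a zero count reports
as $< 1/(n_\mathrm{iter}+1)$ rather than 0: the overlap of the
significant set with a reference set against random same-size sets, and
the median rank of a reference set against medians of random same-size
sets.

# Synthetic data: what it emulates, and what it does not

The generator produces the minimal statistical structure each stage
assumes, at the z-score level (no genotypes — every in-scope computation
consumes summary-level data):

* **Summary statistics:** null z-scores with exchangeable correlation
  $r = \sqrt{r^2_\mathrm{block}}$ within contiguous LD blocks (single
  factor construction), planted loci adding the non-centrality to the
  lead and $r$ times it to block partners, positions every 5 kb, and a
  within-block pair LD table. Defaults: 10,000 variants in blocks of 20
  at $r^2 = 0.5$, ten planted loci at non-centrality 8 (power
  $\approx 0.995$ at $5\times10^{-8}$), case/control counts 15,212 and
  29,677 as in the study this pipeline re-implements. Planted blocks are
  spaced at least 700 kb apart so distinct loci's 250 kb windows cannot
  touch, making planted-gene recovery identifiable.
* **Genes and sets:** lognormal sizes (mean 62.2 kb), a target set whose
  sizes are multiplied by the configured factor (default 2.44), a
  criteria table giving each planted gene 3-6 criteria and every other
  gene at most one. Planted genes sit at their locus lead and are capped
  at 200 kb so a long planted gene cannot shadow a neighbouring planted
  locus.
* **Drug profiles:** independent standard-normal profiles; planted
  reversers follow $-s\,\tilde z + \sqrt{1-s^2}\,\varepsilon$ so a
  strength-1 reverser scores exactly $-1$.

Not emulated: realistic human LD maps, allele-frequency spectra, real
gene coordinate distributions, correlated perturbagen conditions.
Passing tests therefore demonstrate the correctness and calibration of
the computations under the stated statistical model, not performance on
real cohort data.

# Numerical and testing choices

* All randomness flows from explicit integer seeds; the generator has no
  implicit randomness, and the pipeline derives per-stage substreams
  from one seed so partial reruns reproduce.
* Tests run at deliberately scaled problem sizes chosen for statistical
  identifiability: 4,000-variant studies across 100 seeds for locus
  recovery and null cleanliness; 500 drugs for reverser recovery; the
  full 24,051-drug scale is exercised for the ranking constants, where
  the gene universe can be small.
* The null-calibration check of the Monte-Carlo set statistics uses a
  Kolmogorov–Smirnov test across 500 replicates. The overlap count is a
  discrete statistic, so its p-value is only approximately uniform; the
  check is run in the near-continuous regime (500-drug sets from 5,000,
  where the maximal point mass of the overlap distribution is below the
  KS critical distance) chosen from that bound, not from test outcomes.
  For small sets the overlap p-value is valid but conservative, and a KS
  test against the uniform would reject on discreteness alone.
* The permutation-null threshold oracle uses the exact null cosine law
  (affine Beta) rather than the normal approximation.

# Known limitations

* The Wallenius recursion is $O(n \min(n, K))$ per table — exact and
  fast for gene-set-sized tables, but not intended for draws in the
  hundreds of thousands.
* The $\chi^2$/LD filter removes the larger-$\chi^2$ member by design;
  if the original analysis removed both members, counts of removed
  variants will differ (the flagged-pair table supports either policy).
* Wallenius p-values for the published 21-gene analyses could not be
  reconciled with any tail convention (see the reproduction note above)
  and are not asserted.
* Conditional association analysis (secondary signals within a locus)
  requires genotypes; the conventional threshold ($2\times10^{-5}$) is
  documented but nothing is computed.
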