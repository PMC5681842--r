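---
title: "Population differentiation of trait-associated effect alleles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population differentiation of trait-associated effect alleles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popdiffr)
```

# The scientific question

GWAS-identified risk alleles for complex traits such as obesity do not have
the same frequency everywhere: drift and selection leave worldwide
populations with markedly different effect-allele frequencies (EAFs), which
may contribute to population disparities in disease prevalence. `popdiffr`
implements a complete analysis of this question for a panel of
trait-associated SNPs genotyped in a worldwide cohort such as the 1000
Genomes Project phase 3 (26 populations in five continental groups — AFR,
AMR, EAS, EUR, SAS — 2504 individuals):

1. per-population **enrichment/depletion tests** of the effect allele
   against the pooled cohort;
2. **signed log10 p-value heatmaps** with centroid hierarchical clustering
   of populations and SNPs;
3. **linkage disequilibrium** (r²) matrices from phased haplotypes, per
   continental group;
4. an unweighted **composite genetic risk score** per individual, with
   population summaries, a prevalence correlation, and SNP-set bias
   diagnostics.

A synthetic-data module generates complete cohorts under a Balding–Nichols
model so that every stage is testable without access to the real genotype
data.

# The enrichment model

For SNP $s$ and population $p$, let $N$ be the number of observed alleles
in the pooled cohort, $K$ of which are effect alleles, and let $n$ be the
alleles observed in population $p$, $k$ of them effect alleles. Treating
the population's alleles as a draw without replacement from the pool, $k$
is hypergeometric, and we compute two exact one-sided tails:

$$p_{\text{enrich}} = P(X \ge k), \qquad p_{\text{deplete}} = P(X \le k).$$

The pooled cohort deliberately *includes* the tested population (no
leave-one-out correction): the tests ask whether a population deviates from
the worldwide average, and this matches how such analyses are usually
reported. Tests run on allele counts (two per individual), implicitly
assuming the two alleles of a genotype are independent draws; no
Hardy–Weinberg adjustment is applied.

With $S$ SNPs and $P$ populations there are $2SP$ one-sided tests; the
family-wise error rate $\alpha$ is controlled by the Bonferroni-style raw
cutoff $\alpha/(2SP)$. For the canonical 225 SNPs × 26 populations at
$\alpha = 0.01$ this is $0.01/11700 = 8.55\times10^{-7}$. A step-down
procedure would be slightly more powerful, but the plain division matches
the analysis this package reproduces.

For display, each cell is collapsed to a single signed value:
$-\log_{10} p_{\text{enrich}} > 0$ when the enrichment tail is smaller,
$\log_{10} p_{\text{deplete}} < 0$ when the depletion tail is smaller, and
0 on a tie. When *neither* test is significant the sign still follows the
smaller tail; this is a documented display choice (the convention is only
defined by significance in the original analyses) that keeps the heatmap
continuous. Extremely small tails can underflow double precision; they are
floored at the smallest positive double so the log display stays finite.

Degenerate inputs: a cell with no observed alleles has undefined frequency
and is reported as `NA`, never 0; monomorphic SNPs keep p-values of 1 on
one side and are retained in the matrix.

# Clustering

Population and SNP profiles of the signed matrix are clustered
agglomeratively with **centroid linkage over the 1 − Pearson-correlation
distance** (range 0 for perfectly correlated profiles to 2 for
anti-correlated ones). Numerical choices:

* The Lance–Williams centroid update is applied directly to the
  correlation-distance values, the convention of classic expression-heatmap
  tools. Centroid linkage can produce *inversions* (non-monotone merge
  heights); they are kept and rendered as-is.
* **Zero-variance profiles** (e.g. an allele fixed in every population)
  have undefined correlation; they are assigned distance 1 to everything,
  with a warning, so fixed SNPs stay in the matrix instead of being
  dropped.
* **Tie-break**: among equidistant pairs, the pair whose smallest original
  leaf indices sort lowest merges first, making the tree deterministic and
  invariant to input order. (`stats::hclust`'s centroid method agrees with
  the in-package agglomerator on tie-free data; the in-package version
  exists to pin down the tie rule.)

# Linkage disequilibrium

With phased haplotypes, for SNPs $i, j$ with haplotype frequency $p_{AB}$
and allele frequencies $p_A, p_B$ over haplotypes non-missing at both SNPs,

$$r^2 = \frac{(p_{AB} - p_A p_B)^2}{p_A(1-p_A)\,p_B(1-p_B)}.$$

The implementation uses the exact integer-count form, so perfect LD gives
exactly 1. A SNP monomorphic in the stratum has undefined LD (`NA`, not 0).
Continental matrices pool the member populations' haplotypes. Because both
the reference data and the simulator are phased, no EM-based haplotype
estimation is needed or provided.

# The composite genetic risk score

For an individual with $X_i \in \{0,1,2\}$ effect-allele copies at SNP $i$,

$$\text{score} = \frac{\sum_{i=1}^{I} X_i}{2I},$$

over the panel of SNPs whose GWAS p-value is strictly below the
genome-wide significance threshold $5\times10^{-8}$ (a p-value exactly at
the threshold is excluded). The score lies in $[0, 1]$: 1 means two risk
alleles at every SNP, 0 means none, and uniformly random copies give an
expected score of 0.5. Alleles are **unweighted**: effect sizes are known
only for a minority of SNPs and were estimated mainly in European cohorts,
so extrapolating them worldwide would be less defensible than equal
weights. The diagnostic `neighbor_effect_correlation()` quantifies the
partial compensation that clustered SNPs provide: SNPs representing a
genomic region with more panel SNPs within 1 Mb (a closed window, counting
the SNP itself) tend to have larger per-allele effects.

Missing genotypes: an individual's denominator counts only their
non-missing SNPs ($2I'$), so missingness does not deflate scores; an
individual missing the whole panel is an error.

**The central oracle** of this module is the identity: on complete data the
population-level mean score equals the population's mean EAF over the
panel — both equal $\sum_i k_i / (2nI)$ summed in different orders.
`verify_mean_identity()` computes both sides independently and the test
suite requires agreement to $10^{-12}$. With missing data the two
denominators decouple and the identity holds only approximately, which the
function flags.

Downstream comparisons: country-level prevalence is regressed on
country-mean scores by OLS, pooling *individuals* (not averaging population
means) when several populations map to one country; a degenerate fit
(constant prevalence) reports $R^2 = 0$ and p = 1. SNP-set bias comparisons
between two populations use Welch's two-sample t-test by default — the
classical pooled-variance "Student" variant is available via
`var_equal = TRUE` — because equal variances between populations is an
unnecessary assumption; on the data sizes involved the two variants differ
negligibly. Random SNP-set augmentations (`augment_snp_set()`) are drawn
without replacement under an explicit seed. Box-plot summaries use
linear-interpolation quantiles and 1.5 × IQR whisker limits.

# The synthetic cohort generator

`sim_config()` defines the study conditions; its defaults emulate the real
design: the 26 populations with their published sample sizes
(`reference_populations()`, total 2504), 225 SNPs of which 155 carry GWAS
p-values below $5\times10^{-8}$ (log-uniform down to $10^{-30}$) and the
rest sit in $(5\times10^{-8}, 9\times10^{-6})$ — the catalog search
window — 32 significant SNPs with per-allele effect sizes drawn uniformly
from 0.05–0.40 kg/m² (the published range for independent BMI SNPs), and
10% of annotation rows reported on the reverse strand to exercise
orientation.

Differentiation follows a **two-level Balding–Nichols model**. Each SNP
draws an ancestral frequency $p \sim U(0.05, 0.95)$; each continental
group draws from $\mathrm{Beta}\!\left(p\frac{1-F_b}{F_b},
(1-p)\frac{1-F_b}{F_b}\right)$, which has mean $p$ and variance
$F_b\,p(1-p)$; each population repeats the draw around its group frequency
with $F_w$. Defaults $F_b = 0.08$, $F_w = 0.02$ reflect the classic
apportionment of human diversity: most allele-frequency differentiation
lies between continental groups. $F = 0$ or 1 degenerates the Beta and is
rejected. Setting `fst_between = NULL` recovers the classical single-level
model used by several calibration tests.

LD is planted by a **first-order copying chain**: within a block a
haplotype copies its previous-SNP allele with the block's copying
probability, else draws fresh from the population frequency. This gives
monotone, tunable r² decay with clean block boundaries (copy probability 1
gives $r^2 = 1$; probability 0 recovers the null $E[r^2] \approx 1/\#$
haplotypes). The default plants one 15-SNP block at ~3 kb spacing on one
chromosome, mimicking an intronic risk-SNP cluster; remaining SNPs are
spread megabases apart across other chromosomes. Note that within a block
the marginal frequency of later SNPs is pulled toward the block's first
SNP; frequency-recovery tests therefore use block-free configurations.

`plant_enrichment()` shifts a chosen population's true frequencies at
chosen SNPs (clipped to $[0.01, 0.99]$), creating known-positive signal:
with a +0.4 shift and $n = 100$ per population the planted SNPs are
detected at the FWER cutoff essentially always. Fixtures are written as
plain-text VCF 4.1 (phased `GT`, forward-strand alleles; the effect allele
alternates deterministically between REF and ALT so the reader's
allele-pair matching is exercised) plus panel and annotation TSVs, and
round-trip bit-exactly through the readers. All outputs are fixed
bit-for-bit by the configuration seed.

## What the simulator does and does not emulate

It emulates: the population/group layout and sample sizes, F\_ST-scale
differentiation at two levels, block LD, the GWAS p-value split, strand
reporting, and missingness. It does **not** emulate: admixed populations
(no PUR-style European admixture, so synthetic population trees are
cleaner than real ones), selection, the real site-frequency spectrum of
risk alleles — ancestral frequencies are uniform, so near-fixation alleles
(a notable feature of the real panel, e.g. alleles fixed in entire
continental groups) are rare. Consequently, on synthetic cohorts a SNP
significant anywhere tends to be significant in *both* directions, and the
enriched-only/depleted-only classes are smaller than in the real data;
passing synthetic tests demonstrates correctness of the machinery, not
distributional realism of every published summary.

# Strand orientation and I/O conventions

Reference panels report alleles on the forward strand while GWAS catalogs
sometimes report the reverse; `orient_effect_allele()` complements
reverse-reported allele pairs (an involution under strand toggling). A/T
and C/G pairs are their own reverse complement, so their strand of report
cannot be verified from alleles alone; they are processed but flagged,
since resolving them requires the primary reports. VCF records are matched
by (chromosome, position) with allele-pair verification rather than by
rsid (rsids drift between builds); a disjoint allele pair is an error
signalling a strand or build mismatch, annotated SNPs absent from the VCF
go on a skip list, and multi-allelic records at annotated sites are
skipped with a warning. Coordinates are 1-based (VCF convention); there is
no liftover support. Missing calls are excluded from both numerator and
denominator of every frequency, so per-stratum denominators are
$2 \times$ (non-missing samples), not $2n$.

# Problem sizes used in the test suite

The suite exercises full-size synthetic cohorts (26 populations × 2504
samples × 225 SNPs) for the end-to-end checks — a single cohort simulates
in well under a second — and smaller 4-population cohorts for unit-level
properties. Distributional checks use $10^5$ Beta draws (variance
calibration), $10^5$ simulated individuals (mean-score expectation), 100
independent SNP pairs (null r²), and dense hypergeometric grids up to
$N = 60$ against a brute-force enumeration oracle at $10^{-12}$.

# Known limitations

* The heatmap sign convention for doubly-non-significant cells and the
  distance-1 rule for zero-variance profiles are documented choices, not
  uniquely determined by the conventions this package follows.
* Centroid-linkage inversions make merge heights non-monotone; cutting the
  tree by height is therefore ill-defined (cutting by group count `k` is
  what `cut_tree()` does).
* Integer count reconstruction from published frequencies
  (`reconstruct_allele_counts()`) inherits the rounding of the published
  table (±0.005 on frequencies).
* The composite score is unweighted by design; it is a frequency summary,
  not a calibrated phenotype predictor.
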