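---
title: "Detecting genomic imprinting from placental trio RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genomic imprinting from placental trio RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintr)
library(dplyr)
```

## The problem

Genomic imprinting silences one parental copy of a gene through epigenetic
marks laid down in the germ line, so the locus is transcribed (almost)
exclusively from the maternal or the paternal allele. The placenta is the
tissue where imprinting is believed to matter most, yet it is absent from the
large expression atlases, and hundreds of genes have been proposed as
placentally imprinted on thin evidence. Given bulk RNA-seq of placental
tissue together with array genotypes of the placenta and its parents, the
question is directly decidable: at a SNP where the placenta is heterozygous
and the parental genotypes pin each allele to one parent, the ref/alt read
tallies become maternal/paternal read counts, and the allelic ratio of a gene
can be tested formally.

`imprintr` implements that analysis as a reusable pipeline: candidate
filtering, trio/duo-based parental-origin assignment, gene-level exact
binomial testing with Bonferroni correction, three-way classification
(imprinted / parentally biased / biallelic), per-clinical-group reporting,
and a synthetic cohort generator that makes every stage testable without
patient data.

## The model

For gene $g$, let $M_g$ and $P_g$ be the maternal and paternal read totals
pooled over all informative (family, SNP) pairs, and
$\hat\theta_g = M_g / (M_g + P_g)$ the maternal read proportion. Under
biallelic expression each read is maternal with probability $\tfrac12$, so
$M_g \sim \mathrm{Binomial}(M_g + P_g, \tfrac12)$ and the exact two-sided
binomial test applies. With $m$ genes tested, $p_{corr} = \min(1, m\,p)$.
Writing $f_g = \max(\hat\theta_g, 1 - \hat\theta_g)$ for the
preferred-allele fraction, the decision rule is:

* **imprinted** — $p_{corr} < \alpha$ and $f_g > 0.90$;
* **biased** — $p_{corr} < \alpha$ and $0.65 \le f_g \le 0.90$;
* **biallelic** — otherwise (no significant deviation, or both parental
  proportions within 35–65%).

The pooled-ratio convention (summing reads over families before testing)
treats reads, not families, as the sampling unit. That gives enormous power
at high depth and is the convention this pipeline follows; the bootstrap
confidence interval (below) is the place where family-level sampling
variability can be acknowledged instead.

### Assumptions

* Marker SNPs are biallelic, exonic for exactly one gene, and genotyped (not
  imputed) in placenta and parents.
* Reads at a SNP are conditionally independent Bernoulli draws given the
  gene's true maternal share; the binomial model conditions on total depth,
  so the read-depth law itself does not enter the test.
* Reads are summed across a gene's SNPs within a sample, so a fragment
  overlapping two SNPs counts twice. This matches the per-SNP pileup
  convention upstream; it slightly understates the variance of
  $\hat\theta_g$ for genes with closely spaced SNPs.
* Maternal-cell contamination and sequencing error are small perturbations;
  they bias $\hat\theta$ toward the mother's allele mix and toward 0.5
  respectively, which is why a monoallelic gene shows $f \approx 0.97$–0.99
  rather than 1.0.

## Parental-origin assignment

A family is *informative* at a SNP iff the placenta is heterozygous and at
least one parent is homozygous. The decision table in
`classify_family_snp()` realizes this:

* mother homozygous for allele $X$: maternal $= X$, paternal $=$ the other
  allele — provided the father (if genotyped) carries that allele, else the
  call is a `mendelian_error`;
* mother heterozygous (or ungenotyped) and father homozygous for $Y$:
  paternal $= Y$;
* both parents heterozygous, a duo with heterozygous mother, or a
  non-heterozygous placenta: `uninformative`;
* a genotype that the decision actually needs but that is missing:
  `missing_data`.

The second rule — a homozygous *father* rescuing a heterozygous mother — is
the "at least one homozygous parent" reading. It is the one genuinely open
design point in the informativeness logic (a mother-only reading is also
defensible when maternal contamination is a worry, since mother-homozygous
families let contamination be modelled exactly), so it is exposed as
`poe_config(trio_het_mother_informative = FALSE)`. The default keeps the
permissive reading, which maximizes informative families. The whole table is
verified in the test suite against a brute-force oracle that enumerates all
Mendelian-consistent transmissions for each of the 36 genotype combinations.

Mendelian inconsistencies are never silently dropped: they get their own
status, count as non-informative downstream, and are reported, since they
are the natural readout for genotyping errors.

## The filtering cascade

Candidate genes pass through ordered stages, each recorded in a trace whose
gene sets are strictly nested and whose dropouts plus survivors always sum
to the candidate count:

1. **annotation** — the gene must have exon records;
2. **expression** — median normalized count across samples $\ge$ 50 reads.
   Normalization is median-of-ratios (each sample's factor is the median
   ratio of its counts to the per-gene geometric means), the standard
   meaning of "normalized counts" for RNA-seq count matrices; the test
   suite cross-checks the implementation against DESeq2's;
3. **common exonic SNP** — at least one SNP inside the gene's exons (BED
   half-open convention: a 1-based position $p$ is inside $[start, end)$
   iff $start < p \le end$), not on the manual exclusion list, with cohort
   minor allele frequency strictly $> 10\%$ and Hardy-Weinberg chi-square
   $p$ strictly $> 0.05$. The chi-square test (1 df, sample allele
   frequency) is used rather than the exact test: transparent, adequate at
   cohort scale, and monomorphic SNPs return $p = 1$ by convention since no
   departure is testable;
4. **informative families** — the SNP must be informative for $\ge 3$
   trios/duos (boundary inclusive);
5. **read coverage** — median total reads at the SNP across informative
   placentas $\ge 3$ (only medians strictly below drop the SNP).

The MAF and HWE comparisons are strict inequalities, and both decisions are
invariant to swapping the ref/alt labels. Cohort MAF is used by default; an
external population frequency table can stand in by pre-filtering the site
list. The exclusion list replaces a manual inspect-in-IGV curation step for
SNPs in alternative exons overlapping introns of the main transcript — a
curation act, not an algorithm, so a config list is the honest equivalent.

## Numerical choices

* **Binomial p-value.** `binom_test_two_sided()` sums every point
  probability not exceeding the observed one, with relative tolerance
  $10^{-7}$ — the convention of `binom.test()` in R, against which it is
  cross-checked in the tests (together with a brute-force enumeration
  oracle at all $n \le 200$). For $p_0 = 0.5$ this equals
  $\min(1, 2 \times \text{smaller tail})$.
* **Boundary conventions.** "Imprinted" requires $f$ strictly above 0.90;
  $f = 0.90$ falls in the biased band, whose upper bound is therefore
  closed, keeping the three classes a partition. Significance is strict
  ($p_{corr} < 0.05$).
* **Bonferroni divisor.** $m$ defaults to the number of genes that actually
  reach the testing stage in the current run; genes excluded earlier (too
  few informative families, zero reads) do not inflate $m$. A fixed divisor
  can be set via `poe_config(n_tests_bonferroni =)`, e.g. 91 when
  re-analysing the published panel below.
* **Confidence intervals.** Clopper-Pearson (exact beta quantiles) is the
  default; Wilson is available; and a percentile bootstrap that resamples
  whole *families* is provided because the family, not the read, is the
  natural resampling unit when families differ in depth. Intervals are
  reporting-only — classification never uses them.
* **Heatmap transform.** Expression heatmaps use
  $\log_2(\text{normalized count} + 1)$ before per-gene z-scoring
  (population SD, rows exactly mean 0 / SD 1; zero-variance rows become
  zeros with a warning). The log transform is a deliberate, simple variance
  stabilizer; since the z-score dominates the visual, the choice of
  stabilizer matters little. Row/column ordering is average-linkage
  clustering on Minkowski distance (power 2 by default); linkage and power
  are config knobs because only the distance, not the linkage, is dictated
  by convention.

## The synthetic cohort generator

`sim_cohort()` emulates the study design the pipeline targets, and its
defaults *are* those conditions:

* **cohort structure** (`cohort_layout("table1")`): 54 pregnancies — 8
  first-trimester and 6 second-trimester mother–placenta duos, and five
  term groups (uncomplicated, PE, GD, SGA, LGA) of 8 families each, with
  38 trios and 16 duos overall; gestational ages spread evenly over each
  group's observed range.
* **genotypes**: Hardy-Weinberg draws at each SNP's MAF (default 0.30, a
  typical "common SNP" frequency comfortably above the 10% filter);
  Mendelian transmission to the placenta; duos are simulated by drawing a
  father and hiding him, so duo informativeness rules can be scored against
  truth.
* **reads**: total depth is Poisson around `mean_depth` (default 50; the
  depth law only affects power, not correctness, because the test
  conditions on totals). Each read is maternal with probability
  $(1-\rho)\theta$, paternal with $(1-\rho)(1-\theta)$, contaminant with
  $\rho$; contaminant reads carry one of the *mother's own* alleles —
  which is exactly what maternal-cell contamination does to an
  allele-specific signal — and every read flips allele with probability
  $\varepsilon$. Defaults $\rho = 0.0093$ (the median maternal-cell RNA
  fraction estimated for this kind of placental material) and
  $\varepsilon = 0.001$.
* **true maternal shares** $\theta$ per class: 0.98 / 0.02 for imprinted
  maternal/paternal genes, 0.75 / 0.17 for biased, 0.5 for biallelic —
  values bracketing the ranges observed for each class in placental data.
* a **truth ledger** records $\theta$, the implied true class (the decision
  thresholds applied to $\theta$ itself), and every transmitted allele, so
  phase recovery and class recovery are exactly scorable.

Per-SNP depth has no published distribution to copy (only the existence of
a low-coverage filter implies shallow SNPs exist), so `mean_depth` is
documented as a free parameter. What the generator does *not* emulate:
linkage between SNPs beyond the shared gene $\theta$, overdispersed depth
(a knob worth adding if negative-binomial depth is wanted), isoform-specific
imprinting, random monoallelic expression, and somatic aberrations. Passing
recovery tests on this generator therefore demonstrates the pipeline's
correctness under its own model — informativeness logic, counting,
testing, classification — not robustness to every artefact of real tissue.

## What the tests establish

The suite runs at deliberately desk-scale problem sizes: recovery uses 600
simulated genes (200 per class at $\theta = 0.98/0.83/0.5$) across the
54-family layout at depth 30 with contamination 0.0093, requiring $\ge 95\%$
correct class recovery among genes with at least 10 informative families and
a non-biallelic call rate $\le 5\%$ for true-biallelic genes under
Bonferroni correction. The filter-bookkeeping fixture is fully
deterministic — 50 genes with genotype patterns constructed in *exact*
Hardy-Weinberg proportions, so the only HWE violations, low-MAF SNPs,
low-expression genes, under-informative SNPs and low-coverage SNPs present
are the planted ones, and the trace must drop exactly those.

## Worked example: the published 25-gene panel

The package ships the maternal/paternal read totals of the 25 loci reported
with parent-of-origin-driven allelic expression in a published 91-gene
placental screen. Re-analysing them with the screen's Bonferroni divisor:

```{r reference}
summary <- analyze_gene_totals(
  poe_reference_counts(),
  poe_config(n_tests_bonferroni = 91)
)
glance(summary)
class_medians(summary)
```

Eleven genes classify imprinted and fourteen biased, and the class-level
medians of the preferred-allele fraction (97.6% imprinted; 69.3% maternally
vs 83.0% paternally biased) match the published values. One printed-value
caveat: the published 95% CIs for a few loci match no closed-form
proportion interval (consistent with a resampling interval), so printed CI
bounds are not treated as reference values anywhere in this package.

## Limitations

* Pooling reads across families makes the test sensitive to a single
  deep-coverage family; the bootstrap CI surfaces this but the p-value does
  not.
* Genes encoding both imprinted and non-imprinted isoforms can land in the
  biased class when reads from several transcripts are pooled;
  isoform-level analysis is out of scope.
* The heterozygous-mother/homozygous-father rule imports no contamination
  correction; at contamination levels far above ~1% the maternal proportion
  of paternally expressed genes inflates noticeably.
* No formal cross-group heterogeneity test is provided — the per-group
  catalog is descriptive, matching the descriptive treatment such stability
  claims receive in practice.
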