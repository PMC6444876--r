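---
title: "Conditional QTL detection and candidate-gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional QTL detection and candidate-gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlgene)
```

## The problem

Complex traits such as female fertility in dairy cattle are governed by
many variants of small effect. A genome-wide association scan on dense
imputed sequence genotypes finds regions of significance, but turning a
significant region into a short, biologically defensible list of
candidate genes needs several additional steps: separating overlapping
signals, bounding each locus, deciding which genes the signal plausibly
acts through, and checking each gene against independent biology. This
package implements that post-GWAS chain as composable, tested functions,
together with a simulator that makes every stage verifiable without
access to animal data.

## The association model

For a continuous phenotype $y$ (here emulating de-regressed breeding
values, treated as an unweighted trait — reliability weights are not
modeled) and dosage $g_j \in [0,2]$ of variant $j$:

$$y = \mu + \sum_{c \in C} g_c \gamma_c + g_j \beta_j + u + \varepsilon,$$

where $C$ is the set of conditioned lead SNPs, and $u$ is either absent
(OLS mode, the default) or a polygenic effect with
$u \sim N(0, \sigma_g^2 K)$ for a VanRaden genomic relationship matrix
$K$ built from all QC-passing variants. In mixed mode the GRM is
eigendecomposed once, the variance ratio is estimated by profile REML
(one-dimensional optimization on the log scale), and each variant is
tested by GLS in the rotated coordinates; with $K = I$ this reduces
exactly to OLS, which the tests assert at $10^{-8}$. Two-sided P-values
come from the $t$ distribution with the residual degrees of freedom, and
$-\log_{10} P$ is computed on the log scale so it remains usable when $P$
underflows. Conditioned SNPs are excluded from testing (reported with
$P = 1$ and a `covariate` flag): their signal is absorbed by
construction, and testing them would be perfectly collinear.

QC precedes the scan: variants with minor allele frequency below 0.5% or
a 1-df Hardy–Weinberg $\chi^2$ goodness-of-fit P below $10^{-6}$
(dosages rounded to hard genotypes for counting) are excluded with
per-variant reasons. A monomorphic site fits its expected proportions
exactly and receives $P = 1$ from the HWE test; the frequency filter is
what removes it.

## Lead SNPs, solo SNPs, and QTL intervals

Detection is iterative and per chromosome. Round 1 is the unconditional
scan. In each round, a variant qualifies as lead if it (a) exceeds the
genome-wide Bonferroni threshold in the current round, (b) exceeded it in
round 1, and (c) is not a *solo SNP* — a significant SNP with no other
significant SNP within ±1 Mb, treated as a likely imputation artifact.
The qualifying variant with the largest $-\log_{10} P$ is accepted (ties
broken by smaller position, for determinism), its dosage joins the
covariate set, and the chromosome is re-scanned. Conditioned leads are
untestable, so the loop must terminate within as many rounds as there are
round-1 significant SNPs.

The interval around a lead is delineated side by side on the lead's
discovery-round results: scanning outward up to 1 Mb, the boundary is the
first SNP farther than 0.25 Mb from the lead whose $-\log_{10} P$ lies
more than 3 units below the lead's; if none qualifies, that side falls
back to ±0.25 Mb. The rule's text leaves the scan direction and the
fallback open; we scan outward and take the first qualifying SNP, which
is the only reading consistent with intervals whose two flanks can be
asymmetric, and we keep the stated ±0.25 Mb fallback (both the flank cap
and the minimum half-width are `thresholds()` fields, so the wider
reading is a configuration away). Flagged (conditioned/collinear)
variants carry no measured signal in the round and are not boundary
candidates.

## From QTL to genes

Two routes generate *potential* candidates:

- **Nearest gene**: the gene(s) at minimal distance from the lead, with
  bedtools-`closest` distance semantics — 0 inside the gene span,
  otherwise the bp gap to the nearer boundary; ties return all tied
  genes. (The test suite checks feature selection against a
  GenomicRanges nearest-neighbor oracle; note GenomicRanges' `distance()`
  itself counts strictly-between bases and is one smaller than the gap
  convention used here.)
- **Gene-based + LD**: all round-1 significant SNPs with dosage
  $r^2 > 0.2$ with the lead are extracted (genotype-dosage correlation
  squared — the standard surrogate for unphased imputed data, invariant
  to allele recoding), and for each such SNP the closest gene among the
  genome-wide significant gene-based results is taken.

The gene-based test regresses the phenotype on the leading principal
components of the gene's centred dosage matrix — the smallest set
explaining ≥ 99.9% of genotypic variance, always at least one — and
reports the overall F test. With one SNP this is exactly the
single-marker OLS test; duplicating a column changes nothing because the
span is unchanged. Gene-wise significance is Bonferroni over the genes
actually tested (`thr$n_tests_gene` overrides the count, e.g. 20,356 for
a full annotation, giving $2.46\times10^{-6}$).

Potential candidates become *final* candidates when they carry at least
one record in the evidence catalog (sources: GO terms, KEGG pathways,
mouse-phenotype annotations, differential-expression results); genes
without support are reported separately rather than dropped. For DEG
evidence the package flags whether all records for a gene agree in
direction across studies and tissues — concordant cross-study
differential expression is the strongest of these supports. Which
GO/KEGG/phenotype terms count as trait-relevant is deliberately left to
the catalog the user supplies: term curation is a judgment call, and
hard-coding a list would freeze it.

## The simulator and what it does (not) show

`simulate_genotypes()` draws, per haplotype, a latent standard Gaussian
first-order autoregressive process whose correlation between adjacent
sites is $\exp(-d/\texttt{ld\_decay\_bp})$, and emits the allele
indicator of the latent value falling below the site's allele-frequency
quantile. Consequences: marginal allele frequencies hit their targets
exactly in expectation (realized frequencies are binomial over $2n$
haplotypes, so tight at $n = 2000$), dosages are hard 0/1/2, and dosage
correlation decays monotonically with distance at the configured scale.
An earlier founder-copying variant was rejected because an unstructured
founder pool yields no inter-site LD at all; the thresholded AR(1)
process gives the same tunable decay with exact frequency control.

`simulate_phenotype()` builds
$y = \sum_k \text{effect}_k z_k + g + e$ with $z_k$ the standardized
causal dosages, $g$ a polygenic term over all non-causal polymorphic
variants rescaled to variance `h2_polygenic`, and Gaussian noise filling
the variance to 1. Effects are therefore in phenotypic-SD units and
`sum(effect^2)` is the variance fraction explained by the planted QTL.
Defaults (one 0.5-SD QTL, `h2_polygenic = 0.3`) describe a strong,
mappable locus on a polygenic background. Gene models tile the
chromosomes with gamma-distributed lengths, optionally covering each
planted QTL; evidence catalogs plant GO + concordant two-study DEG
records (plus KEGG/MPD each with probability 1/2) on chosen genes and
sprinkle false-positive records on the rest at a configured rate.

What the simulator does **not** emulate: imputation error and dosage
uncertainty, allele-frequency–dependent effect sizes, population and
family structure (no inflation for OLS to fight beyond the planted
polygenes), selection, multi-allelic sites, and realistic gene-density
patterns. Passing recovery tests therefore demonstrates the *logic* of
the chain — thresholding, conditioning, interval and LD rules, gene
mapping, evidence integration — not its behaviour under confounding;
the MLM mode exists precisely for structured data, and is validated here
by its OLS-reduction property and calibration rather than by a
structured-population simulation.

## Numerical and design choices

- Significance comparisons happen on the $-\log_{10} P$ scale; thresholds
  are `-log10(alpha/n_tests)`. In simulations the package uses the
  genome-wide threshold of the full-scale setting it emulates
  (`n_tests_snp = 15551021`, ≈ 8.5): the single simulated chromosome
  stands in for a genome-wide scan, and a desk-scale Bonferroni cutoff
  (≈ 4.3 for 1500 markers) would declare the polygenic background
  "QTL", which it is not meant to be.
- Simulated marker density is kept high relative to the LD decay scale
  (10 kb spacing vs 50 kb decay in the standard recovery scenario, 1500
  markers on 15 Mb, $n = 2000$): with sparse markers a causal lead can
  lack significant LD companions and be discarded by the solo-SNP rule —
  an artifact of sparseness the dense imputed data this emulates does
  not have.
- Test problem sizes: type-I calibration pools 20 null scans of 1000
  variants × 200 individuals (empirical rates checked at α = 0.05 and
  0.01); gene-based null uniformity uses hundreds of genes of 1–50 SNPs
  (Kolmogorov–Smirnov at 0.01); pipeline recovery uses 50 seeds of the
  standard scenario with a ≥ 90% success bar for both interval coverage
  of the causal position and recovery of the evidence-supported causal
  gene.
- Collinearity: a variant whose residual variance after projecting out
  the covariates is below $10^{-10}$ of its raw sum of squares is flagged
  rather than tested. Eigenvalues of the GRM are floored at 0.
- Ties: equal $-\log_{10} P$ leads resolve to the smaller position; tied
  nearest genes are all returned.
- Coordinates are 1-based inclusive throughout; BED input is converted
  on read; VCF output carries `DS` at four decimals (round-trip tested at
  that precision).

## Limitations

Binary traits, X-dosage compensation, multi-allelic sites, REML variance
components beyond the single ratio the GLS needs, summary-statistic
gene-based testing with an external LD reference, per-QTL variance
explained, and consequence *prediction* are out of scope (consequence
annotations are consumed from external VEP-style tables and summarized by
most-severe term). Evidence quality is taken at face value: the package
integrates catalogs, it does not curate them.
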