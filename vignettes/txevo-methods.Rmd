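---
title: "Models and methods in txevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in txevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txevo)
```

`txevo` analyses multiregion tumour transcriptomes against their matched
DNA: allele-specific expression (ASE) under allele-specific copy number,
intratumour expression distance (I-TED), tumour transcript fraction, and
RNA single-base-substitution signatures. This vignette documents the
models, their assumptions, the tunable parameters, the synthetic world
used for validation, and the numerical and design choices a maintainer
should know about.

## The allele-count model

RNA reads at a heterozygous SNP are modelled beta-binomially with mean
`p` and overdispersion `rho`, mapped to shape parameters
`alpha = p(1-rho)/rho`, `beta = (1-p)(1-rho)/rho`. Under this
parameterization `rho` is the intra-class correlation of reads, the
variance is `t·p·(1-p)·(1 + (t-1)·rho)`, and `rho = 0` degenerates
continuously to the binomial — so the overdispersion value 0.05 used
throughout maps directly onto the model's `rho`. The upper tail is
computed from the full log-pmf via the forward ratio recurrence; the
pmf-at-zero term uses the product identity
`B(a, t+b)/B(a, b) = prod_{i<t} (b+i)/(a+b+i)` because the naive
difference of `lbeta` values cancels catastrophically for small `rho`
(the shapes grow like `1/rho`). Tests cross-check the tail against
independent brute-force summation to 1e-10 up to `t = 500`.

A note on limits: the distributional gap between `Betabin(rho)` and the
binomial is itself of order `rho·t^2` in the tail sup-norm, so
"binomial-limit" checks are meaningful only at `rho` small enough for
that true gap to vanish; the test suite uses `rho = 1e-10`.

## ASE testing and classification

Per SNP with `m` major-allele RNA reads of `t` total and copy-number
ratio `CPNratio = major_cn/(major_cn + minor_cn)`:

* test (1): `P(X >= m | t, 0.5)` — any allelic imbalance;
* test (3): `P(X <  m | t, 0.5)` — imbalance favouring the DNA-minor
  allele;
* test (4): `P(X >= m | t, CPNratio)` — imbalance beyond copy number.

The admixture argument: with tumour fraction `f` and allele-specific
copy numbers, the expected RNA allelic ratio lies between 0.5 (pure
normal) and `CPNratio` (pure tumour). Tests (3) and (4) are one-tailed
*against the two ends of that interval*, so a gene must exceed anything
explainable by copy number plus admixture before it can be called
copy-number-independent. This is deliberately stringent; in the
synthetic null world the fraction of genes mislabelled CN-independent
measures ~0.1–0.5%, far below the 5% FDR ceiling, at the cost of
sensitivity for weak allelic shifts.

Operational rules, each with its default and rationale:

* **Coverage**: SNPs require strictly more than 8 RNA reads
  (`min_coverage = 8`); below that no test can reach significance.
* **Independent filter**: keep a SNP iff `CPNratio^t < 0.001`. This is
  `P(X >= t | t, CPNratio)` — the most extreme observation possible —
  so it removes sites that could never be significant, reducing the
  multiple-testing burden without using the observed allele split.
  `CPNratio = 1` (LOH) gives p = 1 and is removed; `CPNratio = 0` is
  removed as incompatible with an expressed heterozygous site. Test (4)
  is undefined at these endpoints (`NA`), which is safe because the
  filter removes them first.
* **Combination**: Fisher's method (`-2·sum(log p)` on `chi^2_{2k}`),
  with p clipped at 1e-300 before the log — a numerical floor that
  cannot change ranking. Combination A uses test (1) per SNP;
  combination B uses `min(p3, p4)` per SNP, uncorrected for the
  implicit two-test selection, as the framework defines it; the
  stringency of requiring both bounds to be exceeded compensates in
  practice (see the null calibration above).
* **FDR**: Benjamini–Hochberg within each sample (tumour region) across
  genes, separately for A and B. Per-sample stratification (rather than
  cohort-wide pooling) keeps samples with few evaluable genes from
  being dominated by deeply covered samples.
* **Labels**: `cn_independent_ase` iff `fdr_B < 0.05`;
  `cn_dependent_ase` iff `fdr_A < 0.05` and not B; else `biallelic`;
  `not_evaluable` exactly when no usable SNP remains. The labels
  partition the evaluable genes.

Downstream summaries: annotation enrichment as a 2x2 Fisher exact test
with sample odds ratios (Haldane 0.5 on zero cells); ITH of
CN-independent ASE as one minus the fraction of recurrently called
genes (called in at least two regions) that are called in *every*
region where testable — genes testable in fewer than two regions cannot
count as homogeneous; per-sample reference bias as the ratio of
reference-overexpressed to alternative-overexpressed CN-independent
events, flagged when the denominator is zero.

**Promoter ASM**: a CpG is an allele-specific-methylation locus when its
99% highest-density interval of the tumour methylation rate lies within
[0.15, 0.75] and the point estimate within [0.2, 0.7] — intermediate
methylation consistent with one methylated allele; a promoter is ASM at
three or more consecutive such loci.

**MSAI**: with phased SNPs, *genomic* mirrored subclonal allelic
imbalance is called when two regions show significant DNA imbalance
(binomial test on phased DNA counts, p < 0.05) favouring opposite
haplotypes; *genomic–transcriptomic* MSAI when a DNA-balanced region
shows CN-independent ASE whose overexpressed haplotype is DNA-minor in
another, imbalanced region. Unphased genes are skipped with a notice.
When DNA counts tie, the reference allele is designated major — a
deterministic, auditable convention.

## Expression diversity

Counts are normalized by median of ratios (size factor per region =
median over all-nonzero genes of count/geometric mean; cross-checked
against the standard RNA-seq implementation in the test suite), genes
kept when above 5 reads in at least 20% of regions (strict inequality),
transformed by `log2(x + 1)` — a pluggable stand-in for a full
variance-stabilizing transformation, which is a library-specific
procedure this package deliberately does not pin down — and ranked by
variance of the transformed values with ties broken by gene identifier.

I-TED uses the biased V-statistic distance correlation from
double-centred distance matrices (validated against an explicit-loop
oracle at 1e-12). Distance correlation, unlike Pearson, is sensitive to
non-linear dependence and is 1 under exact linear maps. Each region's
I-TED is the mean of `1 - dcor` against the other regions of its
tumour; the tumour value is the median over regions, which makes the
statistic insensitive to the number of regions sampled. Single-region
tumours are flagged rather than computed. One caveat is recorded in the
tests: scaling one region's counts is absorbed by the size factors only
up to a cohort-wide constant that interacts with the `+1` pseudo-count,
so scale invariance holds to ~1e-2, not machine precision.

## Tumour transcript fraction

The model fixes non-tumour cells as diploid heterozygous and assumes
equal expression per chromosome copy within the tumour; the full
segmentation/ploidy search of ASCAT-style callers is out of scope. The
folded expected BAF in a segment `(nA, nB)` at transcript fraction
`rho` is `(rho·nA + (1-rho)) / (rho·(nA+nB) + 2(1-rho))`; `rho` is fit
by grid search on [0, 1] at step 0.001.

Two numerical points matter. First, SNP-level BAFs are averaged within
a segment *before* folding: folding individual noisy BAFs biases
near-balanced segments upward (the folded mean exceeds the true mean by
roughly `sd·sqrt(2/pi)` at balance), which propagates into `rho` with a
large lever arm; segment means are nearly noise-free, so folding them
is harmless. Second, balanced segments contribute a `rho`-independent
constant to the loss and cannot bias the argmin; the fit is flagged
unidentifiable only when *no* imbalanced segment exists.

Accuracy is information-limited: the beta-binomial BAF variance has a
depth-independent floor of `p(1-p)·sigma`, and the BAF-to-`rho`
derivative ranges from 1/2 in LOH segments down to ~0.2 for single-copy
gains. Recovery is therefore validated on LOH segments — the canonical
purity-informative configuration — where |error| < 0.05 holds in ≥95%
of runs at `sigma = 0.05` with 100 SNPs; on gain-only landscapes the
same bound holds only ~60–90% of the time even at lower noise, an
identifiability property of the model rather than of the
implementation.

## RNA substitutions

**Filters** (fixed thresholds of the framework): at least 30 germline
DNA reads; at least 30 tumour DNA reads in total; at least 10 RNA
reads; at least 3 alternative reads; VAF of at least 1% (exactly 1%
passes); outside the blacklist; DNA support indistinguishable from
sequencing noise (one-tailed Fisher on
`[[alt, depth-alt], [other_err, depth-other_err]]`, excluded when
p < 0.1 — one concrete reading of comparing variant-supporting DNA
reads with other-variant reads against total coverage, isolated behind
a single function); and 4-nt flanks that are not homopolymers of the
reference or alternative base. Every rule is independent of the others,
so the flag set cannot depend on evaluation order.

**Spectra**: 12 substitution classes x 16 trinucleotide contexts = 192
strand-aware channels, ordered lexicographically (reference,
alternative, 5' base, 3' base) and emitted in every output header —
there is no community standard for RNA spectra, so the order is pinned
explicitly. Variants on `-`-strand transcripts are reverse-complemented
(base and context) so channels always represent the mRNA-sense
substitution; the reverse-complement channel map is an involution,
which the tests verify over all 192 channels. Where annotation provides
overlapping antisense transcripts, the caller is expected to pick the
dominant transcript; ties default to `+`.

**Exposures**: spectra with more than 20 variants (strict) are
normalized and decomposed by non-negative least squares
(Lawson–Hanson active set, deterministic) onto column-stochastic
signature matrices; weights are renormalized only if they sum above 1,
and the residual cosine between spectrum and reconstruction is
reported. Plain NNLS, without iterative signature dropping, keeps the
operation oracle-checkable. De novo extraction is a multiplicative
Frobenius NMF with seeded multi-restarts (lowest loss kept) — a
deterministic stand-in for Bayesian nonparametric tools, with `k`
chosen by the user. Signature ITH is `sd(exposure across a tumour's
regions) / mean(exposure across the cohort)`, flagged when the cohort
mean is zero.

**Hairpins and motifs**: a hairpin is called when some 3–5 nt loop
containing the variant has 3 immediately flanking bases 5' equal to the
reverse complement of the 3 bases 3' (checked against an exhaustive
pairing oracle on random 11-mers). APOBEC motif enrichment tests, per
C>T site (read on either strand), whether the other C>T variants within
±20 nt fall on CAT[C>T] motifs more often than the windows' motif-C
content predicts, via one-tailed Fisher tests with all window C (or
reverse-complement G) positions as the opportunity denominator — the
cited local-enrichment approach does not restate its exact
denominators, so this one is fixed and documented. The reported odds
ratio is the raw cross-product (zero motif variants give 0). A known
calibration limitation: at realistic motif densities the per-site
window tables are so small that the exact test's attainable p-values
rarely reach 0.05 at all; the per-site test is therefore conservative
(its null rejection rate is near zero, not near nominal), and the
pooled cross-site summary double-counts variants in overlapping windows
and is reported descriptively, not as a calibrated test.

## The synthetic world

The generator draws, under one master seed (fully deterministic, with
each stage's stream derived from it):

* tumours with 3 regions each (configurable count or range) and
  purities uniform on [0.3, 0.8];
* integer allele-specific copy-number states per gene from a mostly
  diploid landscape — (1,1) 60%, (2,1) 16%, (2,0) 8%, (3,1) 7%,
  (2,2) 5%, (3,2) 4% — clonal per tumour with 10% of genes re-drawn per
  region (subclonal SCNAs);
* heterozygous SNPs (2 per gene by default) with negative-binomial
  depths (RNA mean 30, DNA mean 50, truncated at 1; the source
  framework is silent on depth distributions, so these are configurable
  conventions, not calibrated values) and RNA major-allele counts
  beta-binomial at `sigma = 0.05` around the admixture-weighted
  expected ratio — 0.5 for balanced non-ASE genes, the purity-weighted
  copy-number ratio for imbalanced ones, and at least the configured
  `ase_allelic_ratio` (default 0.9; imprinted genes 0.95) for true
  CN-independent genes. Every gene x tumour carries exactly one truth
  label in `{none, cn_dep, cn_indep}` with its mechanism;
* expression counts, negative binomial around gene baseline x per-gene
  log-normal tumour effect x per-region perturbation of a random 10%
  gene subset — making within-tumour regions more correlated than
  between-tumour ones, which is the structure I-TED measures;
* a random uniform-composition transcriptome (30 x 1500 nt) with
  per-transcript strand, injected 9-base homopolymer cassettes for
  flank-filter decoys, and a check that all 64 trinucleotide contexts
  exist; RNA variants placed at positions whose mRNA-sense context
  matches the channel drawn from each region's signature mixture, plus
  decoys each violating exactly one filter rule (labelled with that
  rule, so filter tests are one-to-one).

What a green test does *not* establish: the generator draws uniform
base composition (no isoform structure, no expression-weighted variant
placement), simulates counts rather than reads (no alignment artefacts
beyond the modelled decoys), and takes phasing and copy number as
known. Conclusions about caller performance on real data therefore do
not follow; conclusions about the statistical machinery do.

## Known limitations

* Combination B's `min(p3, p4)` is anti-conservative per SNP under a
  balanced null (minimum of two complementary tails); the per-sample
  BH step and the stringency of the two-bound construction keep the
  realized null label rate well under the FDR target, but the per-SNP
  p-values should not be interpreted marginally.
* The transcript-fraction estimate assumes equal per-copy expression;
  genes with strong allele-specific expression in imbalanced segments
  violate this locally.
* NMF extraction requires the user to choose `k` and, like all NMF,
  identifies signatures only up to permutation.
* The motif-enrichment per-site test is exact and conservative; it has
  power only in windows dense in C>T variants.
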