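---
title: "Detecting balancing selection on seep-responsive genes: models and methods"
author: "seepselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting balancing selection on seep-responsive genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seepselect)
```

## The scientific question

Fish populations living at volcanic CO2 seeps experience chronically reduced
seawater pH. If some of them thrive there, the genes they up-regulate in that
environment are candidate targets of natural selection. Because larvae
disperse freely between seep and ambient sites, an allele that is
advantageous only at seeps cannot fix: spatially heterogeneous selection
instead maintains it at intermediate frequency — a form of balancing
selection. Its population-genetic footprint is an excess of
intermediate-frequency variants in and around the selected loci, visible in
the folded site-frequency spectrum (fSFS) of SNPs inside those genes when
compared against genes with no evidence of involvement.

`seepselect` implements that inference chain for RNA-seq-only data sets: no
genome, no DNA resequencing. Every input is derivable from expression data —
a count matrix, per-gene reference coding sequences, per-individual pileups
of reads mapped to those sequences, and per-individual assembled transcripts.

## Pipeline overview

1. **Homology merging.** Assembled transcripts are deduplicated by their
   protein-homology hits: hits with e-value below 1e-6 and identity above
   70% are kept (both strict), the transcript covering the greatest length
   of each reference protein is retained per (species, protein), and hits
   are merged across reference species onto a single anchor-species ortholog
   id. The tie chain beyond aligned length (identity, then e-value, then
   transcript id) makes the merge order-independent.
2. **Sexing.** Zona-pellucida (egg envelope) genes are expressed orders of
   magnitude higher in female than male gonads. Summed normalised marker
   expression is split at the largest gap on the log10 scale; the high group
   is female. The call is refused (all labels `unknown`) when the ratio of
   group geometric means falls below 10 — a guard against degenerate input,
   since real marker separation is far larger.
3. **Differential expression.** Per-gene negative-binomial GLMs with log
   size-factor offsets; the pH effect is tested by a likelihood-ratio test
   of `~ pH + sex + length + pH:sex + pH:length` against `~ sex + length`
   (3 df). Single-factor Wald contrasts (sex only, pH only) feed the
   neutral-set construction; cohort-level ANCOVA and two-way ANOVA test the
   overall expression shift.
4. **Neutral reference set.** Genes with both Wald p-values above 0.05 and
   no functional keyword in common with the up-regulated set.
5. **SNP calling, twice.** A pileup-threshold caller (minimum depth 10, 3
   alternative reads, mean quality 15, variant frequency 0.05, homozygous
   at 0.75) genotypes every individual at every candidate site; an
   independent alignment route projects each individual's assembled
   transcript onto the reference CDS and counts nucleotide columns. Only
   biallelic sites genotyped in all individuals survive; intermediate-
   frequency SNPs must be confirmed by both routes.
6. **Selection tests.** Folded spectra of candidate versus neutral SNP sets
   are compared with a one-sided two-sample Kolmogorov-Smirnov test on the
   raw minor-allele frequencies; heterozygosity summaries and per-SNP
   seep-versus-control Fisher tests (q-value corrected) complete the
   picture.

## The count model

Counts follow a negative-binomial law with mean
$\mu_{gj} = s_j \exp(x_j^\top \beta_g)$ and variance
$\mu + \alpha_g \mu^2$, where $s_j$ is the individual's size factor
(median-of-ratios over genes with no zero count) and $\alpha_g$ the gene's
dispersion. Coefficients at fixed dispersion are fitted by iteratively
reweighted least squares with step halving, to a score norm below 1e-8.

**Dispersion.** Each gene's dispersion is the maximiser of the Cox-Reid
adjusted profile likelihood over $\log\alpha \in [\log 10^{-8}, \log 10]$,
initialised by method of moments. The adjustment
($-\tfrac12\log\det X^\top W X$) corrects the downward bias caused by
estimating six mean parameters from twenty observations. No information is
shared across genes: the empirical-Bayes shrinkage used by the large
RNA-seq packages is deliberately not reproduced, so gene lists will not
numerically match theirs; the package is instead validated by calibration
and recovery on simulated cohorts with known truth.

**Small-sample reference distributions.** With $n = 20$ and a 6-parameter
full model, comparing the LRT statistic against $\chi^2_3$ is badly
anticonservative even with Cox-Reid dispersions (we measure a type-I rate of
about 0.09, and about 0.18 with unadjusted maximum-likelihood dispersions).
The default p-value therefore refers $\mathrm{stat}/3$ to an
$F(3,\, n - p)$ distribution, the same device the quasi-likelihood F-tests
of the field use to absorb dispersion-estimation noise; measured type-I
error is then 0.04-0.06 with near-uniform null p-values. The chi-square
reference remains available (`reference = "chisq"`). Wald statistics are
referred to $t(n - p)$ for the same reason. The LRT keeps a single
dispersion per gene, estimated under the full model and shared with the
reduced fit, so the statistic is non-negative by construction.

**Direction.** A gene is `up_in_seep` when its mean normalised count at
seeps exceeds that at control sites. The interaction terms make a single
coefficient's sign insufficient, so the definition uses group means.

## The spectrum models

The synthetic-data generator plants SNPs under two allele-frequency laws:

* **neutral** — the standard constant-size folded expectation: the
  minor-count class $i$ of $2N$ chromosomes is drawn with weight
  $1/i + 1/(2N-i)$ (halved at the symmetric class), i.e. rare variants
  dominate;
* **balanced** — the allele frequency is Beta(5, 5): one parameter that
  produces the intermediate-frequency excess characteristic of balancing
  selection.

Genotypes are then drawn per individual under Hardy-Weinberg equilibrium,
and any draw leaving the sample monomorphic is rejected, so every planted
SNP segregates. The one-sided Kolmogorov-Smirnov comparison is computed on
the raw per-SNP minor-allele frequencies (binning loses power) with the
direction — candidate stochastically greater — declared by the caller,
never inferred from the data. Because frequencies live on a grid of
$1/2N$, ties are heavy; the exact tie-aware null distribution is used
whenever the product of the two SNP counts is at most 1e4, and the
asymptotic approximation (slightly liberal under ties) otherwise.

## What the generator emulates — and what it does not

The default cohort is twenty diploid fish: ten per site, sexes split
6F + 4M at control and 4F + 6M at seeps, body length Normal(55 mm, 6 mm)
truncated at zero. Counts include log-normal (sdlog 0.15) library-size
factors; marker genes default to a 128-fold female excess. Pileups draw
Poisson depth per position, emit each allele of a heterozygote with
probability one half, substitute errors uniformly among the other three
bases, and clamp Normal(35, 3) base qualities to [2, 41]. Assembled
transcripts are haplotype-collapsed: one random allele per heterozygous
site — which is exactly why the alignment-based caller cannot see
low-frequency variants, reproducing the power asymmetry between the two
calling routes.

Real RNA-seq data differ in ways the generator does not attempt: coverage
tracks expression and decays toward transcript ends, errors are not
uniform, assembly produces chimeras and fragmentation, mapping introduces
reference bias, and dispersions vary across genes. Passing the simulation
suites therefore demonstrates the correctness and calibration of the
*inference machinery* under the stated models, not end-to-end accuracy on
any particular sequencing data set.

## Numerical and design choices

* **Alignment.** Transcripts are aligned to their gene's reference CDS by
  global alignment with free end gaps (match +2, mismatch -3, first gap
  position -5, each extension -2), replacing a multiple alignment: for
  near-identical sequences the column semantics are the same, and per-
  individual projection onto reference coordinates is deterministic and
  cheap. A transcript is unalignable when identity over aligned columns
  falls below 80% or those columns cover less than half of the shorter
  sequence — the coverage guard exists because an unrelated sequence can
  still produce a short, high-identity island under free end gaps.
* **Column caller.** A column is a SNP when at least two distinct bases are
  seen and the minor base occurs at least twice; singletons are
  indistinguishable from assembly error at one haplotype per individual.
* **Pileup caller completion.** Individuals with adequate depth but no
  variant call at a candidate site are homozygous-reference: a
  variants-only caller must be completed this way before an
  "all individuals genotyped" filter makes sense.
* **Reference orientation.** All sequences are handled in CDS orientation;
  the reference allele is the base of the supplied CDS. Ancestral states
  are never needed because the spectrum is folded.
* **Effect sizes in the power scenario.** The differential-expression power
  suite plants 10% of genes at |log2 fold change| at least 2 with
  dispersion 0.4; magnitudes are drawn uniformly on [2, 4] (signs
  balanced), representing a strongly responding gene set rather than one
  sitting uniformly at the detection boundary.
* **Enrichment.** Two-sided Fisher tests, Bonferroni-corrected over the
  terms that occur in the tested set (the natural universe when annotation
  of the genome is sparse).
* **q-values.** Benjamini-Hochberg by default; Storey's lambda-grid
  estimator of the null proportion is available but unstable at small SNP
  counts, which is why it is not the default.
* **Degenerate inputs.** Constant genes get Wald p = 1 and dispersion at
  the floor (1e-8, with cap 10); sites monomorphic in both site groups get
  Fisher p = 1; empty spectra refuse comparison rather than returning a
  number.

## Problem sizes used in validation

The shipped suites run a 20-fish cohort throughout; 2000 genes for null
calibration and for power; 200 replicate spectra of 265 candidate versus
1116 neutral SNPs (the sizes of the motivating study's SNP sets) for the
selection-signal recovery rates; five 300-nt genes at coverage 50 for
caller fidelity; 1e4 random codon substitutions against a whole-protein
translation oracle; and 1e4 Hardy-Weinberg SNPs for the heterozygosity
closure. These sizes give Monte-Carlo error comfortably below every
tolerance asserted.

## Known limitations

* Dispersion is estimated per gene with no shrinkage: at twenty
  individuals, per-gene estimates are noisy, which costs power relative to
  empirical-Bayes machinery on real data.
* The F and t references are small-sample corrections, not exact theory;
  calibration is demonstrated by simulation at the shipped cohort size.
* The alignment caller's minor-count floor of 2 means singleton variants
  can only ever be pileup-supported.
* Expected heterozygosity uses the plain 2p(1-p) with the sample frequency;
  at 2N = 40 it underestimates true heterozygosity by the factor
  (2N-1)/2N, which matters only when comparing against external absolute
  values.
* The Storey estimator's spline can degenerate below a few hundred
  p-values; it falls back to the conservative null proportion of 1.
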