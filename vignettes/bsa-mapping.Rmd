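---
title: "Mapping recessive loci from bulked-segregant sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive loci from bulked-segregant sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 3.5)
set.seed(1)
```

```{r}
library(bsascan)
```

## The method

Bulked segregant analysis maps a Mendelian locus by sequencing two pooled DNA
samples drawn from the phenotypic extremes of a segregating population. For a
fully recessive mutation in an F2, every plant in the mutant bulk is
homozygous for the mutant allele at the causal locus, while the wild-type
bulk — a 1 AA : 2 Aa mixture — carries the mutant allele at frequency 1/3.
Away from the locus, recombination erodes this contrast until both bulks sit
at 1/2.

The per-site statistic is the **SNP-index**: the fraction of reads at a site
carrying the non-reference allele in one pool. It is 0 when every read
matches the reference and 1 when every read differs; sites where a pool drew
no reads are *missing*, never 0. With the mutant parent contributing the
non-reference alleles, the expected indices at the causal site are 1 (mutant
bulk) and 1/3 (wild-type bulk), so the **delta SNP-index**

$$\Delta = \text{index}_{\text{mutant}} - \text{index}_{\text{wildtype}}$$

peaks at $+2/3$ at the locus and is 0 in expectation elsewhere. We orient
$\Delta$ as mutant minus wild type so the causal region is a positive peak;
the statistic is tested two-sided, so the orientation is cosmetic.

Single-site indices are noisy, so indices are averaged in sliding windows
(defaults 1 Mb wide, advancing by 250 kb) and $\Delta$ is formed from the two
window means. Significance comes from Monte-Carlo simulation of the no-locus
null: both bulks are random draws from the F2, so per replicate we draw each
bulk's composition from the Mendelian 1:2:1, form its allele frequency, draw
reads binomially at the observed depth, and record $\Delta$. Two-sided bounds
are the 95% and 99% quantiles of $|\Delta|$.

## Site filtering

Sites whose SNP-index is extreme *in both pools on the same side* (both
below 0.3, or both above 0.7, by default) are removed before windowing. Such
sites are characteristic of shared artefacts — mis-called reference bases or
fixed differences that do not segregate — rather than of a causal locus. The
alternative reading, dropping any site with either pool outside
$[0.3, 0.7]$, would delete the causal site itself (mutant pool near 1,
wild-type pool near 1/3) and with it the method's signal, so the joint rule
is the only self-consistent one. Sites with a zero-depth pool are excluded
from window means rather than imputed, and the filter logs removal counts by
reason. The filter is idempotent, and with the joint rule the causal-site
pattern always survives.

## The synthetic F2 experiment

Because pooled resequencing data of this kind are rarely redistributable,
the package ships a seeded generator whose defaults are the study conditions
the analysis targets: a 20 Mb chromosome carrying a fully recessive causal
locus at 11.2 Mb, 156 F2 plants (200 in the power experiments below, which
makes a mutant class smaller than a 33-plant bulk a $\sim 0.001$ event),
phenotype-selected bulks of 33 + 33, and ~80x mean pooled depth — matching a
typical single-gene cucumber mapping design.

* **Meiosis.** Each F2 plant is the sum of two F1 gametes. A gamete starts
  from a random parental haplotype and switches at crossover breakpoints;
  the number of crossovers is Poisson with mean equal to the chromosome's
  genetic length (default 0.8 Morgans per 20 Mb, ~4 cM/Mb, a typical plant
  rate), positions uniform, no interference. This is the simplest model that
  produces realistic linkage decay, which is all the scan consumes.
* **Phenotype.** Mutant iff homozygous at the causal locus (full
  penetrance). A misclassification rate (default 0) can flip labels before
  bulking, emulating bulk contamination — the main realistic perturbation of
  this design.
* **Reads.** Per site and pool, total depth is Poisson (or fixed: the null
  thresholds condition on depth, and the power experiments use fixed 80x);
  alternate reads are binomial at the error-adjusted bulk frequency
  $f' = f(1-e) + (1-f)e$ with $e = 0.001$ per base, a post-QC Illumina
  figure.
* **Seeding.** One master seed derives a named stream per stage (meiosis,
  phenotype, bulking, base assignment, reads per pool), so identical
  configurations are byte-identical down to the emitted VCF, and adding a
  stage never perturbs another stage's draws.

What the generator does *not* emulate: read-level artefacts (mapping bias,
indels, multi-allelic sites), reference bias from aligning both bulks to one
parent's genome, non-uniform recombination, and segregation distortion.
Passing tests therefore certify the statistics and their calibration under
the stated sampling model, not robustness to alignment pathologies.

```{r}
cfg <- f2_sim_config(n_individuals = 200, depth_model = "fixed", seed = 7)
cfg
records <- simulate_bulk_seq(cfg)
head(records, 3)
```

## Scanning and calling regions

```{r}
scan <- bsa_scan(records, bulk_size = 33, chrom_lengths = cfg$chrom_lengths,
                 seed = 7, quiet = TRUE)
scan
scan$regions
autoplot(scan)
```

The expected $\Delta$ at the causal window is $2/3$; under the null the
per-site spread is, to first order,

$$\mathrm{sd}(\Delta) = \sqrt{2\left(\frac{0.25}{2n} + \frac{0.25}{d}\right)}$$

for bulks of $n$ plants sequenced at depth $d$ — segregation sampling plus
read sampling, doubled across two independent bulks. At $n = 33$, $d = 80$
this is 0.118, so the simulated two-sided 95% bound (~0.23) sits far below
the causal signal. The tests verify the simulated null against this closed
form (within 5%) and against exact enumeration of the full $\Delta$
distribution at enumerable sizes (bulks $\le 2$, depth $\le 3$), where the
pooled allele count is Binomial$(2n, 1/2)$ in closed form.

## Numerical choices

* **Windows** are anchored at position 1 of each chromosome, half-open
  $[s, s + 1\,\text{Mb})$, step 250 kb; the trailing partial window is kept.
  Means are unweighted over contributing sites (no depth weighting). Empty
  windows are reported missing, never zero.
* **Thresholds** are precomputed per distinct observed depth (capped at 200
  grid values, nearest-depth lookup; each site uses its two-pool mean
  depth). Quantiles use R's default type-7 definition; with 10,000
  replicates the realised per-site type-I rate is ~4.7%, slightly
  conservative. A window's bound is the arithmetic mean of its sites'
  bounds. The 0.3/0.7 site filter is not applied inside the null simulation.
* **Regions** are maximal runs of consecutive windows with
  $|\Delta|$ above their 95% bound; each records its peak window (ties
  resolved to the first, i.e. leftmost, maximum) and is upgraded to the 99%
  level if any member window also exceeds its 99% bound.
* **Window-level calibration.** Thresholds are built for single sites.
  Within a 1 Mb window, read-sampling noise averages out across sites while
  segregation noise is shared through linkage, so windowed $\Delta$ has a
  smaller null spread than per-site $\Delta$ and site-built bounds are
  conservative at the window level: fewer than 5% of null *windows* exceed
  the 95% bound. Calibration is therefore asserted at the per-site level,
  and genome-scale null scans are checked for a mean $\Delta$ of zero.
* **Peak localisation.** Within ~1 window width of the causal locus the
  expected $\Delta$ surface is nearly flat (1 Mb is only ~4 cM), so the
  argmax among near-equal windows is noise-driven. At the study design the
  peak window falls within one window width of the locus in ~98% of
  replicates, and the top 95% candidate region contained the locus in 100 of
  100 replicates; localisation below one window width is not a property this
  design can deliver.

## Codon-level annotation

Candidate SNPs inside the mapped interval are annotated against gene models
(GFF3) and the reference sequence (FASTA): the CDS is concatenated in
transcription order (minus-strand genes reverse-complemented, alleles
complemented), the codon slot located from the CDS offset and phase, and the
reference/alternate codons translated with the standard genetic code —
nuclear plant genes use translation table 1. Effects are classified from the
amino-acid pair: synonymous, missense, nonsense (gain of stop), stop-loss.
Because the target phenotype is recessive, an optional pre-filter keeps
sites with mutant-pool SNP-index at or above a cutoff (0.9 by default when
enabled — the pool should be homozygous up to sequencing error and bulk
contamination). Co-segregation checking of shortlisted SNPs is reduced to a
genotype/phenotype concordance rate per marker (`cosegregation_rate()`):
exact concordance is the in-silico equivalent of a co-segregating PCR
marker.

```{r}
snps <- candidate_snp_table()
table(classify_effect(snps$codon_a, snps$codon_b))
```

## Phenotype-side statistics

Mendelian segregation is tested with the Pearson goodness-of-fit statistic
against an integer ratio (3:1 by default), no continuity correction, so 122
dominant : 34 recessive gives $\chi^2 = 0.855 < 3.84$: consistent with a
single recessive locus.

Pigments are quantified from 80% acetone extract absorbances at 663, 646 and
470 nm with the standard spectrophotometric equations
($C_a = 12.21A_{663} - 2.81A_{646}$,
$C_b = 20.13A_{646} - 5.03A_{663}$,
$C_{x.c} = (1000A_{470} - 3.27C_a - 104C_b)/229$). Total chlorophyll is
computed as the sum $C_a + C_b = 7.18A_{663} + 17.32A_{646}$; a form of this
identity sometimes circulates with the $A_{663}$ sign flipped, which is
inconsistent with the defining equations and is not used. Negative
concentrations (possible outside the calibration range) are reported with a
warning rather than clamped, so QC catches bad inputs. The carotenoid share
`car_pig_percent()` is a ratio of the supplied values; applied to genotype
*means* it reproduces published per-replicate-mean ratios only to within a
few tenths of a percentage point, since a ratio of means is not a mean of
ratios.

```{r}
segregation_test(122, 34)
```

## Problem sizes used by the test-suite experiments

The power and calibration experiments in the tests and the acceptance script
use the study design above (2,000 markers on one 20 Mb chromosome, 200 F2
plants, 33 + 33 bulks, fixed 80x): 100 seeded replicates for recovery, 5
genome-scale null scans, 10,000 null replicates per threshold and 20,000 for
calibration checks — sizes at which the Monte-Carlo error of every asserted
quantity is well below its tolerance.

## Limitations

Single biallelic locus, fully penetrant, F2 design only; no indels,
multi-allelic sites or polygenic traits; thresholds assume the two bulks are
independent draws (true under the null, approximate under linked selection);
and the simulator's uniform genetic map ignores recombination cold spots,
which in real data widen mapped intervals near centromeres.
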