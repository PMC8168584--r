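---
title: "Methods: allele-specific chromatin accessibility with ascav"
author: "ascav authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific chromatin accessibility with ascav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascav)
```

# The problem

A heterozygous regulatory variant can change chromatin accessibility on one
chromosome copy but not the other. Reads from an ATAC-seq (or ChIP-seq,
RNA-seq) experiment then favor one haplotype at that site, and the variant
is a candidate allele-specific chromatin accessibility variant (ASCAV). Two
technical problems make the naive read-count comparison unreliable:

1. **Mapping bias.** Reads carrying the non-reference allele align worse to
   a single reference genome. ascav instead builds a *personalized diploid
   genome* — one FASTA per phased haplotype — aligns against both, and
   assigns each read to its haplotype of origin.
2. **Copy-number aberrations.** In aneuploid (e.g. cancer) genomes an
   allelic skew may reflect nothing more than three copies of one haplotype.
   ascav tests assay counts against a *genomic* expectation estimated from
   WGS counts at the same site, and reports an allelic ratio corrected for
   the genomic component.

# Model

## Haplotype-aware read assignment

Each read is aligned to both personalized haplotypes and the two alignments
are compared tier by tier: mapping quality, then aligned (CIGAR M) bases,
then mismatch count. The first differing tier decides the winner — higher
mapping quality, more aligned bases, fewer mismatches; a read equal on all
three maps *commonly*. The orientation of each tier is this package's
choice (each criterion's natural quality direction); the tier *order* is
fixed as stated. Commonly mapping reads whose two placements do not lift
back to the same reference locus are discarded as ambiguous, as are
duplicates (first seen kept among reads sharing both placements; an
`is_dup` flag from an upstream duplicate marker is honoured).

## The imbalance test

At a phased heterozygous site with WGS counts $\#A, \#B$ for the two
alleles, the genomic allele fraction gets the conjugate posterior under a
uniform prior,

$$\theta \mid \#A, \#B \sim \mathrm{Beta}(1 + \#A,\; 1 + \#B),$$

and the assay counts $(k, n-k)$ are tested against the implied
beta-binomial null $K \sim \mathrm{BetaBin}(n, 1+\#A, 1+\#B)$. The
two-sided p-value is the *minimum-likelihood* mass — the sum of
probabilities of all outcomes no more likely than the observation, with a
relative tie tolerance of $10^{-9}$. This definition is exact, symmetric
for symmetric priors, and never exceeds 1; it is generally smaller (more
powerful) than tail doubling. Benjamini–Hochberg correction is applied
across sites.

For accessibility and binding assays, a significant q-value alone is not
enough: the *corrected allelic ratio*

$$\mathrm{odds}(r_{corr}) = \frac{\mathrm{odds}(r_{obs})}
{\mathrm{odds}(r_{gen})} \cdot
\frac{\mathrm{odds}(0.5)}{\mathrm{odds}(b)}$$

(with $b$ the residual reference-mapping bias, 0.5 — i.e. none — for
personalized-genome alignments) must also leave the balance band
$[0.4, 0.6]$. Imbalance fully explained by genomic copy number corrects to
0.5 and is not called. This conjugate machinery plus the odds-space
correction and decision band is a deterministic stand-in for a Bayesian
MCMC caller with the same intent; it is a declared behavioral substitution,
chosen because it is closed-form and oracle-testable. Expression events
(RNA) skip the band, since transcription-level imbalance is meaningful even
when copy-number driven assessments differ.

## Copy-number timing and WGD

The mutation copy number $\mathrm{mcn} = \mathrm{round}(n_{tot} \cdot
\mathrm{VAF} / \rho)$ (half away from zero — the value is immediately
discretized into the $\ge 2$ / $= 1$ rule, so the rounding convention only
matters at exact halves) estimates how many chromosome copies carry a
variant. In segments with LOH plus gain ($n_{minor} = 0, n_{major} \ge 2$)
or gains of both alleles ($n_{minor} \ge 2$), $\mathrm{mcn} \ge 2$ dates
the variant before the gain ("early") and $\mathrm{mcn} = 1$ after
("late"); every other context is untimeable ("na"), as is an inconsistent
$\mathrm{mcn} > n_{major}$. Whole-genome doubling is called by a linear
boundary in the (LOH fraction, ploidy) plane, ploidy $> c_0 - c_1 \cdot
\mathrm{LOH}$; the defaults $(2.9, 2.0)$ are this package's substitute for
an external criterion and are exposed as parameters, not asserted as
canonical.

## Motif deltas, enrichment and explained fraction

For each allele-specific peak the two allele sequences are scored with each
PWM as the best single-site log-odds over all windows on both strands
(pseudocount $10^{-3}$ per cell, uniform background by default). The
**delta** is the preferred-allele score minus the other-allele score —
antisymmetric, exactly 0 for identical sequences. Best-site scoring is a
deliberate simplification of multi-site CRM scoring: at a single variant
the best-site delta captures the gain/loss signal, it is deterministic, and
it is checkable against an exhaustive scan oracle; the scorer is an
interface so a multi-site scorer can be plugged in.

Per motif, a one-sided Fisher test compares how often $|\delta|$ exceeds a
cutoff (default 3.0 log-odds units — a configurable choice, not a canonical
value) in event peaks versus control peaks, with BH across motifs; the
odds ratio is reported as the cross-product with a Haldane 0.5 correction
on zero cells. `direction = "less"` covers negative association (repressor
motifs).

The **explained fraction at FPR $f$** takes per-variant scores (max
$|\delta|$ across motifs or model classes), finds the smallest threshold
$t$ with at most a fraction $f$ of control scores strictly above $t$ (the
empirical $(1-f)$-quantile, higher-interpolation convention), and reports
the share of event scores strictly above $t$. A label-shuffle baseline
should hover near $f$.

## Saturation mutagenesis

`saturationMutagenesis` scores a window and all $3L$ single-nucleotide
substitutions against any `SequenceScorer` (for the standard 500-bp window,
exactly 1,500 mutants) and records per-class score deltas. Deltas are
computed on the scorer's raw [0,1] outputs, not logits. The built-in
`pwmReferenceScorer` maps the best motif site through a calibrated logistic
per class, making engine behaviour exactly predictable; trained models run
out-of-process through `commandScorer`'s sequences-in/scores-out TSV
contract, so no deep-learning framework is a package dependency. For allele
scoring in the presence of indels, each haplotype's window is re-extracted
around the lifted peak summit, so both alleles are scored in centered,
equal-length windows — the anchoring is this package's decision.

# The synthetic-data generator

`simulateDataset` emulates the statistical structure the pipeline assumes:
a miniature diploid genome (default 2 chromosomes x 500 kb), phased het
SNVs (~2,000; one per peak plus background sites), non-overlapping 501-bp
peaks (200), allele-specific copy-number segments (default 60% balanced
diploid, 20% LOH+gain 2+0, 20% balanced gain 2+2, pure sample), WGS counts
binomial at the copy-number-determined allele fraction (depth 40), and
assay counts beta-binomial around the truth ratio. 10% of peak variants
are planted imbalanced at a preferred-allele fraction of 0.85, matching
the depths and effect sizes typical of deeply sequenced cell lines.
Optionally, planted sites are written into the reference as motif gains
(the alt allele completes a consensus on the preferred haplotype), and
`simulateReads` emits read-level fixtures whose per-haplotype mismatch
counts are exact Hamming distances.

What it does **not** emulate: fragment-length and Tn5 insertion bias, GC
bias, mapping error, linked variants on shared fragments, subclonal copy
number. Passing tests therefore demonstrate correctness of the inference
machinery under the stated model, not robustness to every artifact of real
libraries. Read-level fixtures use SNV-only genomes: mismatch metrics are
computed by exact comparison at lifted coordinates, and an indel inside a
read window would require alignment, which the generator intentionally
does not perform.

## Overdispersion and calibration

Assay counts default to a beta-binomial with intra-class correlation
$\rho_{od} = 0.02$ — deliberate extra-model variance so that recovery
experiments are not run under idealized sampling. Calibration runs are the
exception: they evaluate the test's own null, so they set
$\rho_{od} = 0$. Two null designs are used by the test suite:

- **Model null:** the per-site genomic fraction is drawn Uniform(0,1),
  under which $\mathrm{BetaBin}(n, 1+\#A, 1+\#B)$ is the *exact*
  conditional null by conjugacy; p-values are super-uniform up to
  discreteness.
- **Balanced null:** the fraction is fixed at 0.5. Conditioning on a noisy
  WGS draw makes the test mildly anticonservative in the mid p-range, but
  the size at $\alpha = 0.05$ stays below nominal in the suite's runs.

## A power limitation worth knowing

The WGS prior is also the test's bottleneck: at WGS depth 40 the prior's
dispersion ($\rho = 1/43$) roughly doubles the null variance relative to a
known-fraction binomial test. In the suite's recovery runs (500 sites at
preferred-allele fraction 0.85, assay depth 50, among 4,500 null sites,
FDR 0.05) sensitivity plateaus around 0.75 with realized FDP about 0.05,
while an oracle binomial test with the known genomic fraction reaches
0.99 and the same pipeline at WGS depth 80 reaches about 0.92. Deeper WGS
is the single most effective design improvement for this assay
combination. The corresponding acceptance check asserts sensitivity of at
least 0.8 and is expected to fail at WGS depth 40; it is retained
unmodified as an honest record of this limitation.

# Numerical choices

- Internal coordinates are 0-based half-open; VCF is 1-based; BED is
  0-based half-open. Conversion happens at the IO boundary only.
- Ratios of exactly 0 or 1 entering odds space are clamped to
  $[10^{-6}, 1 - 10^{-6}]$.
- Summit extension by 250 bp yields 501-bp regions (slopBed semantics);
  scorers consume a fixed window (default 500), so peak windows handed to
  scorers drop 1 bp at the 3' end.
- Peak consolidation is greedy by score: repeatedly keep the
  highest-scoring peak, remove everything overlapping it. Output peaks are
  input peaks verbatim and pairwise non-overlapping.
- Motif windows containing N score $-\infty$ (never best unless no valid
  window exists).
- Only SNVs and simple indels are applied to haplotypes; multi-nucleotide
  substitutions are rejected with the offending sites named, never
  silently skipped. Since haplotypes are built in-package, coordinate maps
  are exact by construction rather than re-derived by whole-genome
  alignment.

# Problem sizes in the test suite

The suite and the acceptance script run entirely on generated data, sized
for a single CPU: 5,000-site calibration and recovery panels, a
47,250-configuration enumeration-oracle sweep (all $n \le 60$, 25 priors),
10,000 read-comparator pairs, 1,000 motif-scan oracle cases, a 50-event /
500-control planted-gain enrichment with 20 decoy motifs, and the 90-row
exhaustive timing table. The full-scale generator default (2 x 500 kb,
200 peaks) runs the end-to-end CLI path in well under a minute.

# Known limitations

- The imbalance caller is a conjugate approximation; it does not estimate
  reference-mapping bias from data (personalized genomes largely remove
  it) and does not share information across sites.
- Best-site motif scoring ignores homotypic site clusters; a CRM-style
  scorer can be substituted through the scorer interface.
- Allele counting is SNV-level; indel alleles are carried through genome
  construction and window extraction but are not base-level counted.
- The WGD boundary constants are substitutes, not published values.

# Worked example

```{r example, eval = FALSE}
sim <- simulateDataset(simConfig(seed = 7))
rec <- filterMinCoverage(sim$atacCounts)
res <- callEvents(rec, fdrThreshold = 0.05)
table(called = res$calls$significant,
      planted = sim$truth$planted[match(
        paste(res$calls$chrom, res$calls$pos),
        paste(sim$truth$chrom, sim$truth$pos))])
```
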