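---
title: "Admixture or selection? Testing explanations for APOE allele-frequency change"
author: "apoeadmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Admixture or selection? Testing explanations for APOE allele-frequency change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoeadmix)
```

## The question

The apolipoprotein E locus carries three common haplotypes — ε2, ε3, ε4 —
defined by two coding SNPs (rs429358 T/C and rs7412 C/T; ε4 = C–C,
ε3 = T–C, ε2 = T–T). Their frequencies differ markedly across European
populations and through time, and because ε4 raises the risk of Alzheimer's
disease and cardiovascular disease while ε2 is a pro-longevity allele, the
cause of those differences matters. Two explanations compete: natural
selection, and the two great admixture events of European prehistory —
western hunter-gatherers (WHG) mixing with incoming Anatolian-derived early
farmers (EF) to form the late farmers (LF), and Bronze-Age steppe herders
mixing with the LF to form the modern European gene pool.

`apoeadmix` implements a complete, testable pipeline for separating the two
explanations in ancient-DNA-grade genotype data:

1. **Genotyping** — diploid calls at the two APOE SNPs from per-site pileup
   counts, with aDNA damage trimming and depth filtering.
2. **Allele frequencies** — haplotype-aware ε counting, exact 90%
   Clopper–Pearson intervals, pairwise Fisher tests under FDR control.
3. **Supervised admixture** — per-individual ancestry proportions q against
   two fixed parental panels, by maximum likelihood with a site bootstrap.
4. **Admixture-informed expectations** — the core model
   `fexp = kA·fA + kB·fB` composed over the two-step demographic chain,
   with an exact two-sided binomial test of observed against expected.
5. **Selection scans** — per-site Weir–Cockerham FST and 15-kb windowed
   Tajima's D, each ranked against chromosome-wide empirical percentiles.

A synthetic-data module generates every input the pipeline consumes, so all
of the above is exercised end to end without any external download.

## The core model

For an offspring population formed by two parents A and B with ancestry
components `kA + kB = 1` and parental allele frequencies `fA`, `fB`, pure
admixture predicts the offspring allele frequency

```
fexp = kA * fA + kB * fB .
```

The chain is composed over two steps — WHG and EF form LF; LF and steppe
form the later European populations — and each step uses the parents'
*observed* frequencies, not their own expectations, so the test at each
step asks only whether that step's admixture suffices. An observed allele
count `x` out of `n` chromosomes is then compared to `fexp` with an exact
two-sided binomial test using the minimum-likelihood ordering (the p-value
sums the probabilities of all outcomes whose point probability does not
exceed that of `x`). The ordering convention is fixed and documented so
results are reproducible bit-exactly; "two-sided" alone does not pin it
down.

Significant deviation from `fexp` indicates that admixture alone cannot
explain the offspring frequency — the signature the pipeline is built to
detect. Deviations are corroborated (or not) by the selection scans: a
focal-site FST above the chromosome's empirical 95th/97.5th percentile, or
a locus mean Tajima's D low in the chromosome's windowed distribution,
point to selection rather than drift or admixture.

### What is deliberately *not* modelled

The expectations use point estimates of `k` and of the parental
frequencies. Their sampling uncertainty is not propagated into the binomial
test. With parental cohorts of ancient-DNA size (tens of individuals), the
plug-in noise adds variance the binomial null does not account for, so the
test rejects a true null somewhat more often than its nominal level
suggests. The package keeps the literal
test because that is the established procedure, and documents the
anticonservatism here; the test-suite calibration checks therefore fix the
parental frequencies at their true values when probing the test itself, and
use the full plug-in chain only for power (shift-detection) checks. Drift
between admixture and observation is likewise not modelled: a "significant
deviation" is evidence against *pure, instantaneous* admixture, not proof
of selection.

## ε counting rules

ε4 and ε2 are counted from their defining variant alone (rs429358-C,
rs7412-T) over all samples with that site called — maximizing sample size —
while ε3, the T–C haplotype, is counted only over samples with both sites
called. Any unphased diplotype that is not heterozygous at both sites
decomposes uniquely over the {ε2, ε3, ε4} alphabet (ε1, the C–T
recombinant, is excluded: it is vanishingly rare in Europeans and absent
from the populations modelled). Double heterozygotes are ambiguous
(ε2/ε4 or ε1/ε3); they are resolved as ε2/ε4 — the parsimonious choice
under the three-letter alphabet — and their count is always reported
(`n_ambiguous_dhet`) so sensitivity to the alternative resolution can be
assessed. With noisy genotype calls a diplotype can imply an ε1 haplotype
(e.g. a miscalled C at rs429358 in an ε2 carrier); the ε3 contribution is
clipped at zero and a warning raised, which doubles as a data-quality
signal.

## Genotype calling and aDNA filters

The caller is an explicit maximum-likelihood diploid caller over the two
segregating bases under a binomial read-sampling model with symmetric error
(reads from a homozygote show the other base with probability `base_error`;
heterozygote reads are 50/50). QUAL is the phred-scaled complement of the
genotype posterior under a uniform prior — any monotone confidence score
would serve the downstream QUAL > 50 site filter; this one is fixed and
documented. The aDNA-specific rules are:

* genotypes at depth < 3 are *missing* (hets cannot be distinguished
  reliably below that depth); no pseudo-haploid call is ever emitted —
  every call is a diploid pair or missing;
* samples missing diploid calls at **both** APOE sites are dropped; one
  called site suffices to contribute to that allele's count;
* terminal read positions whose C→T mismatch rate exceeds 0.05 are masked
  before calling. "Positions to mask" is operationalized as the smallest
  `m` such that every position at distance ≥ `m` from the read end has a
  rate at or below the threshold — one defensible reading of trimming a
  contiguous damaged run; the damage profile itself is estimated from
  C-context pileups (samples whose interior reads are confidently C);
* scan samples additionally need ≥ 70% chromosome site coverage and a mean
  depth strictly > 5 in a 100-kb window around the locus. Coverage is
  computed over the site universe in the input, not physical bp, because
  the pipeline is site-list based.

Base and mapping quality filtering (> 20) is an input contract: pileups are
assumed pre-filtered, as produced by standard callers.

## Supervised admixture

With parental allele frequencies held fixed, the ancestry proportion q of
one individual maximizes `Σ_l log Binomial(g_l | 2, q·fA_l + (1−q)·fB_l)`.
The per-site success probability is linear in q, so the log-likelihood is
concave and the maximizer unique unless `fA = fB` at every used site (that
degenerate case returns q = 0.5 with a flag). This is the same likelihood
a supervised two-way ADMIXTURE run optimizes, restricted to the quantity
the downstream model consumes (the Q components), and it is exactly
testable: the suite checks the fitted optimum against a 0.001-step grid.
Optimization is bounded scalar maximization (golden-section/parabolic,
tolerance 1e-8) with explicit endpoint refinement. Uncertainty comes from a
site bootstrap (100 replicates by default, matching standard practice);
population components are `kA = mean(q̂)`, `kB = 1 − kA`.

Parental frequencies estimated from reference genotypes are regularized
with a 0.5 pseudocount so the likelihood stays finite at fixation.
Frequency-estimation noise behaves like error-in-variables and biases q̂
toward 0.5, so reference panels must be large enough that this noise is
small relative to the parental divergence; the pipeline default is 50
reference individuals per parent for that reason, and the recovery checks
that probe the ML fit itself hold the panel at the generator's true
frequencies.
LD pruning is an input contract — the generator emits unlinked sites and
real panels should be pruned upstream.

## Selection scans

**FST.** Per-site Weir–Cockerham (1984) two-population variance components
`a` (among populations), `b` (among individuals within), `c` (within
individuals), `θ̂ = a/(a+b+c)`, computed from diploid genotype counts.
Sites monomorphic in both populations are undefined and excluded from the
background; negative estimates are *retained* — clamping at zero would
distort the empirical background the outlier thresholds are built on.
Sites where a population has no called chromosomes, or where the average
sample size is one individual, are flagged undefined.

**Tajima's D.** Per window, `D = (π − S/a1) / sqrt(e1·S + e2·S(S−1))`
with the standard constants from the chromosome sample size; π is computed
from per-site derived-allele counts as `Σ 2x(n−x)/(n(n−1))`. Windows with
no segregating sites are undefined. Windows tile the chromosome half-open
from origin 0 (15 kb by default); VCF positions are converted from 1-based,
so a site at position `start + window_len` (1-based) opens the next window.
The focal locus — the three 15-kb windows spanning TOMM40–APOE–APOC1 in the
motivating application — is a configuration item (chromosome label, window
indices), not a hard-coded coordinate.

**Backgrounds.** Percentile thresholds use linear interpolation between
order statistics (R's type-7 quantile), over defined values only; a focal
value must be *strictly* above a threshold to be flagged. The locus D
summary reports the mean over the defined focal windows, flags against the
5th/95th percentiles, and a below-median indicator — the diagnostic pattern
for old sweeps too weak to clear the percentile thresholds.

## The synthetic-data module

The generator produces every input with the statistical structure the
analysis assumes:

* **Cohorts** — two i.i.d. haplotypes per individual from a population's
  (f_ε2, f_ε3, f_ε4); admixed cohorts draw each haplotype from parent A
  with probability `k_a`, so the expected frequency is exactly the
  admixture expectation. Phase is retained as ground truth.
* **Pileups** — Poisson depth (the depth distribution is otherwise
  unspecified in aDNA practice; Poisson is the standard neutral choice),
  uniform read placement over a 60-bp read, symmetric base error, and
  terminal C→T deamination within 2 bp of read ends. Deaminated reads are
  labelled, so tests can verify that trimming removes exactly the
  damage-origin signal.
* **SNP panels** — ancestral frequencies uniform on (0.05, 0.95), parental
  frequencies from a Balding–Nichols beta around the ancestral value; the
  realized Hudson-type divergence matches the nominal F (checked at
  ±0.02 over 10,000 sites). Sites are unlinked by construction.
* **Windows** — neutral windows draw S ~ Poisson(θ_w·a1(n)) segregating
  sites with derived-allele counts ∝ 1/i (the neutral frequency spectrum;
  under this spectrum E[π] = S/a1, so D is centred near zero by
  construction). Sweep windows skew counts ∝ i^(−skew) and divide the mean
  S by the skew factor — "fewer, rarer variants", the first-order footprint
  of a sweep. This is deliberately not a coalescent: it reproduces the
  sign and percentile behaviour the D scan consumes at a fraction of the
  cost, but has no linkage, no recombination structure, and no genealogical
  variance in S beyond Poisson.

What passing tests therefore show about real data: that the estimators,
filters and decision rules are implemented correctly and behave as designed
on data with the assumed structure. What they do not show: robustness to
reference bias, contamination, UDG-treatment heterogeneity, linked
selection, or population mis-grouping — none of which the generator
emulates.

Default scenario conditions (used by the pipeline demo, the test suite and
the acceptance script): five populations — WHG (n = 25, ε2-free, ε4 = 0.40),
EF (n = 90, the lowest ε4 = 0.05 and highest ε3 = 0.87), Steppe (n = 45,
ε4 = 0.22), LF (n = 110) formed as 0.18 WHG + 0.82 EF, and a modern cohort
(n = 90) formed as 0.5 LF + 0.5 Steppe. The 0.18/0.82 split is the
LF ancestry decomposition the motivating analysis reports; the second-step
0.5/0.5 is a neutral middle of the north–south steppe-ancestry cline, which
is not pinned by a single published value. Sample sizes total 360,
matching the yield scale of the underlying aDNA compendium (358 usable
samples from 3521 datasets). Sequencing defaults (depth 5×, base error
0.005, deamination 0.15 over 2 terminal bp) are plausible aDNA-grade
placeholders — no published damage profile was available to calibrate them,
and they are exercised by the tests rather than asserted as realistic.

## Numerical and degenerate-input choices

* Clopper–Pearson at x = 0 returns a lower bound of exactly 0 (upper
  `1 − (α/2)^{1/n}`), and symmetrically at x = n.
* Fisher two-sided p uses probability ordering; tables with a zero margin
  give p = 1.
* All pairwise Fisher tests (every population pair × every allele) are
  pooled into a single BH family.
* Binomial deviation test at fexp ∈ {0, 1}: p = 1 if the observed count is
  the only possible outcome, else 0.
* More than two observed bases in a pileup: the two most frequent are
  used, with a warning.
* Seeding: one top-level seed; every stochastic stage derives a child seed
  deterministically from the seed and the stage name, so stages are
  independently reproducible and a full re-run is byte-identical.

## Problem sizes

The test suite and acceptance script run at desk scale, chosen to finish
in minutes on one CPU while leaving the statistical checks well-powered:
exact-test oracles enumerate all 2×2 tables to total 30 and all binomial
outcomes to n = 50; admixture recovery uses 10,000 sites × 20 individuals
per grid point; calibration uses 2,000 simulated cohorts of 100 alleles;
scan behaviour uses 500 neutral and 200 sweep replicates and 200 FST
replicates of 1,000 background sites at 50 diploids per population; the
end-to-end demo runs the full 360-sample scenario twice to verify
determinism.

## Known limitations

* Uncertainty in k and parental frequencies is not propagated into the
  deviation test (anticonservative with small parental cohorts; see above).
* The double-heterozygote ε2/ε4 resolution slightly deflates ε3 if ε1 is
  truly present; `n_ambiguous_dhet` quantifies the exposure.
* The windowed simulator is not a coalescent; D's variance under linkage
  is not reproduced, only its location and ordering.
* The FST estimator is the two-population form; multi-population scans are
  computed pairwise.
* Supervised admixture assumes the parental panels are the true sources;
  a mis-specified parent biases q in ways the bootstrap cannot see.
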