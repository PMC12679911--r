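---
title: "Methods: sire prolificacy and hybrid vigor in multi-sire herds"
author: "herdvigor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sire prolificacy and hybrid vigor in multi-sire herds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdvigor)
```

# The problem

In multi-sire breeding pastures, several bulls serve one cow group, so a
bull's contribution to the calf crop — and hence to the genetics of
retained replacement heifers — is unknowable from herd records alone.
DNA parentage testing resolves sire identity; genomic breed-composition
testing quantifies each animal's expected retained heterosis. This
package implements the full analysis chain between those two data
sources and a herd book: sire verification, prolificacy indexing,
calving-cycle analysis, vigor scoring, retained-daughter cohort
accounting, and trait regressions on vigor score.

# Models and procedures

## SNP-exclusion parentage

For a calf and a candidate sire genotyped at biallelic SNPs (0/1/2
copies of the alternate allele), an *opposing homozygote* — one animal 0
and the other 2 — is impossible under Mendelian inheritance without a
genotyping error. `assignSire()` declares a candidate compatible when
its opposing-homozygote count on the 100-locus base panel is at most
`maxMismatches` (default 1 per 100 loci: tolerant of a single genotyping
error, while a random non-sire at intermediate allele frequencies
expects on the order of ten opposing homozygotes per 100 loci, so the
tolerance admits essentially no false sires). One compatible candidate
is a match; several trigger a re-test on the base plus extension loci
(default 20); a residual tie is broken by fewest mismatches, and
anything still unresolved — including zero compatible candidates — is a
`no_sire_match`. Commercial labs do not publish their acceptance
thresholds, so this exclusion rule is a documented, deterministic
stand-in with the same interface (base panel, extension, no-match
outcome). Candidate lists come from the dam's breeding-group service
roster; dam genotypes are not used, since dams are known from calving
records. The test suite verifies on simulations that at zero error rate
the true sire is never excluded, and that the probability a random
non-sire shows no opposing homozygote across loci matches the
closed-form product of per-locus probabilities $\prod_l (1 - 2 p_l^2
q_l^2)$.

## Bull Prolificacy Index

For each sire in a breeding group-year, $\mathrm{BPI} = n / (N / m)$:
calves attributed to the sire over the equal-share expectation given $N$
total matched calves and $m$ sires. Only DNA-verified calves enter $n$
and $N$; dead calves are sampled and tested in the field protocol, so
they count whenever matched. Within a group-year
$\sum_i \mathrm{BPI}_i = m$ exactly — the suite asserts this identity on
every simulated herd. The first-21-day variant substitutes first-cycle
counts for $n$ and $N$, leaving $m$ unchanged; a group-year with no
first-cycle calves is flagged undefined rather than reported as zero.

Two bookkeeping decisions were genuinely open. First, a sire moved
between groups mid-season (injury replacement) is counted in every
group-year where he has matched calves, while $m$ counts the rostered
sires; a matched sire absent from the roster is added with a warning.
Second, stratification into bottom 25% / average 50% / top 25% is
rank-based with quartile size `round(n/4)` and ties broken by sire id —
the published 0.4 and 1.4 cutoffs are treated as empirical quartile
descriptors, not hard classification rules, because they are herd- and
year-specific. Across-year repeatability is the Spearman correlation
between a sire's first use-year BPI and each later use-year, with a
permutation p-value (default 1999 permutations) rather than the
asymptotic approximation, since the paired sire counts are small.

## 21-day calving cycles

The first calving cycle starts at the third mature-cow calving of the
season (mature means 3 years and older at calving; ages are whole
calendar-year differences, since producer records carry no finer
convention). Cycles are half-open 21-day bins: a calf born exactly 21
days after the start is in cycle 2, consistent with "born in the first
21 days". Two degenerate cases get explicit treatment: births before
the computed start (possible for early heifer calvings) clamp to cycle
1 with a flag, and a group-year without three mature-cow calvings — the
replacement-heifer group has none by construction — falls back to the
herd-wide start of that calving year, flagged. Season starts are
computed per breeding group by default because groups calve separately;
`scope = "herd"` gives the single-start alternative.

## Vigor score and breed composition

The genomic vigor score is retained heterozygosity,
$\mathrm{VS} = 1 - \sum_i P_i^2$ over the animal's fractional breed
composition: 0 for a purebred, $1 - 1/k$ for $k$ equal breeds, 0.625
for a 50/25/25 crossbred. The commercial panel reports 13 named breeds
plus an indeterminate remainder; whether the commercial score includes
that remainder in the sum is not public, so both behaviours are
implemented: the default treats the indeterminate fraction as one
pseudo-breed (which keeps $\sum P_i = 1$ and matches the accounting in
which one minus the named-breed total is the indeterminate proportion),
and `includeIndeterminate = FALSE` drops it with renormalization.

Dams without genomic tests are reconstructed from verified trios as
$\mathrm{dam} = 2\,\mathrm{calf} - \mathrm{sire}$, the exact inverse of
parental-mean inheritance. On estimated field compositions individual
components can come out slightly negative; the minimal repair — clamp to
zero and renormalize — is applied and always flagged. On simulated
trios the inversion is exact and the suite asserts a bit-level
round-trip.

## Cohort accounting

Retained daughters of each sire stratum are followed across a shared
calendar window (four calving years by default, anchored at the
earliest cohort's first possible calving). "Percent remaining" is
calvers-in-the-final-year over daughters retained — the reading that
reproduces the published table cells. Two rounding conventions are
deliberate: the average grand calves per sire is rounded half-up (not
half-to-even) to one decimal, and the weaned kg per sire multiplies the
average weaning weight by that *rounded* average — this reproduces the
published accounting exactly (e.g. 196.63 kg × 6.8 = 1337.08 kg, where
the unrounded 6.75 would give 1327.25); `roundedAverage = FALSE`
exposes the full-precision variant for real analyses.

## Trait regressions

Each trait is regressed on vigor score by ordinary least squares and
reported per +0.10 VS; percent-scale scores are normalized first so
percent and fraction inputs agree. Conception is fitted as a linear
probability model at the animal level to match the linear framing of
the benchmark constants (a logistic fit would not be comparable on the
percentage-point scale); AFC excludes heifers that never calved but
keeps them in the conception denominator; lifetime productivity is
cumulative weaned kg over the tabulated parities. No multiple-testing
correction is applied across the four traits — raw p-values are
reported, as is conventional for these commercial benchmark
comparisons. Because the source regressions may have been fitted on
10%-bin means rather than animal records, both modes exist
(`binned = TRUE`); neither is asserted to be the original. Noiseless
fits are handled explicitly (SE 0; p 0 for a nonzero slope, 1 for a
constant trait) since `lm`'s t-test is 0/0 there.

# The synthetic herd generator

`simulateHerd()` emulates the study herd's structure with known ground
truth. Its defaults are the study conditions:

| parameter | default | rationale |
|---|---|---|
| breeding years | 6 | study duration |
| groups (sires/dams) | 6/150, 6/150, 3/70, 4/80 | two mature-cow groups, a 3-year-old group, a heifer group; bull:cow ratios 1:20–1:25, inside the reported 1:19–1:27 |
| calving season | 4 × 21-day cycles | 69–85 day seasons |
| per-cycle conception | 0.62, 0.55, 0.50, 0.45 | gives ≈ two thirds of calves in cycle 1, matching the reported 67% average |
| prolificacy weights | lognormal(0, 0.8), static per bull | reproduces the observed BPI dispersion (≈ 0.04–3.5) and, because weights persist across years, positive across-year repeatability; yearling bulls are down-weighted (× 0.55), reproducing their lower BPI |
| SNP panel | 120 loci, freq ~ U(0.2, 0.8) | 100 verification loci + 20 extension loci; the 50K discovery chip is out of scope |
| VS trait slopes | −0.7 d AFC, +1.74 kg WW, +2 pp conception, +60.3 kg lifetime per +10% VS | the estimated effects, injected as ground truth |
| weaning weight | 190 ± 15 kg (Gaussian) | typical ~172-day weights; noise scale is a package choice, not a reported value |
| retention | top 50% of eligible heifers by weaning weight; togglable third-cycle cull | the "weigh and keep the top females" rule; the third-cycle criterion is the post-ownership-change rule |

Founder bulls come in two pools: purebred-like (one breed at 0.80–0.92,
like straightbred Angus sires, vigor score necessarily below
$1 - 0.8^2 = 0.36$) and composite-like (≥ 5 breeds, none above 0.35,
vigor scores ≈ 0.83–0.88 like composite Beef Booster bulls); dams are
per-animal mixtures between the pools. Offspring compositions are
parental means; founder genotypes are Binomial(2, composition-weighted
allele frequency) and offspring receive one allele per parent.
Conception probability responds to the dam's vigor score through the
configured conception slope, and weaning weight through the WW slope,
so those two effects are mechanistic in the full herd simulation. AFC
and lifetime productivity, by contrast, *emerge* from conception-cycle
timing and cumulative weaned weight; for exact slope-recovery testing
the package therefore also provides `simulateVigorTraits()`, a direct
per-heifer generator with all four slopes injected exactly, and the
acceptance property for slope recovery runs on it at n = 500 with 100
replicates.

What the generator does **not** emulate: linkage and genetic maps
(loci are independent), age-structured fertility in cows, behavioural
sire dominance beyond static weights, seasonal nutrition, twinning, or
economics. Consequently, passing tests demonstrate the *correctness of
the computations* under a faithful structural model — they do not
validate biological effect sizes on real herds, whose records are
private.

# Numerical choices

- BPI, vigor scores and percentages are kept at full precision
  internally; rounding (1–2 decimals, half-up where the published
  tables require it) happens only at display or in the two cohort cells
  documented above.
- Composition validity uses a 1e-9 sum-to-one tolerance; user-supplied
  vectors are checked at 1e-6.
- Vigor bins use exact decimal edges (`round(k * width, 9)`) so scores
  like 0.70 land in [0.70, 0.80) despite floating-point accumulation;
  the top bin is closed.
- Deterministic tie-breaks throughout: candidate sires and strata by
  id, same-day season-start calvings by calf id, retention by weaning
  weight then id.
- The whole pipeline is a pure function of (inputs, config, seed); the
  suite asserts byte-identical outputs across repeated runs.

# Test problem sizes

Unit and property tests run on a down-scaled herd (2 years, 4 groups of
4/60, 4/60, 2/30, 2/30) so the full suite completes in well under a
minute, with the full-size default configuration exercised where the
property demands it: parentage power on a 2-year default herd (~900
calves), weight recovery on a single 2000-calf group, slope recovery at
n = 500 × 100 replicates, and repeatability on a 3-year default herd.

# Known limitations

- The exclusion thresholds of the commercial parentage pipelines are
  proprietary; the implemented rule is a documented stand-in, so
  match/no-match counts on real lab exports may differ at the margin.
- Published group-level summary cells that are arithmetically
  inconsistent with their own printed inputs (a few table extremes
  round differently than the formula value) are not reproduced; the
  package follows the formula.
- The distribution of true sire prolificacy in nature is unknown; the
  lognormal choice is a modelling convenience exposed in
  `SimParams`, not an inference.
- Breed-composition estimation from raw genotypes (ADMIXTURE-style) is
  out of scope: compositions are inputs, supplied or simulated.
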