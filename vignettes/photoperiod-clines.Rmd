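---
title: "Linking photoperiod-temperature climates to clinal allele frequencies"
author: "photocline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking photoperiod-temperature climates to clinal allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photocline)
```

## The question and the model

Small seasonal breeders such as common voles time reproduction by day
length, but the day length that *should* trigger breeding differs
between places: what matters ecologically is when food (spring grass)
appears, and that is governed by temperature, which varies with
latitude, longitude (continentality), and altitude — not by photoperiod
alone. This package operationalises that idea as the **predicted
critical photoperiod (pCPP)**: trace each locality's year as a closed
curve in the (photoperiod, temperature) plane and read off the day
length at the moment in spring when temperature rises through a
threshold proxying the onset of grass growth. Populations adapted to
local seasonality should then show allele frequencies at
photoperiodism genes that follow pCPP more closely than they follow
raw latitude or distance.

The pipeline has four stages, each exposed as ordinary functions and
combined by `runFull()`:

1. climate → pCPP (`buildEllipse()`, `predictedCriticalPhotoperiod()`);
2. alignment → SNPs and per-population allele frequencies
   (`callSnps()`, `snpFrequencySet()`);
3. population structure: multilocus Nei G~ST~ (`fstMatrix()`),
   composite LD (`ldMatrix()`), neighbor-joining tree
   (`populationTree()`);
4. pairwise gene–environment association with Benjamini–Hochberg
   adjustment (`associateAll()`).

## Solar geometry and the pCPP

Day length is the civil-twilight day: the time the sun's center is
above −6°. Solar declination comes from the Spencer Fourier series (a
mean-year fit, error well under 0.3°, ample since a 0.3° declination
error moves mid-latitude day length by ~0.05 h), and the hour-angle
cosine is clamped to [−1, 1] so polar day/night degrade exactly to
24 h/0 h. A 365-day calendar is used; leap days are ignored. Longitude
is irrelevant for day *length* and is not used by the solar model.

Monthly mean temperatures are interpolated to daily values with a
periodic piecewise-linear scheme anchored at mid-month days (Jan 15 =
day 15, ..., Dec 15 = day 349, wrapping December to January). Linear
interpolation was chosen over splines because it cannot overshoot the
monthly extremes, so an annual cycle that never reaches the threshold
in the monthly data can never cross it after interpolation.

**Which crossing is "spring"?** A unimodal annual cycle crosses a
threshold exactly twice: once rising (spring) and once falling
(autumn). Traversing the closed loop from the previous summer, the
spring crossing is the second one; we implement it directly as the last
*rising* crossing before the day of the annual temperature maximum,
which is unambiguous for unimodal cycles and robust to minor secondary
wiggles. The crossing day is refined by linear interpolation between
adjacent days — exact here, because the interpolated temperature is
itself piecewise linear between integer days. The threshold defaults to
6.6 °C (grass growth starts at 5–10 °C; 6.6 °C is the value that keeps
the threshold inside every locality's annual cycle in the motivating
data set) and is a plain argument everywhere, so sensitivity analyses
at other thresholds are one keystroke.

## Variant calling

Input is an aligned FASTA of per-specimen consensus sequences
(`specimen|locality` headers), with heterozygous positions encoded as
IUPAC two-allele codes — the natural product of Sanger chromatogram
reading. Decoding is deterministic: a plain base is a homozygote, an
ambiguity code a heterozygote, `N` a missing genotype (excluded from
both numerator and denominator of frequencies).

The inclusion rule is a **carrier rule**: a column is a SNP only when
strictly more than `minCarriers` (default 3) specimens carry at least
one copy of the non-reference allele. A heterozygote counts as one
carrying specimen — the rule is about specimens containing the variant,
not about allele counts. Columns with three or more segregating bases
are excluded with a warning (the analysis is biallelic throughout).
Position labels count backwards from the intron/exon boundary for
intronic sites (boundary-adjacent base = −1) and forwards from +1 for
exonic sites; with the default 829 bp intron, alignment column 671
(0-based) is SNP −158. Coding effects translate the reference codon
and the alt-substituted codon under the standard genetic code, using
the fragment's reading-frame phase; codons that extend outside the
sequenced exon or contain `N` give `NA` with a warning. The frame
phase of the first exonic base must come from the genome annotation of
the fragment; it defaults to 0.

The lineage question (whether the carrier threshold applies globally
or per lineage) is resolved as: call globally, then treat a SNP as
present in a lineage if it is polymorphic among that lineage's
populations — this is what the per-lineage association stage does.

## Population-genetic summaries

**F~ST~.** The pairwise multilocus fixation index is a Nei/Chesser-style
unbiased G~ST~. Per locus, within-population heterozygosity is the
average of $(2n_i/(2n_i-1))\,2p_iq_i$ over the two populations; total
heterozygosity uses the unweighted mean allele frequency with the
analogous correction factor built from the *harmonic mean* sample size.
The harmonic-mean choice makes two identical populations of equal size
give exactly 0 rather than relying on the negative-value clamp.
Numerator and denominator are summed over loci polymorphic in the
union of the pair before the ratio is taken (fully monomorphic loci
would contribute 0/0 and carry no information); negative estimates are
clamped to 0, matching the convention of reporting a 0.000 floor.
Nei's D~A~ is available as an alternative distance for tree building.

**LD.** Because consensus genotypes are unphased, LD is the *composite*
r²: the squared Pearson correlation of per-specimen alt-allele dosages
(0/1/2), with pairwise deletion of missing genotypes. On
heterozygote-free data this collapses exactly to the haplotype
$D^2/(p_1q_1p_2q_2)$, which the test suite verifies.

**Tree.** Saitou–Nei neighbor joining (via ape) on the pairwise F~ST~
(or D~A~) matrix; negative branch-length estimates are clamped to 0
with a message. No bootstrap is computed.

## Association model and its honesty

For each SNP and proxy the model is linear in the *pairwise
differences*: $|\Delta p|$ against great-circle distance (haversine,
R = 6371.0088 km) or $|\Delta|$ of latitude, longitude, altitude, pCPP,
over all $P(P-1)/2$ population pairs in a fixed lexicographic order.
The p-value is the two-sided t-test on $n-2$ df with $n$ = number of
pairs. Pairs sharing a population are not independent, so this nominal
p is **anticonservative**; the package therefore (a) documents it, (b)
offers a Mantel-style permutation p (`permutations =` argument,
off by default) that restores exchangeability, and (c) the test suite
asserts only *relative* behaviour (planted signal ≫ neutral), never
exact type-I rates. BH adjustment is applied within one proxy across
one lineage's SNPs — five families per lineage, matching the per-panel
presentation of Manhattan-type figures; whether the original analysis
pooled proxies is unknown, and per-proxy families are the conservative
reading of per-panel plots. Significance is `pAdj < alpha`
(default 0.05). A generic `excludePopulations` argument supports
island-exclusion sensitivity analyses.

## The synthetic study and what it does (not) show

`simulateDataset()` generates the full study with known truth, seeded
once from `config$seed` (byte-identical outputs under a fixed seed):

* **Localities**: 15 western + 28 eastern, latitudes uniform on
  42–59 °N, longitudes −6..5 °E (west) and 14..39 °E (east), altitudes
  log-uniform on 4–2146 m, 6 diploid specimens per locality — the
  scale of the motivating data set (278 specimens, 43 localities).
* **Climate**: sinusoidal monthly means
  $T(m)=\mu - A\cos(2\pi(m-1-\ell)/12)$ with annual mean
  $\mu = 23 - 0.245\,\mathrm{lat}$ (°C), amplitude
  $A = 6 + 0.22(\mathrm{lon}+10)$ growing with continentality, and lag
  $\ell = 0.5$ months (coldest around end of January, so temperature
  lags photoperiod and the annual loop opens counter-clockwise). These
  values were fixed on realism grounds: they put the 6.6 °C spring
  crossing in March–May and the resulting pCPPs at roughly 12–16.6 h,
  close to the empirically reported 10.2–15.4 h band. Any
  configuration whose cycle fails to cross the threshold aborts
  generation with an explicit error.
* **Fragment**: 829 + 849 bp, 49 biallelic SNPs split 22 intronic /
  27 exonic; 12 cline SNPs with per-population truth
  $p = \mathrm{clamp}(0.5 + \beta\,(\mathrm{pCPP}-\overline{\mathrm{pCPP}}),
  0.02, 0.98)$, slope $\beta = 0.12$ per hour; labels −158, −128 and
  +126 are reserved for cline SNPs when the fragment is long enough.
  Neutral SNPs draw a Beta($a,a$) baseline independently per lineage
  ($a = 0.5$), which makes the two lineages diverge and reproduces the
  qualitative structure pattern (between-lineage F~ST~ well above
  within-lineage).
* **Drift and sampling**: per-population frequencies get Beta noise
  with concentration $\kappa = 60$ around the truth, and genotypes are
  drawn Binomial(2, p) — together a beta-binomial overdispersion, a
  deliberate shortcut compared with explicit Wright–Fisher generations.
  Columns whose sampled carriers fail the >3 rule are redrawn (with a
  message) so every planted SNP is callable. An `"exact"` genotype
  mode assigns allele counts deterministically for noise-free
  round-trip checks.

What passing tests on this generator show: the pipeline recovers
planted clines, controls the relative ordering of signal vs noise, and
every estimator matches its independent oracle. What they do **not**
show: performance on real data. The generator plants independent
columns (no LD structure, no haplotypes), draws exonic substitutions
uniformly (so its synonymous fraction is far below the
purifying-selection excess seen in real coding variation), uses
sinusoidal climates without weather noise, and its absolute F~ST~
levels follow the divergence knob rather than vole history. At the
default slope and sample sizes, the power to detect a planted cline
SNP at BH 0.05 is high but not certain (roughly 50–90% of the 12
planted SNPs across seeds) — the same marginal-power regime a real
43-SNP, 15-population study occupies.

## Numerical choices and degenerate inputs

* Hour-angle cosine clamped to [−1, 1]; day length computed as
  $\mathrm{acos}/\pi \times 24$ so the clamps are exactly 0 and 24.
* Threshold outside the annual temperature range → `noCrossingError`
  naming the locality; monomorphic alignments → empty SNP set; fewer
  than 3 populations, constant correlation inputs, unknown ids →
  typed errors (`inputError`, `constantInputError`, `formatError`).
* G~ST~ with no shared genotyped loci is an error; identical
  monomorphic pairs return 0 by convention.
* NJ tie-breaking follows ape's deterministic implementation; trees
  need ≥ 3 leaves.
* All pair orderings (proxies, frequencies, LD) use one fixed
  lexicographic scheme, so condensed vectors are directly comparable.

## Problem sizes used by the test suite

The suite exercises the solar oracle on a 19 × 12 grid (±63°; at
near-polar latitudes day length is so sensitive to sub-degree
declination differences that no independent formula can match to
0.15 h, so polar behaviour is asserted via the exact clamps), the pCPP
brute-force scan at 0.01-day resolution on 100 random climates, the
SNP caller against a naive column scanner on 50 random alignments, all
576 single-base codon substitutions against an independent translation
oracle, and one seeded 15-population / 43-SNP end-to-end scenario.
These sizes keep the default test run fast while covering every
estimator with at least one independent-oracle comparison.

## Known limitations

* The pairwise-difference association design is anticonservative by
  construction; use the permutation p-value for calibrated inference.
* No haplotype phasing, no indels, no recombination-aware simulation;
  LD output is descriptive.
* The civil-twilight model ignores refraction beyond the fixed 6°
  depression, elevation of the horizon, and leap years — all far below
  the climatological noise in monthly mean temperatures.
* Real-data F~ST~ magnitudes and the empirical pCPP range depend on
  the deposited specimen data and historical weather records; the
  package reproduces the methods, and its synthetic defaults emulate
  the design, not those exact numbers.
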