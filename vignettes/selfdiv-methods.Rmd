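---
title: "Diversity and genetic load under mixed mating: models and methods"
author: "selfdiv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity and genetic load under mixed mating: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfdiv)
```

# Scope

`selfdiv` quantifies how a population's reproductive mode — exclusive
selfing, partial selfing (mixed mating), or predominant outcrossing — shapes
its genetic diversity and its genetic load. It covers four connected pieces:

1. **Diversity statistics** on phased biallelic SNP genotype matrices:
   per-marker expected and observed heterozygosity (He, Ho), the multilocus
   inbreeding coefficient Fis, identity disequilibrium g2, and the windowed
   effective number of haplotypes he.
2. **Linkage disequilibrium**: pairwise r2 within chromosomes and a
   nonlinear fit of its decay with genetic distance.
3. **A neutral forward simulator** of inbred-line derivation by selfing that
   turns an observed population sample into a drift-only 95% credible
   interval for post-inbreeding diversity.
4. **Survival analysis** of inbred-line extinction (Kaplan–Meier), the
   read-out of genetic load under enforced inbreeding.

A synthetic-data module generates populations with known mating-system
history so every stage can be exercised against ground truth without any
external data.

# Data model

A `PhasedGenotypes` object extends `SummarizedExperiment`: two assays
(`hap1`, `hap2`) hold the two allele calls (0 = REF, 1 = ALT, `NA` =
missing) of each individual at each marker, and `rowData` holds the genetic
map (chromosome, position in centimorgans). Genetic distance, not physical
position, is the coordinate system throughout, because recombination and LD
decay are functions of map distance. Positions are 0-based at the
chromosome start and must be non-decreasing within chromosomes.

The `phased` flag records whether the split into `hap1`/`hap2` is
meaningful. Unphased data are accepted everywhere phase is irrelevant
(He, Ho, Fis, g2, composite LD), but operations that need haplotypes —
window he, the selfing simulator — refuse unphased input with an explicit
error instead of silently pseudo-phasing.

# Diversity statistics

**He and Ho.** Per biallelic marker, `He = 2pq` with `p` the ALT frequency
over non-missing allele calls, and `Ho` the fraction of heterozygous
individuals among those with complete calls. Genome-wide values average
per-chromosome means across chromosomes by default (chromosomes are the
natural replication unit of the linkage-aware analyses; `average = "flat"`
gives the unweighted mean over markers — the two differ only when
chromosomes carry unequal marker numbers).

**Fis.** `Fis = 1 - Ho/He` in the multilocus *ratio-of-means* form,
`1 - mean(Ho)/mean(He)` over markers passing a `He >= 0.05` filter. The
ratio-of-means is preferred over a mean of per-locus ratios because
per-locus Fis is numerically unstable at low-He markers; the filter (default
0.05, configurable) removes markers where sampling noise dominates. Under
neutral mixed mating at equilibrium, Fis converges to `s/(2-s)` for selfing
rate `s` — the anchor used throughout the tests (s = 0, 0.5, 1 giving
0, 1/3, 1).

**Identity disequilibrium g2** measures the correlation of heterozygosity
across loci within individuals, which partial selfing generates through
variance in individual inbreeding history: it is ~0 under pure random
mating, positive under mixed mating, and undefined once no individual is
heterozygous anywhere (exclusive selfing). We implement the David et al.
(2007) finite-sample multilocus estimator as a ratio of sums over marker
pairs, with the product of marginal heterozygosities estimated from ordered
pairs of distinct individuals; missing data are handled per marker pair
using the individuals complete at both markers. The implementation is held
to the brute-force double-loop definition at 1e-10 relative tolerance in
the tests, and its SE comes from a seeded bootstrap over individuals.

**Effective number of haplotypes he.** Haplotypes are defined in
non-overlapping windows of 10 consecutive SNPs tiling each chromosome (a
trailing remainder is dropped), and `he = 1 / sum(k_i^2)` for haplotype
proportions `k_i` — the number of equally frequent haplotypes giving the
observed haplotype homozygosity, a multi-allelic diversity measure that is
far more sensitive to inbreeding than He. Each phased individual
contributes its two window haplotypes (`unit = "haploid"`, default). The
alternative reading — one diploid two-haplotype genotype per individual
(`unit = "diploid"`) — is implemented behind a flag; we default to haploid
units because he is a haplotype-frequency statistic and the haploid
counting keeps `he = 1` exactly for a monomorphic window under both
readings while distinguishing heterozygous from homozygous individuals.
An individual with any missing call in a window is dropped from that window
only.

**Sample-size matching.** Inbred-line panels are larger (often > 50 lines)
than the 16-individual population samples they are compared with, and both
he and He estimates are sample-size dependent. `jackknifeMatch()` and the
simulator therefore evaluate metrics as averages over subsets of exactly 16
individuals (delete-d jackknife); subsets are enumerated exhaustively when
few, sampled otherwise.

# Linkage disequilibrium

For phased data, `D = P(11) - p_i p_j` from observed gametes and
`r2 = D^2 / (p_i(1-p_i) p_j(1-p_j))`, over all within-chromosome pairs with
allele frequencies in [0.05, 0.95]. For unphased data the Burrows composite
estimator `D = mean(XY)/2 - 2 p_i p_j` over genotype dosages is used; it
needs no haplotype inference (no EM), matching a genotypic definition of
disequilibrium.

The decay of r2 with genetic distance c (in cM) is fitted by least squares
to the Sved expectation `E[r2] = 1/(1 + 4xc)`, which equals 1 at c = 0 and
treats `x` as the population-scaled decay rate. `x` is estimated on the log
scale, so the optimizer cannot leave the positive domain, and the SE is
delta-method back-transformed; the Levenberg–Marquardt implementation in
`minpack.lm` is used because it also converges on noiseless (zero-residual)
data, which the Gauss–Newton `nls` does not. Replicate populations are
fitted separately and pooled by inverse-variance weighting — a fixed-effect
approximation of a nonlinear mixed model with replicate random effects that
preserves the population-level comparison without embedding a mixed-model
engine.

# The neutral selfing simulator

The simulator provides the null distribution for "how much diversity should
surviving inbred lines retain if nothing but drift acted during enforced
selfing?". Conditional on an observed phased sample (typically 16
individuals), each of `n_sims` (default 1000) replicates:

1. samples `n_lines` founders *with replacement* from the sample,
2. selfs each founder independently for 13 or 16 generations,
3. computes He / he / Ho among the lines, chromosome by chromosome,
   matched to the sample size by averaging over subsets of 16 lines.

The empirical 2.5 and 97.5 percentiles give the 95% credible interval;
`scoreObserved()` places an observed line panel inside, above, or below it.
Observed diversity **above** the interval indicates balancing (e.g.
overdominant) selection during inbreeding; **below**, purifying selection.

**Meiosis model.** Complete crossover interference: at most one crossover
per chromosome per meiosis. The crossover probability equals the map length
in Morgans (0.5 for the 50 cM F2-scale chromosomes used throughout),
capped at 1, and, given a crossover, its position falls between two
consecutive SNPs with probability proportional to that interval's cM
length. This is the only crossover law consistent with both complete
interference and a 50 cM map; it reproduces the per-generation halving of
heterozygosity exactly (each heterozygous site remains heterozygous with
probability 1/2 per selfing generation, irrespective of linkage), which the
tests verify against `Ho0 * 2^-t`.

The simulator is strictly neutral: no mutation, no selection, no
line extinction (the comparison against real surviving lines is what is
designed to detect survival-biased selection), and strict N = 1 selfing.

# Synthetic data: what it emulates and what it does not

`generateMap()` / `evolvePopulation()` emulate the motivating experimental
design: ~6 chromosomes of 50 cM carrying evenly spaced SNPs, populations
founded from a pool of 16 distinct haplotypes (echoing 16 parental wild
isolates) and evolved forward under a chosen selfing rate `s` — each
offspring is produced by selfing with probability `s`, otherwise by
outcrossing between two distinct parents — with an optional multiplicative
viability step. Returned samples are 16 phased diploids plus full-truth
records (allele frequencies, realized Fis). Sex-determination mechanics are
abstracted into the scalar selfing rate: every statistic in scope depends
on mating outcomes, not on how males/females/hermaphrodites are determined.
The selection coefficient is written `s'` throughout to keep `s` for the
selfing rate.

`deriveInbredLines()` mirrors real line derivation. Under viability
selection, each generation draws a brood of candidate offspring per line
(default 25) and keeps one with probability proportional to its viability,
falling back to a uniform pick if the whole brood is inviable (the backup
rescue used in practice). Selection within a brood acts on *relative*
viability: loci already fixed homozygous in a line contribute a constant
factor and no longer influence which offspring continues, while segregating
overdominant or deleterious-recessive loci are selected against. An
absolute accept/reject scheme was rejected as a design because, with
multiplicative near-lethal fitness, any line with one fixed homozygous
selected locus has all-zero offspring viability and would silently become
neutral.

What the generator does *not* emulate: mutation (negligible over these
timescales), the funnel crossing that built the real ancestral population
(burn-in recombination from a haplotype pool stands in for it), male
frequency dynamics, fertility variation, and block structure in line
derivation. Passing tests therefore demonstrate correctness of the
estimators and the drift null under the stated mating models — not that any
particular biological dataset will match them.

# Line-extinction survival analysis

`kmEstimate()` computes the product-limit estimate of line survival over
selfing generations from right-censored records (`extinct` at the
generation of confirmed failure; `censored` at assay end), with pointwise
95% bands from the Greenwood variance on the log(-log) scale, delegating to
`survival::survfit`. Records from derivation blocks are pooled by default.
Cox / frailty hazard regression is deliberately out of scope; the curves
and per-population survival fractions are the module's products.

# Numerical and testing choices

* Windows with fewer than 10 SNPs are dropped, never padded; an individual
  missing any call in a window is dropped from that window only.
* g2 returns an explicit error (not NaN) when no heterozygotes exist.
* LD fits start from a moment inversion of the median informative pair and
  run Levenberg–Marquardt on `log x`; predicted r2 at c = 0 is exactly 1.
* All stochastic functions take a `seed` and are bit-reproducible given it.
* Test and calibration problem sizes are chosen to keep the full suite in
  minutes on one core: 6 x 20-marker maps, populations of 150–400 evolved
  for 25–30 generations, 150-replicate neutral intervals, 200 coverage
  trials (20 populations x 10 neutral derivations) and 60 detection trials.
  Interval coverage is insensitive to these sizes because the observed
  neutral line panels are generated by exactly the process the simulator
  models, making observation and simulation exchangeable.
* The overdominance detection check uses 12 overdominant loci (one per
  10-SNP window) with mild balancing selection (`s' = 0.3`) while the
  population evolves — keeping the loci polymorphic and heterozygous in the
  founders — and near-lethal homozygotes (`s' = 0.999`) during line
  derivation, the "effectively overdominant" regime of recessive lethals in
  repulsion. This configuration was fixed a priori as the strong-selection
  study condition; weaker, unlinked configurations lose the signal in the
  width of the drift interval.

# Limitations

* The Sved fit assumes a single decay parameter per (replicate) population;
  heterogeneous recombination landscapes are not modeled.
* The Burrows composite r2 is a genotypic approximation; with strong
  departures from random union of gametes it differs from gametic r2.
* The neutral simulator conditions on the observed sample as if it were the
  founding gene pool; founder sampling error beyond the 16 individuals is
  outside the interval.
* `jackknifeMatch()` averages over random subsets when enumeration is
  infeasible, adding a small Monte-Carlo component to matched metrics.

# A compact worked example

```{r example, eval = FALSE}
map <- generateMap(chromosomes = 6, markers_per_chromosome = 20)
pop <- evolvePopulation(s = 0.5, N = 200, generations = 25, map, seed = 2)
x   <- pop$sample

diversityReport(x, population = "partial-selfing", seed = 3)

lines <- deriveInbredLines(x, generations = 13, n_lines = 50, seed = 4)
obs   <- lineDiversityMetrics(lines, seed = 5)
sim   <- neutralInbreedingSim(x, generations = 13, n_sims = 1000,
                              n_lines = 50, seed = 6)
scoreObserved(sim$he, obs[["he"]])

km <- kmEstimate(generateLineExtinctions(200, 0.022, 16, seed = 7))
survivalAt(km, 16)
```
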