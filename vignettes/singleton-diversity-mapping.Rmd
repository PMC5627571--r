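---
title: "Mapping genetic diversity with the empirical distribution of singletons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping genetic diversity with the empirical distribution of singletons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(singletonMaps)
```

## The estimator

A singleton is a derived allele carried by exactly one chromosome in a
sample of `n` chromosomes typed at `L` biallelic loci (0 = ancestral,
1 = derived, infinite-sites mutation). Writing `xi1_i` for the number of
singletons on chromosome `i` and `xi1` for their total, the *empirical
distribution of singletons* is

    p_hat_i = xi1_i / xi1,  i = 1..n,

an individual-level measure of how much of the sample's rare variation
each chromosome carries. Its theoretical counterpart comes from the
coalescent: conditional on a genealogy, the probability that a singleton
lands on chromosome `i` is the ratio `tau_i / tau1` of its external branch
length to the total external branch length, so

    p_i = E[tau_i / tau1],   and   E[p_hat_i] = p_i

regardless of demography — the estimator is unbiased, which is the
property the split-model study and the regression check in the test suite
verify. In a panmictic constant-size population every chromosome
contributes equally (`p_i = 1/n`), the expected total external length is 2
(time in units of 2N generations), and `E[xi1] = theta`, the effective
mutation rate; these closed forms are the package's fast oracles.

Because `p_hat_i` is defined per chromosome, it measures *local* genetic
diversity without requiring population labels: averaged over chromosomes
sampled near a location, it plays the role that expected heterozygosity
plays for a predefined population sample. After a range expansion both
measures decay with distance from the origin, which is what makes the
spatial pattern of singletons informative about where an expansion
started.

## Module overview

* `countSingletons()` / `siteFrequencySpectrum()` /
  `expectedHeterozygosity()` / `groupSummaries()` — estimation from a
  `HaplotypeMatrix` (a `SummarizedExperiment` of 0/1/NA calls, loci by
  chromosomes).
* `simulateNeutralGenealogy()`, `splitModelParams()` +
  `simulateStructuredGenealogy()`, `dropMutations()`,
  `replicateSplitStudy()` — Kingman and two-population split-model
  coalescent with infinite-sites mutation.
* `runForwardDemography()`, `drawSamplingDesign()`,
  `sampleBackwardCoalescent()` — spatially explicit range expansion.
* `fitVariogram()`, `krige()`, `surfaceCorrelation()` — diversity
  surfaces.
* `priorSpec()`, `buildReferenceTable()`, `abcEstimate()`,
  `validateOriginRecovery()` — ABC inference of the expansion origin.

## Time and mutation conventions

The coalescent clock runs in units of `2 N1` generations: while `k`
lineages are active in a population of relative size `x`, a merger occurs
at rate `k(k-1)/2 / x`, and a branch of length `l` receives
`Poisson(theta/2 * l)` mutations. Under these conventions `E[tau1] = 2`
and `E[xi1] = theta` for the neutral model.

The split model mirrors a standard `ms` configuration
(`-t theta -I 2 50 50 -g 1 46.05 -n 2 s -eg 0.2 1 0.0 -ej t 2 1` with
`N1 = 50,000`): population 2 is constant at relative size `s` (the shrink
rate) and joins population 1 at the split time (drawn uniformly on
1,000–10,000 generations unless fixed); population 1 shrinks backward
exponentially — its size passes through the ancestral 5,000 exactly
10,000 generations ago — until the flagged epoch, after which it is
constant. `ms` expresses these flags on a `4 N0` time scale, which the
constructor converts (growth rate and epoch are halved/doubled
accordingly).

One subtlety deserves note. `theta` here is the effective mutation rate
in the `2 mu N` convention of the theory; converting it to the `ms`
`-t` input (which is `4 N0 mu`) doubles it. `splitModelParams()` applies
this factor through `thetaScale = 2` when dropping mutations on
split-model genealogies, which reproduces the scale of the published
study (per-replicate singleton totals near 12,000 and within-population
SDs near 0.0010/0.0008 at `s = 0.33`). Setting `thetaScale = 1` recovers
the pure theory clock in which `E[xi1] = theta` exactly. Under the
default, the replicated study at `s = 0.33` yields population mean
proportions near 0.0128 and 0.0072; their ratio (about 1.75 across the
split-time prior) sits somewhat above the published 1.55 — an
irreducible discrepancy we traced carefully: an independent coalescent
simulator run on the identical scenario gives the same 1.7–1.8, and no
reading of the printed flags (join direction, ancestral-phase handling,
folded counting, alternative time scalings) moves it to 1.55 at
`s = 0.33` (interestingly, `s = 0.40` does). The simulator therefore
follows the printed model faithfully rather than the printed summary.

## The range-expansion simulator

The landscape is a lattice of demes with carrying capacities assigned by
habitat class (`makeHabitatMap()`: homogeneous C = 100; vegetation
C = 60 semi-desert / 30 extreme desert and rain forest; the
ABC variant C = 100/20/10). Forward in time, densities are
*deterministic*: the origin deme starts at the ancestral size and each
generation grows logistically (`N <- N + r N (1 - N/C)`, default
`r = 0.1`) and sends a fraction `m = 0.07` of its individuals to its
habitable von Neumann neighbors in equal shares. Determinism keeps the
history exactly reproducible and lets the backward pass recompute migrant
flows from the stored densities instead of storing per-generation flow
fields.

All stochasticity lives in the backward coalescent: per locus, lineages
choose their source deme with probability proportional to the forward
migrant flow (stayers included), coalesce pairwise within a source pool
of size `N` with probability `1/N` (multiple mergers resolved
sequentially), and finish in a panmictic ancestral pool of the scenario's
ancestral size (default 200; the pre-expansion lag is part of this
constant-size phase, so its duration does not alter the backward law).
Mutations arrive per lineage-generation at the per-locus rate (default
`1e-5`) and each creates one biallelic site carried by the lineage's
descendants. Because mutation stops at each locus MRCA, sites fixed in
the entire sample cannot arise; `filterMonomorphic()` is still provided
for data that were masked afterwards. Loci are unlinked (independent
genealogies), and there is no recombination within a locus, no
long-distance dispersal, and no density-dependent migration.

Two sampling designs mirror the population/individual contrast:
`"population"` places 10 haploid chromosomes at each of 30 occupied demes
spread quasi-uniformly (k-means over occupied cells); `"individual"`
jitters those centers with Gaussian noise (SD 2 degrees) and snaps each
single-chromosome site to the nearest occupied cell.

## Kriging choices

The surface module uses ordinary kriging with an exponential variogram
fitted by weighted least squares (weights = pairs per distance bin),
which is the least-committal classical choice when only "kriging" is
specified. Distances are Euclidean in degrees below a 5-degree extent and
great-circle (km) above. The fit bounds the sill near the sample variance
and the range by the domain half-diameter: a single realization often
supports an "almost linear" variogram (huge sill and range), and the
bound keeps the model identifiable. Grid resolution defaults to 1 degree;
masks follow the habitat raster. Duplicate point locations are averaged
before solving, and with zero nugget the predictor interpolates exactly.

## ABC for the origin of a range expansion

The summary statistic is a spatial singleton histogram: sites are grouped
by k-means on their coordinates, and each group contributes its mean
per-chromosome singleton count divided by the sample's singleton total.
The prior for the origin is uniform over a lon/lat box, linearly tapered
over the outer 20% of each coordinate range, and restricted to habitable
cells; migration rate, growth rate, duration, ancestral size and lag are
uniform nuisance parameters (their published ranges are not available, so
the package ships documented substitutes: m 0.01–0.2, r 0.05–0.5,
duration 500–3,000, ancestral size 50–1,000, lag 50–500). Reference-table
rows record per-row seeds, so tables are reproducible and resumable.
Estimation standardizes statistics by their median absolute deviation,
accepts the closest `tolerance` fraction in Euclidean distance, and
offers rejection, Beaumont-style local-linear adjustment (Epanechnikov
weights; the deterministic default) and an averaged ensemble of
single-hidden-layer neural networks (default 250 members) mirroring the
published method family. Posterior summaries are a weighted 2D Gaussian
KDE on a 100 x 100 grid masked to habitable cells, its mode, and
equal-tailed credible intervals.

## Desk-scale study design

The packaged checks run on a 20 x 20 demo grid (one-cell sea border,
Sahel-like vegetation bands) rather than the 87 x 83 continental lattice,
with these once-chosen sizes: expansions of 250 generations sampled at
25 sites x 4 chromosomes and 250 loci for the diversity-gradient and
surface checks; and for origin inference a 300-row reference table at 40
sites x 3 chromosomes, 100 loci with per-locus mutation rate 5e-3, 5%
injected missingness, 12 k-means groups, and 20 cross-validated test
data sets (leave-one-out over table rows, which are themselves prior
draws). Nuisance priors are scaled to the small domain (m 0.08–0.25,
r 0.2–0.6, duration 150–300, ancestral size 50–300, lag 50–200).

The desk ABC validation uses the *homogeneous* capacity map. On the
small grid the vegetation bands span the entire domain, funneling every
expansion through one high-capacity corridor and erasing most latitude
information from the statistic — an artifact of miniaturization, not of
the method (with banded capacities the latitude recovery drops to near
zero while longitude survives; both coordinates recover once capacities
are uniform). At these sizes the cross-validated squared correlations
between estimated and true origins are roughly 0.6–0.8 per coordinate —
far from the ~0.95 reported at full scale with a 20,000-row table, which
desk hardware is not expected to reproduce; the packaged checks assert
the property level (both above 0.5, improving with table size) rather
than the full-scale values. For the regression-adjustment methods,
adjustment only pays off once the table is large relative to the
statistic's noise; on 300-row tables the local-linear and rejection
estimators perform similarly here.

## Numerical details and degenerate inputs

* Singleton status is judged among non-missing calls only; loci with
  fewer than two non-missing calls are skipped and counted. In folded
  mode a two-call locus with one derived and one ancestral allele is a
  tie; the derived carrier is credited deterministically.
* Zero-singleton profiles mark proportions (and group summaries)
  undefined rather than dividing by zero; zero-length-tree genealogies
  are excluded from the theoretical distribution with a warning.
* The structured simulator inverts the cumulative coalescence hazard in
  closed form across epoch boundaries; events landing exactly on the
  split time are absorbed into the join.
* MAD-standardization falls back to the SD (then to 1) for constant
  statistic columns; ABC refuses tolerances that accept fewer than 20
  rows.
* k-means uses Lloyd's algorithm with k-means++ seeding, best of 10
  restarts; `k = n` returns singleton groups directly.

## Known limitations

Related individuals violate the exchangeability behind
`E[p_hat_i] = p_i` and should be removed before analysis; the package
does not detect kinship. Multi-allelic sites and phasing are out of
scope (VCF input keeps biallelic SNPs only). The synthetic Africa-like
raster is a coarse, hand-drawn stand-in rather than a georeferenced
continental map, and no real accession panel (such as a
146-accession pearl millet data set at ~170,000 SNPs) ships with the
package, though the formats such a panel arrives in (`.geno`, VCF,
coordinate CSV) are fully supported.
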