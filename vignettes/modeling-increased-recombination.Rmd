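---
title: "Modeling recurrent selection under engineered recombination landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling recurrent selection under engineered recombination landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Meiotic crossovers are scarce (rarely more than three per chromosome pair
per meiosis) and unevenly placed: in many crops the pericentromeric
regions, which can cover half a chromosome's physical length, are almost
devoid of them. Two experimental routes can raise recombination in plants:

* **global scaling** ("HyperRec-like"): knocking out anti-crossover genes
  multiplies the recombination rate everywhere, leaving the shape of the
  landscape unchanged — cold regions stay cold;
* **pericentromere warming** ("boosted"): in allotriploid *Brassica*
  hybrids the extra rate appears everywhere, including regions where the
  diploid never recombines — well approximated by *adding* a constant
  cM/Mb rate along the chromosome.

`recsel` simulates, forward in time and individual by individual, what each
route does to the response to selection in a biparental breeding program:
genetic gain, genetic variance, and allele fixation over 20 generations of
phenotypic or genomic (RR-BLUP) selection.

## The model

**Genomes and maps.** Each chromosome carries a Marey map: a monotone
function from physical position (Mb) to genetic position (cM), stored as
genetic positions on a fixed 0.1 Mb grid so that the local rate is an
auditable finite difference and the additive transform is exact
(`fit_map()`, `make_hyperrec()`, `make_boosted()`). Simulation itself
operates purely in genetic space; physical coordinates matter only for
placing QTL. Given a normal map with length `GL_NR` and a target `GL_HR`,
the multiplicative transform scales genetic positions by `GL_HR / GL_NR`,
and the additive transform adds `(GL_HR - GL_NR) / PL` cM/Mb everywhere;
both reach the same per-chromosome total, so the two routes are compared at
equal total map expansion.

**Meiosis.** Crossovers are generated at the gamete scale with an average
of one per 100 cM — the definition of genetic distance. Without
interference the count is Poisson(GL/100) with uniform positions (Haldane).
With interference, inter-crossover distances are gamma with shape `nu`
(mean 100 cM); the renewal process is made stationary by drawing the first
position as a uniform fraction of a length-biased (gamma with shape
`nu + 1`) interval, so the expected count stays GL/100 for every `nu` and
the total-length contract is preserved. `nu = 1` recovers Haldane exactly.
We do not simulate four-strand bivalents or thinning, so `nu` acts as an
effective gamete-scale interference parameter; since the values we use were
estimated under a two-pathway model, interference strength is, if anything,
overestimated. A gamete is a founder-origin mosaic (origin at 0 plus
breakpoints); meiosis merges the parent's two mosaics at the drawn
crossovers, starting from a uniformly chosen gamete.

**Traits.** QTL are biallelic and purely additive. Amplitudes `a` are
gamma(shape 0.4, scale 1.58) — an L-shaped distribution with variance ~1 —
and each allele carries `±a/2`, founder P1 and P2 carrying opposite signs.
QTL physical positions are re-sampled every replicate among gene positions
(without replacement: two QTL at one gene would be a single locus).
Optional coupling/repulsion assigns the founder linkage phase by a walk
along each chromosome: the sign changes (coupling) or stays (repulsion)
with probability `P = (1/2)(1 - exp(-dx/L))`, `dx` the genetic distance to
the previous QTL and `L = 5` cM by default. Because `P` is defined on
genetic distance, the walk is run on each landscape's own genetic
coordinates: the *strength* of coupling between two QTL is a property of
how often they recombine, so an expanded map carries intrinsically weaker
founder phase at the same physical positions. The walk reuses a single set
of uniform draws per replicate (common random numbers), so the scenarios'
sign vectors are maximally paired and differ only where the transition
probability crosses the shared draw — a tighter map can never have fewer
same-sign neighbours than an expanded one within a replicate. Under
`phase_mode = "random"` signs are identical across scenarios.

**Selection schemes.** Founders P1 x P2 give an F1 (g = 1); selection
starts at g = 2 on populations of 250.

* *Fn scheme*: the F1 is selfed to 250 F2s; each later generation keeps the
  best 5 (2%) by breeding value and random-mates them (ordered pairs of
  distinct parents) to produce 250 offspring.
* *DH scheme*: 250 doubled haploids from the F1; selection happens on the
  homozygous panels (even generations), the 5 selected DHs are crossed to
  250 heterozygotes, each of which yields exactly one DH — 10 cycles in 20
  generations.

Phenotypes are `G + N(0, V_E)` with `V_E` calibrated once, in the g = 2
population, to hit the target heritability (`h2 = 0.5` by default) and held
fixed afterwards. Genomic selection uses 1000 equally spaced neutral
markers per chromosome coded -1/0/+1 and RR-BLUP: `Y = 1·beta + Z u + e`,
with the variance ratio `lambda = sigma_e^2 / sigma_u^2` estimated by REML
through the spectral decomposition of `Z Z'` projected orthogonally to the
intercept (1-D profile likelihood, optimized to 1e-8 on the log-ratio), and
`GEBV = beta + Z_g u` in later generations. The model is retrained at g = 2
and then per the recalibration schedule (every fourth generation by
default; alternatives: every second, or only once in the F2). Training uses
only the current generation's 250 individuals, and phenotypes are simulated
only in training generations.

**Metrics.** Gain at g is `mean G(g) - mean G(2)`; since paired scenarios
share the g = 2 variance, gains are not normalized. The efficiency of a
modified landscape is the ratio of across-replicate mean gains
(`gain_ratio()` also reports the mean of per-replicate paired ratios as a
diagnostic; the ratio of means is the headline estimator because it stays
stable when individual replicates have near-zero normal gain). Confidence
intervals are `1.96 sd / sqrt(n)` across replicates.

## The synthetic genome generator

The experimentally measured maps and gene annotations behind the original
landscapes are not redistributable, so `recsel` generates equivalents; a
user can substitute real data via `read_marey_map()` (TSV Marey maps) and
`read_gff_genes()` (GFF3). The generator emulates:

* per-chromosome genetic lengths under normal and increased recombination
  (presets for a 10-chromosome *B. rapa*-like genome, 821.7 to 2774.8 cM in
  total, and a 12-chromosome *O. sativa*-like genome, 1758.54 to 5699.87
  cM — per-chromosome values; both increased landscapes reach the same
  per-chromosome totals);
* a pericentromeric cold region: central 40% of each chromosome's physical
  span at 2% of the uniform-map rate. Measured plant landscapes show
  near-zero pericentromeric rates over a central fraction that can reach
  half the chromosome; these two numbers are free parameters chosen once to
  reproduce that qualitative structure;
* gene density reduced to 30% (relative) inside the cold region, so ~17%
  of QTL land there;
* physical spans of 40 Mb/chromosome. Only rate *ratios* matter downstream
  because simulation operates in genetic space, so PL is a scale
  convention, not a calibrated quantity.

What the generator does **not** emulate: chromosome-specific landscape
shapes (every chromosome shares one geometry), telomeric rate gradients,
transposable elements, non-genic QTL, and real marker noise. Passing tests
on synthetic landscapes therefore show that the *method* reproduces the
reported efficiencies under matched genetic lengths and a cold-pericentromere
structure — not that any particular real chromosome behaves identically.

## Numerical choices

* Map fitting smooths noisy Marey maps (`smooth.spline`, `spar = 0.1`),
  then enforces monotonicity by isotonic projection and interpolates
  linearly onto the 0.1 Mb grid; smoothing exists only to remove noise, and
  monotonicity is the binding requirement. Synthetic maps are generated
  noise-free and fitted with smoothing disabled, which keeps totals exact.
  Whether the additive constant is applied before or after smoothing is not
  prescribed anywhere; we apply it to the smoothed rate.
* Queries outside the mapped physical range are rejected rather than
  extrapolated; gene generation respects the mapped span.
* Coordinates are 0-based, intervals half-open `[start, end)`; a crossover
  at exactly a locus position (measure-zero in continuous space) assigns
  the locus to the right-hand segment.
* Ties in truncation selection break uniformly at random (they are
  measure-zero with continuous phenotypes but matter for degenerate test
  designs).
* Random mating excludes selfing by default (`allow_selfing` switch
  provided): the DH scheme's crossing step implies distinct parents, and we
  mirror that in the Fn scheme.
* No obligate crossover and no cap on crossover number.
* Replicate r of an experiment uses seed `base_seed + r` for its trait
  architecture; each scenario then runs from a seed derived from the
  replicate seed and the scenario index, so scenarios share the trait but
  not meiosis randomness, and every run is reproducible from `base_seed`.
* Interference runs use the per-chromosome `nu` estimates available for the
  diploid (normal) and allotriploid (boosted) landscapes; no estimates
  exist for a HyperRec landscape, so interference experiments compare
  normal vs boosted only.

## Problem sizes

Full-scale comparisons of this kind use on the order of 1000 replicates
per design. The package's
acceptance runs use 100 paired replicates per experiment and thin the
marker panel to 200/chromosome for GEBV computation (gains are not
materially affected; the genome still carries the full QTL architecture).
At that scale the efficiency estimates carry standard errors of roughly
0.02-0.04 on the ratio scale, comfortably inside the comparisons being
made. Unit and property tests run on 2-chromosome uniform genomes with
smaller populations.

## Known limitations

* Single trait, pure additivity: no dominance, epistasis, or
  genotype-by-environment interaction.
* Unsexed, non-overlapping generations with equal family-size expectation.
* The two-pathway interference model (interfering plus non-interfering
  crossovers) is out of scope; single-pathway only.
* Prediction-accuracy decay of the genomic model across generations is
  observable in the trajectories but not analyzed further here.
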