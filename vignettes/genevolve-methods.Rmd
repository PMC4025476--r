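---
title: "Models and methods behind genevolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind genevolve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genevolve)
```

genevolve is a classroom toolkit: its job is to make the standard models of
transmission and population genetics computable, exactly where exactness is
pedagogically important and stochastically where the randomness *is* the
lesson. This vignette documents the models, the parameters that matter, the
numerical choices, and what the simulations do and do not emulate.

## Exact cross enumeration

Loci are biallelic with complete dominance. Every cross probability is a
dyadic rational: each heterozygous locus contributes a factor of 1/2 per
meiosis and loci assort independently. We therefore carry probabilities as
integer numerators over power-of-two denominators and reduce ratio tables
with an integer gcd, so `9:3:3:1` is an identity, not an approximation, and
no floating-point comparison can blur a ratio. The locus cap (default 4,
configurable via `max_loci`) keeps exhaustive enumeration of the up to
`4^k` gamete pairs instantaneous.

Sex is chromosomal (XY) and the Y carries no modeled alleles. One modeling
subtlety: the independence assumption applies *between* loci, but all
X-linked loci of a male necessarily travel together with his single X. A
male's gamete therefore makes one X-versus-Y draw (probability 1/2 each)
that resolves every X-linked locus at once, while autosomal loci still
assort freely. For females, X-linked loci segregate like autosomal ones.
Offspring sex is decided by the paternal gamete, which is also what routes
X-linked alleles: daughters get the father's X allele, sons are hemizygous
for a maternal allele. Phenotype tables pool the sexes when no locus is
X-linked and report sons and daughters separately otherwise — the standard
classroom presentation.

`next_generation()` requires exactly one female and one male. Mass matings
of several selected offspring have no unambiguous single-pair semantics, so
they are deliberately unsupported rather than guessed at.

## Testcross mapping

Problems follow the testcross convention (multiple heterozygote × fully
homozygous recessive) because it is the one design whose offspring
phenotypes read out the heterozygote's gametes directly, making the
count-inspection method well-defined. The solver:

1. pairs each phenotype class with its complement and identifies the
   highest-total pair as parental (fixing the phase) and the lowest as the
   double crossovers;
2. finds the middle locus as the single locus whose allele flips between a
   parental class and the matching DCO class;
3. assigns each single-crossover pair to the interval of the end locus it
   flips, and estimates `r = (SCO + DCO)/n` per interval, capped at 0.5;
4. reports map distance as `100 r` cM with no mapping-function correction
   (Haldane/Kosambi are out of scope: generated problems come from the same
   two-interval model the solver assumes, so a correction would answer a
   different question);
5. reports the coefficient of coincidence `(DCO/n)/(r1 r2)` and
   interference `1 - c` for three-locus problems.

Ties in the parental or DCO identification set an `ambiguous` flag and are
broken lexicographically — the solver never silently guesses. An estimated
`r >= 0.45` flags the interval as likely unlinked, and a 2×2 chi-square test
of independence between the interval's loci is attached, because near 0.5
the point estimate alone cannot distinguish loose linkage from independent
assortment. A gene order and its reversal are the same map, so orders are
canonicalized with the alphabetically first end locus on the left.

The generator draws the true order, per-interval `r` (uniform over
`r_range`, or 0.5 with probability `p_unlinked`), a random phase, computes
the exact eight (or four) class probabilities — parental
`1 - r1 - r2 + c r1 r2`, single crossovers `r_i - c r1 r2`, double
crossovers `c r1 r2`, each split equally within a complementary pair — and
samples counts multinomially (or returns the exact expectations with
`exact = TRUE`, the mode used to verify solver round-trips to machine
precision). The default coefficient of coincidence is 1: no interference,
the simplest defensible classroom assumption, and configurable where an
instructor wants interference problems.

## Selection, drift and inbreeding

The allele-frequency simulator tracks one biallelic locus. Genotype
proportions each generation come from the current `p` and the inbreeding
coefficient `F` (Wright's parameterization `p² + Fpq`, `2pq(1-F)`,
`q² + Fpq`); there is no explicit pedigree — `F` is a standing property of
the mating system, which matches the "expected proportions each generation"
recursion and keeps `F` constant through time. Negative `F` (excess
heterozygosity) is rejected: the parameter is an inbreeding coefficient,
and the excess-heterozygosity regime has different dynamics we do not
model.

With `n = Inf` the recursion is deterministic:
`p' = (P_AA w_AA + P_Aa w_Aa / 2) / wbar`. With finite `n`, the `n`
offspring genotypes are drawn multinomially from the post-selection
expected proportions and alleles are counted. This genotype-sampling drift
is the simulator's contract; at `F = 0` it has the same mean and
one-generation variance `pq/(2N)` as binomial allele sampling (and
`pq(1+F)/(2N)` in general), but it generates every individual, which is
also why very large finite populations are slower than the deterministic
model — trajectories are stored in full, unthinned.

Defaults are chosen as the conditions a genetics class would run: 400
generations, one replicate, `F = 0`, neutral fitnesses. Frequencies 0 and 1
are absorbing; after absorption a replicate is held at the boundary (the
trajectory keeps its full length so replicate sets stay rectangular) and
the absorption generation is recorded. Each replicate runs on an
independent seed substream derived from the master seed, so single
replicates are individually reproducible.

What the simulator does *not* emulate: mutation, migration, two-locus
selection, age structure, or effective-size corrections. Passing tests on
this model therefore validate the sampling scheme and the selection
recursion, not the fit of any real population to them.

## Hardy–Weinberg statistics

Allele frequencies are estimated by counting (`p = (2n_AA + n_Aa)/(2n)`),
expected counts are `n(p², 2pq, q²)`, and the goodness-of-fit chi-square
uses 1 degree of freedom: three classes, minus one for the total, minus one
for the estimated allele frequency. No continuity correction is applied —
besides being the usual genetics-course convention, this preserves the
exact identity `χ² = n F̂²` with `F̂ = 1 - O_Aa/E_Aa`, which the tests check
against brute-force arithmetic on random count triples. A monomorphic
sample yields `χ² = 0` with `F̂` unavailable and a warning; expected counts
below 5 set a flag rather than refusing the test, since the user may well
be a student told to compute it anyway. The test's nominal size is verified
empirically: simulating 10,000 multinomial Hardy–Weinberg samples at
`n = 200`, `p = 0.5` rejects at the 5% level in 5% ± 1% of runs.

## Calculators

The Breeder's equation solver treats `h²` as an opaque heritability in
`[0, 1]`; which variance ratio it denotes (narrow- versus broad-sense) is a
substantive question the calculator cannot settle, so it enforces only the
algebra `R = h²S`. Growth is the continuous-time exponential model
`N_t = N₀ e^{rt}` — the convention implied by offering birth and death
*rates* (`r = b - d`) — not discrete geometric growth. Degenerate requests
(solving `h²` at `S = 0`, solving `t` at `r = 0` with `N_t ≠ N₀`) are
errors with explicit messages, not NaNs.

## Quiz engine and problem batches

Term banks are JSON — an array of `{term, definition}` objects, optionally
wrapped in a `{version, entries}` envelope — loadable from a file or URL so
an instructor can host a class-specific bank. The bundled
`starter_terms.json` is a small synthetic bank of standard genetics terms
written for this package. Distractors are drawn uniformly without
replacement; no semantic-similarity weighting is attempted.

`generate_batch()` spawns one independent seed per item from the master
seed, so an instructor can regenerate item 37 of a 100-problem batch
without touching the rest, and batch files serialize byte-identically under
a fixed seed. Answer checking compares each field independently at explicit
tolerances recorded in the batch metadata (absolute 0.005 on recombination
fractions, relative 10⁻³ elsewhere), accepts a reversed gene order, and
compares phase as an unordered pair.

## Problem sizes used in the test suite

The suite verifies the cross engine against an independent brute-force
gamete-pair enumeration for random crosses of up to 3 loci; mapping order
recovery over 500 seeded problems at `n = 2000` offspring; drift moments
with 20,000 one-generation draws and 1,000–2,000 replicate trajectories at
`N = 20`; and the Hardy–Weinberg type-I error over 10,000 simulated
samples. These sizes give Monte-Carlo standard errors comfortably inside
the asserted tolerances (each stochastic assertion states its 3–4 SE band)
while the whole suite runs in under a minute.

## Known limitations

- No incomplete dominance, codominance, multiallelism or epistasis; no
  linkage between loci in the cross simulator (linkage lives in the mapping
  module's two- and three-locus model only).
- Mapping supports at most three loci and testcross designs; F2 intercross
  mapping and mapping functions are out of scope.
- The drift model is a single locus with constant `N` and `F`; absorption
  is permanent because mutation is absent.
- X-linked Hardy–Weinberg and exact (small-sample) HW tests are not
  provided.
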