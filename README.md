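# genevolve

Teaching-oriented simulations, solvers and problem generators for
transmission and population genetics. The package targets instructors and
students of introductory genetics courses: it enumerates Mendelian crosses
exactly, solves and generates testcross mapping problems, simulates allele
frequencies under selection, drift and inbreeding, tests genotype counts
against Hardy–Weinberg expectations, solves the Breeder's equation and the
exponential growth model, and runs a customizable four-option terminology
quiz. Every stochastic component is seeded, so any problem set or simulation
can be regenerated exactly.

## The models

**Crosses.** Loci are biallelic with complete dominance, autosomal or
X-linked (XY sex determination; the Y carries no modeled alleles), and
assort independently. Offspring distributions are computed by exact
enumeration of gamete pairs with dyadic-rational probabilities, so ratios
such as 3:1 and 9:3:3:1 are reduced bit-exactly, never estimated.

**Mapping.** Testcross problems (multiple heterozygote × fully recessive)
are solved by the classic count-inspection method: the most frequent
complementary phenotype classes are the parental gametes and fix the phase,
the rarest pair are the double crossovers (DCO) and identify the middle
gene, and each interval's recombination fraction is
*r = (SCO + DCO)/n*, with map distance 100·*r* cM, coefficient of
coincidence *c = (DCO/n)/(r₁r₂)* and interference 1 − *c*.

**Population genetics.** One biallelic locus with genotype fitnesses
(*w*<sub>AA</sub>, *w*<sub>Aa</sub>, *w*<sub>aa</sub>) and inbreeding
coefficient *F*. Genotype proportions are *p*² + *Fpq*, 2*pq*(1 − *F*),
*q*² + *Fpq*; the deterministic recursion is
*p′* = (*P*<sub>AA</sub>*w*<sub>AA</sub> + ½*P*<sub>Aa</sub>*w*<sub>Aa</sub>)/*w̄*.
In a finite population of size *N* each generation draws the *N* offspring
genotypes multinomially from the post-selection expected proportions and
counts alleles — genotype-level sampling, not binomial allele sampling.

**Statistics and calculators.** The Hardy–Weinberg fit is a chi-square
goodness-of-fit on 1 df with *F̂* = 1 − *O*<sub>Aa</sub>/*E*<sub>Aa</sub>
(and the exact identity χ² = *nF̂*²); the Breeder's equation is
*R* = *h*²*S*; growth is *N*<sub>t</sub> = *N*₀*e*<sup>rt</sup> with
*r* = *b* − *d*.

## Worked example

```r
library(genevolve)

cross("AaBb", "AaBb", locus_set(2))
#> <cross_result> AaBb (female) x AaBb (male), 2 locus/loci
#> Phenotype ratio:
#>   pooled: 9:3:3:1  (AB : Ab : aB : ab)
#> Genotype ratio:
#>   pooled: 4:2:2:2:2:1:1:1:1  (AaBb : AABb : AaBB : Aabb : aaBb : AABB : AAbb : aaBB : aabb)

solve_threepoint(mapping_problem(c(ABC = 360, abc = 360, aBC = 40, Abc = 40,
                                   ABc = 90, abC = 90, AbC = 10, aBc = 10)))
#> <mapping_solution> order: A - B - C
#>   phase: ABC/abc
#>   A-B: r = 0.1000 (10.00 cM)
#>   B-C: r = 0.2000 (20.00 cM)
#>   coincidence = 1.0000, interference = 0.0000

hw_test(c(50, 30, 20))
#> Hardy-Weinberg goodness-of-fit
#>   counts (AA, Aa, aa): 50, 30, 20   n = 100
#>   p = 0.6500, q = 0.3500
#>   expected: 42.25, 45.50, 12.25
#>   chi-square = 11.6049, df = 1, p-value = 0.0006578
#>   inbreeding coefficient F = 0.3407
```

The dihybrid ratios are exact rationals (16ths); the mapping solution reads
gene order, phase and both map distances off the counts; the
Hardy–Weinberg result shows a significant heterozygote deficit
(*F̂* ≈ 0.34). Trajectories from `simulate_drift()` are tibbles with
`tidy()`, `glance()` and `autoplot()` methods:

```r
ts <- simulate_drift(0.5, c(0.98, 1, 1), n = 50, replicates = 4,
                     generations = 250, seed = 11, allele = "a")
glance(ts)        # per-run summary: fixation proportions, final mean frequency
autoplot(ts)      # the four trajectories
```

## Command line

A thin dispatcher (`inst/cli/genevolve`, exported as `cli_main()`) exposes
every tool: `cross`, `map solve`/`map generate`, `simulate`, `hw`,
`breeders`, `growth`, `quiz`, `generate`, `check`. Example:

```sh
Rscript inst/cli/genevolve simulate --p0 0.5 --wbb 0.98 --N 50 \
    --generations 250 --replicates 4 --seed 11 --out traj.tsv
Rscript inst/cli/genevolve hw --counts 50,30,20
```

Genotype string syntax (EBNF): `genotype = locus, { locus }` where
`locus = allele, allele | allele, "-"`; the dash form is a hemizygous male
X-linked locus, and each `allele` is the locus's single-character dominant
or recessive symbol (uppercase/lowercase of the locus name by default).

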