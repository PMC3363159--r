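---
title: "Mixed-model single-locus GWAS: models, simulator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model single-locus GWAS: models, simulator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmragwas)
```

This vignette documents the statistical models implemented in `mmragwas`,
the assumptions behind them, the design of the synthetic-population
generator, and the numerical and design choices that were genuinely open.

## The analysis chain

The pipeline runs in a fixed order: restrict genotypes to the analysis set
(parents plus phenotyped progeny), marker QC, REML variance components,
the per-SNP mixed-model scan, the permutation threshold, and LD-block
calling among the declared SNPs. QC precedes everything else because the
minor-allele coding and the monomorphic-marker set are defined on the
analysis individuals, not the full population.

## Relationship matrix and REML

The additive relationship matrix is built densely by the tabular method:
`a_ii = 1 + a_{s,d}/2`, `a_ij = (a_{j,s} + a_{j,d})/2` for earlier `j`,
with unknown parents contributing zero. Unknown parents are treated as
unrelated, non-inbred founders — the standard convention, and exact for a
two-generation design whose founders are unrelated by construction. A dense
matrix of 3,220² entries (~80 MB as doubles) is unproblematic at this
scale, so no sparse inverse (Henderson's rules) is used; simplicity and
direct testability win over peak performance.

The animal model `y = 1μ + Za + e` has one random effect, so REML reduces
exactly to a one-dimensional problem: with `K = ZAZ′ = UDU′` computed once,
the marginal covariance is `V = σe²(λK + I)` and, after rotating `y` and
the intercept by `U′`, the observations are independent with weights
`1/(λd_i + 1)`. The residual variance is profiled out analytically; the
profiled restricted log-likelihood is maximised over `log λ` by Brent
search on `λ ∈ [1e-6, 1e3]` with tolerance 1e-6. This is preferred to
iterative EM/AI-REML because it is exact, fast (one eigendecomposition of
the 2,000 × 2,000 phenotyped block), and easy to verify against a dense
brute-force evaluation of the REML criterion — which the test suite does.

Two boundary situations are handled explicitly. If `ZAZ′` is numerically
indistinguishable from the identity (no relatedness among phenotyped
individuals), σa² and σe² are not separately identifiable and the fit
errors rather than returning an arbitrary split. If the likelihood is
maximised at λ → 0, the additive variance is clipped to the boundary and
flagged (`boundary = TRUE`) instead of erroring: under a true null, REML
estimates are the familiar 50:50 mixture of exact zeros and small positive
values, and permutation runs must tolerate such fits.

## The association scan

Each SNP enters as a fixed regression `y = 1μ + bx + Za + e` with the
variance components *fixed* at the no-SNP REML estimates — the P3D/EMMAX
strategy. Re-estimating components per SNP would multiply cost by the
marker count for negligible gain at these effect sizes; fixing them is also
what makes a 10,000-permutation run feasible. The Wald statistic
`b̂²/Var(b̂)` is referred to the upper tail of chi-square(1); no
genomic-control inflation adjustment is applied.

The scan reuses the REML eigendecomposition: rotating the phenotypes and
every genotype column once turns each SNP into a weighted two-covariate
regression, algebraically identical to solving Henderson's mixed model
equations per SNP (the suite asserts agreement with both the MME and a
brute-force GLS to 1e-8). Monomorphic columns cannot occur after QC on the
same individual set; if the scan is invoked standalone on unfiltered data
they yield flagged `NA` records rather than aborting the run.

## Permutation threshold

Phenotype values are permuted uniformly among the phenotyped individuals;
genotypes and pedigree stay fixed, so the permutation null preserves the
marker LD structure while breaking marker–trait association. Each permuted
genome is rescanned and the largest Wald statistic kept; the genome-wide
threshold at level α is the `⌈(1−α)·n_perm⌉`-th smallest of these maxima,
with significance requiring strict exceedance. This order-statistic
convention is one defensible reading of "the 95th percentile" and is stated
in every output file so results are reproducible.

Variance components are *not* re-estimated inside permutations: under a
permuted (null) trait the additive variance would collapse to the boundary
anyway, and reusing the observed-data estimates keeps every permutation a
pure rescan. Note one consequence, verified in the tests: because a raw
permutation of `y` also destroys the family covariance that the mixed
model assumes, the per-SNP Wald test is mildly *conservative* against this
null — which is the safe direction for a family-wise threshold. Exact
calibration of the Wald test itself is checked against the model-faithful
null (phenotypes drawn from the fitted animal model), where rejection at
nominal 5% is spot-on.

Per-permutation RNG streams are derived from `seed + permutation index`,
so the null vector is bit-identical whatever the worker count.

## LD blocks

D′ between significant SNPs is computed from unphased genotypes: two-locus
haplotype frequencies by EM (double heterozygotes split between coupling
and repulsion in proportion to current estimates, starting from linkage
equilibrium, convergence at 1e-8 or 1,000 iterations), then
`D′ = |D|/Dmax` with the usual allele-frequency normalisation. The
confidence interval normalises the multinomial likelihood of the nine
genotype classes over a D′ grid (step 0.01, allele frequencies fixed at
their estimates, the sign of D at its point estimate) and reads the 5th and
95th cumulative points — the one-sided 95% bounds the Gabriel criteria use.
The LOD score is the base-10 likelihood ratio of the EM estimate against
D = 0.

Gabriel thresholds are fixed at the Haploview defaults (strong LD:
CI ≥ 0.70/0.98; strong recombination: upper bound < 0.90; informative
fraction ≥ 0.95) and exposed as arguments. Haploview's extra
marker-count-specific CI rules for very short blocks are deliberately *not*
replicated; the core criteria are applied uniformly, and qualifying
intervals are selected greedily, longest span first, leftmost on ties. The
greedy scan is verified against exhaustive enumeration of all candidate
intervals for panels up to 12 SNPs. Phased truth from the simulator is
never used in the LD computation itself, only as a test oracle.

## The synthetic-population generator

The generator emulates a two-generation half-sib design: 20 sires × 10 dams
each × 15 progeny (10 phenotyped) under the defaults, i.e. 3,220
individuals, 2,000 phenotype records, and 5 chromosomes of 1 Morgan
carrying 1,998 evenly spaced SNPs each (SNP `k` at
`k·length/m` Morgan — the generator defines its own map convention and
records it in the `.map` output).

*Founder LD.* Founder chromosomes are mosaics over a pool of 10 ancestral
haplotypes: the template index switches between adjacent SNPs with
probability `1 − exp(−0.05 · d_cM)` (mean segment ~20 cM) and ancestral
allele frequencies are uniform per SNP. This cheap mechanism yields three
features of the real panel at once — long-range LD that decays with map
distance, a sizeable monomorphic fraction (~18–29% depending on the draw;
SNPs fixed in the 10-template pool plus those lost in the finite founder
sample), and realistic allele-frequency spectra — without forward-in-time
burn-in. It does not emulate fine-scale recombination hotspots or
mutation–drift equilibrium; conclusions about block *sizes* in real data
should not be read off the simulator.

*Transmission.* Gametes recombine under the Haldane map function
(crossover probability `0.5(1 − e^{−2d})` between adjacent SNPs); crossover
events are sampled sparsely per interval, which is exact because the
per-interval indicators are independent. Parental origin is tracked so
imprinted effects are well-defined.

*Trait architecture.* The default QTN set mirrors a workshop-style design:
one large additive QTN on chromosome 1, two additive QTN in coupling phase
on chromosome 2 (both effects positive), two in repulsion on chromosome 3
(opposite signs), one paternally expressed imprinted QTN on chromosome 4,
and one epistatic pair on chromosome 5 (effect requires allele 2 at both
loci). True effect sizes were never published, so the defaults are chosen
to make the chromosome 1 QTN explain roughly 8–10% of phenotypic variance
and the others 2–4% each; everything is configurable. Coupling/repulsion is
encoded through effect signs, with the realised haplotype phase emerging
from the founder LD.

*Variance calibration.* Given the empirical QTN variance `V_q`, the total
genetic variance is `V_q/(1 − polygenic_fraction)` (default fraction 0.3),
the polygenic variance makes up the difference, and the residual variance
is solved so genetic/total equals the target h² = 0.30. Polygenic values
follow the infinitesimal model down the pedigree (founders
`N(0, σ_poly²)`, offspring midparent plus Mendelian sampling of variance
`σ_poly²/2`; parents here are non-inbred). If the architecture carries no
QTN variance, the polygenic variance is fixed at 1 trait unit² to set the
scale. The phenotyped subset (10 of 15 per dam) is drawn uniformly at
random with the run's seed; how the original workshop chose its subset was
never stated.

All randomness flows from a single `seed` in the configuration, so any
simulated population is exactly reproducible.

## What the tests show — and what they do not

The oracle tests (coancestry recursion, dense REML, GLS/MME, gamete
counting, exhaustive interval enumeration) establish that each
computational core computes what it claims, exactly or to stated
tolerances. The statistical tests run at deliberately reduced sizes so the
default suite stays fast: parameter recovery uses 20 replicate default
populations (h² within ±0.05 of 0.30 on average), type-I calibration uses
1,000 model-faithful nulls at n = 200, family-wise error uses 100 null
genomes of 100 SNPs with 100 permutations each, and the end-to-end
detection/non-detection checks use 3 × 100-SNP genomes with 100
permutations. These sizes give the stated Monte-Carlo margins; they do not
demonstrate power at biobank scale, nor do passing tests on simulated
mosaic-LD genomes guarantee block behaviour on real haplotype structure.

Known limitations, by design: single-trait, intercept-only fixed effects,
no dominance/imprinting/epistasis terms in the *analysis* model (the
simulator generates them precisely so the scan's blindness to them can be
demonstrated), no missing-genotype handling (the design genotypes everyone
completely), no genomic relationship matrices, and no FDR-style multiple
testing — the permutation threshold controls the family-wise error rate
instead.
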