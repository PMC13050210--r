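---
title: "Genomic mating with crossplan: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic mating with crossplan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossplan)
```

## The problem

A breeding program advances by crossing selected parents, growing each
family to some evaluated generation (inbred lines, doubled haploids, clones,
or testcross hybrids), and selecting within families. Designing the mating
plan therefore needs, for every candidate pair of parents, a prediction of
the *family mean* and the *within-family variance* of the evaluated
generation, combined in the usefulness criterion

$$U_F = E(g_F) + i_F\, r\, \sqrt{\mathrm{Var}(g_F)},$$

with $i_F$ the within-family selection intensity and $r$ the accuracy of the
marker effects. Maximizing average usefulness alone depletes additive
variance, so the plan is optimized subject to a cap on the *proportion of
additive standard deviation lost* (PropSD), an interpretable diversity
metric: under fixed intensity and accuracy, next-cycle response scales by
$(1 - \mathrm{PropSD})$.

crossplan implements this pipeline for diploids and autotetraploids under
dominance, with a meiosis simulator as an internal Monte-Carlo oracle.

## Family mean and per-locus variances

Genotypic values follow the *genotypic parameterization*: for dosage class
$k$ at locus $j$, the class value is $m(k)\,a_j + w(k)\,d_j$ with the count
score $m(k) = k$ and, for diploids, the heterozygosity indicator
$w = (0, 1, 0)$. The same machinery accepts the breeding parameterization
(breeding values and dominance deviations) by supplying the corresponding
scores and effects; a `class_value_map` carries both score vectors.

For each locus, the package composes exact genotype-class distributions of
the evaluated generation: gamete distributions of both parents (binomial for
diploids; for autotetraploids a hypergeometric draw of 2 of the 4 homologs —
random bivalent pairing, polysomic inheritance, no double reduction), their
convolution for the F1, a per-class Markov recursion for each selfing
generation, gamete pooling for doubled haploids, and convolution with the
tester's gametes for testcross hybrids. The family mean is the sum of the
per-locus means of the class values; the per-locus variance, additive and
dominance components, and their correlation $\rho_{F,j}$ come from the same
distributions. Because these distributions are exact, means are exact up to
the meiosis model, for any scheme, ploidy and parameterization; the
classical two-population F1 formula (exposed as `falconer_f1_mean()` for
comparison only) is not, and the simulator adjudicates the discrepancy in
the test suite.

There is no canonical polysomic dominance score: crossplan refuses a silent
tetraploid default and the synthetic-data module passes
$w(k) = 4k(\phi-k)/\phi^2$ explicitly, which counts heterozygous allele
pairings and reduces to the diploid indicator at $\phi = 2$.

## Genome-wide variance: three LD models

The genome-wide family variance adds cross-locus covariances of genotypic
effects on top of the per-locus variances. Writing $s_j$ for the per-locus
standard deviations, the quadratic form $\mathrm{Var}(g_F) = s^\top C_F s$
needs the between-locus correlation matrix $C_F$ of the family. (The
quadratic form is dimensionally consistent only in standard deviations;
the package never squares them here.) Three models of $C_F$ are offered:

* **independent** — $C_F = I$: the sum of per-locus variances; fast, ignores LD.
* **approx** — source-population LD propagated to the family. Per
  subpopulation, per-locus genotypic effect columns
  $m(M_{ij})a_j + w(M_{ij})d_j$ are centered and their $n$-scaled
  cross-product taken as $\Sigma_k$; the family covariance is initialized at
  the F1 as $\tfrac12(1-2c)\odot(\Sigma_k + \Sigma_l)$, with $c$ the
  recombination-fraction matrix, and carried through the scheme by the
  recursion below.
* **full** — parent-specific LD from phased haplotypes (trivial phase for
  fully homozygous parents). Phase carries purely additive information, so
  cross-locus dominance terms enter through per-locus path coefficients
  $\rho_{F,j}$: the covariance between dominance effects at two loci is
  $\rho_{F,j_1} C_{a,F}[j_1,j_2] \rho_{F,j_2}$ times the dominance SDs, and
  the same-locus dominance term is corrected so that a single-locus family
  reproduces the per-locus variance exactly.

### LD propagation across generations

How much of the parental association between two loci survives to the
evaluated generation depends on the scheme. Published treatments typically
defer these coefficients to external references; crossplan derives them
from first principles as a two-state recursion and validates them against
its own meiosis simulator (the arbiter in the test suite). For a pair of
loci with recombination fraction $c$, track

* $P$: association between alleles on the *same* homolog, and
* $Q$: association between alleles on *different* homologs of one individual.

One round of meiosis plus syngamy maps, elementwise in $c$:

| step | diploid | autotetraploid |
|---|---|---|
| selfing | $P' = (1-c)P + cQ$, $Q' = (P+Q)/2$ | $P' = (1-c)P + (c/3)Q$, $Q' = P/2 + (5/6)Q$ |
| doubled haploid | $P' = Q' = (1-c)P + cQ$ | — |

The dosage covariance of a generation is $P + Q$, and the covariance of the
gametes it transmits (the testcross stage) is $(1-c)P/2 + cQ/2$ for
diploids and $(1-c)P/2 + (1+c)Q/6$ for tetraploids. The approx model starts
from $(P_0, Q_0) = (\tfrac12(1-2c)(\Sigma_k+\Sigma_l),\, 0)$; the full model
starts from exact haplotype-level initial conditions (within-parent
same-homolog and cross-homolog associations plus the between-parent term),
kept in factored low-rank form so that a family's variance is a handful of
matrix-vector products against scheme-level coefficient matrices that are
computed once. For fully homozygous diploid parents the full-model
propagation is exact under the no-interference meiosis model — e.g. it
reproduces the closed forms $(1-2c)$ for DH and $(1-2c)/2$ for F2
covariances — which is why predicted SDs track simulated SDs essentially
perfectly when true effects are known.

Recombination fractions come from map distances through the Haldane
function $c = \tfrac12(1 - e^{-2d})$ (no interference), matching the
simulator, so analytic and simulated LD agree by construction. Negative
propagated variances (possible with estimated effects) are clipped at zero
and counted (`attr(, "n_clipped")`); zero-variance loci get zeroed
correlation rows rather than NaNs; $\rho_{F,j}$ is set to 0 whenever
$\sigma_{a,F,j}\sigma_{d,F,j} = 0$, which cannot change any covariance term.

## PropSD

Additive values of a parent set are modeled as $u \sim N(0, G\sigma_a^2)$
with $G$ a ploidy-generalized VanRaden relationship matrix (centered
dosages, pool allele frequencies). The expected sample SD of $u$ has a
closed form by matching a gamma distribution to the first two moments of the
sample variance ($\alpha = E(s^2)^2/\mathrm{var}(s^2)$,
$\beta = \mathrm{var}(s^2)/E(s^2)$, $E(s) = \sqrt\beta\,
\Gamma(\alpha + \tfrac12)/\Gamma(\alpha)$); for $G = I$ this is exactly the
classical $c_4(n)$ unbiasing constant, which the test suite checks to ten
significant digits. Then

$$\mathrm{PropSD} = 1 - E(s_m)/E(s),$$

comparing the selected parents (submatrix $G_m$) with the pool. The scale
$\sigma_a^2$ cancels, so no marker effects are needed — deliberately, since
misestimated effects would mask the fixation of loci they underrate. A
parent repeated across matings is duplicated in $G_m$ once per mating by
default (`weighting = "contribution"`); a `"unique"` mode is provided since
either convention is defensible.

Under random sampling, predicted PropSD is an unbiased predictor of the
Monte-Carlo mean realized loss. Under directional selection it tracks the
loss of *genic* SD but underestimates the loss of *genetic* SD: selection
induces negative LD among causal loci (the Bulmer effect), which a
relationship-matrix summary cannot see. The selection experiment in the test
suite reproduces exactly this signature (realized genetic loss significantly
above prediction, genic loss not, with visibly smaller dispersion).

## Optimization

A mating plan is a multiset of crosses: a *family* is a parent pair, and
replicating its cross enlarges the family, raising $i_F$ — which makes
fitness plan-dependent and the problem non-convex. Fitness is the average
usefulness across families; constraints (fixed total crosses, repeats
on/off, family count, per-parent bounds, pair whitelist/blacklist, tester
sets, and the PropSD cutoff) are enforced by assigning infeasible plans a
large negative sentinel, keeping the search space connected. The search is a
genetic algorithm with elite retention plus simulated-annealing acceptance
of inferior plans into the breeding pool; operators are cross replacement,
single-parent swap, moving a cross between families, and subset-exchange
crossover. Plans are canonicalized (sorted pairs with multiplicities) so
determinism under a seed is testable; an exhaustive enumerator serves as the
optimality oracle on small instances, where the default configuration
attains the optimum in at least 95% of seeded runs. Selection intensity uses
the infinite-population normal approximation $i = \varphi(z)/p$; no
finite-sample correction is applied.

Multi-tester objectives average usefulness over testers with equal weights
(no weighting is prescribed anywhere; equal weights are the symmetric
choice). Under the approx LD model the tester's own cross-locus LD is not
representable at population level and is omitted from the hybrid covariance;
the full model includes it exactly from the tester's phase.

## Synthetic data: the stated world

The reference simulation mirrors a realistic LD-rich breeding panel: 1,000
loci on 8 chromosomes of 150 cM (evenly spaced — spacing is otherwise
unspecified), allele frequencies uniform on $[0.05, 0.95]$, and founder
haplotypes generated as a Markov chain along each chromosome targeting an
adjacent-locus correlation of 0.95, capped at the Fréchet bound implied by
the two frequencies. The diploid dataset has two independent subpopulations
(heterotic-pool analogs): per pool, 200 haplotypes are paired into founders,
50 random crosses are made, and each F1 is converted to one doubled haploid,
giving 50 fully homozygous phased lines per pool. The autotetraploid dataset
assembles 400 founder haplotypes into 100 tetraploid founders and performs
100 random crosses, giving 100 heterozygous phased genotypes. Marker effects
for two traits (yield, maturity) are drawn at 250 QTL from a bivariate
normal with cross-trait correlation 0.3; dominance effects are drawn at half
the additive scale (the dominance/additive ratio is not otherwise pinned
down; 0.5 gives substantial but not dominant dominance variance).

Estimated-effect settings reproduce stated properties, not algorithms, so
the constructions are the package's own: `QTL_1` adds a random null-space
perturbation of the parental design (identical parental values, different
per-locus effects). `QTL_0.7` and `Markers_0.7` model how estimated effects
arise in practice: parental phenotypes are the true values plus Gaussian
error, marker effects are estimated on the QTL (resp. the non-QTL) score
columns by ridge BLUP with the penalty fixed by the implied heritability
(the rrBLUP equivalence λ = (1−h²)/h² times the summed score variance), and
the phenotype noise is scaled by bisection until the parental
estimated-vs-true correlation is 0.7 ± 0.005. Shrinkage matters here: a
minimum-norm fit of noisy values would book estimation noise as marker
effects and distort the family-variance landscape far more than genomic
prediction actually does, while BLUP spreads effects along LD tracks.
Validation pairs are drawn panel-wide for non-hybrid scenarios (hybrid
scenarios pair within one pool against an opposite-pool tester); the 0.7
calibration refers to the whole panel, so restricting crosses to one pool
would silently lower the effective accuracy the scenario sees.

Because crossing two inbred lines yields a non-segregating F1, a clonal
scenario is only informative on heterozygous parents; for fully homozygous
diploid panels the validation harness derives clone parents as F1 hybrids of
panel lines (`make_clonal_panel()`), which is also how clonal crops look in
practice. Hybrid scenarios draw pairs within one pool and testcross to a
tester from the opposite pool (within/across-pool sampling is not specified;
this choice mirrors reciprocal hybrid breeding).

What a green validation run does *not* establish: the generator has no
mutation, no selection history (so no pre-existing negative LD — Bulmer
equilibrium is deliberately absent, which is exactly why the selection
experiment shows genetic losses above prediction), equal-length chromosomes,
no genotyping error, and complete data. Conclusions about real panels with
strong population structure beyond two pools, or maps with interference, are
outside what the tests demonstrate.

## Numerical choices and limitations

* Haldane mapping (no interference) everywhere, for consistency between
  analytics and simulator; sex-averaged single map.
* Missing genotypes are rejected, not imputed: every formula assumes
  complete data.
* Degenerate gamma in the expected-SD estimator
  ($\mathrm{var}(s^2) \to 0$, or $\alpha$ so large that the gamma ratio
  overflows) falls back to $\sqrt{E(s^2)}$.
* Selfing of a family is modeled per individual (single-seed descent),
  matching the per-class Markov recursion; the simulator carries every
  intermediate individual.
* Unphased heterozygous parents get a uniformly random consistent phase in
  the simulator, with a warning; the analytic full model refuses them.
* The dominance path rule in the full model is an approximation for
  heterozygous parents under selfing (exact per-locus, approximate
  cross-locus); empirically its residual bias is within Monte-Carlo error in
  the oracle tests.
* Usefulness uses the SD convention; a `literal_var` switch exposes the
  variance convention for comparison.
* Out of scope: epistasis, multi-trait selection indices, crossover
  interference, double reduction, aneuploidy, ROH-based inbreeding, exact
  integer programming for the plan search.
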