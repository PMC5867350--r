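---
title: "Methods: karyotype divergence and chromosome-number evolution on phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: karyotype divergence and chromosome-number evolution on phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyevol)
```

karyevol implements a comparative-cytogenetics workflow for groups of
species known from classical karyotyping: diploid number (2n), a pooled
karyotype formula (bi-armed meta-/submetacentric vs uni-armed
subtelo-/acrocentric chromosomes), and C-banded constitutive
heterochromatin (CH) sites. This vignette is the package's account of the
models, conventions and numerical choices; every number quoted here is
produced by code in the package's examples, tests or acceptance script.

## Karyotype divergence

The divergence index between two karyotypes is

$$D = \tfrac{1}{2}\,|\Delta 2n| + \tfrac{1}{2}\,|\Delta FN|,$$

with the fundamental number FN = 2n + (bi-armed count): bi-armed
chromosomes carry two arms, uni-armed one. Because the karyotype formula
pools centromere classes into `m-sm` and `st-a`, no finer arm convention
is expressible, and we made that pooling the type's invariant
(`biarmed + uniarmed == 2n`). The index is reported in raw units
(chromosome-pair changes). Some published analyses print it as a
percentage; we found no normalization that reproduces such percentages
together with the raw zero values, so the package reports raw units and
leaves any rescaling to the caller. $D$ is a semimetric: symmetric,
non-negative, and zero exactly when both 2n and FN agree — so it is blind
to rearrangements (e.g. reciprocal translocations, paracentric
inversions) that change neither.

Species with multiple sex chromosome systems have odd male diploid
numbers; interspecific comparison uses the female complement by default
(even and homomorphic), with `prefer = "male"` available. The example
data set's two conserved sister pairs give index 0 either way.

UPGMA phenograms are built by average-linkage clustering of the index
matrix with merge height $d/2$, so identical karyotypes form zero-height
cherries. Taxa are sorted alphabetically first, which makes tie-breaking
deterministic. An optional `"euclidean"` mode first re-embeds each
taxon's matrix row as a coordinate vector and clusters Euclidean row
distances, the convention of clustering front-ends that accept a
distance matrix as if it were data; the direct mode is the default since
the divergence matrix already is a distance.

## Trees

Input trees are rooted newick topologies with optional internal labels.
Analyses prune to the taxa with data and then assign Grafen branch
lengths: node height $((d-1)/(n-1))^\rho$ for a node with $d$ descendant
leaves out of $n$, leaves at height 0, the root at exactly 1, with
$\rho = 1$ unless overridden (the classical reference for this
transformation gives no exponent; 1 is its default). All downstream rates
are therefore "per root-depth" units.

## Brownian-motion ancestral states and phylogenetic signal

Diploid number is treated as a continuous character under Brownian
motion. Joint ML ancestral states solve the edge-weighted Laplacian
system (weights $1/t_e$) — the sparse form of the re-rooted
weighted-average recursion — and coincide with the GLS reconstruction
from the full phylogenetic covariance matrix; the test suite asserts
equality against an explicit covariance-inversion oracle to 1e-8. The
rate $\hat\sigma^2$ is the ML estimate (standardized-contrast sum of
squares over $n$), per-node variances are the conditional variances of
the ancestral value given the tips scaled by $\hat\sigma^2$, and 95%
intervals use the 97.5% normal quantile (1.959964). A widely used
reference implementation scales by the REML rate (over $n-1$); the
cross-check test pins down that exact $n/(n-1)$ relationship. Zero-length
branches are replaced by 1e-8 of tree height with a warning, and missing
tips are pruned, never imputed.

Pagel's $\lambda$ multiplies off-diagonal covariances; the profile
likelihood is maximized on $[0, \lambda_{max}]$ with
$\lambda_{max} = \max C_{ii} / \max_{i \ne j} C_{ij}$, which keeps the
transformed covariance valid and allows $\hat\lambda$ slightly above 1
when terminal branches permit — on ultrametric trees with signal the
optimum often sits in a narrow spike just below $\lambda_{max}$, so the
search scans a grid densified geometrically toward the boundary before a
local bounded optimization (tolerance 1e-8). The p-value is a
$\chi^2_1$ likelihood-ratio test against $\lambda = 0$ (independent
tips), the natural no-signal null. Blomberg's K is the observed
MSE$_0$/MSE ratio over its Brownian expectation on the same tree; its
p-value is a one-tailed permutation test on MSE with the add-one rule
$(b+1)/(m+1)$, 1000 permutations by default and a mandatory seed.

## Chromosome-number CTMC

Haploid number evolves on the bounded integer space
$[n_{min}, n_{max}]$, by default $\max(1, \min_{obs} - 10)$ and
$2\max_{obs} + 10$ so that duplication targets of observed states are
never truncated. Eight families combine single-step gains (fissions) and
losses (fusions) — constant or linear in the state,
$r(n) = c + \beta\,(n - n_{min})$ clamped at 0 — with optional
duplication ($n \to 2n$) and demi-duplication ($n \to 1.5n$, odd states
splitting the rate between floor and ceiling targets; tied to the
duplication rate except in the `DEMI_EST` families). Transitions leaving
the space are truncated into the diagonal, so rows always sum to zero.

The likelihood is Felsenstein pruning with dense scaling-and-squaring
matrix exponentials, cached per unique branch length (Grafen trees have
few). At the root, conditional likelihoods are combined with
data-weighted frequencies (each state weighted by its own normalized
conditional likelihood), the ML-style convention of chromosome-number
reconstruction tools; a flat prior is available and the choice is
recorded in output provenance. Fitting maximizes over log-rates (slope
terms on the natural scale, since they may be negative) by bounded
L-BFGS-B from 10 Latin-hypercube starts plus one moderate anchor start,
keeping the best optimum; AIC = $2k - 2\log L$, lowest wins, ties go to
the smaller parameter count. Marginal ancestral states come from the
standard two-pass algorithm and are exact against an exhaustive
enumeration oracle to 1e-10 in tests; reported diploid values are exactly
twice the argmax haploid state. Note that when the marginal posterior is
nearly tied between adjacent states — common at deep nodes under
loss-dominated fits — the argmax is a coin-flip summary, which is why the
full posterior is kept in the result object.

Per-branch expected event counts use stochastic mapping: node states are
drawn from their joint conditional distribution, then each branch's path
is drawn exactly, conditional on its endpoints, by uniformization (jump
count from the endpoint-conditioned Poisson mixture, intermediate states
by backward sampling). No rejection is involved, so conditioning on rare
endpoint pairs costs nothing extra; an error is raised only if an
endpoint probability underflows. Monte-Carlo standard errors are
sd/$\sqrt{n_{maps}}$ with 1000 maps by default.

## Rearrangement inference

Between two even diploid numbers, the net event count is
$|\Delta 2n|/2$ Robertsonian fusions (or fissions), each converting two
uni-armed pairs into one bi-armed pair. Pericentric inversions toggle one
pair between uni- and bi-armed without changing 2n: for equal-2n pairs
the count is the absolute difference in bi-armed pair counts, otherwise
the lower-2n karyotype's observed bi-armed pairs are compared against the
higher-2n karyotype's plus the fusion count. This convention reproduces
the worked example's published 17 (brevirostris-hendersoni) and 3
(beebei-hamiltoni, after 2 fusions); for regani-batesi it yields 13 where
the source narrative prints 11 — no single convention we tested
reproduces all three printed counts, so the computed value is reported
and the convention stated in output metadata. Tandem fusions are not
modelled. On trees, fusion/fission counts are annotated per branch from
the reconstructed diploid states; inversions and CH changes are
computed only between sister tips of cherries, because karyotype formulas
are observed only at tips.

## Synthetic data

The generators give every stage a self-contained test surface: Yule trees
rescaled to unit root height (matching the Grafen-prepared empirical
trees); multivariate-normal Brownian tips with tunable $\lambda$;
Gillespie simulation of the bounded chain that records every event (each
branch draws from its own seeded stream derived from the branch's child
node id, so one branch's draws do not depend on traversal order); and
internally consistent random karyotype tables. They emulate the
statistical structure the models assume — ultrametric trees, homogeneous
rates, independent lineages — and deliberately none of the things real
cytogenetic data add (karyotype polymorphism, B chromosomes, rate
heterogeneity, band-size variation), so passing recovery tests
demonstrates correctness of the estimators under their own model, not
robustness to violations.

## Problem sizes and reproducibility

The shipped analyses and tests use sizes a laptop handles comfortably:
the 17-tip example tree with 55 CTMC states, 1000 permutations and 1000
stochastic maps; parameter-recovery studies use 30-100-tip Yule trees
with 100-200 replicates. Every stochastic entry point takes a mandatory
seed, pipeline stages write a JSON provenance block (config, seed,
conventions, package version), and rerunning a stage with the same
configuration reproduces its deterministic outputs byte for byte.

## Worked example

```{r example, eval = FALSE}
res <- run_pipeline(out_dir = "karyevol_out", seed = 1)
res$divergence$matrix["Brachyhypopomus_bennetti",
                      "Brachyhypopomus_walteri"]   # 0
res$asr$signal                                     # lambda ~ 1.02, K ~ 1.41
res$chromevol$selection                            # CONST_RATE_NO_DUPL wins
res$chromevol$events$totals                        # fusions only, ~40 losses
```

On the packaged data set the best-AIC model is `CONST_RATE_NO_DUPL`
(fusion/fission only, no duplication) with the gain rate pinned at its
lower bound: chromosome-number evolution in this group is inferred to be
fusion-driven. The marginal posterior at the genus ancestor is nearly
tied between 2n = 48 and 2n = 50 (0.33 vs 0.35), a tie the source
analysis resolved to 48 and this package's argmax resolves to 50; both
states are reported with their posteriors, and the per-branch fusion
narrative below that node (3 fusions into clade M, 2 into K, 2 on the
hamiltoni branch) is stable.

## Known limitations

Within-species polymorphism, B chromosomes, band sizes, branch-specific
rates, Ornstein-Uhlenbeck alternatives and measurement error are out of
scope. The CTMC state space is truncated, which slightly deflates rates
near its bounds; the defaults keep observed states at least 10 steps from
either bound. Inversion counts between non-sister taxa are pairwise
quantities, not tree-additive reconstructions, because internal karyotype
formulas are unobserved.
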