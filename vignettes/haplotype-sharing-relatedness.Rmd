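---
title: "Haplotype-sharing measures of relatedness: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-sharing measures of relatedness: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapshare)
```

## The model

`hapshare` measures relatedness from the extent of haplotype sharing
rather than from averages of single-SNP statistics. The genome is cut
into `p` intervals; each interval has a set of possible *segments*
(variant DNA strings), and these per-interval sets are disjoint. A
diploid genome is then a multiset of `2p` segments — two per interval,
one from each haplotype — recorded as multiplicities
`x_is ∈ {0, 1, 2}`.

The segmentation is supplied by an acyclic probabilistic finite
automaton (APFA): a leveled directed multigraph with one vertex layer
per interval boundary, a single root and a single sink. Each edge
carries an allele symbol and a transition probability; outgoing
probabilities at every vertex sum to one, so each root-to-sink path is
a haplotype with probability equal to the product of its edge
probabilities. The package identifies **edges with segments**: two
haplotypes that traverse the same edge in an interval are taken to
share the same DNA there. This is a strong assumption — it holds only
as well as the fitted APFA matches true identity-by-state — and it is
the reason segmentations fitted on very small samples (which collapse
too many haplotypes onto shared edges) will overestimate sharing.

Given the N×|E| multiplicity matrix `X` (the haplomarker design
matrix), the two measures are

- intersect: `b_ij = Σ_s min(x_is, x_js) / 2p`, the fraction of shared
  genome, with `b_ii = 1`;
- product: `c_ij = Σ_s x_is x_js / 2p`, i.e. `C = X Xᵀ / 2p`.

For multiplicities in `{0,1,2}`, `xy = 2 min(x,y) − I(x = y = 1)`, so
`C = 2B − κ` with `κ_ij` the fraction of segments heterozygous in both
individuals. Enumerating the four ordered allele pairs per interval
shows that `c_ij` is exactly twice the identity-by-state coefficient of
coancestry and `c_ii = 1 + f_i` with `f_i` the IBS inbreeding
(homozygosity). This is what makes `C` the molecular analogue of the
pedigree numerator matrix `A = (2θ_ij; 1 + θ_i)`, with IBS probabilities
replacing IBD ones.

Both measures are probability-free: they use only edge identities and
multiplicities, so models whose probabilities fail normalization are
still accepted by the combinatorial operations (and rejected by the
ones that genuinely need probabilities, such as path sampling).

## Expectation identities and the simulator

During meiosis a parent genome `G = [H¹ + H²]` is partitioned into two
complementary gametes of `p` segments each, and an offspring receives
one gamete from each parent, the four combinations equiprobable.
Averaging over those four combinations gives, *for any partition
whatsoever*,

```
E(c_ik) = (c_ii + c_ij)/2      E(c_kk) = 1 + c_ij/2     E(f_k) = c_ij/2
E(c_kh) = (c_ih + c_jh)/2      E(b_ik) = E(b_jk) = 1/2 + c_ij/4
```

`exactExpectation()` performs the four-combination enumeration and the
test suite verifies that it matches the closed forms to 1e-12 across
hundreds of random partitions — the invariance is the point, not a
numerical accident. No closed form exists in this framework for
`E(b_kh)` between an offspring and a fourth individual; the package
deliberately offers only Monte-Carlo estimates for it.

Because only partition-invariant properties are used, the simulator's
crossover model can be simple: `makeGametes()` starts on a uniformly
chosen parental haplotype and switches with probability `r`
independently at each of the `p − 1` boundaries. The default
`r = 0.05` corresponds loosely to intervals a few centimorgans apart;
any value in `[0, 1]` satisfies the gamete axioms (`H¹ + H² = G` as
multisets), and none of the exact results depend on it. There is no
crossover interference, no sex-specific map, no mutation or gene
conversion, and one APFA models one chromosome.

## Pedigree-side components

`numeratorMatrix()` is the recursive tabular method: individuals in
topological order (Kahn's algorithm, ties broken by input order so
results are reproducible), `a_kk = 1 + a_ij/2`, `a_kh = (a_ih +
a_jh)/2`, unknown parents contributing 0 — founders are assumed
unrelated and non-inbred. The same recursion run with a genotyped set
`S` fixed to realized values gives the hybrid matrix `R`
(`hybridMatrix()`): `r_ij = c_ij` within S, expectations propagated
downstream. With `S` empty it is `A`; with `S` everyone it is `C`.

`conditionMatrix()` implements the complementary adjustment: regard `A`
as a covariance matrix and replace the marginal covariance of group one
by `A*₁₁` while preserving the conditional covariance of group two.
The contract is the precision-space increment `E = (A*₁₁)⁻¹ − (A₁₁)⁻¹`
added to the group-one block of `A⁻¹`; the implementation uses Cholesky
factorizations (`chol`/`chol2inv`) throughout and treats a failed
factorization as an error rather than silently regularizing.
`consistencyCheck()` repeats this over random group-one draws and
regresses `(A|X₁₁)₂₂` on `X₂₂` off-diagonals: a realized measure
consistent with the pedigree expectation gives a no-intercept slope
near 1.

`vanRadenG()` centers genotype columns by their sample means, which
forces every row of `G` to sum to zero exactly. The scaling denominator
is `Σ_k 2 p̂_k (1 − p̂_k)` with `p̂_k` the sample allele frequency
(mean genotype / 2) — the method-1 scaling, always positive for
polymorphic markers. A variant using the mean genotype in `[0, 2]`
directly is exposed as `denominator = "genotype-mean"` for comparison,
but it can produce a negative denominator and is not the default.
Monomorphic markers are an error unless `dropMonomorphic = TRUE`;
silent NaN propagation would be worse than either choice.

## Numerical choices

- All pairwise sums for `B`, `C` and `κ` are accumulated as integer
  cross products (`X Xᵀ`, `[X=1][X=1]ᵀ`) and divided once by `2p`, so
  `C = 2B − κ` is exact at the count level; after the division it is
  bitwise exact whenever `2p` is a power of two and within one ulp
  otherwise.
- APFA probability normalization is checked to 1e-9; relationship
  matrices must be symmetric within 1e-12; the conditioning contract is
  verified to 1e-8 in tests.
- Canonical edge order is (level, source, target, allele) and generated
  segment ids are `"L{level}E{ordinal}"` (0-based intervals), which
  makes models diff-friendly and file round trips the identity.
  Parallel edges with identical (level, source, target, allele) are
  collapsed on construction: the edge *is* the segment, so duplicates
  can only be a file artifact.
- When a multigraph offers two outgoing edges with the same allele at a
  level, haplotype tracing takes the higher-probability edge
  (lexicographic id as tie-break) and warns; externally fitted models
  resolve this upstream.
- Matrix files are written with 17 significant digits so identities
  survive file round trips bit-for-bit.
- Missing genotypes are a hard error everywhere: the intended pipeline
  phases and imputes before segmentation, and guessing here would
  silently change the measures.

## What the generator emulates — and what it does not

The simulator and the trie-built APFA exist so that every claim in the
package can be exercised end-to-end on data with known truth: founders
drawn as APFA paths, descendants produced by `mate()`, realized `B`/`C`
compared against pedigree expectations (`monteCarloExpectations()`
stratifies by pedigree graph distance). Test problem sizes are chosen
for tight Monte-Carlo bounds at desk scale — e.g. 20-interval genomes,
50-individual pedigrees, 1000 meioses for recovery checks, 100k gene
drops for the IBD oracle — and assertions use 3 standard-error bounds.

What passing these tests shows: the algebra, the recursions, the
expectation identities and the file formats are correct. What they do
not show: that an APFA fitted to real SNP data by haplotype-cluster
model selection yields a segmentation for which the edge-sharing = IBS
assumption holds; that is a property of the fitted model and the
population, not of this implementation. Real analyses should fit the
APFA externally (e.g. a Beagle-3-style DAG ingested by
`readBeagleDag()`); `buildTrieApfa()` is a minimal, deliberately
overfitted stand-in — every training haplotype keeps its empirical
frequency, so sharing between unrelated individuals is
*underestimated*, the opposite bias of an oversimplified model.

## Open design points, resolved

- **Multiple chromosomes.** One APFA models one interval sequence.
  Multi-chromosome data are handled by concatenating per-chromosome
  segment pools with globally unique ids and computing the measures on
  the pooled set (`p` = total intervals); the package does not do the
  concatenation for you.
- **Weighted measures.** `intersectMeasure()`/`productMeasure()` accept
  interval weights `w_1..w_p ≥ 0, Σw = 1` (e.g. proportional to
  inter-marker distance or QTL probability); the weighted forms divide
  by 2 so uniform weights `1/p` reproduce the unweighted measures
  exactly.
- **Distances.** `−log(b_ij)` is a natural dissimilarity for
  principal-coordinates displays; pairs with `b = 0` have infinite
  distance and `principalCoordinates()` refuses them rather than
  imputing.
- **Pedigree distance** is the shortest path in the undirected
  parent–child graph (full/half sibs at 2, first cousins at 4, second
  cousins at 6); note this ignores the number and length of connecting
  lineages, which is exactly why `A` is the better pedigree summary and
  the distance is used only for stratified displays.

## Limitations

Polyploid genomes (multiplicities > 2), gene duplication across
intervals, haplotype-cluster model *selection* (fit your APFA
elsewhere), phasing/imputation, and REML/GBLUP model fitting are out of
scope. `G`-based inbreeding estimates are sensitive to the allele
frequencies used; the package computes sample-frequency `G` only.
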