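# hapshare

Haplotype-sharing measures of genomic relatedness.

Most marker-based relatedness estimators are genome-wide averages of
single-SNP statistics and ignore how long the genomic regions shared by
two individuals are. `hapshare` implements two measures that work at the
haplotype level instead. The genome is divided into `p` intervals; the
variant DNA strings that can occupy an interval are *segments*, and a
diploid genome is a multiset of `2p` segments (two per interval, values
`x_is ∈ {0,1,2}`). The segmentation comes from an acyclic probabilistic
finite automaton (APFA) — a leveled directed multigraph in which every
root-to-sink path is a haplotype and every edge is a segment, the model
family underlying haplotype-cluster methods such as Beagle.

For individuals `i` and `j` with segment multiplicities `x_is`, `x_js`:

- **Intersect measure** `b_ij = Σ_s min(x_is, x_js) / 2p` — the fraction
  of shared genome; `b_ii = 1`, `0 ≤ b_ij ≤ 1`.
- **Product measure** `c_ij = Σ_s x_is x_js / 2p`, i.e. `C = X Xᵀ / 2p`
  with `X` the N×|E| *haplomarker design matrix*. Off the diagonal
  `c_ij` is twice the identity-by-state coefficient of coancestry; on
  the diagonal `c_ii = 1 + f_i` with `f_i` the IBS inbreeding
  (homozygosity). The two are linked exactly by `C = 2B − κ`, where
  `κ_ij` counts segments heterozygous in both genomes.

Around the core measures the package provides the pedigree numerator
relationship matrix `A` (tabular method), vanRaden's `G`, a hybrid
expected/realized matrix `R` for partially genotyped pedigrees, the
conditioning operator `A|A*₁₁` (replace a subgroup's marginal covariance
while preserving conditional covariances) with a consistency-check
procedure, a gene-drop meiosis simulator on segment sequences that
verifies the expectation identities `E(c_ik) = (c_ii + c_ij)/2`,
`E(c_kk) = 1 + c_ij/2`, `E(f_k) = c_ij/2`, `E(c_kh) = (c_ih + c_jh)/2`,
`E(b_ik) = 1/2 + c_ij/4`, and principal-coordinates embedding of the
`−log(b)` distance. Intended users are quantitative/population
geneticists working with phased SNP data and pedigrees.

## Worked example

The classic trio: two parents whose genomes share 30 of the 40 possible
segment pairings (`c_ij = 0.75`), and the offspring expectations checked
against exhaustive gamete enumeration.

```r
library(hapshare)
seg <- function(ord) sprintf("L%dE%d", 0:19, ord)

gi <- Genome("i", seg(0), seg(1))                  # fully heterozygous
gj <- Genome("j", seg(0), c(seg(1)[1:10], seg(2)[11:20]))
C  <- as.matrix(productMeasure(designMatrix(list(gi, gj))))
C["i", "j"]
#> [1] 0.75
(C["i", "i"] + C["i", "j"]) / 2                    # expected c for a child
#> [1] 0.875

set.seed(1)
ex <- exactExpectation(gi, gj, makeGametes(gi), makeGametes(gj))
ex$EcIk                                            # enumeration agrees
#> [1] 0.875
ex$EfK                                             # expected inbreeding
#> [1] 0.375

off <- mate(gi, gj, id = "k")                      # one realized meiosis
genomeHomozygosity(off)
#> [1] 0

h2 <- seg(1); h2[1:9] <- seg(0)[1:9]               # 9 of 20 intervals shared
k  <- Genome("k", seg(0), h2)
as.matrix(productMeasure(designMatrix(list(k))))["k", "k"]
#> [1] 1.45
```

Realized values vary over meioses (this particular one happened to
inherit no matching segments; its expectation is `E(f_k) = 0.375`). An
offspring whose haplotypes share 9 of 20 intervals has homozygosity
0.45 and diagonal `c_kk = 1 + 0.45 = 1.45`: realized inbreeding read
straight off the relationship matrix.

The same computations are available from the shell via the installed
`hapshare` script (`exec/hapshare`), e.g.
`hapshare cmatrix --haplotypes h.tsv --apfa m.tsv -o C.tsv`, with
subcommands for every matrix, the simulator and the comparison
statistics (`hapshare --help`).

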