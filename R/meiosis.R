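## Gene-drop meiosis on segment sequences, exact expectation identities
## and Monte-Carlo summaries.
##
## Segregation is modelled as independent Bernoulli(r) crossovers at
## each interval boundary.  The expectation identities verified by
## exactExpectation() are invariant to the partitioning process, so the
## choice of crossover model does not affect their validity.

#' Simulation configuration
#'
#' @param r per-boundary crossover probability in \[0, 1\].
#' @param seed integer seed (mandatory for stochastic operations).
#' @param replicates replicate count for Monte-Carlo summaries.
#' @return a plain list with class `"SimConfig"`.
#' @export
SimConfig <- function(r = 0.05, seed = NULL, replicates = 100L) {
  if (r < 0 || r > 1) stop("crossover probability r must lie in [0, 1]")
  structure(list(r = r, seed = seed, replicates = as.integer(replicates)),
            class = "SimConfig")
}

#' Partition a genome into two complementary gametes
#'
#' The tracked gamete starts on a uniformly chosen parental haplotype
#' and switches haplotype independently with probability `r` at each of
#' the `p - 1` interval boundaries; the second gamete is the
#' complement, so `H1 + H2` equals the parent genome as a multiset at
#' every interval.  Uses R's current RNG stream.
#'
#' @param genome a [Genome].
#' @param r per-boundary crossover probability.
#' @return a [GametePair].
#' @export
makeGametes <- function(genome, r = 0.05) {
  p <- length(genome@hap1)
  switches <- if (p > 1L) stats::rbinom(p - 1L, 1L, r) else integer(0)
  start <- sample.int(2L, 1L)
  lane <- (cumsum(c(start - 1L, switches)) %% 2L) + 1L   # 1 or 2 per interval
  h1 <- ifelse(lane == 1L, genome@hap1, genome@hap2)
  h2 <- ifelse(lane == 1L, genome@hap2, genome@hap1)
  new("GametePair", h1 = h1, h2 = h2,
      crossovers = which(switches == 1L))
}

#' Mate two genomes
#'
#' Each parent genome is partitioned into two gametes by
#' [makeGametes()]; the offspring receives one uniformly chosen gamete
#' from each parent (the four combinations are equiprobable).
#'
#' @param gi,gj parental [Genome]s over the same segmentation.
#' @param id id for the offspring genome.
#' @param r per-boundary crossover probability.
#' @return a [Genome].
#' @export
mate <- function(gi, gj, id = paste0(gi@id, "x", gj@id), r = 0.05) {
  if (length(gi@hap1) != length(gj@hap1))
    stop("parents have differing interval counts")
  pick <- function(gp) if (sample.int(2L, 1L) == 1L) gp@h1 else gp@h2
  Genome(id, pick(makeGametes(gi, r)), pick(makeGametes(gj, r)))
}

.genomeFromHaps <- function(h1, h2) new("Genome", id = "tmp", hap1 = h1,
                                        hap2 = h2)

.msetOfGenome <- function(g) segmentMultiset(g)

.cTwo <- function(ga, gb) {
  p <- length(ga@hap1)
  msetCardinality(msetProduct(segmentMultiset(ga), segmentMultiset(gb))) /
    (2 * p)
}

.bTwo <- function(ga, gb) {
  p <- length(ga@hap1)
  msetCardinality(msetIntersect(segmentMultiset(ga), segmentMultiset(gb))) /
    (2 * p)
}

#' Exact offspring expectations by gamete enumeration
#'
#' Given fixed gamete partitions of the two parents, averages the
#' offspring relatedness quantities over the four equiprobable gamete
#' combinations by exhaustive enumeration.  The averages satisfy, for
#' any partition whatsoever,
#' `E(c_ik) = (c_ii + c_ij)/2`, `E(c_kk) = 1 + c_ij/2`,
#' `E(f_k) = c_ij/2`, `E(b_ik) = E(b_jk) = 1/2 + c_ij/4` and, for a
#' further individual h, `E(c_kh) = (c_ih + c_jh)/2`: the identities
#' are invariant to how segregation partitioned the parental genomes.
#'
#' @param gi,gj parental [Genome]s.
#' @param partitionI,partitionJ [GametePair]s partitioning `gi` and
#'   `gj` (each must satisfy H1 + H2 = parent as multisets).
#' @param others optional list of further [Genome]s h for which
#'   `E(c_kh)` is averaged.
#' @return list with `EcIk`, `EcJk`, `EcKk`, `EfK`, `EbIk`, `EbJk` and
#'   (when `others` is non-empty) a named vector `EcKh`.
#' @export
exactExpectation <- function(gi, gj, partitionI, partitionJ,
                             others = list()) {
  checkPartition <- function(g, gp) {
    if (!identical(segmentMultiset(g),
                   segmentMultiset(.genomeFromHaps(gp@h1, gp@h2))))
      stop("invalid partition: gametes do not reconstitute the parent ",
           g@id, " as a multiset")
  }
  checkPartition(gi, partitionI)
  checkPartition(gj, partitionJ)
  combos <- list(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))
  acc <- list(EcIk = 0, EcJk = 0, EcKk = 0, EfK = 0, EbIk = 0, EbJk = 0)
  EcKh <- if (length(others))
    stats::setNames(numeric(length(others)),
                    vapply(others, function(g) g@id, "")) else NULL
  for (cb in combos) {
    hi <- if (cb[1L] == 1L) partitionI@h1 else partitionI@h2
    hj <- if (cb[2L] == 1L) partitionJ@h1 else partitionJ@h2
    gk <- .genomeFromHaps(hi, hj)
    acc$EcIk <- acc$EcIk + .cTwo(gi, gk)
    acc$EcJk <- acc$EcJk + .cTwo(gj, gk)
    acc$EcKk <- acc$EcKk + .cTwo(gk, gk)
    acc$EfK <- acc$EfK + genomeHomozygosity(gk)
    acc$EbIk <- acc$EbIk + .bTwo(gi, gk)
    acc$EbJk <- acc$EbJk + .bTwo(gj, gk)
    if (length(others))
      EcKh <- EcKh + vapply(others, function(gh) .cTwo(gk, gh), 0)
  }
  out <- lapply(acc, function(v) v / 4)
  if (length(others)) out$EcKh <- EcKh / 4
  out
}

#' Gene-drop simulation over a pedigree
#'
#' Founders receive two independent root-to-sink haplotype paths
#' sampled from the APFA with their path probabilities; non-founders
#' are produced by [mate()] in topological order.  An individual with a
#' single known parent receives one gamete from that parent and one
#' freshly sampled APFA path on the unknown side.
#'
#' @param apfa an [Apfa] with normalized edge probabilities.
#' @param ped a [Pedigree].
#' @param config a [SimConfig]; its `seed` (when non-NULL) seeds the
#'   RNG before the drop.
#' @return named list of [Genome]s, one per pedigree record.
#' @export
simulatePedigree <- function(apfa, ped, config = SimConfig()) {
  .stopIfNotNormalized(apfa)
  if (!is.null(config$seed)) set.seed(config$seed)
  genomes <- vector("list", length(ped@id))
  names(genomes) <- ped@id
  si <- match(ped@sire, ped@id)
  di <- match(ped@dam, ped@id)
  gamete <- function(parentIdx) {
    if (is.na(parentIdx)) sampleHaplotypePath(apfa)
    else {
      gp <- makeGametes(genomes[[parentIdx]], config$r)
      if (sample.int(2L, 1L) == 1L) gp@h1 else gp@h2
    }
  }
  for (k in ped@order)
    genomes[[k]] <- Genome(ped@id[k], gamete(si[k]), gamete(di[k]))
  genomes
}

#' Marker genotype matrix from simulated genomes
#'
#' Converts segment sequences back to marker dosages by counting, at
#' each interval, the haplotypes whose segment carries the `alt`
#' allele symbol.  Intended for biallelic APFAs (e.g. alleles "0"/"1").
#'
#' @param genomes list of [Genome]s.
#' @param apfa the generating [Apfa].
#' @param alt allele symbol counted as the dosage allele.
#' @return N x p integer matrix of genotypes in \{0, 1, 2\}.
#' @export
genotypeMatrix <- function(genomes, apfa, alt = "1") {
  al <- stats::setNames(apfa@edges$allele, apfa@edges$id)
  t(vapply(genomes, function(g)
    (al[g@hap1] == alt) + (al[g@hap2] == alt),
    integer(apfa@p))) -> M
  rownames(M) <- vapply(genomes, function(g) g@id, "")
  M + 0L
}

#' Monte-Carlo expectation summaries by pedigree distance
#'
#' Replicated gene drops through a pedigree; for every replicate the
#' realized intersect (b), product (c) and vanRaden (g) measures are
#' computed from the simulated genomes, and pooled with the pedigree
#' expectation (a) into per-distance-class summaries: the synthetic
#' analogue of a relatedness-by-distance table.
#'
#' @param apfa an [Apfa] with normalized probabilities.
#' @param ped a [Pedigree].
#' @param config a [SimConfig]; `replicates` drops are run and `seed`
#'   seeds the stream once at the start.
#' @return data.frame with columns `distance`, `n` and mean/sd of b,
#'   c, a and g per distance class (finite distances only).  Zero
#'   replicates give an empty table.
#' @export
monteCarloExpectations <- function(apfa, ped, config = SimConfig()) {
  cols <- c("distance", "n", "mean_b", "sd_b", "mean_c", "sd_c",
            "mean_a", "sd_a", "mean_g", "sd_g")
  if (config$replicates < 1L) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                         cols))
    return(out)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  D <- pedigreeDistance(ped)
  Am <- as.matrix(numeratorMatrix(ped))
  ut <- upper.tri(D)
  keep <- ut & is.finite(D)
  dist <- D[keep]
  a <- Am[keep]
  bs <- cs <- gs <- vector("list", config$replicates)
  for (rep in seq_len(config$replicates)) {
    genomes <- simulatePedigree(apfa, ped,
                                SimConfig(r = config$r, seed = NULL))
    hm <- designMatrix(genomes, apfa)
    bs[[rep]] <- as.matrix(intersectMeasure(hm))[keep]
    cs[[rep]] <- as.matrix(productMeasure(hm))[keep]
    gs[[rep]] <- tryCatch(
      as.matrix(vanRadenG(genotypeMatrix(genomes, apfa),
                          dropMonomorphic = TRUE))[keep],
      error = function(e) rep(NA_real_, sum(keep)))
  }
  dd <- factor(rep(dist, config$replicates), levels = sort(unique(dist)))
  stat <- function(v, f) as.numeric(tapply(v, dd, f))
  b <- unlist(bs); cc <- unlist(cs); g <- unlist(gs)
  aa <- rep(a, config$replicates)
  data.frame(distance = sort(unique(dist)),
             n = as.integer(table(dd)),
             mean_b = stat(b, mean), sd_b = stat(b, stats::sd),
             mean_c = stat(cc, mean), sd_c = stat(cc, stats::sd),
             mean_a = stat(aa, mean), sd_a = stat(aa, stats::sd),
             mean_g = stat(g, function(x) mean(x, na.rm = TRUE)),
             sd_g = stat(g, function(x) stats::sd(x, na.rm = TRUE)))
}
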