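# Fixtures are built in code.  Segment ids follow the "L{level}E{ord}"
# convention so genomes can be built with or without an explicit APFA.

# chain APFA: one vertex per level, all probabilities 1
chainApfa <- function(p = 4L, allele = "0") {
  Apfa(level = 0:(p - 1L), source = paste0("V", 0:(p - 1L)),
       target = paste0("V", 1:p), allele = rep(allele, p), prob = rep(1, p))
}

# p = 2 diamond: two branches at level 0 (probs pr), rejoining paths
diamondApfa <- function(pr = c(0.3, 0.7)) {
  Apfa(level = c(0L, 0L, 1L, 1L),
       source = c("R", "R", "U", "W"),
       target = c("U", "W", "S", "S"),
       allele = c("0", "1", "0", "1"),
       prob = c(pr, 1, 1))
}

# biallelic APFA with full branching: every level has two segments,
# shared by all paths (vertex chain with parallel edges)
biallelicApfa <- function(p = 10L, probs = NULL) {
  if (is.null(probs)) probs <- rep(0.5, p)
  Apfa(level = rep(0:(p - 1L), each = 2L),
       source = rep(paste0("V", 0:(p - 1L)), each = 2L),
       target = rep(paste0("V", 1:p), each = 2L),
       allele = rep(c("0", "1"), p),
       prob = as.numeric(rbind(probs, 1 - probs)))
}

segId <- function(level, ord) sprintf("L%dE%d", level, ord)

# random genome on p intervals with nAlleles segments per interval
randomGenome <- function(id, p = 8L, nAlleles = 3L) {
  pick <- function() segId(0:(p - 1L), sample.int(nAlleles, p, TRUE) - 1L)
  Genome(id, pick(), pick())
}

randomMultiset <- function(nElems = 6L, maxMult = 5L) {
  els <- sample(letters, nElems)
  stats::setNames(sample.int(maxMult + 1L, nElems, TRUE) - 1L, els)
}

# brute-force B/C/kappa/f from genome multisets, straight from the
# multiset definitions (independent of the design-matrix route)
bruteMeasures <- function(genomes) {
  n <- length(genomes)
  p <- nIntervals(genomes[[1]])
  ms <- lapply(genomes, segmentMultiset)
  B <- C <- K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    B[i, j] <- msetCardinality(msetIntersect(ms[[i]], ms[[j]])) / (2 * p)
    C[i, j] <- msetCardinality(msetProduct(ms[[i]], ms[[j]])) / (2 * p)
    both1 <- intersect(names(ms[[i]])[ms[[i]] == 1], names(ms[[j]])[ms[[j]] == 1])
    K[i, j] <- length(both1) / (2 * p)
  }
  f <- vapply(ms, function(m) sum(m == 2) / p, 0)
  ids <- vapply(genomes, function(g) g@id, "")
  dimnames(B) <- dimnames(C) <- dimnames(K) <- list(ids, ids)
  list(B = B, C = C, K = K, f = stats::setNames(f, ids))
}

# random symmetric positive-definite matrix with unit-scale diagonal
randomSpd <- function(n, ids = as.character(seq_len(n))) {
  L <- matrix(rnorm(n * n), n)
  S <- crossprod(L) / n + diag(n)
  dimnames(S) <- list(ids, ids)
  S
}

# random pedigree: nFounders founders then nDesc descendants with
# parents drawn from earlier individuals
randomPedigree <- function(nFounders = 10L, nDesc = 40L) {
  id <- paste0("I", seq_len(nFounders + nDesc))
  sire <- dam <- rep(NA_character_, nFounders + nDesc)
  for (k in (nFounders + 1L):(nFounders + nDesc)) {
    par <- sample(k - 1L, 2L)
    sire[k] <- id[par[1L]]
    dam[k] <- id[par[2L]]
  }
  Pedigree(id, sire, dam)
}

# gene-drop estimate of A: drop unique founder alleles through the
# pedigree at a single unlinked locus, vectorized over drops
geneDropA <- function(ped, drops = 1e5L) {
  ids <- individualIds(ped)
  n <- length(ids)
  si <- match(ped@sire, ids)
  di <- match(ped@dam, ids)
  A1 <- A2 <- matrix(NA_integer_, n, drops)
  nextAllele <- 1L
  for (k in topoOrder(ped)) {
    inherit <- function(pi) {
      if (is.na(pi)) {
        a <- rep(nextAllele, drops)
        nextAllele <<- nextAllele + 1L
        a
      } else {
        takeFirst <- runif(drops) < 0.5
        ifelse(takeFirst, A1[pi, ], A2[pi, ])
      }
    }
    A1[k, ] <- inherit(si[k])
    A2[k, ] <- inherit(di[k])
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n) {
    s <- (A1[i, ] == A1[j, ]) + (A1[i, ] == A2[j, ]) +
      (A2[i, ] == A1[j, ]) + (A2[i, ] == A2[j, ])
    if (i == j) A[i, i] <- 1 + mean(A1[i, ] == A2[i, ])
    else A[i, j] <- A[j, i] <- mean(s) / 2
  }
  A
}

# founder genomes that are pairwise segment-disjoint and non-inbred:
# founder m carries private segments at ordinals (2m, 2m+1)
disjointFounder <- function(id, m, p) {
  Genome(id, segId(0:(p - 1L), 2L * m), segId(0:(p - 1L), 2L * m + 1L))
}
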