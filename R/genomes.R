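## Genomes, the haplomarker design matrix, and tracing of phased
## haplotypes through an APFA.

#' Construct a diploid genome from two haplotype segment sequences
#'
#' @param id individual identifier.
#' @param hap1,hap2 character vectors of segment ids, one per interval.
#'   After recombination these need not be connected APFA paths.
#' @param apfa optional [Apfa]; when supplied, every segment id must
#'   exist in the model and occupy the interval matching its position.
#' @return a [Genome].
#' @export
Genome <- function(id, hap1, hap2, apfa = NULL) {
  g <- new("Genome", id = as.character(id), hap1 = as.character(hap1),
           hap2 = as.character(hap2))
  if (!is.null(apfa)) {
    ed <- apfa@edges
    p <- apfa@p
    if (length(hap1) != p)
      stop("genome ", id, ": haplotype length ", length(hap1),
           " does not match APFA interval count ", p)
    for (h in list(g@hap1, g@hap2)) {
      i <- match(h, ed$id)
      if (anyNA(i))
        stop("genome ", id, ": unknown segment id(s) ",
             paste(h[is.na(i)], collapse = ", "))
      off <- which(ed$level[i] != seq_len(p) - 1L)
      if (length(off))
        stop("genome ", id, ": segment ", h[off[1L]], " at position ",
             off[1L], " belongs to interval ", ed$level[i][off[1L]])
    }
  }
  g
}

#' @rdname nIntervals
#' @export
setMethod("nIntervals", "Genome", function(x) length(x@hap1))

#' @rdname segmentMultiset
#' @export
setMethod("segmentMultiset", "Genome", function(x) {
  t <- table(c(x@hap1, x@hap2))
  stats::setNames(as.integer(t), names(t))
})

#' @export
setMethod("show", "Genome", function(object) {
  ms <- segmentMultiset(object)
  cat("Genome", object@id, "with", length(object@hap1), "intervals;",
      sum(ms == 2L), "homozygous\n")
})

#' Homozygosity of a single genome
#'
#' `f = #(intervals where both haplotypes carry the same segment) / p`;
#' this is the identity-by-state inbreeding coefficient of the genome.
#'
#' @param genome a [Genome].
#' @return numeric in \[0, 1\].
#' @export
genomeHomozygosity <- function(genome)
  mean(genome@hap1 == genome@hap2)

#' Haplomarker design matrix from genomes
#'
#' Builds the N x |E| multiplicity matrix X with one row per genome and
#' one column per segment.  With an [Apfa] the columns follow its
#' canonical edge order and cover all its edges; without one, the
#' column universe is the union of the segments observed in the genomes
#' (sorted), with each segment's interval inferred from its haplotype
#' position.
#'
#' @param genomes list of [Genome]s on a common segmentation.
#' @param apfa optional [Apfa].
#' @return a [HaplomarkerMatrix].
#' @export
designMatrix <- function(genomes, apfa = NULL) {
  if (length(genomes) == 0L) stop("no genomes supplied")
  ids <- vapply(genomes, function(g) g@id, "")
  if (anyDuplicated(ids))
    stop("duplicated individual id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  p <- length(genomes[[1L]]@hap1)
  if (!all(vapply(genomes, function(g) length(g@hap1), 0L) == p))
    stop("genomes have differing interval counts")
  if (!is.null(apfa)) {
    if (apfa@p != p)
      stop("APFA has ", apfa@p, " intervals but genomes have ", p)
    segs <- apfa@edges$id
    level <- apfa@edges$level
  } else {
    seen <- unique(unlist(lapply(genomes, function(g) c(g@hap1, g@hap2))))
    pos <- integer(length(seen))
    names(pos) <- seen
    for (g in genomes) {
      pos[g@hap1] <- seq_len(p) - 1L
      pos[g@hap2] <- seq_len(p) - 1L
    }
    o <- order(pos, seen, method = "radix")
    segs <- seen[o]
    level <- unname(pos[o])
  }
  X <- matrix(0L, length(genomes), length(segs),
              dimnames = list(unname(ids), segs))
  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    j <- match(g@hap1, segs)
    if (anyNA(j)) stop("genome ", g@id, ": segment(s) not in the APFA: ",
                       paste(g@hap1[is.na(j)], collapse = ", "))
    X[i, j] <- X[i, j] + 1L
    j <- match(g@hap2, segs)
    if (anyNA(j)) stop("genome ", g@id, ": segment(s) not in the APFA: ",
                       paste(g@hap2[is.na(j)], collapse = ", "))
    X[i, j] <- X[i, j] + 1L
  }
  new("HaplomarkerMatrix", X = X, level = as.integer(level), p = as.integer(p))
}

#' @rdname nIntervals
#' @export
setMethod("nIntervals", "HaplomarkerMatrix", function(x) x@p)

#' @rdname individualIds
#' @export
setMethod("individualIds", "HaplomarkerMatrix", function(x) rownames(x@X))

#' Extract the multiplicity matrix
#'
#' @param x a [HaplomarkerMatrix].
#' @return the underlying N x |E| integer matrix.
#' @export
hmMatrix <- function(x) x@X

#' @export
setMethod("show", "HaplomarkerMatrix", function(object) {
  cat("HaplomarkerMatrix:", nrow(object@X), "individuals x",
      ncol(object@X), "segments over", object@p, "intervals\n")
})

#' Trace phased haplotypes through an APFA
#'
#' Maps phased allele sequences onto APFA edges by walking from the
#' root and, at each level, following the outgoing edge whose allele
#' symbol matches.  When a multigraph offers several matching edges the
#' higher-probability edge is chosen (ties broken by lexicographic edge
#' id) and a warning is issued.  Missing alleles are a hard error:
#' tracing requires complete phased input.
#'
#' @param haplotypes phased input: a character matrix of allele symbols
#'   with 2 rows per individual (rownames give individual ids, each id
#'   appearing exactly twice) and one column per marker.
#' @param apfa an [Apfa].
#' @return list of [Genome]s, one per individual, in first-appearance
#'   order.
#' @export
haplotypesToGenomes <- function(haplotypes, apfa) {
  m <- as.matrix(haplotypes)
  mode(m) <- "character"
  if (is.null(rownames(m)))
    stop("haplotype matrix must have individual ids as rownames")
  if (nrow(m) %% 2L != 0L)
    stop("expected 2 haplotype rows per individual, got ", nrow(m), " rows")
  if (ncol(m) != apfa@p)
    stop("haplotypes have ", ncol(m), " markers but the APFA has ",
         apfa@p, " intervals")
  if (anyNA(m) || any(m == "." | m == ""))
    stop("missing alleles are not supported; provide complete phased input")
  ids <- unique(rownames(m))
  cnt <- table(rownames(m))
  if (any(cnt != 2L))
    stop("individual(s) without exactly 2 haplotype rows: ",
         paste(names(cnt)[cnt != 2L], collapse = ", "))
  ed <- apfa@edges
  root <- .rootVertex(apfa)
  trace1 <- function(alleles, id, hapno) {
    path <- character(apfa@p)
    vertex <- root
    for (k in seq_len(apfa@p)) {
      idx <- which(ed$source == vertex & ed$level == k - 1L &
                     ed$allele == alleles[k])
      if (length(idx) == 0L)
        stop("untraceable haplotype: individual ", id, ", haplotype ",
             hapno, ", level ", k - 1L, ": no outgoing edge with allele \"",
             alleles[k], "\" from vertex ", vertex)
      if (length(idx) > 1L) {
        o <- order(-ed$prob[idx], ed$id[idx], method = "radix")
        idx <- idx[o]
        warning("ambiguous allele \"", alleles[k], "\" at level ", k - 1L,
                " for individual ", id,
                "; taking the higher-probability edge ", ed$id[idx[1L]])
      }
      path[k] <- ed$id[idx[1L]]
      vertex <- ed$target[idx[1L]]
    }
    path
  }
  lapply(ids, function(id) {
    rows <- which(rownames(m) == id)
    Genome(id, trace1(m[rows[1L], ], id, 1L), trace1(m[rows[2L], ], id, 2L))
  })
}
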