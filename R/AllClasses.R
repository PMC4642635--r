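#' @import methods
NULL

#' Acyclic probabilistic finite automaton (APFA)
#'
#' A leveled directed multigraph modelling the joint distribution of `p`
#' markers at the haplotype level.  Vertices are assigned levels
#' `0, ..., p` with a single root at level 0 and a single sink at level
#' `p`; every edge connects a level-`k` vertex to a level-`(k+1)` vertex
#' and carries a marker allele symbol and a transition probability.
#' Every root-to-sink path is a haplotype, with probability equal to the
#' product of its edge probabilities.
#'
#' The edges of the APFA are identified with chromosomal *segments*: two
#' haplotypes that traverse the same edge in an interval are taken to
#' share the same DNA there.  Edge (segment) ids are globally unique and
#' each edge belongs to exactly one level, so the per-interval segment
#' sets are disjoint by construction.
#'
#' @slot p integer, number of intervals (levels); `>= 1`.
#' @slot edges `data.frame` with columns `id` (unique segment id),
#'   `level` (0-based interval index), `source`, `target` (vertex ids),
#'   `allele` (allele symbol) and `prob` (transition probability).
#'
#' @seealso [buildTrieApfa()], [readApfa()], [validateApfa()]
#' @export
setClass("Apfa", representation(p = "integer", edges = "data.frame"))

setValidity("Apfa", function(object) {
  msg <- character()
  need <- c("id", "level", "source", "target", "allele", "prob")
  if (!all(need %in% names(object@edges)))
    msg <- c(msg, paste("edges must have columns:", paste(need, collapse = ", ")))
  if (length(object@p) != 1L || is.na(object@p) || object@p < 1L)
    msg <- c(msg, "p must be a single integer >= 1")
  if (length(msg) == 0L && anyDuplicated(object@edges$id))
    msg <- c(msg, "edge ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Diploid genome as a pair of segment sequences
#'
#' A genome is a collection of 2p segments: two haplotypes, each one
#' segment per interval.  After recombination a haplotype need not be a
#' connected APFA path, so the class stores per-interval segment ids
#' rather than paths.  The derived multiplicity representation (values
#' in {0,1,2}, summing to 2p) is available via [segmentMultiset()].
#'
#' @slot id individual identifier.
#' @slot hap1,hap2 character vectors of segment ids, one per interval.
#' @export
setClass("Genome", representation(id = "character", hap1 = "character",
                                  hap2 = "character"))

setValidity("Genome", function(object) {
  msg <- character()
  if (length(object@id) != 1L) msg <- c(msg, "id must be a single string")
  if (length(object@hap1) != length(object@hap2))
    msg <- c(msg, "haplotypes must have equal length")
  if (length(object@hap1) < 1L) msg <- c(msg, "haplotypes must be non-empty")
  if (anyNA(object@hap1) || anyNA(object@hap2))
    msg <- c(msg, "missing segment ids are not allowed")
  if (length(msg)) msg else TRUE
})

#' Haplomarker design matrix
#'
#' The N x |E| integer matrix X of segment multiplicities: row i, column
#' s holds x_is, the multiplicity (0, 1 or 2) of segment s in genome i.
#' Each row sums to 2p and within each interval the row block sums to 2.
#' Columns follow the canonical edge order of the generating APFA and
#' carry their interval (level) so that weighted measures can be formed.
#'
#' @slot X integer matrix, rownames individual ids, colnames segment ids.
#' @slot level 0-based interval index of each column.
#' @slot p number of intervals.
#' @seealso [designMatrix()]
#' @export
setClass("HaplomarkerMatrix",
         representation(X = "matrix", level = "integer", p = "integer"))

setValidity("HaplomarkerMatrix", function(object) {
  msg <- character()
  if (length(object@level) != ncol(object@X))
    msg <- c(msg, "level must have one entry per column of X")
  if (!all(object@X %in% c(0L, 1L, 2L)))
    msg <- c(msg, "multiplicities must lie in {0,1,2}")
  if (nrow(object@X) > 0L && !all(rowSums(object@X) == 2L * object@p))
    msg <- c(msg, "each row must sum to 2p")
  if (length(msg)) msg else TRUE
})

#' Labeled symmetric relationship matrix
#'
#' An N x N symmetric matrix of pairwise relatedness values with a kind
#' tag recording its provenance: "A" (pedigree numerator matrix), "B"
#' (intersect measure), "C" (product measure), "G" (vanRaden), "R"
#' (hybrid expected/realized) or "conditioned".
#'
#' @slot values numeric matrix with matching row/column names.
#' @slot kind character tag.
#' @export
setClass("RelationshipMatrix",
         representation(values = "matrix", kind = "character"))

setValidity("RelationshipMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (is.null(rownames(v)) || is.null(colnames(v)) ||
      !identical(rownames(v), colnames(v)))
    msg <- c(msg, "row and column names must be present and identical")
  else if (nrow(v) && max(abs(v - t(v))) > 1e-12)
    msg <- c(msg, "matrix must be symmetric within 1e-12")
  if (length(msg)) msg else TRUE
})

#' Pedigree
#'
#' Individual records with optional sire and dam references (NA =
#' unknown).  The pedigree must be acyclic; a topological order in which
#' parents precede their offspring is computed at construction (Kahn's
#' algorithm, ties broken by input order) and stored.
#'
#' @slot id,sire,dam character vectors; `sire`/`dam` are NA when unknown.
#' @slot order integer permutation giving the topological order.
#' @export
setClass("Pedigree",
         representation(id = "character", sire = "character",
                        dam = "character", order = "integer"))

setValidity("Pedigree", function(object) {
  msg <- character()
  n <- length(object@id)
  if (length(object@sire) != n || length(object@dam) != n)
    msg <- c(msg, "id, sire and dam must have equal length")
  if (anyDuplicated(object@id))
    msg <- c(msg, paste("duplicated individual ids:",
                        paste(unique(object@id[duplicated(object@id)]), collapse = ", ")))
  known <- c(object@sire, object@dam)
  known <- known[!is.na(known)]
  if (!all(known %in% object@id))
    msg <- c(msg, paste("parents not recorded as individuals:",
                        paste(unique(setdiff(known, object@id)), collapse = ", ")))
  if (length(object@order) != n)
    msg <- c(msg, "order must be a permutation of the records")
  if (length(msg)) msg else TRUE
})

#' Gamete pair from one meiosis
#'
#' The two complementary haplotypes H1 and H2 into which a parent genome
#' is partitioned during meiosis, together with the crossover positions
#' used.  At every interval the two gametes carry the parent's two
#' segments between them, so H1 + H2 equals the parent genome as a
#' multiset.
#'
#' @slot h1,h2 character vectors of segment ids (length p each).
#' @slot crossovers integer vector of boundary indices (1-based,
#'   boundary k lies between intervals k and k+1) where the tracked
#'   gamete switches parental haplotype.
#' @export
setClass("GametePair",
         representation(h1 = "character", h2 = "character",
                        crossovers = "integer"))

setValidity("GametePair", function(object) {
  if (length(object@h1) != length(object@h2))
    "gametes must have equal length" else TRUE
})
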