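#' Number of intervals (levels)
#'
#' @param x an [Apfa], [Genome] or [HaplomarkerMatrix].
#' @return integer, the number of genomic intervals p.
#' @export
setGeneric("nIntervals", function(x) standardGeneric("nIntervals"))

#' Segment multiplicity multiset of a genome
#'
#' @param x a [Genome].
#' @return named integer vector: multiplicity (1 or 2) of each segment
#'   present in the genome; absent segments are omitted (multiplicity 0).
#' @export
setGeneric("segmentMultiset", function(x) standardGeneric("segmentMultiset"))

#' Edge table of an APFA
#'
#' @param x an [Apfa].
#' @return data.frame of edges (id, level, source, target, allele, prob)
#'   in canonical order.
#' @export
setGeneric("apfaEdges", function(x) standardGeneric("apfaEdges"))

#' Kind tag of a relationship matrix
#'
#' @param x a [RelationshipMatrix].
#' @return character tag such as "A", "B", "C", "G", "R" or "conditioned".
#' @export
setGeneric("relKind", function(x) standardGeneric("relKind"))

#' Individual ids
#'
#' @param x a [Pedigree], [RelationshipMatrix] or [HaplomarkerMatrix].
#' @return character vector of individual ids, in storage order.
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' Topological order of a pedigree
#'
#' @param x a [Pedigree].
#' @return integer permutation; `x@id[topoOrder(x)]` lists parents
#'   before their offspring.
#' @export
setGeneric("topoOrder", function(x) standardGeneric("topoOrder"))
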