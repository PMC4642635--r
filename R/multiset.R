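## Multiset algebra over segments.
##
## A multiset is represented as a named numeric vector mapping element
## ids to non-negative multiplicities; absent names have multiplicity 0.
## The operators are element-wise over the union of supports, so the
## identities |A+B| = |A|+|B|, Ax[B+C] = [AxB]+[AxC] and
## A+[B cap C] = [A+B] cap [A+C] hold exactly in integer arithmetic.

.msetAlign <- function(a, b) {
  els <- union(names(a), names(b))
  rbind(ifelse(is.na(match(els, names(a))), 0, a[match(els, names(a))]),
        ifelse(is.na(match(els, names(b))), 0, b[match(els, names(b))])) ->
    m
  colnames(m) <- els
  m
}

.msetCheck <- function(a) {
  a <- unlist(a)
  if (length(a) && (is.null(names(a)) || any(!nzchar(names(a)))))
    stop("multisets must be named vectors (element -> multiplicity)")
  if (any(a < 0)) stop("multiplicities must be non-negative")
  a
}

#' Multiset operations
#'
#' Element-wise intersection (minimum of multiplicities), sum, product
#' and cardinality (total multiplicity) of multisets represented as
#' named non-negative vectors.
#'
#' @param a,b named numeric vectors; names are element ids, values are
#'   multiplicities.  Elements absent from a vector have multiplicity 0.
#' @return `msetIntersect`, `msetSum` and `msetProduct` return a named
#'   vector over the union of supports (zero entries retained);
#'   `msetCardinality` returns the sum of multiplicities.
#' @examples
#' a <- c(fig = 2, pear = 5, plum = 3)
#' b <- c(fig = 1, pear = 10)
#' msetIntersect(a, b)  # fig 1, pear 5, plum 0
#' msetSum(a, b)        # fig 3, pear 15, plum 3
#' msetProduct(a, b)    # fig 2, pear 50, plum 0
#' msetCardinality(a)   # 10
#' @export
msetIntersect <- function(a, b) {
  m <- .msetAlign(.msetCheck(a), .msetCheck(b))
  stats::setNames(pmin(m[1L, ], m[2L, ]), colnames(m))
}

#' @rdname msetIntersect
#' @export
msetSum <- function(a, b) {
  m <- .msetAlign(.msetCheck(a), .msetCheck(b))
  stats::setNames(m[1L, ] + m[2L, ], colnames(m))
}

#' @rdname msetIntersect
#' @export
msetProduct <- function(a, b) {
  m <- .msetAlign(.msetCheck(a), .msetCheck(b))
  stats::setNames(m[1L, ] * m[2L, ], colnames(m))
}

#' @rdname msetIntersect
#' @export
msetCardinality <- function(a) sum(.msetCheck(a))
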