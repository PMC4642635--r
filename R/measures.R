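## Haplotype-sharing relatedness measures B and C, their companions
## kappa and f, vanRaden's G, matrix-comparison statistics and the
## -log(b) principal-coordinates embedding.
##
## B and C are probability-free: they use only segment identities and
## multiplicities.  All pairwise sums are accumulated as integer cross
## products and divided once, so the identity C = 2B - kappa is exact.

#' Construct a relationship matrix
#'
#' @param values square numeric matrix with identical row/column names.
#' @param kind provenance tag ("A", "B", "C", "G", "R", "conditioned").
#' @return a [RelationshipMatrix].
#' @export
RelationshipMatrix <- function(values, kind = "custom") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) && is.null(colnames(values)))
    dimnames(values) <- list(as.character(seq_len(nrow(values))),
                             as.character(seq_len(nrow(values))))
  else if (is.null(rownames(values))) rownames(values) <- colnames(values)
  else if (is.null(colnames(values))) colnames(values) <- rownames(values)
  new("RelationshipMatrix", values = values, kind = kind)
}

#' @rdname relKind
#' @export
setMethod("relKind", "RelationshipMatrix", function(x) x@kind)

#' @rdname individualIds
#' @export
setMethod("individualIds", "RelationshipMatrix",
          function(x) rownames(x@values))

#' @describeIn RelationshipMatrix extract the numeric matrix.
#' @param x a [RelationshipMatrix].
#' @param ... unused.
#' @export
setMethod("as.matrix", "RelationshipMatrix", function(x, ...) x@values)

#' @export
setMethod("show", "RelationshipMatrix", function(object) {
  v <- object@values
  cat(sprintf("RelationshipMatrix (kind %s), %d x %d\n", object@kind,
              nrow(v), ncol(v)))
  cat(sprintf("  diagonal: [%.4f, %.4f]; off-diagonal: [%.4f, %.4f]\n",
              min(diag(v)), max(diag(v)),
              min(v[row(v) != col(v)], Inf), max(v[row(v) != col(v)], -Inf)))
})

#' @export
setMethod("dim", "RelationshipMatrix", function(x) dim(x@values))

.checkWeights <- function(weights, p) {
  if (is.null(weights)) return(NULL)
  weights <- as.numeric(weights)
  if (length(weights) != p)
    stop("expected ", p, " interval weights, got ", length(weights))
  if (any(weights < 0)) stop("interval weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("interval weights must sum to 1 (got ",
         format(sum(weights), digits = 12), ")")
  weights
}

## Integer building blocks shared by B, C and kappa:
##   P = X X^T          (sum_s x_is x_js)
##   K = [X==1][X==1]^T (#{s: x_is = x_js = 1})
## and since for x, y in {0,1,2} min(x,y) = (xy + I(x=y=1)) / 2,
##   sum_s min(x_is, x_js) = (P + K) / 2.
.pairCounts <- function(hm, weights = NULL) {
  X <- hm@X
  H <- (X == 1L) + 0L
  if (is.null(weights)) {
    list(P = X %*% t(X), K = H %*% t(H), denom = 2 * hm@p)
  } else {
    w <- weights[hm@level + 1L]
    list(P = X %*% (w * t(X)), K = H %*% (w * t(H)), denom = 2)
  }
}

#' Intersect measure B: fraction of shared genome
#'
#' `b_ij = |G_i intersect G_j| / 2p = sum_s min(x_is, x_js) / 2p`.
#' `b_ii = 1`; `b_ij = 0` iff the genomes share no segments and 1 iff
#' they are identical.  With interval weights `w_1..w_p` (non-negative,
#' summing to 1) the weighted form `sum_s w_l(s) min(x_is, x_js) / 2`
#' is used; uniform weights `1/p` reproduce the unweighted measure.
#'
#' @param hm a [HaplomarkerMatrix].
#' @param weights optional numeric vector of p interval weights.
#' @return a [RelationshipMatrix] of kind "B".
#' @export
intersectMeasure <- function(hm, weights = NULL) {
  weights <- .checkWeights(weights, hm@p)
  pc <- .pairCounts(hm, weights)
  RelationshipMatrix((pc$P + pc$K) / 2 / pc$denom, kind = "B")
}

#' Product measure C: twice the IBS coancestry
#'
#' `c_ij = |G_i x G_j| / 2p = sum_s x_is x_js / 2p`, i.e. `C = X X' / 2p`.
#' Off the diagonal `c_ij` equals twice the identity-by-state
#' coefficient of coancestry; on the diagonal `c_ii = 1 + f_i` with
#' `f_i` the IBS inbreeding (homozygosity) coefficient.  Weighted form
#' as in [intersectMeasure()].
#'
#' @inheritParams intersectMeasure
#' @return a [RelationshipMatrix] of kind "C".
#' @export
productMeasure <- function(hm, weights = NULL) {
  weights <- .checkWeights(weights, hm@p)
  pc <- .pairCounts(hm, weights)
  RelationshipMatrix(pc$P / pc$denom, kind = "C")
}

#' Shared heterozygosity kappa and homozygosity f
#'
#' `kappa_ij = #\{s: x_is = x_js = 1\} / 2p` measures shared
#' heterozygosity and links the two measures through the exact identity
#' `C = 2B - kappa`.  `f_i = #\{s: x_is = 2\} / p` is the homozygosity
#' (IBS inbreeding) of individual i, with `c_ii = 1 + f_i`.
#'
#' @param hm a [HaplomarkerMatrix].
#' @return `sharedHeterozygosity`: symmetric numeric matrix;
#'   `homozygosity`: named numeric vector.
#' @export
sharedHeterozygosity <- function(hm) {
  pc <- .pairCounts(hm)
  pc$K / pc$denom
}

#' @rdname sharedHeterozygosity
#' @export
homozygosity <- function(hm)
  rowSums(hm@X == 2L) / hm@p

#' vanRaden's genomic relationship matrix G
#'
#' `g_ij = sum_k (m_ik - mbar_k)(m_jk - mbar_k) / sum_k 2 phat_k (1 - phat_k)`
#' where `mbar_k` is the sample mean genotype of marker k and
#' `phat_k = mbar_k / 2` the sample allele frequency.  Centering by the
#' sample means makes every row of G sum to zero exactly.
#'
#' The `denominator` option controls the scaling sum: the default
#' `"allele-frequency"` uses `2 phat_k (1 - phat_k)` (the method-1
#' scaling, guaranteed positive for polymorphic markers); the
#' alternative `"genotype-mean"` uses `2 mbar_k (1 - mbar_k)` with the
#' mean genotype in \[0, 2\], which can be negative and is provided only
#' for comparison.
#'
#' @param M numeric matrix N x p of genotypes in \{0, 1, 2\}; rownames
#'   are individual ids.
#' @param denominator `"allele-frequency"` (default) or
#'   `"genotype-mean"`; see Details.
#' @param dropMonomorphic drop zero-variance markers instead of
#'   raising an error.
#' @return a [RelationshipMatrix] of kind "G".
#' @export
vanRadenG <- function(M, denominator = c("allele-frequency", "genotype-mean"),
                      dropMonomorphic = FALSE) {
  denominator <- match.arg(denominator)
  M <- as.matrix(M)
  if (nrow(M) < 2L) stop("G needs at least 2 individuals")
  if (!all(M %in% c(0, 1, 2))) stop("genotypes must lie in {0, 1, 2}")
  if (is.null(rownames(M))) rownames(M) <- as.character(seq_len(nrow(M)))
  mono <- apply(M, 2L, function(x) length(unique(x)) == 1L)
  if (any(mono)) {
    labs <- if (is.null(colnames(M))) which(mono) else colnames(M)[mono]
    if (!dropMonomorphic)
      stop("monomorphic marker(s): ", paste(labs, collapse = ", "),
           " (use dropMonomorphic = TRUE to remove them)")
    M <- M[, !mono, drop = FALSE]
    if (ncol(M) == 0L) stop("no polymorphic markers left")
  }
  mbar <- colMeans(M)
  denom <- switch(denominator,
                  "allele-frequency" = sum(2 * (mbar / 2) * (1 - mbar / 2)),
                  "genotype-mean" = sum(2 * mbar * (1 - mbar)))
  if (abs(denom) < .Machine$double.eps * ncol(M))
    stop("zero scaling denominator")
  Z <- sweep(M, 2L, mbar)
  RelationshipMatrix(tcrossprod(Z) / denom, kind = "G")
}

#' Compare two relationship matrices over their off-diagonals
#'
#' Computes the mean squared deviation and the adjusted R-squared of
#' simple linear regressions of the off-diagonal entries of `y` on
#' those of `x`, with and without an intercept (closed-form least
#' squares over the N(N-1)/2 unordered pairs).
#'
#' @param x,y [RelationshipMatrix]es (or plain matrices) over the same
#'   individuals in the same order.
#' @return list with `msd`, `adjR2NoIntercept`, `adjR2WithIntercept`,
#'   `slopeNoIntercept`, `slope`, `intercept` and `n` (number of pairs).
#' @export
compareMatrices <- function(x, y) {
  xv <- if (is(x, "RelationshipMatrix")) x@values else as.matrix(x)
  yv <- if (is(y, "RelationshipMatrix")) y@values else as.matrix(y)
  if (!all(dim(xv) == dim(yv)))
    stop("matrices have different dimensions")
  if (!is.null(rownames(xv)) && !is.null(rownames(yv)) &&
      !identical(rownames(xv), rownames(yv)))
    stop("matrices are over different (or differently ordered) individuals")
  ut <- upper.tri(xv)
  xo <- xv[ut]; yo <- yv[ut]
  n <- length(xo)
  msd <- mean((xo - yo)^2)
  ## no-intercept fit: y = b x
  b0 <- sum(xo * yo) / sum(xo * xo)
  rss0 <- sum((yo - b0 * xo)^2)
  tss0 <- sum(yo^2)                    # uncentered total SS, 1 df used
  adjR2No <- 1 - (rss0 / (n - 1)) / (tss0 / n)
  ## with intercept
  xc <- xo - mean(xo); yc <- yo - mean(yo)
  b1 <- sum(xc * yc) / sum(xc * xc)
  a1 <- mean(yo) - b1 * mean(xo)
  rss1 <- sum((yo - a1 - b1 * xo)^2)
  tss1 <- sum(yc^2)
  adjR2With <- 1 - (rss1 / (n - 2)) / (tss1 / (n - 1))
  list(msd = msd, adjR2NoIntercept = adjR2No, adjR2WithIntercept = adjR2With,
       slopeNoIntercept = b0, slope = b1, intercept = a1, n = n)
}

#' Haplotype-sharing distance and principal coordinates
#'
#' `bToDistance` converts an intersect-measure matrix B to the distance
#' `d_ij = -log(b_ij)` (with `d_ii = 0`); pairs with `b_ij = 0` get
#' infinite distance.  `principalCoordinates` performs classical
#' multidimensional scaling (double-centering of squared distances and
#' eigen-decomposition) of a finite distance matrix, returning the
#' leading `k` coordinate axes ordered by eigenvalue.
#'
#' @param B a [RelationshipMatrix] of kind "B" (or any matrix with
#'   entries in \[0, 1\] and unit diagonal).
#' @return `bToDistance`: symmetric distance matrix (possibly with
#'   `Inf` entries); `principalCoordinates`: N x k matrix of
#'   coordinates with an `eigenvalues` attribute.
#' @export
bToDistance <- function(B) {
  v <- if (is(B, "RelationshipMatrix")) B@values else as.matrix(B)
  if (any(v < 0 | v > 1)) stop("b values must lie in [0, 1]")
  d <- -log(v)
  diag(d) <- 0
  if (any(is.infinite(d)))
    message("some pairs share no segments; their distance is infinite")
  d
}

#' @rdname bToDistance
#' @param D symmetric distance matrix with finite entries.
#' @param k number of coordinate axes to return (`k <= N - 1`).
#' @export
principalCoordinates <- function(D, k = 2L) {
  D <- as.matrix(D)
  if (any(!is.finite(D)))
    stop("principal coordinates require finite distances; ",
         "some pairs share no segments (infinite -log(b))")
  if (k > nrow(D) - 1L) stop("k must be at most N - 1")
  fit <- stats::cmdscale(stats::as.dist(D), k = k, eig = TRUE)
  coords <- fit$points
  rownames(coords) <- rownames(D)
  attr(coords, "eigenvalues") <- fit$eig
  coords
}
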