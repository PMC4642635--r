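## Conditioning a relationship (covariance) matrix on a subgroup, and
## the consistency-check procedure built on it.

#' Replace the marginal covariance of a subgroup
#'
#' Treats the relationship matrix A as a covariance matrix and returns
#' the matrix `A | A11*` whose marginal covariance over group one is
#' `A11*` while the conditional (co)variance of group two given group
#' one is unchanged.  The construction adds the increment
#' `E = (A11*)^-1 - (A11)^-1` to the group-one block of the precision
#' matrix `A^-1` and inverts back; all inversions use Cholesky
#' factorizations, so A, A11 and A11* must be symmetric positive
#' definite (a failed factorization is an error).
#'
#' @param A a [RelationshipMatrix] (or SPD matrix).
#' @param group1 character vector of ids (or integer indices) forming
#'   group one.
#' @param A11star SPD replacement matrix for the group-one block, in
#'   `group1` order.
#' @return a [RelationshipMatrix] of kind "conditioned", in the
#'   original id order.
#' @export
conditionMatrix <- function(A, group1, A11star) {
  Av <- if (is(A, "RelationshipMatrix")) A@values else as.matrix(A)
  ids <- rownames(Av)
  if (is.numeric(group1)) group1 <- ids[group1]
  if (!all(group1 %in% ids))
    stop("group-one ids not in the matrix: ",
         paste(setdiff(group1, ids), collapse = ", "))
  A11star <- as.matrix(A11star)
  if (!all(dim(A11star) == length(group1)))
    stop("replacement block must be ", length(group1), " x ",
         length(group1))
  if (max(abs(A11star - t(A11star))) > 1e-8)
    stop("replacement block must be symmetric")
  cholInv <- function(M, what) {
    ch <- tryCatch(chol(M), error = function(e)
      stop(what, " is not symmetric positive definite: ",
           conditionMessage(e), call. = FALSE))
    chol2inv(ch)
  }
  g1 <- match(group1, ids)
  P <- cholInv(Av, "A")
  E <- cholInv(A11star, "A11*") - cholInv(Av[g1, g1, drop = FALSE], "A11")
  P[g1, g1] <- P[g1, g1] + E
  out <- cholInv((P + t(P)) / 2, "the conditioned precision matrix")
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(Av)
  RelationshipMatrix(out, kind = "conditioned")
}

#' Consistency of a realized measure with the pedigree expectation
#'
#' Repeatedly samples a random group one of `group1Size` individuals,
#' forms `A | X11` (the pedigree matrix with the group-one block
#' replaced by the realized measure) and compares its group-two block
#' with the realized `X22` over the off-diagonals using
#' [compareMatrices()].  If the realized measure is consistent with the
#' pedigree expectation, the adjusted values `(A|X11)22` track `X22`
#' closely (no-intercept slope near 1).
#'
#' @param A pedigree [RelationshipMatrix].
#' @param X realized [RelationshipMatrix] over the same individuals in
#'   the same order.
#' @param group1Size number of individuals sampled into group one
#'   (`< N`).
#' @param replicates number of random group-one draws.
#' @param seed integer seed; results are reproducible given the seed.
#' @return data.frame with one row per replicate: `msd`,
#'   `adjR2NoIntercept`, `adjR2WithIntercept`, `slopeNoIntercept`.
#' @export
consistencyCheck <- function(A, X, group1Size, replicates = 10L, seed) {
  Av <- if (is(A, "RelationshipMatrix")) A@values else as.matrix(A)
  Xv <- if (is(X, "RelationshipMatrix")) X@values else as.matrix(X)
  if (!identical(dim(Av), dim(Xv)) ||
      !identical(rownames(Av), rownames(Xv)))
    stop("A and X must be over the same individuals in the same order")
  n <- nrow(Av)
  if (group1Size >= n) stop("group1Size must be smaller than N = ", n)
  set.seed(seed)
  out <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    g1 <- sort(sample.int(n, group1Size))
    g2 <- setdiff(seq_len(n), g1)
    cond <- conditionMatrix(Av, rownames(Av)[g1],
                            Xv[g1, g1, drop = FALSE])
    st <- compareMatrices(Xv[g2, g2, drop = FALSE],
                          as.matrix(cond)[g2, g2, drop = FALSE])
    out[[r]] <- data.frame(replicate = r, msd = st$msd,
                           adjR2NoIntercept = st$adjR2NoIntercept,
                           adjR2WithIntercept = st$adjR2WithIntercept,
                           slopeNoIntercept = st$slopeNoIntercept)
  }
  do.call(rbind, out)
}
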