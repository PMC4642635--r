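## Pedigree handling and the numerator relationship matrix A.

#' Construct a pedigree
#'
#' Records are individual / sire / dam triples; unknown parents may be
#' coded `NA`, `"0"` or `""`.  Every named parent must itself appear as
#' an individual.  A topological order with parents before offspring is
#' computed by Kahn's algorithm with ties broken by input order; a
#' cycle (an individual being its own ancestor) is an error naming the
#' individuals involved.
#'
#' @param id,sire,dam character vectors of equal length.
#' @return a [Pedigree].
#' @export
Pedigree <- function(id, sire, dam) {
  id <- as.character(id)
  clean <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & (x == "0" | x == "")] <- NA_character_
    x
  }
  sire <- clean(sire); dam <- clean(dam)
  n <- length(id)
  si <- match(sire, id); di <- match(dam, id)
  ## Kahn's algorithm; queue kept in input order for determinism
  indeg <- integer(n)
  children <- vector("list", n)
  for (k in seq_len(n)) {
    for (pi in c(si[k], di[k])) {
      if (!is.na(pi)) {
        indeg[k] <- indeg[k] + 1L
        children[[pi]] <- c(children[[pi]], k)
      }
    }
  }
  order <- integer(0)
  ready <- which(indeg == 0L)
  while (length(ready)) {
    k <- ready[1L]; ready <- ready[-1L]
    order <- c(order, k)
    for (ch in children[[k]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- sort(c(ready, ch))
    }
  }
  if (length(order) < n)
    stop("pedigree contains a cycle involving: ",
         paste(id[setdiff(seq_len(n), order)], collapse = ", "))
  new("Pedigree", id = id, sire = sire, dam = dam, order = order)
}

#' @rdname individualIds
#' @export
setMethod("individualIds", "Pedigree", function(x) x@id)

#' @rdname topoOrder
#' @export
setMethod("topoOrder", "Pedigree", function(x) x@order)

#' @export
setMethod("show", "Pedigree", function(object) {
  founders <- sum(is.na(object@sire) & is.na(object@dam))
  cat("Pedigree with", length(object@id), "individuals (",
      founders, "founders )\n")
})

#' @export
setMethod("length", "Pedigree", function(x) length(x@id))

#' Read / write a pedigree TSV
#'
#' Three columns `id<TAB>sire<TAB>dam`; unknown parents coded 0, NA or
#' empty.  A header row is detected when the first row reads
#' id/sire/dam (case-insensitive).
#'
#' @param path file path.
#' @return `readPedigree` returns a [Pedigree].
#' @export
readPedigree <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "character", na.strings = c("NA", ""))
  if (ncol(d) < 3L) stop("pedigree file ", path, " needs 3 columns")
  if (nrow(d) && all(tolower(unlist(d[1L, 1:3])) == c("id", "sire", "dam")))
    d <- d[-1L, , drop = FALSE]
  Pedigree(d[[1L]], d[[2L]], d[[3L]])
}

#' @rdname readPedigree
#' @param ped a [Pedigree].
#' @export
writePedigree <- function(ped, path) {
  enc <- function(x) ifelse(is.na(x), "0", x)
  utils::write.table(
    data.frame(id = ped@id, sire = enc(ped@sire), dam = enc(ped@dam)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Pedigree numerator relationship matrix A
#'
#' The recursive tabular method in topological order: for individual k
#' with parents i and j, `a_kk = 1 + a_ij / 2` and
#' `a_kh = (a_ih + a_jh) / 2` for previously processed h, an unknown
#' parent contributing 0.  Founders are assumed unrelated and
#' non-inbred, so `a_ii = 1 + theta_i` (inbreeding on the diagonal) and
#' `a_ij = 2 theta_ij` (twice the coefficient of coancestry) off it.
#'
#' @param ped a [Pedigree].
#' @return a [RelationshipMatrix] of kind "A", in the input id order.
#' @export
numeratorMatrix <- function(ped)
  .pedigreeRecursion(ped, NULL, NULL, kind = "A")

## Shared engine for A and the hybrid expected/realized matrix R:
## entries with both individuals in S keep the supplied realized values,
## everything else is filled by the tabular recursion.
.pedigreeRecursion <- function(ped, S, realized, kind) {
  n <- length(ped@id)
  ord <- ped@order
  si <- match(ped@sire, ped@id)
  di <- match(ped@dam, ped@id)
  inS <- if (is.null(S)) rep(FALSE, n) else ped@id %in% S
  R <- matrix(0, n, n, dimnames = list(ped@id, ped@id))
  if (any(inS)) {
    sIds <- ped@id[inS]
    R[sIds, sIds] <- realized[sIds, sIds]
  }
  done <- integer(0)
  for (k in ord) {
    i <- si[k]; j <- di[k]
    for (h in done) {
      if (!(inS[h] && inS[k])) {
        rih <- if (is.na(i)) 0 else R[i, h]
        rjh <- if (is.na(j)) 0 else R[j, h]
        R[h, k] <- R[k, h] <- (rih + rjh) / 2
      }
    }
    if (!inS[k]) {
      rij <- if (is.na(i) || is.na(j)) 0 else R[i, j]
      R[k, k] <- 1 + rij / 2
    }
    done <- c(done, k)
  }
  RelationshipMatrix(R, kind = kind)
}

#' Hybrid expected/realized relationship matrix R
#'
#' For a genotyped subset S of the pedigree, entries among S are set to
#' the realized genomic relatedness `c_ij`, and all remaining entries
#' are filled by the numerator-matrix recursion in topological order
#' (`r_kk = 1 + r_ij/2`, `r_hk = (r_ih + r_jh)/2`, unknown parents
#' contributing 0).  The recursion thereby propagates the realized
#' values downstream of S.  With `S` empty the result is A; with S
#' covering the whole pedigree it is `realized` itself.
#'
#' @param ped a [Pedigree].
#' @param S character vector of genotyped individual ids (subset of the
#'   pedigree).
#' @param realized [RelationshipMatrix] (or matrix) of realized
#'   relatedness whose row/column names cover S.
#' @return a [RelationshipMatrix] of kind "R".
#' @export
hybridMatrix <- function(ped, S, realized = NULL) {
  S <- as.character(S)
  if (!all(S %in% ped@id))
    stop("genotyped individuals not in the pedigree: ",
         paste(setdiff(S, ped@id), collapse = ", "))
  if (length(S) == 0L) return(.pedigreeRecursion(ped, NULL, NULL, "R"))
  rv <- if (is(realized, "RelationshipMatrix")) realized@values else
    as.matrix(realized)
  if (!all(S %in% rownames(rv)))
    stop("realized matrix does not cover all genotyped individuals")
  .pedigreeRecursion(ped, S, rv, "R")
}

#' Pedigree graph distance
#'
#' Length of the shortest path between two individuals in the
#' undirected parent-child graph of the pedigree: parent-offspring
#' pairs are at distance one, full and half sibs at distance two, first
#' cousins at four, second cousins at six.  Unreachable pairs get
#' `Inf`.
#'
#' @param ped a [Pedigree].
#' @param ids optional character vector restricting the result; default
#'   all individuals.
#' @return symmetric numeric matrix of distances.
#' @export
pedigreeDistance <- function(ped, ids = NULL) {
  if (is.null(ids)) ids <- ped@id
  if (!all(ids %in% ped@id))
    stop("unknown individual(s): ", paste(setdiff(ids, ped@id), collapse = ", "))
  keep <- !is.na(ped@sire) | !is.na(ped@dam)
  from <- c(ped@id[!is.na(ped@sire)], ped@id[!is.na(ped@dam)])
  to <- c(ped@sire[!is.na(ped@sire)], ped@dam[!is.na(ped@dam)])
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to),
    directed = FALSE,
    vertices = data.frame(name = ped@id))
  d <- igraph::distances(g, v = ids, to = ids)
  d[ids, ids, drop = FALSE]
}
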