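## APFA construction, validation, probabilities and file formats.
##
## Canonical form: edges ordered by (level, source, target, allele);
## segment ids are "L{level}E{ordinal}" with the ordinal counted within
## the level, so a model read twice (or written and re-read) gets
## identical ids.

#' Construct an APFA from an edge table
#'
#' Edges are brought into canonical order (level, source, target,
#' allele).  When `ids` is NULL, deterministic segment ids of the form
#' `"L{level}E{ordinal}"` are generated.  Parallel edges with identical
#' (level, source, target, allele) are collapsed by summing their
#' probabilities/counts: the edge *is* the segment, so duplicates can
#' only be a file artifact.
#'
#' @param level integer vector of 0-based interval indices.
#' @param source,target character vectors of vertex ids.
#' @param allele character vector of allele symbols.
#' @param prob numeric vector of transition probabilities (or counts to
#'   be normalized by the caller).
#' @param ids optional character vector of segment ids; kept as given
#'   (but reordered canonically) when supplied.
#' @return an [Apfa].
#' @export
Apfa <- function(level, source, target, allele, prob, ids = NULL) {
  ed <- data.frame(level = as.integer(level), source = as.character(source),
                   target = as.character(target), allele = as.character(allele),
                   prob = as.numeric(prob), stringsAsFactors = FALSE)
  if (nrow(ed) == 0L) stop("an APFA needs at least one edge")
  key <- paste(ed$level, ed$source, ed$target, ed$allele, sep = "\r")
  if (anyDuplicated(key)) {
    prob <- vapply(split(ed$prob, key), sum, numeric(1))
    ed <- ed[!duplicated(key), , drop = FALSE]
    ed$prob <- prob[paste(ed$level, ed$source, ed$target, ed$allele, sep = "\r")]
    if (!is.null(ids)) ids <- NULL  # collapsed: regenerate
  }
  o <- order(ed$level, ed$source, ed$target, ed$allele, method = "radix")
  ed <- ed[o, , drop = FALSE]
  if (is.null(ids)) {
    ord <- stats::ave(ed$level, ed$level, FUN = seq_along) - 1L
    ed$id <- sprintf("L%dE%d", ed$level, ord)
  } else {
    ed$id <- as.character(ids)[o]
  }
  rownames(ed) <- NULL
  p <- max(ed$level) + 1L
  new("Apfa", p = p, edges = ed[c("id", "level", "source", "target",
                                  "allele", "prob")])
}

#' @rdname nIntervals
#' @export
setMethod("nIntervals", "Apfa", function(x) x@p)

#' @rdname apfaEdges
#' @export
setMethod("apfaEdges", "Apfa", function(x) x@edges)

#' @export
setMethod("show", "Apfa", function(object) {
  ed <- object@edges
  cat("Apfa with", object@p, "intervals,",
      length(unique(c(ed$source, ed$target))), "vertices,",
      nrow(ed), "edges (segments)\n")
  cat("alleles:", paste(sort(unique(ed$allele)), collapse = " "), "\n")
})

## vertex -> level map implied by the edges; inconsistent vertices get NA
.vertexLevels <- function(ed) {
  lev <- c(stats::setNames(ed$level, ed$source),
           stats::setNames(ed$level + 1L, ed$target))
  out <- tapply(lev, names(lev), function(v) {
    u <- unique(v)
    if (length(u) == 1L) u else NA_integer_
  })
  stats::setNames(as.integer(out), names(out))
}

#' Validate the structure of an APFA
#'
#' Checks the leveling (every edge connects level k to level k+1 and
#' every vertex has a single consistent level), the existence of a
#' single root (level 0) and a single sink (level p), probability
#' normalization of the outgoing edges of every non-sink vertex
#' (tolerance 1e-9), that every vertex lies on a root-to-sink path, and
#' uniqueness of edge ids.  Violations are reported as diagnostics, not
#' raised as errors, so that probability-free (purely combinatorial)
#' operations can still run on models failing only the normalization
#' checks.
#'
#' @param apfa an [Apfa].
#' @return character vector of diagnostics; empty iff all invariants hold.
#' @export
validateApfa <- function(apfa) {
  ed <- apfa@edges
  out <- character()
  if (anyDuplicated(ed$id))
    out <- c(out, paste0("duplicated edge ids: ",
                         paste(unique(ed$id[duplicated(ed$id)]), collapse = ", ")))
  bad <- ed$prob < 0 | ed$prob > 1 | is.na(ed$prob)
  if (any(bad))
    out <- c(out, paste0("edge ", ed$id[bad],
                         ": probability outside [0,1] (", ed$prob[bad], ")"))
  vl <- .vertexLevels(ed)
  inc <- names(vl)[is.na(vl)]
  if (length(inc))
    out <- c(out, paste0("vertex ", inc,
                         ": inconsistent level (edge skips a level or level mismatch)"))
  roots <- names(vl)[!is.na(vl) & vl == 0L]
  sinks <- names(vl)[!is.na(vl) & vl == apfa@p]
  if (length(roots) != 1L)
    out <- c(out, paste0("expected a single root at level 0, found ",
                         length(roots)))
  if (length(sinks) != 1L)
    out <- c(out, paste0("expected a single sink at level ", apfa@p,
                         ", found ", length(sinks)))
  missing_lev <- setdiff(0:(apfa@p - 1L), unique(ed$level))
  if (length(missing_lev))
    out <- c(out, paste0("no edges at level ", missing_lev))
  ## outgoing probability normalization per non-sink vertex
  s <- vapply(split(ed$prob, ed$source), sum, numeric(1))
  off <- abs(s - 1) > 1e-9
  if (any(off))
    out <- c(out, paste0("vertex ", names(s)[off],
                         ": outgoing probabilities sum to ",
                         format(s[off], digits = 12), ", not 1"))
  ## reachability: forward from root, backward from sink
  if (length(roots) == 1L && length(sinks) == 1L && !length(inc)) {
    fwd <- roots
    repeat {
      nxt <- unique(c(fwd, ed$target[ed$source %in% fwd]))
      if (length(nxt) == length(fwd)) break
      fwd <- nxt
    }
    bwd <- sinks
    repeat {
      nxt <- unique(c(bwd, ed$source[ed$target %in% bwd]))
      if (length(nxt) == length(bwd)) break
      bwd <- nxt
    }
    orphan <- setdiff(names(vl), intersect(fwd, bwd))
    if (length(orphan))
      out <- c(out, paste0("vertex ", orphan,
                           ": not on any root-to-sink path"))
  }
  out
}

.stopIfNotNormalized <- function(apfa) {
  s <- vapply(split(apfa@edges$prob, apfa@edges$source), sum, numeric(1))
  if (any(abs(s - 1) > 1e-9))
    stop("APFA edge probabilities are not normalized; ",
         "this operation needs a valid probability model")
  invisible(apfa)
}

.rootVertex <- function(apfa) {
  vl <- .vertexLevels(apfa@edges)
  names(vl)[!is.na(vl) & vl == 0L][1L]
}

#' Probability of a haplotype path
#'
#' The probability of a haplotype under the APFA is the product of the
#' probabilities of the edges in its root-to-sink path.
#'
#' @param apfa an [Apfa] with normalized edge probabilities.
#' @param path character vector of edge ids, one per level `0..p-1`,
#'   consecutive edges sharing the intermediate vertex.
#' @return numeric probability in \[0, 1\].
#' @export
haplotypeProbability <- function(apfa, path) {
  ed <- apfa@edges
  i <- match(path, ed$id)
  if (anyNA(i))
    stop("unknown edge id(s): ", paste(path[is.na(i)], collapse = ", "))
  if (length(path) != apfa@p)
    stop("path has ", length(path), " edges but the APFA has ", apfa@p,
         " levels")
  if (!all(ed$level[i] == seq_len(apfa@p) - 1L))
    stop("invalid path: edges are not one per level in order")
  if (apfa@p > 1L &&
      !all(ed$target[i[-apfa@p]] == ed$source[i[-1L]]))
    stop("invalid path: consecutive edges do not share a vertex")
  prod(ed$prob[i])
}

#' Enumerate all root-to-sink paths
#'
#' Exhaustive enumeration; intended for small models (tests, oracles).
#'
#' @param apfa an [Apfa].
#' @return list of character vectors of edge ids.
#' @export
enumeratePaths <- function(apfa) {
  ed <- apfa@edges
  root <- .rootVertex(apfa)
  grow <- function(vertex, level) {
    if (level == apfa@p) return(list(character()))
    idx <- which(ed$source == vertex & ed$level == level)
    out <- list()
    for (i in idx) {
      for (tail in grow(ed$target[i], level + 1L))
        out[[length(out) + 1L]] <- c(ed$id[i], tail)
    }
    out
  }
  grow(root, 0L)
}

#' Build a prefix-tree APFA from training haplotypes
#'
#' A minimal segmentation model: one vertex per distinct allele prefix,
#' merged into a single sink at level p.  The probability of an edge is
#' the fraction of training haplotypes passing through its source vertex
#' that take the edge, so every training haplotype has positive
#' probability under the model (its own empirical frequency when all
#' haplotypes separate at level 0).
#'
#' @param haplotypes a character matrix (rows = haplotypes, columns =
#'   markers) or a list of equal-length character vectors of allele
#'   symbols.
#' @return an [Apfa].
#' @export
buildTrieApfa <- function(haplotypes) {
  if (is.list(haplotypes)) {
    if (length(haplotypes) == 0L) stop("no haplotypes supplied")
    len <- lengths(haplotypes)
    if (length(unique(len)) != 1L)
      stop("ragged input: haplotype lengths ",
           paste(unique(len), collapse = ", "))
    haplotypes <- do.call(rbind, lapply(haplotypes, as.character))
  }
  haplotypes <- as.matrix(haplotypes)
  if (nrow(haplotypes) == 0L || ncol(haplotypes) == 0L)
    stop("no haplotypes supplied")
  mode(haplotypes) <- "character"
  p <- ncol(haplotypes)
  n <- nrow(haplotypes)
  ## prefix string per haplotype and level; the "^" sentinel keeps the
  ## root prefix a non-empty (indexable) name
  prefix <- vector("list", p + 1L)
  prefix[[1L]] <- rep("^", n)
  for (k in seq_len(p))
    prefix[[k + 1L]] <- paste(prefix[[k]], haplotypes[, k], sep = "\x01")
  ## vertex id per distinct prefix at each level; single sink at level p
  vertexOf <- function(k) {
    u <- sort(unique(prefix[[k + 1L]]))
    stats::setNames(sprintf("V%d.%d", k, seq_along(u) - 1L), u)
  }
  lev <- src <- tgt <- al <- prb <- list()
  vsrc <- c(stats::setNames("V0.0", "^"))
  for (k in seq_len(p)) {
    vtgt <- if (k < p) vertexOf(k) else
      stats::setNames(sprintf("V%d.0", p), NA)
    pair <- paste(prefix[[k]], haplotypes[, k], sep = "\x01")
    keep <- !duplicated(pair)
    cntEdge <- table(pair)[pair[keep]]
    cntSrc <- table(prefix[[k]])[prefix[[k]][keep]]
    lev[[k]] <- rep(k - 1L, sum(keep))
    src[[k]] <- unname(vsrc[prefix[[k]][keep]])
    tgt[[k]] <- if (k < p) unname(vtgt[prefix[[k + 1L]][keep]]) else
      rep(sprintf("V%d.0", p), sum(keep))
    al[[k]] <- haplotypes[keep, k]
    prb[[k]] <- as.numeric(cntEdge) / as.numeric(cntSrc)
    if (k < p) vsrc <- vtgt
  }
  Apfa(level = unlist(lev), source = unlist(src), target = unlist(tgt),
       allele = unlist(al), prob = unlist(prb))
}

#' Read / write the native APFA TSV format
#'
#' One edge per row with header
#' `level<TAB>source<TAB>target<TAB>allele<TAB>prob`.  Writing uses
#' canonical edge order and 17 significant digits, so
#' `readApfa(writeApfa(x))` reproduces `x` exactly (segment ids are
#' regenerated canonically and therefore stable).
#'
#' @param path file path.
#' @return `readApfa` returns an [Apfa]; `writeApfa` returns `path`
#'   invisibly.
#' @export
readApfa <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("APFA file ", path, " has no edge rows")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  need <- c("level", "source", "target", "allele", "prob")
  if (!all(need %in% header))
    stop("APFA file ", path, ": missing column(s) ",
         paste(setdiff(need, header), collapse = ", "))
  ix <- match(need, header)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf < length(header))) {
    bad <- which(nf < length(header))[1L]
    stop("APFA file ", path, " line ", bad + 1L, ": expected ",
         length(header), " fields, found ", nf[bad])
  }
  f <- function(j) vapply(rows, `[`, "", ix[j])
  prob <- suppressWarnings(as.numeric(f(5L)))
  if (anyNA(prob)) {
    bad <- which(is.na(prob))[1L]
    stop("APFA file ", path, " line ", bad + 1L,
         ": non-numeric prob \"", f(5L)[bad], "\"")
  }
  level <- suppressWarnings(as.integer(f(1L)))
  if (anyNA(level)) {
    bad <- which(is.na(level))[1L]
    stop("APFA file ", path, " line ", bad + 1L,
         ": non-integer level \"", f(1L)[bad], "\"")
  }
  lev <- sort(unique(level))
  if (!identical(lev, seq(min(lev), max(lev))) || min(lev) != 0L)
    stop("APFA file ", path, ": levels have gaps or do not start at 0 (",
         paste(lev, collapse = ", "), ")")
  Apfa(level = level, source = f(2L), target = f(3L), allele = f(4L),
       prob = prob)
}

#' @rdname readApfa
#' @param apfa an [Apfa].
#' @export
writeApfa <- function(apfa, path) {
  ed <- apfa@edges
  out <- c(paste(c("level", "source", "target", "allele", "prob"),
                 collapse = "\t"),
           paste(ed$level, ed$source, ed$target, ed$allele,
                 sprintf("%.17g", ed$prob), sep = "\t"))
  writeLines(out, path)
  invisible(path)
}

#' Read a Beagle-3-style DAG file
#'
#' Whitespace-delimited dialect: lines beginning with `#` are comments;
#' data rows give `level parent child allele count`.  Edge identity is
#' (level, parent, child, allele); duplicate rows have their counts
#' summed.  Counts are converted to probabilities by normalizing over
#' the outgoing edges of each parent node within each level.
#'
#' @param path file path.
#' @return an [Apfa] that passes [validateApfa()].
#' @export
readBeagleDag <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  rows <- strsplit(trimws(lines[keep]), "\\s+")
  if (length(rows) == 0L) stop("Beagle DAG file ", path,
                               ": no data rows (empty model)")
  lineno <- which(keep)
  nf <- lengths(rows)
  if (any(nf != 5L)) {
    bad <- which(nf != 5L)[1L]
    stop("Beagle DAG file ", path, " line ", lineno[bad],
         ": expected 5 whitespace-delimited fields, found ", nf[bad])
  }
  f <- function(j) vapply(rows, `[`, "", j)
  level <- suppressWarnings(as.integer(f(1L)))
  count <- suppressWarnings(as.numeric(f(5L)))
  if (anyNA(level) || anyNA(count)) {
    bad <- which(is.na(level) | is.na(count))[1L]
    stop("Beagle DAG file ", path, " line ", lineno[bad],
         ": malformed row")
  }
  if (any(count < 0))
    stop("Beagle DAG file ", path, ": negative counts")
  ## vertex ids must be globally unique, Beagle node labels are per level
  src <- paste0("N", level, ".", f(2L))
  tgt <- paste0("N", level + 1L, ".", f(3L))
  ## collapse duplicates, then normalize per source vertex
  key <- paste(level, src, tgt, f(4L), sep = "\r")
  agg <- vapply(split(count, key), sum, numeric(1))
  first <- !duplicated(key)
  level <- level[first]; src <- src[first]; tgt <- tgt[first]
  allele <- f(4L)[first]
  count <- unname(agg[paste(level, src, tgt, allele, sep = "\r")])
  tot <- vapply(split(count, src), sum, numeric(1))
  if (any(tot <= 0))
    stop("Beagle DAG file ", path, ": zero total count at node(s) ",
         paste(names(tot)[tot <= 0], collapse = ", "))
  prob <- count / tot[src]
  apfa <- Apfa(level = level, source = src, target = tgt, allele = allele,
               prob = prob)
  diag <- validateApfa(apfa)
  if (length(diag))
    stop("Beagle DAG file ", path, " yields an invalid APFA:\n  ",
         paste(diag, collapse = "\n  "))
  apfa
}

#' Sample a root-to-sink haplotype path
#'
#' Draws a path by walking from the root, choosing each outgoing edge
#' with its transition probability.  Uses R's current RNG stream.
#'
#' @param apfa an [Apfa] with normalized probabilities.
#' @return character vector of edge ids (length p).
#' @export
sampleHaplotypePath <- function(apfa) {
  .stopIfNotNormalized(apfa)
  ed <- apfa@edges
  path <- character(apfa@p)
  vertex <- .rootVertex(apfa)
  for (k in seq_len(apfa@p)) {
    idx <- which(ed$source == vertex & ed$level == k - 1L)
    i <- if (length(idx) == 1L) idx else
      idx[sample.int(length(idx), 1L, prob = ed$prob[idx])]
    path[k] <- ed$id[i]
    vertex <- ed$target[i]
  }
  path
}
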